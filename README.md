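# qsevo — quaternary-structure variability across protein orthogroups

Homologous enzymes with the same catalytic function often adopt different
quaternary structures (QS) in different species, a pattern usually read as
evidence that homomer evolution is largely stochastic.  Moonlighting
(multifunctional) proteins offer a sharp test: if QS carries non-canonical
function, protein families containing moonlighting proteins (moonlighting
orthogroups, MOs) should show *more* QS variability than families without
them; if QS evolution is stochastic, the two groups should look alike even
when their functional annotation differs.

`qsevo` implements that comparison as a tested, reusable R pipeline for
structural bioinformaticians and molecular evolution researchers:

* **Interfaces** — classify residues as interface / surface / buried from
  per-residue SASA tables (FreeSASA-style output): interface iff monomeric
  RSA ≥ 0.2 and ≥ 10% of monomeric SASA buried on complexation; interface
  area = (ΣSASA_monomers − SASA_complex) / n_subunits.
* **Topologies** — interface overlap between aligned homomers
  (aligned interface–interface pairs / smaller interface); same-count
  structures with overlap < 0.5 are different topologies; classes form by
  single-linkage within subunit-count strata.
* **Diversity** — four orthogroup metrics: mean subunit count, topology
  count, Shannon index −Σ pᵢ ln pᵢ over topology frequencies, and mean
  number of distinct QSs per protein.
* **Phylogenetics** — cophenetic outlier exclusion (mean + 3 SD), minimal
  ancestor deviation rooting, ancestral QS reconstruction by equal-rates
  Mk maximum likelihood (Felsenstein pruning, marginal probabilities,
  51%-resolution rule) and by ACCTRAN parsimony, and QS change rates
  (changed parent–child pairs / usable pairs, split into gains, losses and
  lateral changes) stratified by homomer/monomer root.
* **Annotations** — OBO ontology reader, removal of hierarchically
  redundant terms (only the most specific term of an ancestor–descendant
  pair is kept), evidence-code subsets, annotation-richness comparisons.
* **Statistics** — two-sided Wilcoxon rank-sum (exact where applicable),
  continuity-corrected tests of proportions with Wilson 95% CIs, ANCOVA
  and Spearman partial correlation with orthogroup size as covariate, and
  one study-wide Benjamini–Hochberg pass over every p-value of a run.
* **Synthetic data** — a seeded generator for every input (Yule trees, QS
  characters evolved on a 1–2–4–8 gain/loss ladder, toy complexes with
  planted interfaces, random ontology DAGs, two-arm study bundles with
  controllable effect sizes), so the whole pipeline runs offline with
  known ground truth.

## Worked example

Generate a synthetic two-arm study (12 orthogroups per arm, default
conditions: no MO effect on QS transition rates, 1.5× MO annotation
enrichment) and run the full pipeline:

```r
library(qsevo)
bundle <- gen_study(sim_config(seed = 42, n_orthogroups = 12))
report <- run_study(bundle)
report
#> QS study report
#>   proteins kept: 398  excluded: 0
#>   orthogroups measured: 24
#>   trees analysed: 24 ( 16 homomer-root, 4 monomer-root, 4 unresolved )
#>   comparisons: 23  ( 1 adjusted-significant at 0.05 )

cmp <- report$comparisons
cmp[cmp$test %in% c("change_rate_total_all", "metric_shannon", "richness_GO-MF"),
    c("test", "statistic", "p_raw", "p_adj", "effect")]
#>                  test statistic    p_raw   p_adj effect
#> change_rate_total_all      74.5 9.08e-01 1.00000 0.0165
#>        metric_shannon      94.0 2.14e-01 0.61981 0.1660
#>        richness_GO-MF     140.0 9.73e-05 0.00224 2.4466
```

The report reads exactly like the underlying science: under the
generator's null the MO vs non-MO QS change-rate comparison is flat
(median difference 0.0165, adjusted p = 1) and the Shannon-index contrast
is unremarkable, while the planted annotation enrichment is detected
(MOs average ~2.4 more filtered GO terms per protein,
adjusted p = 0.0022).  `effect` is the difference of medians for rank-sum
rows, the group coefficient for ANCOVA rows, and the partial rho for
Spearman rows; `p_adj` comes from the single Benjamini–Hochberg pass over
all 23 p-values of the run.

Individual stages are plain functions on plain tables — e.g.
`classify_residues()` on a SASA data frame, `mad_root()` on an `ape::phylo`
tree, `fit_er_asr()` / `acctran_asr()` for ancestral states,
`filter_redundant_terms()` on term sets — see the package vignette for the
models, defaults and numerical choices.

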