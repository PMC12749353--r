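---
title: "Quaternary-structure variability across orthogroups: models and methods"
author: "qsevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quaternary-structure variability across orthogroups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Homologous enzymes with the same catalytic function often have different
quaternary structures (QS) in different species — a pattern read as evidence
that homomer evolution is largely stochastic.  Multifunctional
("moonlighting") proteins complicate that reading: if the non-canonical
function of a protein depends on its oligomeric state, QS variability within
a family could be adaptive after all.  The discriminating observation is a
group comparison: orthogroups that contain moonlighting proteins (MOs)
versus orthogroups that do not (non-MOs).  Under stochastic QS evolution the
two groups should show similar QS variability even when their functional
annotation differs; under the adaptive account MOs should be more variable.

`qsevo` implements that comparison as a reusable pipeline: interface
detection from solvent accessibility, QS topology classification from
structural-alignment overlap, orthogroup diversity metrics, ancestral-state
reconstruction with change-rate statistics on rooted trees, ontology-aware
annotation richness, and the group-statistics battery with one study-wide
false-discovery-rate pass.  A synthetic-data generator produces every input
with known ground truth, so each stage — and the pipeline end to end — is
testable without any external database.

# Interface and surface residues

The raw material is a per-residue table of solvent-accessible surface area
(SASA, in square Angstroms) computed twice: for the residue in the assembled
complex and in the isolated monomeric subunit.  Computing SASA from
coordinates is out of scope (that is FreeSASA's job); the package consumes
its output.

Relative solvent accessibility is `RSA = SASA / max_area(residue type)`,
with the theoretical maxima of Tien et al. (2013) packaged as the reference
denominators.  A residue is an **interface** residue when

* its monomeric RSA is at least 0.2 (inclusive), and
* complexation buries at least 10% of its monomeric SASA
  (`(SASA_monomer - SASA_complex) / SASA_monomer >= 0.10`).

A residue that is not interface and has RSA strictly above 0.2 is
**surface**; everything else is **buried**.  Two numerical edge rules:
negative burial (complex SASA above monomer SASA, which occurs as numerical
noise) counts as zero burial, and a residue with zero monomeric SASA is
never an interface residue.

Two decisions here were genuinely open and are worth recording.  First, the
RSA gate is evaluated on the *monomeric* SASA by default
(`rsa_context = "monomer"`): a residue deeply buried by oligomerisation is
exactly the signal being sought, and gating on its complex-context RSA would
reject it.  The alternative context is available as a switch for
sensitivity analyses.  Second, the 10% burial criterion is relative to the
residue's monomeric SASA, not to its reference maximum area; the
relative-to-monomer reading makes the criterion scale-free per residue.

Interface area of a complex is the buried area per subunit,
`(sum of monomer SASA - complex SASA) / n_subunits`, clamped at zero.
Homomers with interfaces smaller than 1000 A^2 — a regime where
crystallographic artefacts are common — can be recounted as monomers with
`relabel_small_interfaces()` for sensitivity analyses.

# QS topologies and overlap

Two homomers share a QS topology when they have the same subunit count
*and* their interfaces overlap: the overlap is the number of structurally
aligned residue pairs with both ends in an interface, divided by the size of
the smaller interface.  Structures with equal subunit counts but overlap
below 0.5 are topologically different.

Pairwise overlap is not transitive, so forming topology *classes* requires a
clustering rule.  The package uses single-linkage connected components
within each subunit-count stratum: deterministic, order-independent, and as
close to the pairwise "different if overlap < 0.5" language as any
clustering can be.  The documented consequence is that a chain A–B–C with
overlaps 0.6, 0.6, 0.3 forms one class.  Class identifiers are the
lexicographically smallest member id.  A missing overlap between same-count
structures is conservatively treated as "different" (this inflates
diversity uniformly in both comparison arms); a flag flips it.

All monomers share one topology class — there is no interface to
distinguish them.

# Diversity metrics

Four orthogroup-level metrics, computed from one representative structure
per protein (except the fourth):

1. **Average subunit count**, monomers included.
2. **QS diversity** — the number of distinct topology classes.
3. **Shannon index** — `-sum p_i ln p_i` over topology-class frequencies.
   One monomer among nine dimers (0.325) scores below a five/five split
   (ln 2 = 0.693): the index weights classes by how common they are.
4. **QS per protein** — the number of distinct topologies among all
   deposited entries of each protein, averaged over the orthogroup.

Frequencies are computed over proteins, each counted once through its
representative structure.  Metrics are computable for any orthogroup but
group comparisons use orthogroups with at least three proteins
(`eligible` flag); the phylogenetic stage uses ten or more.

# Phylogenetic stage

**Tree hygiene.**  For each tip, the mean cophenetic distance to all other
tips is computed; tips above the grand mean plus three standard deviations
are excluded in a single pass.  A caveat worth knowing: with sample
standard deviation, a single outlier among `n` tips cannot exceed
`(n-1)/sqrt(n)` SDs, so the rule cannot fire for a lone outlier in trees of
ten or fewer tips — it targets gross outliers in reasonably sized trees.

**Rooting.**  Trees are rooted by minimal ancestor deviation: for a
candidate root position on a branch, every straddling tip pair `(b, c)`
would under a strict clock satisfy `d(root, b) = d(b, c) / 2`; the position
minimising the root-mean-square of `|2 d(root,b)/d(b,c) - 1|` over
straddling pairs is the root.  Within a branch the squared criterion is a
quadratic in the offset, so the per-branch minimiser is closed-form; the
global minimum over branches is taken, with ties broken by branch index
then offset.  The package's criterion scores straddling pairs; the original
formulation also includes same-side pairs, whose contribution does not
depend on the offset within a branch.  Tests verify the implementation
against a dense-grid scan.

**Ancestral states by ML.**  The QS character (topology-class label of the
tip protein) evolves under the equal-rates (ER) Mk model: all transitions
share one rate `r`, so `P(t)` has the closed form
`P_ij(t) = (1 - e^{-krt})/k` off the diagonal.  The likelihood is computed
by Felsenstein pruning with per-edge rescaling; `r` is estimated by
bracketed scalar maximisation (tolerance 1e-8) after a log-spaced grid
bracket.  The grid matters: on data generated by a gain/loss ladder the ER
likelihood can be bimodal, with a saturated optimum at very large `r`
(all transition probabilities `1/k`) that sometimes exceeds the interior
optimum, and a plain golden-section search over a wide interval can land on
the flat plateau.  Marginal node probabilities come from the standard
outside-pass (re-rooting) reconstruction with a uniform root prior — the
natural match to the symmetric ER model; an empirical-frequency prior is
available.  The state space is the set of states observed at the tips of
that tree: unobserved QS classes are not imputed.  A node is *resolved*
when its best marginal probability exceeds 0.51; trees whose root is
unresolved are excluded from root-type strata.  Zero-length branches are
floored at 1e-8 for the transition probabilities; multifurcations are
resolved deterministically left-to-right with zero-length branches.

**Ancestral states by parsimony.**  Fitch (unordered, equal-cost) parsimony
with ACCTRAN disambiguation: the root takes the first state of its
preliminary set, and each child keeps its parent's state whenever the
preliminary set allows, committing changes as close to the root as
possible.  The implied change count always equals the Fitch score, which
tests verify against exhaustive minimisation.

**Change rates.**  Over all parent–child pairs (tip edges included), a pair
is skipped when either endpoint is unresolved; among the used pairs, the
change rate is the fraction whose states differ.  Changes split into gains
(child has more subunits), losses (fewer), and lateral changes (same count,
different topology class), reported separately.  In ML mode the node state
is the argmax marginal with ties broken toward the parent, which avoids
manufacturing changes on exactly ambiguous nodes.  One subtlety feeds a
design choice in the validation: at high true rates the ML route saturates
(more nodes fall below the 0.51 threshold and drop out, and argmax
smoothing absorbs changes), so the monotonicity of the change-rate
statistic in the true simulation rate is checked on the parsimony
reconstruction, which is always fully resolved.

# Annotation richness

GO/Reactome-style ontologies are read from OBO files into a DAG over
`is_a` and `part_of` edges; edges crossing namespaces never enter ancestry,
and obsolete terms are dropped with a warning.  A protein's term set is
de-redundified by removing every term that is an ancestor of another term
in the set — of "mitochondrion" and "mitochondrial inner membrane" only the
latter survives.  The result is an antichain and the operation is
idempotent, both verified on random term sets.  Evidence-code subsets
(`drop_IEA`, `experimental_only` with the standard experimental +
high-throughput codes) support the GO-independence sensitivity analyses.
Richness of a protein group is the mean number of (filtered) terms per
protein, with unannotated proteins counted as zero.

# Statistics

All tests are two-sided.  Rank-sum comparisons use the exact null when the
smaller sample has at most eight observations and the pooled data are
tie-free, otherwise the normal approximation with continuity and tie
corrections.  Proportions are compared with the continuity-corrected
chi-square test, with Wilson 95% intervals per group (the interval type was
unstated in the design; Wilson behaves well at boundaries).  The
covariate-adjusted comparisons run both parametrically (OLS
`y ~ group + covariate`, t-test of the group coefficient, residual
diagnostics attached but never auto-remedied) and non-parametrically
(first-order Spearman partial correlation on ranks, t-approximation on
`n - 3` df).  Every p-value a run produces is collected and corrected
jointly with Benjamini–Hochberg at the end — one study-wide FDR pass, so
adding analyses to a run changes all adjusted values consistently.

# The synthetic-data generator

`gen_study()` emulates the statistical structure the analysis assumes,
with every random draw governed by one seed (identical configuration gives
an identical bundle):

* **Trees**: Yule (pure-birth) trees, by default 10–24 tips per orthogroup
  and birth rate 1; branch lengths are in the same arbitrary
  substitutions-per-site unit as the ER rate.  Pure birth rather than
  birth–death keeps the branch-length distribution simple; nothing
  downstream depends on extinction.
* **QS character**: a one-step gain/loss ladder over subunit counts
  1–2–4–8, simulated by exact event sampling along each branch.  Default
  gain rate 0.3 and loss rate 0.15 per unit branch length — gains twice as
  frequent as losses, mirroring the reported bias of subunit turnover
  toward gains; the root state is drawn uniformly.  `qs_effect` multiplies
  both rates in the MO arm and defaults to 1: *no* QS-rate difference
  between arms is the generator's null, matching the study design's
  central question.
* **Structures**: toy complexes as SASA tables with planted interfaces
  placed strictly beyond both classification thresholds (margin 0.02), and
  non-interface residues strictly below at least one; within an orthogroup,
  same-subunit-count structures share the planted set, so overlap-based
  topology assignment has signal.
* **Annotations**: a random `is_a`/`part_of` DAG; per-protein term counts
  negative-binomial (mean 4, dispersion 2 in the non-MO arm), with a 1.5x
  MO enrichment by default — the annotation contrast the study does report
  — and redundant ancestors injected with probability 0.5 so the
  de-redundancy filter has real work.
* **Records**: resolutions 1.2–2.9 A, coverages 0.85–1.0, lengths 120–600,
  i.e. all passing the quality filters (resolution strictly better than
  3 A, coverage strictly above 80%, length at least 100); the filter logic
  itself is unit-tested on hand-made boundary cases.

What the generator does *not* emulate: real PDB pathologies (wrong-biounit
assignments, heteromer contamination), sequence-level evolution (trees are
given, not inferred), correlation between annotation richness and QS, and
the long-tailed orthogroup-size distribution of real data.  Passing tests
therefore demonstrate correctness of the machinery and calibration of the
statistics under the stated generative model — not that any biological
conclusion transfers to a particular database snapshot.

# Validation sizes and numerical choices

The test suite validates each stage against an independent oracle:
exhaustive enumeration of joint ancestral assignments for the pruning
likelihood and marginals (200 trees, up to 6 tips and 3 states, tolerance
1e-8) and for parsimony scores (200 trees, up to 7 tips); a 1e-4 grid scan
for MAD rooting (100 eight-tip trees); complete enumeration of rank-sum
splits (all group sizes up to 6); and closed forms for the diversity
metrics.  Simulation checks: median ML rate within 15% of the true 0.5 on
200 sixty-four-tip trees; exact planted-interface recovery on 500 toy
complexes; type-I error of the comparison battery within [0.03, 0.07] over
2000 null studies; and the end-to-end null/effect contrast on 100 replicate
studies of 100 trees per arm with 32 tips each.  These sizes were chosen to
give stable verdicts at interactive runtimes; `scripts/acceptance.R` reruns
the headline quantities at reduced replication and writes them as JSON.

# Known limitations

* The ER model is symmetric; the generator's ladder is not (no direct
  1 -> 8 transitions, gain/loss asymmetry).  The ML stage is therefore a
  deliberately misspecified-but-standard estimator, exactly as in practice.
* Single-linkage topology classes can chain distinct interfaces together
  through intermediates.
* The rate search returns the global ER optimum; on weakly informative
  trees this can be the saturated solution, whose uniform marginals mark
  all nodes unresolved — such trees drop out of the change-rate strata
  rather than contributing noise.
* Phylogenetically independent contrasts, mixed models and
  all-rates-different Mk variants are out of scope.
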