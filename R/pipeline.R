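# End-to-end orchestration: record filtering, orthogroup grouping, the
# per-tree phylogenetic analysis, and the study-wide comparison table with
# a single joint Benjamini-Hochberg pass at the end.

#' Filter protein records on structure quality
#'
#' Keeps records with resolution strictly better than `resolution_max`
#' Angstroms, structure coverage strictly above `coverage_min` of the
#' sequence, and length at least `min_length` residues.  Every exclusion is
#' logged with its reason.
#'
#' @param records Data frame with columns `protein_id`, `resolution`,
#'   `coverage`, `length`.
#' @param resolution_max Exclusive upper bound on resolution (default 3.0).
#' @param coverage_min Exclusive lower bound on coverage (default 0.80).
#' @param min_length Inclusive minimum length (default 100).
#' @return List: `kept` (filtered data frame) and `excluded` (data frame
#'   with a `reason` column).
#' @export
filter_protein_records <- function(records, resolution_max = 3.0,
                                   coverage_min = 0.80, min_length = 100) {
  needed <- c("protein_id", "resolution", "coverage", "length")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  for (col in needed) {
    if (anyNA(records[[col]]))
      stop("missing ", col, " for record(s): ",
           paste(utils::head(records$protein_id[is.na(records[[col]])], 5),
                 collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(records))
  reason[records$length < min_length] <- "length below minimum"
  reason[records$coverage <= coverage_min] <- "coverage not above threshold"
  reason[records$resolution >= resolution_max] <- "resolution not better than threshold"
  keep <- is.na(reason)
  list(kept = records[keep, , drop = FALSE],
       excluded = cbind(records[!keep, , drop = FALSE],
                        reason = reason[!keep]))
}

#' Partition orthogroups into moonlighting and non-moonlighting groups
#'
#' An orthogroup is a moonlighting orthogroup (MO) when at least one member
#' is a known moonlighting protein.  Flags supported only by prediction can
#' be ignored (`use_predicted = FALSE`) for analyses that must stay
#' independent of GO-based prediction.
#'
#' @param members Data frame with columns `orthogroup_id`, `protein_id`.
#' @param moonlighting_ids Protein ids flagged as moonlighting.
#' @param predicted_ids Subset of `moonlighting_ids` whose only support is
#'   prediction.
#' @param use_predicted Count predicted-only flags (default `TRUE`).
#' @return Data frame `orthogroup_id`, `is_mo`; unmatched moonlighting ids
#'   are attached as the `unmatched` attribute.
#' @export
define_mo_groups <- function(members, moonlighting_ids,
                             predicted_ids = character(0),
                             use_predicted = TRUE) {
  ids <- moonlighting_ids
  if (!use_predicted) ids <- setdiff(ids, predicted_ids)
  unmatched <- setdiff(ids, members$protein_id)
  flagged <- members$protein_id %in% ids
  is_mo <- tapply(flagged, members$orthogroup_id, any)
  out <- data.frame(orthogroup_id = names(is_mo), is_mo = as.logical(is_mo),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "unmatched") <- unmatched
  out
}

#' Relabel homomers with small interfaces as monomers
#'
#' Sensitivity-analysis mode: homomers whose per-subunit interface area is
#' below `threshold` square Angstroms (a regime where crystallographic
#' artefacts are frequent) are counted among the monomers.
#'
#' @param proteins Data frame with columns `n_subunits` and
#'   `interface_area`.
#' @param threshold Area threshold in square Angstroms (default 1000,
#'   strict `<`).
#' @return The data frame with affected rows set to `n_subunits = 1` and a
#'   logical `relabeled` column.
#' @export
relabel_small_interfaces <- function(proteins, threshold = 1000) {
  if (is.null(proteins$interface_area))
    stop("interface_area column required")
  hit <- proteins$n_subunits > 1 & proteins$interface_area < threshold
  proteins$relabeled <- hit
  proteins$n_subunits[hit] <- 1L
  if (!is.null(proteins$topology_class))
    proteins$topology_class[hit] <- "1"
  proteins
}

#' Per-tree phylogenetic QS analysis
#'
#' Runs the ancestral-state stage on one orthogroup tree: optional
#' long-branch exclusion, ER-ML (or ACCTRAN) ancestral reconstruction of
#' the QS character, root typing and change-rate statistics.
#'
#' @param tree Rooted `ape::phylo`.
#' @param tip_states Named state vector for the tips.
#' @param state_subunits Named numeric vector, state -> subunit count.
#' @param method `"ML"` (default) or `"parsimony"`.
#' @param filter_k Outlier SD multiplier (`Inf` disables filtering).
#' @param min_tips Minimum tips after filtering (default 10).
#' @return One-row data frame of tree statistics, or `NULL` when the tree
#'   is too small.
#' @export
analyze_tree <- function(tree, tip_states, state_subunits,
                         method = c("ML", "parsimony"), filter_k = 3.0,
                         min_tips = 10) {
  method <- match.arg(method)
  if (is.finite(filter_k) && ape::Ntip(tree) >= 4) {
    fl <- filter_outliers(tree, filter_k)
    tree <- fl$tree
  }
  if (ape::Ntip(tree) < min_tips) return(NULL)
  ts <- tip_states[tree$tip.label]
  asr <- if (method == "ML") fit_er_asr(tree, ts) else acctran_asr(tree, ts)
  cr <- qs_change_rate(asr, state_subunits)
  data.frame(n_tips = ape::Ntip(tree),
             root_type = root_type(asr, state_subunits),
             rate = if (method == "ML") asr$rate else NA_real_,
             n_pairs_used = cr$n_pairs_used,
             rate_total = cr$rate_total, rate_gain = cr$rate_gain,
             rate_loss = cr$rate_loss, stringsAsFactors = FALSE)
}

# MO vs non-MO Wilcoxon comparisons of change rates, overall and within
# root-type strata (trees with unresolved roots are excluded from strata).
compare_change_rates <- function(tree_stats) {
  out <- list()
  cmp <- function(df, var, label) {
    x <- df[[var]][df$is_mo]; y <- df[[var]][!df$is_mo]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    wilcoxon_rank_sum(x, y, test = label)
  }
  strata <- list(all = tree_stats,
                 homomer_root = tree_stats[tree_stats$root_type == "homomer", ],
                 monomer_root = tree_stats[tree_stats$root_type == "monomer", ])
  for (s in names(strata)) {
    for (v in c("rate_total", "rate_gain", "rate_loss")) {
      r <- cmp(strata[[s]], v, paste("change", v, s, sep = "_"))
      if (!is.null(r)) out[[length(out) + 1L]] <- r
    }
  }
  do.call(rbind, out)
}

#' Run the full study on a synthetic or assembled input bundle
#'
#' Executes the pipeline end-to-end: record quality filtering, orthogroup
#' QS diversity metrics, per-tree ancestral reconstruction and change
#' rates stratified by root type, annotation richness, and the MO vs
#' non-MO comparison battery (Wilcoxon on every metric and change rate,
#' homomer-fraction test of proportions, ANCOVA and Spearman partial
#' correlation with orthogroup size as covariate), finishing with one
#' Benjamini-Hochberg pass over every p-value produced.
#'
#' @param bundle A `qs_study_bundle` from [gen_study()], or a directory
#'   written by [write_study_bundle()].
#' @param min_og_size Minimum orthogroup size for diversity comparisons
#'   (default 3).
#' @param min_tree_tips Minimum tips for the phylogenetic stage (default 10).
#' @param asr_method `"ML"` or `"parsimony"`.
#' @param filter_k Long-branch exclusion multiplier (default 3).
#' @return List of class `qs_study_report`: `filter` (kept/excluded),
#'   `metrics` (per-orthogroup diversity table), `tree_stats`,
#'   `comparisons` (test table with `p_raw` and study-wide `p_adj`),
#'   `richness` (per-arm annotation richness, if annotations present).
#' @export
run_study <- function(bundle, min_og_size = 3, min_tree_tips = 10,
                      asr_method = c("ML", "parsimony"), filter_k = 3.0) {
  asr_method <- match.arg(asr_method)
  if (is.character(bundle)) bundle <- read_study_bundle(bundle)
  states <- bundle$states
  state_subunits <- stats::setNames(states$n_subunits, states$state)

  flt <- filter_protein_records(bundle$proteins)
  prot <- flt$kept

  metrics <- orthogroup_metrics(prot, min_size = min_og_size)
  em <- metrics[metrics$eligible & !is.na(metrics$is_mo), , drop = FALSE]

  rows <- list()
  tree_stats <- list()
  for (og in names(bundle$trees)) {
    keep <- prot$protein_id[prot$orthogroup_id == og]
    tr <- bundle$trees[[og]]
    drop <- setdiff(tr$tip.label, keep)
    if (length(drop)) {
      if (ape::Ntip(tr) - length(drop) < 3) next
      tr <- ape::drop.tip(tr, drop)
    }
    st <- analyze_tree(tr, bundle$tip_states[[og]], state_subunits,
                       method = asr_method, filter_k = filter_k,
                       min_tips = min_tree_tips)
    if (is.null(st)) next
    st$orthogroup_id <- og
    st$is_mo <- bundle$truth[[og]]$is_mo
    tree_stats[[og]] <- st
  }
  tree_stats <- if (length(tree_stats)) do.call(rbind, tree_stats) else NULL

  # --- comparison battery ---
  if (!is.null(tree_stats) && any(tree_stats$is_mo) && any(!tree_stats$is_mo))
    rows[[length(rows) + 1L]] <- compare_change_rates(tree_stats)

  if (nrow(em) && any(em$is_mo) && any(!em$is_mo)) {
    for (v in c("avg_subunits", "qs_diversity", "shannon",
                "avg_qs_per_protein")) {
      if (anyNA(em[[v]])) next
      rows[[length(rows) + 1L]] <-
        wilcoxon_rank_sum(em[[v]][em$is_mo], em[[v]][!em$is_mo],
                          test = paste0("metric_", v))
      # covariate-adjusted tests are skipped when degenerate (e.g. all
      # orthogroups the same size)
      if (stats::var(em$n_proteins) > 0) {
        rows[[length(rows) + 1L]] <-
          ancova_group_effect(em[[v]], em$is_mo, em$n_proteins,
                              test = paste0("ancova_", v))
        rows[[length(rows) + 1L]] <-
          spearman_partial(em[[v]], as.numeric(em$is_mo), em$n_proteins,
                           test = paste0("spearman_", v))
      }
    }
    # fraction of orthogroups with a homomer majority
    maj <- tapply(prot$n_subunits > 1, prot$orthogroup_id, mean) > 0.5
    mo_of <- tapply(prot$is_mo, prot$orthogroup_id, any)
    ok <- names(maj)[names(maj) %in% em$orthogroup_id]
    k1 <- sum(maj[ok][mo_of[ok]]); n1 <- sum(mo_of[ok])
    k2 <- sum(maj[ok][!mo_of[ok]]); n2 <- sum(!mo_of[ok])
    if (n1 >= 1 && n2 >= 1)
      rows[[length(rows) + 1L]] <- prop_test_ci(k1, n1, k2, n2,
                                                test = "homomer_majority")
  }

  rich <- NULL
  if (!is.null(bundle$annotations)) {
    per_og <- lapply(split(prot, prot$orthogroup_id), function(m)
      data.frame(orthogroup_id = m$orthogroup_id[1], is_mo = any(m$is_mo),
                 richness = richness(bundle$annotations, m$protein_id,
                                     source = "GO-MF",
                                     dag = bundle$ontology)))
    rich <- do.call(rbind, per_og)
    rownames(rich) <- NULL
    if (any(rich$is_mo) && any(!rich$is_mo))
      rows[[length(rows) + 1L]] <-
        wilcoxon_rank_sum(rich$richness[rich$is_mo],
                          rich$richness[!rich$is_mo],
                          test = "richness_GO-MF")
  }

  comparisons <- if (length(rows)) finalize_results(rbind_stats(rows))
                 else NULL
  structure(list(filter = flt, metrics = metrics, tree_stats = tree_stats,
                 comparisons = comparisons, richness = rich),
            class = "qs_study_report")
}

#' @export
print.qs_study_report <- function(x, ...) {
  cat("QS study report\n")
  cat("  proteins kept:", nrow(x$filter$kept), " excluded:",
      nrow(x$filter$excluded), "\n")
  cat("  orthogroups measured:", nrow(x$metrics), "\n")
  if (!is.null(x$tree_stats))
    cat("  trees analysed:", nrow(x$tree_stats), "(",
        sum(x$tree_stats$root_type == "homomer"), "homomer-root,",
        sum(x$tree_stats$root_type == "monomer"), "monomer-root,",
        sum(x$tree_stats$root_type == "unresolved"), "unresolved )\n")
  if (!is.null(x$comparisons)) {
    cat("  comparisons:", nrow(x$comparisons), " (",
        sum(x$comparisons$p_adj < 0.05, na.rm = TRUE),
        "adjusted-significant at 0.05 )\n")
  }
  invisible(x)
}

#' Read a study bundle directory written by [write_study_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `qs_study_bundle` list (without ground-truth node states
#'   beyond what the manifest records).
#' @export
read_study_bundle <- function(dir) {
  proteins <- utils::read.delim(file.path(dir, "proteins.tsv"),
                                stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  states <- as.data.frame(manifest$states)
  tfiles <- list.files(file.path(dir, "trees"), pattern = "\\.nwk$",
                       full.names = TRUE)
  trees <- lapply(tfiles, read_newick)
  names(trees) <- sub("\\.nwk$", "", basename(tfiles))
  tip_states <- list(); truth <- list()
  for (og in names(trees)) {
    m <- proteins[proteins$orthogroup_id == og, ]
    tip_states[[og]] <- stats::setNames(as.character(m$topology_class),
                                        m$protein_id)
    truth[[og]] <- list(is_mo = as.logical(m$is_mo[1]),
                        root_state = manifest$root_states[[og]])
  }
  bundle <- list(proteins = proteins, trees = trees, tip_states = tip_states,
                 truth = truth, states = states, config = manifest$config)
  sf <- file.path(dir, "sasa.tsv")
  if (file.exists(sf)) {
    stab <- read_sasa_table(sf)
    bundle$sasa <- split(stab, stab$protein_id)
  }
  af <- file.path(dir, "annotations.tsv")
  if (file.exists(af)) bundle$annotations <- utils::read.delim(af,
                                                               stringsAsFactors = FALSE)
  of <- file.path(dir, "ontology.obo")
  if (file.exists(of)) bundle$ontology <- read_obo(of)
  class(bundle) <- "qs_study_bundle"
  bundle
}
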