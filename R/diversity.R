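#' Orthogroup-level quaternary-structure variability metrics
#'
#' Four metrics summarise QS variability within an orthogroup, each computed
#' from one representative structure per protein except the per-protein QS
#' count, which uses all deposited entries of each protein:
#' \describe{
#'   \item{`avg_subunits`}{arithmetic mean subunit count, monomers included.}
#'   \item{`qs_diversity`}{number of distinct QS topology classes present.}
#'   \item{`shannon_index`}{`-sum(p_i * log(p_i))` over topology-class
#'     frequencies `p_i` (natural log); 0 for a single class. Unlike the
#'     raw class count it weights classes by how common they are, so one
#'     monomer among nine dimers scores lower than a five/five split.}
#'   \item{`avg_qs_per_protein`}{mean over member proteins of the number of
#'     distinct QSs among that protein's own entries.}
#' }
#'
#' @param profile Data frame with one row per member protein: columns
#'   `n_subunits`, `topology_class` and (for `avg_qs_per_protein`)
#'   `qs_count`.
#' @return A single numeric value.
#' @name diversity_metrics
NULL

#' @rdname diversity_metrics
#' @export
avg_subunits <- function(profile) {
  if (nrow(profile) == 0) stop("empty orthogroup profile")
  mean(profile$n_subunits)
}

#' @rdname diversity_metrics
#' @export
qs_diversity <- function(profile) {
  if (nrow(profile) == 0) stop("empty orthogroup profile")
  if (is.null(profile$topology_class) || anyNA(profile$topology_class))
    stop("topology classes must be assigned before computing QS diversity")
  length(unique(profile$topology_class))
}

#' @rdname diversity_metrics
#' @export
shannon_index <- function(profile) {
  if (nrow(profile) == 0) stop("empty orthogroup profile")
  if (is.null(profile$topology_class) || anyNA(profile$topology_class))
    stop("topology classes must be assigned before computing the Shannon index")
  p <- table(profile$topology_class) / nrow(profile)
  -sum(p * log(p))
}

#' @rdname diversity_metrics
#' @export
avg_qs_per_protein <- function(profile) {
  if (nrow(profile) == 0) stop("empty orthogroup profile")
  if (is.null(profile$qs_count) || anyNA(profile$qs_count))
    stop("per-protein QS counts missing")
  mean(profile$qs_count)
}

#' All four QS variability metrics for a set of orthogroups
#'
#' @param members Data frame with columns `orthogroup_id`, `protein_id`,
#'   `n_subunits`, `topology_class`, optionally `qs_count` and `is_mo`.
#' @param min_size Minimum orthogroup size for group comparisons (default 3);
#'   smaller orthogroups are still measured but flagged `eligible = FALSE`.
#' @return Data frame with one row per orthogroup: `orthogroup_id`,
#'   `n_proteins`, `avg_subunits`, `qs_diversity`, `shannon`,
#'   `avg_qs_per_protein` (NA when counts are absent), `is_mo` (if given)
#'   and `eligible`.
#' @export
orthogroup_metrics <- function(members, min_size = 3) {
  sp <- split(members, members$orthogroup_id)
  rows <- lapply(sp, function(m) {
    data.frame(
      orthogroup_id = m$orthogroup_id[1],
      n_proteins = nrow(m),
      avg_subunits = avg_subunits(m),
      qs_diversity = qs_diversity(m),
      shannon = shannon_index(m),
      avg_qs_per_protein = if (!is.null(m$qs_count) && !anyNA(m$qs_count))
        avg_qs_per_protein(m) else NA_real_,
      is_mo = if (!is.null(m$is_mo)) any(m$is_mo) else NA,
      eligible = nrow(m) >= min_size,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$orthogroup_id), , drop = FALSE]
}
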