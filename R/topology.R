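#' Interface overlap between two aligned homomers
#'
#' Fraction of the smaller interface whose residues are structurally aligned
#' onto interface residues of the other structure: the number of aligned
#' residue pairs with both ends in an interface, divided by the size of the
#' smaller interface.  Symmetric in the two structures.
#'
#' @param map Alignment map: data frame with columns `chain_a`, `resid_a`,
#'   `chain_b`, `resid_b`, one row per structurally aligned residue pair
#'   (one-to-one).
#' @param iface_a,iface_b Character vectors of `"chain:residue_index"` keys,
#'   the interface residue sets of the two structures.
#' @return Overlap fraction in `[0, 1]`, or `NA_real_` when either
#'   interface is empty.
#' @export
interface_overlap <- function(map, iface_a, iface_b) {
  if (length(iface_a) == 0 || length(iface_b) == 0) return(NA_real_)
  ka <- paste(map$chain_a, map$resid_a, sep = ":")
  kb <- paste(map$chain_b, map$resid_b, sep = ":")
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("alignment map is not one-to-one")
  hits <- sum(ka %in% iface_a & kb %in% iface_b)
  hits / min(length(iface_a), length(iface_b))
}

#' Are two quaternary structures the same topology?
#'
#' Two structures share a QS topology when they have the same subunit count
#' and their interface overlap is at least `threshold` (structures with
#' overlap below 0.5 are topologically different).  A missing overlap
#' between equal-count structures is conservatively treated as different
#' unless `missing_as_same = TRUE`.
#'
#' @param n_subunits_a,n_subunits_b Subunit counts.
#' @param overlap Interface overlap in `[0, 1]` or `NA`.
#' @param threshold Overlap threshold (default 0.5, `>=`).
#' @param missing_as_same How to treat `NA` overlaps between equal counts.
#' @return Logical scalar.
#' @export
same_topology <- function(n_subunits_a, n_subunits_b, overlap,
                          threshold = 0.5, missing_as_same = FALSE) {
  if (n_subunits_a != n_subunits_b) return(FALSE)
  if (n_subunits_a == 1) return(TRUE)  # monomers: no interface to compare
  if (is.na(overlap)) return(missing_as_same)
  overlap >= threshold
}

#' Partition structures into QS topology classes
#'
#' Within each subunit-count stratum, classes are the connected components of
#' the graph whose edges join pairs with interface overlap at or above
#' `threshold` (single linkage; a non-transitive overlap relation is closed
#' into components).  All monomers form a single class.  Class ids are the
#' lexicographically smallest member id of each class, so the partition is
#' deterministic and invariant to input order.
#'
#' @param structures Data frame with columns `id` (unique) and `n_subunits`.
#' @param overlaps Data frame with columns `id_a`, `id_b`, `overlap`
#'   (rows for pairs with unequal subunit counts are ignored; missing pairs
#'   follow `missing_as_same`).
#' @inheritParams same_topology
#' @return The input `structures` with a `topology_class` column added.
#' @export
assign_topologies <- function(structures, overlaps = NULL, threshold = 0.5,
                              missing_as_same = FALSE) {
  if (anyDuplicated(structures$id)) stop("structure ids must be unique")
  n <- nrow(structures)
  cls <- character(n)
  for (k in unique(structures$n_subunits)) {
    idx <- which(structures$n_subunits == k)
    ids <- sort(structures$id[idx])
    if (k == 1 || length(ids) == 1) {
      cls[idx] <- ids[1]
      next
    }
    edges <- character(0)
    if (!is.null(overlaps) && nrow(overlaps)) {
      sel <- overlaps$id_a %in% ids & overlaps$id_b %in% ids &
        !is.na(overlaps$overlap) & overlaps$overlap >= threshold
      edges <- rbind(overlaps$id_a[sel], overlaps$id_b[sel])
    }
    if (missing_as_same) {
      # unlisted pairs count as linked: complement of the below-threshold pairs
      listed <- overlaps[overlaps$id_a %in% ids & overlaps$id_b %in% ids, , drop = FALSE]
      low <- listed[!is.na(listed$overlap) & listed$overlap < threshold, , drop = FALSE]
      all_pairs <- utils::combn(ids, 2)
      pk <- function(a, b) paste(pmin(a, b), pmax(a, b))
      lowk <- pk(low$id_a, low$id_b)
      keep <- !(pk(all_pairs[1, ], all_pairs[2, ]) %in% lowk)
      edges <- all_pairs[, keep, drop = FALSE]
    }
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
    if (length(edges)) g <- g + igraph::edges(as.vector(edges))
    comp <- igraph::components(g)$membership
    lab <- vapply(split(names(comp), comp), function(m) sort(m)[1], character(1))
    cls[idx] <- lab[as.character(comp[structures$id[idx]])]
  }
  structures$topology_class <- cls
  structures
}

#' Number of distinct quaternary structures of one protein
#'
#' Counts topology classes among all deposited entries of a single protein:
#' entries with different subunit counts are different QSs, and entries with
#' the same subunit count but interface overlap below `threshold` are also
#' different QSs.  Monomeric entries together count as one class.
#'
#' @param entries Data frame with columns `id` (entry id) and `n_subunits`.
#' @param overlaps Pairwise overlaps among the entries (see
#'   [assign_topologies()]).
#' @inheritParams same_topology
#' @return Integer count >= 1.
#' @export
qs_per_protein <- function(entries, overlaps = NULL, threshold = 0.5,
                           missing_as_same = FALSE) {
  if (nrow(entries) < 1) stop("at least one entry required")
  a <- assign_topologies(entries, overlaps, threshold, missing_as_same)
  length(unique(a$topology_class))
}

#' Read an alignment map TSV
#'
#' Headered TSV with columns `protein_a`, `chain_a`, `resid_a`, `protein_b`,
#' `chain_b`, `resid_b`: one row per structurally aligned residue pair.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_alignment_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("protein_a", "chain_a", "resid_a", "protein_b", "chain_b", "resid_b")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) stop("alignment map lacks column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Parse TM-align plain output into an alignment map
#'
#' Convenience reader for the three-line alignment block of TM-align's
#' standard output (sequence A, match line, sequence B).  Aligned positions
#' (non-gap in both sequences, match character `:` or `.`) are numbered
#' sequentially along each chain.
#'
#' @param path Path to a TM-align output file.
#' @param protein_a,protein_b Ids for the two structures.
#' @param chain_a,chain_b Chain labels for the map (default `"A"`).
#' @return Alignment map data frame as in [read_alignment_map()].
#' @export
parse_tmalign <- function(path, protein_a, protein_b,
                          chain_a = "A", chain_b = "A") {
  lines <- readLines(path)
  anchor <- grep("denotes (aligned residue pairs|residue pairs of)", lines)
  if (length(anchor) == 0) stop("no alignment block found in ", path)
  block <- lines[(anchor[1] + 1):(anchor[1] + 3)]
  sa <- strsplit(block[1], "")[[1]]
  mk <- strsplit(block[2], "")[[1]]
  sb <- strsplit(block[3], "")[[1]]
  n <- min(length(sa), length(mk), length(sb))
  sa <- sa[seq_len(n)]; mk <- mk[seq_len(n)]; sb <- sb[seq_len(n)]
  ia <- cumsum(sa != "-")
  ib <- cumsum(sb != "-")
  sel <- sa != "-" & sb != "-" & mk %in% c(":", ".")
  data.frame(protein_a = protein_a, chain_a = chain_a, resid_a = ia[sel],
             protein_b = protein_b, chain_b = chain_b, resid_b = ib[sel],
             stringsAsFactors = FALSE)
}
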