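#' Reference maximum accessible surface areas
#'
#' Theoretical maximum accessible surface area (ASA) per residue type, in
#' square Angstroms, used as the denominator of relative solvent
#' accessibility (RSA).  The packaged values are the theoretical maxima of
#' Tien et al. (2013, PLoS ONE 8:e80635), the standard "full amino acid
#' areas" reference.
#'
#' @param path Optional path to a two-column headered TSV
#'   (`residue_type`, `max_area`) overriding the packaged table.
#' @return A named numeric vector mapping one-letter residue codes to
#'   maximum areas (all > 0).
#' @export
#' @examples
#' ma <- max_area_table()
#' ma["A"]
max_area_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "max_sasa_tien2013.tsv", package = "qsevo",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue_type", "max_area") %in% names(tab)))
    stop("max-area table must have columns 'residue_type' and 'max_area'")
  if (any(tab$max_area <= 0)) stop("all maximum areas must be > 0")
  stats::setNames(tab$max_area, tab$residue_type)
}

#' Relative solvent accessibility of a residue
#'
#' RSA is the residue's solvent-accessible surface area divided by the
#' reference maximum area for its residue type.  Values above 1 are possible
#' (extended conformations) and are not clamped.
#'
#' @param sasa Accessible surface area in square Angstroms (>= 0). Vectorised.
#' @param residue_type One-letter amino-acid code(s), recycled against `sasa`.
#' @param max_areas Named numeric vector from [max_area_table()].
#' @return Numeric vector of RSA values (>= 0).
#' @export
compute_rsa <- function(sasa, residue_type, max_areas = max_area_table()) {
  if (any(sasa < 0)) stop("negative SASA value")
  unknown <- setdiff(unique(residue_type), names(max_areas))
  if (length(unknown))
    stop("unknown residue type(s): ", paste(unknown, collapse = ", "))
  as.numeric(sasa) / as.numeric(max_areas[residue_type])
}

check_sasa_table <- function(table) {
  needed <- c("chain_id", "residue_index", "residue_type",
              "sasa_complex", "sasa_monomer")
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("SASA table must be a non-empty data frame")
  miss <- setdiff(needed, names(table))
  if (length(miss)) stop("SASA table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(table$sasa_complex < 0) || any(table$sasa_monomer < 0))
    stop("negative SASA value in table")
  keycols <- intersect(c("protein_id", "chain_id", "residue_index"), names(table))
  if (any(duplicated(table[keycols])))
    stop("duplicated residue_index within a chain")
  invisible(table)
}

#' Classify residues as interface, surface or buried
#'
#' A residue is an interface residue when its RSA in the monomeric subunit is
#' at least `rsa_threshold` and oligomerisation buries at least
#' `burial_threshold` of its monomeric SASA
#' (`(sasa_monomer - sasa_complex) / sasa_monomer`).  Residues that are not
#' interface and have RSA strictly above `rsa_threshold` are surface; the
#' rest are buried.  Negative burial (complex SASA exceeding monomer SASA,
#' numerical noise) counts as zero burial, and residues with zero monomeric
#' SASA are never interface.
#'
#' The RSA gate is evaluated in the monomer context by default
#' (`rsa_context = "monomer"`): a residue strongly buried by oligomerisation
#' would otherwise fail the accessibility gate in the complex, defeating the
#' purpose of detecting interface burial.  `rsa_context = "complex"` is
#' available for sensitivity analyses.
#'
#' @param table Data frame with columns `chain_id`, `residue_index`,
#'   `residue_type`, `sasa_complex`, `sasa_monomer` (areas in square
#'   Angstroms, >= 0).
#' @param max_areas Named vector from [max_area_table()].
#' @param rsa_threshold Minimum RSA for interface/surface calls (default 0.2;
#'   interface uses `>=`, surface uses strict `>`).
#' @param burial_threshold Minimum fraction of monomeric SASA buried on
#'   complexation for an interface call (default 0.10, `>=`).
#' @param rsa_context `"monomer"` (default) or `"complex"`: which SASA feeds
#'   the RSA gate.
#' @return The input data frame with added columns `rsa` (in the chosen
#'   context), `burial_fraction` and `label` (one of `"interface"`,
#'   `"surface"`, `"buried"`).
#' @export
classify_residues <- function(table, max_areas = max_area_table(),
                              rsa_threshold = 0.2, burial_threshold = 0.10,
                              rsa_context = c("monomer", "complex")) {
  rsa_context <- match.arg(rsa_context)
  check_sasa_table(table)
  rsa_sasa <- if (rsa_context == "monomer") table$sasa_monomer else table$sasa_complex
  rsa <- compute_rsa(rsa_sasa, table$residue_type, max_areas)
  burial <- ifelse(table$sasa_monomer > 0,
                   pmax(0, (table$sasa_monomer - table$sasa_complex) / table$sasa_monomer),
                   0)
  iface <- table$sasa_monomer > 0 & rsa >= rsa_threshold & burial >= burial_threshold
  surf <- !iface & rsa > rsa_threshold
  out <- table
  out$rsa <- rsa
  out$burial_fraction <- burial
  out$label <- ifelse(iface, "interface", ifelse(surf, "surface", "buried"))
  out
}

#' Per-subunit interface area of a complex
#'
#' Buried area per subunit: the difference between the summed SASA of the
#' isolated monomeric subunits and the SASA of the complex, divided by the
#' number of subunits.  Negative differences (noise) are reported as zero.
#'
#' @param total_sasa_monomers Summed SASA of all isolated subunits (A^2).
#' @param total_sasa_complex SASA of the assembled complex (A^2).
#' @param n_subunits Number of subunits (integer >= 1).
#' @return Interface area in square Angstroms (>= 0).
#' @export
interface_area <- function(total_sasa_monomers, total_sasa_complex, n_subunits) {
  if (any(n_subunits < 1)) stop("n_subunits must be >= 1")
  if (any(total_sasa_monomers < 0) || any(total_sasa_complex < 0))
    stop("SASA totals must be >= 0")
  pmax(0, total_sasa_monomers - total_sasa_complex) / n_subunits
}

#' Summarise the interface of one protein's complex
#'
#' Runs [classify_residues()] on a per-residue SASA table of one subunit and
#' derives the complex-level interface summary.  SASA totals are scaled by
#' the subunit count (all subunits of a homomer are copies of the tabulated
#' chain set).  A monomer has zero interface area and no interface residues.
#'
#' @inheritParams classify_residues
#' @param protein_id Identifier attached to the summary.
#' @param n_subunits Subunit count of the representative complex.
#' @return A list of class `qs_interface_summary`: `protein_id`,
#'   `n_subunits`, `interface_area`, `interface_residues` and
#'   `surface_residues` (character vectors of `"chain:residue_index"` keys),
#'   plus the classified residue table.
#' @export
interface_summary <- function(table, protein_id, n_subunits,
                              max_areas = max_area_table(),
                              rsa_threshold = 0.2, burial_threshold = 0.10) {
  cls <- classify_residues(table, max_areas, rsa_threshold, burial_threshold)
  key <- paste(cls$chain_id, cls$residue_index, sep = ":")
  if (n_subunits == 1) {
    ifr <- character(0)
    area <- 0
    # a chain in isolation buries nothing; surface set still meaningful
    surf <- key[cls$label != "buried" & cls$rsa > rsa_threshold]
  } else {
    ifr <- key[cls$label == "interface"]
    surf <- key[cls$label == "surface"]
    area <- interface_area(n_subunits * sum(cls$sasa_monomer),
                           n_subunits * sum(cls$sasa_complex),
                           n_subunits)
  }
  structure(list(protein_id = protein_id, n_subunits = n_subunits,
                 interface_area = area, interface_residues = ifr,
                 surface_residues = surf, residues = cls),
            class = "qs_interface_summary")
}

#' Interface-minus-surface conservation difference
#'
#' Mean conservation over interface residues minus mean conservation over
#' surface residues of one structure.  Returns `NA` when either set is
#' empty (e.g. monomers); errors only when a required residue lacks a score.
#'
#' @param classification Result of [classify_residues()].
#' @param conservation Named numeric vector of per-residue conservation
#'   scores keyed by `"chain:residue_index"`.
#' @return A single numeric difference, or `NA_real_`.
#' @export
conservation_difference <- function(classification, conservation) {
  key <- paste(classification$chain_id, classification$residue_index, sep = ":")
  ik <- key[classification$label == "interface"]
  sk <- key[classification$label == "surface"]
  if (length(ik) == 0 || length(sk) == 0) return(NA_real_)
  miss <- setdiff(c(ik, sk), names(conservation))
  if (length(miss))
    stop("conservation scores missing for residue(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  mean(conservation[ik]) - mean(conservation[sk])
}

#' Read / write per-residue SASA tables
#'
#' Headered TSV with columns `protein_id`, `chain_id`, `residue_index`,
#' `residue_type`, `sasa_complex`, `sasa_monomer`.  Reading returns a data
#' frame (possibly covering several proteins).
#'
#' @param path File path.
#' @param table Data frame to write.
#' @return `read_sasa_table` returns a data frame; `write_sasa_table`
#'   returns `path` invisibly.
#' @export
read_sasa_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_sasa_table(tab)
  tab
}

#' @rdname read_sasa_table
#' @export
write_sasa_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
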