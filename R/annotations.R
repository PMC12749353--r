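#' Read an OBO ontology file
#'
#' Minimal reader for the OBO flat-file format covering what term filtering
#' needs: term ids, names, namespaces, obsolescence, `is_a` edges and
#' `relationship: part_of` edges.  Obsolete terms are dropped with a
#' warning.  Edges whose two ends live in different namespaces are excluded
#' from ancestry (term pairs connecting separate ontologies are never
#' treated as redundant).
#'
#' @param path Path to an `.obo` file.
#' @return An object of class `qs_ontology`: list with `terms` (data frame
#'   `id`, `name`, `namespace`, one row per non-obsolete term) and `edges`
#'   (data frame `child`, `parent`, `relation`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\[Term\\]$", lines)
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(grep("^\\[", lines), length(lines) + 1L)
  terms <- list(); edges <- list()
  n_obs <- 0L
  for (s in starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):e]
    field <- function(key) sub(paste0("^", key, ": "), "",
                               grep(paste0("^", key, ": "), block, value = TRUE))
    id <- field("id")[1]
    if (is.na(id)) next
    if (any(grepl("^is_obsolete: true", block))) {
      n_obs <- n_obs + 1L
      next
    }
    name <- field("name")[1]
    ns <- field("namespace")[1]
    if (is.na(ns)) ns <- "default"
    terms[[length(terms) + 1L]] <- data.frame(
      id = id, name = if (is.na(name)) id else name, namespace = ns,
      stringsAsFactors = FALSE)
    isa <- sub(" !.*$", "", field("is_a"))
    for (p in isa)
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = p,
                                                relation = "is_a",
                                                stringsAsFactors = FALSE)
    rel <- field("relationship")
    po <- sub(" !.*$", "", sub("^part_of ", "", grep("^part_of ", rel, value = TRUE)))
    for (p in po)
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = p,
                                                relation = "part_of",
                                                stringsAsFactors = FALSE)
  }
  if (n_obs > 0) warning(n_obs, " obsolete term(s) dropped")
  make_ontology(do.call(rbind, terms),
                if (length(edges)) do.call(rbind, edges)
                else data.frame(child = character(0), parent = character(0),
                                relation = character(0)))
}

#' Build an ontology DAG from term and edge tables
#'
#' @param terms Data frame with columns `id`, `namespace` (and optionally
#'   `name`).
#' @param edges Data frame with columns `child`, `parent` and optionally
#'   `relation` (`is_a` / `part_of`; Reactome-style parent-child relations
#'   use a single generic relation).
#' @return A `qs_ontology` object (see [read_obo()]).
#' @export
make_ontology <- function(terms, edges) {
  if (is.null(terms$name)) terms$name <- terms$id
  if (is.null(edges$relation)) edges$relation <- "is_a"
  ns <- stats::setNames(terms$namespace, terms$id)
  # cross-namespace and dangling edges never enter ancestry
  keep <- edges$child %in% terms$id & edges$parent %in% terms$id &
    ns[edges$child] == ns[edges$parent]
  edges <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = terms$id)
  if (!igraph::is_dag(g)) stop("ontology relations contain a cycle")
  # process parents before children so ancestor lists can be reused
  ord <- rev(names(igraph::topo_sort(g, mode = "out")))
  anc <- stats::setNames(vector("list", length(ord)), ord)
  adj <- igraph::adjacent_vertices(g, ord, mode = "out")
  for (i in seq_along(ord)) {
    ps <- names(adj[[i]])
    anc[[ord[i]]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  structure(list(terms = terms, edges = edges, ancestors = anc),
            class = "qs_ontology")
}

#' @export
print.qs_ontology <- function(x, ...) {
  cat("Ontology DAG:", nrow(x$terms), "terms,", nrow(x$edges), "edges,",
      length(unique(x$terms$namespace)), "namespace(s)\n")
  invisible(x)
}

#' Ancestors of a term in the ontology
#'
#' Transitive closure over `is_a`/`part_of` within the term's namespace.
#'
#' @param dag A `qs_ontology` object.
#' @param term Term id.
#' @return Character vector of ancestor ids (excluding the term itself).
#' @export
term_ancestors <- function(dag, term) {
  if (!term %in% names(dag$ancestors)) stop("unknown term id: ", term)
  dag$ancestors[[term]]
}

#' Remove hierarchically redundant ontology terms
#'
#' Terms that stand in an ancestor-descendant relationship describe the same
#' annotation at different granularity; only the most specific (lowest
#' level) term is kept.  A term is dropped exactly when it is an ancestor
#' (via the `is_a`/`part_of` closure, within its namespace) of another term
#' in the set — e.g. of `{mitochondrion, mitochondrial inner membrane}` only
#' the inner-membrane term survives.  The result is an antichain of the DAG
#' and the operation is idempotent.
#'
#' @param terms Character vector of term ids.
#' @param dag A `qs_ontology` object.
#' @return The reduced term set (same order as input).
#' @export
filter_redundant_terms <- function(terms, dag) {
  terms <- unique(terms)
  if (length(terms) == 0) return(character(0))
  unknown <- setdiff(terms, dag$terms$id)
  if (length(unknown))
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  anc_of_set <- unique(unlist(dag$ancestors[terms], use.names = FALSE))
  terms[!terms %in% anc_of_set]
}

#' Filter a GO annotation table by evidence code
#'
#' @param table Annotation data frame with columns `protein_id`, `source`,
#'   `term_id` and (for GO sources) `evidence`.
#' @param mode `"all"` (identity), `"drop_IEA"` (remove electronically
#'   inferred terms) or `"experimental_only"`.
#' @param experimental Evidence codes counted as experimental (the standard
#'   GO experimental + high-throughput set).
#' @return The filtered annotation table.
#' @export
evidence_subset <- function(table,
                            mode = c("all", "drop_IEA", "experimental_only"),
                            experimental = c("EXP", "IDA", "IPI", "IMP", "IGI",
                                             "IEP", "HTP", "HDA", "HMP", "HGI",
                                             "HEP")) {
  mode <- match.arg(mode)
  if (mode == "all") return(table)
  if (is.null(table$evidence)) stop("evidence codes required for mode ", mode)
  if (mode == "drop_IEA") table[table$evidence != "IEA", , drop = FALSE]
  else table[table$evidence %in% experimental, , drop = FALSE]
}

#' Mean annotation richness of a protein group
#'
#' Mean number of (optionally redundancy-filtered) terms per protein over a
#' group; proteins without any annotation count as zero.
#'
#' @param table Annotation data frame (`protein_id`, `source`, `term_id`).
#' @param group Character vector of protein ids (non-empty).
#' @param source Annotation source to count (e.g. `"GO-MF"`); `NULL` counts
#'   all sources together.
#' @param dag Optional `qs_ontology`; when given, each protein's term set is
#'   passed through [filter_redundant_terms()] before counting.
#' @return Mean terms per protein (numeric scalar).
#' @export
richness <- function(table, group, source = NULL, dag = NULL) {
  if (length(group) == 0) stop("empty protein group")
  t2 <- table
  if (!is.null(source)) t2 <- t2[t2$source == source, , drop = FALSE]
  t2 <- t2[t2$protein_id %in% group, , drop = FALSE]
  sets <- split(t2$term_id, t2$protein_id)
  counts <- vapply(sets, function(s) {
    s <- unique(s)
    if (!is.null(dag)) s <- filter_redundant_terms(s, dag)
    length(s)
  }, numeric(1))
  sum(counts) / length(group)  # unannotated proteins contribute 0
}
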