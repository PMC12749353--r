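# Synthetic inputs with known ground truth for every pipeline stage:
# Yule trees, QS characters evolved under a gain/loss Markov chain, toy
# complexes expressed as SASA tables, alignment maps, a small ontology DAG
# with a negative-binomial annotation sampler, and a full two-arm study
# bundle (moonlighting vs non-moonlighting orthogroups).

#' Simulate a Yule (pure-birth) tree
#'
#' Rooted binary tree with `n_tips` tips under a constant birth rate;
#' branch-length units are arbitrary "substitutions/site", matching the
#' unit of the ER transition rate.  Deterministic under `seed`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Birth rate per lineage per unit time (> 0).
#' @param seed Optional integer seed (set internally when given).
#' @param labels Optional tip labels (length `n_tips`).
#' @return An `ape::phylo` tree.
#' @export
sim_tree <- function(n_tips, birth_rate = 1, seed = NULL, labels = NULL) {
  if (n_tips < 3) stop("n_tips must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  if (!is.null(labels)) {
    if (length(labels) != n_tips) stop("labels must have length n_tips")
    tr$tip.label <- labels
  }
  tr
}

#' Default quaternary-structure state ladder
#'
#' One-step gain/loss ladder over subunit counts 1, 2, 4, 8 (monomer,
#' dimer, tetramer, octamer); state labels are the subunit counts.
#'
#' @param counts Subunit counts, strictly increasing.
#' @return Data frame with columns `state` and `n_subunits`.
#' @export
qs_states <- function(counts = c(1, 2, 4, 8)) {
  if (is.unsorted(counts, strictly = TRUE)) stop("counts must be increasing")
  data.frame(state = as.character(counts), n_subunits = counts,
             stringsAsFactors = FALSE)
}

#' Evolve a quaternary-structure character along a tree
#'
#' Continuous-time Markov chain on the state ladder: gains move one state
#' up (rate `gain_rate`), losses one state down (rate `loss_rate`), sampled
#' by exact event-by-event (Gillespie) simulation along every branch from
#' the root.  The full node-state truth is returned for ancestral-state
#' recovery tests.
#'
#' @param tree Rooted `ape::phylo` tree with branch lengths.
#' @param states State ladder from [qs_states()] (>= 2 states, ordered by
#'   subunit count).
#' @param gain_rate,loss_rate Events per unit branch length (>= 0).
#' @param seed Optional integer seed.
#' @param root_state Starting state label; default: drawn uniformly.
#' @return List: `tip_states` (named by tip label), `node_states` (all
#'   nodes, ape numbering), `root_state`, `n_events`.
#' @export
evolve_qs <- function(tree, states = qs_states(), gain_rate, loss_rate,
                      seed = NULL, root_state = NULL) {
  if (nrow(states) < 2) stop("need >= 2 states")
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(states)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  if (is.null(root_state)) root_state <- sample(states$state, 1)
  i0 <- match(root_state, states$state)
  if (is.na(i0)) stop("root_state not in the state set")
  node_idx <- integer(n_tip + tree$Nnode)
  node_idx[root] <- i0
  n_events <- 0L
  pe <- ape::reorder.phylo(tree, "postorder")
  for (r in rev(seq_len(nrow(pe$edge)))) {   # preorder: parents first
    par <- pe$edge[r, 1]; ch <- pe$edge[r, 2]
    len <- pe$edge.length[r]
    i <- node_idx[par]
    t <- 0
    repeat {
      up <- if (i < k) gain_rate else 0
      down <- if (i > 1) loss_rate else 0
      tot <- up + down
      if (tot == 0) break
      t <- t + stats::rexp(1, tot)
      if (t > len) break
      i <- if (stats::runif(1) < up / tot) i + 1L else i - 1L
      n_events <- n_events + 1L
    }
    node_idx[ch] <- i
  }
  node_states <- states$state[node_idx]
  list(tip_states = stats::setNames(node_states[seq_len(n_tip)],
                                    tree$tip.label),
       node_states = node_states, root_state = root_state,
       n_events = n_events)
}

#' Generate a toy complex as a SASA table with a planted interface
#'
#' Monomer SASA values are drawn so that exactly the planted residues pass
#' both interface thresholds (monomer RSA >= 0.2 and >= 10% SASA burial on
#' complexation) with a safety `margin`, while the remaining residues fail
#' at least one threshold by the same margin (half of them accessible but
#' essentially unburied, half below the RSA gate).
#'
#' @param protein_id Identifier written into the table.
#' @param n_subunits Subunit count of the complex (1 = monomer: no burial).
#' @param n_residues Number of residues in the chain.
#' @param planted_interface Integer residue indices to plant (subset of
#'   `1:n_residues`; ignored for monomers).
#' @param seed Optional integer seed.
#' @param margin Distance from the 0.2 / 0.10 thresholds (default 0.02).
#' @param max_areas Reference maxima from [max_area_table()].
#' @return List: `sasa` (the residue table), `planted`
#'   (`"chain:residue"` keys of the planted set), `n_subunits`.
#' @export
gen_toy_complex <- function(protein_id, n_subunits, n_residues = 60,
                            planted_interface = integer(0), seed = NULL,
                            margin = 0.02, max_areas = max_area_table()) {
  if (!is.null(seed)) set.seed(seed)
  if (length(planted_interface) &&
      !all(planted_interface %in% seq_len(n_residues)))
    stop("planted interface outside the residue range")
  if (n_subunits == 1) planted_interface <- integer(0)
  aa <- sample(names(max_areas), n_residues, replace = TRUE)
  mx <- as.numeric(max_areas[aa])
  rsa <- numeric(n_residues)
  burial <- numeric(n_residues)
  planted <- seq_len(n_residues) %in% planted_interface
  others <- which(!planted)
  low_rsa <- others[seq_along(others) %% 2 == 0]
  surf <- setdiff(others, low_rsa)
  rsa[planted] <- stats::runif(sum(planted), 0.2 + margin, 0.9)
  burial[planted] <- stats::runif(sum(planted), 0.1 + margin, 0.6)
  rsa[surf] <- stats::runif(length(surf), 0.2 + margin, 0.9)
  burial[surf] <- stats::runif(length(surf), 0, max(0.1 - margin, 0))
  rsa[low_rsa] <- stats::runif(length(low_rsa), 0.01, max(0.2 - margin, 0.01))
  burial[low_rsa] <- stats::runif(length(low_rsa), 0, 0.5)
  monomer <- rsa * mx
  complex <- monomer * (1 - burial)
  tab <- data.frame(protein_id = protein_id, chain_id = "A",
                    residue_index = seq_len(n_residues), residue_type = aa,
                    sasa_complex = complex, sasa_monomer = monomer,
                    stringsAsFactors = FALSE)
  list(sasa = tab,
       planted = paste("A", which(planted), sep = ":"),
       n_subunits = n_subunits)
}

#' Identity alignment map between two equally long chains
#'
#' @param protein_a,protein_b Structure ids.
#' @param n_residues Chain length.
#' @return Alignment map data frame (residue i of a onto residue i of b).
#' @export
identity_alignment_map <- function(protein_a, protein_b, n_residues) {
  data.frame(protein_a = protein_a, chain_a = "A", resid_a = seq_len(n_residues),
             protein_b = protein_b, chain_b = "A", resid_b = seq_len(n_residues),
             stringsAsFactors = FALSE)
}

#' Generate a random ontology DAG
#'
#' Per namespace, a rooted tree of the given depth and branching factor,
#' plus occasional extra `part_of` edges to shallower nodes (so the DAG is
#' not a plain tree).  Term ids are `T:<n>`, zero-padded.
#'
#' @param depth Tree depth (>= 2; root = depth 0).
#' @param branching Children per node.
#' @param seed Optional integer seed.
#' @param namespaces Namespace names (one DAG each).
#' @param extra_edge_prob Probability a non-root term gets one extra
#'   `part_of` parent at a strictly smaller depth.
#' @return A `qs_ontology` object with an extra `leaves` element (ids of
#'   terms without children, per namespace).
#' @export
gen_ontology <- function(depth = 4, branching = 3, seed = NULL,
                         namespaces = "molecular_function",
                         extra_edge_prob = 0.1) {
  if (depth < 2) stop("depth must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  terms <- list(); edges <- list()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("T:%06d", counter)
  }
  for (ns in namespaces) {
    levels <- vector("list", depth + 1)
    root <- new_id()
    terms[[length(terms) + 1L]] <- data.frame(id = root, name = root,
                                              namespace = ns)
    levels[[1]] <- root
    for (d in seq_len(depth)) {
      lev <- character(0)
      for (parent in levels[[d]]) {
        for (b in seq_len(branching)) {
          id <- new_id()
          lev <- c(lev, id)
          terms[[length(terms) + 1L]] <- data.frame(id = id, name = id,
                                                    namespace = ns)
          edges[[length(edges) + 1L]] <- data.frame(child = id, parent = parent,
                                                    relation = "is_a")
          shallower <- unlist(levels[seq_len(d)])
          if (length(shallower) > 1 && stats::runif(1) < extra_edge_prob) {
            extra <- sample(setdiff(shallower, parent), 1)
            edges[[length(edges) + 1L]] <- data.frame(child = id, parent = extra,
                                                      relation = "part_of")
          }
        }
      }
      levels[[d + 1]] <- lev
    }
  }
  dag <- make_ontology(do.call(rbind, terms), do.call(rbind, edges))
  kids <- unique(dag$edges$parent)
  dag$leaves <- split(setdiff(dag$terms$id, kids),
                      dag$terms$namespace[match(setdiff(dag$terms$id, kids),
                                                dag$terms$id)])
  dag
}

#' Sample annotation tables from an ontology
#'
#' Per-protein term counts are negative-binomial with the given mean; terms
#' are sampled from the DAG's leaves, and with probability `ancestor_prob`
#' each sampled leaf also drags in one of its ancestors (a hierarchically
#' redundant term, removed again by [filter_redundant_terms()]).
#'
#' @param dag Ontology from [gen_ontology()].
#' @param protein_ids Character vector of proteins to annotate.
#' @param mu Mean terms per protein (negative-binomial mean).
#' @param size Negative-binomial dispersion (default 2).
#' @param ancestor_prob Redundant-ancestor injection probability.
#' @param source Source label (default `"GO-MF"`).
#' @param seed Optional integer seed.
#' @param iea_prob Probability an annotation carries the IEA evidence code
#'   (otherwise an experimental code is drawn).
#' @return Annotation data frame: `protein_id`, `source`, `term_id`,
#'   `evidence`.
#' @export
sample_annotations <- function(dag, protein_ids, mu, size = 2,
                               ancestor_prob = 0.5, source = "GO-MF",
                               seed = NULL, iea_prob = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  leaves <- unlist(dag$leaves, use.names = FALSE)
  rows <- vector("list", length(protein_ids))
  exp_codes <- c("IDA", "IMP", "IPI", "IGI", "HDA")
  for (i in seq_along(protein_ids)) {
    n <- stats::rnbinom(1, mu = mu, size = size)
    if (n == 0) next
    picked <- unique(sample(leaves, min(n, length(leaves))))
    anc <- character(0)
    for (t in picked) {
      a <- dag$ancestors[[t]]
      if (length(a) && stats::runif(1) < ancestor_prob)
        anc <- c(anc, sample(a, 1))
    }
    all_terms <- unique(c(picked, anc))
    ev <- ifelse(stats::runif(length(all_terms)) < iea_prob, "IEA",
                 sample(exp_codes, length(all_terms), replace = TRUE))
    rows[[i]] <- data.frame(protein_id = protein_ids[i], source = source,
                            term_id = all_terms, evidence = ev,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), source = character(0),
                      term_id = character(0), evidence = character(0))
  out
}

#' Simulation configuration for a full synthetic study
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' two arms of orthogroups (with / without moonlighting proteins), Yule
#' trees, a one-step gain/loss ladder over 1-2-4-8 subunits with gains
#' twice as frequent as losses, no MO effect on QS transition rates
#' (`qs_effect = 1`, the null the study design tests), and a 1.5-fold MO
#' enrichment in annotation terms.
#'
#' @param seed Integer seed governing every random draw.
#' @param n_orthogroups Orthogroups per arm.
#' @param tips_min,tips_max Orthogroup sizes are drawn uniformly in this
#'   range.
#' @param birth_rate Yule birth rate.
#' @param states State ladder ([qs_states()]).
#' @param gain_rate,loss_rate QS transition rates per unit branch length.
#' @param qs_effect Multiplier on both transition rates in the MO arm.
#' @param annotation_effect Multiplier on mean terms/protein in the MO arm.
#' @param annotation_mu Mean terms per protein in the non-MO arm.
#' @param n_residues Residues per toy chain.
#' @param interface_size Planted interface residues per homomer.
#' @param with_structures,with_annotations Generate SASA tables / alignment
#'   maps and ontology / annotations (disable for tree-only studies).
#' @return A validated list of class `qs_sim_config`.
#' @export
sim_config <- function(seed = 1, n_orthogroups = 50, tips_min = 10,
                       tips_max = 24, birth_rate = 1, states = qs_states(),
                       gain_rate = 0.3, loss_rate = 0.15, qs_effect = 1,
                       annotation_effect = 1.5, annotation_mu = 4,
                       n_residues = 60, interface_size = 12,
                       with_structures = TRUE, with_annotations = TRUE) {
  stopifnot(n_orthogroups >= 1, tips_min >= 3, tips_max >= tips_min,
            birth_rate > 0, gain_rate >= 0, loss_rate >= 0, qs_effect >= 0,
            annotation_effect >= 0, annotation_mu >= 0,
            interface_size <= n_residues)
  structure(as.list(environment()), class = "qs_sim_config")
}

#' Generate a full synthetic study bundle
#'
#' Produces every input the pipeline consumes, with ground truth: per-arm
#' orthogroups with Yule trees, evolved QS tip and node states, per-protein
#' record metadata (all passing the quality filters), optional toy SASA
#' tables and within-orthogroup alignment maps, and an optional ontology
#' with annotation tables whose MO mean is `annotation_effect` times the
#' non-MO mean.  Identical configuration (including seed) yields an
#' identical bundle.
#'
#' @param config A [sim_config()] object.
#' @param dir Optional directory: when given, the bundle is also written to
#'   disk in the pipeline's file formats (Newick, TSV, OBO, JSON manifest).
#' @return List of class `qs_study_bundle`: `proteins` (record table with
#'   `protein_id`, `orthogroup_id`, `is_mo`, `n_subunits`,
#'   `topology_class`, `qs_count`, `resolution`, `coverage`, `length`),
#'   `trees` (named list of `phylo`), `tip_states`, `truth` (node states,
#'   root states, per-arm rates), `states`, optional `sasa`, `planted`,
#'   `alignments`, `ontology`, `annotations`, and `config`.
#' @export
gen_study <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "qs_sim_config"))
  set.seed(config$seed)
  states <- config$states
  arms <- c(FALSE, TRUE)  # non-MO, MO
  proteins <- list(); trees <- list(); tip_states <- list()
  truth <- list()
  sasa <- list(); planted <- list(); alignments <- list()
  for (mo in arms) {
    mult <- if (mo) config$qs_effect else 1
    for (g in seq_len(config$n_orthogroups)) {
      og <- sprintf("OG%s%03d", if (mo) "M" else "N", g)
      sizes <- seq(config$tips_min, config$tips_max)
      n <- sizes[sample.int(length(sizes), 1)]
      ids <- sprintf("%s_p%02d", og, seq_len(n))
      tr <- sim_tree(n, config$birth_rate, labels = ids)
      ev <- evolve_qs(tr, states, config$gain_rate * mult,
                      config$loss_rate * mult)
      trees[[og]] <- tr
      tip_states[[og]] <- ev$tip_states
      truth[[og]] <- list(node_states = ev$node_states,
                          root_state = ev$root_state, is_mo = mo,
                          gain_rate = config$gain_rate * mult,
                          loss_rate = config$loss_rate * mult)
      nsub <- states$n_subunits[match(ev$tip_states, states$state)]
      proteins[[og]] <- data.frame(
        protein_id = ids, orthogroup_id = og, is_mo = mo,
        n_subunits = nsub,
        topology_class = as.character(ev$tip_states),
        qs_count = 1L + stats::rpois(n, 0.3),
        resolution = stats::runif(n, 1.2, 2.9),
        coverage = stats::runif(n, 0.85, 1.0),
        length = sample(120:600, n, replace = TRUE),
        stringsAsFactors = FALSE)
      if (config$with_structures) {
        # one shared planted interface per subunit-count stratum of the
        # orthogroup, so same-count structures overlap fully
        iface_by_count <- list()
        for (i in seq_len(n)) {
          if (nsub[i] > 1) {
            key <- as.character(nsub[i])
            if (is.null(iface_by_count[[key]]))
              iface_by_count[[key]] <- sort(sample(config$n_residues,
                                                   config$interface_size))
            pl <- iface_by_count[[key]]
          } else pl <- integer(0)
          tc <- gen_toy_complex(ids[i], nsub[i], config$n_residues, pl)
          sasa[[ids[i]]] <- tc$sasa
          planted[[ids[i]]] <- tc$planted
        }
      }
    }
  }
  proteins <- do.call(rbind, proteins)
  rownames(proteins) <- NULL
  bundle <- list(proteins = proteins, trees = trees,
                 tip_states = tip_states, truth = truth, states = states,
                 config = config)
  if (config$with_structures) {
    bundle$sasa <- sasa
    bundle$planted <- planted
  }
  if (config$with_annotations) {
    dag <- gen_ontology(depth = 4, branching = 3,
                        namespaces = "molecular_function")
    ann_mo <- sample_annotations(dag, proteins$protein_id[proteins$is_mo],
                                 mu = config$annotation_mu *
                                   config$annotation_effect)
    ann_non <- sample_annotations(dag, proteins$protein_id[!proteins$is_mo],
                                  mu = config$annotation_mu)
    bundle$ontology <- dag
    bundle$annotations <- rbind(ann_non, ann_mo)
  }
  class(bundle) <- "qs_study_bundle"
  if (!is.null(dir)) write_study_bundle(bundle, dir)
  bundle
}

#' Write a study bundle to disk in the pipeline's input formats
#'
#' Trees as one Newick file per orthogroup, protein records and tip states
#' as TSV, SASA tables as a single TSV, the ontology as OBO, annotations as
#' TSV, and a JSON manifest of the ground-truth parameters.
#'
#' @param bundle A `qs_study_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tdir <- file.path(dir, "trees")
  dir.create(tdir, showWarnings = FALSE)
  for (og in names(bundle$trees))
    write_newick(bundle$trees[[og]], file.path(tdir, paste0(og, ".nwk")))
  utils::write.table(bundle$proteins, file.path(dir, "proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$sasa))
    write_sasa_table(do.call(rbind, bundle$sasa), file.path(dir, "sasa.tsv"))
  if (!is.null(bundle$annotations))
    utils::write.table(bundle$annotations, file.path(dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$ontology)) write_obo(bundle$ontology,
                                           file.path(dir, "ontology.obo"))
  cfg <- unclass(bundle$config)
  cfg$states <- NULL
  manifest <- list(config = cfg,
                   states = bundle$states,
                   root_states = as.list(vapply(bundle$truth, `[[`, "",
                                                "root_state")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Write an ontology as a minimal OBO file
#'
#' @param dag A `qs_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2\n", con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i])), con)
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$relation[j] == "is_a")
        writeLines(paste0("is_a: ", e$parent[j]), con)
      else
        writeLines(paste0("relationship: part_of ", e$parent[j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
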