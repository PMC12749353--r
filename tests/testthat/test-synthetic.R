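test_that("Yule simulation: size arithmetic, determinism, depth scaling", {
  tr <- sim_tree(3, 1, seed = 1)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  expect_equal(nrow(tr$edge), 4)
  expect_identical(ape::write.tree(sim_tree(10, 1, seed = 5)),
                   ape::write.tree(sim_tree(10, 1, seed = 5)))
  # branch lengths scale like 1/birth_rate
  set.seed(2)
  len1 <- mean(replicate(40, sum(sim_tree(16, 1)$edge.length)))
  len4 <- mean(replicate(40, sum(sim_tree(16, 4)$edge.length)))
  expect_equal(len1 / len4, 4, tolerance = 0.35)
  expect_error(sim_tree(2), ">= 3")
})

test_that("QS evolution respects rate-zero limits and the ladder direction", {
  tr <- sim_tree(12, 1, seed = 3)
  st <- qs_states()
  frozen <- evolve_qs(tr, st, 0, 0, seed = 1, root_state = "2")
  expect_true(all(frozen$node_states == "2"))
  # pure gains: subunit counts never decrease root-to-tip
  up <- evolve_qs(tr, st, 2, 0, seed = 2, root_state = "1")
  idx <- match(up$node_states, st$state)
  for (e in seq_len(nrow(tr$edge)))
    expect_gte(idx[tr$edge[e, 2]], idx[tr$edge[e, 1]])
  expect_identical(evolve_qs(tr, st, 0.5, 0.2, seed = 9)$tip_states,
                   evolve_qs(tr, st, 0.5, 0.2, seed = 9)$tip_states)
})

test_that("two-state occupation over long branches matches the CTMC closed form", {
  # single branch of length t: P(state 2 | start 1) = g/(g+l) (1 - e^{-(g+l)t})
  g <- 0.6; l <- 0.3; t_len <- 1.4
  tr <- ape::read.tree(text = sprintf("(a:%f,b:0.0001);", t_len))
  st <- qs_states(c(1, 2))
  set.seed(71)
  hits <- replicate(4000, {
    ev <- evolve_qs(tr, st, g, l, root_state = "1")
    ev$tip_states[["a"]] == "2"
  })
  expected <- g / (g + l) * (1 - exp(-(g + l) * t_len))
  expect_equal(mean(hits), expected, tolerance = 0.05)
})

test_that("toy complexes plant exactly the requested interface", {
  set.seed(13)
  for (i in 1:15) {
    n_res <- sample(30:80, 1)
    planted <- sort(sample(n_res, sample(0:12, 1)))
    tc <- gen_toy_complex("P", 2, n_res, planted)
    cls <- classify_residues(tc$sasa)
    found <- paste("A", which(cls$label == "interface"), sep = ":")
    expect_setequal(found, paste("A", planted, sep = ":"))
  }
  # planted sets sharing a fraction of residues give the matching overlap
  a <- gen_toy_complex("a", 2, 40, 1:8, seed = 1)
  b <- gen_toy_complex("b", 2, 40, 5:12, seed = 2)
  map <- identity_alignment_map("a", "b", 40)
  expect_equal(interface_overlap(map, a$planted, b$planted), 4 / 8)
})

test_that("toy-complex interface area equals the summed planted burial", {
  set.seed(17)
  tc <- gen_toy_complex("P", 4, 50, 10:21)
  s <- interface_summary(tc$sasa, "P", 4)
  expect_equal(s$interface_area,
               sum(tc$sasa$sasa_monomer - tc$sasa$sasa_complex))
  expect_setequal(s$interface_residues, tc$planted)
})

test_that("random ontologies are DAGs whose sampler injects redundant ancestors", {
  dag <- gen_ontology(depth = 3, branching = 3, seed = 21)
  expect_s3_class(dag, "qs_ontology")
  leaves <- unlist(dag$leaves)
  expect_true(all(leaves %in% dag$terms$id))
  ann <- sample_annotations(dag, sprintf("p%d", 1:50), mu = 4,
                            ancestor_prob = 1, seed = 2)
  # with certain ancestor injection, some per-protein sets must shrink
  shrunk <- vapply(split(ann$term_id, ann$protein_id), function(s)
    length(filter_redundant_terms(unique(s), dag)) < length(unique(s)),
    logical(1))
  expect_true(any(shrunk))
  none <- sample_annotations(dag, sprintf("p%d", 1:30), mu = 4,
                             ancestor_prob = 0, seed = 3)
  kept <- vapply(split(none$term_id, none$protein_id), function(s)
    length(filter_redundant_terms(unique(s), dag)) == length(unique(s)),
    logical(1))
  expect_true(all(kept))  # leaves form an antichain already
})

test_that("annotation effect size shows up in mean richness", {
  dag <- gen_ontology(depth = 4, branching = 4, seed = 31)
  set.seed(32)
  base <- sample_annotations(dag, sprintf("n%d", 1:400), mu = 4,
                             ancestor_prob = 0)
  boosted <- sample_annotations(dag, sprintf("m%d", 1:400), mu = 6,
                                ancestor_prob = 0)
  r0 <- richness(base, sprintf("n%d", 1:400))
  r1 <- richness(boosted, sprintf("m%d", 1:400))
  expect_equal(r1 / r0, 1.5, tolerance = 0.15)
})

test_that("study bundles are deterministic under the seed and round-trip to disk", {
  cfg <- sim_config(seed = 99, n_orthogroups = 3, tips_min = 6, tips_max = 9)
  b1 <- gen_study(cfg)
  b2 <- gen_study(cfg)
  expect_identical(b1$proteins, b2$proteins)
  expect_identical(lapply(b1$trees, ape::write.tree),
                   lapply(b2$trees, ape::write.tree))
  expect_identical(b1$annotations, b2$annotations)
  dir <- withr::local_tempdir()
  write_study_bundle(b1, dir)
  back <- read_study_bundle(dir)
  expect_setequal(names(back$trees), names(b1$trees))
  expect_equal(nrow(back$proteins), nrow(b1$proteins))
  expect_identical(back$tip_states[["OGM001"]][order(names(back$tip_states[["OGM001"]]))],
                   b1$tip_states[["OGM001"]][order(names(b1$tip_states[["OGM001"]]))])
  expect_s3_class(back$ontology, "qs_ontology")
})

test_that("invalid configurations are rejected before generation", {
  expect_error(sim_config(n_orthogroups = 0))
  expect_error(sim_config(gain_rate = -1))
  expect_error(sim_config(tips_min = 2))
  expect_error(sim_config(interface_size = 100, n_residues = 50))
})
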