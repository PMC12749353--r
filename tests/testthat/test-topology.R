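iface_keys <- function(idx) paste("A", idx, sep = ":")

test_that("interface overlap is the min-normalised aligned-pair fraction", {
  map <- identity_alignment_map("p1", "p2", 20)
  # self-alignment with identical interfaces
  expect_equal(interface_overlap(map, iface_keys(1:6), iface_keys(1:6)), 1)
  # disjoint interfaces never align onto each other
  expect_equal(interface_overlap(map, iface_keys(1:4), iface_keys(10:15)), 0)
  # |A|=4, |B|=6, two aligned interface-interface pairs -> 2/4
  expect_equal(interface_overlap(map, iface_keys(c(1, 2, 18, 19)),
                                 iface_keys(c(1, 2, 5, 6, 7, 8))), 0.5)
  expect_true(is.na(interface_overlap(map, character(0), iface_keys(1:3))))
})

test_that("interface overlap is symmetric", {
  set.seed(11)
  for (i in 1:20) {
    map <- identity_alignment_map("a", "b", 30)
    ia <- iface_keys(sample(30, sample(3:10, 1)))
    ib <- iface_keys(sample(30, sample(3:10, 1)))
    rev_map <- data.frame(protein_a = "b", chain_a = map$chain_b,
                          resid_a = map$resid_b, protein_b = "a",
                          chain_b = map$chain_a, resid_b = map$resid_a)
    expect_identical(interface_overlap(map, ia, ib),
                     interface_overlap(rev_map, ib, ia))
  }
})

test_that("same_topology needs equal subunit counts and overlap >= 0.5", {
  expect_false(same_topology(2, 4, 0.99))
  expect_false(same_topology(2, 2, 0.49))
  expect_true(same_topology(2, 2, 0.5))   # boundary is inclusive
  expect_true(same_topology(1, 1, NA))    # monomers always share a topology
  expect_false(same_topology(2, 2, NA))   # missing overlap: different
  expect_true(same_topology(2, 2, NA, missing_as_same = TRUE))
})

test_that("topology classes are single-linkage components within subunit strata", {
  st <- data.frame(id = c("d1", "d2", "d3"), n_subunits = 2)
  ov <- data.frame(id_a = c("d1", "d2", "d1"), id_b = c("d2", "d3", "d3"),
                   overlap = c(0.9, 0.9, 0.9))
  expect_equal(unique(assign_topologies(st, ov)$topology_class), "d1")
  ov$overlap <- c(0.2, 0.2, 0.2)
  expect_equal(length(unique(assign_topologies(st, ov)$topology_class)), 3)
  # non-transitive closure: A-B and B-C linked, A-C not -> still one class
  ov$overlap <- c(0.6, 0.6, 0.3)
  expect_equal(unique(assign_topologies(st, ov)$topology_class), "d1")
})

test_that("class assignment is invariant to input order and bounded by structure count", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 8
    st <- data.frame(id = sprintf("s%02d", 1:n),
                     n_subunits = sample(c(1, 2, 2, 4), n, replace = TRUE))
    pairs <- t(utils::combn(st$id, 2))
    ov <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                     overlap = runif(nrow(pairs)))
    a1 <- assign_topologies(st, ov)
    perm <- sample(n)
    a2 <- assign_topologies(st[perm, ], ov[sample(nrow(ov)), ])
    m <- match(a1$id, a2$id)
    expect_identical(a1$topology_class, a2$topology_class[m])
    expect_lte(length(unique(a1$topology_class)), n)
  }
  # all overlaps below threshold: one class per multimer plus one monomer class
  st <- data.frame(id = c("a", "b", "c"), n_subunits = 2)
  ov <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                   overlap = 0.1)
  expect_equal(length(unique(assign_topologies(st, ov)$topology_class)), 3)
})

test_that("per-protein QS counts distinguish subunit number and interfaces", {
  one <- data.frame(id = "e1", n_subunits = 2)
  expect_equal(qs_per_protein(one), 1)
  two <- data.frame(id = c("e1", "e2"), n_subunits = c(1, 2))
  expect_equal(qs_per_protein(two), 2)
  dimers <- data.frame(id = c("e1", "e2"), n_subunits = 2)
  ov <- data.frame(id_a = "e1", id_b = "e2", overlap = 0.3)
  expect_equal(qs_per_protein(dimers, ov), 2)
  ov$overlap <- 0.8
  expect_equal(qs_per_protein(dimers, ov), 1)
})

test_that("TM-align output parsing yields sequential aligned residue pairs", {
  txt <- c("(\":\" denotes aligned residue pairs of d < 5.0 A, \".\" denotes other aligned residues)",
           "MKV-LT",
           "::. : ",
           "MKVAL-")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(txt, path)
  map <- parse_tmalign(path, "pA", "pB")
  # columns 1,2 aligned ':', column 3 '.', column 4 gap in A, column 5 ':',
  # column 6 gap in B
  expect_equal(map$resid_a, c(1, 2, 3, 4))
  expect_equal(map$resid_b, c(1, 2, 3, 5))
})
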