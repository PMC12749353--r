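ma <- max_area_table()

toy_table <- function(rsa_mono, burial, types = NULL) {
  n <- length(rsa_mono)
  if (is.null(types)) types <- rep("A", n)
  mono <- rsa_mono * as.numeric(ma[types])
  data.frame(protein_id = "P1", chain_id = "A", residue_index = seq_len(n),
             residue_type = types, sasa_complex = mono * (1 - burial),
             sasa_monomer = mono, stringsAsFactors = FALSE)
}

test_that("RSA is the area ratio against the residue's reference maximum", {
  expect_equal(compute_rsa(0, "W", ma), 0)
  expect_equal(compute_rsa(ma[["G"]], "G", ma), 1)
  expect_equal(compute_rsa(ma[["A"]] / 2, "A", ma), 0.5)
  expect_equal(compute_rsa(2 * ma[["V"]], "V", ma), 2)  # not clamped
  expect_error(compute_rsa(10, "X", ma), "unknown residue")
  expect_error(compute_rsa(-1, "A", ma), "negative")
})

test_that("packaged maximum-area table covers the 20 standard amino acids", {
  expect_setequal(names(ma), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_true(all(ma > 0))
})

test_that("residue classification applies both thresholds with the stated boundaries", {
  tab <- toy_table(rsa_mono = c(0.25, 0.15, 0.30, 0.19),
                   burial = c(0.50, 0.90, 0.05, 0.00))
  cls <- classify_residues(tab, ma)
  # accessible + buried on complexation -> interface
  expect_equal(cls$label[1], "interface")
  # deeply buried residue fails the RSA gate even with 90% burial
  expect_equal(cls$label[2], "buried")
  # accessible but hardly buried -> surface
  expect_equal(cls$label[3], "surface")
  # RSA below 0.2, no burial -> buried
  expect_equal(cls$label[4], "buried")
})

test_that("threshold boundaries: RSA >= 0.2 and burial >= 0.10 are inclusive, surface needs RSA > 0.2", {
  # integer-valued areas against a max of 500 make the ratios exact
  ma500 <- c(A = 500)
  tab <- data.frame(protein_id = "P", chain_id = "A", residue_index = 1:3,
                    residue_type = "A",
                    sasa_monomer = c(100, 100, 100),
                    sasa_complex = c(90, 91, 100),
                    stringsAsFactors = FALSE)
  cls <- classify_residues(tab, ma500)
  expect_equal(cls$rsa, rep(0.2, 3))
  expect_equal(cls$burial_fraction[1], 0.1)
  expect_equal(cls$label[1], "interface")  # both thresholds met exactly
  expect_equal(cls$label[2], "buried")     # burial 9% < 10%; RSA not > 0.2
  expect_equal(cls$label[3], "buried")     # surface requires strict RSA > 0.2
})

test_that("no SASA change means no interface residues", {
  tab <- toy_table(rsa_mono = runif(30, 0.05, 0.9), burial = rep(0, 30))
  cls <- classify_residues(tab, ma)
  expect_false(any(cls$label == "interface"))
})

test_that("negative burial and zero-SASA residues are handled, bad input errors", {
  tab <- toy_table(c(0.5, 0.0), c(0, 0))
  tab$sasa_complex[1] <- tab$sasa_monomer[1] * 1.1  # numerical noise
  cls <- classify_residues(tab, ma)
  expect_equal(cls$burial_fraction[1], 0)
  expect_equal(cls$label[1], "surface")
  expect_equal(cls$label[2], "buried")      # zero monomer SASA, never interface
  expect_error(classify_residues(tab[0, ], ma), "non-empty")
  tab$sasa_monomer[1] <- -5
  expect_error(classify_residues(tab, ma), "negative")
})

test_that("raising either threshold never increases the interface count", {
  set.seed(42)
  tab <- toy_table(runif(200, 0, 1.2), runif(200, 0, 0.6))
  n_iface <- function(r, b)
    sum(classify_residues(tab, ma, rsa_threshold = r, burial_threshold = b)$label == "interface")
  for (r in c(0.1, 0.2, 0.3, 0.5)) {
    expect_true(n_iface(r + 0.1, 0.1) <= n_iface(r, 0.1))
    expect_true(n_iface(0.2, r + 0.1) <= n_iface(0.2, r))
  }
})

test_that("interface area is the per-subunit buried area", {
  expect_equal(interface_area(2 * 10000, 18000, 2), 1000)
  expect_equal(interface_area(15000, 15000, 3), 0)
  expect_equal(interface_area(3 * 5000, 12000, 3), 1000)
  expect_equal(interface_area(100, 150, 2), 0)  # noise clamped
  expect_error(interface_area(100, 50, 0), "n_subunits")
})

test_that("interface summary is order- and relabel-invariant; monomers empty", {
  set.seed(7)
  tc <- gen_toy_complex("P1", 2, 40, planted_interface = c(3, 7, 11))
  s1 <- interface_summary(tc$sasa, "P1", 2)
  shuf <- tc$sasa[sample(nrow(tc$sasa)), ]
  s2 <- interface_summary(shuf, "P1", 2)
  expect_equal(s1$interface_area, s2$interface_area)
  expect_setequal(s1$interface_residues, s2$interface_residues)
  relab <- tc$sasa
  relab$chain_id <- "B"
  s3 <- interface_summary(relab, "P1", 2)
  expect_equal(s3$interface_area, s1$interface_area)
  mono <- interface_summary(tc$sasa, "P1", 1)
  expect_equal(mono$interface_area, 0)
  expect_length(mono$interface_residues, 0)
})

test_that("conservation difference is interface mean minus surface mean", {
  tab <- toy_table(rsa_mono = c(0.4, 0.4, 0.4), burial = c(0.5, 0.5, 0.0))
  cls <- classify_residues(tab, ma)
  cons <- c("A:1" = 0.5, "A:2" = 1.5, "A:3" = 1.0)
  expect_equal(conservation_difference(cls, cons), 0.0)
  cons2 <- c("A:1" = 1, "A:2" = 1, "A:3" = 0)
  expect_equal(conservation_difference(cls, cons2), 1.0)
  expect_equal(conservation_difference(cls, cons + 2), 0.0)  # constant shift
  # empty surface set -> missing, not an error
  tab2 <- toy_table(rsa_mono = c(0.4, 0.1), burial = c(0.5, 0))
  cls2 <- classify_residues(tab2, ma)
  expect_true(is.na(conservation_difference(cls2, cons)))
  expect_error(conservation_difference(cls, cons[1:2]), "missing")
})

test_that("SASA tables round-trip through TSV", {
  set.seed(1)
  tc <- gen_toy_complex("P9", 4, 25, planted_interface = 1:5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sasa_table(tc$sasa, path)
  back <- read_sasa_table(path)
  expect_equal(back$sasa_monomer, tc$sasa$sasa_monomer, tolerance = 1e-12)
  expect_equal(back$residue_type, tc$sasa$residue_type)
})
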