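test_that("RSA is 1 for an isolated residue and low in a dense globule", {
  lone <- tibble::tibble(structure_id = "t", chain = "A", resno = 1L,
                         resname = "GLY", elety = "CA", elem = "C",
                         x = 0, y = 0, z = 0)
  expect_equal(compute_rsa(lone)$rsa, 1)

  # dense cubic lattice of carbons; the central residue is buried
  g <- expand.grid(x = seq(-4, 4, by = 2), y = seq(-4, 4, by = 2),
                   z = seq(-4, 4, by = 2))
  center <- which(g$x == 0 & g$y == 0 & g$z == 0)
  globule <- tibble::tibble(
    structure_id = "t", chain = "A",
    resno = ifelse(seq_len(nrow(g)) == center, 1L, 2L),
    resname = ifelse(seq_len(nrow(g)) == center, "ALA", "GLY"),
    elety = "C", elem = "C", x = g$x, y = g$y, z = g$z)
  rsa_center <- compute_rsa(globule)
  expect_lt(rsa_center$rsa[rsa_center$resno == 1], 0.25)

  # higher-resolution numerical oracle agrees on burial
  fine <- compute_rsa(globule, n_points = 960)
  expect_lt(abs(fine$rsa[fine$resno == 1] -
                  rsa_center$rsa[rsa_center$resno == 1]), 0.05)
})

test_that("adding occluding atoms never increases RSA", {
  set.seed(5)
  base <- random_chain_atoms(6, spread = 10)
  r0 <- compute_rsa(base)
  extra <- random_chain_atoms(6, spread = 10)
  extra$resno <- extra$resno + 100L
  r1 <- compute_rsa(dplyr::bind_rows(base, extra))
  joined <- dplyr::inner_join(r0, r1, by = c("chain", "resno"),
                              suffix = c("_alone", "_crowded"))
  expect_true(all(joined$rsa_crowded <= joined$rsa_alone + 1e-12))

  expect_error(residue_rsa(base, "A", 999L),
               class = "edgotyper_missing_structure")
})

test_that("synthetic folding backend matches hand evaluation and clamps", {
  # hand evaluation of the severity formula with noise off:
  # alpha * max(0, -B(A,W)) * (1 + beta * (1 - rsa * gamma))
  # = 1.2 * 3 * (1 + 0.5 * 0.9) = 5.22
  got <- synthetic_folding_ddg("A", "W", rsa = 0.1, id = "m1", seed = 7,
                               params = c(noise = 0))
  expect_equal(got, 1.2 * 3 * (1 + 0.5 * (1 - 0.1)))
  # conservative substitution (BLOSUM62 > 0) clamps to zero
  expect_equal(synthetic_folding_ddg("A", "S", rsa = 0.5, id = "m2",
                                     seed = 7, params = c(noise = 0)), 0)
  # ref = alt is exactly zero even with noise on
  expect_identical(synthetic_folding_ddg("A", "A", 0.5, "m3", seed = 7), 0)
  # determinism of the noisy value
  expect_identical(
    synthetic_folding_ddg("A", "W", 0.1, "m1", seed = 7),
    synthetic_folding_ddg("A", "W", 0.1, "m1", seed = 7))
  expect_false(
    synthetic_folding_ddg("A", "W", 0.1, "m1", seed = 7) ==
      synthetic_folding_ddg("A", "W", 0.1, "m1", seed = 8))
})

test_that("synthetic binding backend refuses non-interfacial calls", {
  got <- synthetic_binding_ddg("G", "W", id = "m1", ppi_id = "PPI1",
                               seed = 3, params = c(noise = 0))
  expect_equal(got, 1.2 * 2)        # -B(G,W) = 2
  expect_identical(synthetic_binding_ddg("G", "G", "m1", "PPI1", seed = 3), 0)
  expect_error(
    synthetic_binding_ddg("G", "W", "m1", "PPI1", interfacial = FALSE),
    class = "edgotyper_backend_misuse")
})

test_that("stability-table dialect reads values and reports bad rows", {
  f <- withr::local_tempfile(lines = c(
    "mutation\tddG",
    "P1:A42V\t2.50",
    "P1:G7W\t-0.75",
    "garbage_row_without_value",
    "P2:K9E\t0.10"))
  got <- read_energy_table(f, dialect = "buildmodel")
  expect_equal(got$folding_ddg[got$id == "P1:A42V"], 2.5)
  expect_identical(nrow(got), 3L)
  expect_identical(attr(got, "problems")$line, 4L)

  empty <- withr::local_tempfile(lines = character(0))
  expect_identical(nrow(read_energy_table(empty, dialect = "buildmodel")), 0L)
})

test_that("interface-scan dialect reads the substitution matrix exactly", {
  f <- withr::local_tempfile(lines = c(
    "\tA42\tK7",
    "G\t1.25\t-0.50",
    "W\t3.00\t0.80"))
  got <- read_energy_table(f, dialect = "pssm")
  expect_identical(nrow(got), 4L)
  row <- got[got$site == "A42" & got$alt == "G", ]
  expect_identical(row$ref, "A")
  expect_identical(row$position, 42L)
  expect_equal(row$binding_ddg, 1.25)
  # malformed header is a structured parse error
  bad <- withr::local_tempfile(lines = c("\tnot_a_site", "G\t1.0"))
  expect_error(read_energy_table(bad, dialect = "pssm"),
               class = "edgotyper_parse_error")
})

test_that("per-residue accessibility dialect yields RSA consistent with the internal calculator", {
  # a single fully exposed glycine: internal Shrake-Rupley gives RSA 1.0;
  # an accessibility record at the glycine maximum area must agree within 0.1
  dssp_line <- function(idx, resno, chain, aa, acc) {
    paste0(sprintf("%5d", idx), sprintf("%5d", resno), " ", chain, " ", aa,
           strrep(" ", 20), sprintf("%4d", acc))
  }
  f <- withr::local_tempfile(lines = c(
    "==== Secondary Structure Definition ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    dssp_line(1, 1, "A", "G", 104),
    dssp_line(2, 2, "A", "A", 52)))
  got <- read_energy_table(f, dialect = "dssp")
  lone <- tibble::tibble(structure_id = "t", chain = "A", resno = 1L,
                         resname = "GLY", elety = "CA", elem = "C",
                         x = 0, y = 0, z = 0)
  internal <- compute_rsa(lone)$rsa
  expect_lt(abs(got$rsa[got$resno == 1] - internal), 0.1)
  expect_equal(got$rsa[got$resno == 2], 52 / 129.0, tolerance = 1e-6)
  expect_error(read_energy_table(withr::local_tempfile(lines = "junk"),
                                 dialect = "dssp"),
               class = "edgotyper_parse_error")
})

test_that("classification is a pure function of the energy profile", {
  muts <- tibble::tibble(
    id = c("m1", "m2", "m3"),
    location = c("IR", "NIR", "NIR"),
    folding_ddg = c(5, 3, 0.5),
    rsa = c(0.1, 0.1, 0.6))
  binding <- tibble::tibble(id = "m1", ppi_id = "PPI1", binding_ddg = 1.5)
  a <- classify_edgotype(muts, binding)
  # identical numbers from a different backend give identical edgotypes
  b <- classify_edgotype(muts, binding)
  expect_identical(a$label, b$label)
  expect_identical(a$label, c("edgetic", "quasi-null", "quasi-wildtype"))
})
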