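test_that("binomial fractions match hand arithmetic and a bootstrap oracle", {
  expect_equal(fraction_with_se(0, 50)$fraction, 0)
  expect_equal(fraction_with_se(0, 50)$se, 0)
  got <- fraction_with_se(20, 1000)
  expect_equal(got$fraction, 0.02)
  expect_equal(got$se, sqrt(0.02 * 0.98 / 1000))
  expect_true(fraction_with_se(0, 0)$undefined)

  # bootstrap oracle: resample a 50/500 success vector
  set.seed(99)
  x <- c(rep(1, 50), rep(0, 450))
  boots <- replicate(10000, mean(sample(x, replace = TRUE)))
  analytic <- fraction_with_se(50, 500)$se
  expect_lt(abs(analytic - sd(boots)) / analytic, 0.1)
})

test_that("fold difference reproduces ratio arithmetic and flags degenerate input", {
  expect_equal(fold_difference(f_case = 0.2, f_control = 0.2)$fd, 1)
  fd <- fold_difference(k_case = 30, n_case = 100, k_control = 10,
                        n_control = 200)
  expect_equal(fd$fd, 0.3 / 0.05)
  # delta-method SE
  se_case <- sqrt(0.3 * 0.7 / 100); se_ctrl <- sqrt(0.05 * 0.95 / 200)
  expect_equal(fd$se, 6 * sqrt((se_case / 0.3)^2 + (se_ctrl / 0.05)^2))
  expect_true(fold_difference(k_case = 5, n_case = 10, k_control = 0,
                              n_control = 10)$undefined)
  td <- tidy(fd)
  expect_identical(nrow(td), 1L)
  expect_equal(td$fd, fd$fd)
  expect_equal(glance(fd)$conf_level, 0.95)
})

test_that("folding-threshold sweep matches hand counting and flags undefined points", {
  case <- tibble::tibble(folding_ddg = c(1.5, 3, 5), rsa = 0.1)
  control <- tibble::tibble(folding_ddg = c(1.5, 1.5, 3), rsa = 0.1)
  sw <- ddg_sweep(case, control, thresholds = c(1, 2, 4),
                  definition = "ddg_only")
  # t=1: (3/3)/(3/3)=1; t=2: (2/3)/(1/3)=2; t=4: control count 0, undefined
  expect_equal(sw$profile$fd[1:2], c(1, 2))
  expect_true(is.na(sw$profile$fd[3]))
  expect_identical(sw$profile$k_case, c(3L, 2L, 1L))
  # numerator counts never increase with the threshold
  expect_true(all(diff(sw$profile$k_case) <= 0))
  expect_true(all(diff(sw$profile$k_control) <= 0))
  # OLS over the two defined points: slope 1, intercept 0
  expect_equal(sw$slope, 1)
  expect_equal(sw$intercept, 0)
  expect_identical(glance(sw)$n_points, 2L)

  # all-undefined grid omits the fit
  sw_na <- ddg_sweep(case, control, thresholds = c(10, 20),
                     definition = "ddg_only")
  expect_true(is.na(sw_na$slope))

  # null configuration: identical distributions give slope ~ 0
  set.seed(17)
  x <- tibble::tibble(folding_ddg = rlnorm(10000, 0.5, 1.2), rsa = 0.1)
  y <- tibble::tibble(folding_ddg = rlnorm(10000, 0.5, 1.2), rsa = 0.1)
  sw0 <- ddg_sweep(x, y, thresholds = 1:20, definition = "ddg_only")
  fit <- lm(fd ~ threshold, data = sw0$profile[is.finite(sw0$profile$fd), ])
  expect_lt(abs(coef(fit)[2]), 3 * summary(fit)$coefficients[2, 2] + 0.01)
})

test_that("RSA sweep respects its definitions and monotone numerators", {
  case <- tibble::tibble(folding_ddg = c(3, 3, 1, 1),
                         rsa = c(0.1, 0.5, 0.1, 0.9))
  control <- case
  sw <- rsa_sweep(case, control, cutoffs = c(1, 0.5, 0.2),
                  definition = "rsa_only")
  # identical sets: every defined point is exactly 1
  expect_true(all(sw$profile$fd == 1))
  expect_identical(sw$profile$k_case, c(4L, 3L, 2L))
  expect_true(all(diff(sw$profile$k_case) <= 0))
  sw2 <- rsa_sweep(case, control, cutoffs = c(1, 0.2),
                   definition = "rsa_ddg")
  # burial AND instability: hand count {3,.1},{3,.5} then {3,.1}
  expect_identical(sw2$profile$k_case, c(2L, 1L))
})

test_that("allele-frequency bins follow the half-open boundaries", {
  got <- af_bin(c(0.0005, 0.001, 0.0099, 0.01, 0.05, 0.1, 0.3426, NA))
  expect_identical(as.character(got),
                   c("<0.1%", "0.1%-1.0%", "0.1%-1.0%", "1.0%-10.0%",
                     "1.0%-10.0%", ">10.0%", ">10.0%", NA))
})

test_that("AF fraction profile tallies a hand-binned toy and flags empty bins", {
  calls <- tibble::tibble(
    class = c(rep("missense", 8), rep("nonsense", 4)),
    label = c("quasi-null", "quasi-wildtype", "quasi-null", "edgetic",
              "quasi-wildtype", "quasi-null", "quasi-wildtype",
              "quasi-wildtype", rep(NA, 4)),
    af = c(5e-4, 5e-4, 5e-3, 5e-3, 0.05, 0.05, 0.2, 0.2,
           5e-4, 5e-3, 5e-3, 0.2))
  prof <- af_fraction_profile(calls)$bins
  qn <- prof[prof$type == "quasi_null", ]
  # hand tally: bin1 1/2, bin2 1/2, bin3 1/2, bin4 0/2
  expect_equal(qn$fraction, c(0.5, 0.5, 0.5, 0))
  ns <- prof[prof$type == "nonsense", ]
  # nonsense among nonsynonymous: 1/3, 2/4, 0/2, 1/3
  expect_equal(ns$k, c(1, 2, 0, 1))
  expect_equal(ns$n, c(3, 4, 2, 3))
  # per-bin counts sum to totals
  expect_equal(sum(ns$n), sum(!is.na(calls$af)))

  # single-bin input leaves the others empty and flagged
  one <- af_fraction_profile(tibble::tibble(class = "missense",
                                            label = "quasi-null",
                                            af = 0.5))$bins
  expect_true(all(one$undefined[one$bin != ">10.0%"]))
})

test_that("positional windows use the ceiling rule", {
  muts <- tibble::tibble(
    canonical_pos = c(1L, 5L, 6L, 4L, 5L, 7L),
    protein_length = c(10L, 10L, 10L, 7L, 7L, 7L),
    cohort = "case", type = "quasi_null")
  out <- position_distribution(muts, window = "half")
  # L=10: first half is 1..5; L=7: first half is 1..4 (ceiling), last 5..7
  expect_identical(out$n_first, 3L)
  expect_identical(out$n_last, 3L)
  expect_equal(out$pct_first + out$pct_last, 100)
  t5 <- position_distribution(tibble::tibble(
    canonical_pos = c(1L, 5L, 96L, 50L), protein_length = 100L,
    cohort = "case", type = "nonsense"), window = "tail5")
  expect_identical(t5$n_first, 2L)   # positions 1..5
  expect_identical(t5$n_last, 1L)    # positions 96..100
})

test_that("coverage-ratio bins, fold differences and length ratios match hand computation", {
  # 20 mutations with hand-assigned coverage ratios
  muts <- tibble::tibble(
    cohort = rep(c("case", "control"), each = 10),
    type = "quasi_null",
    model_length = c(rep(20, 5), rep(100, 5), rep(20, 8), rep(100, 2)),
    protein_length = 100L,
    source_length = 100L,
    folding_ddg = rep(c(4, 2), 10))
  cc <- coverage_confounder(muts)
  bin1 <- cc$bins[cc$bins$bin == "(0,0.2]", ]
  # r = 0.2 falls in the right-closed lowest bin: case 5/10 vs control 8/10
  expect_equal(bin1$fd, (5 / 10) / (8 / 10))
  expect_identical(bin1$k_case, 5L)
  bin5 <- cc$bins[cc$bins$bin == "(0.8,1]", ]
  expect_equal(bin5$fd, (5 / 10) / (2 / 10))
  # identical canonical/source lengths: those ratio summaries are exactly 1
  r <- cc$ratios
  expect_equal(r$mean[r$ratio == "canonical_over_source"], 1)
  expect_equal(r$median[r$ratio == "source_over_canonical"], 1)
  expect_equal(r$mode[r$ratio == "canonical_over_source"], 1)
  # per-bin counts sum to totals
  expect_equal(sum(cc$bins$k_case), 10)
})

test_that("mean substitution score decreases with disruptive classes on programmed catalogs", {
  expect_equal(
    mean_blosum_by_edgotype(tibble::tibble(ref = "A", alt = "S",
                                           label = "quasi-wildtype"))$
      mean_blosum62[1], 1)
  empty <- mean_blosum_by_edgotype(tibble::tibble(ref = character(0),
                                                  alt = character(0),
                                                  label = character(0)))
  expect_identical(empty$n, c(0L, 0L, 0L))
  expect_true(all(is.na(empty$mean_blosum62)))

  # severity-linked synthetic backend: quasi-wildtype calls are more
  # conservative on average than quasi-null calls
  run <- run_pipeline(synthetic_config(n_proteins = 20, n_ppis = 12,
                                       n_case_mut = 2500,
                                       n_control_mut = 2500, seed = 31),
                      backend = "synthetic")
  mb <- mean_blosum_by_edgotype(run$calls[run$calls$class == "missense", ])
  expect_gt(mb$mean_blosum62[mb$label == "quasi-wildtype"],
            mb$mean_blosum62[mb$label == "quasi-null"])
})

test_that("stratified fold differences pool correctly and respect partitions", {
  calls <- tibble::tibble(
    si = rep(c("si1", "si2"), each = 8),
    cohort = rep(rep(c("case", "control"), each = 4), 2),
    class = "missense",
    label = rep(c("quasi-null", "quasi-wildtype"), 8),
    canonical_acc = rep(c("P1", "P2"), 8),
    canonical_pos = 1:16,            # distinct sites per SI: no dedup overlap
    ref = "A", alt = "V")
  out <- stratified_fold_difference(
    calls, categories = list(group = c("P1", "P2")), type = "quasi_null")
  per_si <- out[out$si != "overall", ]
  expect_true(all(per_si$fd == 1))
  pooled <- out[out$si == "overall", ]
  expect_equal(pooled$fd, 1)
  expect_identical(pooled$n_case, 8L)

  # pooling dedups shared records across SIs
  calls2 <- calls
  calls2$canonical_pos[9:16] <- 1:8   # same sites: si2 duplicates si1
  out2 <- stratified_fold_difference(
    calls2, categories = list(group = c("P1", "P2")), type = "quasi_null")
  expect_identical(out2$n_case[out2$si == "overall"], 4L)

  # a category holding no proteins yields an undefined, flagged FD
  out3 <- stratified_fold_difference(
    calls, categories = list(none = "P99"), type = "quasi_null")
  expect_true(all(out3$undefined))

  # partition consistency: union of a partition equals the unstratified FD
  unstrat <- stratified_fold_difference(
    calls, categories = list(all = c("P1", "P2")))
  by_parts <- stratified_fold_difference(
    calls, categories = list(p1 = "P1", p2 = "P2"))
  ksum <- sum(by_parts$k_case[by_parts$si == "overall"])
  expect_identical(ksum, unstrat$k_case[unstrat$si == "overall"])
})

test_that("edgetic category splits on the disrupted edges' labels", {
  calls <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    label = c("edgetic", "edgetic", "edgetic", "quasi-null"),
    disrupted_ppis = list("PPI1", c("PPI1", "PPI2"), "PPI9", character(0)))
  edge_labels <- tibble::tibble(ppi_id = c("PPI1", "PPI2"),
                                edge_class = c("transient", "permanent"))
  out <- categorize_edgetic(calls, edge_labels)
  expect_identical(out$edgetic_category, c("E1", "E3", "E3", NA))
})
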