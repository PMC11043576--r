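test_that("duplicate collapsing averages concordant pairs and drops discordant ones", {
  values <- matrix(c(24.0, 24.4,
                     24.0, 26.0,
                     30.0, 30.0,
                     25.0, NA), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("m", 1:4), c("S1_A", "S1_B")))
  ct <- ct_matrix(values, pairs = data.frame(sample_id = "S1", col_a = "S1_A",
                                             col_b = "S1_B"))
  out <- collapse_duplicates(ct, max_discordance = 1.0)
  expect_equal(unname(out$values[, "S1"]), c(24.2, NA, 30.0, 25.0))
  expect_null(out$pairs)
  expect_error(collapse_duplicates(out), "no duplicate pairing")
})

test_that("Ct QC excludes values strictly above the cutoff and unusable miRNAs", {
  values <- matrix(c(34.5, 33.0, 20.0, 21.0, 22.0,
                     34.0, 33.5, 25.0, 26.0, 24.0,
                     35.0, 36.0, 35.5, 20.0, 21.0),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("m", 1:3), paste0("S", 1:5)))
  res <- qc_filter(ct_matrix(values), ct_max = 34, max_missing_fraction = 0.5)
  expect_true(is.na(res$ct$values["m1", "S1"]))     # 34.5 > 34 -> missing
  expect_equal(res$ct$values["m2", "S1"], 34.0)     # exactly 34 retained
  expect_equal(res$report$dropped, "m3")            # 60% missing -> dropped
  expect_equal(nrow(res$ct$values), 2)
  all_high <- ct_matrix(matrix(39, 2, 3,
                               dimnames = list(c("a", "b"), paste0("S", 1:3))))
  expect_error(qc_filter(all_high), "nothing to analyze")
})

test_that("imputation fills cell means and never alters observed values", {
  cohort <- tiny_cohort(3, 3)
  # cases S01-S03 (hormone T,F,T), controls S04-S06 (F,T,F)
  values <- matrix(c(20, NA, 22, 25, 26, 27,
                     10, 11, 12, 13, 14, 15), nrow = 2, byrow = TRUE,
                   dimnames = list(c("m1", "m2"), cohort$sample_id))
  out <- suppressWarnings(impute_missing(ct_matrix(values), cohort))
  # S02 is the only non-hormone case -> empty cell -> grand-mean fallback
  expect_equal(suppressWarnings(
    impute_missing(ct_matrix(values), cohort))$values["m1", "S02"],
    mean(c(20, 22, 25, 26, 27)))
  expect_equal(out$values[2, ], values[2, ])

  same_cell <- cohort_table(data.frame(
    sample_id = paste0("S", 1:3), group = "case",
    hormone_use = TRUE, age = 18))
  v2 <- matrix(c(20, 22, NA), 1, dimnames = list("m1", paste0("S", 1:3)))
  expect_equal(impute_missing(ct_matrix(v2), same_cell)$values[1, "S3"], 21)

  no_miss <- ct_matrix(values[2, , drop = FALSE])
  expect_identical(impute_missing(no_miss, cohort)$values, no_miss$values)

  all_na <- matrix(NA_real_, 1, 3, dimnames = list("m1", paste0("S", 1:3)))
  expect_error(impute_missing(ct_matrix(all_na), same_cell), "no observed")
})

test_that("global normalization centers samples and ignores loading shifts", {
  v <- matrix(c(20, 22, 24), 3, 1, dimnames = list(paste0("m", 1:3), "S1"))
  expect_equal(unname(global_normalize(ct_matrix(v))$values[, 1]), c(-2, 0, 2))
  const <- matrix(5, 3, 2, dimnames = list(paste0("m", 1:3), c("S1", "S2")))
  expect_true(all(global_normalize(ct_matrix(const))$values == 0))
  # metamorphic: shifting one whole sample column changes nothing
  set.seed(1)
  m <- matrix(runif(40, 18, 30), 8, 5,
              dimnames = list(paste0("m", 1:8), paste0("S", 1:5)))
  base <- global_normalize(ct_matrix(m))$values
  m2 <- m; m2[, 3] <- m2[, 3] + 1.7
  expect_equal(global_normalize(ct_matrix(m2))$values, base)
  expect_equal(max(abs(colMeans(base))), 0, tolerance = 1e-12)
})

test_that("2^-ddCt fold changes follow the signed convention", {
  # case delta-Ct {4, 5}, control {6, 7} -> ddCt = -2 -> signed FC +4
  v <- matrix(c(4, 5, 6, 7), 1, 4,
              dimnames = list("m1", paste0("S", 1:4)))
  expr <- normalized_expr(v)
  fc <- ddct_fold_change(expr, c("S1", "S2"), c("S3", "S4"))
  expect_equal(unname(fc$ddct), -2)
  expect_equal(unname(fc$fold_change), 4)
  # ddCt = 0 -> 1 ; ddCt = +1 -> -2
  v0 <- matrix(c(3, 3), 1, 2, dimnames = list("m", c("a", "b")))
  expect_equal(unname(ddct_fold_change(normalized_expr(v0), "a", "b")$fold_change), 1)
  v1 <- matrix(c(4, 3), 1, 2, dimnames = list("m", c("a", "b")))
  expect_equal(unname(ddct_fold_change(normalized_expr(v1), "a", "b")$fold_change), -2)
})

test_that("signed fold changes have magnitude >= 1 and flip under group swap", {
  set.seed(7)
  for (i in 1:10) {
    v <- matrix(rnorm(24), 3, 8,
                dimnames = list(paste0("m", 1:3), paste0("S", 1:8)))
    expr <- normalized_expr(v)
    cases <- paste0("S", 1:4); controls <- paste0("S", 5:8)
    fwd <- ddct_fold_change(expr, cases, controls)$fold_change
    rev <- ddct_fold_change(expr, controls, cases)$fold_change
    expect_true(all(abs(fwd) >= 1))
    expect_equal(fwd, -rev)
  }
})

test_that("planted log2 effects are recovered exactly without noise", {
  cohort <- tiny_cohort(6, 6)
  eff <- effect_spec(c("miR-sim-0001", "miR-sim-0002"), c("both", "both"),
                     c(1.5, -2))
  truth <- simulation_truth(effects = eff, noise_sd_ct = 0, duplicate_sd = 0,
                            missing_rate = 0, global_shift_sd = 0,
                            reference_sd = 0)
  ct <- collapse_duplicates(simulate_ct_matrix(cohort, truth, 15L, seed = 2L))
  expr <- global_normalize(ct)
  expr$reference_set <- truth$reference_mirnas
  fc <- ddct_fold_change(expr, cohort$sample_id[cohort$group == "case"],
                         cohort$sample_id[cohort$group == "control"])
  expect_equal(unname(fc$fold_change["miR-sim-0001"]), 2^1.5)
  expect_equal(unname(fc$fold_change["miR-sim-0002"]), -2^2)
})

test_that("pooled t-test kernel matches the hand formula and permutation oracle", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("m1", paste0("S", 1:6)))
  res <- endomiR:::row_ttests(v, 1:3, 4:6)
  # hand evaluation: sp^2 = 1, t = -3/sqrt(2/3) = -3.674, df = 4
  expect_equal(unname(res$p), 0.02131164, tolerance = 1e-6)
  expect_equal(unname(res$mean_diff), -3)
  # exact permutation over all 20 assignments: only the 2 most extreme
  # splits reach |t| = 3.674, so the permutation p-value is 2/20
  z <- c(1, 2, 3, 4, 5, 6)
  perm_t <- apply(utils::combn(6, 3), 2, function(i) {
    a <- z[i]; b <- z[-i]
    sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
    (mean(a) - mean(b)) / sqrt(sp2 * 2 / 3)
  })
  expect_equal(mean(abs(perm_t) >= 3.674), 2 / 20)
})

test_that("stratified t-tests are symmetric and null-calibrated", {
  cohort <- tiny_cohort(6, 6)
  set.seed(3)
  v <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("m", 1:5), cohort$sample_id))
  expr <- normalized_expr(v)
  res <- stratified_ttests(expr, cohort)
  expect_true(all(res$p_hormone >= 0 & res$p_hormone <= 1))
  # swapping case/control labels flips fold-change sign, p unchanged
  swapped <- cohort
  swapped$group <- ifelse(cohort$group == "case", "control", "case")
  res_sw <- stratified_ttests(expr, cohort_table(as.data.frame(swapped)))
  expect_equal(res_sw$p_hormone, res$p_hormone)
  expect_equal(res_sw$fc_hormone, -res$fc_hormone)
  # identical groups -> t = 0, p = 1
  v_eq <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 1), 1, 6,
                 dimnames = list("m1", paste0("S", 1:6)))
  eq <- endomiR:::row_ttests(v_eq, 1:3, 4:6)
  expect_equal(unname(eq$p), 1)
})

test_that("the dual-threshold inclusion rule fires the right clause", {
  res <- discovery_selection_rule(
    p_hormone = c(0.007, 0.02, 0.2, NA, 0.0001),
    p_nonhormone = c(0.04, 0.004, 0.2, NA, NA))
  expect_equal(res$included, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$inclusion_reason,
               c("both_strata_p05", "either_stratum_p005", "none", "none",
                 "either_stratum_p005"))
  expect_error(discovery_selection_rule(1.2, 0.5), "0, 1")
})

test_that("panel assembly preserves categories and rejects overlaps", {
  panel <- assemble_panel(sprintf("d%02d", 1:49), sprintf("l%d", 1:8),
                          sprintf("p%d", 1:3), sprintf("n%d", 1:3))
  expect_equal(nrow(panel), 63)
  expect_equal(unname(table(panel$category)["discovery"]), 49L)
  expect_equal(assemble_panel(c("a", "b"))$probe_id, c("a", "b"))
  expect_error(assemble_panel(c("a", "b"), literature_additions = "a"),
               "more than one category")
})

test_that("outlier flagging removes a gross singleton and spares clean data", {
  v <- matrix(c(20, 20.1, 19.9, 20.2, 35,
                20, 20.1, 19.9, 20.2, 20.1), 2, 5, byrow = TRUE,
              dimnames = list(c("m1", "m2"), paste0("S", 1:5)))
  out <- flag_outliers(ct_matrix(v), groups = rep("case", 5), alpha = 0.05)
  expect_true(is.na(out$values["m1", "S5"]))
  expect_equal(sum(is.na(out$values["m2", ])), 0)
})
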