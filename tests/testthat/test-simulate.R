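test_that("simulated cohorts have the requested shape and are deterministic", {
  cohort <- simulate_cohort(54L, 2L, 0.78, c(13L, 25L), seed = 1L)
  expect_equal(nrow(cohort), 162)
  expect_equal(sum(cohort$group == "case"), 54)
  expect_true(all(cohort$age >= 13 & cohort$age <= 25))
  again <- simulate_cohort(54L, 2L, 0.78, c(13L, 25L), seed = 1L)
  expect_identical(as.data.frame(cohort), as.data.frame(again))

  tiny <- simulate_cohort(1L, 1L, 0.0, c(18L, 18L), seed = 2L)
  expect_equal(nrow(tiny), 2)
  expect_false(any(tiny$hormone_use))
})

test_that("zero-noise zero-effect Ct matrices are exactly null", {
  cohort <- tiny_cohort(4, 4)
  ct <- simulate_ct_matrix(cohort, null_truth(noise = FALSE),
                           n_mirnas = 20L, seed = 1L)
  collapsed <- collapse_duplicates(ct)
  delta <- global_normalize(ct_matrix(collapsed$values))$values
  is_case <- cohort$group == "case"
  diff <- rowMeans(delta[, is_case]) - rowMeans(delta[, !is_case])
  expect_equal(max(abs(diff)), 0)
})

test_that("planted effects appear in the right stratum with the stated size", {
  cohort <- tiny_cohort(6, 6)
  eff <- effect_spec("miR-sim-0001", "both", 2)
  truth <- simulation_truth(effects = eff, noise_sd_ct = 0, duplicate_sd = 0,
                            missing_rate = 0, global_shift_sd = 0,
                            reference_sd = 0)
  ct <- collapse_duplicates(simulate_ct_matrix(cohort, truth, 12L, seed = 1L))
  v <- ct$values["miR-sim-0001", ]
  is_case <- cohort$group == "case"
  # planted +2 on the expression scale lowers case Ct by exactly 2 cycles
  expect_equal(mean(v[is_case]) - mean(v[!is_case]), -2)

  eff_h <- effect_spec("miR-sim-0001", "hormone", 2)
  truth_h <- simulation_truth(effects = eff_h, noise_sd_ct = 0,
                              duplicate_sd = 0, missing_rate = 0,
                              global_shift_sd = 0, reference_sd = 0)
  ct_h <- collapse_duplicates(simulate_ct_matrix(cohort, truth_h, 12L, seed = 1L))
  vh <- ct_h$values["miR-sim-0001", ]
  non_users <- !cohort$hormone_use
  expect_equal(mean(vh[is_case & non_users]) - mean(vh[!is_case & non_users]), 0)
  users <- cohort$hormone_use
  expect_equal(mean(vh[is_case & users]) - mean(vh[!is_case & users]), -2)
})

test_that("MFI simulation produces the expected well layout", {
  cohort <- simulate_cohort(54L, 2L, 0.78, seed = 4L)
  panel <- sprintf("p%02d", 1:10)
  mfi <- simulate_mfi_matrix(cohort, null_truth(), panel,
                             blank_wells = 3L, qc_fraction = 0.05, seed = 9L)
  expect_equal(sum(mfi$well_role == "qc_pool"), 8)  # round(0.05 * 162)
  expect_equal(sum(mfi$well_role == "blank"), 3)
  expect_equal(sum(mfi$well_role == "study"), 162)
  # no negatives without background probes or injection
  expect_true(all(mfi$values[, mfi$well_role == "study"] > 0))

  bg <- simulate_mfi_matrix(cohort, null_truth(), panel,
                            background_probes = "p01", seed = 9L)
  expect_true(any(bg$values["p01", bg$well_role == "study"] < 0))

  quiet <- simulate_mfi_matrix(tiny_cohort(3, 3), null_truth(noise = FALSE),
                               panel, blank_wells = 0L, qc_fraction = 0,
                               seed = 2L)
  expect_equal(apply(quiet$values, 1, stats::sd), rep(0, 10),
               ignore_attr = TRUE)
})

test_that("recovery reports count hits and false selections", {
  truth <- simulation_truth()
  planted <- truth$effects$mirna_id
  expect_equal(recovery_report(planted, truth)$recall, 1)
  expect_equal(recovery_report(planted, truth)$n_false, 0)
  expect_equal(recovery_report(c("x", "y"), truth)$recall, 0)
  extra <- recovery_report(c(planted, "x"), truth)
  expect_equal(extra$recall, 1)
  expect_equal(extra$n_false, 1)
})

test_that("expression matrices round-trip through TSV", {
  cohort <- tiny_cohort(3, 3)
  ct <- simulate_ct_matrix(cohort, simulation_truth(), 10L, seed = 5L)
  path <- tempfile(fileext = ".tsv")
  write_expr_tsv(ct, path)
  back <- read_expr_tsv(path, type = "ct")
  expect_equal(back$values, ct$values)
  expect_equal(back$pairs, ct$pairs)

  mfi <- simulate_mfi_matrix(cohort, simulation_truth(), sprintf("p%d", 1:4),
                             seed = 6L)
  path2 <- tempfile(fileext = ".tsv")
  write_expr_tsv(mfi, path2)
  back2 <- read_expr_tsv(path2, type = "mfi")
  expect_equal(back2$values, mfi$values)
  expect_identical(back2$well_role, mfi$well_role)
})

test_that("generators are pure functions of parameters and seed", {
  cohort <- tiny_cohort(5, 5)
  truth <- simulation_truth()
  a <- simulate_ct_matrix(cohort, truth, 30L, seed = 77L)
  b <- simulate_ct_matrix(cohort, truth, 30L, seed = 77L)
  expect_identical(a, b)
  c <- simulate_ct_matrix(cohort, truth, 30L, seed = 78L)
  expect_false(identical(a$values, c$values))
  m1 <- simulate_mfi_matrix(cohort, truth, sprintf("p%d", 1:6), seed = 3L)
  m2 <- simulate_mfi_matrix(cohort, truth, sprintf("p%d", 1:6), seed = 3L)
  expect_identical(m1, m2)
})
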