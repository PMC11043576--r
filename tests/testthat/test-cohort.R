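test_that("sample sheets parse with tolerant booleans and validate ids", {
  path <- write_sheet(c(
    "sample_id,group,hormone_use,age",
    "S1,case,yes,18",
    "S2,control,no,19",
    "S3,control,1,20"))
  cohort <- read_sample_sheet(path)
  expect_s3_class(cohort, "cohort_table")
  expect_equal(nrow(cohort), 3)
  expect_equal(sum(cohort$group == "case"), 1)
  expect_equal(cohort$hormone_use, c(TRUE, FALSE, TRUE))

  dup <- write_sheet(c("sample_id,group,hormone_use,age",
                       "S1,case,yes,18", "S1,control,no,19"))
  expect_error(read_sample_sheet(dup), "duplicate sample_id")

  missing_col <- write_sheet(c("sample_id,group,age", "S1,case,18"))
  expect_error(read_sample_sheet(missing_col), "hormone_use")

  expect_error(
    cohort_table(data.frame(sample_id = "S1", group = "control",
                            hormone_use = TRUE, age = 20,
                            pathology_confirmed = TRUE)),
    "pathology_confirmed")
})

test_that("sample sheets round-trip bit-identically", {
  cohort <- tiny_cohort(3, 5)
  path <- tempfile(fileext = ".tsv")
  write_sample_sheet(cohort, path)
  back <- read_sample_sheet(path, phase = "discovery")
  expect_identical(as.data.frame(cohort), as.data.frame(back))
  path2 <- tempfile(fileext = ".tsv")
  write_sample_sheet(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("frequency matching fills strata at the requested ratio", {
  cases <- cohort_table(data.frame(
    sample_id = c("C1", "C2"), group = "case",
    hormone_use = c(TRUE, FALSE), age = c(18, 20)))
  pool <- cohort_table(data.frame(
    sample_id = sprintf("P%02d", 1:12), group = "control",
    hormone_use = rep(c(TRUE, FALSE), each = 6),
    age = rep(c(18, 19, 20), 4)))
  matched <- frequency_match(cases, pool, ratio = 2L, age_tolerance = 2, seed = 7L)
  expect_equal(nrow(matched), 6)  # 2 cases + 4 controls
  controls <- matched[matched$group == "control", ]
  expect_equal(sum(controls$hormone_use), 2)
  expect_equal(sum(!controls$hormone_use), 2)
  # controls drawn without replacement, case set untouched
  expect_false(anyDuplicated(matched$sample_id) > 0)
  expect_identical(matched$sample_id[matched$group == "case"], cases$sample_id)
})

test_that("frequency matching warns and best-effort fills sparse strata", {
  cases <- cohort_table(data.frame(
    sample_id = "C1", group = "case", hormone_use = TRUE, age = 18))
  pool <- cohort_table(data.frame(
    sample_id = "P1", group = "control", hormone_use = TRUE, age = 18))
  expect_warning(matched <- frequency_match(cases, pool, ratio = 3L, seed = 1L),
                 "wanted 3")
  expect_equal(nrow(matched), 2)
  expect_equal(attr(matched, "match_summary")$got, 1L)
})

test_that("paper-scale frequency matching yields a 1:2 cohort", {
  set.seed(42)
  cases <- cohort_table(data.frame(
    sample_id = sprintf("C%02d", 1:54), group = "case",
    hormone_use = runif(54) < 0.78, age = sample(13:25, 54, TRUE)))
  pool <- cohort_table(data.frame(
    sample_id = sprintf("P%03d", 1:600), group = "control",
    hormone_use = runif(600) < 0.78, age = sample(13:25, 600, TRUE)))
  matched <- frequency_match(cases, pool, ratio = 2L, age_tolerance = 2, seed = 5L)
  expect_equal(sum(matched$group == "control"), 108)
  expect_equal(nrow(matched), 162)
})

test_that("stratified split honours largest-remainder counts and is seeded", {
  cohort <- simulate_cohort(54L, 2L, 0.78, seed = 3L)
  split <- stratified_split(cohort, 2 / 3, strata = "group", seed = 11L)
  tab <- table(split$group, split$split)
  expect_equal(unname(tab["case", "train"]), 36)
  expect_equal(unname(tab["case", "test"]), 18)
  expect_equal(unname(tab["control", "train"]), 72)
  expect_equal(unname(tab["control", "test"]), 36)
  # deterministic given seed
  split2 <- stratified_split(cohort, 2 / 3, strata = "group", seed = 11L)
  expect_identical(split$split, split2$split)
  split3 <- stratified_split(cohort, 2 / 3, strata = "group", seed = 12L)
  expect_false(identical(split$split, split3$split))
})

test_that("a 3-sample stratum at fraction 2/3 rounds to 2 train, 1 test", {
  cohort <- tiny_cohort(3, 0)
  split <- suppressWarnings(
    stratified_split(cohort, 2 / 3, strata = "group", seed = 1L))
  expect_equal(sum(split$split == "train"), 2)
  expect_equal(sum(split$split == "test"), 1)
})

test_that("per-stratum split counts match the largest-remainder formula", {
  # independent largest-remainder oracle
  lr_oracle <- function(n, frac) {
    quota <- n * frac
    base <- floor(quota)
    rem <- round(sum(n) * frac) - sum(base)
    ord <- order(-(quota - base), seq_along(n))
    if (rem > 0) base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    base
  }
  set.seed(99)
  for (i in 1:20) {
    n_case <- sample(5:60, 1)
    n_control <- sample(5:120, 1)
    frac <- runif(1, 0.3, 0.9)
    cohort <- simulate_cohort(n_case, 1L, 0.5, seed = i)
    cohort <- cohort[c(seq_len(n_case), n_case + seq_len(min(n_control, n_case))), ]
    cohort <- cohort_table(as.data.frame(cohort))
    split <- suppressWarnings(
      stratified_split(cohort, frac, strata = "group", seed = i))
    got <- table(factor(split$group, c("case", "control")),
                 factor(split$split, c("train", "test")))[, "train"]
    want <- vapply(c("case", "control"), function(g) {
      lr_oracle(sum(split$group == g), frac)
    }, numeric(1))
    expect_equal(unname(got), unname(want))
  }
})
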