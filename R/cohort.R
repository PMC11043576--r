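#' Construct and validate a cohort table
#'
#' A cohort table is the per-sample metadata backbone of the workflow: one row
#' per participant with case/control status, exogenous hormone use at blood
#' draw (the study's key effect modifier), age, and -- for cases -- whether the
#' diagnosis was pathology-confirmed. An optional `split` column records the
#' train/test assignment used in the replication phase.
#'
#' @param df data.frame with columns `sample_id`, `group` ("case"/"control"),
#'   `hormone_use` (logical), `age` (numeric years). Optional:
#'   `pathology_confirmed` (logical, cases only), `months_since_surgery`,
#'   `split` ("train"/"test").
#' @param phase "discovery" or "replication"; stored as an attribute.
#' @return validated data.frame of class `cohort_table`.
#' @export
cohort_table <- function(df, phase = c("discovery", "replication")) {
  phase <- match.arg(phase)
  req <- c("sample_id", "group", "hormone_use", "age")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(df$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'", call. = FALSE)
  }
  if (!is.logical(df$hormone_use)) {
    stop("hormone_use must be logical", call. = FALSE)
  }
  if (!is.null(df$pathology_confirmed)) {
    bad <- !is.na(df$pathology_confirmed) & df$group == "control"
    if (any(bad)) {
      stop("pathology_confirmed defined for control sample(s): ",
           paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
    }
  } else {
    df$pathology_confirmed <- ifelse(df$group == "case", NA, NA)
  }
  if (is.null(df$months_since_surgery)) df$months_since_surgery <- NA_real_
  df$months_since_surgery <- as.numeric(df$months_since_surgery)
  if (!is.null(df$split)) {
    if (!all(is.na(df$split) | df$split %in% c("train", "test"))) {
      stop("split must be 'train' or 'test'", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  structure(df, phase = phase, class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table: %d samples (%d cases, %d controls), phase = %s>\n",
              nrow(x), sum(x$group == "case"), sum(x$group == "control"),
              attr(x, "phase")))
  if (!is.null(x$split) && any(!is.na(x$split))) {
    tab <- table(x$group, x$split)
    print(tab)
  }
  invisible(x)
}

# tolerant boolean parser for sample-sheet columns
parse_bool <- function(x, column) {
  if (is.logical(x)) return(x)
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(key))
  out[key %in% c("1", "yes", "true", "t", "y")] <- TRUE
  out[key %in% c("0", "no", "false", "f", "n")] <- FALSE
  bad <- !is.na(key) & key != "" & key != "na" & is.na(out)
  if (any(bad)) {
    stop("column '", column, "' has unparseable boolean value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a sample sheet
#'
#' Reads a CSV or TSV sample sheet (columns `sample_id`, `group`,
#' `hormone_use`, `age`, optionally `pathology_confirmed`,
#' `months_since_surgery`, `split`) into a [cohort_table()]. Boolean columns
#' accept 0/1, yes/no, true/false case-insensitively.
#'
#' @param path file path.
#' @param dialect "csv" or "tsv"; guessed from the extension by default.
#' @param phase phase label passed to [cohort_table()].
#' @return a `cohort_table`.
#' @export
read_sample_sheet <- function(path, dialect = NULL,
                              phase = c("discovery", "replication")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  for (col in intersect(c("hormone_use", "pathology_confirmed"), names(df))) {
    df[[col]] <- parse_bool(df[[col]], col)
  }
  cohort_table(df, phase = match.arg(phase))
}

#' Write a cohort table back to disk
#'
#' @param cohort a `cohort_table`.
#' @param path output path; extension picks the dialect as in
#'   [read_sample_sheet()].
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(cohort), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# age-bin index: bins of width 2*tolerance anchored at the youngest case
age_bin <- function(age, anchor, tolerance) {
  floor((age - anchor) / (2 * tolerance))
}

#' Frequency-match controls to cases
#'
#' Selects controls from a pool so that, within each (hormone use x age-bin)
#' stratum, the control count equals `ratio` times the case count whenever the
#' pool allows. This is frequency matching (stratum totals, not pairs): age is
#' binned with width `2 * age_tolerance` anchored at the youngest case, and
#' controls are drawn uniformly at random within each stratum under `seed`.
#'
#' @param cases `cohort_table` of cases.
#' @param control_pool `cohort_table` of candidate controls.
#' @param ratio controls per case (integer >= 1).
#' @param age_tolerance matching half-width in years (default 2: "within two
#'   years").
#' @param seed integer seed for the within-stratum draws.
#' @return a `cohort_table` containing the cases plus the selected controls,
#'   with a `match_summary` attribute (per-stratum wanted/got counts).
#' @export
frequency_match <- function(cases, control_pool, ratio = 2L,
                            age_tolerance = 2, seed = 1L) {
  stopifnot(ratio >= 1, nrow(control_pool) > 0)
  if (any(cases$group != "case")) stop("'cases' must contain only cases", call. = FALSE)
  anchor <- min(cases$age)
  case_strata <- paste(cases$hormone_use, age_bin(cases$age, anchor, age_tolerance))
  pool_strata <- paste(control_pool$hormone_use,
                       age_bin(control_pool$age, anchor, age_tolerance))
  wanted <- table(case_strata) * ratio
  set.seed(seed)
  picked <- integer(0)
  summary <- data.frame(stratum = names(wanted),
                        wanted = as.integer(wanted),
                        got = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(wanted)) {
    stratum <- names(wanted)[i]
    avail <- which(pool_strata == stratum)
    n_take <- min(length(avail), wanted[[i]])
    if (n_take < wanted[[i]]) {
      warning(sprintf("stratum '%s': wanted %d controls, pool has %d",
                      stratum, wanted[[i]], length(avail)), call. = FALSE)
    }
    if (n_take > 0) {
      take <- avail[sample.int(length(avail), n_take)]
      picked <- c(picked, take)
      summary$got[i] <- n_take
    }
  }
  controls <- as.data.frame(control_pool)[picked, , drop = FALSE]
  out <- rbind(as.data.frame(cases)[, names(controls), drop = FALSE], controls)
  out <- cohort_table(out, phase = attr(cases, "phase"))
  attr(out, "match_summary") <- summary
  out
}

# largest-remainder apportionment of round(sum(n) * fraction) train slots
# across strata with quotas n * fraction
largest_remainder <- function(n, fraction) {
  quota <- n * fraction
  base <- floor(quota)
  total <- round(sum(n) * fraction)
  rem <- total - sum(base)
  if (rem > 0) {
    frac_part <- quota - base
    # ties broken by stratum order (stable)
    order_idx <- order(-frac_part, seq_along(n))
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1L
  }
  pmin(base, n)
}

#' Stratified train/test split
#'
#' Randomly assigns samples to a training and a testing set within strata,
#' with largest-remainder rounding of the per-stratum training counts so that
#' the overall training fraction is honoured exactly. A 2:1 split of 54 cases
#' and 108 controls stratified by group yields 36/72 training and 18/36
#' testing samples.
#'
#' @param cohort a `cohort_table`.
#' @param train_fraction fraction assigned to training (default 2/3).
#' @param strata character vector of stratification columns (default
#'   `c("group", "hormone_use")`).
#' @param seed integer seed.
#' @return the cohort with its `split` column filled.
#' @export
stratified_split <- function(cohort, train_fraction = 2 / 3,
                             strata = c("group", "hormone_use"), seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  missing_cols <- setdiff(strata, names(cohort))
  if (length(missing_cols)) {
    stop("stratum column(s) not in cohort: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- interaction(as.data.frame(cohort)[, strata, drop = FALSE], drop = TRUE)
  levels_key <- levels(key)
  n_per <- as.integer(table(key))
  # largest-remainder within each group so case/control totals match the
  # group-level formula exactly
  grp <- vapply(levels_key, function(l) {
    as.character(as.data.frame(cohort)$group[match(l, key)])
  }, character(1))
  n_train <- integer(length(n_per))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    n_train[idx] <- largest_remainder(n_per[idx], train_fraction)
  }
  set.seed(seed)
  split <- rep(NA_character_, nrow(cohort))
  for (i in seq_along(levels_key)) {
    members <- which(key == levels_key[i])
    if (length(members) < 2L) {
      warning("stratum '", levels_key[i], "' has < 2 samples; all to train",
              call. = FALSE)
      split[members] <- "train"
      next
    }
    train_idx <- members[sample.int(length(members), n_train[i])]
    split[members] <- "test"
    split[train_idx] <- "train"
  }
  cohort$split <- split
  cohort
}
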