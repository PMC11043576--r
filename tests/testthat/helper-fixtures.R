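# in-code fixtures shared across test files

# minimal cohort: n_case cases then n_control controls, alternating hormone use
tiny_cohort <- function(n_case = 4, n_control = 4, phase = "discovery") {
  n <- n_case + n_control
  cohort_table(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = rep(c("case", "control"), c(n_case, n_control)),
    hormone_use = rep(c(TRUE, FALSE), length.out = n),
    age = rep(18:21, length.out = n),
    stringsAsFactors = FALSE
  ), phase = phase)
}

# collapsed Ct matrix from explicit values
tiny_ct <- function(values, sample_ids = NULL) {
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  ct_matrix(values, pairs = NULL)
}

# write a sample sheet to a temp file and return the path
write_sheet <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# feature table built directly from a samples x probes matrix
tiny_features <- function(x, group, hormone = NULL, split = NULL) {
  n <- nrow(x)
  if (is.null(hormone)) hormone <- rep(c(TRUE, FALSE), length.out = n)
  if (is.null(split)) split <- rep("train", n)
  df <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                   group = group, hormone_use = as.numeric(hormone),
                   split = split, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x, check.names = FALSE))
  structure(df, probes = colnames(x),
            class = c("feature_table", "data.frame"))
}
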