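#' Replicate-level quality control for qPCR Ct values
#'
#' Summarises the replicate wells of one sample x assay combination,
#' excluding outlier wells by one of two +/- 2 SD policies and recomputing
#' the mean Ct on the surviving wells.
#'
#' The `"literal_2sd"` policy excludes a well when its Ct lies more than two
#' sample standard deviations (n - 1 denominator) from the mean of *all*
#' replicates. For a quadruplicate this rule can never fire: the largest
#' attainable |z| with the sample SD is (n - 1)/sqrt(n) = 1.5 < 2. The
#' default `"leave_one_out_2sd"` policy therefore judges each well against
#' the mean +/- 2 SD of the *other* replicates, which does catch a single
#' aberrant well.
#'
#' @param cts Numeric vector of replicate Ct values (cycles), length >= 1.
#' @param policy Outlier policy, `"leave_one_out_2sd"` (default) or
#'   `"literal_2sd"`.
#' @param min_valid Minimum surviving replicates before the sample is flagged
#'   for rerun (default 2).
#'
#' @return A one-row tibble with columns `mean_ct`, `n_valid`, `n_excluded`,
#'   `rerun` (logical), and list-columns `valid_cts`, `excluded_cts`.
#' @examples
#' qc_replicates(c(18.0, 18.1, 17.9, 25.0))
#' @export
qc_replicates <- function(cts,
                          policy = c("leave_one_out_2sd", "literal_2sd"),
                          min_valid = 2) {
  policy <- match.arg(policy)
  if (length(cts) == 0) abort("no replicates")
  if (!is.numeric(cts) || any(!is.finite(cts))) {
    abort("Ct values must be finite numbers")
  }

  n <- length(cts)
  if (n == 1) {
    keep <- TRUE
  } else if (policy == "literal_2sd") {
    m <- mean(cts)
    s <- sd(cts)
    keep <- if (s == 0) rep(TRUE, n) else abs(cts - m) <= 2 * s
  } else {
    # each well judged against the mean +/- 2 SD of the remaining wells;
    # decisions are simultaneous, not sequential
    keep <- vapply(seq_len(n), function(i) {
      others <- cts[-i]
      m <- mean(others)
      if (length(others) < 2) return(abs(cts[i] - m) <= 0)
      s <- sd(others)
      abs(cts[i] - m) <= 2 * s
    }, logical(1))
  }

  valid <- cts[keep]
  tibble(
    mean_ct = mean(valid),
    n_valid = length(valid),
    n_excluded = n - length(valid),
    rerun = length(valid) < min_valid,
    valid_cts = list(valid),
    excluded_cts = list(cts[!keep])
  )
}

#' Coefficient of variation of an assay
#'
#' CV% = 100 * SD / mean with the sample SD (n - 1 denominator), the
#' convention used for inter- and intra-assay precision of replicate
#' measurements.
#'
#' @param values Numeric vector, length >= 2, with nonzero mean.
#' @param label Optional label carried into the output.
#' @return One-row tibble: `label`, `mean_value`, `sd_value`, `cv_percent`.
#' @examples
#' assay_cv(c(100, 105, 95))
#' @export
assay_cv <- function(values, label = NA_character_) {
  if (length(values) < 2) abort("need at least two values for a CV")
  if (any(!is.finite(values))) abort("values must be finite")
  m <- mean(values)
  if (m == 0) abort("mean is zero; CV undefined")
  tibble(
    label = label,
    mean_value = m,
    sd_value = sd(values),
    cv_percent = 100 * sd(values) / m
  )
}
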