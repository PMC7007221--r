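# Chromatin-accessibility QTL calling from allele-specific read counts:
# testability filter, beta-binomial density/tail helpers, global
# method-of-moments overdispersion, and the per-variant imbalance test.

#' Filter variants testable for allelic imbalance
#'
#' Keeps variants observed in at least `min_subjects` heterozygous subjects
#' whose counts, summed across subjects, carry at least `min_reads` reads on
#' each allele (bounds inclusive). A per-subject mode applies the read
#' filter within every subject instead.
#'
#' @param records data frame `variant_id`, `subject_id`, `ref_count`,
#'   `alt_count`.
#' @param min_subjects,min_reads filter thresholds.
#' @param per_subject apply the read filter per subject rather than to
#'   cross-subject sums.
#' @return data frame `variant_id`, `n_het_subjects`, `ref_total`,
#'   `alt_total` for testable variants.
#' @export
filter_testable <- function(records, min_subjects = 2L, min_reads = 5L,
                            per_subject = FALSE) {
  agg <- do.call(rbind, lapply(split(records, records$variant_id), function(d) {
    ok <- if (per_subject)
      nrow(d) >= min_subjects && all(d$ref_count >= min_reads) &&
        all(d$alt_count >= min_reads)
    else
      nrow(d) >= min_subjects && sum(d$ref_count) >= min_reads &&
        sum(d$alt_count) >= min_reads
    if (!ok) return(NULL)
    data.frame(variant_id = d$variant_id[1], n_het_subjects = nrow(d),
               ref_total = sum(d$ref_count), alt_total = sum(d$alt_count),
               stringsAsFactors = FALSE)
  }))
  if (is.null(agg))
    agg <- data.frame(variant_id = character(0), n_het_subjects = integer(0),
                      ref_total = integer(0), alt_total = integer(0))
  rownames(agg) <- NULL
  agg
}

# beta-binomial log-density and lower tail, parameterized by mean fraction
# `prob` and overdispersion rho in [0,1); rho = 0 degrades to binomial
dbetabinom <- function(x, size, prob = 0.5, rho = 0) {
  if (rho <= 0) return(stats::dbinom(x, size, prob))
  a <- prob * (1 / rho - 1); b <- (1 - prob) * (1 / rho - 1)
  exp(lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b))
}

pbetabinom <- function(q, size, prob = 0.5, rho = 0) {
  if (rho <= 0) return(stats::pbinom(q, size, prob))
  vapply(q, function(qi)
    if (qi < 0) 0 else sum(dbetabinom(0:qi, size, prob, rho)), 0)
}

#' Method-of-moments overdispersion of balanced allele counts
#'
#' Estimates the extra-binomial dispersion rho by matching the median of the
#' standardized squared deviations of per-variant reference fractions around
#' 1/2 to its null expectation (the chi-square(1) median). Matching the
#' median rather than the mean keeps the estimate stable when a minority of
#' variants carries genuine allelic imbalance; negative estimates truncate
#' to 0.
#'
#' @param totals,refs per-variant total and reference read counts.
#' @return rho in `[0, 1)`.
#' @export
estimate_overdispersion <- function(totals, refs) {
  keep <- totals > 1
  totals <- totals[keep]; refs <- refs[keep]
  if (!length(totals)) return(0)
  # under the null, (ref - n/2)^2 / (n/4 * (1 + (n-1) rho)) ~ chi-sq(1) approx
  s <- (refs - totals / 2)^2 / (totals / 4)
  med_target <- stats::qchisq(0.5, 1)
  f <- function(rho) stats::median(s / (1 + (totals - 1) * rho)) - med_target
  if (f(0) <= 0) return(0)
  if (f(0.99) >= 0) return(0.99)
  stats::uniroot(f, c(0, 0.99), tol = 1e-8)$root
}

#' Test variants for allelic imbalance in chromatin accessibility
#'
#' Each testable variant's summed reference count is tested against the
#' balanced expectation (half the total reads) under an extra-binomially
#' overdispersed count model (beta-binomial given total depth) whose
#' dispersion is estimated globally from all testable variants by the method
#' of moments; with dispersion 0 the test is the exact binomial test.
#' Two-sided p = min(1, 2 * min(lower tail, upper tail)); BH across
#' variants; caQTLs flagged at q < `fdr`.
#'
#' When the dispersion is estimated from the data, a second pass excludes
#' variants called imbalanced in the first pass and re-estimates on the
#' remainder, so that genuine caQTLs do not inflate the null dispersion
#' (and thereby deflate power).
#'
#' @param testable output of [filter_testable()].
#' @param dispersion overdispersion rho; `NULL` (default) estimates it
#'   globally, which requires at least `min_for_estimation` variants.
#' @param fdr FDR threshold for the caQTL flag.
#' @param min_for_estimation minimum variants for global dispersion
#'   estimation.
#' @return data frame `variant_id`, `n_het_subjects`, `ref_total`,
#'   `alt_total`, `fraction`, `p`, `q`, `is_caqtl`, with the dispersion used
#'   as attribute `dispersion`.
#' @export
test_imbalance <- function(testable, dispersion = NULL, fdr = 0.05,
                           min_for_estimation = 20L) {
  tot <- testable$ref_total + testable$alt_total
  keep <- tot > 0
  d <- testable[keep, , drop = FALSE]
  tot <- tot[keep]
  run_pass <- function(rho) {
    p <- vapply(seq_len(nrow(d)), function(i) {
      lower <- pbetabinom(d$ref_total[i], tot[i], 0.5, rho)
      upper <- 1 - pbetabinom(d$ref_total[i] - 1L, tot[i], 0.5, rho)
      min(1, 2 * min(lower, upper))
    }, 0)
    data.frame(d, fraction = d$ref_total / tot, p = p,
               q = p.adjust(p, method = "BH"))
  }
  if (is.null(dispersion)) {
    if (nrow(d) < min_for_estimation)
      stop("fewer than ", min_for_estimation, " testable variants; supply ",
           "`dispersion` explicitly")
    dispersion <- estimate_overdispersion(tot, d$ref_total)
    first <- run_pass(dispersion)
    null_like <- first$q >= fdr
    if (sum(null_like) >= min_for_estimation && any(!null_like))
      dispersion <- estimate_overdispersion(tot[null_like],
                                            d$ref_total[null_like])
  }
  out <- run_pass(dispersion)
  out$is_caqtl <- out$q < fdr
  attr(out, "dispersion") <- dispersion
  out
}

#' Run the full caQTL analysis from a counts table
#'
#' Convenience wrapper: [filter_testable()] then [test_imbalance()].
#'
#' @param records allele-count records.
#' @param ... passed to [test_imbalance()].
#' @inheritParams filter_testable
#' @return see [test_imbalance()].
#' @export
call_caqtls <- function(records, min_subjects = 2L, min_reads = 5L, ...) {
  test_imbalance(filter_testable(records, min_subjects, min_reads), ...)
}
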