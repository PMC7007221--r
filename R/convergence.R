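# Convergence between CNN regulatory scores and fine-mapping: threshold
# curves over PPA with permutation nulls preserving credible-set structure,
# per-rank curves, ranked-set enrichment, group rank tests, signal
# refinement and signal-level overlap summaries.

# join a variant_scores object (or a data frame with variant_id/min_q) onto
# a credible-variant table
.join_scores <- function(scores, variants) {
  sc <- if (inherits(scores, "variant_scores")) scores$scores else scores
  idx <- match(variants$variant_id, sc$variant_id)
  if (all(is.na(idx))) stop("scores and variants share no variant_id")
  data.frame(variants, min_q = sc$min_q[idx], stringsAsFactors = FALSE)
}

#' Fraction of regulatory variants above descending PPA thresholds
#'
#' At each threshold t from 1.00 down to 0.00 in steps of 0.01 (101 points),
#' computes the fraction of variants with regulatory q-value < `alpha` among
#' variants with PPA >= t. Thresholds with an empty denominator are carried
#' as missing and skipped in the (threshold-axis normalized) trapezoidal
#' AUC.
#'
#' @param scores a `variant_scores` object (or data frame with `variant_id`,
#'   `min_q`).
#' @param variants credible-variant table with `gppa`/`fppa` columns.
#' @param ppa_field `"gppa"` or `"fppa"`.
#' @param alpha regulatory q-value cutoff.
#' @return object of class `threshold_curve`: data frame `threshold`,
#'   `n_variants`, `fraction`, with the normalized `auc` as an attribute.
#' @export
threshold_curve <- function(scores, variants, ppa_field = c("gppa", "fppa"),
                            alpha = 0.05) {
  ppa_field <- match.arg(ppa_field)
  j <- .join_scores(scores, variants)
  .threshold_curve_impl(j[[ppa_field]], j$min_q < alpha)
}

.curve_thresholds <- seq(100L, 0L) / 100

.threshold_curve_impl <- function(ppa, sig) {
  ok <- !is.na(ppa) & !is.na(sig)
  ppa <- ppa[ok]; sig <- sig[ok]
  if (!length(ppa)) stop("no variants with defined PPA and q")
  o <- order(ppa, decreasing = TRUE)
  ppa_s <- ppa[o]; sig_s <- cumsum(sig[o])
  n_at <- findInterval(-.curve_thresholds, -ppa_s) # variants with PPA >= t
  frac <- ifelse(n_at > 0, sig_s[pmax(n_at, 1L)] / n_at, NA_real_)
  out <- data.frame(threshold = .curve_thresholds, n_variants = n_at,
                    fraction = frac)
  def <- !is.na(frac)
  auc <- if (sum(def) >= 2)
    trapezoid_auc(.curve_thresholds[def], frac[def]) /
      diff(range(.curve_thresholds[def]))
  else NA_real_
  attr(out, "auc") <- auc
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' @rdname threshold_curve
#' @param x a `threshold_curve`.
#' @export
curve_auc <- function(x) attr(x, "auc")

#' Permutation test of convergence between regulatory scores and PPA
#'
#' The observed threshold-curve AUC is compared with a null obtained by
#' permuting the q-value assignments across all credible-set variants
#' (credible-set memberships and PPAs stay fixed, so set sizes, structure
#' and the global number of significant variants are preserved). The
#' one-sided p-value uses the add-one estimator
#' p = (1 + #\{null AUC >= observed\}) / (1 + n_perm).
#'
#' @inheritParams threshold_curve
#' @param n_perm number of permutations (>= 100).
#' @param seed permutation seed.
#' @param scheme `"global"` permutes q across all variants; `"size_stratified"`
#'   permutes only among variants belonging to credible sets of equal size.
#' @return object of class `permutation_null`: list with `observed_auc`,
#'   `null_auc` (vector), `p`, `n_perm`, `curve`.
#' @export
permutation_test <- function(scores, variants, ppa_field = c("gppa", "fppa"),
                             alpha = 0.05, n_perm = 1000L, seed = 1L,
                             scheme = c("global", "size_stratified")) {
  ppa_field <- match.arg(ppa_field)
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 100L)
  j <- .join_scores(scores, variants)
  ok <- !is.na(j[[ppa_field]]) & !is.na(j$min_q)
  j <- j[ok, , drop = FALSE]
  ppa <- j[[ppa_field]]
  sig <- j$min_q < alpha
  curve <- .threshold_curve_impl(ppa, sig)
  obs <- attr(curve, "auc")

  # precompute fixed pieces: variant order by PPA and denominators
  o <- order(ppa, decreasing = TRUE)
  ppa_s <- ppa[o]
  n_at <- findInterval(-.curve_thresholds, -ppa_s)
  def <- n_at > 0
  th_def <- .curve_thresholds[def]
  span <- diff(range(th_def))
  # trapezoid weights over the defined thresholds
  auc_from_sig <- function(sig_perm) {
    cs <- cumsum(sig_perm[o])
    frac <- cs[pmax(n_at, 1L)][def] / n_at[def]
    trapezoid_auc(th_def, frac) / span
  }
  strat <- if (scheme == "size_stratified") {
    sizes <- ave(seq_len(nrow(j)), j$signal_id, FUN = length)
    split(seq_len(nrow(j)), sizes)
  } else list(seq_len(nrow(j)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  null_auc <- vapply(seq_len(n_perm), function(r) {
    sp <- sig
    for (g in strat) sp[g] <- sig[g][sample.int(length(g))]
    auc_from_sig(sp)
  }, 0)
  p <- (1 + sum(null_auc >= obs)) / (1 + n_perm)
  structure(list(observed_auc = obs, null_auc = null_auc, p = p,
                 n_perm = n_perm, curve = curve, ppa_field = ppa_field),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %s: observed AUC %.4f, null mean %.4f, p = %.4g (%d perms)\n",
              x$ppa_field, x$observed_auc, mean(x$null_auc), x$p, x$n_perm))
  invisible(x)
}

#' Regulatory fraction by within-signal PPA rank
#'
#' Within each credible set, variants are ranked by descending PPA (ties
#' receive average ranks, with their regulatory mass split across the tied
#' integer ranks); the curve reports the fraction of regulatory variants at
#' each rank. Optionally restricted to signals of one class, and accompanied
#' by a permutation band under random q assignment.
#'
#' @inheritParams permutation_test
#' @param class_filter optional `signal_class` value to restrict to.
#' @param n_perm permutations for the band (0 disables).
#' @return data frame `rank`, `mass`, `fraction`, plus band columns `lo`,
#'   `hi` when `n_perm > 0`.
#' @export
rank_curve <- function(scores, variants, ppa_field = c("gppa", "fppa"),
                       alpha = 0.05, class_filter = NULL, n_perm = 0L,
                       seed = 1L) {
  ppa_field <- match.arg(ppa_field)
  j <- .join_scores(scores, variants)
  if (!is.null(class_filter)) {
    if (!class_filter %in% j$signal_class)
      stop("no signals with class '", class_filter, "'")
    j <- j[j$signal_class == class_filter, , drop = FALSE]
  }
  sizes <- table(j$signal_id)
  if (any(sizes < 2L)) stop("every signal must have >= 2 variants")
  max_rank <- max(sizes)
  sig <- j$min_q < alpha

  mass_fraction <- function(sigv) {
    num <- den <- numeric(max_rank)
    for (s in split(seq_len(nrow(j)), j$signal_id)) {
      r <- rank(-j[[ppa_field]][s], ties.method = "average")
      for (i in seq_along(s)) {
        lo <- floor(r[i] - (sum(r == r[i]) - 1) / 2)
        span <- lo:(lo + sum(r == r[i]) - 1)
        # tied variants spread mass evenly over the tied integer ranks
        w <- 1 / length(span)
        den[span] <- den[span] + w
        if (sigv[s[i]]) num[span] <- num[span] + w
      }
    }
    list(fraction = ifelse(den > 0, num / den, NA_real_), mass = den)
  }
  obs <- mass_fraction(sig)
  out <- data.frame(rank = seq_len(max_rank), mass = obs$mass,
                    fraction = obs$fraction)
  if (n_perm > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    perms <- vapply(seq_len(n_perm), function(r)
      mass_fraction(sig[sample.int(length(sig))])$fraction,
      numeric(max_rank))
    out$lo <- apply(perms, 1L, quantile, 0.025, na.rm = TRUE)
    out$hi <- apply(perms, 1L, quantile, 0.975, na.rm = TRUE)
  }
  out
}

#' Ranked-set enrichment (gage-style two-sample rank test)
#'
#' Variants are ranked by a statistic (smaller = closer to the "top" of the
#' list, e.g. a q-value); for each set a two-sample t-test on the
#' rank-transformed values compares members against the complement, giving
#' one-sided p-values for enrichment at the top and at the bottom; BH
#' correction is applied across sets, per direction.
#'
#' @param statistic named numeric vector (names identify variants; smaller
#'   values rank toward the top).
#' @param sets named list of character vectors of variant names.
#' @return data frame `set`, `size`, `p_top`, `p_bottom`, `q_top`,
#'   `q_bottom`, `direction`.
#' @export
ranked_set_enrichment <- function(statistic, sets) {
  stopifnot(!is.null(names(statistic)), length(sets) >= 1L)
  r <- rank(statistic, ties.method = "average")
  rows <- lapply(names(sets), function(nm) {
    mem <- names(statistic) %in% sets[[nm]]
    if (sum(mem) < 2L || sum(!mem) < 2L) {
      warning("set '", nm, "' has fewer than 2 members (or complement); skipped")
      return(NULL)
    }
    tt_top <- t.test(r[mem], r[!mem], alternative = "less")
    tt_bot <- t.test(r[mem], r[!mem], alternative = "greater")
    data.frame(set = nm, size = sum(mem),
               p_top = tt_top$p.value, p_bottom = tt_bot$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), size = integer(0),
                      p_top = numeric(0), p_bottom = numeric(0),
                      q_top = numeric(0), q_bottom = numeric(0),
                      direction = character(0)))
  out$q_top <- p.adjust(out$p_top, method = "BH")
  out$q_bottom <- p.adjust(out$p_bottom, method = "BH")
  out$direction <- ifelse(out$p_top <= out$p_bottom, "top", "bottom")
  out
}

#' One-sided rank comparison of two groups
#'
#' Wilcoxon rank-sum test: exact when the smaller group has at most 10
#' observations and there are no ties, normal approximation with tie
#' correction otherwise.
#'
#' @param a,b numeric vectors.
#' @param side `"greater"` tests a > b; `"less"` tests a < b;
#'   `"two.sided"` available for completeness.
#' @return p-value.
#' @export
group_rank_test <- function(a, b, side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied; p = 1")
    return(1)
  }
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && min(length(a), length(b)) <= 10L
  wilcox.test(a, b, alternative = side, exact = exact,
              correct = !exact)$p.value
}

#' Refine ambiguous signals to single candidate variants
#'
#' Signals with at least two variants at fPPA >= `fppa_floor` are flagged
#' ambiguous. Among those, a signal resolves to a single candidate when
#' exactly one of its variants is regulatory (q < `alpha`), or when the top
#' variant's -log10(q) exceeds the runner-up by more than `logq_gap`.
#'
#' @inheritParams threshold_curve
#' @param fppa_floor fPPA threshold defining top candidates.
#' @param logq_gap required -log10(q) lead of the top variant.
#' @return data frame, one row per ambiguous signal: `signal_id`,
#'   `n_candidates`, `n_regulatory`, `candidate`, `candidate_q`,
#'   `runner_up_q`, `logq_gap`, `top_feature`, `delta_top`, `resolved`.
#' @export
signal_refinement <- function(scores, variants, fppa_floor = 0.2,
                              logq_gap = 100, alpha = 0.05) {
  j <- .join_scores(scores, variants)
  have_delta <- inherits(scores, "variant_scores")
  rows <- list()
  for (s in split(j, j$signal_id)) {
    cand <- s[!is.na(s$fppa) & s$fppa >= fppa_floor, , drop = FALSE]
    if (nrow(cand) < 2L) next # unambiguous signal, not reported
    q <- s$min_q
    reg <- which(!is.na(q) & q < alpha)
    o <- order(q)
    top_q <- q[o[1]]; runner_q <- q[o[2]]
    gap <- -log10(top_q) - -log10(runner_q)
    resolved <- length(reg) == 1L || (is.finite(gap) && gap > logq_gap)
    cand_id <- if (length(reg) == 1L) s$variant_id[reg] else
      if (resolved) s$variant_id[o[1]] else NA_character_
    top_feature <- delta_top <- NA
    if (!is.na(cand_id) && have_delta) {
      i <- match(cand_id, scores$scores$variant_id)
      top_feature <- scores$scores$top_feature[i]
      delta_top <- scores$delta[i, top_feature]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      signal_id = s$signal_id[1], n_candidates = nrow(cand),
      n_regulatory = length(reg), candidate = cand_id,
      candidate_q = top_q, runner_up_q = runner_q, logq_gap = gap,
      top_feature = top_feature, delta_top = delta_top,
      resolved = resolved, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(signal_id = character(0), n_candidates = integer(0),
                      n_regulatory = integer(0), candidate = character(0),
                      candidate_q = numeric(0), runner_up_q = numeric(0),
                      logq_gap = numeric(0), top_feature = character(0),
                      delta_top = numeric(0), resolved = logical(0)))
  do.call(rbind, rows)
}

#' Count signals carrying at least one regulatory variant
#'
#' @inheritParams threshold_curve
#' @param annotations optional named list of signal-id sets to cross-tabulate
#'   against.
#' @return list with `overall` (data frame `n_signals`,
#'   `n_with_regulatory`, `fraction`) and `by_annotation` (data frame per
#'   set, NULL when no annotations given).
#' @export
signal_overlap_summary <- function(scores, variants, alpha = 0.05,
                                   annotations = NULL) {
  j <- .join_scores(scores, variants)
  per_signal <- tapply(!is.na(j$min_q) & j$min_q < alpha, j$signal_id, any)
  overall <- data.frame(n_signals = length(per_signal),
                        n_with_regulatory = sum(per_signal),
                        fraction = mean(per_signal))
  by_ann <- NULL
  if (!is.null(annotations) && length(annotations)) {
    by_ann <- do.call(rbind, lapply(names(annotations), function(nm) {
      ids <- intersect(annotations[[nm]], names(per_signal))
      data.frame(annotation = nm, n_signals = length(ids),
                 n_with_regulatory = sum(per_signal[ids]),
                 fraction = if (length(ids)) mean(per_signal[ids]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(overall = overall, by_annotation = by_ann)
}
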