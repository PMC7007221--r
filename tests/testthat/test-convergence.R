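# Convergence statistics: threshold/rank curves, permutation nulls,
# ranked-set enrichment, rank tests, signal refinement and summaries.

# a small credible-set scaffold with known PPAs and q-values
make_sets <- function(n_signals = 30, k = 5, seed = 1) {
  set.seed(seed)
  variants <- data.frame(
    signal_id = rep(sprintf("s%03d", seq_len(n_signals)), each = k),
    variant_id = sprintf("v%04d", seq_len(n_signals * k)),
    gppa = as.vector(replicate(n_signals, { g <- rgamma(k, 1); g / sum(g) })),
    fppa = as.vector(replicate(n_signals, { g <- rgamma(k, 1); g / sum(g) })),
    signal_class = rep(sample(c("secretion", "action", "other"), n_signals,
                              replace = TRUE), each = k),
    stringsAsFactors = FALSE)
  variants
}

test_that("threshold curves evaluate all 101 thresholds and trivial cases", {
  v <- make_sets()
  all_reg <- data.frame(variant_id = v$variant_id, min_q = 1e-8)
  tc <- threshold_curve(all_reg, v, "gppa")
  expect_equal(nrow(tc), 101L)
  expect_equal(tc$threshold[1], 1.00)
  expect_equal(tc$threshold[101], 0.00)
  defined <- !is.na(tc$fraction)
  expect_true(all(tc$fraction[defined] == 1))
  expect_equal(curve_auc(tc), 1)
  none <- data.frame(variant_id = v$variant_id, min_q = 0.9)
  expect_equal(curve_auc(threshold_curve(none, v, "gppa")), 0)
})

test_that("with q independent of PPA the curve sits at the overall fraction", {
  v <- make_sets(n_signals = 40)
  overall <- 0.2
  fracs <- replicate(600, {
    sc <- data.frame(variant_id = v$variant_id,
                     min_q = ifelse(runif(nrow(v)) < overall, 0.01, 0.5))
    tc <- threshold_curve(sc, v, "gppa")
    mean(tc$fraction[tc$threshold <= 0.3], na.rm = TRUE) # well-populated bins
  })
  expect_equal(mean(fracs), overall, tolerance = 0.02)
})

test_that("the trapezoid AUC helper agrees with numerical integration", {
  x <- seq(0, 1, by = 0.01)
  y <- x^2
  num <- stats::integrate(function(t) t^2, 0, 1)$value
  expect_equal(epiconv:::trapezoid_auc(x, y), num, tolerance = 1e-3)
  expect_equal(epiconv:::trapezoid_auc(rev(x), rev(y)),
               epiconv:::trapezoid_auc(x, y))
})

test_that("perfect convergence yields the minimal add-one permutation p", {
  v <- make_sets(n_signals = 30)
  top <- unlist(lapply(split(seq_len(nrow(v)), v$signal_id),
                       function(i) i[which.max(v$gppa[i])]))
  sc <- data.frame(variant_id = v$variant_id, min_q = 1)
  sc$min_q[top] <- 1e-9
  pt <- permutation_test(sc, v, "gppa", n_perm = 1000, seed = 5)
  expect_equal(pt$p, 1 / 1001)
  expect_s3_class(pt$curve, "threshold_curve")
})

test_that("the permutation test is calibrated under the null", {
  v <- make_sets(n_signals = 40)
  sig_pool <- rep(c(TRUE, FALSE), c(30, nrow(v) - 30))
  set.seed(6)
  pvals <- replicate(600, {
    sc <- data.frame(variant_id = v$variant_id,
                     min_q = ifelse(sample(sig_pool), 0.01, 0.5))
    permutation_test(sc, v, "gppa", n_perm = 200,
                     seed = sample.int(1e6, 1))$p
  })
  rej <- mean(pvals < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.075)
})

test_that("size-stratified permutations preserve per-size significant counts", {
  v <- rbind(make_sets(10, k = 3, seed = 2), make_sets(10, k = 6, seed = 3))
  v$signal_id <- paste0(v$signal_id, rep(c("a", "b"), c(30, 60)))
  v$variant_id <- sprintf("w%04d", seq_len(nrow(v)))
  sc <- data.frame(variant_id = v$variant_id,
                   min_q = ifelse(seq_len(nrow(v)) %% 4 == 0, 0.01, 0.6))
  pt <- permutation_test(sc, v, "gppa", n_perm = 100, seed = 1,
                         scheme = "size_stratified")
  expect_true(pt$p > 0 && pt$p <= 1)
})

test_that("rank curves recover convergence structure and reject bad input", {
  v <- make_sets(n_signals = 50)
  top <- unlist(lapply(split(seq_len(nrow(v)), v$signal_id),
                       function(i) i[which.max(v$gppa[i])]))
  sc <- data.frame(variant_id = v$variant_id, min_q = 1)
  sc$min_q[top] <- 1e-9
  rc <- rank_curve(sc, v, "gppa")
  expect_equal(rc$fraction[1], 1)
  expect_true(all(rc$fraction[-1] < 0.05))
  expect_error(rank_curve(sc, v, "gppa", class_filter = "nonexistent"),
               "no signals")
  rc_sec <- rank_curve(sc, v, "gppa", class_filter = "secretion")
  expect_equal(rc_sec$fraction[1], 1)
  # permuted q-values give a flat profile
  set.seed(7)
  sc_perm <- sc; sc_perm$min_q <- sample(sc$min_q)
  rc_p <- rank_curve(sc_perm, v, "gppa", n_perm = 50)
  expect_lt(max(rc_p$fraction) - min(rc_p$fraction), 0.25)
  expect_true(all(c("lo", "hi") %in% names(rc_p)))
})

test_that("tied PPAs split their regulatory mass across tied ranks", {
  v <- data.frame(signal_id = "s1", variant_id = c("a", "b", "c"),
                  gppa = c(0.4, 0.4, 0.2), fppa = c(0.4, 0.4, 0.2),
                  signal_class = "other")
  sc <- data.frame(variant_id = c("a", "b", "c"), min_q = c(0.01, 1, 1))
  rc <- rank_curve(sc, v, "gppa")
  expect_equal(rc$fraction[1:2], c(0.5, 0.5))
  expect_equal(rc$mass, c(1, 1, 1))
})

test_that("ranked-set enrichment finds constructed extremes and is calibrated", {
  set.seed(8)
  stat <- setNames(runif(1000), sprintf("v%04d", 1:1000))
  top_decile <- names(sort(stat))[1:100]
  res <- ranked_set_enrichment(stat, list(top = top_decile))
  expect_lt(res$p_top, 1e-6)
  expect_gt(res$p_bottom, 0.999)
  # random sets: uniform p_top
  ps <- replicate(400, {
    ranked_set_enrichment(stat, list(r = sample(names(stat), 50)))$p_top
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  # complementarity of two covering disjoint sets
  half <- names(sort(stat))[1:500]
  res2 <- ranked_set_enrichment(stat, list(a = half,
                                           b = setdiff(names(stat), half)))
  expect_equal(res2$direction, c("top", "bottom"))
  expect_warning(ranked_set_enrichment(stat, list(tiny = names(stat)[1])),
                 "skipped")
})

test_that("ranked-set p-values match a brute-force permutation null", {
  set.seed(9)
  stat <- setNames(rnorm(40), sprintf("v%02d", 1:40))
  memb <- sample(names(stat), 12)
  res <- ranked_set_enrichment(stat, list(s = memb))
  r <- rank(stat); inset <- names(stat) %in% memb
  obs <- mean(r[inset]) - mean(r[!inset])
  null <- replicate(1e4, {
    sh <- sample(inset)
    mean(r[sh]) - mean(r[!sh])
  })
  p_perm <- (1 + sum(null <= obs)) / (1 + 1e4)
  expect_equal(res$p_top, p_perm, tolerance = 0.25 * p_perm + 0.02)
})

test_that("group rank tests reproduce exact enumeration and symmetry", {
  # A = {3,4,5}, B = {1,2}: only 1 of the C(5,2)=10 splits puts both B values
  # below all of A, so the exact one-sided p is 1/10
  expect_equal(group_rank_test(c(3, 4, 5), c(1, 2), "greater"), 0.1)
  enum <- combn(5, 2)
  vals <- c(1, 2, 3, 4, 5)
  wobs <- sum(rank(vals)[3:5]) # A ranks
  wall <- apply(enum, 2, function(i) sum(rank(vals)[setdiff(1:5, i)]))
  expect_equal(mean(wall >= wobs), 0.1)
  # identical groups: p at least one half
  expect_gte(suppressWarnings(group_rank_test(c(1, 2, 3), c(1, 2, 3),
                                              "greater")), 0.5)
  # complementary sides under exactness
  pg <- group_rank_test(c(5, 7, 9), c(2, 3), "greater")
  pl <- group_rank_test(c(5, 7, 9), c(2, 3), "less")
  expect_equal(pg + pl, 1 + 1 / choose(5, 2)) # discrete overlap at the observed value
  expect_warning(group_rank_test(c(2, 2), c(2, 2)), "tied")
})

test_that("group rank test matches brute-force permutation p with ties", {
  set.seed(10)
  a <- sample(1:8, 20, replace = TRUE)
  b <- sample(2:9, 15, replace = TRUE)
  p <- group_rank_test(a, b, "greater")
  r <- rank(c(a, b)); obs <- sum(r[seq_along(a)])
  null <- replicate(1e4, {
    sh <- sample(length(r), length(a))
    sum(r[sh])
  })
  p_perm <- (1 + sum(null >= obs)) / (1 + 1e4)
  expect_equal(p, p_perm, tolerance = 0.2 * max(p, p_perm) + 0.01)
})

test_that("signal refinement applies the gate, gap and tie rules", {
  v <- data.frame(
    signal_id = rep(c("gap", "single", "tie", "onecand"), each = 2),
    variant_id = sprintf("v%02d", 1:8),
    gppa = 0.5, fppa = c(0.5, 0.4, 0.5, 0.3, 0.5, 0.4, 0.5, 0.1),
    signal_class = "other", stringsAsFactors = FALSE)
  sc <- data.frame(
    variant_id = v$variant_id,
    min_q = c(1e-160, 2e-3,   # gap signal: -log10 gap ~ 157 > 100 -> resolved
              1e-4, 0.5,      # single regulatory variant -> resolved
              1e-6, 1e-6,     # equal q -> unresolved
              1e-8, 0.9))     # only one fPPA >= 0.2 -> not reported
  out <- signal_refinement(sc, v, fppa_floor = 0.2, logq_gap = 100)
  expect_setequal(out$signal_id, c("gap", "single", "tie"))
  gap_row <- out[out$signal_id == "gap", ]
  expect_true(gap_row$resolved)
  expect_equal(gap_row$candidate, "v01")
  expect_equal(gap_row$logq_gap, -log10(1e-160) + log10(2e-3), tolerance = 1e-6)
  expect_true(out[out$signal_id == "single", "resolved"])
  expect_false(out[out$signal_id == "tie", "resolved"])
})

test_that("signal overlap summaries count signals with regulatory variants", {
  v <- make_sets(n_signals = 20)
  sc <- data.frame(variant_id = v$variant_id, min_q = 1)
  hit_signals <- sprintf("s%03d", 1:7)
  sc$min_q[v$signal_id %in% hit_signals &
             !duplicated(v$signal_id)] <- 1e-6
  out <- signal_overlap_summary(sc, v)
  expect_equal(out$overall$n_signals, 20L)
  expect_equal(out$overall$n_with_regulatory, 7L)
  # alpha = 1 counts every signal
  expect_equal(signal_overlap_summary(sc, v, alpha = 1.01)$overall$fraction, 1)
  ann <- list(hits = hit_signals, none = sprintf("s%03d", 15:20))
  out2 <- signal_overlap_summary(sc, v, annotations = ann)
  expect_equal(out2$by_annotation$n_with_regulatory, c(7L, 0L))
  expect_null(signal_overlap_summary(sc, v, annotations = NULL)$by_annotation)
})
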