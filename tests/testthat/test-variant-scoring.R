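# Variant scoring contracts: allele antisymmetry, order invariance,
# q-value bookkeeping, saturated-mutagenesis consistency, and the internal
# motif scanner.

test_that("scoring skips mismatching or out-of-bounds variants and records them", {
  fx <- tiny_fixture()
  v <- fx$study$credible[1:25, ]
  g1 <- substr(as.character(fx$study$genome[[v$chrom[1]]]), v$pos[1], v$pos[1])
  v$ref[1] <- setdiff(c("A", "C", "G", "T"), g1)[1] # force a mismatch
  v$pos[2] <- 10L                                   # too close to the edge
  vs <- score_variants(fx$ensemble, fx$study$genome, v, min_variants = 5L)
  expect_equal(nrow(vs$skipped), 2L)
  expect_match(vs$skipped$reason[1], "ref mismatch")
  expect_match(vs$skipped$reason[2], "out of bounds")
  expect_equal(nrow(vs$scores), 23L)
})

test_that("a variant whose alternative equals the reference has zero effect", {
  fx <- tiny_fixture()
  v <- fx$study$credible[1:24, ]
  v$alt <- v$ref
  vs <- score_variants(fx$ensemble, fx$study$genome, v, min_variants = 5L)
  expect_true(all(vs$delta == 0))
})

test_that("swapping ref and alt negates every delta and keeps p-values", {
  fx <- tiny_fixture()
  v <- fx$study$credible[1:30, ]
  vs1 <- score_variants(fx$ensemble, fx$study$genome, v, min_variants = 5L,
                        center = "zero")
  vsw <- v; vsw$ref <- v$alt; vsw$alt <- v$ref
  # the swapped table fails the genome check by construction, so score the
  # swapped alleles through the window builder directly
  vw <- epiconv:::.variant_windows(fx$study$genome, v,
                                   fx$ensemble$window_length)
  d_fwd <- epiconv:::.ensemble_delta(fx$ensemble, vw$ref_seq, vw$alt_seq)
  d_rev <- epiconv:::.ensemble_delta(fx$ensemble, vw$alt_seq, vw$ref_seq)
  l_fwd <- attr(d_fwd, "logit"); l_rev <- attr(d_rev, "logit")
  attr(d_fwd, "logit") <- attr(d_rev, "logit") <- NULL
  expect_equal(d_rev, -d_fwd, tolerance = 1e-12)
  expect_equal(l_rev, -l_fwd, tolerance = 1e-12)
  # with zero-centered standardization two-sided p is allele-order invariant
  z_fwd <- sweep(d_fwd, 2, apply(d_fwd, 2, sd), "/")
  z_rev <- sweep(d_rev, 2, apply(d_rev, 2, sd), "/")
  expect_equal(2 * pnorm(-abs(z_fwd)), 2 * pnorm(-abs(z_rev)),
               tolerance = 1e-12)
  expect_true(all(vs1$q > 0 & vs1$q <= 1, na.rm = TRUE))
})

test_that("scoring is invariant to variant input order", {
  fx <- tiny_fixture()
  v <- fx$study$credible[1:30, ]
  vs1 <- score_variants(fx$ensemble, fx$study$genome, v, min_variants = 5L)
  o <- rev(seq_len(nrow(v)))
  vs2 <- score_variants(fx$ensemble, fx$study$genome, v[o, ], min_variants = 5L)
  m <- match(vs1$scores$variant_id, vs2$scores$variant_id)
  expect_equal(vs1$scores$min_q, vs2$scores$min_q[m])
  expect_equal(vs1$delta, vs2$delta[m, ])
})

test_that("min_q is the minimum over per-feature q-values", {
  fx <- tiny_fixture()
  v <- fx$study$credible[1:30, ]
  vs <- score_variants(fx$ensemble, fx$study$genome, v, min_variants = 5L)
  expect_equal(vs$scores$min_q,
               apply(vs$q, 1, min, na.rm = TRUE))
  expect_true(all(vs$scores$min_q <= vs$q, na.rm = TRUE))
  # top_feature attains the minimum
  for (i in seq_len(nrow(vs$scores)))
    expect_equal(unname(vs$q[i, vs$scores$top_feature[i]]),
                 vs$scores$min_q[i])
})

test_that("the scoring floor on variant count is enforced", {
  fx <- tiny_fixture()
  expect_error(score_variants(fx$ensemble, fx$study$genome,
                              fx$study$credible[1:5, ]),
               "stable standardization")
})

test_that("saturated mutagenesis zeroes reference cells and matches scoring", {
  fx <- tiny_fixture()
  tv <- fx$study$truth$variants
  v <- fx$study$credible[fx$study$credible$variant_id %in%
                           tv$variant_id[tv$causal], ][1, ]
  feat <- fx$ensemble$feature_names[1]
  sm <- saturated_mutagenesis(fx$ensemble, fx$study$genome, v$chrom, v$pos,
                              feat, flank = 10L)
  expect_equal(dim(sm$delta), c(21L, 4L))
  # reference-base cells are identically zero
  for (i in seq_along(sm$positions))
    expect_identical(sm$delta[i, sm$ref_bases[i]], 0)
  # the (pos, alt) cell equals the scoring delta computed on the same members
  vw <- epiconv:::.variant_windows(fx$study$genome, v,
                                   fx$ensemble$window_length)
  d <- epiconv:::.ensemble_delta(fx$ensemble, vw$ref_seq, vw$alt_seq)
  expect_identical(unname(sm$delta[as.character(v$pos), v$alt]),
                   unname(d[1, feat]))
  # importance is the largest-magnitude delta, signed
  for (i in seq_along(sm$positions))
    expect_equal(sm$importance[i],
                 sm$delta[i, which.max(abs(sm$delta[i, ]))])
  expect_error(saturated_mutagenesis(fx$ensemble, fx$study$genome, v$chrom,
                                     v$pos, "no_such_feature"),
               "available")
})

test_that("the motif scanner finds planted instances over the variant", {
  fx <- tiny_fixture()
  inst <- fx$study$truth$motif_instances[1, ]
  center <- inst$start + (inst$end - inst$start) %/% 2 + 1L
  hits <- motif_overlap_scan(fx$study$genome, inst$chrom, center,
                             fx$cfg$motifs, flank = 30L)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$motif[1], inst$motif)
  expect_equal(hits$strand[1], "+")
  expect_equal(hits$start[1], inst$start + 1L)
})

test_that("the scanner finds reverse-strand motifs with the strand flag", {
  # build a tiny genome carrying the reverse complement of a demo motif
  m <- demo_motifs()[[2]]
  cons <- pwm_consensus(m)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]),
                                     collapse = ""))
  set.seed(12)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  seq <- paste0(substr(bg, 1, 200), rc, substr(bg, 201, 400))
  genome <- Biostrings::DNAStringSet(c(chrT = seq))
  hits <- motif_overlap_scan(genome, "chrT", 206L, list(m), flank = 40L)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$strand[1], "-")
  expect_equal(hits$motif[1], m$name)
})

test_that("scans of pure background stay near the nominal false-positive rate", {
  set.seed(13)
  db <- c(demo_motifs(), decoy_motifs(5, seed = 21))
  n_hits <- replicate(30, {
    bg <- paste(sample(c("A", "C", "G", "T"), 301, TRUE), collapse = "")
    genome <- Biostrings::DNAStringSet(c(chrB = bg))
    nrow(motif_overlap_scan(genome, "chrB", 151L, db, flank = 150L))
  })
  # ~ 8 motifs x 2 strands x ~290 placements x 1e-4, restricted to hits over
  # the center: well below one expected hit per window
  expect_lt(mean(n_hits), 1)
})

test_that("variant score tables round-trip to TSV", {
  fx <- tiny_fixture()
  vs <- score_variants(fx$ensemble, fx$study$genome,
                       fx$study$credible[1:30, ], min_variants = 5L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_scores(vs, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(vs$scores))
  expect_true(all(c("variant_id", "min_q", "top_feature") %in% names(back)))
})
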