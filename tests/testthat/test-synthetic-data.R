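# Generators: determinism, conservation counts, credible-set and
# allele-count construction against their stated distributions.

small_cfg <- function(...) {
  sim_config(seed = 11, n_chroms = 2L, chrom_length = 60000L,
             n_instances_per_motif = 20L, n_signals = 6L,
             window_length = 500L, ...)
}

test_that("genome generation is deterministic and respects placement counts", {
  cfg <- small_cfg()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$motif_instances, g2$truth$motif_instances)
  inst <- g1$truth$motif_instances
  expect_equal(nrow(inst), 3L * 20L)
  # non-overlap within chromosomes
  for (ch in unique(inst$chrom)) {
    d <- inst[inst$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("zero motifs give a pure background genome", {
  cfg <- sim_config(seed = 2, n_chroms = 1L, chrom_length = 20000L,
                    motifs = list(), n_instances_per_motif = 0L,
                    feature_motif_matrix = matrix(0, 0, 0),
                    window_length = 500L)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$truth$motif_instances), 0L)
  expect_equal(Biostrings::width(g$genome), 20000L)
})

test_that("three motifs x 200 instances yield 600 non-overlapping intervals", {
  cfg <- sim_config(seed = 7, n_chroms = 3L, chrom_length = 300000L,
                    n_instances_per_motif = 200L)
  inst <- generate_genome(cfg)$truth$motif_instances
  expect_equal(nrow(inst), 600L)
  expect_equal(unname(table(inst$motif)[c("hnf1_like", "fox_like", "ctcf_like")]),
               rep(200L, 3), ignore_attr = TRUE)
})

test_that("excessive motif density fails with an explicit error", {
  cfg <- sim_config(seed = 1, n_chroms = 1L, chrom_length = 6000L,
                    n_instances_per_motif = 400L, window_length = 500L)
  expect_error(generate_genome(cfg), "density")
})

test_that("peak tracks conserve counts and honor the association matrix", {
  fm <- rbind(one = c(1, 0, 0), none = c(0, 0, 0), both = c(1, 1, 0))
  cfg <- small_cfg(feature_motif_matrix = fm, background_peak_rate = 0,
                   allow_background_features = TRUE)
  g <- generate_genome(cfg)
  tracks <- generate_peak_tracks(g$truth, cfg)
  expect_equal(nrow(tracks$one), 20L)   # exactly one peak per instance
  expect_equal(nrow(tracks$none), 0L)   # all-zero row, zero background rate
  expect_equal(nrow(tracks$both), 40L)
  # features sharing a motif share peak centers
  c_one <- with(tracks$one, paste(chrom, start + (end - start) %/% 2))
  c_both <- with(tracks$both, paste(chrom, start + (end - start) %/% 2))
  expect_true(all(c_one %in% c_both))
  # peak geometry: halfwidth on each side
  expect_equal(unique(tracks$one$end - tracks$one$start),
               2L * cfg$peak_halfwidth)
})

test_that("credible sets have one causal variant per signal and unit gPPA mass", {
  cfg <- small_cfg(convergence_pi = 1)
  g <- generate_genome(cfg)
  cred <- generate_credible_sets(g$genome, g$truth, cfg)
  v <- cred$variants
  expect_equal(nrow(v), cfg$n_signals * cfg$variants_per_signal)
  sums <- tapply(v$gppa, v$signal_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  tr <- cred$truth
  expect_equal(unname(tapply(tr$causal, tr$signal_id, sum)),
               rep(1, cfg$n_signals), ignore_attr = TRUE)
  # convergence_pi = 1 forces the causal variant to carry the top gPPA
  for (s in split(seq_len(nrow(v)), v$signal_id))
    expect_true(tr$causal[s][which.max(v$gppa[s])])
  # causal variants substitute a genome base inside a motif instance
  inst <- g$truth$motif_instances
  for (i in which(tr$causal)) {
    hit <- inst$chrom == v$chrom[i] & inst$start <= v$pos[i] - 1 &
      inst$end > v$pos[i] - 1
    expect_true(any(hit))
    expect_equal(substr(as.character(g$genome[[v$chrom[i]]]),
                        v$pos[i], v$pos[i]), v$ref[i])
    expect_true(v$alt[i] != v$ref[i])
  }
})

test_that("causal top-rank frequency matches convergence_pi", {
  # with symmetric Dirichlet PPAs and pi = 1/k, the causal variant should be
  # top-ranked in about 1/k of signals (swap either hits it or leaves a
  # uniformly random top)
  cfg <- sim_config(seed = 21, n_chroms = 2L, chrom_length = 200000L,
                    n_instances_per_motif = 400L, n_signals = 1000L,
                    variants_per_signal = 4L, convergence_pi = 0.25,
                    window_length = 500L, peak_halfwidth = 50L)
  g <- generate_genome(cfg)
  cred <- generate_credible_sets(g$genome, g$truth, cfg)
  v <- cred$variants; tr <- cred$truth
  top_causal <- vapply(split(seq_len(nrow(v)), v$signal_id),
                       function(s) tr$causal[s][which.max(v$gppa[s])], TRUE)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.25) / 1000
  expect_gt(mean(top_causal), ci[1])
  expect_lt(mean(top_causal), ci[2])
})

test_that("fewer than two variants per signal is rejected", {
  cfg <- small_cfg(variants_per_signal = 1L)
  g <- generate_genome(cfg)
  expect_error(generate_credible_sets(g$genome, g$truth, cfg),
               "variants_per_signal")
})

test_that("allelic counts are deterministic and match stated moments", {
  cfg <- small_cfg()
  g <- generate_genome(cfg)
  cred <- generate_credible_sets(g$genome, g$truth, cfg)
  c1 <- generate_allelic_counts(cred, cfg)
  c2 <- generate_allelic_counts(cred, cfg)
  expect_identical(c1, c2)
  expect_true(all(c1$ref_count >= 0 & c1$alt_count >= 0))

  # dispersion 0, balanced: ref fraction variance ~ p(1-p)/depth over 1e4 draws
  cfg0 <- sim_config(seed = 9, n_chroms = 2L, chrom_length = 200000L,
                     n_instances_per_motif = 300L, n_signals = 500L,
                     variants_per_signal = 4L, nb_dispersion = 0,
                     n_het_subjects = 5L, window_length = 500L,
                     peak_halfwidth = 50L, convergence_pi = 0)
  g0 <- generate_genome(cfg0)
  cred0 <- generate_credible_sets(g0$genome, g0$truth, cfg0)
  cred0$truth$true_fraction <- 0.5 # all balanced for the moment check
  cc <- generate_allelic_counts(cred0, cfg0)
  tot <- cc$ref_count + cc$alt_count
  keep <- tot >= 30
  frac <- cc$ref_count[keep] / tot[keep]
  expected_var <- mean(0.25 / tot[keep])
  expect_equal(var(frac), expected_var, tolerance = 0.1)
})

test_that("ground truth round-trips through JSON", {
  cfg <- small_cfg()
  study <- simulate_study(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(study$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$motif_instances, study$truth$motif_instances)
  expect_equal(back$variants, study$truth$variants)
})

test_that("redraw_ppas preserves structure and obeys convergence", {
  cfg <- small_cfg()
  g <- generate_genome(cfg)
  cred <- generate_credible_sets(g$genome, g$truth, cfg)
  v2 <- redraw_ppas(cred$variants, cred$truth, convergence_pi = 1, seed = 3)
  expect_identical(v2$variant_id, cred$variants$variant_id)
  sums <- tapply(v2$gppa, v2$signal_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  tr <- cred$truth
  for (s in split(seq_len(nrow(v2)), v2$signal_id))
    expect_true(tr$causal[s][which.max(v2$gppa[s])])
})
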