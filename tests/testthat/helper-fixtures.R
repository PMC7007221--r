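# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# small study + briefly trained 1-member ensemble: fast, used for contract
# tests (antisymmetry, consistency, interfaces) where predictive quality is
# irrelevant
tiny_fixture <- function() {
  if (!is.null(.fixture_cache$tiny)) return(.fixture_cache$tiny)
  cfg <- sim_config(seed = 101, n_chroms = 5L, chrom_length = 80000L,
                    n_instances_per_motif = 30L, n_signals = 12L,
                    window_length = 500L)
  study <- simulate_study(cfg)
  lw <- merge_peaks(epiconv:::peaks_from_tracks(study$tracks), 500L, 100L,
                    seqlengths = setNames(Biostrings::width(study$genome),
                                          names(study$genome)))
  ds <- encode_windows(lw, study$genome)
  ds <- split_by_chromosome(ds, "chr4", "chr5")
  hp <- hyperparams(conv_filters = c(12L, 12L, 16L),
                    conv_filter_sizes = c(14L, 5L, 5L),
                    fc_sizes = c(32L, 16L), seed = 1)
  ens <- train_ensemble(ds, list(hp), seed = 3, patience = 5L,
                        max_epochs = 12L)
  .fixture_cache$tiny <- list(cfg = cfg, study = study, dataset = ds,
                              ensemble = ens)
  .fixture_cache$tiny
}

# the standard synthetic benchmark (3 motifs, 6 features, 2.1 Mb genome)
# with a 5-member small ensemble; expensive, shared by the acceptance tests
benchmark_fixture <- function() {
  if (!is.null(.fixture_cache$bench)) return(.fixture_cache$bench)
  cfg <- sim_config(seed = 5)
  study <- simulate_study(cfg)
  lw <- merge_peaks(epiconv:::peaks_from_tracks(study$tracks), 1000L, 200L,
                    seqlengths = setNames(Biostrings::width(study$genome),
                                          names(study$genome)))
  ds <- encode_windows(lw, study$genome)
  ds <- split_by_chromosome(ds, "chr4", "chr5")
  ens <- train_ensemble(ds, small_hp_grid(5), seed = 5, patience = 25L,
                        max_epochs = 180L)
  scores <- score_variants(ens, study$genome, study$credible)
  .fixture_cache$bench <- list(cfg = cfg, study = study, dataset = ds,
                               ensemble = ens, scores = scores)
  .fixture_cache$bench
}
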