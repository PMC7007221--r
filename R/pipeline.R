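# Pipeline orchestration: a declarative configuration, staged execution
# with JSON manifests (input checksums, parameters, seed), and an
# end-to-end demo configuration sized for a laptop CPU.

#' Pipeline configuration
#'
#' Collects all stage parameters and paths behind one object. Every knob of
#' the underlying modules is mirrored here with its standard default.
#'
#' @param out_dir output directory (stages write TSV/JSON plus a manifest).
#' @param sim a [sim_config()] describing the synthetic study (stage
#'   `simulate`); pass `NULL` when running from external files.
#' @param hp_grid hyperparameter grid for training.
#' @param replicates replicates per grid setting.
#' @param window_length,max_overlap dataset construction.
#' @param validation_chroms,test_chroms chromosome hold-out.
#' @param patience,max_epochs training.
#' @param alpha regulatory q-value cutoff.
#' @param n_perm convergence permutations.
#' @param flank saturated-mutagenesis flank (bp).
#' @param fppa_floor,logq_gap signal refinement.
#' @param fdr,min_networks motif recurrence / caQTL thresholds
#'   (`min_networks = NULL` auto-scales).
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            hp_grid = small_hp_grid(),
                            replicates = 1L,
                            window_length = 1000L,
                            max_overlap = 200L,
                            validation_chroms = "chr4",
                            test_chroms = "chr5",
                            patience = 10L,
                            max_epochs = 120L,
                            alpha = 0.05,
                            n_perm = 1000L,
                            flank = 20L,
                            fppa_floor = 0.2,
                            logq_gap = 100,
                            fdr = 0.05,
                            min_networks = NULL,
                            seed = 1L) {
  structure(list(out_dir = out_dir, sim = sim, hp_grid = hp_grid,
                 replicates = as.integer(replicates),
                 window_length = as.integer(window_length),
                 max_overlap = as.integer(max_overlap),
                 validation_chroms = validation_chroms,
                 test_chroms = test_chroms,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 alpha = alpha, n_perm = as.integer(n_perm),
                 flank = as.integer(flank), fppa_floor = fppa_floor,
                 logq_gap = logq_gap, fdr = fdr, min_networks = min_networks,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Demo configuration: small genome, two members, minutes on one CPU
#' @param out_dir output directory.
#' @param seed master seed.
#' @return a `pipeline_config`.
#' @export
demo_config <- function(out_dir, seed = 1L) {
  pipeline_config(
    out_dir = out_dir,
    sim = sim_config(seed = seed, n_chroms = 5L, chrom_length = 160000L,
                     n_instances_per_motif = 60L, n_signals = 24L,
                     window_length = 600L),
    hp_grid = small_hp_grid(2),
    window_length = 600L,
    max_epochs = 60L,
    n_perm = 500L,
    min_networks = 2L,
    seed = seed)
}

.stage_order <- c("simulate", "build_dataset", "train", "evaluate", "motifs",
                  "score_variants", "satmut", "converge", "caqtl", "report")

.write_manifest <- function(config, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    parameters = config[setdiff(names(config), c("sim", "hp_grid"))],
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = outputs,
    package_version = as.character(utils::packageVersion("epiconv")))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.require_upstream <- function(config, files, needed_for, run_first) {
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("stage '", needed_for, "' is missing upstream output(s) ",
         paste(basename(missing), collapse = ", "),
         "; run stage '", run_first, "' first")
}

#' Run one pipeline stage
#'
#' Stages (in order): `simulate`, `build_dataset`, `train`, `evaluate`,
#' `motifs`, `score_variants`, `satmut`, `converge`, `caqtl`, `report`.
#' Each stage reads the previous stages' outputs from `out_dir`, writes its
#' own outputs plus a JSON manifest (parameters, seed, input checksums), and
#' is reproducible given the same inputs and seed. `state` carries in-memory
#' objects (dataset, ensemble) between stages within one session.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @param state environment carrying in-memory stage products.
#' @return the updated `state`, invisibly.
#' @export
run_stage <- function(name, config, state = new.env(parent = emptyenv())) {
  name <- match.arg(name, .stage_order)
  od <- config$out_dir
  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  genome_fa <- file.path(od, "genome.fa")
  cred_tsv <- file.path(od, "credible_sets.tsv")

  if (name == "simulate") {
    study <- simulate_study(config$sim, dir = od)
    state$study <- study
    .write_manifest(config, name, character(0),
                    c("genome.fa", "credible_sets.tsv", "allelic_counts.tsv",
                      "ground_truth.json"))
  } else if (name == "build_dataset") {
    .require_upstream(config, genome_fa, name, "simulate")
    study <- state$study
    peaks <- peaks_from_tracks(study$tracks)
    lw <- merge_peaks(peaks, config$window_length, config$max_overlap,
                      seqlengths = setNames(Biostrings::width(study$genome),
                                            names(study$genome)))
    ds <- encode_windows(lw, study$genome)
    ds <- split_by_chromosome(ds, config$validation_chroms, config$test_chroms)
    state$dataset <- ds
    write_tsv(data.frame(split = levels(ds$split),
                         n = as.integer(table(ds$split))),
              file.path(od, "dataset_splits.tsv"))
    .write_manifest(config, name, genome_fa, "dataset_splits.tsv")
  } else if (name == "train") {
    if (is.null(state$dataset)) stop("stage 'train' needs the dataset; run stage 'build_dataset' first")
    state$ensemble <- train_ensemble(state$dataset, config$hp_grid,
                                     config$replicates, seed = config$seed,
                                     patience = config$patience,
                                     max_epochs = config$max_epochs)
    logs <- do.call(rbind, lapply(seq_along(state$ensemble$members), function(m)
      data.frame(member = m, state$ensemble$members[[m]]$log)))
    write_tsv(logs, file.path(od, "training_log.tsv"))
    .write_manifest(config, name, genome_fa, "training_log.tsv")
  } else if (name == "evaluate") {
    if (is.null(state$ensemble)) stop("stage 'evaluate' needs a trained ensemble; run stage 'train' first")
    perf <- evaluate_model(state$ensemble, state$dataset, "test")
    write_tsv(perf, file.path(od, "performance.tsv"))
    state$performance <- perf
    .write_manifest(config, name, genome_fa, "performance.tsv")
  } else if (name == "motifs") {
    if (is.null(state$ensemble)) stop("stage 'motifs' needs a trained ensemble; run stage 'train' first")
    db <- c(config$sim$motifs,
            decoy_motifs(seed = config$seed + 7L,
                         dissimilar_to = config$sim$motifs))
    test_idx <- which(state$dataset$split == "test")
    matches <- ensemble_filter_matches(
      state$ensemble, state$dataset$x[, , test_idx, drop = FALSE], db,
      seed = config$seed)
    rec <- recurrent_motifs(matches, fdr = config$fdr,
                            min_networks = config$min_networks)
    write_tsv(rec, file.path(od, "recurrent_motifs.tsv"))
    state$recurrence <- rec
    state$motif_db <- db
    .write_manifest(config, name, genome_fa, "recurrent_motifs.tsv")
  } else if (name == "score_variants") {
    .require_upstream(config, c(genome_fa, cred_tsv), name, "simulate")
    if (is.null(state$ensemble)) stop("stage 'score_variants' needs a trained ensemble; run stage 'train' first")
    variants <- read_credible_sets(cred_tsv)
    vs <- score_variants(state$ensemble, state$study$genome, variants)
    write_variant_scores(vs, file.path(od, "variant_scores.tsv"))
    state$variants <- variants
    state$scores <- vs
    .write_manifest(config, name, c(genome_fa, cred_tsv), "variant_scores.tsv")
  } else if (name == "satmut") {
    if (is.null(state$scores)) stop("stage 'satmut' needs variant scores; run stage 'score_variants' first")
    top <- state$scores$scores[order(state$scores$scores$min_q), ][1, ]
    v <- state$variants[state$variants$variant_id == top$variant_id, ]
    sm <- saturated_mutagenesis(state$ensemble, state$study$genome,
                                v$chrom, v$pos, top$top_feature,
                                flank = config$flank)
    grid <- data.frame(position = sm$positions, ref = sm$ref_bases,
                       sm$delta, importance = sm$importance)
    write_tsv(grid, file.path(od, "satmut_top_variant.tsv"))
    state$satmut <- sm
    .write_manifest(config, name, genome_fa, "satmut_top_variant.tsv")
  } else if (name == "converge") {
    if (is.null(state$scores)) stop("stage 'converge' needs variant scores; run stage 'score_variants' first")
    pt_g <- permutation_test(state$scores, state$variants, "gppa",
                             alpha = config$alpha, n_perm = config$n_perm,
                             seed = config$seed)
    pt_f <- permutation_test(state$scores, state$variants, "fppa",
                             alpha = config$alpha, n_perm = config$n_perm,
                             seed = config$seed + 1L)
    refine <- signal_refinement(state$scores, state$variants,
                                config$fppa_floor, config$logq_gap,
                                config$alpha)
    write_tsv(as.data.frame(pt_g$curve), file.path(od, "threshold_curve_gppa.tsv"))
    write_tsv(refine, file.path(od, "signal_refinement.tsv"))
    conv <- data.frame(ppa_field = c("gppa", "fppa"),
                       observed_auc = c(pt_g$observed_auc, pt_f$observed_auc),
                       p = c(pt_g$p, pt_f$p))
    write_tsv(conv, file.path(od, "convergence.tsv"))
    state$convergence <- list(gppa = pt_g, fppa = pt_f, refinement = refine)
    .write_manifest(config, name, cred_tsv,
                    c("convergence.tsv", "signal_refinement.tsv"))
  } else if (name == "caqtl") {
    counts_tsv <- file.path(od, "allelic_counts.tsv")
    .require_upstream(config, counts_tsv, name, "simulate")
    counts <- read.delim(counts_tsv, stringsAsFactors = FALSE)
    res <- call_caqtls(counts, fdr = config$fdr)
    write_tsv(res, file.path(od, "caqtl.tsv"))
    state$caqtl <- res
    .write_manifest(config, name, counts_tsv, "caqtl.tsv")
  } else if (name == "report") {
    if (is.null(state$performance) || is.null(state$convergence))
      stop("stage 'report' needs evaluation and convergence results; run those stages first")
    report <- list(
      mean_test_auroc = mean(state$performance$auroc, na.rm = TRUE),
      mean_test_auprc = mean(state$performance$auprc, na.rm = TRUE),
      n_recurrent_motifs = sum(state$recurrence$recurrent %||% logical(0)),
      n_regulatory_variants = sum(state$scores$scores$min_q < config$alpha,
                                  na.rm = TRUE),
      convergence_p_gppa = state$convergence$gppa$p,
      convergence_p_fppa = state$convergence$fppa$p,
      n_caqtls = if (!is.null(state$caqtl)) sum(state$caqtl$is_caqtl) else NA)
    jsonlite::write_json(report, file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    .write_manifest(config, name, cred_tsv, "report.json")
  }
  invisible(state)
}

#' Run the full pipeline
#'
#' Executes all stages in order (see [run_stage()]).
#'
#' @param config a [pipeline_config()].
#' @param stages stages to run, in order.
#' @return the final state environment, invisibly.
#' @export
run_pipeline <- function(config, stages = .stage_order) {
  state <- new.env(parent = emptyenv())
  for (s in stages) run_stage(s, config, state)
  invisible(state)
}
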