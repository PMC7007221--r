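# Synthetic study generator: genomes with planted motif instances, per-feature
# peak tracks driven by a feature x motif association matrix, fine-mapping
# credible sets with one designated causal (motif-disrupting) variant per
# signal, and overdispersed allele-specific read counts. Every generator is
# deterministic under the master seed via named substreams.

#' Configuration of a synthetic study
#'
#' Defines the conditions a simulated study is generated under. Defaults are
#' the package's standard benchmark: a 2.1 Mb genome (5 chromosomes of
#' 420 kb), three planted motifs with 150 instances each, six epigenomic
#' features driven by a feature x motif matrix, credible sets of 5 variants
#' with genetic-functional convergence 0.9, and allele counts from 4
#' heterozygous subjects at mean depth 50 with beta-binomial overdispersion
#' 0.01 and a 70:30 planted imbalance at causal variants.
#'
#' @param seed master seed; all generator substreams derive from it.
#' @param n_chroms,chrom_length number of chromosomes and their length (bp).
#' @param gc_content background GC fraction in (0,1).
#' @param motifs list of [motif_pwm()] objects to plant.
#' @param n_instances_per_motif instances planted per motif.
#' @param feature_motif_matrix binary features x motifs matrix: which motifs
#'   drive which features. Unless `allow_background_features` is TRUE, every
#'   feature must be driven by at least one motif.
#' @param peak_halfwidth peaks extend this many bp either side of a motif
#'   instance center.
#' @param background_peak_rate Poisson rate of spurious peaks, per Mb per
#'   feature.
#' @param n_signals,variants_per_signal credible-set structure
#'   (`variants_per_signal` must be >= 2; rank analyses are undefined below
#'   that).
#' @param convergence_pi probability that the causal variant receives the top
#'   gPPA of its signal; `convergence_pi_f` is the analogous (independent)
#'   probability for fPPA.
#' @param convergence_pi_f functional-PPA convergence; defaults to
#'   `convergence_pi`.
#' @param n_het_subjects,read_depth_mean,nb_dispersion,imbalance_effect
#'   allele-count generation: number of heterozygous subjects, mean read
#'   depth per subject, beta-binomial overdispersion (rho, 0 = binomial),
#'   and the true reference-allele fraction at causal variants.
#' @param window_length model window length the genome must accommodate.
#' @param allow_background_features allow all-zero rows in
#'   `feature_motif_matrix` (features made of background peaks only).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 5L,
                       chrom_length = 420000L,
                       gc_content = 0.41,
                       motifs = demo_motifs(),
                       n_instances_per_motif = 150L,
                       feature_motif_matrix = default_feature_motif_matrix(length(motifs)),
                       peak_halfwidth = 200L,
                       background_peak_rate = 5,
                       n_signals = 40L,
                       variants_per_signal = 5L,
                       convergence_pi = 0.9,
                       convergence_pi_f = convergence_pi,
                       n_het_subjects = 4L,
                       read_depth_mean = 50,
                       nb_dispersion = 0.01,
                       imbalance_effect = 0.7,
                       window_length = 1000L,
                       allow_background_features = FALSE) {
  stopifnot(gc_content > 0, gc_content < 1,
            chrom_length >= 10 * window_length,
            nb_dispersion >= 0, nb_dispersion < 1,
            imbalance_effect > 0, imbalance_effect < 1,
            convergence_pi >= 0, convergence_pi <= 1,
            convergence_pi_f >= 0, convergence_pi_f <= 1)
  if (length(motifs) > 0) {
    stopifnot(is.matrix(feature_motif_matrix),
              ncol(feature_motif_matrix) == length(motifs))
    if (!allow_background_features && any(rowSums(feature_motif_matrix) == 0))
      stop("feature_motif_matrix has a feature with no driving motif; ",
           "set allow_background_features = TRUE to permit all-background features")
  }
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length), gc_content = gc_content,
              motifs = motifs,
              n_instances_per_motif = as.integer(n_instances_per_motif),
              feature_motif_matrix = feature_motif_matrix,
              peak_halfwidth = as.integer(peak_halfwidth),
              background_peak_rate = background_peak_rate,
              n_signals = as.integer(n_signals),
              variants_per_signal = as.integer(variants_per_signal),
              convergence_pi = convergence_pi,
              convergence_pi_f = convergence_pi_f,
              n_het_subjects = as.integer(n_het_subjects),
              read_depth_mean = read_depth_mean,
              nb_dispersion = nb_dispersion,
              imbalance_effect = imbalance_effect,
              window_length = as.integer(window_length))
  cfg$substreams <- substream_seeds(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param n_motifs number of motifs the default matrix should cover.
#' @export
default_feature_motif_matrix <- function(n_motifs = 3) {
  if (n_motifs == 0) return(matrix(0, 0, 0))
  single <- diag(1L, n_motifs)
  pairs <- t(vapply(seq_len(n_motifs), function(i) {
    v <- integer(n_motifs)
    v[c(i, i %% n_motifs + 1L)] <- 1L
    v
  }, integer(n_motifs)))
  m <- rbind(single, if (n_motifs > 1) pairs)
  rownames(m) <- c(paste0("open_", seq_len(n_motifs)),
                   if (n_motifs > 1) paste0("mark_", seq_len(n_motifs)))
  colnames(m) <- vapply(seq_len(n_motifs), function(i) paste0("m", i), "")
  m
}

#' Generate a background genome with planted motif instances
#'
#' Background bases are i.i.d. with the configured GC content. A sequence is
#' sampled from each motif's PWM for every instance (the highest-information
#' column is forced to its consensus base so that the designated causal
#' variant can disrupt it unambiguously) and implanted at non-overlapping
#' positions away from chromosome edges.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `truth`
#'   (ground-truth list; `truth$motif_instances` is a data frame of 0-based
#'   half-open intervals).
#' @export
generate_genome <- function(config) {
  set.seed(config$substreams[["genome"]])
  gc <- config$gc_content
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  seqs <- lapply(chroms, function(ch)
    sample(DNA_BASES, config$chrom_length, replace = TRUE, prob = probs))
  names(seqs) <- chroms

  margin <- config$window_length
  placements <- list()
  occupied <- lapply(chroms, function(ch) matrix(numeric(0), ncol = 2))
  names(occupied) <- chroms
  for (mi in seq_along(config$motifs)) {
    pwm <- config$motifs[[mi]]
    k <- nrow(pwm$mat)
    ic <- pwm_information(pwm)
    # highest-information column; among near-ties prefer the most central
    # (edge columns under-constrain a detector and make disruption ambiguous)
    cand <- which(ic >= max(ic) - 1e-9)
    hi_col <- cand[which.min(abs(cand - (k + 1) / 2))]
    n_inst <- config$n_instances_per_motif
    placed <- 0L
    tries <- 0L
    max_tries <- 200L * max(n_inst, 1L)
    rows <- vector("list", n_inst)
    while (placed < n_inst) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n_inst, " instances of motif '", pwm$name,
             "' without overlap: motif density exceeds what chrom_length ",
             config$chrom_length, " x ", config$n_chroms, " chroms can host")
      ch <- sample(chroms, 1L)
      start <- sample.int(config$chrom_length - 2L * margin - k, 1L) + margin
      occ <- occupied[[ch]]
      if (nrow(occ) && any(start < occ[, 2] & (start + k) > occ[, 1])) next
      occupied[[ch]] <- rbind(occ, c(start, start + k))
      inst_seq <- sample_pwm_sequence(pwm, force_consensus_at = hi_col)
      seqs[[ch]][(start + 1L):(start + k)] <- strsplit(inst_seq, "")[[1]]
      placed <- placed + 1L
      rows[[placed]] <- data.frame(chrom = ch, start = start, end = start + k,
                                   motif = pwm$name, motif_index = mi,
                                   hi_col = hi_col,
                                   stringsAsFactors = FALSE)
    }
    placements[[mi]] <- do.call(rbind, rows)
  }
  inst <- if (length(placements)) do.call(rbind, placements) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               motif = character(0), motif_index = integer(0),
               hi_col = integer(0))
  if (nrow(inst)) {
    inst <- inst[order(inst$chrom, inst$start), , drop = FALSE]
    inst$instance_id <- sprintf("inst_%05d", seq_len(nrow(inst)))
    rownames(inst) <- NULL
  } else {
    inst$instance_id <- character(0)
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- chroms
  list(genome = genome, truth = list(motif_instances = inst))
}

#' Generate per-feature peak tracks around planted motif instances
#'
#' Each feature receives a peak of `peak_halfwidth` either side of the center
#' of every instance of its associated motifs, plus Poisson background peaks
#' at `background_peak_rate` per Mb. Intervals are BED-style 0-based
#' half-open.
#'
#' @param truth ground truth from [generate_genome()].
#' @param config a [sim_config()].
#' @return named list (one per feature) of data frames with columns
#'   `chrom`, `start`, `end`, `origin` (`"motif"` or `"background"`).
#' @export
generate_peak_tracks <- function(truth, config) {
  set.seed(config$substreams[["peaks"]])
  fm <- config$feature_motif_matrix
  inst <- truth$motif_instances
  hw <- config$peak_halfwidth
  chroms <- paste0("chr", seq_len(config$n_chroms))
  mb <- config$chrom_length / 1e6
  tracks <- vector("list", nrow(fm))
  names(tracks) <- rownames(fm)
  for (f in seq_len(nrow(fm))) {
    keep <- inst[inst$motif_index %in% which(fm[f, ] == 1), , drop = FALSE]
    center <- keep$start + (keep$end - keep$start) %/% 2L
    motif_peaks <- data.frame(chrom = keep$chrom,
                              start = center - hw, end = center + hw,
                              origin = rep("motif", nrow(keep)),
                              stringsAsFactors = FALSE)
    bg <- lapply(chroms, function(ch) {
      n <- rpois(1L, config$background_peak_rate * mb)
      if (!n) return(NULL)
      c0 <- sample.int(config$chrom_length - 2L * config$window_length, n) +
        config$window_length
      data.frame(chrom = ch, start = c0 - hw, end = c0 + hw,
                 origin = "background", stringsAsFactors = FALSE)
    })
    tr <- rbind(motif_peaks, do.call(rbind, bg))
    tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
    rownames(tr) <- NULL
    tracks[[f]] <- tr
  }
  tracks
}

#' Write / read peak tracks as one BED file per feature
#' @param tracks output of [generate_peak_tracks()].
#' @param dir output directory.
#' @return `write_peak_beds` returns the file paths invisibly.
#' @export
write_peak_beds <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tracks), function(f) {
    p <- file.path(dir, paste0(f, ".bed"))
    gr <- GenomicRanges::GRanges(
      tracks[[f]]$chrom,
      IRanges::IRanges(tracks[[f]]$start + 1L, tracks[[f]]$end),
      name = tracks[[f]]$origin)
    rtracklayer::export(gr, p, format = "BED")
    p
  }, "")
  invisible(paths)
}

#' Generate fine-mapping credible sets with one causal variant per signal
#'
#' Each signal hosts `variants_per_signal` variants: one causal variant that
#' substitutes the consensus base at the highest-information column of a
#' planted motif instance with that column's least-probable base, and
#' background variants placed outside motif instances. Per-signal gPPAs are
#' drawn from a symmetric Dirichlet; with probability `convergence_pi` the
#' largest gPPA is swapped onto the causal variant. fPPAs are generated
#' analogously and independently with `convergence_pi_f`.
#'
#' @param genome,truth output of [generate_genome()].
#' @param config a [sim_config()].
#' @param seed_offset optional extra offset added to the `ppa` substream so
#'   replicate credible-set draws can be generated from one genome.
#' @return list with `variants` (the credible-set table; `pos` is 1-based)
#'   and `truth` (per-variant causal flag, affected features, true allelic
#'   fraction).
#' @export
generate_credible_sets <- function(genome, truth, config, seed_offset = 0L) {
  if (config$variants_per_signal < 2L)
    stop("variants_per_signal must be >= 2 (rank analyses are undefined)")
  inst <- truth$motif_instances
  if (nrow(inst) < config$n_signals)
    stop("not enough motif instances (", nrow(inst), ") to host ",
         config$n_signals, " causal variants")
  set.seed((config$substreams[["ppa"]] + as.integer(seed_offset)) %%
             .Machine$integer.max)
  fm <- config$feature_motif_matrix
  chrom_seqs <- as.character(genome)

  causal_idx <- sample.int(nrow(inst), config$n_signals)
  classes <- sample(c("secretion", "action", "other"), config$n_signals,
                    replace = TRUE, prob = c(0.4, 0.3, 0.3))
  vps <- config$variants_per_signal
  margin <- config$window_length

  assign_ppa <- function(k, causal_slot, pi) .draw_ppa(k, causal_slot, pi)

  used_pos <- paste(inst$chrom, "x") # placeholder; real collision set below
  taken <- new.env(hash = TRUE)
  for (i in seq_len(nrow(inst)))
    for (pp in inst$start[i]:(inst$end[i] - 1L))
      assign(paste0(inst$chrom[i], ":", pp), TRUE, envir = taken)

  vrows <- list(); trows <- list()
  vid <- 0L
  for (s in seq_len(config$n_signals)) {
    ci <- inst[causal_idx[s], ]
    pwm <- config$motifs[[ci$motif_index]]
    col <- ci$hi_col
    pos0 <- ci$start + col - 1L
    ref <- substr(chrom_seqs[[ci$chrom]], pos0 + 1L, pos0 + 1L)
    alt <- DNA_BASES[which.min(pwm$mat[col, ])]
    if (alt == ref) { # genome carries the consensus here, so only ties possible
      ord <- order(pwm$mat[col, ])
      alt <- DNA_BASES[setdiff(ord, match(ref, DNA_BASES))[1]]
    }
    slot <- sample.int(vps, 1L)
    feats <- rownames(fm)[fm[, ci$motif_index] == 1]
    sig_id <- sprintf("signal_%03d", s)
    gppa <- assign_ppa(vps, slot, config$convergence_pi)
    fppa <- assign_ppa(vps, slot, config$convergence_pi_f)
    for (v in seq_len(vps)) {
      vid <- vid + 1L
      if (v == slot) {
        chrom <- ci$chrom; p0 <- pos0; rf <- ref; al <- alt; causal <- TRUE
      } else {
        repeat {
          chrom <- sample(names(chrom_seqs), 1L)
          p0 <- sample.int(config$chrom_length - 2L * margin, 1L) + margin
          key <- paste0(chrom, ":", p0)
          if (!exists(key, envir = taken, inherits = FALSE)) break
        }
        rf <- substr(chrom_seqs[[chrom]], p0 + 1L, p0 + 1L)
        al <- sample(setdiff(DNA_BASES, rf), 1L)
        causal <- FALSE
      }
      assign(paste0(chrom, ":", p0), TRUE, envir = taken)
      vrows[[vid]] <- data.frame(
        signal_id = sig_id, variant_id = sprintf("var_%05d", vid),
        chrom = chrom, pos = p0 + 1L, ref = rf, alt = al,
        gppa = gppa[v], fppa = fppa[v], signal_class = classes[s],
        conservation = if (causal) rnorm(1, 2, 1) else rnorm(1, 0, 1),
        stringsAsFactors = FALSE)
      trows[[vid]] <- data.frame(
        variant_id = sprintf("var_%05d", vid), signal_id = sig_id,
        causal = causal,
        affected_features = if (causal) paste(feats, collapse = ",") else "",
        true_fraction = if (causal) config$imbalance_effect else 0.5,
        stringsAsFactors = FALSE)
    }
  }
  list(variants = do.call(rbind, vrows), truth = do.call(rbind, trows))
}

# draw one signal's PPA vector: symmetric Dirichlet, then the causal slot
# receives the top value with probability exactly `pi` (if the swap branch is
# not taken and the causal slot happens to lead, it is swapped away onto a
# uniformly chosen other slot, so `pi` is exact and interpretable)
.draw_ppa <- function(k, causal_slot, pi) {
  g <- rgamma(k, 1)
  p <- g / sum(g)
  top <- which.max(p)
  if (runif(1) < pi) {
    tmp <- p[causal_slot]; p[causal_slot] <- p[top]; p[top] <- tmp
  } else if (top == causal_slot) {
    other <- if (k == 2) setdiff(1:2, causal_slot) else
      sample(setdiff(seq_len(k), causal_slot), 1L)
    tmp <- p[causal_slot]; p[causal_slot] <- p[other]; p[other] <- tmp
  }
  p
}

#' Redraw per-signal PPA assignments for an existing credible-set table
#'
#' Draws fresh symmetric-Dirichlet gPPAs (and, independently, fPPAs) per
#' signal and swaps the largest value onto the causal variant with the
#' configured convergence probabilities, leaving variant identities and
#' positions untouched. Useful for replicate convergence experiments from a
#' single scored variant set.
#'
#' @param variants credible-set table (from [generate_credible_sets()]).
#' @param truth per-variant ground truth with `causal` flags.
#' @param convergence_pi,convergence_pi_f convergence probabilities.
#' @param seed integer seed.
#' @return the variant table with new `gppa` and `fppa` columns.
#' @export
redraw_ppas <- function(variants, truth, convergence_pi,
                        convergence_pi_f = convergence_pi, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  causal <- truth$causal[match(variants$variant_id, truth$variant_id)]
  for (idx in split(seq_len(nrow(variants)), variants$signal_id)) {
    slot <- which(causal[idx])
    for (field in c("gppa", "fppa")) {
      pi <- if (field == "gppa") convergence_pi else convergence_pi_f
      variants[[field]][idx] <- if (length(slot) == 1L)
        .draw_ppa(length(idx), slot, pi)
      else { g <- rgamma(length(idx), 1); g / sum(g) }
    }
  }
  variants
}

#' Generate allele-specific read counts at heterozygous sites
#'
#' Per variant and subject, total depth is drawn from an overdispersed count
#' distribution (negative binomial, mean `read_depth_mean`); the reference
#' count is beta-binomial given depth, with allelic fraction 0.5 at
#' non-causal variants and `imbalance_effect` at causal variants, and
#' extra-binomial dispersion `nb_dispersion` (0 reduces to binomial).
#'
#' @param cred output of [generate_credible_sets()].
#' @param config a [sim_config()].
#' @param seed_offset optional extra offset added to the `counts` substream.
#' @return data frame `variant_id`, `subject_id`, `ref_count`, `alt_count`.
#' @export
generate_allelic_counts <- function(cred, config, seed_offset = 0L) {
  stopifnot(config$n_het_subjects >= 1L)
  set.seed((config$substreams[["counts"]] + as.integer(seed_offset)) %%
             .Machine$integer.max)
  tr <- cred$truth
  n <- nrow(tr) * config$n_het_subjects
  vid <- rep(tr$variant_id, each = config$n_het_subjects)
  frac <- rep(tr$true_fraction, each = config$n_het_subjects)
  subj <- rep(sprintf("subj_%02d", seq_len(config$n_het_subjects)), nrow(tr))
  depth <- rnbinom(n, mu = config$read_depth_mean, size = 10)
  rho <- config$nb_dispersion
  p <- if (rho > 0) {
    a <- frac * (1 / rho - 1); b <- (1 - frac) * (1 / rho - 1)
    rbeta(n, a, b)
  } else frac
  ref <- rbinom(n, depth, p)
  data.frame(variant_id = vid, subject_id = subj,
             ref_count = ref, alt_count = depth - ref,
             stringsAsFactors = FALSE)
}

#' Run every generator of a configuration, optionally writing all artifacts
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `peaks/<feature>.bed`, `credible_sets.tsv`, `allelic_counts.tsv`,
#'   `motifs.meme` and `ground_truth.json`.
#' @return list with `genome`, `truth`, `tracks`, `credible`, `counts`,
#'   `config`.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  gen <- generate_genome(config)
  tracks <- generate_peak_tracks(gen$truth, config)
  cred <- generate_credible_sets(gen$genome, gen$truth, config)
  counts <- generate_allelic_counts(cred, config)
  truth <- list(motif_instances = gen$truth$motif_instances,
                variants = cred$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(gen$genome, file.path(dir, "genome.fa"))
    write_peak_beds(tracks, file.path(dir, "peaks"))
    write_tsv(cred$variants, file.path(dir, "credible_sets.tsv"))
    write_tsv(counts, file.path(dir, "allelic_counts.tsv"))
    write_meme(config$motifs, file.path(dir, "motifs.meme"))
    write_ground_truth(truth, file.path(dir, "ground_truth.json"))
  }
  list(genome = gen$genome, truth = truth, tracks = tracks,
       credible = cred$variants, counts = counts, config = config)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ground-truth JSON round trip
#' @param truth,path ground-truth list and file path.
#' @return `read_ground_truth` returns the ground-truth list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, as.data.frame, stringsAsFactors = FALSE)
}
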