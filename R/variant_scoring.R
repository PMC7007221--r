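# Variant regulatory-effect scoring: ensemble-averaged prediction
# differences between alleles, per-feature normal-CDF p-values with BH
# correction, in-silico saturated mutagenesis, and a log-odds PWM scan for
# motifs overlapping a variant.

#' Read a credible-set variant table
#'
#' Expects a TSV with header `signal_id variant_id chrom pos ref alt gppa
#' fppa` and optional `signal_class`, `conservation`. `pos` is 1-based.
#'
#' @param path file path.
#' @return data frame of credible variants.
#' @export
read_credible_sets <- function(path) {
  v <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("signal_id", "variant_id", "chrom", "pos", "ref", "alt",
            "gppa", "fppa")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("credible-set table lacks column(s): ",
                         paste(miss, collapse = ", "))
  v
}

# build ref/alt window sequences for variants; returns list with character
# vectors ref_seq/alt_seq and logical keep (in-bounds, ref matches genome)
.variant_windows <- function(genome, variants, window_length) {
  half <- window_length %/% 2L
  start0 <- variants$pos - 1L - half # variant sits at 0-based offset `half`
  widths <- setNames(Biostrings::width(genome), names(genome))
  keep <- variants$chrom %in% names(genome) &
    start0 >= 0 & (start0 + window_length) <= widths[variants$chrom]
  keep[is.na(keep)] <- FALSE
  ref_seq <- alt_seq <- rep(NA_character_, nrow(variants))
  reason <- rep(NA_character_, nrow(variants))
  reason[!keep] <- "window out of bounds"
  idx <- which(keep)
  if (length(idx)) {
    seqs <- extract_sequences(genome, variants$chrom[idx], start0[idx],
                              start0[idx] + window_length)
    obs <- toupper(substr(seqs, half + 1L, half + 1L))
    ok <- obs == toupper(variants$ref[idx])
    reason[idx[!ok]] <- sprintf("ref mismatch: genome has %s", obs[!ok])
    keep[idx[!ok]] <- FALSE
    good <- idx[ok]
    ref_seq[good] <- seqs[ok]
    alt <- seqs[ok]
    substr(alt, half + 1L, half + 1L) <- toupper(variants$alt[good])
    alt_seq[good] <- alt
  }
  list(ref_seq = ref_seq, alt_seq = alt_seq, keep = keep, reason = reason)
}

# mean over ensemble members of (prediction(alt) - prediction(ref)), on the
# probability scale and on the log-odds scale; accumulated in fixed member
# order, with each window predicted independently (batch size 1), so that
# the same variant yields bit-identical effects regardless of how many
# windows are scored alongside it
.ensemble_delta <- function(ensemble, ref_seq, alt_seq, batch_size = 1L) {
  batch_size <- 1L # per-window prediction; see comment above
  x_ref <- one_hot_encode(ref_seq)
  x_alt <- one_hot_encode(alt_seq)
  M <- length(ensemble$members)
  lgt <- function(p) {
    p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
    log(p / (1 - p))
  }
  delta <- dlogit <- NULL
  for (m in seq_len(M)) {
    pr <- cpp_cnn_predict(ensemble$members[[m]]$params, x_ref, batch_size)
    pa <- cpp_cnn_predict(ensemble$members[[m]]$params, x_alt, batch_size)
    d <- pa - pr
    dl <- lgt(pa) - lgt(pr)
    delta <- if (is.null(delta)) d else delta + d
    dlogit <- if (is.null(dlogit)) dl else dlogit + dl
  }
  delta <- delta / M
  dlogit <- dlogit / M
  colnames(delta) <- colnames(dlogit) <- ensemble$feature_names
  attr(delta, "logit") <- dlogit
  delta
}

#' Score variants by ensemble prediction differences
#'
#' For each variant, predictions are made for two `window_length` sequences
#' centered on the variant, carrying the reference and alternative allele;
#' the per-feature effect is the mean prediction difference (alt - ref)
#' across ensemble members. Per feature, effects are standardized across the
#' scored variants (z), converted to normal-CDF p-values, and BH-adjusted
#' within the feature; each variant's overall regulatory score is its lowest
#' q-value across features.
#'
#' @param ensemble a `cnn_ensemble`.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param variants credible-variant data frame (see [read_credible_sets()]).
#' @param center `"empirical"` standardizes against the mean effect of the
#'   scored set; `"zero"` uses mu = 0.
#' @param effect_scale scale on which the standardized test statistic is
#'   computed: `"logit"` (default) uses log-odds prediction differences,
#'   which are variance-stable across the sigmoid's range; `"probability"`
#'   tests the raw probability differences. Reported `delta` values are
#'   always probability differences.
#' @param sided `"two"` (default) or `"one"` (lower tail of z).
#' @param min_variants required number of scored variants for stable
#'   standardization.
#' @param batch_size prediction batch size.
#' @return object of class `variant_scores`: list with `scores` (data frame
#'   `variant_id`, `signal_id`, `min_q`, `top_feature`), matrices `delta`,
#'   `z`, `p`, `q` (variants x features), `feature_names`, and `skipped`
#'   (per-variant error records).
#' @export
score_variants <- function(ensemble, genome, variants,
                           center = c("empirical", "zero"),
                           effect_scale = c("logit", "probability"),
                           sided = c("two", "one"),
                           min_variants = 20L, batch_size = 256L) {
  center <- match.arg(center)
  effect_scale <- match.arg(effect_scale)
  sided <- match.arg(sided)
  genome <- load_genome(genome)
  vw <- .variant_windows(genome, variants, ensemble$window_length)
  skipped <- data.frame(variant_id = variants$variant_id[!vw$keep],
                        reason = vw$reason[!vw$keep],
                        stringsAsFactors = FALSE)
  keep <- which(vw$keep)
  if (length(keep) < min_variants)
    stop("only ", length(keep), " scoreable variants; >= ", min_variants,
         " required for stable standardization")
  delta <- .ensemble_delta(ensemble, vw$ref_seq[keep], vw$alt_seq[keep],
                           batch_size)
  eff <- if (effect_scale == "logit") attr(delta, "logit") else delta
  attr(delta, "logit") <- NULL
  mu <- if (center == "empirical") colMeans(eff) else
    rep(0, ncol(eff))
  sigma <- apply(eff, 2L, sd)
  z <- p <- q <- matrix(NA_real_, nrow(delta), ncol(delta),
                        dimnames = dimnames(delta))
  for (f in seq_len(ncol(delta))) {
    if (!is.finite(sigma[f]) || sigma[f] == 0) {
      warning("feature '", colnames(delta)[f],
              "' has zero effect variance and was skipped")
      next
    }
    z[, f] <- (eff[, f] - mu[f]) / sigma[f]
    p[, f] <- if (sided == "two") 2 * pnorm(-abs(z[, f])) else pnorm(z[, f])
    q[, f] <- p.adjust(p[, f], method = "BH")
  }
  min_q <- apply(q, 1L, function(r) if (all(is.na(r))) NA_real_ else
    min(r, na.rm = TRUE))
  top_feature <- colnames(q)[apply(q, 1L, function(r)
    if (all(is.na(r))) NA_integer_ else which.min(r))]
  scores <- data.frame(variant_id = variants$variant_id[keep],
                       signal_id = variants$signal_id[keep],
                       min_q = min_q, top_feature = top_feature,
                       stringsAsFactors = FALSE)
  structure(list(scores = scores, delta = delta, z = z, p = p, q = q,
                 feature_names = ensemble$feature_names, skipped = skipped),
            class = "variant_scores")
}

#' @export
print.variant_scores <- function(x, ...) {
  cat(sprintf("<variant_scores> %d variants x %d features; %d with min q < 0.05\n",
              nrow(x$scores), length(x$feature_names),
              sum(x$scores$min_q < 0.05, na.rm = TRUE)))
  if (nrow(x$skipped)) cat(" skipped:", nrow(x$skipped), "variant(s)\n")
  invisible(x)
}

#' Write variant scores as a wide TSV
#' @param scores a `variant_scores` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variant_scores <- function(scores, path) {
  wide <- cbind(scores$scores,
                setNames(as.data.frame(scores$delta),
                         paste0("delta_", colnames(scores$delta))),
                setNames(as.data.frame(scores$q),
                         paste0("q_", colnames(scores$q))))
  write_tsv(wide, path)
}

#' In-silico saturated mutagenesis around a genomic position
#'
#' For every position within `flank` bp of `pos` and every non-reference
#' base, computes the ensemble-mean prediction difference for one feature.
#' Per-position importance is the largest-magnitude difference at that
#' position, signed.
#'
#' @param ensemble a `cnn_ensemble`.
#' @param genome genome (DNAStringSet or FASTA path).
#' @param chrom,pos variant chromosome and 1-based position.
#' @param feature feature name to track.
#' @param flank bp either side of `pos` (default 20, i.e. a 41-position
#'   grid).
#' @param batch_size prediction batch size.
#' @return object of class `satmut_result`: list with `positions` (1-based),
#'   `ref_bases`, `delta` (positions x 4 matrix, reference cells 0),
#'   `importance`, `feature`.
#' @export
saturated_mutagenesis <- function(ensemble, genome, chrom, pos, feature,
                                  flank = 20L, batch_size = 256L) {
  genome <- load_genome(genome)
  fi <- match(feature, ensemble$feature_names)
  if (is.na(fi))
    stop("unknown feature '", feature, "'; available: ",
         paste(ensemble$feature_names, collapse = ", "))
  positions <- (pos - flank):(pos + flank)
  grid <- expand.grid(pos = positions, alt = DNA_BASES,
                      stringsAsFactors = FALSE)
  half <- ensemble$window_length %/% 2L
  ref_at <- function(p) toupper(extract_sequences(genome, chrom, p - 1L, p))
  ref_bases <- vapply(positions, ref_at, "")
  grid$ref <- ref_bases[match(grid$pos, positions)]
  grid <- grid[grid$alt != grid$ref, , drop = FALSE]
  vt <- data.frame(variant_id = sprintf("mut_%d_%s", grid$pos, grid$alt),
                   chrom = chrom, pos = grid$pos, ref = grid$ref,
                   alt = grid$alt, stringsAsFactors = FALSE)
  vw <- .variant_windows(genome, vt, ensemble$window_length)
  if (!all(vw$keep)) stop("mutagenesis window exceeds the contig")
  d <- .ensemble_delta(ensemble, vw$ref_seq, vw$alt_seq, batch_size)
  attr(d, "logit") <- NULL
  d <- d[, fi]
  delta <- matrix(0, length(positions), 4L,
                  dimnames = list(positions, DNA_BASES))
  delta[cbind(match(grid$pos, positions), match(grid$alt, DNA_BASES))] <- d
  importance <- apply(delta, 1L, function(r) r[which.max(abs(r))])
  structure(list(positions = positions, ref_bases = ref_bases, delta = delta,
                 importance = unname(importance), feature = feature,
                 flank = flank),
            class = "satmut_result")
}

#' Scan a window for database motifs overlapping a variant
#'
#' Log-odds scan of both strands against a background base composition; the
#' null distribution of single-placement scores is computed exactly by
#' discretized dynamic programming over the background, as in standard motif
#' scanners. Hits overlapping the variant position below the p-value
#' threshold are returned.
#'
#' @param genome genome (DNAStringSet or FASTA path).
#' @param chrom,pos variant chromosome and 1-based position.
#' @param database list of `motif_pwm`.
#' @param flank scan window half-width in bp.
#' @param p_threshold per-placement p-value threshold.
#' @param background base composition (A, C, G, T); default uniform.
#' @return data frame `motif`, `start`, `end` (1-based inclusive genome
#'   coordinates), `strand`, `score`, `p`, restricted to hits overlapping
#'   `pos`, sorted by p.
#' @export
motif_overlap_scan <- function(genome, chrom, pos, database, flank = 50L,
                               p_threshold = 1e-4,
                               background = rep(0.25, 4)) {
  genome <- load_genome(genome)
  width <- setNames(Biostrings::width(genome), names(genome))[chrom]
  s0 <- max(0L, pos - 1L - flank)
  e0 <- min(width, pos + flank)
  seq <- toupper(extract_sequences(genome, chrom, s0, e0))
  base_idx <- match(strsplit(seq, "")[[1]], DNA_BASES)
  rows <- list()
  for (db in database) {
    for (strand in c("+", "-")) {
      pwm <- if (strand == "+") db else pwm_revcomp(db)
      lo <- log2((pwm$mat + 1e-3) / (1 + 4e-3)) -
        matrix(log2(background), nrow(pwm$mat), 4, byrow = TRUE)
      null <- .logodds_null(lo, background)
      k <- nrow(lo)
      if (length(base_idx) < k) next
      for (off in 0:(length(base_idx) - k)) {
        idx <- base_idx[(off + 1):(off + k)]
        if (anyNA(idx)) next
        sc <- sum(lo[cbind(seq_len(k), idx)])
        pv <- null$pval(sc)
        if (pv < p_threshold) {
          start <- s0 + off + 1L # back to 1-based
          end <- start + k - 1L
          if (pos >= start && pos <= end)
            rows[[length(rows) + 1L]] <-
              data.frame(motif = db$name, start = start, end = end,
                         strand = strand, score = sc, p = pv,
                         stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), start = integer(0), end = integer(0),
               strand = character(0), score = numeric(0), p = numeric(0))
  out[order(out$p), , drop = FALSE]
}

# exact discretized null of the log-odds score of one placement under the
# background: convolve per-position score distributions on an integer grid
.logodds_null <- function(lo, background, scale = 100) {
  k <- nrow(lo)
  grid <- round(lo * scale)
  offset <- -sum(apply(grid, 1L, min))
  len <- sum(apply(grid, 1L, max)) + offset + 1L
  pmf <- numeric(len); pmf[1] <- 1 # distribution of shifted partial sums
  shift <- 0L
  for (i in seq_len(k)) {
    mn <- min(grid[i, ])
    new <- numeric(len)
    for (b in 1:4) {
      d <- grid[i, b] - mn
      if (background[b] > 0)
        new[(1 + d):len] <- new[(1 + d):len] +
          pmf[1:(len - d)] * background[b]
    }
    pmf <- new
    shift <- shift + mn
  }
  cum <- rev(cumsum(rev(pmf))) # upper tail
  list(pval = function(score) {
    s <- round(score * scale) - shift + 1L
    if (s <= 0) 1 else if (s > len) 0 else cum[s]
  })
}
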