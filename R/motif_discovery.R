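# Motif discovery from first-layer convolutional filters: filter -> PWM via
# half-maximum activating subsequences, an internal PWM-vs-PWM matcher
# (column-Pearson alignment score with a column-shuffle permutation null and
# BH correction), cross-network recurrence, and redundancy filtering.

#' Derive PWMs from first-layer filter activations
#'
#' For each first-layer filter, activations are computed over a sample of
#' encoded sequences; all subsequence alignments activating the filter to
#' more than half of its maximum value over that sample are stacked, and
#' per-position base counts (plus a pseudocount) are normalized into a PWM.
#' Filters whose activation standard deviation is zero are flagged
#' non-informative and yield no PWM, as do filters with no positive
#' activation.
#'
#' @param model a trained `cnn_model`.
#' @param x a 4 x L x N one-hot array or `encoded_dataset` sample.
#' @param pseudocount added to every base count before normalization.
#' @param max_windows cap on the number of sample windows used.
#' @return object of class `filter_pwms`: list with `summary` (data frame:
#'   `filter`, `activation_sd`, `max_activation`, `n_sites`, `informative`)
#'   and `pwms` (list of `motif_pwm` or NULL).
#' @export
filter_pwms <- function(model, x, pseudocount = 0.5, max_windows = 200L) {
  if (inherits(x, "encoded_dataset")) x <- x$x
  n <- dim(x)[3]
  if (n > max_windows) x <- x[, , seq_len(max_windows), drop = FALSE]
  act <- cpp_conv1_activations(model$params, x) # filters x positions x windows
  k <- model$hp$conv_filter_sizes[1]
  nf <- dim(act)[1]
  pwms <- vector("list", nf)
  sds <- maxs <- numeric(nf)
  nsites <- integer(nf)
  for (f in seq_len(nf)) {
    a <- act[f, , ]
    sds[f] <- sd(a)
    maxs[f] <- max(a)
    if (sds[f] == 0 || maxs[f] <= 0) next
    hits <- which(a > maxs[f] / 2, arr.ind = TRUE) # (position, window)
    counts <- matrix(0, nrow = k, ncol = 4, dimnames = list(NULL, DNA_BASES))
    for (h in seq_len(nrow(hits)))
      counts <- counts +
        t(x[, hits[h, 1]:(hits[h, 1] + k - 1L), hits[h, 2]])
    nsites[f] <- nrow(hits)
    counts <- counts + pseudocount
    pwms[[f]] <- motif_pwm(counts / rowSums(counts),
                           name = sprintf("filter_%03d", f))
  }
  structure(list(
    summary = data.frame(filter = seq_len(nf), activation_sd = sds,
                         max_activation = maxs, n_sites = nsites,
                         informative = sds > 0),
    pwms = pwms), class = "filter_pwms")
}

# normalized PWM columns for Pearson scoring: row i of the result is the
# centered, unit-norm base distribution at position i (zero row if constant)
.pwm_norm <- function(mat) {
  c0 <- mat - rowMeans(mat)
  nrm <- sqrt(rowSums(c0^2))
  nrm[nrm < 1e-12] <- Inf
  c0 / nrm
}

# complement columns without reversing (reversal handled by index order)
.pwm_complement <- function(mat) {
  m <- mat[, c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- DNA_BASES
  m
}

# best summed-column-Pearson score over all offsets for a given column-order
# cross-correlation matrix C (Lq x Ld), overlap >= min_ov
.best_offset_score <- function(C, min_ov) {
  Lq <- nrow(C); Ld <- ncol(C)
  best <- -Inf; best_off <- 0L
  for (s in (-(Lq - min_ov)):(Ld - min_ov)) {
    i <- max(1L, 1L - s):min(Lq, Ld - s)
    sc <- sum(C[cbind(i, i + s)])
    if (sc > best) { best <- sc; best_off <- s }
  }
  c(best, best_off)
}

#' Match a query PWM against a motif database
#'
#' For each database motif the best alignment over all offsets and both
#' orientations is scored by the sum of per-column Pearson correlations;
#' p-values come from a permutation null in which the database motif's
#' columns are shuffled, and are BH-adjusted across the database.
#'
#' @param query a `motif_pwm`.
#' @param database list of `motif_pwm`.
#' @param n_shuffles permutation null size.
#' @param seed seed for the shuffles.
#' @param min_overlap minimum aligned columns (query must be at least this
#'   long).
#' @return data frame: `motif`, `score`, `offset`, `orientation`, `p`, `q`,
#'   sorted by increasing p.
#' @export
match_pwm <- function(query, database, n_shuffles = 500L, seed = 1L,
                      min_overlap = 4L) {
  stopifnot(length(database) >= 1L)
  if (nrow(query$mat) < min_overlap)
    stop("query PWM shorter than the minimum alignment overlap (", min_overlap, ")")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  qn <- .pwm_norm(query$mat)
  Lq <- nrow(qn)
  rows <- lapply(database, function(db) {
    dn <- .pwm_norm(db$mat)
    dnc <- .pwm_norm(.pwm_complement(db$mat))
    Ld <- nrow(db$mat)
    Cf <- qn %*% t(dn)   # forward, db in native column order
    C2 <- qn %*% t(dnc)  # complemented columns (reversal via index order)
    Cr <- C2[, Ld:1, drop = FALSE] # reverse complement
    fwd <- .best_offset_score(Cf, min_overlap)
    rev_ <- .best_offset_score(Cr, min_overlap)
    if (fwd[1] >= rev_[1]) {
      obs <- fwd[1]; off <- fwd[2]; ori <- "+"
    } else {
      obs <- rev_[1]; off <- rev_[2]; ori <- "-"
    }
    # permutation null, vectorized over shuffles: P[r, ] is the r-th column
    # order of the database motif; an alignment's null score accumulates
    # C[i_k, P[, j_k]] over the overlapping columns
    P <- t(vapply(seq_len(n_shuffles), function(r) sample.int(Ld),
                  integer(Ld)))
    best <- rep(-Inf, n_shuffles)
    for (s in (-(Lq - min_overlap)):(Ld - min_overlap)) {
      i <- max(1L, 1L - s):min(Lq, Ld - s)
      j <- i + s
      sc_f <- numeric(n_shuffles)
      sc_r <- numeric(n_shuffles)
      for (k in seq_along(i)) {
        sc_f <- sc_f + Cf[i[k], ][P[, j[k]]]
        sc_r <- sc_r + C2[i[k], ][P[, Ld + 1L - j[k]]]
      }
      best <- pmax(best, sc_f, sc_r)
    }
    data.frame(motif = db$name, score = obs, offset = off, orientation = ori,
               p = (1 + sum(best >= obs)) / (1 + n_shuffles),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$motif), , drop = FALSE]
}

#' Match all informative filters of an ensemble against a database
#'
#' @param ensemble a `cnn_ensemble`.
#' @param x one-hot sample used for activations (array or
#'   `encoded_dataset`).
#' @param database list of `motif_pwm`.
#' @param n_shuffles,seed permutation-null settings for [match_pwm()].
#' @param max_windows,pseudocount passed to [filter_pwms()].
#' @return list, one element per ensemble member, each a data frame of
#'   filter-level matches with columns `network`, `filter`, `motif`,
#'   `score`, `p`, `q` (BH across the database, per filter).
#' @export
ensemble_filter_matches <- function(ensemble, x, database,
                                    n_shuffles = 500L, seed = 1L,
                                    max_windows = 200L, pseudocount = 0.5) {
  lapply(seq_along(ensemble$members), function(m) {
    fp <- filter_pwms(ensemble$members[[m]], x, pseudocount = pseudocount,
                      max_windows = max_windows)
    keep <- which(!vapply(fp$pwms, is.null, TRUE))
    rows <- lapply(keep, function(f) {
      mt <- match_pwm(fp$pwms[[f]], database, n_shuffles = n_shuffles,
                      seed = seed + 7919L * m + f)
      mt$network <- m
      mt$filter <- f
      mt
    })
    do.call(rbind, rows)
  })
}

#' Recurrent motifs across networks
#'
#' Counts, per database motif, the networks in which it is matched below the
#' FDR threshold (each network counted once, via its best-matching filter)
#' and keeps motifs detected in at least `min_networks` networks. With the
#' historical 1000-network ensemble the default threshold is 50 networks;
#' for other ensemble sizes it scales as `ceiling(0.05 * n_networks)` unless
#' given explicitly.
#'
#' @param matches list of per-network match tables
#'   (from [ensemble_filter_matches()]).
#' @param fdr q-value threshold for counting a match.
#' @param min_networks recurrence threshold (see above).
#' @return data frame `motif`, `n_networks`, `recurrent`, sorted by
#'   decreasing `n_networks`.
#' @export
recurrent_motifs <- function(matches, fdr = 0.05, min_networks = NULL) {
  stopifnot(length(matches) >= 1L)
  n_networks <- length(matches)
  if (is.null(min_networks))
    min_networks <- if (n_networks == 1000L) 50L else
      as.integer(ceiling(0.05 * n_networks))
  per_net <- lapply(matches, function(mt) {
    if (is.null(mt) || !nrow(mt)) return(character(0))
    sig <- mt[mt$q < fdr, , drop = FALSE]
    unique(sig$motif)
  })
  counts <- table(unlist(per_net))
  if (!length(counts))
    return(data.frame(motif = character(0), n_networks = integer(0),
                      recurrent = logical(0)))
  out <- data.frame(motif = names(counts), n_networks = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$recurrent <- out$n_networks >= min_networks
  out <- out[order(-out$n_networks, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_networks") <- min_networks
  out
}

#' Collapse redundant database motifs in a recurrence table
#'
#' Database motifs are compared all-against-all with [match_pwm()]; the
#' recurrence table is then collapsed greedily by descending network count,
#' reporting each absorbed motif under its representative as a secondary
#' motif.
#'
#' @param recurrence output of [recurrent_motifs()] (recurrent rows are
#'   used).
#' @param database the motif database (list of `motif_pwm`).
#' @param fdr q-value threshold for declaring two database motifs redundant.
#' @param n_shuffles,seed permutation-null settings for the all-vs-all
#'   comparison.
#' @return data frame `motif`, `n_networks`, `secondary` (comma-separated).
#' @export
deduplicate_motifs <- function(recurrence, database, fdr = 0.05,
                               n_shuffles = 500L, seed = 1L) {
  rec <- recurrence[recurrence$recurrent, , drop = FALSE]
  if (!nrow(rec)) return(data.frame(motif = character(0),
                                    n_networks = integer(0),
                                    secondary = character(0)))
  names(database) <- vapply(database, `[[`, "", "name")
  similar <- lapply(rec$motif, function(nm) {
    others <- database[setdiff(names(database), nm)]
    if (!length(others)) return(character(0))
    mt <- match_pwm(database[[nm]], others, n_shuffles = n_shuffles,
                    seed = seed + utf8ToInt(substr(nm, 1, 1)))
    mt$motif[mt$q < fdr]
  })
  names(similar) <- rec$motif
  remaining <- rec[order(-rec$n_networks, rec$motif), , drop = FALSE]
  out <- list()
  while (nrow(remaining)) {
    top <- remaining[1L, ]
    sec <- intersect(similar[[top$motif]], remaining$motif[-1L])
    out[[length(out) + 1L]] <- data.frame(
      motif = top$motif, n_networks = top$n_networks,
      secondary = paste(sec, collapse = ","), stringsAsFactors = FALSE)
    remaining <- remaining[!(remaining$motif %in% c(top$motif, sec)), ,
                           drop = FALSE]
  }
  do.call(rbind, out)
}
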