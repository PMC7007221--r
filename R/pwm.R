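# Position weight matrices: construction, information content, reverse
# complement, MEME minimal format I/O, and the demo motif/decoy generators
# used by the synthetic benchmark.

DNA_BASES <- c("A", "C", "G", "T")

#' Create a position weight matrix object
#'
#' A `motif_pwm` is a positions x 4 matrix of per-position nucleotide
#' probabilities (columns A, C, G, T), each row summing to one.
#'
#' @param mat numeric matrix, positions x 4. Rows are renormalized only if
#'   within `1e-6` of summing to one; otherwise an error is raised.
#' @param name motif name.
#' @return an object of class `motif_pwm`.
#' @export
motif_pwm <- function(mat, name = "motif") {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(mat) < 4L) stop("PWM must have length >= 4")
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-6)) stop("PWM rows must sum to 1 (tolerance 1e-6)")
  mat <- mat / rs
  colnames(mat) <- DNA_BASES
  rownames(mat) <- NULL
  structure(list(name = as.character(name), mat = mat), class = "motif_pwm")
}

#' @export
print.motif_pwm <- function(x, ...) {
  cat(sprintf("<motif_pwm> %s  (%d bp, IC %.1f bits)\n",
              x$name, nrow(x$mat), sum(pwm_information(x))))
  cat(" consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Per-position information content of a PWM, in bits
#' @param pwm a `motif_pwm`.
#' @return numeric vector, one value per motif position.
#' @export
pwm_information <- function(pwm) {
  p <- pwm$mat
  apply(p, 1L, function(v) {
    v <- v[v > 0]
    2 + sum(v * log2(v))
  })
}

#' @rdname pwm_information
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[max.col(pwm$mat, ties.method = "first")], collapse = "")
}

#' Reverse complement of a PWM
#' @param pwm a `motif_pwm`.
#' @return a `motif_pwm` on the opposite strand.
#' @export
pwm_revcomp <- function(pwm) {
  m <- pwm$mat[rev(seq_len(nrow(pwm$mat))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- DNA_BASES
  motif_pwm(m, name = pwm$name)
}

# sample a sequence from a PWM; optionally force one column to its consensus
sample_pwm_sequence <- function(pwm, force_consensus_at = integer(0)) {
  n <- nrow(pwm$mat)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (i %in% force_consensus_at) {
      DNA_BASES[which.max(pwm$mat[i, ])]
    } else {
      sample(DNA_BASES, 1L, prob = pwm$mat[i, ])
    }
  }
  paste(out, collapse = "")
}

# build a PWM from a consensus string with a given per-position probability
# on the consensus base; the remaining mass is split asymmetrically
# (0.65/0.25/0.10, rotated by position) so that every column has a
# well-defined least-probable base
pwm_from_consensus <- function(seq, strength = 0.92, name = "motif") {
  bases <- strsplit(toupper(seq), "")[[1]]
  if (length(strength) == 1L) strength <- rep(strength, length(bases))
  mat <- matrix(0, nrow = length(bases), ncol = 4,
                dimnames = list(NULL, DNA_BASES))
  shares <- c(0.65, 0.25, 0.10)
  for (i in seq_along(bases)) {
    if (bases[i] == "N") {
      mat[i, ] <- 0.25
    } else {
      mat[i, bases[i]] <- strength[i]
      others <- setdiff(DNA_BASES, bases[i])
      rot <- (i - 1L) %% 3L
      mat[i, others] <- (1 - strength[i]) *
        shares[(seq_len(3) + rot - 1L) %% 3L + 1L]
    }
  }
  motif_pwm(mat, name = name)
}

#' Demonstration motifs planted by the synthetic benchmark
#'
#' Three distinct high-information motifs loosely shaped after well-known
#' transcription-factor binding site families (an HNF1-like palindrome, a
#' forkhead-like A/T-rich core, and a GC-rich CTCF-like site). These are
#' synthetic constructions, not database motifs.
#'
#' @return list of three `motif_pwm` objects.
#' @export
demo_motifs <- function() {
  list(
    pwm_from_consensus("GTTAATGATTAAC",
                       strength = c(.97, .985, .985, .97, .97, .985, .4,
                                    .97, .985, .985, .97, .97, .97),
                       name = "hnf1_like"),
    pwm_from_consensus("ATGTTTACTTTG", strength = 0.98, name = "fox_like"),
    pwm_from_consensus("CCACCAGAGGGCGC",
                       strength = c(.95, .97, .97, .97, .96, .97, .96,
                                    .95, .97, .97, .97, .96, .95, .94),
                       name = "ctcf_like")
  )
}

#' Random decoy motifs
#'
#' Generates random PWMs with realistic information content, used as decoys
#' in the motif-recovery experiments: each position concentrates probability
#' on a randomly chosen base.
#'
#' @param n number of decoys.
#' @param length_range motif lengths are drawn uniformly from this range.
#' @param strength probability on the preferred base at each position.
#' @param seed integer seed.
#' @param dissimilar_to optional list of `motif_pwm`; candidate decoys that
#'   the internal matcher itself would flag against any of them (permutation
#'   p below `max_match_p`) are rejected and redrawn, so the decoys are null
#'   by the matcher's own standard.
#' @param max_match_p rejection threshold for `dissimilar_to`.
#' @return list of `motif_pwm` objects named `decoy_01`, ...
#' @export
decoy_motifs <- function(n = 7, length_range = c(10, 14), strength = 0.9,
                         seed = 99, dissimilar_to = NULL,
                         max_match_p = 0.1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lens <- seq(length_range[1], length_range[2])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:100) {
      len <- lens[sample.int(length(lens), 1L)]
      cons <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      cand <- pwm_from_consensus(cons, strength = strength,
                                 name = sprintf("decoy_%02d", i))
      ok <- TRUE
      if (length(dissimilar_to)) {
        mt <- match_pwm(cand, dissimilar_to, n_shuffles = 200L,
                        seed = seed + 131L * i + try)
        ok <- min(mt$p) > max_match_p
      }
      if (ok) break
    }
    if (!ok) stop("could not draw a decoy dissimilar to the given motifs")
    out[[i]] <- cand
  }
  out
}

#' Read / write motifs in MEME minimal format
#'
#' @param path file path.
#' @return `read_meme` returns a list of `motif_pwm`; `write_meme` is called
#'   for its side effect and returns `path` invisibly.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF records in ", path)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    name <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > starts[i]][1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    out[[i]] <- motif_pwm(mat, name = name)
  }
  out
}

#' @rdname read_meme
#' @param motifs list of `motif_pwm` objects.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(m$mat)), con)
    writeLines(apply(m$mat, 1L, function(r) paste(sprintf("%.6f", r),
                                                  collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
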