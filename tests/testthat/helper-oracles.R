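# Independent oracles used by several test files. These deliberately use
# different algorithms and data structures than the implementations.

# brute-force AUROC: concordant-pair counting over all (pos, neg) pairs
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force AUPRC: explicit threshold sweep over distinct scores,
# step integration of precision over recall from first principles
oracle_auprc <- function(scores, labels) {
  P <- sum(labels == 1)
  if (P == 0 || P == length(labels)) return(NA_real_)
  ths <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prev_rec <- 0
  for (t in ths) {
    called <- scores >= t
    prec <- sum(labels[called] == 1) / sum(called)
    rec <- sum(labels[called] == 1) / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# brute-force greedy merger, recomputing the full pairwise overlap matrix
# at every step (same largest-overlap / leftmost tie rule, same weighted
# center rule; a deliberately naive O(n^3) reference)
oracle_merge <- function(peaks, window_length, max_overlap) {
  if (!nrow(peaks)) return(data.frame(midpoint = numeric(0), n = integer(0)))
  om <- peaks$start + (peaks$end - peaks$start) / 2
  units <- lapply(seq_len(nrow(peaks)), function(i)
    list(mid = sign(om[i]) * floor(abs(om[i]) + 0.5), members = i))
  repeat {
    k <- length(units)
    if (k < 2) break
    mids <- vapply(units, `[[`, 0, "mid")
    ord <- order(mids)
    best <- -Inf; pair <- NULL
    for (a in seq_len(k - 1)) {
      i <- ord[a]; j <- ord[a + 1]
      ov <- window_length - abs(units[[i]]$mid - units[[j]]$mid)
      if (ov > best) { best <- ov; pair <- c(i, j) }
    }
    if (best <= max_overlap) break
    mem <- c(units[[pair[1]]]$members, units[[pair[2]]]$members)
    m <- sum(om[mem]) / length(mem) # unit weights: one feature per peak
    newu <- list(mid = sign(m) * floor(abs(m) + 0.5), members = mem)
    units <- c(units[-pair], list(newu))
  }
  mids <- vapply(units, `[[`, 0, "mid")
  n <- vapply(units, function(u) length(u$members), 0L)
  o <- order(mids)
  data.frame(midpoint = mids[o], n = n[o])
}

# random peak instance generator for merge tests (fully seeded, away from
# the chromosome origin so no window clips)
random_peaks <- function(seed, span = 6000, max_n = 20) {
  set.seed(seed)
  n <- sample(2:max_n, 1)
  mid <- sort(sample(600:span, n))
  w <- sample(c(200L, 300L, 400L), n, replace = TRUE)
  data.frame(chrom = "chr1", start = mid - w / 2, end = mid + w / 2,
             feature = sample.int(3L, n, replace = TRUE))
}
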