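# From per-feature peak tracks to fixed-length one-hot windows with
# multi-feature labels, split by chromosome.

#' Read peak BED files, one per epigenomic feature
#'
#' @param files character vector of BED paths.
#' @param feature_names feature names; defaults to file base names.
#' @return data frame of peaks (`chrom`, `start`, `end` 0-based half-open,
#'   `feature` integer index) with `feature_names` attribute.
#' @export
read_peak_beds <- function(files, feature_names = NULL) {
  if (is.null(feature_names))
    feature_names <- sub("\\.bed$", "", basename(files))
  peaks <- do.call(rbind, lapply(seq_along(files), function(i) {
    gr <- rtracklayer::import(files[i], format = "BED")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               feature = i, stringsAsFactors = FALSE)
  }))
  structure(peaks, feature_names = feature_names)
}

# generator tracks -> the same peak data frame
peaks_from_tracks <- function(tracks) {
  peaks <- do.call(rbind, lapply(seq_along(tracks), function(i)
    data.frame(chrom = tracks[[i]]$chrom, start = tracks[[i]]$start,
               end = tracks[[i]]$end, feature = i, stringsAsFactors = FALSE)))
  structure(peaks, feature_names = names(tracks))
}

#' Greedily merge peaks into fixed-length labeled windows
#'
#' Every peak first becomes a window of `window_length` centered on its
#' midpoint. While any two windows on a chromosome overlap by strictly more
#' than `max_overlap` bp, the pair with the largest overlap (ties broken by
#' leftmost coordinate) is merged: the merged center is the nearest integer
#' (half away from zero) to the feature-count-weighted mean of the original
#' constituent peak midpoints, and labels are the union. Windows running past
#' a chromosome end are dropped with a warning.
#'
#' @param peaks peak data frame from [read_peak_beds()] (or any data frame
#'   with `chrom`, `start`, `end`, `feature`).
#' @param window_length window size in bp (even).
#' @param max_overlap largest tolerated pairwise overlap in bp (strict:
#'   exactly `max_overlap` is allowed).
#' @param seqlengths optional named vector of chromosome lengths used to drop
#'   out-of-bounds windows.
#' @return object of class `labeled_windows`: list with `windows` (data
#'   frame: `chrom`, `start`, `end`, `midpoint`, `source_peak_count`),
#'   `labels` (windows x features 0/1 matrix) and `feature_names`.
#' @export
merge_peaks <- function(peaks, window_length = 1000L, max_overlap = 200L,
                        seqlengths = NULL) {
  stopifnot(window_length %% 2L == 0L, max_overlap < window_length)
  feature_names <- attr(peaks, "feature_names") %||%
    paste0("feature_", seq_len(max(peaks$feature, 0L)))
  nf <- length(feature_names)
  if (nrow(peaks) && max(peaks$feature) > nf)
    stop("peak feature index exceeds the feature catalogue")
  half <- window_length %/% 2L
  if (!nrow(peaks)) {
    return(structure(list(
      windows = data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), midpoint = integer(0),
                           source_peak_count = integer(0)),
      labels = matrix(0L, 0, nf, dimnames = list(NULL, feature_names)),
      feature_names = feature_names), class = "labeled_windows"))
  }
  out_rows <- list(); out_labels <- list()
  dropped <- 0L
  for (ch in sort(unique(peaks$chrom))) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    om <- pk$start + (pk$end - pk$start) / 2 # original peak midpoints
    ow <- rep(1, nrow(pk))                   # features per original peak
    members <- as.list(seq_len(nrow(pk)))
    mid <- round_half_away(om)
    repeat {
      o <- order(mid)
      if (length(mid) < 2L) break
      ov <- window_length - diff(mid[o])
      best <- max(ov)
      if (best <= max_overlap) break
      i <- which(ov == best)[1L] # leftmost among ties (sorted order)
      a <- o[i]; b <- o[i + 1L]
      mem <- c(members[[a]], members[[b]])
      new_mid <- round_half_away(sum(om[mem] * ow[mem]) / sum(ow[mem]))
      keep <- setdiff(seq_along(mid), c(a, b))
      members <- c(members[keep], list(mem))
      mid <- c(mid[keep], new_mid)
    }
    for (i in seq_along(mid)) {
      start <- mid[i] - half; end <- mid[i] + half
      if (start < 0 ||
          (!is.null(seqlengths) && !is.na(seqlengths[ch]) &&
           end > seqlengths[ch])) {
        dropped <- dropped + 1L
        next
      }
      lab <- integer(nf)
      lab[unique(pk$feature[members[[i]]])] <- 1L
      out_rows[[length(out_rows) + 1L]] <-
        data.frame(chrom = ch, start = start, end = end, midpoint = mid[i],
                   source_peak_count = length(members[[i]]),
                   stringsAsFactors = FALSE)
      out_labels[[length(out_labels) + 1L]] <- lab
    }
  }
  if (dropped)
    warning(dropped, " window(s) extended past a chromosome end and were dropped")
  if (!length(out_rows)) {
    return(structure(list(
      windows = data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), midpoint = numeric(0),
                           source_peak_count = integer(0)),
      labels = matrix(0L, 0, nf, dimnames = list(NULL, feature_names)),
      feature_names = feature_names), class = "labeled_windows"))
  }
  windows <- do.call(rbind, out_rows)
  labels <- do.call(rbind, out_labels)
  colnames(labels) <- feature_names
  o <- order(windows$chrom, windows$start)
  structure(list(windows = windows[o, , drop = FALSE],
                 labels = labels[o, , drop = FALSE],
                 feature_names = feature_names),
            class = "labeled_windows")
}

#' One-hot encode labeled windows against a genome
#'
#' Bases A, C, G, T (case-insensitive) map to unit columns in fixed row
#' order A, C, G, T; any other base (e.g. N) becomes an all-zero column.
#'
#' @param windows a `labeled_windows` object from [merge_peaks()].
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @return object of class `encoded_dataset`: list with `x` (4 x L x N
#'   array), `y` (N x F 0/1 matrix), `chrom`, `start`, `end`,
#'   `source_peak_count`, `feature_names`, and `split` (NULL until
#'   [split_by_chromosome()] is applied).
#' @export
encode_windows <- function(windows, genome) {
  genome <- load_genome(genome)
  w <- windows$windows
  bad <- which(!(w$chrom %in% names(genome)) |
                 w$end > Biostrings::width(genome)[match(w$chrom, names(genome))] |
                 w$start < 0)
  if (length(bad))
    stop("window ", w$chrom[bad[1]], ":", w$start[bad[1]], "-", w$end[bad[1]],
         " exceeds its contig")
  seqs <- extract_sequences(genome, w$chrom, w$start, w$end)
  x <- one_hot_encode(seqs)
  structure(list(x = x, y = windows$labels,
                 chrom = w$chrom, start = w$start, end = w$end,
                 source_peak_count = w$source_peak_count,
                 feature_names = windows$feature_names, split = NULL),
            class = "encoded_dataset")
}

load_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  }
  stopifnot(is(genome, "DNAStringSet"))
  genome
}

# extract 0-based half-open intervals as character sequences
extract_sequences <- function(genome, chrom, start, end) {
  vapply(seq_along(chrom), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]], start[i] + 1L, end[i])),
    "")
}

#' One-hot encode / decode DNA strings
#'
#' @param seqs character vector of equal-length sequences.
#' @return `one_hot_encode`: 4 x L x N binary array (rows A, C, G, T);
#'   ambiguous bases give all-zero columns. `one_hot_decode`: character
#'   vector (zero columns decode to `"N"`).
#' @export
one_hot_encode <- function(seqs) {
  n <- length(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  m <- matrix(match(unlist(strsplit(toupper(seqs), "")), DNA_BASES),
              nrow = L, ncol = n) # L x N base indices (NA = ambiguous)
  x <- array(0, dim = c(4L, L, n))
  for (b in 1:4) {
    sl <- matrix(0, L, n)
    sl[which(m == b)] <- 1
    x[b, , ] <- sl
  }
  x
}

#' @rdname one_hot_encode
#' @param x a 4 x L x N one-hot array.
#' @export
one_hot_decode <- function(x) {
  apply(x, 3L, function(s) {
    idx <- max.col(t(s), ties.method = "first")
    idx[colSums(s) == 0] <- NA
    paste(ifelse(is.na(idx), "N", DNA_BASES[idx]), collapse = "")
  })
}

#' Assign train / validation / test splits by chromosome
#'
#' Windows on `validation_chroms` form the validation set, those on
#' `test_chroms` the test set, and all remaining windows the training set;
#' the two lists must be disjoint and every split must be non-empty.
#'
#' @param dataset an `encoded_dataset`.
#' @param validation_chroms,test_chroms chromosome names.
#' @return the dataset with a `split` factor (`train`, `validation`, `test`).
#' @export
split_by_chromosome <- function(dataset, validation_chroms, test_chroms) {
  if (length(intersect(validation_chroms, test_chroms)))
    stop("validation and test chromosomes must be disjoint")
  missing <- setdiff(c(validation_chroms, test_chroms), dataset$chrom)
  if (length(missing))
    stop("chromosome(s) not present in dataset: ", paste(missing, collapse = ", "))
  split <- rep("train", length(dataset$chrom))
  split[dataset$chrom %in% validation_chroms] <- "validation"
  split[dataset$chrom %in% test_chroms] <- "test"
  split <- factor(split, levels = c("train", "validation", "test"))
  counts <- table(split)
  if (counts[["test"]] == 0L) stop("test split is empty")
  if (counts[["validation"]] == 0L) stop("validation split is empty")
  if (counts[["train"]] == 0L) stop("train split is empty")
  dataset$split <- split
  dataset
}

# subset an encoded_dataset by window index
dataset_subset <- function(dataset, idx) {
  dataset$x <- dataset$x[, , idx, drop = FALSE]
  dataset$y <- dataset$y[idx, , drop = FALSE]
  dataset$chrom <- dataset$chrom[idx]
  dataset$start <- dataset$start[idx]
  dataset$end <- dataset$end[idx]
  dataset$source_peak_count <- dataset$source_peak_count[idx]
  if (!is.null(dataset$split)) dataset$split <- dataset$split[idx]
  dataset
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf("<encoded_dataset> %d windows x %d bp, %d features\n",
              dim(x$x)[3], dim(x$x)[2], ncol(x$y)))
  if (!is.null(x$split)) print(table(x$split))
  invisible(x)
}

#' Write labeled windows as BED6
#'
#' `name` is the label bitmask (feature indices as bits, printed as an
#' integer) and `score` the number of source peaks.
#'
#' @param windows a `labeled_windows` object.
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  w <- windows$windows
  mask <- as.integer(windows$labels %*% 2^(seq_len(ncol(windows$labels)) - 1L))
  df <- data.frame(w$chrom, w$start, w$end, mask,
                   pmin(w$source_peak_count, 1000L), ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Save / load an encoded dataset
#'
#' The tensor is stored in R's native serialization; a sidecar JSON carries
#' the feature names, window coordinates and split assignment for
#' inspection without loading the tensor.
#'
#' @param dataset an `encoded_dataset`.
#' @param path file path (`.rds`); the sidecar is written at `<path>.json`.
#' @return `load_dataset` returns the dataset.
#' @export
save_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  jsonlite::write_json(
    list(feature_names = dataset$feature_names,
         n_windows = dim(dataset$x)[3],
         window_length = dim(dataset$x)[2],
         chrom = dataset$chrom, start = dataset$start,
         split = as.character(dataset$split %||% NA)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)
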