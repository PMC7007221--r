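# Multi-task CNN ensemble: hyperparameters, model construction, training
# with early stopping on mean validation AUROC, ensemble training with
# deterministically derived member seeds, prediction, and evaluation.

#' Hyperparameters of a single CNN
#'
#' The architecture is fixed at three convolutional stages (each ReLU +
#' max-pooling) followed by two fully connected hidden layers and a sigmoid
#' multi-task output; hyperparameters select the sizes within that shape.
#'
#' @param conv_filters integer(3): filters per convolutional layer.
#' @param conv_filter_sizes integer(3): filter widths in bp.
#' @param pool_sizes integer(3): max-pooling widths.
#' @param fc_sizes integer(2): fully connected hidden sizes.
#' @param dropout dropout fraction on the fully connected hidden layers.
#' @param weight_decay L2 penalty applied to all weights during training.
#' @param learning_rate RMSprop learning rate.
#' @param batch_size minibatch size.
#' @param seed seed for weight initialization, shuffling and dropout.
#' @return object of class `hyperparams`.
#' @export
hyperparams <- function(conv_filters = c(32L, 32L, 48L),
                        conv_filter_sizes = c(15L, 5L, 5L),
                        pool_sizes = c(4L, 4L, 4L),
                        fc_sizes = c(64L, 32L),
                        dropout = 0.1,
                        weight_decay = 2e-3,
                        learning_rate = 0.004,
                        batch_size = 32L,
                        seed = 1L) {
  stopifnot(length(conv_filters) == 3L, length(conv_filter_sizes) == 3L,
            length(pool_sizes) == 3L, length(fc_sizes) == 2L,
            all(conv_filters > 0), all(conv_filter_sizes > 0),
            all(pool_sizes > 0), all(fc_sizes > 0),
            dropout >= 0, dropout < 1, weight_decay >= 0, learning_rate > 0,
            batch_size > 0)
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_filter_sizes = as.integer(conv_filter_sizes),
                 pool_sizes = as.integer(pool_sizes),
                 fc_sizes = as.integer(fc_sizes),
                 dropout = dropout, weight_decay = weight_decay,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "hyperparams")
}

#' Default hyperparameter grid (10 settings)
#'
#' Settings at the scale used by published sequence-to-chromatin CNNs,
#' varying the number and width of first-layer filters (100-320 filters,
#' widths 8-21 bp).
#'
#' @return list of 10 `hyperparams`.
#' @export
default_hp_grid <- function() {
  f1 <- c(100L, 150L, 200L, 250L, 300L, 320L, 100L, 200L, 300L, 320L)
  k1 <- c(8L, 11L, 15L, 18L, 21L, 15L, 21L, 8L, 11L, 19L)
  lapply(seq_along(f1), function(i)
    hyperparams(conv_filters = c(f1[i], 200L, 200L),
                conv_filter_sizes = c(k1[i], 11L, 7L),
                pool_sizes = c(3L, 4L, 4L),
                fc_sizes = c(1000L, 512L),
                dropout = 0.3, seed = i))
}

#' Small hyperparameter grid for desk-scale experiments
#' @param n number of settings (recycled from 5 base settings).
#' @return list of `hyperparams`.
#' @export
small_hp_grid <- function(n = 5) {
  base <- list(
    hyperparams(conv_filters = c(32L, 24L, 32L), conv_filter_sizes = c(16L, 5L, 5L)),
    hyperparams(conv_filters = c(24L, 24L, 32L), conv_filter_sizes = c(14L, 5L, 5L)),
    hyperparams(conv_filters = c(32L, 32L, 32L), conv_filter_sizes = c(18L, 5L, 5L)),
    hyperparams(conv_filters = c(40L, 24L, 32L), conv_filter_sizes = c(16L, 7L, 5L)),
    hyperparams(conv_filters = c(32L, 24L, 48L), conv_filter_sizes = c(15L, 5L, 5L)))
  lapply(seq_len(n), function(i) {
    hp <- base[[(i - 1L) %% length(base) + 1L]]
    hp$seed <- i
    hp
  })
}

#' Build an untrained CNN
#'
#' @param hp a [hyperparams()].
#' @param n_features number of output features (F).
#' @param window_length input window length in bp.
#' @param feature_names optional feature names.
#' @return object of class `cnn_model`.
#' @export
build_model <- function(hp, n_features, window_length = 1000L,
                        feature_names = NULL) {
  params <- cpp_cnn_init(hp$conv_filters, hp$conv_filter_sizes, hp$pool_sizes,
                         hp$fc_sizes, as.integer(n_features),
                         as.integer(window_length), hp$seed)
  structure(list(params = params, hp = hp, n_features = as.integer(n_features),
                 window_length = as.integer(window_length),
                 feature_names = feature_names %||%
                   paste0("feature_", seq_len(n_features)),
                 trained = FALSE, log = NULL),
            class = "cnn_model")
}

#' Train a CNN with early stopping
#'
#' Minimizes mean binary cross-entropy over features with RMSprop. After
#' each epoch the mean validation AUROC (over features with both classes
#' present in the validation split; absent features are excluded with a
#' warning) is recorded; training stops when it has not improved for
#' `patience` epochs, and parameters are restored to the best epoch.
#'
#' @param model a `cnn_model` from [build_model()].
#' @param dataset an `encoded_dataset` with splits assigned.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs hard cap on epochs.
#' @param augment_rc also train on the reverse complement of every training
#'   window (labels copied); validation stays unaugmented.
#' @return the trained `cnn_model` with `log`, `best_epoch`,
#'   `best_val_auroc`.
#' @export
train_model <- function(model, dataset, patience = 10L, max_epochs = 120L,
                        augment_rc = FALSE) {
  if (is.null(dataset$split)) stop("dataset has no splits; run split_by_chromosome()")
  tr <- which(dataset$split == "train")
  va <- which(dataset$split == "validation")
  if (!length(tr) || !length(va)) stop("train and validation splits must be non-empty")
  yv <- dataset$y[va, , drop = FALSE]
  absent <- colSums(yv) %in% c(0L, nrow(yv))
  if (any(absent))
    warning("feature(s) with a single class in the validation split excluded ",
            "from the stopping metric: ",
            paste(dataset$feature_names[absent], collapse = ", "))
  xtr <- dataset$x[, , tr, drop = FALSE]
  ytr <- dataset$y[tr, , drop = FALSE]
  if (augment_rc) {
    xtr <- .abind3(xtr, .reverse_complement_onehot(xtr))
    ytr <- rbind(ytr, ytr)
  }
  fit <- cpp_cnn_train(model$params,
                       xtr,
                       ytr,
                       dataset$x[, , va, drop = FALSE],
                       yv,
                       model$hp$learning_rate, model$hp$batch_size,
                       as.integer(patience), as.integer(max_epochs),
                       model$hp$dropout, model$hp$weight_decay %||% 0,
                       model$hp$seed, 256L)
  model$params <- fit$params
  model$log <- fit$log
  model$best_epoch <- fit$best_epoch
  model$best_val_auroc <- fit$best_val_auroc
  model$trained <- TRUE
  model
}

#' Train an ensemble of CNNs
#'
#' Member seeds are derived deterministically from the master seed; each
#' hyperparameter setting is trained `replicates` times. A failing member
#' aborts the ensemble build, naming the member.
#'
#' @param dataset an `encoded_dataset` with splits.
#' @param hp_grid list of [hyperparams()].
#' @param replicates replicate models per setting.
#' @param seed master seed for member-seed derivation.
#' @param patience,max_epochs,augment_rc passed to [train_model()].
#' @return object of class `cnn_ensemble`.
#' @export
train_ensemble <- function(dataset, hp_grid = small_hp_grid(), replicates = 1L,
                           seed = 1L, patience = 10L, max_epochs = 120L,
                           augment_rc = FALSE) {
  stopifnot(length(hp_grid) >= 1L)
  n_members <- length(hp_grid) * replicates
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max - 1L, n_members)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  members <- vector("list", n_members)
  m <- 0L
  for (h in seq_along(hp_grid)) {
    for (r in seq_len(replicates)) {
      m <- m + 1L
      hp <- hp_grid[[h]]
      hp$seed <- member_seeds[m]
      members[[m]] <- tryCatch({
        mod <- build_model(hp, ncol(dataset$y), dim(dataset$x)[2],
                           dataset$feature_names)
        train_model(mod, dataset, patience = patience,
                    max_epochs = max_epochs, augment_rc = augment_rc)
      }, error = function(e)
        stop("ensemble member ", m, " (setting ", h, ", replicate ", r,
             ") failed: ", conditionMessage(e)))
    }
  }
  structure(list(members = members,
                 feature_names = dataset$feature_names,
                 window_length = dim(dataset$x)[2]),
            class = "cnn_ensemble")
}

#' @export
print.cnn_ensemble <- function(x, ...) {
  cat(sprintf("<cnn_ensemble> %d members, %d features, %d bp windows\n",
              length(x$members), length(x$feature_names), x$window_length))
  invisible(x)
}

#' Ensemble predictions
#'
#' @param object a `cnn_ensemble`.
#' @param x a 4 x L x N one-hot array or an `encoded_dataset`.
#' @param batch_size prediction batch size.
#' @param ... unused.
#' @return list with `mean` (N x F matrix, ensemble average) and `member`
#'   (N x F x M array of member-level predictions).
#' @export
predict.cnn_ensemble <- function(object, x, batch_size = 256L, ...) {
  if (inherits(x, "encoded_dataset")) x <- x$x
  if (dim(x)[2] != object$window_length)
    stop("input window length ", dim(x)[2], " does not match ensemble (",
         object$window_length, ")")
  M <- length(object$members)
  member <- array(NA_real_,
                  dim = c(dim(x)[3], length(object$feature_names), M))
  for (m in seq_len(M))
    member[, , m] <- cpp_cnn_predict(object$members[[m]]$params, x,
                                     as.integer(batch_size))
  mean_pred <- member[, , 1, drop = FALSE][, , 1, drop = FALSE]
  dim(mean_pred) <- dim(member)[1:2]
  if (M > 1) {
    for (m in 2:M) mean_pred <- mean_pred + member[, , m]
    mean_pred <- mean_pred / M
  }
  colnames(mean_pred) <- object$feature_names
  list(mean = mean_pred, member = member)
}

#' @export
predict.cnn_model <- function(object, x, batch_size = 256L, ...) {
  if (inherits(x, "encoded_dataset")) x <- x$x
  p <- cpp_cnn_predict(object$params, x, as.integer(batch_size))
  colnames(p) <- object$feature_names
  p
}

#' Area under the ROC curve (mid-rank statistic)
#'
#' @param scores numeric predictions.
#' @param labels 0/1 labels.
#' @return AUROC in `[0,1]`, or `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integration)
#'
#' Precision-recall points are computed at every distinct score threshold
#' (tied scores collapsed) and integrated as a step function in recall.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0,1]`, or `NA` if no positives.
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  P <- sum(labels == 1)
  if (P == 0 || P == length(labels)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); n <- seq_along(y)
  last <- c(s[-1] != s[-length(s)], TRUE) # last index of each tie group
  prec <- tp[last] / n[last]
  rec <- tp[last] / P
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate predictive performance on a split
#'
#' @param object a `cnn_ensemble` or `cnn_model`.
#' @param dataset an `encoded_dataset` with splits.
#' @param split which split to evaluate (`"test"` by default).
#' @param groups optional factor/character of length F assigning features to
#'   groups; per-group mean AUROC/AUPRC are then attached as an attribute.
#' @return data frame with one row per feature: `feature`, `prevalence`,
#'   `auroc`, `auprc` (NA where the split has a single class).
#' @export
evaluate_model <- function(object, dataset, split = "test", groups = NULL) {
  idx <- if (is.null(dataset$split)) seq_along(dataset$chrom) else
    which(dataset$split == split)
  if (!length(idx)) stop("split '", split, "' is empty")
  x <- dataset$x[, , idx, drop = FALSE]
  y <- dataset$y[idx, , drop = FALSE]
  p <- if (inherits(object, "cnn_ensemble")) predict(object, x)$mean
       else predict(object, x)
  res <- data.frame(
    feature = dataset$feature_names,
    prevalence = colMeans(y),
    auroc = vapply(seq_len(ncol(y)), function(f) auroc(p[, f], y[, f]), 0),
    auprc = vapply(seq_len(ncol(y)), function(f) auprc(p[, f], y[, f]), 0),
    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    g <- split(res, groups)
    attr(res, "group_means") <- data.frame(
      group = names(g),
      auroc = vapply(g, function(d) mean(d$auroc, na.rm = TRUE), 0),
      auprc = vapply(g, function(d) mean(d$auprc, na.rm = TRUE), 0),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res
}


# reverse complement of a one-hot array: reverse positions, swap A<->T, C<->G
.reverse_complement_onehot <- function(x) {
  x[c(4L, 3L, 2L, 1L), rev(seq_len(dim(x)[2])), , drop = FALSE]
}

# bind two 4 x L x N arrays along the third axis
.abind3 <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

#' Save / load a trained ensemble
#'
#' Parameters are stored in R's native serialization with a sidecar JSON of
#' member metadata (hyperparameters, seeds, best epochs, validation AUROC).
#'
#' @param ensemble a `cnn_ensemble`.
#' @param path file path (`.rds`); metadata is written at `<path>.json`.
#' @return `load_ensemble` returns the ensemble.
#' @export
save_ensemble <- function(ensemble, path) {
  saveRDS(ensemble, path)
  meta <- lapply(ensemble$members, function(m)
    list(hp = m$hp[setdiff(names(m$hp), "")], best_epoch = m$best_epoch,
         best_val_auroc = m$best_val_auroc))
  jsonlite::write_json(
    list(members = meta, feature_names = ensemble$feature_names,
         window_length = ensemble$window_length),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) readRDS(path)
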