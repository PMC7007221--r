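# Model construction, training mechanics, prediction contracts, and the
# AUROC/AUPRC implementations against brute-force oracles.

# fast toy dataset: fixed-position 8-mer in half the windows
toy_dataset <- function(n = 240, L = 60, seed = 42) {
  set.seed(seed)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), L, TRUE),
                             collapse = ""))
  lab <- rep(c(0L, 1L), length.out = n)
  for (i in which(lab == 1)) substr(seqs[i], 21, 28) <- "TTTTGGGG"
  structure(list(
    x = one_hot_encode(seqs), y = matrix(lab, ncol = 1),
    chrom = rep(c("c1", "c1", "c2"), length.out = n),
    start = integer(n), end = integer(n), source_peak_count = integer(n),
    feature_names = "f",
    split = factor(rep(c("train", "train", "validation"), length.out = n),
                   levels = c("train", "validation", "test"))),
    class = "encoded_dataset")
}

toy_hp <- function(seed = 1) {
  hyperparams(conv_filters = c(8L, 8L, 8L), conv_filter_sizes = c(8L, 3L, 3L),
              pool_sizes = c(2L, 2L, 2L), fc_sizes = c(16L, 8L),
              dropout = 0, learning_rate = 0.003, batch_size = 32L,
              seed = seed)
}

# a constant-output stub member: all weights zero, output bias = logit(p)
constant_member <- function(p, n_features = 1L, L = 60L) {
  m <- build_model(toy_hp(), n_features, L)
  m$params$W <- lapply(m$params$W, function(w) w * 0)
  m$params$b <- lapply(m$params$b, function(b) b * 0)
  m$params$b[[6]] <- rep(log(p / (1 - p)), n_features)
  m
}

test_that("model output dimension equals the number of features", {
  hp <- toy_hp()
  m30 <- build_model(hp, 30L, 100L)
  p <- predict(m30, one_hot_encode(strrep("ACGT", 25)))
  expect_equal(dim(p), c(1L, 30L))
  expect_true(all(p > 0 & p < 1))
  m1 <- build_model(hp, 1L, 100L)
  expect_equal(dim(predict(m1, one_hot_encode(strrep("ACGT", 25)))), c(1L, 1L))
})

test_that("initialization is deterministic in the seed", {
  a <- build_model(toy_hp(seed = 7), 3L, 80L)
  b <- build_model(toy_hp(seed = 7), 3L, 80L)
  c <- build_model(toy_hp(seed = 8), 3L, 80L)
  expect_identical(a$params$W, b$params$W)
  expect_false(identical(a$params$W, c$params$W))
})

test_that("incompatible pooling chains fail with computed sizes", {
  hp <- hyperparams(conv_filters = c(4L, 4L, 4L),
                    conv_filter_sizes = c(8L, 8L, 8L),
                    pool_sizes = c(10L, 10L, 10L))
  expect_error(build_model(hp, 2L, 60L), "pool")
})

test_that("training learns a planted fixed-position motif", {
  ds <- toy_dataset()
  m <- build_model(toy_hp(3), 1L, 60L, "f")
  m <- train_model(m, ds, patience = 10L, max_epochs = 40L)
  expect_true(m$trained)
  expect_gt(m$best_val_auroc, 0.8)
  expect_equal(m$log$val_auroc[m$best_epoch], m$best_val_auroc)
})

test_that("early stopping halts after `patience` non-improving epochs", {
  ds <- toy_dataset(n = 60)
  hp <- toy_hp(5)
  hp$learning_rate <- 1e-12 # frozen model: constant validation AUROC
  m <- build_model(hp, 1L, 60L, "f")
  m <- train_model(m, ds, patience = 4L, max_epochs = 50L)
  expect_equal(m$best_epoch, 1L)
  expect_equal(nrow(m$log), 1L + 4L)
})

test_that("training is bit-reproducible for a fixed seed", {
  ds <- toy_dataset(n = 120)
  m1 <- train_model(build_model(toy_hp(9), 1L, 60L, "f"), ds,
                    patience = 3L, max_epochs = 5L)
  m2 <- train_model(build_model(toy_hp(9), 1L, 60L, "f"), ds,
                    patience = 3L, max_epochs = 5L)
  expect_identical(m1$params$W, m2$params$W)
  expect_identical(m1$log, m2$log)
})

test_that("ensembles count members and average their predictions", {
  ds <- toy_dataset(n = 120)
  ens <- train_ensemble(ds, list(toy_hp(1), toy_hp(2)), replicates = 3L,
                        seed = 4, patience = 2L, max_epochs = 3L)
  expect_equal(length(ens$members), 6L)

  # stub ensemble of two constant models: mean of 0.2 and 0.6 is 0.4
  stub <- structure(list(members = list(constant_member(0.2),
                                        constant_member(0.6)),
                         feature_names = "f", window_length = 60L),
                    class = "cnn_ensemble")
  x <- toy_dataset(n = 10)$x
  pr <- predict(stub, x)
  expect_equal(unname(pr$mean[, 1]), rep(0.4, 10), tolerance = 1e-12)
  expect_equal(unname(pr$member[, 1, 1]), rep(0.2, 10), tolerance = 1e-12)

  # an ensemble of one equals its single member
  one <- structure(list(members = stub$members[1], feature_names = "f",
                        window_length = 60L), class = "cnn_ensemble")
  expect_equal(predict(one, x)$mean[, 1], predict(one, x)$member[, 1, 1])

  expect_error(predict(stub, one_hot_encode("ACGT")), "window length")
})

test_that("prediction is invariant to batch partitioning", {
  ds <- toy_dataset(n = 50)
  m <- train_model(build_model(toy_hp(2), 1L, 60L, "f"), ds,
                   patience = 2L, max_epochs = 3L)
  full <- predict(m, ds$x, batch_size = 256L)
  mini <- predict(m, ds$x, batch_size = 7L)
  expect_equal(full, mini, tolerance = 1e-12)
})

test_that("AUROC and AUPRC match brute-force oracles on all arrangements", {
  set.seed(8)
  for (n in c(4, 7, 12)) {
    scores <- round(runif(n), 2)
    for (rep in 1:40) {
      labels <- rbinom(n, 1, 0.5)
      if (all(labels == labels[1])) next
      expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
      expect_equal(auprc(scores, labels), oracle_auprc(scores, labels))
    }
    scores <- sample(c(0.2, 0.5, 0.8), n, replace = TRUE) # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (!all(labels == labels[1])) {
      expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
      expect_equal(auprc(scores, labels), oracle_auprc(scores, labels))
    }
  }
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(9)
  s <- runif(30); y <- rbinom(30, 1, 0.4)
  expect_equal(auroc(s, y), auroc(qnorm(s), y))
  expect_equal(auroc(s, y), auroc(s^3 + 2, y))
})

test_that("random-model AUPRC approaches class prevalence", {
  set.seed(10)
  y <- rbinom(4000, 1, 0.15)
  s <- runif(4000)
  expect_equal(auprc(s, y), mean(y), tolerance = 0.05)
})

test_that("evaluation reports NA (not zero) for single-class features", {
  ds <- toy_dataset(n = 90)
  ds$y <- cbind(f = ds$y[, 1], empty = 0L)
  ds$feature_names <- c("f", "empty")
  m <- constant_member(0.3, 2L)
  m$feature_names <- c("f", "empty")
  perf <- evaluate_model(m, ds, split = "validation")
  expect_true(is.na(perf$auroc[2]))
  expect_true(is.na(perf$auprc[2]))
  expect_false(is.na(perf$auroc[1]))
})

test_that("AUROC agrees with an independent library on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(11)
  s <- runif(200); y <- rbinom(200, 1, 0.3)
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("ensembles round-trip through their checkpoint format", {
  ds <- toy_dataset(n = 90)
  ens <- train_ensemble(ds, list(toy_hp(4)), seed = 2, patience = 2L,
                        max_epochs = 3L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(ens, path)
  back <- load_ensemble(path)
  expect_identical(predict(back, ds$x)$mean, predict(ens, ds$x)$mean)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  expect_equal(length(meta$members), 1L)
  expect_equal(meta$window_length, 60L)
})
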