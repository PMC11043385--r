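test_that("evaluation measures follow their confusion-count definitions", {
  perfect <- compute_metrics(confusion_counts(50, 50, 0, 0))
  expect_equal(unlist(perfect[c("ACC", "SN", "SP", "MCC", "F1")]),
               c(ACC = 1, SN = 1, SP = 1, MCC = 1, F1 = 1))
  expect_equal(perfect$FPR, 0)

  m <- compute_metrics(confusion_counts(40, 30, 20, 10))
  expect_equal(m$ACC, 0.70)
  expect_equal(m$SN, 0.80)
  expect_equal(m$SP, 0.60)
  expect_equal(m$FPR, 1 - m$SP)
  expect_equal(m$F1, 2 * 40 / (2 * 40 + 20 + 10))
  expect_equal(m$MCC, (40 * 30 - 20 * 10) / sqrt(50 * 60 * 50 * 40))
  expect_false(m$mcc_degenerate)

  degen <- compute_metrics(confusion_counts(0, 30, 20, 0))
  expect_equal(degen$MCC, 0)
  expect_true(degen$mcc_degenerate)
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")

  # ACC decomposes into class-conditional rates; MCC symmetry under class swap
  set.seed(8)
  for (rep in 1:25) {
    cnt <- as.list(sample(0:40, 4, TRUE))
    names(cnt) <- c("tp", "tn", "fp", "fn")
    if (cnt$tp + cnt$fn == 0 || cnt$tn + cnt$fp == 0) next
    mm <- compute_metrics(do.call(confusion_counts, cnt))
    P <- cnt$tp + cnt$fn; N <- cnt$tn + cnt$fp
    expect_equal(mm$ACC, (mm$SN * P + mm$SP * N) / (P + N))
    sw <- compute_metrics(confusion_counts(cnt$tn, cnt$tp, cnt$fn, cnt$fp))
    expect_equal(sw$MCC, mm$MCC)
    inv <- compute_metrics(confusion_counts(cnt$fn, cnt$fp, cnt$tn, cnt$tp))
    expect_equal(inv$MCC, -mm$MCC)
  }
})

test_that("trapezoidal AUC equals the Mann-Whitney rank statistic", {
  y <- c(rep(1, 5), rep(0, 5))
  expect_equal(auc_roc(c(5:1 + 10, 5:1), y), 1)
  expect_equal(auc_roc(rep(1, 10), y), 0.5)
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)   # rounding forces ties
    expect_equal(auc_roc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("all eleven classifiers separate Gaussian blobs and are seeded", {
  set.seed(4)
  n <- 60
  X <- rbind(matrix(rnorm(n * 4, 0), n), matrix(rnorm(n * 4, 3), n))
  y <- rep(c(0L, 1L), each = n)
  tr <- c(1:45, n + 1:45); te <- setdiff(seq_len(2 * n), tr)
  for (nm in names(classifier_grid())) {
    spec <- classifier_spec(nm)
    res <- train_and_predict(X[tr, ], y[tr], X[te, ], spec, seed = 6)
    acc <- mean(res$pred == y[te])
    expect_gte(acc, 0.9)
    expect_true(is.numeric(res$score))
    res2 <- train_and_predict(X[tr, ], y[tr], X[te, ], spec, seed = 6)
    expect_identical(res$pred, res2$pred)
    expect_identical(res$score, res2$score)
  }
  expect_error(train_and_predict(X[1:10, ], rep(1L, 10), X[te, ],
                                 classifier_spec("SVM")), "single class")
  expect_error(classifier_spec("MLP"), "unknown classifier")
})

test_that("label-shuffled data yields chance-level SVM cross-validation", {
  set.seed(12)
  n <- 200
  X <- matrix(rnorm(n * 6), n)
  y <- rep(c(0L, 1L), each = n / 2)
  cv <- cross_validate(X, y, classifier_spec("SVM"), k = 5, seed = 3)
  expect_gte(cv$mean$ACC, 0.4)
  expect_lte(cv$mean$ACC, 0.6)
})

test_that("cross-validation folds are stratified, exhaustive, reproducible", {
  ids <- sprintf("s%03d", 1:100)
  y <- rep(c(0L, 1L), 50)
  fold <- stratified_folds(ids, y, k = 5, seed = 2)
  expect_equal(sort(unique(fold)), 1:5)
  for (f in 1:5) {
    expect_equal(sum(fold == f), 20L)
    expect_equal(sum(fold == f & y == 1), 10L)
  }
  expect_identical(stratified_folds(ids, y, 5, 2), fold)
  expect_false(identical(stratified_folds(ids, y, 5, 3), fold))
  # fold assignment depends on ids, not on row order
  perm <- sample(100)
  expect_identical(stratified_folds(ids[perm], y[perm], 5, 2)[order(perm)],
                   fold)
  expect_error(stratified_folds(ids[1:6], c(1L, 1L, 1L, 1L, 1L, 0L), 5, 1),
               "fewer members")
})

test_that("ensemble enumeration covers all unordered encoder pairs", {
  grid <- enumerate_ensembles()
  expect_equal(nrow(grid), choose(13, 2) * 11)
  expect_equal(nrow(unique(grid)), nrow(grid))
  expect_true(all(grid$encoder1 < grid$encoder2))
  expect_equal(nrow(enumerate_ensembles(c("a", "b", "c"), c("x", "y"))), 6L)
  expect_equal(nrow(enumerate_ensembles(c("a", "b"), "x")), 1L)
  expect_error(enumerate_ensembles(c("a", "a"), "x"), "duplicate")
})

test_that("rank scores average per-dataset ranks of max-over-length ACC", {
  grid <- expand.grid(dataset = c("d1", "d2"), encoder = c("e1", "e2"),
                      classifier = c("c1", "c2"), length = c(1000, 2000),
                      stringsAsFactors = FALSE)
  # e1 dominates everywhere -> rank 1 for every classifier
  grid$ACC <- ifelse(grid$encoder == "e1", 0.9, 0.6)
  rt <- rank_scores(grid, "encoder")
  expect_equal(unname(rt["e1", ]), c(1, 1))
  expect_equal(unname(rt["e2", ]), c(2, 2))

  # identical ACC everywhere -> all ranks tie at the mean
  grid$ACC <- 0.7
  rt2 <- rank_scores(grid, "encoder")
  expect_true(all(rt2 == 1.5))

  # hand-built table: max over lengths decides, means taken across datasets
  acc <- c(d1_e1_c1 = 0.8, d1_e2_c1 = 0.7, d2_e1_c1 = 0.6, d2_e2_c1 = 0.9)
  grid$ACC <- 0.5
  grid$ACC[grid$length == 2000] <- NA
  for (nm in names(acc)) {
    parts <- strsplit(nm, "_")[[1]]
    sel <- grid$dataset == parts[1] & grid$encoder == parts[2] &
      grid$classifier == parts[3]
    grid$ACC[sel & grid$length == 1000] <- acc[[nm]]
    grid$ACC[sel & grid$length == 2000] <- acc[[nm]] - 0.2
  }
  grid$ACC[is.na(grid$ACC)] <- 0.1
  rt3 <- rank_scores(grid, "encoder")
  # c1: e1 ranks 1 on d1, 2 on d2 -> mean 1.5; e2 the mirror
  expect_equal(unname(rt3["e1", "c1"]), 1.5)
  expect_equal(unname(rt3["e2", "c1"]), 1.5)

  gap <- grid[!(grid$dataset == "d1" & grid$encoder == "e1" &
                  grid$classifier == "c1"), ]
  expect_error(rank_scores(gap, "encoder"), "missing grid cells")
})

test_that("independent-test evaluation runs end to end on a split corpus", {
  ds <- generate_dataset(synthetic_spec(n_pos = 40L, n_neg = 40L,
                                        length_range = c(300L, 800L),
                                        B = 300L, delta = 0.9, seed = 15L))
  ds <- split_train_test(ds, 0.25, seed = 15)
  m <- evaluate_independent(ds, c("cksnap", "pseeiip"),
                            classifier_spec("SVM"),
                            length_threshold = 500L, seed = 15)
  expect_gte(m$ACC, 0.8)
  expect_gte(m$AUCROC, 0.8)
})
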