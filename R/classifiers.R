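# The eleven classifier specifications and a uniform train/predict surface.
# Parameter values follow the benchmark grid: LR (l2, C=1), KNN (k=5), DT
# (gini, best split, unlimited depth), Gaussian NB, Bagging (10 trees), RF
# (100 trees, sqrt features), AdaBoost (50 stumps, lr=1), GB (lr=0.1, 100
# trees, depth 3), LDA (svd), SVM (C=1, RBF, scale-heuristic gamma), ET
# (100 trees, sqrt features).

CLASSIFIER_NAMES <- c("LR", "KNN", "DT", "NB", "Bagging", "RF", "AB", "GB",
                      "LDA", "SVM", "ET")

#' Classifier specification
#'
#' @param name one of LR, KNN, DT, NB, Bagging, RF, AB, GB, LDA, SVM, ET.
#' @param ... parameter overrides (e.g. `k`, `n_estimators`, `cost`).
#' @return a `classifier_spec` list with `name` and `params`.
#' @export
classifier_spec <- function(name, ...) {
  if (!name %in% CLASSIFIER_NAMES) {
    stop("unknown classifier: ", name, " (expected one of ",
         paste(CLASSIFIER_NAMES, collapse = ", "), ")", call. = FALSE)
  }
  defaults <- switch(name,
    LR = list(),
    KNN = list(k = 5L),
    DT = list(),
    NB = list(),
    Bagging = list(n_estimators = 10L),
    RF = list(n_estimators = 100L),
    AB = list(n_estimators = 50L, learning_rate = 1.0),
    GB = list(n_estimators = 100L, learning_rate = 0.1, max_depth = 3L),
    LDA = list(),
    SVM = list(cost = 1.0, kernel = "radial", degree = 3L),
    ET = list(n_estimators = 100L))
  params <- utils::modifyList(defaults, list(...))
  structure(list(name = name, params = params), class = "classifier_spec")
}

#' The full classifier grid
#'
#' @return named list of the 11 default `classifier_spec`s.
#' @export
classifier_grid <- function() {
  stats::setNames(lapply(CLASSIFIER_NAMES, classifier_spec), CLASSIFIER_NAMES)
}

# z-score standardization fit on training rows; constant columns dropped.
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  keep <- which(sdv > 0)
  if (length(keep) == 0L) stop("all features constant in training data",
                               call. = FALSE)
  list(mu = mu[keep], sd = sdv[keep], keep = keep)
}
apply_standardizer <- function(std, X) {
  sweep(sweep(X[, std$keep, drop = FALSE], 2L, std$mu, "-"),
        2L, std$sd, "/")
}

# unpruned classification tree (gini, best splits)
fit_tree <- function(df, weights = NULL, maxdepth = 30L) {
  rpart::rpart(y ~ ., data = df, weights = weights, method = "class",
               parms = list(split = "gini"),
               control = rpart::rpart.control(minsplit = 2L, minbucket = 1L,
                                              cp = 0, xval = 0L,
                                              maxdepth = maxdepth))
}

#' Train a classifier and predict on test features
#'
#' Features are z-score standardized using training statistics (the RBF-SVM
#' and KNN are scale-sensitive); disable with `standardize = FALSE`. Scores
#' are real-valued and monotone with class-1 confidence (probabilities, or
#' decision values for the SVM).
#'
#' @param X_train,X_test numeric feature matrices with aligned columns.
#' @param y_train training labels in {0, 1}; both classes must be present.
#' @param spec a `classifier_spec`.
#' @param seed integer seed (stochastic learners are deterministic under it).
#' @param standardize z-score features on training statistics (default TRUE).
#' @return list with `pred` (integer labels) and `score` (numeric).
#' @export
train_and_predict <- function(X_train, y_train, X_test, spec, seed = 1L,
                              standardize = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"),
            ncol(X_train) == ncol(X_test))
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (standardize) {
    std <- fit_standardizer(X_train)
    X_train <- apply_standardizer(std, X_train)
    X_test <- apply_standardizer(std, X_test)
  }
  colnames(X_train) <- colnames(X_test) <- sprintf("f%d", seq_len(ncol(X_train)))
  set.seed(substream_seed(seed, paste0("clf:", spec$name)))
  p <- spec$params
  yf <- factor(y_train, levels = c(0L, 1L))
  dtr <- data.frame(y = yf, X_train, check.names = FALSE)
  dte <- data.frame(X_test, check.names = FALSE)
  score <- switch(spec$name,
    LR = {
      fit <- suppressWarnings(stats::glm(y ~ ., data = dtr,
                                         family = stats::binomial()))
      suppressWarnings(as.numeric(stats::predict(fit, dte, type = "response")))
    },
    KNN = {
      pr <- class::knn(X_train, X_test, cl = yf, k = p$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    DT = {
      fit <- fit_tree(dtr)
      stats::predict(fit, dte, type = "prob")[, "1"]
    },
    NB = {
      fit <- e1071::naiveBayes(X_train, yf)
      suppressWarnings(stats::predict(fit, X_test, type = "raw")[, "1"])
    },
    Bagging = {
      n <- nrow(X_train)
      probs <- vapply(seq_len(p$n_estimators), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        while (length(unique(yf[idx])) < 2L) {
          idx <- sample.int(n, n, replace = TRUE)
        }
        fit <- fit_tree(dtr[idx, , drop = FALSE])
        stats::predict(fit, dte, type = "prob")[, "1"]
      }, numeric(nrow(X_test)))
      rowMeans(probs)
    },
    RF = {
      fit <- randomForest::randomForest(X_train, yf,
                                        ntree = p$n_estimators)
      stats::predict(fit, X_test, type = "prob")[, "1"]
    },
    AB = adaboost_score(dtr, dte, yf, p$n_estimators, p$learning_rate),
    GB = {
      fit <- xgboost::xgboost(X_train, yf, objective = "binary:logistic",
                              nrounds = p$n_estimators,
                              learning_rate = p$learning_rate,
                              max_depth = p$max_depth, subsample = 1,
                              nthreads = 1L, verbosity = 0)
      stats::predict(fit, X_test, type = "response")
    },
    LDA = {
      fit <- suppressWarnings(MASS::lda(X_train, grouping = yf))
      stats::predict(fit, X_test)$posterior[, "1"]
    },
    SVM = {
      gam <- 1 / (ncol(X_train) * mean(apply(X_train, 2L, stats::var)))
      fit <- e1071::svm(X_train, yf, kernel = p$kernel, cost = p$cost,
                        degree = p$degree, gamma = gam, scale = FALSE)
      pr <- stats::predict(fit, X_test, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      if (startsWith(colnames(dv)[1L], "1")) dv[, 1L] else -dv[, 1L]
    },
    ET = {
      fit <- ranger::ranger(x = X_train, y = yf,
                            num.trees = p$n_estimators,
                            mtry = max(1L, floor(sqrt(ncol(X_train)))),
                            splitrule = "extratrees", num.random.splits = 1L,
                            min.node.size = 1L, probability = TRUE,
                            replace = FALSE, sample.fraction = 1,
                            seed = substream_seed(seed, "ranger"),
                            num.threads = 1L)
      stats::predict(fit, X_test, num.threads = 1L)$predictions[, "1"]
    })
  score <- as.numeric(score)
  threshold <- if (spec$name == "SVM") 0 else 0.5
  list(pred = as.integer(score > threshold), score = score)
}

# Discrete AdaBoost (SAMME) over depth-1 stumps; returns the additive score.
adaboost_score <- function(dtr, dte, yf, n_estimators, learning_rate) {
  n <- nrow(dtr)
  w <- rep(1 / n, n)
  y_pm <- ifelse(yf == "1", 1, -1)
  score <- numeric(nrow(dte))
  for (b in seq_len(n_estimators)) {
    fit <- fit_tree(dtr, weights = w, maxdepth = 1L)
    pred_tr <- ifelse(stats::predict(fit, dtr, type = "class") == "1", 1, -1)
    err <- sum(w * (pred_tr != y_pm))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5 && b > 1L) break
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * y_pm * pred_tr)
    w <- w / sum(w)
    pred_te <- ifelse(stats::predict(fit, dte, type = "class") == "1", 1, -1)
    score <- score + alpha * pred_te
  }
  1 / (1 + exp(-2 * score))   # logistic squash: monotone class-1 confidence
}
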