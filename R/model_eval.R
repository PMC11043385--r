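# Evaluation protocols: stratified 5-fold cross-validation, independent
# test, ensemble enumeration, rank-score summaries.

#' Stratified k-fold assignment
#'
#' Samples are ordered by id before the seeded draw so folds are
#' bit-reproducible regardless of input order.
#'
#' @param ids sample ids.
#' @param labels labels in {0, 1}.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold assignment (1..k) aligned with `ids`.
#' @export
stratified_folds <- function(ids, labels, k = 5L, seed = 1L) {
  stopifnot(length(ids) == length(labels), k >= 2L)
  for (cls in unique(labels)) {
    if (sum(labels == cls) < k) {
      stop("class ", cls, " has fewer members than folds", call. = FALSE)
    }
  }
  fold <- integer(length(ids))
  set.seed(substream_seed(seed, "folds"))
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[order(ids[idx])]
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Each fold is held out once; feature standardization is fit on each
#' training fold and applied to its test fold inside [train_and_predict()].
#'
#' @param X feature matrix (rownames used as ids when present).
#' @param y labels in {0, 1}.
#' @param spec a `classifier_spec`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list with `per_fold` (list of metric sets), `mean` (metric-wise
#'   mean), and `folds` (assignment vector).
#' @export
cross_validate <- function(X, y, spec, k = 5L, seed = 1L) {
  ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(nrow(X)))
  fold <- stratified_folds(ids, y, k, seed)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- fold != f; te <- fold == f
    res <- train_and_predict(X[tr, , drop = FALSE], y[tr],
                             X[te, , drop = FALSE], spec, seed = seed)
    compute_metrics(count_predictions(res$pred, y[te]),
                    scores = res$score, labels = y[te])
  })
  metric_names <- c("ACC", "SN", "SP", "FPR", "F1", "MCC", "AUCROC")
  means <- lapply(metric_names, function(mn) {
    mean(vapply(per_fold, function(m) m[[mn]], 0))
  })
  list(per_fold = per_fold,
       mean = stats::setNames(means, metric_names),
       folds = fold)
}

#' Train on the train split, evaluate on the independent test split
#'
#' @param dataset labeled, split sequence data.frame (see [build_dataset()]).
#' @param encoders encoder ids to fuse (see [encoder_ids()]).
#' @param spec a `classifier_spec`.
#' @param length_threshold fixed sequence length before encoding
#'   (default 1000).
#' @param seed integer seed.
#' @param ... encoder parameters passed to [encode_matrix()].
#' @return metric set on the test split (with AUC-ROC).
#' @export
evaluate_independent <- function(dataset, encoders, spec,
                                 length_threshold = 1000L, seed = 1L, ...) {
  validate_seqs(dataset, require_label = TRUE)
  if (!"split" %in% names(dataset)) stop("dataset has no split column",
                                         call. = FALSE)
  fixed <- fix_length_seqs(dataset, length_threshold)
  X <- encode_matrix(fixed, encoders, ...)
  tr <- dataset$split == "train"; te <- dataset$split == "test"
  res <- train_and_predict(X[tr, , drop = FALSE], dataset$label[tr],
                           X[te, , drop = FALSE], spec, seed = seed)
  compute_metrics(count_predictions(res$pred, dataset$label[te]),
                  scores = res$score, labels = dataset$label[te])
}

#' Enumerate encoder-pair x classifier ensemble configurations
#'
#' All unordered pairs of distinct encoders crossed with all classifiers,
#' in deterministic lexicographic order (13 encoders x 11 classifiers give
#' the 858-configuration grid).
#'
#' @param encoders character vector of unique encoder ids.
#' @param classifiers character vector of classifier names.
#' @return data.frame with columns `encoder1`, `encoder2`, `classifier`.
#' @export
enumerate_ensembles <- function(encoders = encoder_ids(),
                                classifiers = CLASSIFIER_NAMES) {
  if (anyDuplicated(encoders)) stop("duplicate encoder ids", call. = FALSE)
  if (length(encoders) < 2L) stop("need at least two encoders", call. = FALSE)
  pairs <- t(utils::combn(sort(encoders), 2L))
  out <- expand.grid(classifier = sort(classifiers), pair = seq_len(nrow(pairs)),
                     stringsAsFactors = FALSE)
  out <- out[order(out$pair, out$classifier), ]
  data.frame(encoder1 = pairs[out$pair, 1L], encoder2 = pairs[out$pair, 2L],
             classifier = out$classifier, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank-score summary of a results grid
#'
#' For every (encoder, classifier, dataset) cell the maximum ACC over
#' sequence lengths is taken; encoders are then ranked within each
#' (classifier, dataset) group (rank 1 = best, ties share the mean rank),
#' and the final score is the mean rank across datasets. `axis =
#' "classifier"` transposes the roles.
#'
#' @param results data.frame with columns `dataset`, `encoder`,
#'   `classifier`, `length`, `ACC` covering a full grid.
#' @param axis rank encoders (default) or classifiers.
#' @return matrix of mean ranks; rows = ranked entities, columns = the
#'   conditioning entities.
#' @export
rank_scores <- function(results, axis = c("encoder", "classifier")) {
  axis <- match.arg(axis)
  needed <- c("dataset", "encoder", "classifier", "length", "ACC")
  if (!all(needed %in% names(results))) {
    stop("results need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  other <- if (axis == "encoder") "classifier" else "encoder"
  # max ACC over lengths per (encoder, classifier, dataset)
  agg <- stats::aggregate(ACC ~ dataset + encoder + classifier,
                          data = results, FUN = max)
  full <- expand.grid(dataset = unique(agg$dataset),
                      encoder = unique(agg$encoder),
                      classifier = unique(agg$classifier),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$dataset, d$encoder, d$classifier, sep = "\r")
  missing <- setdiff(key(full), key(agg))
  if (length(missing)) {
    stop("missing grid cells: ",
         paste(utils::head(gsub("\r", "/", missing), 5L), collapse = "; "),
         call. = FALSE)
  }
  ranked <- unique(agg[[axis]]); cond <- unique(agg[[other]])
  datasets <- unique(agg$dataset)
  out <- matrix(0, nrow = length(ranked), ncol = length(cond),
                dimnames = list(sort(ranked), sort(cond)))
  for (co in colnames(out)) {
    rank_by_ds <- vapply(datasets, function(ds) {
      sub <- agg[agg[[other]] == co & agg$dataset == ds, ]
      r <- rank(-sub$ACC, ties.method = "average")
      r[match(rownames(out), sub[[axis]])]
    }, numeric(nrow(out)))
    out[, co] <- rowMeans(rank_by_ds)
  }
  out
}

#' Long-format grid results writer
#'
#' @param results grid results data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_grid_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
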