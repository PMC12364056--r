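# Distance-based nearest-neighbor evaluation protocols: leave-one-out
# 1-NN, and k-NN under stratified cross-validation repeated over many
# seeds, with macro-averaged metrics so every class carries equal
# weight regardless of size.

#' Drop samples whose class is too small
#'
#' Retains only samples belonging to classes with at least `min_size`
#' members (the classification protocols restrict evaluation to
#' families with at least 15 representatives by default).
#'
#' @param labels Named character vector (id -> class).
#' @param min_size Minimum class size (default 15).
#' @return Filtered named character vector, with attribute `dropped`
#'   listing the removed classes.
#' @export
filter_min_class_size <- function(labels, min_size = 15L) {
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_size]
  if (length(keep) == 0L)
    .stopf("no class has >= %d members", min_size)
  out <- labels[labels %in% keep]
  attr(out, "dropped") <- setdiff(names(sizes), keep)
  out
}

# Nearest neighbors of column `i` among candidate indices, ties broken
# by smallest id.
.order_by_distance <- function(d, ids) {
  order(d, ids)
}

#' Leave-one-out 1-NN evaluation
#'
#' Each sample is classified by the label of its nearest other sample
#' under the precomputed distance; ties go to the smallest id.  A
#' sample is correct iff the neighbor shares its label.
#'
#' @param D Symmetric distance matrix with id dimnames.
#' @param labels Named character vector covering all ids in `D`.
#' @return List with `accuracy` and `verdicts` (data frame: id,
#'   neighbor, label, predicted, correct).
#' @export
loo_1nn <- function(D, labels) {
  ids <- rownames(D)
  stopifnot(length(ids) >= 2L, all(ids %in% names(labels)))
  verdicts <- lapply(seq_along(ids), function(i) {
    others <- setdiff(seq_along(ids), i)
    nb <- others[.order_by_distance(D[i, others], ids[others])[1L]]
    data.frame(id = ids[i], neighbor = ids[nb],
               label = unname(labels[ids[i]]),
               predicted = unname(labels[ids[nb]]))
  })
  verdicts <- do.call(rbind, verdicts)
  verdicts$correct <- verdicts$label == verdicts$predicted
  list(accuracy = mean(verdicts$correct), verdicts = verdicts)
}

# Macro metrics of a prediction on one test fold.  Macro averages run
# over the classes present in the truth of the fold; precision of a
# class never predicted is counted as 0.
.fold_metrics <- function(truth, predicted) {
  classes <- sort(unique(truth))
  recall <- vapply(classes, function(cl)
    mean(predicted[truth == cl] == cl), numeric(1))
  precision <- vapply(classes, function(cl) {
    hits <- predicted == cl
    if (!any(hits)) 0 else mean(truth[hits] == cl)
  }, numeric(1))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  c(acc = mean(truth == predicted),
    balanced_accuracy = mean(recall),
    macro_f1 = mean(f1),
    macro_recall = mean(recall),
    macro_precision = mean(precision))
}

# Stratified fold assignment: per class, shuffle members and deal them
# round-robin over folds.
.stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  names(fold) <- names(labels)
  for (cl in unique(labels)) {
    members <- sample(names(labels)[labels == cl])
    fold[members] <- rep_len(seq_len(folds), length(members))
  }
  fold
}

# k-NN prediction for test ids against training ids on a precomputed
# distance matrix.  Majority vote among the k nearest; ties are broken
# by the smaller summed distance of the tied label's neighbors, then by
# the smallest label.
.knn_predict <- function(D, labels, train, test, k) {
  vapply(test, function(id) {
    ord <- .order_by_distance(D[id, train], train)
    nn <- train[ord[seq_len(min(k, length(train)))]]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    sums <- vapply(top, function(cl)
      sum(D[id, nn[labels[nn] == cl]]), numeric(1))
    top[order(sums, top)][1L]
  }, character(1))
}

#' k-NN classification under repeated stratified cross-validation
#'
#' Per seed, samples are assigned to stratified folds; each fold is
#' classified by majority vote among its `k` nearest training samples
#' on the precomputed distances.  Accuracy, balanced accuracy, macro
#' F1, macro recall and macro precision are computed per fold and
#' aggregated as mean and standard deviation over all seed-by-fold
#' runs.
#'
#' @param D Symmetric distance matrix with id dimnames.
#' @param labels Named character vector covering all ids in `D`.
#' @param k Number of neighbors (default 5).
#' @param folds Number of folds (default 5); every class must have at
#'   least `folds` members.
#' @param seeds Integer vector of RNG seeds (default `0:29`).
#' @return Object of class `cakl_cv`: list with `runs` (one row per
#'   seed x fold) and `aggregate` (mean and sd per metric).
#' @export
knn_cv <- function(D, labels, k = 5L, folds = 5L, seeds = 0:29) {
  ids <- rownames(D)
  stopifnot(all(ids %in% names(labels)))
  labels <- labels[ids]
  sizes <- table(labels)
  if (length(sizes) < 2L)
    .stopf("cross-validated k-NN needs at least 2 classes")
  small <- names(sizes)[sizes < folds]
  if (length(small) > 0L)
    .stopf("class(es) smaller than %d folds: %s", folds,
           paste(small, collapse = ", "))
  runs <- list()
  for (s in seeds) {
    fold <- .stratified_folds(labels, folds, seed = s)
    for (f in seq_len(folds)) {
      test <- names(fold)[fold == f]
      train <- names(fold)[fold != f]
      pred <- .knn_predict(D, labels, train, test, k)
      m <- .fold_metrics(unname(labels[test]), unname(pred))
      runs[[length(runs) + 1L]] <-
        data.frame(seed = s, fold = f, t(m))
    }
  }
  runs <- do.call(rbind, runs)
  metrics <- setdiff(names(runs), c("seed", "fold"))
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(runs[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) sd(runs[[m]]), numeric(1)))
  structure(list(runs = runs, aggregate = aggregate, k = k,
                 folds = folds, seeds = seeds),
            class = "cakl_cv")
}

#' @export
print.cakl_cv <- function(x, ...) {
  cat(sprintf("%d-NN, %d-fold CV over %d seeds (%d runs)\n",
              x$k, x$folds, length(x$seeds), nrow(x$runs)))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' One row per seed x fold, followed by aggregate rows.
#'
#' @param report A `cakl_cv` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_tsv <- function(report, path) {
  write.table(report$runs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat("# aggregate (metric\tmean\tsd)\n", file = path, append = TRUE)
  for (i in seq_len(nrow(report$aggregate)))
    cat(sprintf("# %s\t%.10g\t%.10g\n", report$aggregate$metric[i],
                report$aggregate$mean[i], report$aggregate$sd[i]),
        file = path, append = TRUE)
  invisible(path)
}
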