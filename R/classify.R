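# KNN classification, one-vs-rest confusion accounting, and stratified
# k-fold cross-validation.

# Numeric design matrix of a feature table: the canonical 16 columns when
# present, otherwise every numeric column except `label`.
.fm_matrix <- function(fm) {
  if (all(feature_names() %in% names(fm))) {
    as.matrix(fm[, feature_names(), drop = FALSE])
  } else {
    keep <- vapply(fm, is.numeric, logical(1)) & names(fm) != "label"
    as.matrix(fm[, keep, drop = FALSE])
  }
}

#' k-nearest-neighbor prediction
#'
#' Euclidean distance in the 16-dimensional feature space, majority vote
#' over the `k` nearest training rows. Ties are broken deterministically:
#' first by the smallest summed distance among the tied classes, then by
#' lexicographic class name. With `k = 1` the query takes the single nearest
#' neighbour's label.
#'
#' @param train A feature matrix (see [build_feature_matrix()]) with labels.
#' @param query Numeric feature vector, or a matrix/data frame of query rows.
#' @param k Number of neighbours (default 5); must not exceed the number of
#'   training rows.
#' @return Character label, or a vector of labels for multiple queries.
#' @export
knn_predict <- function(train, query, k = 5) {
  x <- .fm_matrix(train)
  labels <- train$label
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  if (k > nrow(x)) {
    stop(sprintf("k = %d exceeds the %d training instances", k, nrow(x)),
         call. = FALSE)
  }
  if (is.data.frame(query)) query <- .fm_matrix(query)
  if (is.matrix(query)) {
    return(vapply(seq_len(nrow(query)), function(i) {
      .knn_one(x, labels, as.numeric(query[i, ]), k)
    }, character(1)))
  }
  .knn_one(x, labels, as.numeric(query), k)
}

.knn_one <- function(x, labels, q, k) {
  if (length(q) != ncol(x)) {
    stop("query length does not match the feature count", call. = FALSE)
  }
  d <- sqrt(colSums((t(x) - q)^2))
  ord <- order(d, seq_along(d))[seq_len(k)]
  .vote(labels[ord], d[ord])
}

# Majority vote with summed-distance then lexicographic tie-breaking.
.vote <- function(lab, dist) {
  counts <- table(lab)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    sums <- vapply(top, function(cl) sum(dist[lab == cl]), numeric(1))
    top <- top[sums == min(sums)]
    top <- sort(top)
  }
  top[1L]
}

#' One-vs-rest confusion counts
#'
#' Per-class TP, TN, FP, FN from paired truth/prediction vectors; for every
#' class the four counts sum to the number of instances.
#'
#' @param truth,pred Character vectors of equal length.
#' @return Data frame with columns `class`, `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("`truth` and `pred` must have equal length", call. = FALSE)
  }
  classes <- sort(unique(c(truth, pred)))
  n <- length(truth)
  out <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    data.frame(class = cl, tp = tp, tn = n - tp - fp - fn, fp = fp, fn = fn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classification accuracy (percent)
#'
#' `(TP + TN) / (TP + TN + FP + FN) * 100`, on one-vs-rest counts.
#'
#' @param counts Named list/vector with `tp`, `tn`, `fp`, `fn`, or one row
#'   of [confusion_counts()].
#' @return Percentage in `[0, 100]`.
#' @examples
#' accuracy_pct(list(tp = 2, tn = 3, fp = 1, fn = 0))  # 83.33
#' @export
accuracy_pct <- function(counts) {
  cts <- .as_counts(counts)
  denom <- sum(cts)
  if (denom == 0) stop("undefined metric: all counts are zero", call. = FALSE)
  (cts[["tp"]] + cts[["tn"]]) / denom * 100
}

#' Specificity (true-negative rate)
#'
#' `TN / (TN + FP)`, a fraction in `[0, 1]`.
#'
#' @inheritParams accuracy_pct
#' @return Fraction in `[0, 1]`.
#' @export
specificity_frac <- function(counts) {
  cts <- .as_counts(counts)
  if (cts[["tn"]] + cts[["fp"]] == 0) {
    stop("undefined metric: TN + FP = 0", call. = FALSE)
  }
  cts[["tn"]] / (cts[["tn"]] + cts[["fp"]])
}

.as_counts <- function(counts) {
  cts <- unlist(counts[c("tp", "tn", "fp", "fn")])
  if (length(cts) != 4L || anyNA(cts) || any(cts < 0)) {
    stop("`counts` must supply non-negative tp, tn, fp, fn", call. = FALSE)
  }
  cts
}

#' Stratified k-fold cross-validation of the KNN classifier
#'
#' Shuffles each class with the seeded generator, deals its instances
#' round-robin over `folds` folds, then trains/tests KNN per fold and
#' aggregates the confusion matrix over all folds. Per-class accuracy
#' (percent, one-vs-rest) and specificity are computed from the aggregated
#' counts; `average_*` are their arithmetic means over classes, and
#' `overall_accuracy` is the plain percentage of correct predictions
#' (chance level 33.3% for three balanced classes). Fully deterministic
#' given the seed.
#'
#' @param fm Feature matrix with a `label` column.
#' @param k Neighbour count for [knn_predict()] (default 5).
#' @param folds Number of folds (default 10); every class needs at least
#'   `folds` instances.
#' @param seed Integer seed for the fold shuffle (default 0).
#' @param scale Optionally z-score features per fold using the training
#'   statistics (default `FALSE`, i.e. raw feature distances).
#' @return An object of class `classification_report`.
#' @export
cross_validate <- function(fm, k = 5, folds = 10, seed = 0, scale = FALSE) {
  .check_feature_matrix(fm)
  labels <- fm$label
  classes <- sort(unique(labels))
  tab <- table(labels)
  if (any(tab < folds)) {
    stop(sprintf("every class needs >= %d instances (smallest has %d)",
                 folds, min(tab)), call. = FALSE)
  }
  n <- nrow(fm)
  fold_of <- integer(n)
  shuffles <- with_seed(seed, {
    lapply(classes, function(cl) sample(which(labels == cl)))
  })
  for (s in shuffles) fold_of[s] <- rep_len(seq_len(folds), length(s))

  x <- .fm_matrix(fm)
  pred <- character(n)
  for (f in seq_len(folds)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    xtr <- x[tr, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    if (scale) {
      mu <- colMeans(xtr)
      sd <- apply(xtr, 2, stats::sd)
      sd[sd == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sd, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sd, "/")
    }
    pred[te] <- .knn_batch(xtr, labels[tr], xte, k)
  }

  counts <- confusion_counts(labels, pred)
  per_class <- data.frame(
    class = counts$class,
    accuracy = vapply(seq_len(nrow(counts)), function(i) accuracy_pct(counts[i, ]), numeric(1)),
    specificity = vapply(seq_len(nrow(counts)), function(i) specificity_frac(counts[i, ]), numeric(1)),
    recall = counts$tp / (counts$tp + counts$fn),
    stringsAsFactors = FALSE
  )
  confusion <- table(truth = factor(labels, classes), pred = factor(pred, classes))
  structure(
    list(per_class = per_class,
         average_accuracy = mean(per_class$accuracy),
         average_specificity = mean(per_class$specificity),
         overall_accuracy = 100 * mean(pred == labels),
         counts = counts, confusion = confusion,
         fold_assignments = fold_of, predictions = pred,
         k = k, folds = folds, seed = seed, scaled = scale),
    class = "classification_report"
  )
}

# Batch KNN used inside CV: squared-distance matrix via the expanded form.
.knn_batch <- function(xtr, labtr, xte, k) {
  if (k > nrow(xtr)) {
    stop(sprintf("k = %d exceeds the %d training instances", k, nrow(xtr)),
         call. = FALSE)
  }
  d2 <- outer(rowSums(xte^2), rep(1, nrow(xtr))) +
    outer(rep(1, nrow(xte)), rowSums(xtr^2)) - 2 * tcrossprod(xte, xtr)
  d2[d2 < 0] <- 0
  vapply(seq_len(nrow(xte)), function(i) {
    d <- sqrt(d2[i, ])
    ord <- order(d, seq_along(d))[seq_len(k)]
    .vote(labtr[ord], d[ord])
  }, character(1))
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> KNN k=%d, %d-fold CV, seed %d\n",
              x$k, x$folds, x$seed))
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("average accuracy %.2f%%, average specificity %.3f, overall %.2f%% correct\n",
              x$average_accuracy, x$average_specificity, x$overall_accuracy))
  invisible(x)
}
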