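#' Confusion matrix
#'
#' @param true_labels,predicted_labels Equal-length label vectors; all
#'   values must appear in \code{classes}.
#' @param classes Ordered class labels fixing row/column order; default
#'   sorted union of observed labels.
#' @return K x K integer matrix, rows = true class, columns = predicted
#'   class, class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             classes = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length", call. = FALSE)
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (is.null(classes))
    classes <- sort(unique(c(true_labels, predicted_labels)))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad))
    stop("labels not in classes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cm <- table(factor(true_labels, levels = classes),
              factor(predicted_labels, levels = classes))
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Per-class precision, sensitivity and total accuracy
#'
#' Precision is column-wise TP/(TP+FP), sensitivity row-wise
#' TP/(TP+FN), total accuracy trace/total. A class never predicted has
#' undefined precision, reported as \code{NA} (never 0) and excluded
#' from macro averages.
#'
#' @param cm A \code{\link{confusion_matrix}}.
#' @return list with \code{precision}, \code{sensitivity} (named
#'   per-class vectors), \code{total_accuracy},
#'   \code{macro_precision}, \code{macro_sensitivity}.
#' @export
class_metrics <- function(cm) {
  cm <- unclass(cm)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  col_tot <- colSums(cm)
  row_tot <- rowSums(cm)
  precision <- ifelse(col_tot > 0, tp / col_tot, NA_real_)
  sensitivity <- ifelse(row_tot > 0, tp / row_tot, NA_real_)
  names(precision) <- names(sensitivity) <- rownames(cm)
  if (anyNA(precision))
    message("precision undefined for never-predicted class(es): ",
            paste(rownames(cm)[is.na(precision)], collapse = ", "))
  list(precision = precision, sensitivity = sensitivity,
       total_accuracy = sum(tp) / n,
       macro_precision = mean(precision, na.rm = TRUE),
       macro_sensitivity = mean(sensitivity, na.rm = TRUE))
}

# cap A_ortho at the generic count of Y-orthogonal feature directions,
# max(0, p - (K - 1)); beyond it fit_oplsda raises a rank-error
feasible_ortho <- function(A_ortho, K, p) {
  cap <- max(0L, p - (K - 1L))
  if (A_ortho > cap) {
    warning(sprintf(
      "reducing A_ortho from %d to %d (only p - (K-1) orthogonal directions exist)",
      A_ortho, cap))
    return(cap)
  }
  as.integer(A_ortho)
}

# stratified fold assignment, deterministic under the active RNG state
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(sample(seq_len(k)), length(idx))
  }
  fold
}

feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  cols <- c("area", "protein", "nucleic_acid", "saturated_lipid",
            "unsaturated_lipid")
  if (all(cols %in% names(features)))
    return(as.matrix(features[, cols]))
  as.matrix(features[vapply(features, is.numeric, TRUE)])
}

#' Stratified k-fold cross-validation of OPLS-DA
#'
#' Splits samples into k stratified folds; for each fold the scaler and
#' the OPLS-DA model are fitted on the training folds only and the held
#' out fold predicted; predictions are pooled into one confusion
#' matrix. If the smallest class has fewer than \code{k} members, k is
#' reduced to that count with a warning. Deterministic for a fixed
#' seed.
#'
#' @param features Feature table (data.frame with the 5 feature
#'   columns) or a numeric matrix.
#' @param labels Class label per row (>= 2 classes).
#' @param k Number of folds (default 7).
#' @param A_pred,A_ortho OPLS-DA component counts (defaults: all
#'   supportable predictive components, one orthogonal component, with
#'   A_ortho capped at the feasible count for the given K and p).
#' @param seed Integer seed for fold assignment.
#' @return list with \code{confusion} (pooled
#'   \code{\link{confusion_matrix}}), \code{metrics}
#'   (\code{\link{class_metrics}}), \code{k}, \code{fold} assignment
#'   and \code{predicted} labels in input order.
#' @export
cross_validate <- function(features, labels, k = 7L, A_pred = NULL,
                           A_ortho = 1L, seed = 1L) {
  X <- feature_matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  min_n <- min(table(labels))
  if (min_n < k) {
    warning(sprintf("reducing k from %d to smallest class count %d",
                    k, min_n))
    k <- min_n
  }
  if (k < 2L) stop("need k >= 2 (every class >= 2 samples)",
                   call. = FALSE)
  A_ortho <- feasible_ortho(A_ortho, length(classes), ncol(X))
  fold <- withr::with_seed(as.integer(seed), stratified_folds(labels, k))
  pred <- character(length(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- fit_oplsda(autoscale(X[tr, , drop = FALSE]), labels[tr],
                        A_pred = A_pred, A_ortho = A_ortho)
    pred[!tr] <- predict_oplsda(model,
                                X[!tr, , drop = FALSE])$predicted_label
  }
  cm <- confusion_matrix(labels, pred, classes)
  list(confusion = cm, metrics = class_metrics(cm), k = k,
       fold = fold, predicted = pred)
}

#' Resubstitution (training-set) metrics of an OPLS-DA fit
#'
#' Fits on the full table and evaluates on the same samples; the
#' optimistic counterpart of \code{\link{cross_validate}}, reported
#' alongside it.
#'
#' @inheritParams cross_validate
#' @return list with \code{confusion}, \code{metrics}, \code{model}.
#' @export
resubstitution_metrics <- function(features, labels, A_pred = NULL,
                                   A_ortho = 1L) {
  X <- feature_matrix(features)
  labels <- as.character(labels)
  A_ortho <- feasible_ortho(A_ortho, length(unique(labels)), ncol(X))
  model <- fit_oplsda(autoscale(X), labels, A_pred = A_pred,
                      A_ortho = A_ortho)
  pred <- predict_oplsda(model, X)$predicted_label
  cm <- confusion_matrix(labels, pred, sort(unique(labels)))
  list(confusion = cm, metrics = class_metrics(cm), model = model)
}
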