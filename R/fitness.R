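#' Hyperparameter set for the mixed-kernel SVM
#'
#' One point of the search space the optimizer explores: the
#' regularization coefficient C together with the kernel parameters
#' (m, d, g).
#'
#' @param C positive regularization coefficient.
#' @param m mixture weight of the polynomial kernel.
#' @param d polynomial order (2 or 3).
#' @param g positive RBF parameter.
#' @param g_as RBF convention, see [kernel_params()].
#' @return An object of class \code{"hyper_params"}.
#' @export
hyper_params <- function(C, m, d, g, g_as = "width") {
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("C must be a single positive value", call. = FALSE)
  structure(list(C = C, kernel_params = kernel_params(m, d, g, g_as)),
            class = "hyper_params")
}

#' @export
print.hyper_params <- function(x, ...) {
  p <- x$kernel_params
  cat(sprintf("C = %g, g = %g (%s), m = %g, d = %d\n",
              x$C, p$g, p$g_as, p$m, p$d))
  invisible(x)
}

#' Confusion counts for -1/+1 classification
#'
#' +1 is the positive (nodule) class.
#'
#' @param y_true,y_pred -1/+1 vectors of equal length.
#' @return A list with integer counts \code{TP}, \code{FP}, \code{TN},
#'   \code{FN}.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length", call. = FALSE)
  check_labels(y_true)
  check_labels(y_pred)
  list(TP = sum(y_true == 1 & y_pred == 1),
       FP = sum(y_true == -1 & y_pred == 1),
       TN = sum(y_true == -1 & y_pred == -1),
       FN = sum(y_true == 1 & y_pred == -1))
}

#' Recognition accuracy (percent)
#'
#' ACC = 100 (TP + TN) / (TP + TN + FP + FN).
#'
#' @param counts confusion counts from [confusion_counts()].
#' @return Accuracy as a percentage in \[0, 100\].
#' @export
acc <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("accuracy undefined on empty counts", call. = FALSE)
  100 * (counts$TP + counts$TN) / total
}

#' Sensitivity (percent)
#'
#' SEN = 100 TP / (TP + FN): the fraction of true nodules detected.
#'
#' @param counts confusion counts from [confusion_counts()].
#' @return Sensitivity as a percentage in \[0, 100\].
#' @export
sen <- function(counts) {
  pos <- counts$TP + counts$FN
  if (pos == 0)
    stop("sensitivity undefined: no positive samples", call. = FALSE)
  100 * counts$TP / pos
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of k cross-validation folds, shuffling
#' within each class and distributing classes round-robin so fold sizes
#' differ by at most one both overall and within each class.
#'
#' @param y -1/+1 label vector.
#' @param k number of folds.
#' @param seed integer seed; the assignment is deterministic given
#'   (y, k, seed).
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
stratified_folds <- function(y, k, seed) {
  check_labels(y, require_both = TRUE)
  classes <- sort(unique(y), decreasing = TRUE)
  for (cl in classes) {
    if (sum(y == cl) < k)
      stop(sprintf("class %+d has fewer than k = %d members", cl, k),
           call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    offset <- 0L
    for (cl in classes) {
      idx <- sample(which(y == cl))
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

#' Cross-validated accuracy fitness
#'
#' The optimizer's objective: k-fold cross-validated recognition accuracy
#' of the mixed-kernel SVM at one hyperparameter point. Within each fold
#' the features are z-scored with training-fold statistics only, the SVM
#' is trained on the training folds' Gram matrix, and out-of-fold
#' predictions are pooled into one confusion table, whose ACC (percent)
#' is returned. Pooling keeps the fitness a rational number with
#' denominator l (e.g. 160/170 = 94.1176), matching per-sample counting.
#'
#' @param data a [feature_dataset()].
#' @param hp a [hyper_params()] point.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param kkt_tol,max_iter passed to [train_svm()].
#' @return CV accuracy in percent; deterministic in (data, hp, k, seed).
#' @export
cv_fitness <- function(data, hp, k = 5, seed = 1, kkt_tol = 1e-3,
                       max_iter = NULL) {
  stopifnot(inherits(data, "feature_dataset"), inherits(hp, "hyper_params"))
  folds <- stratified_folds(data$y, k, seed)
  tp <- fp <- tn <- fn <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    sc <- fold_scaler(data$X[tr, , drop = FALSE])
    Ztr <- sc$transform(data$X[tr, , drop = FALSE])
    Zva <- sc$transform(data$X[!tr, , drop = FALSE])
    Ktr <- gram_matrix(Ztr, params = hp$kernel_params)
    model <- tryCatch(
      train_svm(Ktr, data$y[tr], hp$C, kkt_tol = kkt_tol,
                max_iter = max_iter),
      error = function(e) {
        stop(sprintf("solver failure in fold %d: %s", f, conditionMessage(e)),
             call. = FALSE)
      })
    Kva <- gram_matrix(Ztr, Zva, hp$kernel_params)
    pred <- predict(model, Kva)
    truth <- data$y[!tr]
    tp <- tp + sum(truth == 1 & pred == 1)
    fp <- fp + sum(truth == -1 & pred == 1)
    tn <- tn + sum(truth == -1 & pred == -1)
    fn <- fn + sum(truth == 1 & pred == -1)
  }
  acc(list(TP = tp, FP = fp, TN = tn, FN = fn))
}

# z-scoring closure from training-fold statistics; constant features are
# centered but left unscaled
fold_scaler <- function(Xtr) {
  mu <- colMeans(Xtr)
  n <- nrow(Xtr)
  v <- (colSums(Xtr^2) - n * mu^2) / max(n - 1, 1)
  s <- sqrt(pmax(v, 0))
  s[s < 1e-12] <- 1
  list(mu = mu, sd = s,
       transform = function(X)
         sweep(sweep(as.matrix(X), 2, mu, "-"), 2, s, "/"))
}
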