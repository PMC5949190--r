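#' Train a soft-margin SVM on a precomputed Gram matrix
#'
#' Solves the dual problem
#' \deqn{\min_\alpha \frac12 \sum_{ij} y_i y_j K_{ij} \alpha_i \alpha_j -
#'   \sum_j \alpha_j, \quad \sum_i y_i \alpha_i = 0,\; 0 \le \alpha_i \le C}
#' with a sequential-minimal-optimization (SMO) working-set solver using
#' second-order pair selection, then recovers the offset b by averaging
#' over unbounded support vectors.
#'
#' @param K l x l symmetric positive-semidefinite Gram matrix of the
#'   training points.
#' @param y length-l vector of -1/+1 labels; both classes required.
#' @param C positive regularization (misclassification penalty)
#'   coefficient.
#' @param kkt_tol stopping tolerance on the maximal KKT violation.
#' @param max_iter maximal number of SMO pair updates; default
#'   \code{10 * l^2}.
#' @return An object of class \code{"svm_model"}: a list with
#'   \code{alpha}, \code{b}, \code{support} (indices with
#'   \eqn{\alpha_i > 10^{-8} C}), \code{C}, \code{y}, the dual
#'   \code{objective} (maximization form), \code{iterations} and
#'   \code{kkt_gap}.
#' @seealso [decision_values()], [predict.svm_model()], [mkl_svm()]
#' @export
train_svm <- function(K, y, C, kkt_tol = 1e-3, max_iter = NULL) {
  K <- as.matrix(K)
  l <- nrow(K)
  if (ncol(K) != l) stop("K must be square", call. = FALSE)
  if (length(y) != l) stop("length(y) must match nrow(K)", call. = FALSE)
  check_labels(y, require_both = TRUE)
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("C must be a single positive value", call. = FALSE)
  if (is.null(max_iter)) max_iter <- 10L * l^2
  res <- smo_solve(K, as.numeric(y), C, kkt_tol, as.integer(max_iter))
  alpha <- res$alpha
  if (!res$converged) {
    stop(errorCondition(
      sprintf("SMO did not converge within %d pair updates (KKT gap %.3g)",
              as.integer(max_iter), res$kkt_gap),
      class = c("mklpso_convergence_error", "error", "condition"),
      alpha = alpha, kkt_gap = res$kkt_gap))
  }
  b <- compute_offset(alpha, y, K, C)
  ay <- alpha * y
  structure(list(
    alpha = alpha,
    b = b,
    support = which(alpha > 1e-8 * C),
    C = C,
    y = y,
    objective = sum(alpha) - 0.5 * drop(crossprod(ay, K %*% ay)),
    iterations = res$iterations,
    kkt_gap = res$kkt_gap
  ), class = "svm_model")
}

#' Dual objective of a multiplier vector
#'
#' Maximization-form objective
#' \eqn{\sum_i \alpha_i - \frac12 \sum_{ij} y_i y_j K_{ij}\alpha_i\alpha_j};
#' used to compare solver output against an independent QP solution.
#'
#' @param alpha multiplier vector.
#' @param y -1/+1 labels.
#' @param K Gram matrix.
#' @return The dual objective value.
#' @export
svm_dual_objective <- function(alpha, y, K) {
  ay <- alpha * y
  sum(alpha) - 0.5 * drop(crossprod(ay, as.matrix(K) %*% ay))
}

#' Recover the SVM offset from a dual solution
#'
#' For every unbounded support vector j (\eqn{0 < \alpha_j < C}) the KKT
#' conditions give \eqn{b = y_j - \sum_i y_i \alpha_i K_{ij}}; the offset
#' is averaged over all such j to reduce floating-point sensitivity. When
#' no unbounded support vector exists, the midpoint of the feasible
#' interval for b implied by the bounded points is used.
#'
#' @param alpha multiplier vector.
#' @param y -1/+1 labels.
#' @param K training Gram matrix.
#' @param C regularization coefficient used in training.
#' @return The scalar offset b.
#' @export
compute_offset <- function(alpha, y, K, C) {
  K <- as.matrix(K)
  g0 <- drop(K %*% (alpha * y)) # decision values without offset
  thr <- 1e-8 * C
  free <- alpha > thr & alpha < C - thr
  if (any(free)) return(mean(y[free] - g0[free]))
  # feasible interval for b from the bounded points:
  #   alpha_i = 0:  y_i (g0_i + b) >= 1;   alpha_i = C:  y_i (g0_i + b) <= 1
  at0 <- alpha <= thr
  atC <- alpha >= C - thr
  lo <- suppressWarnings(max(c((1 - g0)[at0 & y > 0], (-1 - g0)[atC & y < 0])))
  hi <- suppressWarnings(min(c((-1 - g0)[at0 & y < 0], (1 - g0)[atC & y > 0])))
  if (!is.finite(lo) && !is.finite(hi))
    stop("cannot determine offset: no constraints on b", call. = FALSE)
  if (!is.finite(lo)) return(hi)
  if (!is.finite(hi)) return(lo)
  (lo + hi) / 2
}

#' Decision values of an SVM model on new points
#'
#' \eqn{g(x) = \sum_i \alpha_i y_i K(x_i, x) + b} for every test column
#' of the cross-Gram matrix.
#'
#' @param model an \code{"svm_model"}.
#' @param K_test l x m cross-Gram matrix between the l training rows and
#'   m test points.
#' @return Numeric vector of m decision values.
#' @export
decision_values <- function(model, K_test) {
  stopifnot(inherits(model, "svm_model"))
  K_test <- as.matrix(K_test)
  if (nrow(K_test) != length(model$alpha))
    stop("K_test must have one row per training point", call. = FALSE)
  drop(crossprod(K_test, model$alpha * model$y)) + model$b
}

#' Predict -1/+1 labels from an SVM model
#'
#' The label is the sign of the decision value; an exact tie g(x) = 0 is
#' mapped to +1 (the positive, nodule class) — the recall-favoring rule.
#'
#' @param object an \code{"svm_model"}.
#' @param K_test cross-Gram matrix between training and test points.
#' @param type \code{"class"} for -1/+1 labels, \code{"decision"} for raw
#'   decision values.
#' @param ... unused.
#' @return A numeric vector of labels or decision values.
#' @export
predict.svm_model <- function(object, K_test, type = c("class", "decision"),
                              ...) {
  type <- match.arg(type)
  g <- decision_values(object, K_test)
  if (type == "decision") return(g)
  ifelse(g >= 0, 1, -1)
}

#' Fit a mixed-kernel SVM to a feature matrix
#'
#' Convenience wrapper binding the kernel and the dual solver: computes
#' the mixed-kernel Gram matrix of \code{X}, trains the SVM, and stores
#' the training rows so new points can be classified directly.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y -1/+1 labels.
#' @param C positive regularization coefficient.
#' @param params a [kernel_params()] object.
#' @param ... passed to [train_svm()].
#' @return An object of class \code{"mkl_svm"} wrapping the
#'   \code{"svm_model"} together with \code{X} and \code{params}.
#' @examples
#' X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
#' y <- c(-1, -1, 1, 1)
#' fit <- mkl_svm(X, y, C = 10, kernel_params(m = 0.1, d = 2, g = 0.5))
#' predict(fit, X)
#' @export
mkl_svm <- function(X, y, C, params, ...) {
  X <- as.matrix(X)
  K <- gram_matrix(X, params = params)
  model <- train_svm(K, y, C, ...)
  structure(list(model = model, X = X, params = params), class = "mkl_svm")
}

#' @rdname mkl_svm
#' @param object an \code{"mkl_svm"} fit.
#' @param newdata feature matrix of points to classify.
#' @param type \code{"class"} or \code{"decision"}.
#' @export
predict.mkl_svm <- function(object, newdata,
                            type = c("class", "decision"), ...) {
  type <- match.arg(type)
  K_test <- gram_matrix(object$X, as.matrix(newdata), object$params)
  predict(object$model, K_test, type = type)
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf(
    "SVM dual solution: %d support vectors / %d points, C = %g, b = %.6g\n",
    length(x$support), length(x$alpha), x$C, x$b))
  invisible(x)
}
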