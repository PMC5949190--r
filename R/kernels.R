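#' Parameters of the polynomial + RBF mixture kernel
#'
#' Bundles the three quantities that define the mixed kernel
#' \eqn{K(x, x') = m (x \cdot x' + 1)^d + (1 - m) \exp(-\|x - x'\|^2 / 2g^2)}:
#' the mixture weight \code{m} on the polynomial part, the polynomial
#' order \code{d} and the RBF width \code{g}.
#'
#' Some SVM toolboxes parameterize the RBF kernel by \eqn{\gamma} in
#' \eqn{\exp(-\gamma \|x - x'\|^2)} rather than by the width \eqn{g} in
#' \eqn{\exp(-\|x-x'\|^2 / 2g^2)}. \code{g_as} selects the interpretation
#' of \code{g}; the two are related by \eqn{\gamma = 1 / (2 g^2)}.
#'
#' @param m mixture weight of the polynomial kernel, in \[0, 1\]. The
#'   optimizer keeps \code{m} strictly inside (0, 1); the boundary values
#'   collapse the mixture to a single kernel and are accepted here for
#'   explicit single-kernel use.
#' @param d polynomial order, 2 or 3.
#' @param g positive RBF parameter; its meaning depends on \code{g_as}.
#' @param g_as \code{"width"} (default) for the \eqn{2g^2} denominator
#'   convention, or \code{"gamma"} for the \eqn{\exp(-g r^2)} convention.
#' @return An object of class \code{"kernel_params"}.
#' @examples
#' p <- kernel_params(m = 0.8, d = 2, g = 19.0653)
#' mixed_kernel(c(1, 0), c(0, 1), p)
#' @export
kernel_params <- function(m, d, g, g_as = c("width", "gamma")) {
  g_as <- match.arg(g_as)
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m > 1)
    stop("m must be a single value in [0, 1]", call. = FALSE)
  if (!(d %in% c(2, 3)))
    stop("polynomial order d must be 2 or 3", call. = FALSE)
  if (!is.numeric(g) || length(g) != 1L || g <= 0)
    stop("g must be a single positive value", call. = FALSE)
  structure(list(m = m, d = as.integer(d), g = g, g_as = g_as),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("mixed kernel: m = %g (poly weight), d = %d, g = %g (%s)\n",
              x$m, x$d, x$g, x$g_as))
  invisible(x)
}

# coefficient of -||x - y||^2 in the RBF exponent
rbf_exponent_coef <- function(p) {
  if (p$g_as == "gamma") p$g else 1 / (2 * p$g^2)
}

#' Convert between RBF width and gamma conventions
#'
#' @param g positive width (or gamma).
#' @return \code{gamma_from_width}: \eqn{1/(2g^2)}; \code{width_from_gamma}:
#'   \eqn{1/\sqrt{2\gamma}}.
#' @export
gamma_from_width <- function(g) {
  stopifnot(g > 0)
  1 / (2 * g^2)
}

#' @rdname gamma_from_width
#' @export
width_from_gamma <- function(g) {
  stopifnot(g > 0)
  1 / sqrt(2 * g)
}

#' Polynomial kernel
#'
#' \eqn{K_{poly}(x, y) = (x \cdot y + 1)^d}.
#'
#' @param x,y numeric feature vectors of equal length.
#' @param d integer polynomial order, at least 1.
#' @return A single kernel value.
#' @export
poly_kernel <- function(x, y, d) {
  if (length(x) != length(y))
    stop("x and y must have the same dimension", call. = FALSE)
  if (d < 1) stop("d must be >= 1", call. = FALSE)
  (sum(x * y) + 1)^d
}

#' Radial basis (Gaussian) kernel
#'
#' \eqn{K_{rbf}(x, y) = \exp(-\|x - y\|^2 / 2g^2)} (width convention).
#'
#' @param x,y numeric feature vectors of equal length.
#' @param g positive kernel width.
#' @return A single kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, y, g) {
  if (length(x) != length(y))
    stop("x and y must have the same dimension", call. = FALSE)
  if (g <= 0) stop("g must be positive", call. = FALSE)
  exp(-sum((x - y)^2) / (2 * g^2))
}

#' Mixed polynomial + RBF kernel
#'
#' Convex two-kernel mixture
#' \eqn{m K_{poly}(x, y; d) + (1 - m) K_{rbf}(x, y; g)}.
#'
#' @param x,y numeric feature vectors of equal length.
#' @param params a [kernel_params()] object.
#' @return A single kernel value.
#' @export
mixed_kernel <- function(x, y, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (length(x) != length(y))
    stop("x and y must have the same dimension", call. = FALSE)
  coef <- rbf_exponent_coef(params)
  params$m * (sum(x * y) + 1)^params$d +
    (1 - params$m) * exp(-coef * sum((x - y)^2))
}

#' Convex combination of kernel evaluations
#'
#' General U-kernel form: a weighted sum of kernel values whose weights
#' are positive and sum to one, which is again a valid kernel value.
#'
#' @param values numeric vector of kernel evaluations at a common (x, y).
#' @param weights numeric vector of mixture weights, same length as
#'   \code{values}, each in (0, 1\], summing to 1 within 1e-9.
#' @return The combined kernel value.
#' @export
combine_kernels <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values and weights must have the same length", call. = FALSE)
  if (any(weights <= 0) || any(weights > 1))
    stop("each weight must lie in (0, 1]", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  sum(values * weights)
}

#' Gram matrix of the mixed kernel
#'
#' Computes the matrix of mixed-kernel values between the rows of \code{A}
#' and the rows of \code{B} in vectorized form. With \code{B} omitted the
#' self-Gram matrix of \code{A} is returned (symmetric by construction).
#'
#' @param A numeric matrix, n rows of feature vectors.
#' @param B optional numeric matrix with the same number of columns;
#'   defaults to \code{A}.
#' @param params a [kernel_params()] object.
#' @return An n x m numeric matrix with entry (i, j) =
#'   \code{mixed_kernel(A[i, ], B[j, ], params)}.
#' @export
gram_matrix <- function(A, B = NULL, params) {
  stopifnot(inherits(params, "kernel_params"))
  A <- as.matrix(A)
  self <- is.null(B)
  B <- if (self) A else as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("A and B must share the feature dimension", call. = FALSE)
  P <- tcrossprod(A, B)
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * P
  sq[sq < 0] <- 0 # clip negative round-off of squared distances
  coef <- rbf_exponent_coef(params)
  K <- params$m * (P + 1)^params$d + (1 - params$m) * exp(-coef * sq)
  if (self) K <- (K + t(K)) / 2
  K
}

#' Positive-semidefiniteness check of a kernel matrix
#'
#' A Mercer kernel's Gram matrix must be positive semidefinite; this is
#' the executable form of the convex-combination kernel validity result.
#' Floating-point eigenvalues of a true Gram matrix can be slightly
#' negative, hence the tolerance.
#'
#' @param K square symmetric numeric matrix.
#' @param tol nonnegative tolerance; default \code{1e-8 * max(diag(K))}.
#' @return A list with \code{is_psd} (logical) and \code{min_eigenvalue}.
#' @export
check_psd <- function(K, tol = 1e-8 * max(diag(K))) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K))
    stop("K must be square", call. = FALSE)
  if (max(abs(K - t(K))) > max(tol, 1e-8))
    stop("K must be symmetric", call. = FALSE)
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(is_psd = min(ev) >= -tol, min_eigenvalue = min(ev))
}
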