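#' Normalized Euclidean error norm of a fitness trace
#'
#' Root-mean-square gap between the best and average fitness curves from
#' generation t onward:
#' \deqn{F_{gy} = \sqrt{\sum_{k=t}^{T} (V_{best}(k) - V_{ave}(k))^2 /
#'   (T - t + 1)}.}
#' Dividing by the window length makes runs with different convergence
#' generations (hence different error-vector dimensions) comparable.
#'
#' @param v_best,v_ave equal-length numeric vectors (percent units).
#' @param t window start generation, 1 <= t <= length(v_best).
#' @return The RMS gap over generations t..maxgen.
#' @export
normalized_error_norm <- function(v_best, v_ave, t) {
  if (length(v_best) != length(v_ave))
    stop("v_best and v_ave must have equal length", call. = FALSE)
  n <- length(v_best)
  if (t < 1 || t > n) stop("t out of range", call. = FALSE)
  w <- t:n
  sqrt(sum((v_best[w] - v_ave[w])^2) / (n - t + 1))
}

#' Convergence generation of an average-fitness curve
#'
#' The smallest generation t such that the curve stays within
#' \code{epsilon} times its total range of its final value for all
#' k >= t. When only the final generation itself qualifies — i.e. the
#' curve is still oscillating outside the band at maxgen - 1 — no
#' convergence generation is reported (\code{NA}), mirroring traces where
#' no obvious convergence can be found.
#'
#' @param v_ave numeric average-fitness curve.
#' @param epsilon band half-width as a fraction of the curve's range
#'   (default 0.01).
#' @return Integer generation, or \code{NA_integer_} if the curve has not
#'   settled.
#' @export
convergence_generation <- function(v_ave, epsilon = 0.01) {
  n <- length(v_ave)
  if (n == 0) stop("empty trace", call. = FALSE)
  rng <- max(v_ave) - min(v_ave)
  if (rng == 0) return(1L)
  inside <- abs(v_ave - v_ave[n]) <= epsilon * rng
  # last generation outside the band; converged from the next one on
  out <- which(!inside)
  t <- if (length(out) == 0) 1L else max(out) + 1L
  if (t >= n) NA_integer_ else as.integer(t)
}

#' Summary statistics of a fitness trace
#'
#' The per-run curve summaries used to compare inertia-weight regimes:
#' maximum of the best-fitness curve, mean and median of the average
#' curve, the Euclidean norm of the full best-minus-average gap vector
#' over all generations, the convergence generation t, and the
#' normalized post-convergence error norm F_gy (NA when t is NA).
#'
#' @param trace a data.frame with columns \code{v_best} and \code{v_ave}
#'   (as produced by [pso_optimize()]), or a list with those elements.
#' @param epsilon convergence-band fraction, see
#'   [convergence_generation()].
#' @return A list of class \code{"curve_summary"} with fields
#'   \code{max_vbest}, \code{mean_vave}, \code{median_vave},
#'   \code{global_error_norm}, \code{t}, \code{fgy}.
#' @export
curve_summary <- function(trace, epsilon = 0.01) {
  vb <- trace$v_best
  va <- trace$v_ave
  if (is.null(vb) || is.null(va) || length(vb) != length(va))
    stop("trace must carry equal-length v_best and v_ave", call. = FALSE)
  t <- convergence_generation(va, epsilon)
  structure(list(
    max_vbest = max(vb),
    mean_vave = mean(va),
    median_vave = median(va),
    global_error_norm = sqrt(sum((vb - va)^2)),
    t = t,
    fgy = if (is.na(t)) NA_real_ else normalized_error_norm(vb, va, t)
  ), class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf(
    paste0("max(v_best) = %.4f  mean(v_ave) = %.4f  median(v_ave) = %.4f\n",
           "global error norm = %.4f  t = %s  F_gy = %s\n"),
    x$max_vbest, x$mean_vave, x$median_vave, x$global_error_norm,
    ifelse(is.na(x$t), "-", x$t),
    ifelse(is.na(x$fgy), "-", sprintf("%.4f", x$fgy))))
  invisible(x)
}

#' Tukey boxplot statistics
#'
#' Median, adjacent values and outlier count under the Tukey convention:
#' quartiles by linear interpolation (quantile type 7), whisker fences at
#' Q1 - 1.5 IQR and Q3 + 1.5 IQR, adjacents the extreme data points
#' inside the fences, outliers the points outside.
#'
#' @param values numeric vector, at least 4 values.
#' @return A list with \code{median}, \code{lower_adjacent},
#'   \code{upper_adjacent}, \code{n_outliers}.
#' @export
boxplot_stats <- function(values) {
  if (length(values) < 4)
    stop("need at least 4 values", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lower_fence <- q[1] - 1.5 * iqr
  upper_fence <- q[3] + 1.5 * iqr
  inside <- values >= lower_fence & values <= upper_fence
  list(median = q[2],
       lower_adjacent = min(values[inside]),
       upper_adjacent = max(values[inside]),
       n_outliers = sum(!inside))
}
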