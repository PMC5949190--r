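#' Default hyperparameter grids
#'
#' C on a log2 grid 2^-1..2^7 (9 points), g on 2^-3..2^5 (9 points),
#' m from 0.1 to 0.9 in steps of 0.1, d in \{2, 3\}: 1458 grid points.
#'
#' @return A named list of numeric vectors \code{C}, \code{g}, \code{m},
#'   \code{d}.
#' @export
default_grids <- function() {
  list(C = 2^(-1:7), g = 2^(-3:5), m = seq(0.1, 0.9, by = 0.1), d = c(2, 3))
}

#' Exhaustive grid search over (C, g, m, d)
#'
#' Evaluates the cross-validated accuracy fitness at every grid point and
#' returns the maximizer; ties are broken toward smaller C, then smaller
#' g, then smaller m, then smaller d. This is the baseline the swarm
#' optimizer is compared against at equal evaluation budget.
#'
#' @param data a [feature_dataset()].
#' @param grids named list of candidate values for \code{C}, \code{g},
#'   \code{m} and \code{d} (d must be a subset of \{2, 3\}); default
#'   [default_grids()].
#' @param k number of CV folds.
#' @param seed integer seed fixing the fold assignment (shared by all
#'   grid points, so fitnesses are comparable).
#' @param g_as RBF convention, see [kernel_params()].
#' @return A list with \code{best} (a [hyper_params()]),
#'   \code{best_fitness} (percent) and \code{table}, a data.frame of all
#'   grid points with their fitness.
#' @export
grid_search <- function(data, grids = default_grids(), k = 5, seed = 1,
                        g_as = "width") {
  stopifnot(inherits(data, "feature_dataset"))
  need <- c("C", "g", "m", "d")
  if (!all(need %in% names(grids)) || any(lengths(grids[need]) == 0))
    stop("grids must supply nonempty C, g, m and d", call. = FALSE)
  if (!all(grids$d %in% c(2, 3)))
    stop("d grid must be a subset of {2, 3}", call. = FALSE)
  # lexicographic row order (C slowest would invert which.max); sort so
  # the first maximum is the tie-break winner: smallest C, then g, m, d
  tab <- expand.grid(d = sort(grids$d), m = sort(grids$m),
                     g = sort(grids$g), C = sort(grids$C))
  tab <- tab[order(tab$C, tab$g, tab$m, tab$d), c("C", "g", "m", "d")]
  rownames(tab) <- NULL
  tab$fitness <- vapply(seq_len(nrow(tab)), function(i) {
    hp <- hyper_params(tab$C[i], tab$m[i], tab$d[i], tab$g[i], g_as = g_as)
    tryCatch(cv_fitness(data, hp, k = k, seed = seed),
             error = function(e)
               stop(sprintf("grid point (C=%g, g=%g, m=%g, d=%d): %s",
                            tab$C[i], tab$g[i], tab$m[i], tab$d[i],
                            conditionMessage(e)), call. = FALSE))
  }, numeric(1))
  i <- which.max(tab$fitness)
  list(best = hyper_params(tab$C[i], tab$m[i], tab$d[i], tab$g[i],
                           g_as = g_as),
       best_fitness = tab$fitness[i],
       table = tab)
}
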