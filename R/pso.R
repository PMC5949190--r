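#' Swarm configuration
#'
#' Collects the particle-swarm settings: swarm size, generation budget,
#' acceleration factors, inertia-weight schedule with its endpoints, the
#' search box and velocity cap, and the seed.
#'
#' Defaults follow the tuning protocol used throughout: n = 20 particles,
#' maxgen = 200 generations, acceleration factors c1 = c2 = 1.49445 (the
#' standard constriction-derived values), inertia decreasing from 0.9 to
#' 0.4 for the dynamic schedules, and the 3-dimensional (C, g, m) box.
#'
#' @param bounds D x 2 numeric matrix of per-dimension \[lower, upper\]
#'   position bounds; default [default_mkl_bounds()].
#' @param n number of particles (>= 2).
#' @param maxgen maximal number of generations (T_max).
#' @param c1,c2 nonnegative acceleration factors toward the personal and
#'   global best.
#' @param omega_start,omega_end inertia-weight endpoints for the dynamic
#'   schedules.
#' @param schedule inertia-weight schedule id, see [inertia_weight()].
#' @param c_exp constant c of the exponential-ratio schedule.
#' @param vmax per-dimension velocity cap; default 0.2 x (upper - lower).
#' @param seed integer seed for initialization and the stochastic
#'   updates.
#' @return An object of class \code{"swarm_config"}.
#' @export
swarm_config <- function(bounds = default_mkl_bounds(), n = 20, maxgen = 200,
                         c1 = 1.49445, c2 = 1.49445,
                         omega_start = 0.9, omega_end = 0.4,
                         schedule = c("constant", "lin_a", "lin_b",
                                      "quad_late", "quad_early", "exp_ratio"),
                         c_exp = 10, vmax = NULL, seed = 1) {
  schedule <- match.arg(schedule)
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2 || any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be a D x 2 matrix with lower < upper", call. = FALSE)
  if (n < 2) stop("need at least 2 particles", call. = FALSE)
  if (maxgen < 1) stop("maxgen must be >= 1", call. = FALSE)
  if (c1 < 0 || c2 < 0)
    stop("acceleration factors must be nonnegative", call. = FALSE)
  if (is.null(vmax)) vmax <- 0.2 * (bounds[, 2] - bounds[, 1])
  vmax <- rep_len(vmax, nrow(bounds))
  if (any(vmax <= 0)) stop("vmax must be positive", call. = FALSE)
  structure(list(bounds = bounds, n = as.integer(n),
                 maxgen = as.integer(maxgen), c1 = c1, c2 = c2,
                 omega_start = omega_start, omega_end = omega_end,
                 schedule = schedule, c_exp = c_exp, vmax = vmax,
                 seed = as.integer(seed)),
            class = "swarm_config")
}

#' Default (C, g, m) search box
#'
#' C in \[0.1, 100\], g in \[0.01, 50\], m in \[0.01, 0.99\]: wide enough
#' to bracket optima such as (C = 29.7, g = 19.1, m = 0.8) with headroom,
#' while keeping m strictly inside (0, 1) so the mixture never collapses
#' to a single kernel during the search.
#'
#' @return A 3 x 2 matrix with rownames C, g, m.
#' @export
default_mkl_bounds <- function() {
  matrix(c(0.1, 100, 0.01, 50, 0.01, 0.99), nrow = 3, byrow = TRUE,
         dimnames = list(c("C", "g", "m"), c("lower", "upper")))
}

#' Inertia-weight schedules
#'
#' Value of the inertia weight at generation k under one of six regimes
#' (ws = omega_start, we = omega_end, T = maxgen):
#' \describe{
#'   \item{constant}{1 for all k.}
#'   \item{lin_a, lin_b}{linear decrease ws -> we; two algebraically
#'     identical writings, kept as separate ids because the two linear
#'     regimes are reported as separate rows in comparison tables.}
#'   \item{quad_late}{ws - (ws - we)(k/T)^2 — decays slowly early, fast
#'     late (strong early global search).}
#'   \item{quad_early}{ws - (ws - we)(2k/T - (k/T)^2) — decays fast
#'     early, slowly late.}
#'   \item{exp_ratio}{we (ws/we)^(1/(1 + c k/T)) — exponential-ratio
#'     decay; equals ws at k = 0 but approaches we only asymptotically,
#'     never reaching it at k = T.}
#' }
#'
#' @param schedule schedule id.
#' @param k generation index (vectorized), 0 <= k <= maxgen.
#' @param cfg a [swarm_config()] supplying the endpoints, maxgen and
#'   c_exp.
#' @return Numeric vector of inertia weights.
#' @export
inertia_weight <- function(schedule, k, cfg) {
  if (any(k < 0 | k > cfg$maxgen))
    stop("k must lie in [0, maxgen]", call. = FALSE)
  ws <- cfg$omega_start
  we <- cfg$omega_end
  r <- k / cfg$maxgen
  switch(schedule,
    constant   = rep(1, length(k)),
    lin_a      = ws - (ws - we) * r,
    lin_b      = we + (ws - we) * (cfg$maxgen - k) / cfg$maxgen,
    quad_late  = ws - (ws - we) * r^2,
    quad_early = ws - (ws - we) * (2 * r - r^2),
    exp_ratio  = we * (ws / we)^(1 / (1 + cfg$c_exp * r)),
    stop(sprintf("unknown schedule '%s'", schedule), call. = FALSE))
}

#' Velocity update of the swarm
#'
#' \eqn{V \leftarrow \omega V + c_1 r_1 (P_i - X) + c_2 r_2 (P_g - X)}
#' with fresh uniform r1, r2 drawn per particle and per dimension from
#' the current RNG stream, followed by clamping to \[-vmax, vmax\].
#'
#' @param state swarm state list with elements \code{X}, \code{V} (n x D
#'   matrices), \code{P} (personal bests, n x D) and \code{Pg} (global
#'   best, length D).
#' @param omega inertia weight for this generation.
#' @param cfg a [swarm_config()].
#' @return The state with updated \code{V}.
#' @export
update_velocity <- function(state, omega, cfg) {
  n <- nrow(state$X)
  D <- ncol(state$X)
  r1 <- matrix(runif(n * D), n, D)
  r2 <- matrix(runif(n * D), n, D)
  Pg <- matrix(state$Pg, n, D, byrow = TRUE)
  V <- omega * state$V + cfg$c1 * r1 * (state$P - state$X) +
    cfg$c2 * r2 * (Pg - state$X)
  Vcap <- matrix(cfg$vmax, n, D, byrow = TRUE)
  state$V <- pmin(pmax(V, -Vcap), Vcap)
  state
}

#' Position update of the swarm
#'
#' \eqn{X \leftarrow X + V}, clamped to the search box; a velocity
#' component whose position was clamped is zeroed so particles do not
#' press against the boundary.
#'
#' @param state swarm state with updated velocities.
#' @param cfg a [swarm_config()].
#' @return The state with updated \code{X} (and zeroed clamped \code{V}).
#' @export
update_position <- function(state, cfg) {
  n <- nrow(state$X)
  D <- ncol(state$X)
  lo <- matrix(cfg$bounds[, 1], n, D, byrow = TRUE)
  hi <- matrix(cfg$bounds[, 2], n, D, byrow = TRUE)
  X <- state$X + state$V
  hit <- X < lo | X > hi
  X <- pmin(pmax(X, lo), hi)
  state$V[hit] <- 0
  state$X <- X
  state
}

#' Particle swarm maximization over a bounded box
#'
#' Runs the swarm for \code{maxgen} generations from a seeded uniform
#' initialization inside the box. Per generation: compute the inertia
#' weight, update velocities and positions, evaluate the fitness of every
#' particle, and update personal and global bests (ties broken toward the
#' first achiever: earlier generation, then lower particle index). The
#' returned trace records \code{v_best}, the running maximum of all
#' evaluations up to each generation, and \code{v_ave}, the mean fitness
#' of the n current particles — so \code{v_best} is non-decreasing and
#' \code{v_best >= v_ave} elementwise.
#'
#' @param fitness_fn function mapping a length-D position vector to a
#'   scalar fitness (maximized); must be defined everywhere in the box
#'   and must not consume the caller-visible RNG stream.
#' @param cfg a [swarm_config()].
#' @return A list with \code{best_position}, \code{best_fitness} and
#'   \code{trace}, a data.frame with columns \code{generation},
#'   \code{v_best}, \code{v_ave}, \code{omega}.
#' @examples
#' cfg <- swarm_config(bounds = cbind(rep(-5, 3), rep(5, 3)),
#'                     schedule = "quad_late", maxgen = 50, seed = 7)
#' res <- pso_optimize(function(x) -sum((x - 1)^2), cfg)
#' res$best_fitness
#' @export
pso_optimize <- function(fitness_fn, cfg) {
  stopifnot(inherits(cfg, "swarm_config"))
  n <- cfg$n
  D <- nrow(cfg$bounds)
  lo <- cfg$bounds[, 1]
  hi <- cfg$bounds[, 2]
  eval_all <- function(X, gen) {
    vapply(seq_len(nrow(X)), function(i) {
      f <- tryCatch(fitness_fn(X[i, ]), error = function(e)
        stop(sprintf("fitness failure at generation %d, particle %d: %s",
                     gen, i, conditionMessage(e)), call. = FALSE))
      as.numeric(f)
    }, numeric(1))
  }
  with_seed(cfg$seed, {
    X <- matrix(runif(n * D), n, D)
    X <- sweep(sweep(X, 2, hi - lo, "*"), 2, lo, "+")
    Vcap <- matrix(cfg$vmax, n, D, byrow = TRUE)
    V <- (matrix(runif(n * D), n, D) * 2 - 1) * Vcap
    fit <- eval_all(X, 0L)
    P <- X
    Pfit <- fit
    gi <- which.max(Pfit)
    Pg <- P[gi, ]
    Pg_fit <- Pfit[gi]
    v_best <- v_ave <- omega_used <- numeric(cfg$maxgen)
    state <- list(X = X, V = V, P = P, Pg = Pg)
    for (gen in seq_len(cfg$maxgen)) {
      w <- inertia_weight(cfg$schedule, gen - 1, cfg)
      state <- update_velocity(state, w, cfg)
      state <- update_position(state, cfg)
      fit <- eval_all(state$X, gen)
      improved <- fit > Pfit
      state$P[improved, ] <- state$X[improved, ]
      Pfit[improved] <- fit[improved]
      if (max(Pfit) > Pg_fit) {
        gi <- which.max(Pfit)
        Pg <- state$P[gi, ]
        Pg_fit <- Pfit[gi]
        state$Pg <- Pg
      }
      v_best[gen] <- Pg_fit
      v_ave[gen] <- mean(fit)
      omega_used[gen] <- w
    }
    list(best_position = stats::setNames(Pg, rownames(cfg$bounds)),
         best_fitness = Pg_fit,
         trace = data.frame(generation = seq_len(cfg$maxgen),
                            v_best = v_best, v_ave = v_ave,
                            omega = omega_used))
  })
}

#' Write / read a per-generation fitness trace
#'
#' Traces are exchanged as plain CSV with columns generation, v_best,
#' v_ave, omega.
#'
#' @param trace trace data.frame from [pso_optimize()].
#' @param path file path.
#' @return \code{read_trace} returns the trace data.frame.
#' @export
write_trace <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  read.csv(path)
}
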