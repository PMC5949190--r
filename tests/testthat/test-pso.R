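cfg200 <- swarm_config(bounds = cbind(rep(-5, 3), rep(5, 3)),
                       maxgen = 200, seed = 1)
dynamic <- c("lin_a", "lin_b", "quad_late", "quad_early", "exp_ratio")

test_that("inertia-weight schedules hit their analytic values", {
  Tm <- cfg200$maxgen
  for (s in dynamic)
    expect_equal(inertia_weight(s, 0, cfg200), 0.9)
  expect_equal(inertia_weight("constant", 123, cfg200), 1)
  expect_equal(inertia_weight("lin_a", Tm / 2, cfg200), 0.65)
  expect_equal(inertia_weight("lin_b", Tm / 2, cfg200), 0.65)
  expect_equal(inertia_weight("quad_late", Tm / 2, cfg200), 0.9 - 0.5 * 0.25)
  expect_equal(inertia_weight("quad_early", Tm / 2, cfg200), 0.9 - 0.5 * 0.75)
  expect_equal(inertia_weight("exp_ratio", 0, cfg200), 0.9)
  expect_equal(inertia_weight("exp_ratio", Tm, cfg200),
               0.4 * (0.9 / 0.4)^(1 / 11), tolerance = 1e-12)
  expect_equal(round(inertia_weight("exp_ratio", Tm, cfg200), 4), 0.4306)
  expect_error(inertia_weight("lin_a", -1, cfg200), "maxgen")
  expect_error(inertia_weight("bogus", 1, cfg200), "unknown schedule")
})

test_that("the two linear writings agree and quadratics bracket them", {
  k <- 0:cfg200$maxgen
  la <- inertia_weight("lin_a", k, cfg200)
  lb <- inertia_weight("lin_b", k, cfg200)
  expect_equal(la, lb, tolerance = 1e-12)
  mid <- k[k > 0 & k < cfg200$maxgen]
  ql <- inertia_weight("quad_late", mid, cfg200)
  qe <- inertia_weight("quad_early", mid, cfg200)
  expect_true(all(ql > la[mid + 1]))
  expect_true(all(la[mid + 1] > qe))
  # all dynamic schedules decrease monotonically; exp_ratio stays above
  # omega_end and never reaches it
  for (s in dynamic) {
    w <- inertia_weight(s, k, cfg200)
    expect_true(all(diff(w) <= 1e-12))
  }
  er <- inertia_weight("exp_ratio", k, cfg200)
  expect_true(all(er > 0.4))
})

test_that("velocity updates attract, clamp, and freeze where indicated", {
  cfg <- swarm_config(bounds = cbind(c(0, 0), c(10, 10)), n = 3,
                      maxgen = 10, seed = 1)
  X <- matrix(2, 3, 2)
  V <- matrix(c(0.5, -0.3), 3, 2, byrow = TRUE)
  state <- list(X = X, V = V, P = X, Pg = X[1, ])
  # personal and global best at the current position: no attraction
  s2 <- update_velocity(state, omega = 1, cfg)
  expect_equal(s2$V, V)
  # omega = 0 and zero acceleration: velocity dies
  cfg0 <- swarm_config(bounds = cbind(c(0, 0), c(10, 10)), n = 3,
                       maxgen = 10, c1 = 0, c2 = 0, seed = 1)
  s3 <- update_velocity(state, omega = 0, cfg0)
  expect_equal(s3$V, matrix(0, 3, 2))
  # clamping contract under violent attraction
  far <- list(X = matrix(0, 3, 2), V = matrix(0, 3, 2),
              P = matrix(100, 3, 2), Pg = c(100, 100))
  s4 <- update_velocity(far, omega = 1, cfg)
  expect_true(all(abs(s4$V) <= matrix(cfg$vmax, 3, 2, byrow = TRUE) + 1e-12))
})

test_that("position updates clamp to the box and zero the clamped velocity", {
  cfg <- swarm_config(bounds = cbind(c(0, 0), c(1, 1)), n = 2,
                      maxgen = 10, seed = 1)
  state <- list(X = rbind(c(0.5, 1.0), c(0.2, 0.2)),
                V = rbind(c(0.1, 0.1), c(0, 0)),
                P = matrix(0.5, 2, 2), Pg = c(0.5, 0.5))
  s2 <- update_position(state, cfg)
  expect_equal(s2$X[1, ], c(0.6, 1.0))    # second coordinate clamped
  expect_equal(s2$V[1, ], c(0.1, 0))      # its velocity zeroed
  expect_equal(s2$X[2, ], c(0.2, 0.2))    # zero velocity: unchanged
})

test_that("the optimizer trace honors the running-max contract", {
  cfg <- swarm_config(bounds = cbind(rep(-2, 2), rep(2, 2)), n = 8,
                      maxgen = 30, schedule = "lin_a", seed = 9)
  res <- pso_optimize(function(x) -sum(x^2), cfg)
  expect_equal(nrow(res$trace), 30)
  expect_true(all(diff(res$trace$v_best) >= 0))
  expect_true(all(res$trace$v_best >= res$trace$v_ave - 1e-12))
  # constant fitness: both curves flat at that constant
  resc <- pso_optimize(function(x) 42, cfg)
  expect_true(all(resc$trace$v_best == 42))
  expect_true(all(resc$trace$v_ave == 42))
})

test_that("identical configuration and seed reproduce the identical trace", {
  cfg <- swarm_config(bounds = cbind(rep(-3, 3), rep(3, 3)), n = 10,
                      maxgen = 25, schedule = "quad_late", seed = 77)
  f <- function(x) -sum((x - 0.5)^2)
  r1 <- pso_optimize(f, cfg)
  r2 <- pso_optimize(f, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
})

test_that("the swarm never evaluates fitness outside the box", {
  lo <- c(-1, 0, 2); hi <- c(1, 5, 3)
  cfg <- swarm_config(bounds = cbind(lo, hi), n = 6, maxgen = 20,
                      schedule = "quad_early", seed = 3)
  seen_bad <- FALSE
  f <- function(x) {
    if (any(x < lo - 1e-12) || any(x > hi + 1e-12)) seen_bad <<- TRUE
    -sum(x^2)
  }
  pso_optimize(f, cfg)
  expect_false(seen_bad)
})

test_that("dynamic schedules localize a quadratic optimum", {
  target <- c(1.3, -2.1, 0.7)
  for (s in c("lin_a", "quad_late")) {
    cfg <- swarm_config(bounds = cbind(rep(-5, 3), rep(5, 3)), n = 20,
                        maxgen = 100, schedule = s, seed = 5)
    res <- pso_optimize(function(x) -sum((x - target)^2), cfg)
    expect_lt(sqrt(sum((res$best_position - target)^2)), 1e-2)
  }
})

test_that("traces round-trip through their CSV interchange format", {
  cfg <- swarm_config(bounds = cbind(rep(-1, 2), rep(1, 2)), n = 5,
                      maxgen = 10, seed = 2)
  res <- pso_optimize(function(x) -sum(x^2), cfg)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trace(res$trace, path)
  expect_equal(read_trace(path), res$trace, tolerance = 1e-12)
})
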