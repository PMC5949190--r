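#' Tune the mixed-kernel SVM by particle swarm optimization
#'
#' Runs one PSO search per polynomial order d (d is not a particle
#' dimension: only d = 2 and d = 3 are meaningful orders, so the swarm
#' searches the continuous (C, g, m) box and d is enumerated outside,
#' ties broken toward d = 2). The fitness of a position is the k-fold
#' cross-validated accuracy on \code{data}; the fold assignment is fixed
#' by \code{fold_seed} so every evaluation is comparable.
#'
#' @param data training [feature_dataset()].
#' @param cfg a [swarm_config()] over the 3-D (C, g, m) box.
#' @param k number of CV folds.
#' @param fold_seed seed for the fold assignment (default: cfg$seed).
#' @param d_values polynomial orders to enumerate, subset of \{2, 3\}.
#' @param g_as RBF convention, see [kernel_params()].
#' @return A list with \code{best} ([hyper_params()] including the best
#'   d), \code{best_fitness}, \code{d_best}, and \code{traces}, a named
#'   list of per-d fitness traces.
#' @export
tune_mkl_svm_pso <- function(data, cfg = swarm_config(), k = 5,
                             fold_seed = NULL, d_values = c(2, 3),
                             g_as = "width") {
  stopifnot(inherits(data, "feature_dataset"))
  if (!all(d_values %in% c(2, 3)))
    stop("d_values must be a subset of {2, 3}", call. = FALSE)
  if (is.null(fold_seed)) fold_seed <- cfg$seed
  best <- NULL
  best_fitness <- -Inf
  d_best <- NA_integer_
  traces <- list()
  for (d in sort(d_values)) {
    fitness_fn <- function(pos) {
      hp <- hyper_params(C = pos[1], m = pos[3], d = d, g = pos[2],
                         g_as = g_as)
      cv_fitness(data, hp, k = k, seed = fold_seed)
    }
    cfg_d <- cfg
    cfg_d$seed <- cfg$seed + (d - min(d_values)) # distinct stream per d
    res <- pso_optimize(fitness_fn, cfg_d)
    traces[[paste0("d", d)]] <- res$trace
    if (res$best_fitness > best_fitness) { # strict: ties stay at lower d
      best_fitness <- res$best_fitness
      best <- hyper_params(C = res$best_position[1],
                           m = res$best_position[3], d = d,
                           g = res$best_position[2], g_as = g_as)
      d_best <- d
    }
  }
  list(best = best, best_fitness = best_fitness, d_best = d_best,
       traces = traces)
}

#' Fit the final model at chosen hyperparameters
#'
#' Z-scores the full training set, trains the mixed-kernel SVM, and
#' returns a classifier that applies the training scaler to new data.
#'
#' @param train training [feature_dataset()].
#' @param hp a [hyper_params()] point.
#' @return An object of class \code{"mkl_svm_final"}.
#' @export
fit_final_model <- function(train, hp) {
  stopifnot(inherits(train, "feature_dataset"),
            inherits(hp, "hyper_params"))
  sc <- fold_scaler(train$X)
  fit <- mkl_svm(sc$transform(train$X), train$y, hp$C, hp$kernel_params)
  structure(list(fit = fit, scaler = sc, hp = hp),
            class = "mkl_svm_final")
}

#' @rdname fit_final_model
#' @param object an \code{"mkl_svm_final"}.
#' @param newdata feature matrix or [feature_dataset()].
#' @param ... unused.
#' @export
predict.mkl_svm_final <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_dataset")) newdata$X else
    as.matrix(newdata)
  predict(object$fit, object$scaler$transform(X))
}

#' Evaluate a final model on a test set
#'
#' @param model an \code{"mkl_svm_final"}.
#' @param test test [feature_dataset()].
#' @return A list with \code{counts} (confusion counts), \code{acc} and
#'   \code{sen} (percent).
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(test, "feature_dataset"))
  pred <- predict(model, test)
  counts <- confusion_counts(test$y, pred)
  list(counts = counts, acc = acc(counts), sen = sen(counts))
}

#' Experiment configuration
#'
#' Validated settings for a full comparison run. Defaults encode the
#' reference protocol: a 270-sample table split 170 train / 100 test,
#' n = 20 particles, maxgen = 200 generations, 5-fold CV fitness, d
#' enumerated over \{2, 3\}, all six inertia-weight schedules, 20
#' repeats.
#'
#' @param schedules character vector of schedule ids to compare.
#' @param repeats number of repeated runs per schedule.
#' @param n,maxgen swarm size and generation budget.
#' @param k CV fold count.
#' @param bounds (C, g, m) search box.
#' @param d_values polynomial orders, subset of \{2, 3\} (asserted).
#' @param n_train,n_test split sizes (asserted to match the data at run
#'   time).
#' @param include_grid also run the grid-search baseline row.
#' @param grids grid for the baseline, default [default_grids()].
#' @param seed master seed; per-repeat and per-schedule substreams are
#'   derived deterministically.
#' @return A list of class \code{"experiment_config"}.
#' @export
experiment_config <- function(schedules = c("constant", "lin_a", "lin_b",
                                            "quad_late", "quad_early",
                                            "exp_ratio"),
                              repeats = 20, n = 20, maxgen = 200, k = 5,
                              bounds = default_mkl_bounds(),
                              d_values = c(2, 3),
                              n_train = 170, n_test = 100,
                              include_grid = TRUE, grids = default_grids(),
                              seed = 1) {
  known <- c("constant", "lin_a", "lin_b", "quad_late", "quad_early",
             "exp_ratio")
  problems <- character()
  if (!all(schedules %in% known))
    problems <- c(problems, sprintf("unknown schedules: %s",
      paste(setdiff(schedules, known), collapse = ", ")))
  if (!all(d_values %in% c(2, 3)))
    problems <- c(problems, "d_values must be a subset of {2, 3}")
  if (repeats < 1) problems <- c(problems, "repeats must be >= 1")
  if (n_train < 1 || n_test < 1)
    problems <- c(problems, "split sizes must be positive")
  if (k < 2) problems <- c(problems, "k must be >= 2")
  if (length(problems))
    stop(paste(problems, collapse = "; "), call. = FALSE)
  structure(list(schedules = schedules, repeats = as.integer(repeats),
                 n = as.integer(n), maxgen = as.integer(maxgen),
                 k = as.integer(k), bounds = as.matrix(bounds),
                 d_values = d_values, n_train = as.integer(n_train),
                 n_test = as.integer(n_test),
                 include_grid = include_grid, grids = grids,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' End-to-end comparison of inertia-weight regimes
#'
#' For each schedule and repeat: tune (C, g, m, d) by PSO on the training
#' split, refit at the best parameters on the full training set, and
#' evaluate accuracy and sensitivity on the held-out test split. Results
#' are aggregated per schedule with means and (for >= 4 repeats) Tukey
#' boxplot statistics of the best fitness; an optional grid-search row
#' gives the baseline. The split is made once from the master seed and
#' shared by all schedules and repeats, so rows differ only in the
#' optimizer.
#'
#' @param data full [feature_dataset()] with
#'   \code{config$n_train + config$n_test} samples.
#' @param config an [experiment_config()].
#' @return A list of class \code{"experiment_result"} with the
#'   \code{split}, per-schedule \code{runs} (best params, fitness, test
#'   metrics, traces, seeds), the optional \code{grid} result, and
#'   \code{report}, a summary data.frame with one row per regime.
#' @export
run_experiment <- function(data, config = experiment_config()) {
  stopifnot(inherits(data, "feature_dataset"),
            inherits(config, "experiment_config"))
  if (nrow(data$X) != config$n_train + config$n_test)
    stop(sprintf("data has %d samples; config expects %d train + %d test",
                 nrow(data$X), config$n_train, config$n_test),
         call. = FALSE)
  split <- split_train_test(data, n_train = config$n_train,
                            seed = config$seed)
  stopifnot(nrow(split$train$X) == config$n_train,
            nrow(split$test$X) == config$n_test)
  fold_seed <- config$seed
  runs <- list()
  rows <- list()
  for (si in seq_along(config$schedules)) {
    sched <- config$schedules[si]
    sched_runs <- vector("list", config$repeats)
    for (r in seq_len(config$repeats)) {
      run_seed <- config$seed + 7919L * r + 131L * si
      cfg <- swarm_config(bounds = config$bounds, n = config$n,
                          maxgen = config$maxgen, schedule = sched,
                          seed = run_seed)
      tuned <- tune_mkl_svm_pso(split$train, cfg, k = config$k,
                                fold_seed = fold_seed,
                                d_values = config$d_values)
      final <- fit_final_model(split$train, tuned$best)
      ev <- evaluate_model(final, split$test)
      sched_runs[[r]] <- list(seed = run_seed, best = tuned$best,
                              best_fitness = tuned$best_fitness,
                              d_best = tuned$d_best,
                              traces = tuned$traces,
                              test_acc = ev$acc, test_sen = ev$sen,
                              counts = ev$counts)
    }
    runs[[sched]] <- sched_runs
    fits <- vapply(sched_runs, `[[`, numeric(1), "best_fitness")
    rows[[sched]] <- data.frame(
      regime = sched,
      mean_best_fitness = mean(fits),
      mean_test_acc = mean(vapply(sched_runs, `[[`, numeric(1), "test_acc")),
      mean_test_sen = mean(vapply(sched_runs, `[[`, numeric(1), "test_sen")),
      fitness_median = if (config$repeats >= 4) boxplot_stats(fits)$median
                       else median(fits))
  }
  grid_res <- NULL
  if (config$include_grid) {
    grid_res <- grid_search(split$train, grids = config$grids,
                            k = config$k, seed = fold_seed)
    final <- fit_final_model(split$train, grid_res$best)
    ev <- evaluate_model(final, split$test)
    rows[["grid"]] <- data.frame(regime = "grid_search",
                                 mean_best_fitness = grid_res$best_fitness,
                                 mean_test_acc = ev$acc,
                                 mean_test_sen = ev$sen,
                                 fitness_median = grid_res$best_fitness)
    grid_res$test_acc <- ev$acc
    grid_res$test_sen <- ev$sen
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(split = split, runs = runs, grid = grid_res,
                 report = report, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("MKL-SVM tuning comparison\n")
  print(x$report, digits = 5)
  invisible(x)
}

#' Write an experiment report as CSV
#'
#' @param result an \code{"experiment_result"}.
#' @param path CSV file path.
#' @export
write_report <- function(result, path) {
  write.csv(result$report, path, row.names = FALSE)
  invisible(path)
}
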