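#' Labeled feature table
#'
#' Container for a ROI feature matrix with -1/+1 labels (+1 = nodule,
#' -1 = non-nodule).
#'
#' @param X numeric feature matrix, one row per ROI.
#' @param y -1/+1 label vector, one per row of X.
#' @param ids optional row identifiers.
#' @return An object of class \code{"feature_dataset"}.
#' @export
feature_dataset <- function(X, y, ids = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    stop("X and y must have matching lengths", call. = FALSE)
  if (!all(is.finite(X)))
    stop("feature values must be finite", call. = FALSE)
  check_labels(y)
  if (is.null(ids)) ids <- seq_len(nrow(X))
  structure(list(X = X, y = as.numeric(y), ids = ids),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("feature dataset: %d samples x %d features (%d pos / %d neg)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == -1)))
  invisible(x)
}

#' Two-Gaussian synthetic feature table
#'
#' Emulates an imbalanced two-class ROI feature table with controllable
#' linear separability: both classes are spherical unit-variance
#' Gaussians whose means sit at +/- separation/2 along the first feature
#' axis. The default class sizes (80 positive nodules vs 190 negative
#' false-positives) reproduce the imbalance of the clinical protocol this
#' package targets.
#'
#' @param n_pos,n_neg class sizes (defaults 80 and 190).
#' @param dims feature dimension (default 10).
#' @param separation mean shift between the classes in pooled-sd units;
#'   0 makes the classes indistinguishable. Default 3 (Bayes error about
#'   7 percent, comparable to a realistic nodule task).
#' @param seed integer seed; output is deterministic given all arguments.
#' @return A [feature_dataset()].
#' @export
generate_gaussian_classes <- function(n_pos = 80, n_neg = 190, dims = 10,
                                      separation = 3, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1, dims >= 1)
  with_seed(seed, {
    Xp <- matrix(rnorm(n_pos * dims), n_pos, dims)
    Xn <- matrix(rnorm(n_neg * dims), n_neg, dims)
    Xp[, 1] <- Xp[, 1] + separation / 2
    Xn[, 1] <- Xn[, 1] - separation / 2
    feature_dataset(rbind(Xp, Xn), c(rep(1, n_pos), rep(-1, n_neg)))
  })
}

#' Disc-versus-annulus synthetic feature table
#'
#' A linearly inseparable 2-D fixture exercising the nonlinear part of
#' the mixed kernel: positives fill a unit disc, negatives sit on an
#' annulus of radius 2, both with radial Gaussian noise. With
#' \code{noise_sd = 0} the classes are radially disjoint.
#'
#' @param n_pos,n_neg class sizes (defaults 80 and 190).
#' @param noise_sd radial noise standard deviation (default 0.2, giving
#'   a narrow but not empty margin between the classes).
#' @param seed integer seed.
#' @return A [feature_dataset()] with 2 feature columns.
#' @export
generate_ring_classes <- function(n_pos = 80, n_neg = 190, noise_sd = 0.2,
                                  seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1, noise_sd >= 0)
  with_seed(seed, {
    # positives: uniform over the unit disc, plus radial noise
    r_pos <- sqrt(runif(n_pos)) + rnorm(n_pos, sd = noise_sd)
    a_pos <- runif(n_pos, 0, 2 * pi)
    # negatives: annulus at radius 2, radial noise only
    r_neg <- 2 + rnorm(n_neg, sd = noise_sd)
    a_neg <- runif(n_neg, 0, 2 * pi)
    X <- rbind(cbind(r_pos * cos(a_pos), r_pos * sin(a_pos)),
               cbind(r_neg * cos(a_neg), r_neg * sin(a_neg)))
    feature_dataset(X, c(rep(1, n_pos), rep(-1, n_neg)))
  })
}

#' Random train/test split
#'
#' Splits a feature dataset into disjoint, exhaustive train and test
#' subsets; with \code{stratify = TRUE} class proportions are preserved
#' within one sample.
#'
#' @param data a [feature_dataset()].
#' @param n_train number of training samples (default 170, paired with a
#'   270-sample table to give the 170/100 protocol split).
#' @param seed integer seed.
#' @param stratify preserve class proportions (default TRUE).
#' @return A list with elements \code{train} and \code{test}, both
#'   [feature_dataset()]s.
#' @export
split_train_test <- function(data, n_train = 170, seed = 1, stratify = TRUE) {
  stopifnot(inherits(data, "feature_dataset"))
  n <- nrow(data$X)
  if (n_train < 1 || n_train >= n)
    stop("n_train must be in [1, n - 1]", call. = FALSE)
  idx <- with_seed(seed, {
    if (stratify) {
      pos <- which(data$y == 1)
      neg <- which(data$y == -1)
      # per-class counts proportional to n_train, largest-remainder fixup
      k_pos <- round(n_train * length(pos) / n)
      k_pos <- min(max(k_pos, n_train - length(neg)), length(pos), n_train)
      c(sample(pos, k_pos), sample(neg, n_train - k_pos))
    } else {
      sample(n, n_train)
    }
  })
  take <- function(i) feature_dataset(data$X[i, , drop = FALSE], data$y[i],
                                      data$ids[i])
  list(train = take(sort(idx)), test = take(setdiff(seq_len(n), idx)))
}

#' Read / write feature tables as CSV
#'
#' Plain-text interchange format: a header row, numeric feature columns,
#' and a final \code{label} column holding -1/+1.
#'
#' @param data a [feature_dataset()].
#' @param path CSV file path.
#' @return \code{read_feature_table} returns a [feature_dataset()].
#' @export
write_feature_table <- function(data, path) {
  stopifnot(inherits(data, "feature_dataset"))
  df <- as.data.frame(data$X)
  names(df) <- sprintf("f%02d", seq_len(ncol(data$X)))
  df$label <- as.integer(data$y)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path)
  if (!"label" %in% names(df))
    stop("feature table must carry a 'label' column", call. = FALSE)
  y <- df$label
  X <- as.matrix(df[setdiff(names(df), "label")])
  feature_dataset(X, y)
}
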