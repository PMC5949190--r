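test_that("confusion counts follow the +1 = nodule convention", {
  c1 <- confusion_counts(c(1, 1, -1, -1), c(1, -1, -1, 1))
  expect_equal(c1, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  c2 <- confusion_counts(rep(c(1, -1), c(6, 4)), rep(c(1, -1), c(6, 4)))
  expect_equal(c2, list(TP = 6L, FP = 0L, TN = 4L, FN = 0L))
  # flipping every prediction swaps TP<->FN and TN<->FP
  y <- rep(c(1, -1), c(7, 3))
  set.seed(2)
  pred <- sample(c(-1, 1), 10, replace = TRUE)
  a <- confusion_counts(y, pred)
  b <- confusion_counts(y, -pred)
  expect_equal(b$TP, a$FN); expect_equal(b$FN, a$TP)
  expect_equal(b$TN, a$FP); expect_equal(b$FP, a$TN)
  expect_error(confusion_counts(c(1, -1), c(1, -1, 1)), "length")
})

test_that("ACC and SEN are percentages with the documented edge behavior", {
  expect_equal(acc(list(TP = 16, TN = 0, FP = 1, FN = 0)), 100 * 16 / 17,
               tolerance = 1e-10)
  expect_equal(round(acc(list(TP = 16, TN = 0, FP = 1, FN = 0)), 4), 94.1176)
  expect_equal(acc(list(TP = 5, TN = 5, FP = 0, FN = 0)), 100)
  expect_equal(acc(list(TP = 0, TN = 0, FP = 3, FN = 2)), 0)
  expect_error(acc(list(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
  expect_equal(round(sen(list(TP = 8, FN = 1, FP = 0, TN = 0)), 2), 88.89)
  expect_equal(sen(list(TP = 3, FN = 0, FP = 5, TN = 1)), 100)
  expect_equal(sen(list(TP = 0, FN = 5, FP = 0, TN = 0)), 0)
  expect_error(sen(list(TP = 0, FN = 0, FP = 2, TN = 1)), "no positive")
  # ACC invariant under class relabeling, SEN not
  ct <- list(TP = 4, FP = 2, TN = 7, FN = 1)
  sw <- list(TP = ct$TN, FP = ct$FN, TN = ct$TP, FN = ct$FP)
  expect_equal(acc(ct), acc(sw))
  expect_false(isTRUE(all.equal(sen(ct), sen(sw))))
})

test_that("stratified folds balance both classes and are seed-deterministic", {
  y <- rep(c(1, -1), each = 5)
  f <- stratified_folds(y, k = 5, seed = 3)
  for (i in 1:5) {
    expect_equal(sum(f == i & y == 1), 1)
    expect_equal(sum(f == i & y == -1), 1)
  }
  expect_identical(f, stratified_folds(y, k = 5, seed = 3))
  expect_false(identical(f, stratified_folds(y, k = 5, seed = 4)))
  # protocol-sized table: 170 samples in 5 folds of exactly 34
  y170 <- rep(c(1, -1), c(50, 120))
  f170 <- stratified_folds(y170, k = 5, seed = 1)
  expect_equal(as.vector(table(f170)), rep(34L, 5))
  # per-class sizes differ by at most one
  expect_lte(diff(range(table(f170[y170 == 1]))), 1)
  expect_lte(diff(range(table(f170[y170 == -1]))), 1)
  expect_error(stratified_folds(rep(c(1, -1), c(3, 20)), k = 5, seed = 1),
               "fewer than k")
})

test_that("cv fitness is deterministic and reaches 100 on separated classes", {
  d <- generate_gaussian_classes(n_pos = 20, n_neg = 40, dims = 4,
                                 separation = 10, seed = 8)
  hp <- hyper_params(C = 10, m = 0.5, d = 2, g = 1)
  f1 <- cv_fitness(d, hp, k = 5, seed = 8)
  expect_equal(f1, 100)
  expect_identical(f1, cv_fitness(d, hp, k = 5, seed = 8))
})

test_that("pooled-count fitness equals the sample-weighted mean of fold accuracies", {
  d <- generate_gaussian_classes(n_pos = 15, n_neg = 30, dims = 3,
                                 separation = 2, seed = 4)
  hp <- hyper_params(C = 5, m = 0.3, d = 2, g = 1)
  k <- 5; seed <- 4
  pooled <- cv_fitness(d, hp, k = k, seed = seed)
  # independent per-fold recomputation with the same fold assignment
  folds <- stratified_folds(d$y, k, seed)
  correct <- 0
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- d$X[tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    s <- apply(Xtr, 2, sd); s[s < 1e-12] <- 1
    Ztr <- sweep(sweep(Xtr, 2, mu), 2, s, "/")
    Zva <- sweep(sweep(d$X[!tr, , drop = FALSE], 2, mu), 2, s, "/")
    model <- train_svm(gram_matrix(Ztr, params = hp$kernel_params),
                       d$y[tr], hp$C)
    pred <- predict(model, gram_matrix(Ztr, Zva, hp$kernel_params))
    correct <- correct + sum(pred == d$y[!tr])
  }
  expect_equal(pooled, 100 * correct / length(d$y))
})

test_that("label permutation pulls fitness to the majority-class rate", {
  d <- generate_gaussian_classes(n_pos = 80, n_neg = 190, dims = 5,
                                 separation = 0, seed = 6)
  hp <- hyper_params(C = 1, m = 0.5, d = 2, g = 2)
  f <- cv_fitness(d, hp, k = 5, seed = 6)
  majority <- 100 * 190 / 270
  expect_lt(abs(f - majority), 10) # binomial noise around chance level
})
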