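# Independent oracles and fixture builders shared across the test files.

# Interior-point QP solution of the SVM dual (kernlab::ipop), independent
# of the package's SMO path.
svm_dual_oracle <- function(K, y, C) {
  l <- length(y)
  H <- (y %o% y) * K
  r <- kernlab::ipop(c = rep(-1, l), H = H, A = matrix(y, 1), b = 0,
                     r = 0, l = rep(0, l), u = rep(C, l),
                     sigf = 9, maxiter = 200)
  alpha <- kernlab::primal(r)
  list(alpha = alpha, objective = svm_dual_objective(alpha, y, K))
}

# small random dual problem with both classes guaranteed
random_svm_problem <- function(l, dims = 3) {
  X <- matrix(rnorm(l * dims), l)
  y <- c(1, -1, sample(c(-1, 1), l - 2, replace = TRUE))
  p <- kernel_params(m = runif(1, 0.1, 0.9), d = sample(2:3, 1),
                     g = runif(1, 0.5, 3))
  list(X = X, y = y, params = p, C = runif(1, 0.5, 20),
       K = gram_matrix(X, params = p))
}

# the classic 4-point XOR fixture: linearly inseparable
xor_fixture <- function() {
  list(X = rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)),
       y = c(-1, -1, 1, 1))
}

# an svm_model built by hand (no training), for decision-rule contracts
manual_model <- function(alpha, y, b, C = 1) {
  structure(list(alpha = alpha, b = b, support = which(alpha > 0),
                 C = C, y = y, objective = NA_real_,
                 iterations = 0L, kkt_gap = 0),
            class = "svm_model")
}
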