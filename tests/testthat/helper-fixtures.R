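# shared fixtures: small datasets and independent oracle computations

# tiny dataset with one continuous covariate and a known GLM structure
make_glm_dataset <- function(n = 400, seed = 3, b0 = 0.5, b1 = 0.3) {
  set.seed(seed)
  x <- rnorm(n)
  count_dataset(rpois(n, exp(b0 + b1 * x)), matrix(x, ncol = 1,
                                                   dimnames = list(NULL, "x")))
}

# two-point Poisson mixture without covariates (plain mixture conditions)
make_two_point_dataset <- function(n = 2000, lam = c(8, 2), pi1 = 0.5,
                                   seed = 42) {
  set.seed(seed)
  z <- rbinom(n, 1, 1 - pi1) + 1L       # 1 with prob pi1
  y <- rpois(n, lam[z])
  list(data = count_dataset(y, matrix(1, n, 1)), labels = z)
}

# naive mixture log-likelihood: direct summation without log-sum-exp
naive_mixture_loglik <- function(y, lam_mat, pi_mat) {
  sum(log(rowSums(pi_mat * dpois(y, lam_mat))))
}

# weighted Poisson log-likelihood (for generic-optimizer oracles)
weighted_poisson_negll <- function(b, X, y, w) {
  eta <- drop(X %*% b)
  -sum(w * (y * eta - exp(eta) - lgamma(y + 1)))
}

# weighted multinomial-logit log-likelihood with reference category `ref`
weighted_multinom_negll <- function(theta, W, tau, ref = 1L) {
  C <- ncol(tau)
  d <- ncol(W)
  G <- matrix(0, d, C)
  G[, setdiff(seq_len(C), ref)] <- theta
  E <- W %*% G
  P <- exp(E - apply(E, 1, max))
  P <- P / rowSums(P)
  -sum(tau * log(P))
}

# random valid gate and design for property tests
random_gate_case <- function(K, q, n, seed) {
  set.seed(seed)
  W <- cbind(1, matrix(rnorm(n * q), n, q))
  gamma0 <- c(0, rnorm(K - 1))
  gamma <- rbind(0, matrix(rnorm((K - 1) * q), K - 1, q))
  list(W = W, wm = gate_weights(gamma0, gamma))
}

expect_monotone_trace <- function(model, slack = 1e-10) {
  expect_true(all(diff(model$fit$trace) >= -slack))
}

# write a small Cleveland-format fixture with one missing cell in `ca`
write_cleveland_fixture <- function(path) {
  rows <- c(
    "63,1,1,145,233,1,2,150,0,2.3,3,0,6,0",
    "67,1,4,160,286,0,2,108,1,1.5,2,3,3,2",
    "67,1,4,120,229,0,2,129,1,2.6,2,2,7,1",
    "37,1,3,130,250,0,0,187,0,3.5,3,?,3,0",
    "41,0,2,130,204,0,2,172,0,1.4,1,0,3,1"
  )
  writeLines(rows, path)
  path
}
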