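test_that("poisson log-pmf matches closed forms and normalizes", {
  expect_equal(poisson_log_pmf(0, 1), -1)
  expect_equal(poisson_log_pmf(2, 2), log(2) - 2)
  expect_equal(poisson_log_pmf(0:3, c(1, 1, 1, 1)), dpois(0:3, 1, log = TRUE))
  # brute-force normalization over the support
  expect_equal(sum(exp(poisson_log_pmf(0:200, rep(3.7, 201)))), 1,
               tolerance = 1e-12)
  # indicator on the nonnegative integers
  expect_identical(poisson_log_pmf(c(-1, 1.5), c(2, 2)), c(-Inf, -Inf))
  expect_error(poisson_log_pmf(1, 0), "positive")
  expect_error(poisson_log_pmf(NA_real_, 1), "finite")
})

test_that("component rates exponentiate the linear predictor", {
  X <- cbind(1, matrix(rnorm(20), 10, 2))
  zero <- component_params(c(0, 0), matrix(0, 2, 2))
  expect_equal(component_rates(X, zero), matrix(1, 10, 2),
               ignore_attr = TRUE)
  io <- component_params(c(log(2), log(5)), matrix(0, 2, 0))
  lam <- component_rates(X[, 1, drop = FALSE], io)
  expect_equal(unname(lam[, 1]), rep(2, 10))
  expect_equal(unname(lam[, 2]), rep(5, 10))
  # independent matrix-product oracle
  set.seed(9)
  cp <- component_params(rnorm(3), matrix(rnorm(6), 3, 2))
  lam <- component_rates(X, cp)
  for (k in 1:3) {
    eta_k <- cp$beta0[k] + X[, -1] %*% cp$beta[k, ]
    expect_equal(unname(lam[, k]), drop(exp(eta_k)))
  }
  expect_error(component_rates(X[, 1:2], cp), "columns")
})

test_that("gate probabilities: closed forms, shift invariance, normalization", {
  W <- cbind(1, rnorm(15))
  uni <- gate_weights(c(0, 0, 0), matrix(0, 3, 1))
  expect_equal(concomitant_weights(W, uni), matrix(1 / 3, 15, 3))
  two <- gate_weights(c(0, 0.5), matrix(0, 2, 1))
  P <- concomitant_weights(W, two)
  expect_equal(P[, 2], rep(plogis(0.5), 15))
  expect_equal(P[1, ], c(1 - plogis(0.5), plogis(0.5)), tolerance = 1e-12)
  # fixed mode broadcasts
  Pf <- concomitant_weights(W, fixed_weights(c(0.3, 0.7)))
  expect_equal(Pf, matrix(c(0.3, 0.7), 15, 2, byrow = TRUE))
  # softmax shift invariance: adding c to all intercepts changes nothing,
  # verified against an unidentified gate built directly from softmax
  set.seed(2)
  E <- cbind(0, 1.3 + W %*% c(0.4, -0.7))
  P1 <- exp(E) / rowSums(exp(E))
  P2 <- concomitant_weights(W, gate_weights(c(0, 1.3),
                                            matrix(c(0, -0.7), 2, 1)))
  # the identified gate absorbs the shared w-coefficient 0.4 differently;
  # instead check invariance by shifting both categories of an identified
  # gate through the raw softmax
  Eb <- E + 5
  expect_equal(P1, exp(Eb - apply(Eb, 1, max)) /
                 rowSums(exp(Eb - apply(Eb, 1, max))))
  expect_equal(P2[, 2], drop(plogis(1.3 - 0.7 * W[, 2])))
  # normalization property over 100 random gates
  for (s in 1:100) {
    case <- random_gate_case(K = sample(2:4, 1), q = sample(1:3, 1),
                             n = 20, seed = s)
    P <- concomitant_weights(case$W, case$wm)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("mixture log-likelihood: special cases and naive-arithmetic oracle", {
  d <- make_glm_dataset(n = 50, seed = 5)
  cp1 <- component_params(0.4, matrix(0.2, 1, 1))
  m1 <- poismix_model(cp1, fixed_weights(1))
  lam <- exp(0.4 + 0.2 * d$X[, 2])
  expect_equal(mixture_log_likelihood(d, m1),
               sum(dpois(d$y, lam, log = TRUE)))
  # identical components collapse to the single-component value
  cp2 <- component_params(c(0.4, 0.4), matrix(0.2, 2, 1))
  m2 <- poismix_model(cp2, fixed_weights(c(0.3, 0.7)))
  expect_equal(mixture_log_likelihood(d, m2), mixture_log_likelihood(d, m1))
  # n = 10, K = 2 against direct summation without log-sum-exp
  d10 <- count_dataset(d$y[1:10], d$X[1:10, , drop = FALSE])
  cp <- component_params(c(0.8, -0.2), matrix(c(0.3, -0.1), 2, 1))
  mm <- poismix_model(cp, fixed_weights(c(0.35, 0.65)))
  lam_mat <- cbind(exp(0.8 + 0.3 * d10$X[, 2]), exp(-0.2 - 0.1 * d10$X[, 2]))
  pi_mat <- matrix(c(0.35, 0.65), 10, 2, byrow = TRUE)
  expect_equal(mixture_log_likelihood(d10, mm),
               naive_mixture_loglik(d10$y, lam_mat, pi_mat))
  # label-swap symmetry
  cp_sw <- component_params(c(-0.2, 0.8), matrix(c(-0.1, 0.3), 2, 1))
  mm_sw <- poismix_model(cp_sw, fixed_weights(c(0.65, 0.35)))
  expect_equal(mixture_log_likelihood(d10, mm_sw),
               mixture_log_likelihood(d10, mm))
  expect_error(mixture_log_likelihood(list(), m1))
})

test_that("mixture moments satisfy the mean/variance decomposition", {
  n <- 8
  X <- matrix(1, n, 1)
  mm <- poismix_model(component_params(c(log(1), log(3))),
                      fixed_weights(c(0.5, 0.5)))
  mo <- mixture_moments(mm, X)
  expect_equal(mo$mean, rep(2, n))
  expect_equal(mo$v, rep(1, n))
  expect_equal(mo$var, rep(3, n))
  # equal rates give v = 0
  eq <- poismix_model(component_params(c(log(3), log(3))),
                      fixed_weights(c(0.2, 0.8)))
  expect_equal(mixture_moments(eq, X)$v, rep(0, n), tolerance = 1e-12)
  # Monte-Carlo oracle for the two-point mixture above
  set.seed(99)
  N <- 1e6
  z <- rbinom(N, 1, 0.5)
  draws <- rpois(N, ifelse(z == 1, 3, 1))
  se_mean <- sqrt(3 / N)
  expect_lt(abs(mean(draws) - 2), 3 * se_mean)
  expect_lt(abs(var(draws) - 3), 3 * sqrt(2 * 9 / N) + 0.05)
  # v >= 0 on random covariate-dependent mixtures
  set.seed(17)
  Xr <- cbind(1, rnorm(30))
  cp <- component_params(c(0.5, -0.5), matrix(rnorm(2), 2, 1))
  mo2 <- mixture_moments(poismix_model(cp, fixed_weights(c(0.4, 0.6))), Xr)
  expect_true(all(mo2$v >= 0))
  expect_true(all(mo2$var >= mo2$mean))
})

test_that("rate ratios exponentiate and round-trip the coefficients", {
  cp <- component_params(c(0, log(1.5)), matrix(c(log(2), 0), 2, 1))
  mm <- poismix_model(cp, fixed_weights(c(0.5, 0.5)))
  rr <- rate_ratios(mm)
  expect_equal(rr["(Intercept)", "comp1"], 1)
  expect_equal(rr["(Intercept)", "comp2"], 1.5)
  expect_equal(rr[2, "comp1"], 2)
  # inverse-function check on a random model
  set.seed(31)
  cp2 <- component_params(rnorm(3), matrix(rnorm(12), 3, 4))
  mm2 <- poismix_model(cp2, fixed_weights(rep(1 / 3, 3)))
  back <- log(as.matrix(rate_ratios(mm2)))
  expect_equal(unname(back[1, ]), cp2$beta0, tolerance = 1e-12)
  expect_equal(unname(t(back[-1, ])), unname(cp2$beta), tolerance = 1e-12)
})

test_that("count_dataset enforces its invariants", {
  expect_error(count_dataset(c(1, -1), matrix(0, 2, 1)), "nonnegative")
  expect_error(count_dataset(c(1, 1.5), matrix(0, 2, 1)), "nonnegative")
  expect_error(count_dataset(c(1, NA), matrix(0, 2, 1)), "finite")
  expect_error(count_dataset(1:3, matrix(0, 2, 1)), "rows")
  d <- count_dataset(0:2, matrix(rnorm(3), 3, 1))
  expect_equal(unname(d$X[, 1]), rep(1, 3))
  expect_identical(colnames(d$X)[1], "(Intercept)")
})
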