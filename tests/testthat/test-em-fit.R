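test_that("responsibility initialization is seeded and feasible", {
  cfg <- fit_config(seed = 7)
  t1 <- init_responsibilities(20, 3, cfg)
  t2 <- init_responsibilities(20, 3, cfg)
  expect_identical(t1, t2)
  expect_equal(rowSums(t1), rep(1, 20))
  expect_equal(init_responsibilities(5, 1, cfg), matrix(1, 5, 1))
  expect_error(init_responsibilities(2, 3, cfg), "cannot initialize")
  # quantile split: low counts to component 1, high to component 2
  qs <- fit_config(init_method = "quantile_split", seed = 1)
  tq <- init_responsibilities(4, 2, qs, y = c(0, 0, 4, 4))
  expect_equal(tq[, 1], c(0.9, 0.9, 0.1, 0.1))
  expect_equal(tq[, 2], c(0.1, 0.1, 0.9, 0.9))
})

test_that("E-step posteriors follow Bayes' rule", {
  d <- make_glm_dataset(n = 60, seed = 8)
  # identical components: posterior equals the prior weights
  cp <- component_params(c(0.4, 0.4), matrix(0.2, 2, 1))
  es <- e_step(d, poismix_model(cp, fixed_weights(c(0.3, 0.7))))
  expect_equal(es$tau, matrix(c(0.3, 0.7), 60, 2, byrow = TRUE))
  # closed form for y = 0 with rates 0.1 and 10 at equal priors
  d0 <- count_dataset(0, matrix(1, 1, 1))
  cp2 <- component_params(c(log(0.1), log(10)))
  es0 <- e_step(d0, poismix_model(cp2, fixed_weights(c(0.5, 0.5))))
  expect_equal(es0$tau[1, 1], exp(-0.1) / (exp(-0.1) + exp(-10)),
               tolerance = 1e-12)
  # normalization on random instances, and loglik consistency
  set.seed(12)
  for (s in 1:20) {
    cp3 <- component_params(rnorm(2, 0, 0.5), matrix(rnorm(2, 0, 0.3), 2, 1))
    m3 <- poismix_model(cp3, fixed_weights(c(0.4, 0.6)))
    es3 <- e_step(d, m3)
    expect_equal(rowSums(es3$tau), rep(1, 60), tolerance = 1e-12)
    expect_equal(es3$loglik, mixture_log_likelihood(d, m3))
  }
})

test_that("component M-step solves the weighted Poisson GLM", {
  d <- make_glm_dataset(n = 120, seed = 21)
  n <- length(d$y)
  # all mass on one component, intercept-only design: rate = weighted mean
  dio <- count_dataset(d$y, matrix(1, n, 1))
  tau <- cbind(rep(1, n), rep(1e-3, n))
  tau <- tau / rowSums(tau)
  cp <- m_step_components(dio, tau)
  wbar1 <- sum(tau[, 1] * d$y) / sum(tau[, 1])
  expect_equal(cp$beta0[1], log(wbar1), tolerance = 1e-8)
  # weight-equivalence: duplicating rows with halved weights changes nothing
  d2 <- count_dataset(rep(d$y, 2), rbind(dio$X, dio$X))
  tau2 <- rbind(tau, tau) / 2
  cp_dup <- m_step_components(d2, tau2)
  expect_equal(cp_dup$beta0, cp$beta0, tolerance = 1e-8)
  # generic-optimizer oracle on a random soft-weighted two-component case
  set.seed(33)
  tauw <- matrix(runif(2 * n), n, 2)
  tauw <- tauw / rowSums(tauw)
  cpw <- m_step_components(d, tauw)
  for (k in 1:2) {
    opt <- optim(c(0, 0), weighted_poisson_negll, X = d$X, y = d$y,
                 w = tauw[, k], method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    expect_equal(unname(c(cpw$beta0[k], cpw$beta[k, ])), opt$par,
                 tolerance = 1e-6)
  }
  # vanishing responsibility mass aborts
  bad <- cbind(rep(1, n), rep(1e-9, n))
  expect_error(m_step_components(d, bad), "vanishing")
})

test_that("weight M-step: closed form in fixed mode, oracle in gate mode", {
  set.seed(44)
  n <- 150
  W <- cbind(1, rnorm(n))
  tau <- matrix(runif(2 * n), n, 2)
  tau <- tau / rowSums(tau)
  wf <- m_step_weights(W, tau, mode = "fixed")
  expect_equal(wf$pi, colMeans(tau), tolerance = 1e-12)
  # constant responsibilities give zero gate slopes and matching intercepts
  tc <- matrix(c(0.25, 0.75), n, 2, byrow = TRUE)
  wc <- m_step_weights(W, tc, mode = "concomitant")
  expect_equal(wc$gamma[2, 1], 0, tolerance = 1e-6)
  P <- concomitant_weights(W, wc)
  expect_equal(P[1, ], c(0.25, 0.75), tolerance = 1e-6)
  # independent numeric maximizer of the weighted multinomial likelihood
  wcg <- m_step_weights(W, tau, mode = "concomitant")
  opt <- optim(c(0, 0), weighted_multinom_negll, W = W, tau = tau,
               method = "BFGS", control = list(reltol = 1e-15, maxit = 1000))
  expect_equal(c(wcg$gamma0[2], wcg$gamma[2, ]), opt$par, tolerance = 1e-5)
})

test_that("K = 1 fits match the independent Poisson GLM oracle", {
  d <- make_glm_dataset(n = 400, seed = 3)
  m1 <- fit_em(d, 1, config = fit_config(n_restarts = 2, seed = 1))
  g <- glm(d$y ~ d$X[, -1], family = poisson())
  expect_equal(unname(c(m1$components$beta0, m1$components$beta[1, ])),
               unname(coef(g)), tolerance = 1e-6)
  expect_equal(m1$fit$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(AIC(m1), AIC(g), tolerance = 1e-6)
  expect_equal(count_parameters(m1), attr(logLik(g), "df"))
})

test_that("plain two-point mixture recovers rates and proportions", {
  tp <- make_two_point_dataset(n = 2000, lam = c(8, 2), pi1 = 0.5, seed = 42)
  m <- fit_em(tp$data, 2, mode = "standard",
              config = fit_config(n_restarts = 5, seed = 10))
  lam_hat <- exp(m$components$beta0)   # ordered high to low by relabelling
  expect_lt(abs(lam_hat[1] - 8) / 8, 0.10)
  expect_lt(abs(lam_hat[2] - 2) / 2, 0.10)
  expect_lt(abs(m$weights$pi[1] - 0.5), 0.05)
  expect_monotone_trace(m)
})

test_that("EM ascent holds across modes and misspecified K", {
  d <- make_glm_dataset(n = 250, seed = 6)
  for (mode in c("standard", "concomitant")) {
    for (K in 1:3) {
      m <- fit_em(d, K, mode = mode,
                  config = fit_config(n_restarts = 2, seed = K, max_iter = 200))
      expect_monotone_trace(m)
    }
  }
})

test_that("relabelling orders components by decreasing mean rate", {
  sim <- simulate_dataset(two_component_spec(n = 1500, seed = 3))
  fits <- lapply(c(1, 99), function(s)
    fit_em(sim$data, 2, config = fit_config(n_restarts = 3, seed = s)))
  for (m in fits) {
    lam <- component_rates(sim$data$X, m$components)
    expect_gt(mean(lam[, 1]), mean(lam[, 2]))
  }
  # both seeds reach the same maximum: identical ordered estimates
  expect_equal(fits[[1]]$components$beta0, fits[[2]]$components$beta0,
               tolerance = 1e-4)
  expect_equal(fits[[1]]$fit$loglik, fits[[2]]$fit$loglik, tolerance = 1e-6)
})

test_that("posterior classification partitions the sample", {
  tp <- make_two_point_dataset(n = 800, lam = c(12, 1), pi1 = 0.5, seed = 9)
  m <- fit_em(tp$data, 2, mode = "standard",
              config = fit_config(n_restarts = 3, seed = 2))
  cls <- posterior_classify(m, tp$data)
  expect_equal(sum(cls$sizes), 800)
  expect_equal(unname(cls$priors), unname(m$weights$pi))
  # well-separated rates: labels agree with truth wherever the margin is wide
  conf <- apply(cls$tau, 1, max) > 0.95
  agree <- mean(cls$labels[conf] == tp$labels[conf])
  expect_gt(agree, 0.99)
  # K = 1 trivially puts everyone in one cluster
  m1 <- fit_em(tp$data, 1, config = fit_config(n_restarts = 1, seed = 1))
  cls1 <- posterior_classify(m1, tp$data)
  expect_equal(unname(cls1$sizes), 800)
})

test_that("bootstrap intervals are deterministic and cover a K = 1 intercept", {
  # constant response: interval collapses onto log(y)
  dcon <- count_dataset(rep(3, 120), matrix(1, 120, 1))
  mcon <- fit_em(dcon, 1, config = fit_config(n_restarts = 1, seed = 1))
  ci <- bootstrap_confidence_intervals(dcon, mcon, B = 50,
                                       config = fit_config(seed = 5))
  expect_equal(ci$lower[1], log(3), tolerance = 1e-6)
  expect_equal(ci$upper[1], log(3), tolerance = 1e-6)
  # determinism: same seed stream gives identical intervals
  d <- make_glm_dataset(n = 150, seed = 13)
  m <- fit_em(d, 1, config = fit_config(n_restarts = 1, seed = 1))
  ci1 <- bootstrap_confidence_intervals(d, m, B = 50,
                                        config = fit_config(seed = 5))
  ci2 <- bootstrap_confidence_intervals(d, m, B = 50,
                                        config = fit_config(seed = 5))
  expect_identical(ci1, ci2)
  # coverage of the intercept CI across synthetic replicates of a K = 1 model
  hits <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    dr <- count_dataset(rpois(500, exp(0.7)), matrix(1, 500, 1))
    mr <- fit_em(dr, 1, config = fit_config(n_restarts = 1, seed = r))
    cir <- bootstrap_confidence_intervals(dr, mr, B = 60,
                                          config = fit_config(seed = r))
    if (cir$lower[1] <= 0.7 && cir$upper[1] >= 0.7) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90 - 2 * sqrt(0.05 * 0.95 / n_rep))
  expect_lte(hits / n_rep, 1)
})
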