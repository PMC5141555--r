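#' EM fitting configuration
#'
#' Tuning knobs shared by all fitting routines.
#'
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence threshold on the relative log-likelihood change
#'   `|dll| / (|ll| + 1)`.
#' @param n_restarts number of independently initialized EM runs; the run
#'   with the highest final log-likelihood wins.
#' @param seed base seed; restart r uses `seed + r - 1`, so runs are fully
#'   reproducible.
#' @param init_method `"random_responsibilities"` draws each responsibility
#'   row from a flat Dirichlet; `"quantile_split"` hard-assigns rows by
#'   K-quantiles of the response and softens to 0.9 / rest-uniform.
#' @param ridge small nonnegative regularizer added to every M-step Hessian
#'   (stabilizes collinear designs; negligible bias at the default).
#' @param min_component_weight a component whose total responsibility falls
#'   below `min_component_weight * n` aborts the run as degenerate.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(max_iter = 500L, tol = 1e-8, n_restarts = 10L,
                       seed = NULL,
                       init_method = c("random_responsibilities",
                                       "quantile_split"),
                       ridge = 1e-8, min_component_weight = 1e-4) {
  init_method <- match.arg(init_method)
  .assert(max_iter >= 1 && tol > 0 && n_restarts >= 1 && ridge >= 0,
          "invalid fit configuration")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts), seed = seed,
                 init_method = init_method, ridge = ridge,
                 min_component_weight = min_component_weight),
            class = "fit_config")
}

#' Initial responsibilities
#'
#' Seeds an EM run with an n x K matrix of membership probabilities.
#'
#' @param n number of observations; must be at least `K`.
#' @param K number of components.
#' @param config a [fit_config()]; supplies the method and (default) seed.
#' @param y response vector, required by `"quantile_split"`.
#' @param seed overrides `config$seed` (used internally for restarts).
#' @return n x K matrix with rows summing to 1.
#' @export
init_responsibilities <- function(n, K, config = fit_config(), y = NULL,
                                  seed = config$seed) {
  .assert(n >= K, sprintf("cannot initialize %d components with %d rows", K, n),
          class = "poismix_infeasible")
  if (!is.null(seed)) set.seed(seed)
  if (K == 1L) return(matrix(1, n, 1L))
  if (config$init_method == "quantile_split") {
    .assert(!is.null(y) && length(y) == n, "quantile_split needs y")
    grp <- ceiling(K * rank(y, ties.method = "first") / n)
    tau <- matrix(0.1 / (K - 1), n, K)
    tau[cbind(seq_len(n), grp)] <- 0.9
  } else {
    tau <- matrix(rexp(n * K), n, K)
    tau <- tau / rowSums(tau)
  }
  tau
}

# prepend a structural-zero column: zeros of y get half their mass on it
.init_resp <- function(n, K, config, y, zip, seed) {
  tau <- init_responsibilities(n, K, config, y, seed)
  if (!zip) return(tau)
  s <- ifelse(y == 0, 0.5, 0)
  cbind(s, tau * (1 - s))
}

#' E-step: posterior responsibilities and log-likelihood
#'
#' Computes \eqn{\tau_{ik} = \pi_{ik} f(y_i|\lambda_{ik}) / \sum_h \pi_{ih}
#' f(y_i|\lambda_{ih})} in log space, returning the observed-data
#' log-likelihood from the same evaluation.  For zero-inflated models the
#' first column is the structural-zero component, which is exactly 0 for
#' observations with a positive count.
#'
#' @param data a [count_dataset()].
#' @param model a `poismix` model.
#' @return list with `tau` (n x K or n x (K+1) matrix) and `loglik`.
#' @export
e_step <- function(data, model) {
  parts <- .loglik_parts(data, model)
  M <- parts$logpi + parts$logf
  ll_i <- .row_logsumexp(M)
  if (any(!is.finite(ll_i))) {
    bad <- which(!is.finite(ll_i))[1L]
    .assert(FALSE, sprintf(
      "all component densities vanish for row %d (y = %g)", bad, data$y[bad]),
      class = "poismix_numeric")
  }
  tau <- exp(M - ll_i)
  list(tau = tau, loglik = sum(ll_i))
}

# weighted Poisson log-link IRLS (Newton with step-halving); maximizes
# sum_i w_i (y_i eta_i - exp(eta_i)) - ridge/2 |b|^2
.irls_poisson <- function(X, y, w, b0, ridge = 1e-8, max_iter = 50L,
                          tol = 1e-10) {
  b <- b0
  qfun <- function(b) {
    eta <- .clip(drop(X %*% b), 700)
    sum(w * (y * eta - exp(eta))) - ridge / 2 * sum(b^2)
  }
  q <- qfun(b)
  for (iter in seq_len(max_iter)) {
    eta <- .clip(drop(X %*% b), 700)
    mu <- exp(eta)
    g <- drop(crossprod(X, w * (y - mu))) - ridge * b
    H <- crossprod(X, X * (w * mu)) + diag(ridge, ncol(X))
    delta <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-6, ncol(X)), g))
    .assert(all(is.finite(delta)), "non-finite IRLS step",
            class = "poismix_numeric")
    t_ <- 1
    repeat {
      b_new <- b + t_ * delta
      q_new <- qfun(b_new)
      if (q_new >= q - 1e-12 || t_ < 1e-10) break
      t_ <- t_ / 2
    }
    done <- max(abs(b_new - b)) < tol
    b <- b_new
    q <- q_new
    if (done) break
  }
  b
}

#' M-step for the component regressions
#'
#' For each component k, maximizes the \eqn{\tau_{\cdot k}}-weighted Poisson
#' log-likelihood on the log link by ridge-stabilized iteratively reweighted
#' least squares, warm-started from `start` so the expected complete-data
#' log-likelihood never decreases.
#'
#' @param data a [count_dataset()].
#' @param tau responsibility matrix over the count components.
#' @param config a [fit_config()].
#' @param start optional [component_params()] warm start.
#' @return a [component_params()] object.
#' @export
m_step_components <- function(data, tau, config = fit_config(),
                              start = NULL) {
  X <- data$X
  y <- data$y
  n <- length(y)
  K <- ncol(tau)
  cs <- colSums(tau)
  if (any(cs < config$min_component_weight * n)) {
    .assert(FALSE, sprintf(
      "component %d has vanishing responsibility mass (%.3g)",
      which.min(cs), min(cs)), class = "poismix_degenerate")
  }
  d <- ncol(X)
  B <- matrix(0, d, K)
  if (!is.null(start)) {
    B <- .coef_matrix(start)
  } else {
    B[1L, ] <- log(pmax(drop(crossprod(tau, y)) / cs, 1e-8))
  }
  for (k in seq_len(K)) {
    B[, k] <- .irls_poisson(X, y, tau[, k], B[, k], ridge = config$ridge)
  }
  cp <- component_params(beta0 = B[1L, ], beta = t(B[-1L, , drop = FALSE]))
  colnames(cp$beta) <- colnames(X)[-1L]
  cp
}

# weighted multinomial-logit maximization by Newton iterations with
# step-halving; `ref` category held at zero for identification
.newton_multinom <- function(W, tau, ref = 1L, ridge = 1e-8, G0 = NULL,
                             max_iter = 50L, tol = 1e-10, clamp = 15) {
  d <- ncol(W)
  C <- ncol(tau)
  free <- setdiff(seq_len(C), ref)
  G <- if (is.null(G0)) matrix(0, d, C) else G0
  if (length(free) == 0L) {   # single category: gate fully determined
    return(list(G = G, separated = FALSE))
  }
  qfun <- function(G) {
    P <- .softmax_rows(W %*% G)
    sum(tau * log(pmax(P, 1e-300))) -
      ridge / 2 * sum(G[, free]^2)
  }
  q <- qfun(G)
  separated <- FALSE
  idx <- function(a) ((a - 1L) * d + 1L):(a * d)
  for (iter in seq_len(max_iter)) {
    P <- .softmax_rows(W %*% G)
    m <- d * length(free)
    g <- numeric(m)
    H <- matrix(0, m, m)   # negative Hessian (positive semi-definite)
    for (a in seq_along(free)) {
      ca <- free[a]
      g[idx(a)] <- drop(crossprod(W, tau[, ca] - P[, ca])) -
        ridge * G[, ca]
      for (b in a:length(free)) {
        cb <- free[b]
        wts <- if (ca == cb) P[, ca] * (1 - P[, ca]) else -P[, ca] * P[, cb]
        blk <- crossprod(W, W * wts)
        H[idx(a), idx(b)] <- blk
        if (b > a) H[idx(b), idx(a)] <- t(blk)
      }
    }
    H <- H + diag(ridge + 1e-10, m)
    delta <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-6, m), g))
    # (quasi-)separation guard: shorten the step so every coefficient stays
    # inside the clamp box, keeping the objective monotone (a post-hoc clip
    # would not be)
    gfree <- as.vector(G[, free])
    room <- ifelse(delta > 0, clamp - gfree, -clamp - gfree)
    with_dir <- delta != 0
    t_max <- if (any(with_dir)) {
      min(1, room[with_dir] / delta[with_dir])
    } else {
      1
    }
    if (t_max < 1) separated <- TRUE
    t_ <- max(t_max, 0)
    repeat {
      G_new <- G
      for (a in seq_along(free)) {
        G_new[, free[a]] <- G[, free[a]] + t_ * delta[idx(a)]
      }
      q_new <- qfun(G_new)
      if (q_new >= q - 1e-12 || t_ < 1e-10) break
      t_ <- t_ / 2
    }
    if (q_new < q) {   # no admissible ascent step (boundary or stall)
      G_new <- G
      q_new <- q
    }
    done <- abs(q_new - q) < tol * (abs(q) + 1)
    G <- G_new
    q <- q_new
    if (done) break
  }
  list(G = G, separated = separated)
}

#' M-step for the mixing weights
#'
#' Fixed mode has the closed form \eqn{\hat\pi_k = n^{-1}\sum_i \tau_{ik}}.
#' Concomitant mode maximizes the responsibility-weighted multinomial-logit
#' log-likelihood by Newton iterations (reference category fixed at zero);
#' (quasi-)separation is detected by a coefficient-magnitude threshold and
#' handled by clipping the step, flagged via the `"separation"` attribute.
#'
#' @param W gate design block.
#' @param tau responsibility matrix over all gate categories.
#' @param mode `"fixed"` or `"concomitant"`.
#' @param config a [fit_config()].
#' @param start optional `weight_model` warm start.
#' @param ref reference category (first count component; used by the
#'   zero-inflated fitter to keep the structural category free).
#' @return a `weight_model`.
#' @export
m_step_weights <- function(W, tau, mode = c("fixed", "concomitant"),
                           config = fit_config(), start = NULL, ref = 1L) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    return(fixed_weights(colMeans(tau) / sum(colMeans(tau))))
  }
  G0 <- if (!is.null(start) && start$mode == "concomitant") {
    .gate_matrix(start)
  }
  fit <- .newton_multinom(W, tau, ref = ref, ridge = config$ridge, G0 = G0)
  gam <- t(fit$G[-1L, , drop = FALSE])
  colnames(gam) <- colnames(W)[-1L]
  wm <- gate_weights(gamma0 = fit$G[1L, ], gamma = gam, ref = ref)
  attr(wm, "separation") <- fit$separated
  wm
}

# one EM run from either an initial responsibility matrix or a warm-start
# model; errors with class poismix_degenerate / poismix_numeric on failure
.em_run <- function(data, K, mode, zip, config, tau0 = NULL, model0 = NULL) {
  n <- length(data$y)
  ref <- if (zip) 2L else 1L
  comps <- NULL
  wm <- NULL
  if (!is.null(model0)) {
    es <- e_step(data, model0)
    tau <- es$tau
    ll <- es$loglik
    comps <- model0$components
    wm <- model0$weights
    trace <- ll
  } else {
    tau <- tau0
    ll <- -Inf
    trace <- numeric(0)
  }
  converged <- FALSE
  iter <- 0L
  separation <- FALSE
  for (iter in seq_len(config$max_iter)) {
    count_cols <- if (zip) tau[, -1L, drop = FALSE] else tau
    comps <- m_step_components(data, count_cols, config, start = comps)
    wm <- m_step_weights(data$W, tau, mode, config, start = wm, ref = ref)
    separation <- separation || isTRUE(attr(wm, "separation"))
    model <- poismix_model(comps, wm, zero_inflated = zip)
    es <- e_step(data, model)
    trace <- c(trace, es$loglik)
    rel <- abs(es$loglik - ll) / (abs(ll) + 1)
    tau <- es$tau
    ll <- es$loglik
    if (is.finite(rel) && rel < config$tol) {
      converged <- TRUE
      break
    }
  }
  list(model = model, tau = tau, loglik = ll, trace = trace,
       converged = converged, n_iter = iter, separation = separation)
}

# relabel so component 1 has the highest mean fitted rate; gate re-zeroed
# on the new reference by softmax shift invariance
.relabel <- function(model, data) {
  lam <- component_rates(data$X, model$components)
  ord <- order(colMeans(lam), decreasing = TRUE)
  if (identical(ord, seq_len(model$K))) return(model)
  .permute_components(model, ord)
}

.permute_components <- function(model, ord) {
  cp <- model$components
  cp2 <- component_params(cp$beta0[ord], cp$beta[ord, , drop = FALSE])
  colnames(cp2$beta) <- colnames(cp$beta)
  zip <- model$zero_inflated
  cat_ord <- if (zip) c(1L, 1L + ord) else ord
  wm <- model$weights
  if (wm$mode == "fixed") {
    wm2 <- fixed_weights(wm$pi[cat_ord])
  } else {
    G <- .gate_matrix(wm)[, cat_ord, drop = FALSE]
    newref <- if (zip) 2L else 1L
    G <- G - G[, newref]
    gam <- t(G[-1L, , drop = FALSE])
    colnames(gam) <- colnames(wm$gamma)
    wm2 <- gate_weights(G[1L, ], gam, ref = newref)
  }
  poismix_model(cp2, wm2, zip, fit = model$fit)
}

.normalize_mode <- function(mode) {
  mode <- match.arg(mode, c("concomitant", "standard", "fixed"))
  if (mode == "standard") "fixed" else mode
}

#' Fit a finite Poisson mixture regression by EM
#'
#' Runs `n_restarts` independently seeded EM runs (E-step, weighted-IRLS
#' component M-step, weight M-step, until the relative log-likelihood change
#' drops below `tol`) and keeps the best final log-likelihood.  Components
#' are relabelled in decreasing order of mean fitted rate, so component 1 is
#' always the high-rate ("high-risk") group.  Within every run the
#' log-likelihood trace is non-decreasing, the standard EM ascent guarantee.
#'
#' @param data a [count_dataset()].
#' @param K number of components (K = 1 reduces to a Poisson GLM).
#' @param mode `"concomitant"` for the covariate-gated model,
#'   `"standard"`/`"fixed"` for fixed mixing proportions.
#' @param config a [fit_config()].
#' @return fitted `poismix` model; `$fit` carries `loglik`, `converged`,
#'   `n_iter`, `trace`, `tau` (final responsibilities), `seed`,
#'   `restarts_used`, and the configuration.
#' @examples
#' set.seed(1)
#' d <- count_dataset(rpois(200, 3), matrix(rnorm(200), ncol = 1))
#' m <- fit_em(d, K = 1, config = fit_config(n_restarts = 2, seed = 1))
#' coef_matrix <- rate_ratios(m)
#' @export
fit_em <- function(data, K, mode = c("concomitant", "standard", "fixed"),
                   config = fit_config()) {
  mode <- .normalize_mode(mode)
  .fit_mixture(data, K, mode, zip = FALSE, config = config)
}

.fit_mixture <- function(data, K, mode, zip, config) {
  n <- length(data$y)
  p <- ncol(data$X) - 1L
  q <- ncol(data$W) - 1L
  df <- .df_formula(K, p, q, mode, zip)
  .assert(n > df, sprintf("n = %d does not exceed the %d parameters", n, df),
          class = "poismix_infeasible")
  base <- config$seed %||% 1L
  runs <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    tau0 <- .init_resp(n, K, config, data$y, zip, seed = base + r - 1L)
    runs[[r]] <- tryCatch(
      .em_run(data, K, mode, zip, config, tau0 = tau0),
      poismix_degenerate = function(e) e,
      poismix_numeric = function(e) e
    )
  }
  ok <- !vapply(runs, inherits, logical(1), "condition")
  if (!any(ok)) {
    msgs <- vapply(runs, conditionMessage, character(1))
    .assert(FALSE, paste0("all EM restarts failed:\n  ",
                          paste(msgs, collapse = "\n  ")),
            class = "poismix_fit_failure")
  }
  lls <- vapply(runs, function(r) if (is.list(r) && !is.null(r$loglik))
    r$loglik else -Inf, numeric(1))
  best <- runs[[which.max(lls)]]
  model <- .relabel(best$model, data)
  es <- e_step(data, model)   # responsibilities under the final labelling
  model$fit <- list(
    loglik = es$loglik, n_obs = n, converged = best$converged,
    n_iter = best$n_iter, seed = base, restarts_used = config$n_restarts,
    n_failed_restarts = sum(!ok), trace = best$trace, tau = es$tau,
    separation = best$separation, mode = mode, config = config,
    p = p, q = q
  )
  model
}

#' Hard classification from posterior responsibilities
#'
#' Assigns each observation to the component with the largest posterior
#' probability (ties to the lowest index) and summarizes cluster sizes and
#' average prior weights.
#'
#' @param model fitted `poismix` model.
#' @param data a [count_dataset()].
#' @return list with `labels` (category index per row; category 1 is the
#'   structural-zero class for zero-inflated models), `sizes`, `priors`
#'   (column means of the prior weights), and `tau`.
#' @export
posterior_classify <- function(model, data) {
  es <- e_step(data, model)
  labels <- max.col(es$tau, ties.method = "first")
  C <- ncol(es$tau)
  nm <- .category_names(model)
  sizes <- setNames(tabulate(labels, C), nm)
  priors <- setNames(colMeans(concomitant_weights(data$W, model$weights)), nm)
  list(labels = labels, sizes = sizes, priors = priors, tau = es$tau)
}

# flatten all free parameters to a named vector (bootstrap bookkeeping)
.flatten_params <- function(model) {
  B <- .coef_matrix(model$components)
  out <- setNames(as.vector(B),
                  paste0(rep(colnames(B), each = nrow(B)), ":",
                         rep(rownames(B), ncol(B))))
  wm <- model$weights
  nm <- .category_names(model)
  if (wm$mode == "fixed") {
    out <- c(out, setNames(wm$pi, paste0("pi:", nm)))
  } else {
    G <- .gate_matrix(wm)
    free <- setdiff(seq_len(wm$K), wm$ref)
    for (cc in free) {
      out <- c(out, setNames(G[, cc],
                             paste0("gate:", nm[cc], ":", rownames(G))))
    }
  }
  out
}

#' Nonparametric bootstrap confidence intervals
#'
#' Case-resampling bootstrap: each replicate resamples rows with
#' replacement, refits the model by EM warm-started from the point estimate,
#' relabels by the mean-rate ordering rule, and contributes one draw per
#' parameter.  Percentile intervals are returned.  Replicates whose fit
#' degenerates are dropped; a failure rate above 20% is flagged.
#'
#' @param data a [count_dataset()].
#' @param model fitted `poismix` model.
#' @param B number of bootstrap replicates (at least 50).
#' @param config a [fit_config()]; defaults to the one stored in the fit.
#'   Replicate b uses seed `config$seed + b`.
#' @param level confidence level (default 0.95).
#' @return data frame with `param`, `estimate`, `lower`, `upper`;
#'   attributes `n_failed` and `failure_warning`.
#' @export
bootstrap_confidence_intervals <- function(data, model, B = 200L,
                                           config = NULL, level = 0.95) {
  .assert(B >= 50, "need at least 50 bootstrap replicates")
  config <- config %||% model$fit$config %||% fit_config()
  base <- config$seed %||% 1L
  point <- .flatten_params(model)
  draws <- matrix(NA_real_, B, length(point),
                  dimnames = list(NULL, names(point)))
  n <- length(data$y)
  mode <- model$weights$mode
  for (b in seq_len(B)) {
    set.seed(base + b)
    idx <- sample.int(n, n, replace = TRUE)
    nd <- count_dataset(data$y[idx], data$X[idx, , drop = FALSE],
                        data$W[idx, , drop = FALSE])
    r <- tryCatch(
      .em_run(nd, model$K, mode, model$zero_inflated, config, model0 = model),
      error = function(e) NULL
    )
    if (!is.null(r)) {
      draws[b, ] <- .flatten_params(.relabel(r$model, nd))
    }
  }
  n_failed <- sum(is.na(draws[, 1L]))
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2L, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- data.frame(param = names(point), estimate = unname(point),
                    lower = qs[1L, ], upper = qs[2L, ], row.names = NULL)
  attr(out, "n_failed") <- n_failed
  attr(out, "failure_warning") <- n_failed / B > 0.2
  out
}
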