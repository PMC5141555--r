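#' Covariate schema entries
#'
#' Building blocks for [synthetic_spec()] covariate tables: independent
#' continuous (normal), binary (Bernoulli) and small-integer ordinal
#' (categorical score) columns.
#'
#' @param name column name (unique within a schema).
#' @param mean,sd normal parameters for continuous covariates.
#' @param prob success probability for binary covariates.
#' @param levels,probs support and probabilities for ordinal covariates.
#' @return a schema entry list.
#' @name covariate_schema
NULL

#' @rdname covariate_schema
#' @export
cov_continuous <- function(name, mean, sd) {
  .assert(sd > 0, "sd must be positive")
  list(name = name, kind = "continuous", mean = mean, sd = sd)
}

#' @rdname covariate_schema
#' @export
cov_binary <- function(name, prob) {
  .assert(prob >= 0 && prob <= 1, "prob must be a probability")
  list(name = name, kind = "binary", prob = prob)
}

#' @rdname covariate_schema
#' @export
cov_ordinal <- function(name, levels, probs) {
  .assert(length(levels) == length(probs) && all(probs >= 0) &&
            abs(sum(probs) - 1) < 1e-10, "invalid ordinal specification")
  list(name = name, kind = "ordinal", levels = levels, probs = probs)
}

#' Cleveland-style covariate schema
#'
#' Thirteen mixed clinical covariates mirroring the UCI Cleveland
#' heart-disease attributes: five continuous (age, trestbps, chol, thalach,
#' oldpeak), three binary (sex, fbs, exang) and five small-integer
#' categorical scores (cp, restecg, slope, ca, thal).  All distribution
#' constants are deliberately round numbers chosen to resemble the published
#' summaries of that dataset, not estimates from it, so no download is
#' needed anywhere in the package.
#'
#' @return list of schema entries.
#' @export
cleveland_schema <- function() {
  list(
    cov_continuous("age", 54, 9),
    cov_binary("sex", 0.68),
    cov_ordinal("cp", 1:4, c(0.1, 0.2, 0.3, 0.4)),
    cov_continuous("trestbps", 130, 18),
    cov_continuous("chol", 245, 50),
    cov_binary("fbs", 0.15),
    cov_ordinal("restecg", 0:2, c(0.5, 0.1, 0.4)),
    cov_continuous("thalach", 150, 23),
    cov_binary("exang", 0.33),
    cov_continuous("oldpeak", 1, 1.2),
    cov_ordinal("slope", 1:3, c(0.45, 0.45, 0.1)),
    cov_ordinal("ca", 0:3, c(0.55, 0.2, 0.15, 0.1)),
    cov_ordinal("thal", c(3, 6, 7), c(0.55, 0.1, 0.35))
  )
}

#' Ground-truth generative specification
#'
#' Everything needed to simulate a dataset with the exact statistical
#' structure the models assume: a covariate schema, true component
#' coefficients, a true weight model (fixed or concomitant gate), an
#' optional structural-zero gate row, and an optional response cap.
#'
#' @param n number of rows.
#' @param components true [component_params()] (p must equal the number of
#'   schema covariates).
#' @param gate true `weight_model` over the K count components.
#' @param schema list of covariate schema entries (may be empty for
#'   intercept-only populations).
#' @param structural_zero optional structural-zero gate row: a scalar prior
#'   mass for fixed gates, or a length `1 + q` coefficient vector for
#'   concomitant gates (relative to the reference count component).
#' @param cap_response optional maximum count; larger draws are truncated
#'   and the truncation fraction recorded.
#' @param seed RNG seed; simulation is bit-reproducible.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n, components, gate, schema = list(),
                           structural_zero = NULL, cap_response = NULL,
                           seed = 1L) {
  .assert(n >= 1, "n must be positive")
  .assert(inherits(components, "component_params"), "bad components")
  .assert(inherits(gate, "weight_model"), "bad gate")
  .assert(gate$K == components$K, "gate and components disagree on K")
  p <- length(schema)
  nms <- vapply(schema, `[[`, character(1), "name")
  .assert(!anyDuplicated(nms), "schema names must be unique")
  .assert(components$p == p,
          sprintf("components expect %d covariates, schema has %d",
                  components$p, p))
  if (gate$mode == "concomitant") {
    .assert(gate$q == p, "gate coefficients must cover the schema covariates")
  }
  if (!is.null(structural_zero)) {
    if (gate$mode == "fixed") {
      .assert(length(structural_zero) == 1 && structural_zero > 0 &&
                structural_zero < 1, "structural mass must be in (0,1)")
    } else {
      .assert(length(structural_zero) == 1 + p,
              "structural gate row needs 1 + q coefficients")
    }
  }
  structure(list(n = as.integer(n), K = components$K, schema = schema,
                 components = components, gate = gate,
                 structural_zero = structural_zero,
                 cap_response = cap_response, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# weight model over all categories (structural first when present)
.true_weights <- function(spec) {
  gate <- spec$gate
  if (is.null(spec$structural_zero)) return(gate)
  if (gate$mode == "fixed") {
    s <- spec$structural_zero
    fixed_weights(c(s, (1 - s) * gate$pi))
  } else {
    G <- cbind(spec$structural_zero, .gate_matrix(gate))
    gam <- t(G[-1L, , drop = FALSE])
    colnames(gam) <- colnames(gate$gamma)
    gate_weights(G[1L, ], gam, ref = 1L + gate$ref)
  }
}

#' Simulate a dataset from a generative specification
#'
#' Draws covariates independently per the schema, latent category labels
#' from the (possibly structural-zero-extended) gate, and counts from the
#' component-specific Poisson rates.  Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (a [count_dataset()]) and `truth` (labels —
#'   category 1 is the structural class when present — the rate matrix, the
#'   row-wise prior weights, the true `poismix` model and the truncation
#'   fraction).
#' @export
simulate_dataset <- function(spec) {
  .assert(inherits(spec, "synthetic_spec"), "not a synthetic_spec")
  set.seed(spec$seed)
  n <- spec$n
  cols <- lapply(spec$schema, function(sc) {
    switch(sc$kind,
      continuous = rnorm(n, sc$mean, sc$sd),
      binary = rbinom(n, 1L, sc$prob),
      ordinal = sample(sc$levels, n, replace = TRUE, prob = sc$probs)
    )
  })
  p <- length(cols)
  Xr <- if (p) {
    matrix(unlist(cols), n, p,
           dimnames = list(NULL, vapply(spec$schema, `[[`, character(1),
                                        "name")))
  } else {
    matrix(0, n, 0L)
  }
  X <- cbind(`(Intercept)` = rep(1, n), Xr)
  wm <- .true_weights(spec)
  zip <- !is.null(spec$structural_zero)
  model <- poismix_model(spec$components, wm, zero_inflated = zip)
  P <- concomitant_weights(X, wm)
  u <- runif(n)
  cum <- P
  if (ncol(P) > 1L) {
    for (j in 2:ncol(P)) cum[, j] <- cum[, j - 1L] + P[, j]
  }
  label <- rowSums(u > cum) + 1L
  lam <- component_rates(X, spec$components)
  comp <- if (zip) pmax(label - 1L, 1L) else label
  y <- rpois(n, lam[cbind(seq_len(n), comp)])
  if (zip) y[label == 1L] <- 0
  trunc_frac <- 0
  if (!is.null(spec$cap_response)) {
    trunc_frac <- mean(y > spec$cap_response)
    y <- pmin(y, spec$cap_response)
  }
  list(data = count_dataset(y, X),
       truth = list(labels = label, rates = lam, weights = P, model = model,
                    truncation_fraction = trunc_frac, spec = spec))
}

#' A well-separated two-component concomitant specification
#'
#' The reference condition for parameter-recovery experiments: two
#' standardized continuous covariates, component log-rates
#' `1.8 + 0.5 z1 - 0.5 z2` versus `0.5 - 0.5 z1 + 0.5 z2` (rate scales
#' e^1.8 vs e^0.5), and a gate with effects of magnitude 1.5 on both
#' covariates.
#'
#' @param n rows (default 3000).
#' @param seed RNG seed.
#' @return a [synthetic_spec()].
#' @export
two_component_spec <- function(n = 3000L, seed = 1L) {
  comps <- component_params(
    beta0 = c(1.8, 0.5),
    beta = matrix(c(0.5, -0.5, -0.5, 0.5), nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, c("z1", "z2")))
  )
  gate <- gate_weights(
    gamma0 = c(0, 0),
    gamma = matrix(c(0, 0, 1.5, -1.5), nrow = 2, byrow = TRUE,
                   dimnames = list(NULL, c("z1", "z2")))
  )
  synthetic_spec(n, comps, gate,
                 schema = list(cov_continuous("z1", 0, 1),
                               cov_continuous("z2", 0, 1)),
                 seed = seed)
}

#' A zero-inflated single-component specification
#'
#' Intercept-only population with one Poisson component (rate
#' `lambda`) and a structural-zero class holding prior mass
#' `structural_mass` through the gate intercept
#' `log(structural_mass / (1 - structural_mass))`.
#'
#' @param n rows (default 3000).
#' @param structural_mass prior structural-zero probability (default 0.4).
#' @param lambda Poisson rate of the count component (default 3).
#' @param seed RNG seed.
#' @return a [synthetic_spec()].
#' @export
zip_single_component_spec <- function(n = 3000L, structural_mass = 0.4,
                                      lambda = 3, seed = 1L) {
  comps <- component_params(beta0 = log(lambda))
  gate <- gate_weights(gamma0 = 0)
  synthetic_spec(n, comps, gate, schema = list(),
                 structural_zero = log(structural_mass / (1 - structural_mass)),
                 seed = seed)
}

#' Cleveland-like two-class generative specification
#'
#' Emulates the structure assumed for the heart-disease table: the 13-column
#' [cleveland_schema()] covariates, a high-rate "disease" class and a
#' low-rate class, membership gated on sex, chest pain, exercise angina,
#' vessels, heart rate and ST depression.  With `zero_inflated = TRUE` a
#' structural no-disease class (gate intercept 0.6, prior mass about 0.36)
#' is added.  All coefficients are round numbers documented in the methods
#' vignette; they are a plausible condition, not estimates from real data.
#'
#' @param n rows (default 303, the classical table size).
#' @param zero_inflated add the structural no-disease class?
#' @param seed RNG seed.
#' @return a [synthetic_spec()].
#' @export
cleveland_like_spec <- function(n = 303L, zero_inflated = FALSE, seed = 1L) {
  nms <- vapply(cleveland_schema(), `[[`, character(1), "name")
  beta <- matrix(0, 2, 13, dimnames = list(NULL, nms))
  beta[1, ] <- c(0.005, 0.25, 0.15, 0.002, 0.0005, 0.1, 0.1, -0.004,
                 0.25, 0.12, 0.1, 0.2, 0.05)
  beta[2, c("sex", "cp")] <- c(0.05, 0.05)
  comps <- component_params(beta0 = c(-0.75, -1.6), beta = beta)
  gamma <- matrix(0, 2, 13, dimnames = list(NULL, nms))
  gamma[2, c("sex", "cp", "exang", "ca", "thalach", "oldpeak")] <-
    c(-0.8, -0.3, -0.8, -0.4, 0.01, -0.3)
  gate <- gate_weights(gamma0 = c(0, 0.83), gamma = gamma)
  structural <- if (zero_inflated) c(0.6, rep(0, 13))
  synthetic_spec(n, comps, gate, schema = cleveland_schema(),
                 structural_zero = structural, seed = seed)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates from a specification, refits with the matching model
#' class, aligns labels to the truth by the mean-rate ordering rule, and
#' records coefficient error, gate error, the adjusted Rand index of the
#' hard classification against the true labels, the recovered structural
#' mass (zero-inflated specs) and, optionally, the BIC-selected K.
#'
#' @param spec a [synthetic_spec()].
#' @param config a [fit_config()] for the refits.
#' @param n_reps number of replicates.
#' @param master_seed replicate i simulates with seed `master_seed + i`.
#' @param scan_K optional K range for a BIC selection scan per replicate.
#' @return list with `reps` (per-replicate data frame) and `summary`
#'   (medians; `selected_K_table` when scanning).
#' @export
recovery_experiment <- function(spec, config = fit_config(), n_reps = 20L,
                                master_seed = 1L, scan_K = NULL) {
  .assert(n_reps >= 1, "need at least one replicate")
  zip <- !is.null(spec$structural_zero)
  mode <- spec$gate$mode
  true_model <- poismix_model(spec$components, .true_weights(spec),
                              zero_inflated = zip)
  rows <- lapply(seq_len(n_reps), function(i) {
    spec_i <- spec
    spec_i$seed <- master_seed + i
    sim <- simulate_dataset(spec_i)
    cfg <- config
    cfg$seed <- master_seed + 1000L * i
    fitter <- if (zip) fit_zip else fit_em
    fit <- tryCatch(
      suppressWarnings(fitter(sim$data, spec$K, mode = mode, config = cfg)),
      error = function(e) e)
    if (inherits(fit, "condition")) {
      return(data.frame(rep = i, ok = FALSE, coef_mae = NA, gate_err = NA,
                        ari = NA, structural_prop = NA,
                        selected_K = NA, loglik = NA))
    }
    truth_aligned <- .align_to_rate_order(true_model, sim$data)
    coef_mae <- mean(abs(.coef_matrix(fit$components) -
                           .coef_matrix(truth_aligned$components)))
    gate_err <- if (mode == "concomitant") {
      mean(abs(.gate_matrix(fit$weights) -
                 .gate_matrix(truth_aligned$weights)))
    } else {
      mean(abs(fit$weights$pi - truth_aligned$weights$pi))
    }
    cls <- posterior_classify(fit, sim$data)
    ari <- mclust::adjustedRandIndex(cls$labels, sim$truth$labels)
    structural_prop <- if (zip) {
      mean(structural_zero_probability(fit, sim$data$W))
    } else {
      NA_real_
    }
    selected_K <- if (!is.null(scan_K)) {
      tab <- tryCatch(
        scan_components(sim$data, scan_K, mode = mode, config = cfg,
                        zero_inflated = zip),
        error = function(e) NULL)
      if (is.null(tab)) NA_integer_ else tab$K[tab$model_tag ==
                                                 attr(tab, "best_by_bic")]
    } else {
      NA_integer_
    }
    data.frame(rep = i, ok = TRUE, coef_mae = coef_mae, gate_err = gate_err,
               ari = ari, structural_prop = structural_prop,
               selected_K = selected_K, loglik = fit$fit$loglik)
  })
  reps <- do.call(rbind, rows)
  okr <- reps[reps$ok, , drop = FALSE]
  summary <- list(
    n_reps = n_reps, n_failed = sum(!reps$ok),
    median_coef_mae = median(okr$coef_mae),
    median_gate_err = median(okr$gate_err),
    median_ari = median(okr$ari),
    median_structural_prop = if (zip) median(okr$structural_prop) else NULL,
    selected_K_table = if (!is.null(scan_K)) table(okr$selected_K) else NULL
  )
  list(reps = reps, summary = summary)
}

# permute a true model's components with the same decreasing-mean-rate rule
# the fitter uses, so fitted and true parameters are comparable
.align_to_rate_order <- function(model, data) {
  lam <- component_rates(data$X, model$components)
  ord <- order(colMeans(lam), decreasing = TRUE)
  if (identical(ord, seq_len(model$K))) model else
    .permute_components(model, ord)
}

#' @importFrom stats median
NULL
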