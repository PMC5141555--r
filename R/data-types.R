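#' Bundle a count response with its design blocks
#'
#' Container for one modelling problem: a vector of nonnegative integer
#' counts `y`, a component design block `X` (drives the class-specific
#' Poisson rates) and a gate design block `W` (drives the mixing weights in
#' concomitant-variable models).  Both blocks carry a leading intercept
#' column of ones; the two covariate sets may overlap partially or fully,
#' and by default `W = X`.
#'
#' @param y numeric vector of nonnegative integer counts.
#' @param X numeric matrix (or data frame) of component covariates; an
#'   intercept column is prepended when the first column is not identically 1.
#' @param W gate covariate block, same convention; defaults to `X`.
#' @param row_ids optional labels carried through to reports.
#' @return an object of class `count_dataset` with elements `y`, `X`, `W`,
#'   `row_ids`.
#' @examples
#' d <- count_dataset(rpois(20, 2), matrix(rnorm(20), ncol = 1))
#' dim(d$X)
#' @export
count_dataset <- function(y, X, W = NULL, row_ids = NULL) {
  y <- as.numeric(y)
  .assert(length(y) > 0L, "empty response vector")
  .assert(all(is.finite(y)), "response contains non-finite values")
  .assert(all(y >= 0 & y == round(y)),
          "response must contain nonnegative integers")
  X <- .design_block(X, length(y), "X")
  W <- if (is.null(W)) X else .design_block(W, length(y), "W")
  if (is.null(row_ids)) row_ids <- seq_along(y)
  .assert(length(row_ids) == length(y), "row_ids length mismatch")
  structure(list(y = y, X = X, W = W, row_ids = row_ids),
            class = "count_dataset")
}

.design_block <- function(M, n, what) {
  if (is.data.frame(M)) M <- as.matrix(M)
  if (is.null(dim(M))) M <- matrix(M, ncol = 1L)
  storage.mode(M) <- "double"
  .assert(nrow(M) == n, sprintf("%s has %d rows, response has %d",
                                what, nrow(M), n))
  .assert(all(is.finite(M)), sprintf("%s contains non-finite entries", what))
  if (ncol(M) == 0L || !all(M[, 1L] == 1)) {
    M <- cbind(`(Intercept)` = rep(1, n), M)
  }
  if (is.null(colnames(M))) {
    colnames(M) <- c("(Intercept)",
                     if (ncol(M) > 1L) paste0("x", seq_len(ncol(M) - 1L)))
  }
  colnames(M)[1L] <- "(Intercept)"
  blank <- colnames(M) == "" | is.na(colnames(M))
  colnames(M)[blank] <- paste0("x", which(blank) - 1L)
  M
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: n = %d, %d component covariate(s), %d gate covariate(s)\n",
              length(x$y), ncol(x$X) - 1L, ncol(x$W) - 1L))
  cat(sprintf("  response: mean %.3f, var %.3f, %d zero(s)\n",
              mean(x$y), stats::var(x$y), sum(x$y == 0)))
  invisible(x)
}

#' Component regression coefficients
#'
#' Per-component coefficients of the log-linear Poisson rates:
#' `beta0[k]` is the intercept of component k and `beta[k, ]` its covariate
#' coefficients, all on the log-rate scale.
#'
#' @param beta0 numeric vector of K intercepts.
#' @param beta K x p coefficient matrix (may have zero columns for
#'   intercept-only models).
#' @return object of class `component_params`.
#' @export
component_params <- function(beta0, beta = NULL) {
  beta0 <- as.numeric(beta0)
  K <- length(beta0)
  .assert(K >= 1L, "need at least one component")
  if (is.null(beta)) beta <- matrix(0, K, 0L)
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = K)
  storage.mode(beta) <- "double"
  .assert(nrow(beta) == K, "beta must have one row per component")
  .assert(all(is.finite(beta0)) && all(is.finite(beta)),
          "coefficients must be finite")
  structure(list(beta0 = beta0, beta = beta, K = K, p = ncol(beta)),
            class = "component_params")
}

# canonical (1+p) x K coefficient matrix, intercept row first
.coef_matrix <- function(cp) {
  B <- rbind(cp$beta0, t(cp$beta))
  rn <- colnames(cp$beta)
  rownames(B) <- c("(Intercept)", rn %||% if (cp$p) paste0("x", seq_len(cp$p)))
  colnames(B) <- paste0("comp", seq_len(cp$K))
  B
}

#' Fixed mixing proportions
#'
#' Weight model for the standard mixture: every observation shares the same
#' prior probability vector `pi`.
#'
#' @param pi length-K probability vector (nonnegative, sums to 1).
#' @return object of class `weight_model`, mode `"fixed"`.
#' @export
fixed_weights <- function(pi) {
  pi <- as.numeric(pi)
  .assert(all(pi >= 0), "pi entries must be nonnegative")
  .assert(abs(sum(pi) - 1) < 1e-10, "pi must sum to 1 (tolerance 1e-10)")
  structure(list(mode = "fixed", pi = pi, K = length(pi)),
            class = "weight_model")
}

#' Concomitant-variable (multinomial logit) gate
#'
#' Weight model in which class membership depends on gate covariates through
#' a softmax: \eqn{\pi_{ik} \propto \exp(\gamma_{0k} + w_i'\gamma_k)}.  The
#' reference category (`ref`, the first by default) has its coefficients
#' fixed at zero for identification.
#'
#' @param gamma0 length-K vector of gate intercepts.
#' @param gamma K x q gate coefficient matrix.
#' @param ref reference category index (coefficients must be exactly zero).
#' @return object of class `weight_model`, mode `"concomitant"`.
#' @export
gate_weights <- function(gamma0, gamma = NULL, ref = 1L) {
  gamma0 <- as.numeric(gamma0)
  K <- length(gamma0)
  if (is.null(gamma)) gamma <- matrix(0, K, 0L)
  if (is.null(dim(gamma))) gamma <- matrix(gamma, nrow = K)
  storage.mode(gamma) <- "double"
  .assert(nrow(gamma) == K, "gamma must have one row per category")
  .assert(all(is.finite(gamma0)) && all(is.finite(gamma)),
          "gate coefficients must be finite")
  .assert(gamma0[ref] == 0 && all(gamma[ref, ] == 0),
          "reference category coefficients must be exactly zero")
  structure(list(mode = "concomitant", gamma0 = gamma0, gamma = gamma,
                 K = K, q = ncol(gamma), ref = as.integer(ref)),
            class = "weight_model")
}

# (1+q) x K gate coefficient matrix, intercept row first
.gate_matrix <- function(wm) {
  G <- rbind(wm$gamma0, t(wm$gamma))
  rownames(G) <- c("(Intercept)",
                   colnames(wm$gamma) %||% if (wm$q) paste0("w", seq_len(wm$q)))
  G
}

#' Assemble a Poisson mixture regression model
#'
#' Builds an (unfitted or fitted) model object from component coefficients
#' and a weight model.  For zero-inflated models the weight model covers
#' K + 1 categories, the first being the structural component degenerate at
#' zero (no rate parameters of its own).
#'
#' @param components a [component_params()] object (K count components).
#' @param weights a [fixed_weights()] or [gate_weights()] object over K
#'   categories (K + 1 when `zero_inflated`).
#' @param zero_inflated add a structural zero component?
#' @param fit optional fit metadata list (filled by [fit_em()]).
#' @return object of class `poismix`.
#' @export
poismix_model <- function(components, weights, zero_inflated = FALSE,
                          fit = NULL) {
  .assert(inherits(components, "component_params"), "bad components")
  .assert(inherits(weights, "weight_model"), "bad weights")
  K <- components$K
  ncat <- K + as.integer(zero_inflated)
  .assert(weights$K == ncat,
          sprintf("weight model covers %d categories, expected %d",
                  weights$K, ncat))
  structure(list(K = K, components = components, weights = weights,
                 zero_inflated = isTRUE(zero_inflated), link = "log",
                 fit = fit),
            class = "poismix")
}

.category_names <- function(model) {
  nm <- paste0("comp", seq_len(model$K))
  if (model$zero_inflated) nm <- c("zero", nm)
  nm
}

#' @export
print.poismix <- function(x, digits = 4, ...) {
  kind <- if (x$zero_inflated) "zero-inflated Poisson mixture regression"
          else "Poisson mixture regression"
  gate <- if (x$weights$mode == "fixed") "fixed weights" else "concomitant gate"
  cat(sprintf("%s: K = %d count component(s), %s\n", kind, x$K, gate))
  cat("Component coefficients (log-rate scale):\n")
  print(round(.coef_matrix(x$components), digits))
  if (x$weights$mode == "fixed") {
    cat("Mixing proportions:", paste(round(x$weights$pi, digits),
                                     collapse = " "), "\n")
  } else {
    cat("Gate coefficients (multinomial logit, reference category",
        x$weights$ref, "):\n")
    G <- .gate_matrix(x$weights)
    colnames(G) <- .category_names(x)
    print(round(G, digits))
  }
  if (!is.null(x$fit)) {
    cat(sprintf("log-likelihood %.4f on %d parameter(s), n = %d, %s in %d iteration(s)\n",
                x$fit$loglik, count_parameters(x), x$fit$n_obs,
                if (isTRUE(x$fit$converged)) "converged" else "NOT converged",
                x$fit$n_iter))
  }
  invisible(x)
}
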