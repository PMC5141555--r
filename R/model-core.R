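#' Poisson log probability mass
#'
#' Elementwise log density \eqn{y \log\lambda - \lambda - \log y!} of the
#' Poisson distribution.  Values of `y` outside the support (negative or
#' non-integer) get `-Inf`, realizing the indicator on the nonnegative
#' integers; downstream log-sum-exp arithmetic tolerates the floor.
#'
#' @param y numeric vector of counts (recycled against `lam`).
#' @param lam positive rate vector.
#' @return vector of log probabilities.
#' @examples
#' poisson_log_pmf(0, 1)   # -1
#' poisson_log_pmf(2, 2)   # log(2) - 2
#' @export
poisson_log_pmf <- function(y, lam) {
  .assert(is.numeric(y) && all(is.finite(y)), "y must be finite numeric")
  .assert(is.numeric(lam) && all(is.finite(lam)) && all(lam > 0),
          "lam must be finite and strictly positive")
  out <- y * log(lam) - lam - lgamma(y + 1)
  out[y < 0 | y != round(y)] <- -Inf
  out
}

#' Component-specific Poisson rates
#'
#' Evaluates \eqn{\lambda_{ik} = \exp(\beta_{0k} + x_i'\beta_k)} for every
#' observation and component.  The linear predictor is clipped at
#' `+/- clip` before exponentiation to guard against overflow.
#'
#' @param X component design block (leading intercept column).
#' @param params a [component_params()] object.
#' @param clip clipping bound for the linear predictor (default 30).
#' @return n x K matrix of positive rates.
#' @export
component_rates <- function(X, params, clip = 30) {
  B <- .coef_matrix(params)
  .assert(ncol(X) == nrow(B),
          sprintf("design block has %d columns, coefficients expect %d",
                  ncol(X), nrow(B)))
  exp(.clip(X %*% B, clip))
}

#' Prior membership probabilities
#'
#' Row-wise prior class probabilities implied by a weight model.  In
#' concomitant mode these are the multinomial-logit gate probabilities
#' \eqn{\pi_{ik} = \exp(\gamma_{0k} + w_i'\gamma_k)/\sum_h \exp(\gamma_{0h} + w_i'\gamma_h)}
#' (computed with max subtraction); in fixed mode the constant `pi` vector
#' is broadcast to every row.
#'
#' @param W gate design block.
#' @param weights a `weight_model`.
#' @return n x K matrix with rows summing to 1.
#' @export
concomitant_weights <- function(W, weights) {
  .assert(inherits(weights, "weight_model"), "bad weight model")
  if (weights$mode == "fixed") {
    P <- matrix(weights$pi, nrow(W), weights$K, byrow = TRUE)
  } else {
    G <- .gate_matrix(weights)
    .assert(ncol(W) == nrow(G),
            sprintf("gate block has %d columns, gate expects %d",
                    ncol(W), nrow(G)))
    P <- .softmax_rows(W %*% G)
  }
  colnames(P) <- NULL
  P
}

# n x C log-density matrix over all categories (structural zero first when
# zero-inflated) and matching n x C prior matrix
.loglik_parts <- function(data, model) {
  lam <- component_rates(data$X, model$components)
  logf <- matrix(poisson_log_pmf(rep(data$y, model$K), as.vector(lam)),
                 ncol = model$K)
  if (model$zero_inflated) {
    logf <- cbind(ifelse(data$y == 0, 0, -Inf), logf)
  }
  P <- concomitant_weights(data$W, model$weights)
  list(logf = logf, logpi = log(P), P = P, lam = lam)
}

#' Observed-data log-likelihood of a mixture model
#'
#' \eqn{\sum_i \log \sum_k \pi_{ik} f(y_i \mid \lambda_{ik})}, evaluated in
#' log space with log-sum-exp.  For zero-inflated models the structural
#' component contributes its gate mass on observations with `y = 0`.
#'
#' @param data a [count_dataset()].
#' @param model a [poismix_model()].
#' @return scalar log-likelihood.
#' @export
mixture_log_likelihood <- function(data, model) {
  .assert(inherits(data, "count_dataset") && length(data$y) > 0L,
          "empty or invalid dataset")
  parts <- .loglik_parts(data, model)
  sum(.row_logsumexp(parts$logpi + parts$logf))
}

#' Mixture mean, variance and excess-variance decomposition
#'
#' Per observation, the marginal mean \eqn{\mu_i = \sum_k \pi_{ik}\lambda_{ik}},
#' the between-component excess
#' \eqn{v_i = \sum_k \pi_{ik}\lambda_{ik}^2 - \mu_i^2 \ge 0}, and the
#' marginal variance \eqn{\mu_i + v_i}.  `v` is zero exactly when all
#' component rates for the row coincide, so positive `v` is the mixture's
#' overdispersion relative to a single Poisson.  The structural component of
#' zero-inflated models enters as a degenerate rate of 0.
#'
#' @param model a `poismix` model.
#' @param X,W design blocks to evaluate at.
#' @return data frame with columns `mean`, `v`, `var`.
#' @export
mixture_moments <- function(model, X, W = X) {
  lam <- component_rates(X, model$components)
  if (model$zero_inflated) lam <- cbind(0, lam)
  P <- concomitant_weights(W, model$weights)
  mu <- rowSums(P * lam)
  v <- pmax(rowSums(P * lam^2) - mu^2, 0)
  data.frame(mean = mu, v = v, var = mu + v)
}

#' Rate ratios (exponentiated coefficients)
#'
#' Exponentiates the component coefficients, giving the multiplicative
#' change in the component's event rate per unit increase of each covariate
#' — the usual reporting scale for Poisson regression.  Optionally also
#' exponentiates the gate coefficients (odds-ratio scale for membership).
#'
#' @param model a `poismix` model.
#' @param gate also return exponentiated gate coefficients?
#' @return data frame, covariates x components; with `gate = TRUE`, a list
#'   with elements `rates` and `gate`.
#' @export
rate_ratios <- function(model, gate = FALSE) {
  RR <- as.data.frame(exp(.coef_matrix(model$components)))
  if (!gate) return(RR)
  G <- if (model$weights$mode == "concomitant") {
    g <- as.data.frame(exp(.gate_matrix(model$weights)))
    names(g) <- .category_names(model)
    g
  }
  list(rates = RR, gate = G)
}
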