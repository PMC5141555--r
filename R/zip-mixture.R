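#' E-step of the zero-inflated Poisson mixture
#'
#' Identical to [e_step()] but asserts the model carries a structural-zero
#' component.  For positive counts the structural responsibility is exactly
#' zero and the remaining columns are the ordinary mixture posteriors over
#' the count components; for zeros the structural category competes with
#' each component's \eqn{e^{-\lambda_{ik}}}.
#'
#' @param data a [count_dataset()].
#' @param model a zero-inflated `poismix` model.
#' @return list with `tau` (n x (K+1); column 1 structural) and `loglik`.
#' @export
zip_e_step <- function(data, model) {
  .assert(isTRUE(model$zero_inflated), "model has no structural-zero component")
  e_step(data, model)
}

#' Fit a zero-inflated Poisson mixture regression (ZIPMR)
#'
#' Adds a structural component degenerate at zero to the K-component Poisson
#' mixture and fits by EM.  The structural component has no rate parameters;
#' it enters only through the gate, which is a single multinomial over the
#' K + 1 categories (structural, component 1, ..., component K) with the
#' first count component as reference.  Observed zeros are thus explained by
#' two routes: structural membership or a small Poisson rate.
#'
#' @param data a [count_dataset()]; should contain at least one zero (if it
#'   does not, the structural component is unidentified: a warning is issued
#'   and [fit_em()] is returned instead).
#' @param K number of count components.
#' @param mode `"concomitant"` (default) or `"standard"`/`"fixed"`.
#' @param config a [fit_config()].
#' @return fitted `poismix` model with `zero_inflated = TRUE`.
#' @export
fit_zip <- function(data, K, mode = c("concomitant", "standard", "fixed"),
                    config = fit_config()) {
  mode <- .normalize_mode(mode)
  if (!any(data$y == 0)) {
    warning("no zeros in the response; structural component unidentified, ",
            "fitting a plain mixture instead")
    return(.fit_mixture(data, K, mode, zip = FALSE, config = config))
  }
  .fit_mixture(data, K, mode, zip = TRUE, config = config)
}

#' Per-observation structural-zero probability
#'
#' The gate's prior mass on the structural component degenerate at zero,
#' i.e. the modelled probability that an observation is a "true" zero
#' (never at risk) rather than a sampled Poisson zero.
#'
#' @param model fitted zero-inflated `poismix` model.
#' @param W gate design block to evaluate at.
#' @return numeric vector in (0, 1).
#' @export
structural_zero_probability <- function(model, W) {
  .assert(isTRUE(model$zero_inflated), "model has no structural-zero component")
  concomitant_weights(W, model$weights)[, 1L]
}
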