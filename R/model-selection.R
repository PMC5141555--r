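# parameter-count convention: K free coefficient vectors of length 1+p,
# plus K-1 free gate categories (each 1+q coefficients when concomitant,
# one proportion when fixed), plus one extra free gate category when a
# structural-zero component is present
.df_formula <- function(K, p, q, mode, zip) {
  comp <- K * (1L + p)
  gate_cats <- (K - 1L) + as.integer(zip)
  gate <- if (mode == "concomitant") gate_cats * (1L + q) else gate_cats
  comp + gate
}

#' Number of free parameters
#'
#' Component block `K (1 + p)` plus gate block: `(K - 1)(1 + q)` free gate
#' categories in concomitant mode or `K - 1` free proportions in fixed mode,
#' with one extra gate category when the model is zero-inflated.
#'
#' @param model a `poismix` model.
#' @return integer degrees of freedom.
#' @export
count_parameters <- function(model) {
  p <- model$components$p
  q <- if (model$weights$mode == "concomitant") model$weights$q
       else model$fit$q %||% 0L
  .df_formula(model$K, p, q, model$weights$mode, model$zero_inflated)
}

#' @export
logLik.poismix <- function(object, ...) {
  .assert(!is.null(object$fit) && is.finite(object$fit$loglik),
          "model has not been fitted")
  structure(object$fit$loglik, df = count_parameters(object),
            nobs = object$fit$n_obs, class = "logLik")
}

#' @export
nobs.poismix <- function(object, ...) {
  .assert(!is.null(object$fit), "model has not been fitted")
  object$fit$n_obs
}

#' Integrated completed likelihood criterion
#'
#' `ICL = BIC + 2 E`, where `E = -sum_ik tau_ik log tau_ik` is the entropy
#' of the posterior responsibilities (with `0 log 0 = 0`).  The entropy
#' penalty favours well-separated components: ICL equals BIC exactly when
#' every observation is classified with certainty.
#'
#' @param model fitted `poismix` model.
#' @param data optional [count_dataset()]; when omitted the responsibilities
#'   stored at fit time are used.
#' @return scalar ICL value (always `>= BIC`).
#' @export
icl <- function(model, data = NULL) {
  tau <- if (is.null(data)) model$fit$tau else e_step(data, model)$tau
  .assert(!is.null(tau), "no responsibilities available; pass data")
  BIC(model) + 2 * .posterior_entropy(tau)
}

.posterior_entropy <- function(tau) {
  tl <- tau * log(tau)
  tl[tau == 0] <- 0
  -sum(tl)
}

#' Scan candidate component counts
#'
#' Fits the model for every K in `K_range` (K = 1 being the GLM baseline)
#' and tabulates degrees of freedom, log-likelihood, AIC, BIC and ICL.  The
#' BIC-minimizing model is marked as best (ties to the smaller K); failed or
#' degenerate fits are recorded with `NA` criteria and never win.
#'
#' @param data a [count_dataset()].
#' @param K_range integer vector of candidate component counts.
#' @param mode `"concomitant"`, `"standard"`/`"fixed"`.
#' @param config a [fit_config()]; candidate K uses seed
#'   `config$seed + 131 K` so the scan is reproducible as a whole.
#' @param zero_inflated scan ZIPMR models instead?
#' @param intercept_only drop all component covariates (plain mixture scan)?
#' @return a `selection_table` data frame; attributes `best_by_bic` (tag)
#'   and `models` (the fitted objects).
#' @export
scan_components <- function(data, K_range, mode = c("concomitant",
                                                    "standard", "fixed"),
                            config = fit_config(), zero_inflated = FALSE,
                            intercept_only = FALSE) {
  .assert(length(K_range) > 0, "empty K range")
  mode <- .normalize_mode(mode)
  K_range <- sort(unique(as.integer(K_range)))
  if (intercept_only) {
    data <- count_dataset(data$y,
                          matrix(1, length(data$y), 1L,
                                 dimnames = list(NULL, "(Intercept)")),
                          data$W, row_ids = data$row_ids)
  }
  base <- config$seed %||% 1L
  models <- list()
  rows <- lapply(K_range, function(K) {
    cfg <- config
    cfg$seed <- base + 131L * K
    fitter <- if (zero_inflated) fit_zip else fit_em
    m <- tryCatch(suppressWarnings(fitter(data, K, mode = mode, config = cfg)),
                  error = function(e) e)
    tag <- paste0(if (zero_inflated) "zip_", mode, "_K", K)
    if (inherits(m, "condition")) {
      return(data.frame(model_tag = tag, K = K, mode = mode,
                        zero_inflated = zero_inflated, df = NA_integer_,
                        loglik = NA_real_, AIC = NA_real_, BIC = NA_real_,
                        ICL = NA_real_, converged = FALSE))
    }
    models[[tag]] <<- m
    data.frame(model_tag = tag, K = K, mode = mode,
               zero_inflated = zero_inflated, df = count_parameters(m),
               loglik = m$fit$loglik, AIC = AIC(m), BIC = BIC(m),
               ICL = icl(m), converged = m$fit$converged)
  })
  tab <- do.call(rbind, rows)
  .assert(any(!is.na(tab$BIC)), "every candidate K failed to fit",
          class = "poismix_fit_failure")
  ord <- order(tab$BIC, tab$K)   # ties to smaller K
  attr(tab, "best_by_bic") <- tab$model_tag[ord[1L]]
  attr(tab, "models") <- models
  attr(tab, "data") <- data   # possibly intercept-only; used downstream
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' @export
print.selection_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  cat("best by BIC:", attr(x, "best_by_bic"), "\n")
  invisible(x)
}

#' Pull the BIC-best fitted model out of a scan
#'
#' @param table a `selection_table` from [scan_components()].
#' @return the fitted `poismix` model minimizing BIC.
#' @export
best_model <- function(table) {
  attr(table, "models")[[attr(table, "best_by_bic")]]
}

#' Dispersion diagnostic for a count response
#'
#' Sample mean and variance of the response with the variance/mean ratio;
#' under a homogeneous Poisson model the ratio is 1, so ratios outside the
#' equi-dispersion band motivate mixture (over) or point to under-dispersion.
#'
#' @param y numeric count vector or a [count_dataset()].
#' @param band equi-dispersion band on the ratio (default `[0.9, 1.1]`).
#' @return list with `mean`, `variance`, `ratio`, `verdict` in
#'   `"under"`, `"equi"`, `"over"`.
#' @export
dispersion_check <- function(y, band = c(0.9, 1.1)) {
  if (inherits(y, "count_dataset")) y <- y$y
  .assert(length(y) >= 2, "need at least two observations")
  m <- mean(y)
  v <- var(y)
  ratio <- if (m == 0 || v == 0) 0 else v / m
  verdict <- if (ratio < band[1L]) "under"
             else if (ratio > band[2L]) "over" else "equi"
  list(mean = m, variance = v, ratio = ratio, verdict = verdict)
}
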