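# poismix

Model-based clustering of count outcomes with **finite mixtures of Poisson
regressions**, built for heart-disease risk stratification on tables shaped
like the classical Cleveland heart-disease data (a 0–4 angiographic disease
status as the count response plus 13 mixed clinical covariates), and for
any comparable count-response problem.

A population is modelled as K latent classes, each a log-linear Poisson
regression:

    f(y_i) = Σ_k π_ik · Pois(y_i; λ_ik),    log λ_ik = β_0k + x_i' β_k

with three weight models:

* **standard** — fixed mixing proportions π_k;
* **concomitant** — class membership depends on covariates through a
  multinomial-logit gate, π_ik ∝ exp(γ_0k + w_i' γ_k) (component 1 is the
  reference category);
* **zero-inflated (ZIPMR)** — one extra component degenerate at zero,
  sharing the same gate, separating structural ("never at risk") zeros
  from sampled Poisson zeros.

Models are fitted by multi-restart EM (weighted IRLS for the component
regressions, Newton iterations for the gate), the number of components is
chosen by AIC/BIC/ICL scans, uncertainty comes from a case-resampling
bootstrap, and separation is diagnosed with posterior-probability
rootograms.  A synthetic-data generator reproduces the exact statistical
structure the models assume — including a Cleveland-like 13-covariate
schema — so the whole pipeline is testable without any download.

## Worked example

Simulate a 303-row Cleveland-like table with a structural no-disease class
and run the full pipeline:

```r
library(poismix)
sim <- simulate_dataset(cleveland_like_spec(n = 303, zero_inflated = TRUE,
                                            seed = 11))
report <- run_analysis(sim$data, K_range = 1:3, seed = 4,
                       config = fit_config(seed = 4, n_restarts = 3))
print(report)
```

```
== poismix analysis report ==
n = 303 observations
dispersion: mean 0.634, var 1.710, ratio 2.698 (over-dispersed)

Best model per class (by BIC):
        class          model_tag K        mode zero_inflated df    loglik
 no_covariate           fixed_K2 2       fixed         FALSE  3 -306.4928
     standard           fixed_K2 2       fixed         FALSE 29 -268.6392
  concomitant     concomitant_K2 2 concomitant         FALSE 42 -260.5089
          zip zip_concomitant_K1 1 concomitant          TRUE 28 -282.4600
      AIC      BIC      ICL converged
 618.9857 630.1269 730.0065      TRUE
 595.2785 702.9767 911.9733      TRUE
 605.0178 760.9946 963.4844      TRUE
 620.9200 724.9045 867.8000      TRUE

[no_covariate] fixed_K2: sizes 49/254, priors 0.217/0.783, separation 0.891
[standard] fixed_K2: sizes 236/67, priors 0.646/0.354, separation 0.630
[concomitant] concomitant_K2: sizes 120/183, priors 0.427/0.573, separation 0.637
[zip] zip_concomitant_K1: sizes 215/88, priors 0.628/0.372, separation 0.799
```

Reading the output: the response is over-dispersed (variance/mean 2.7), so
a single Poisson GLM is inadequate and every class of mixture improves on
it.  Each line under "Best model per class" is the BIC-chosen member of
that class; `sizes` are hard-classified cluster sizes (for the ZIP model
the first cluster is the structural no-disease class), `priors` the mean
gate weights, and `separation` the fraction of observations classified
with posterior above 0.8.  `rate_ratios(model)` returns the exponentiated
coefficients — the multiplicative change in a component's event rate per
unit covariate — which is how risk factors are compared per cluster.

Real files work the same way: `run_analysis("cleveland.csv", ...)` parses
the canonical comma-delimited 14-column layout with `?` for missing cells
and applies complete-case deletion (both row counts are reported).

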