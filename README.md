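# nutrimoe

Diet-gated mixture-of-experts models for microbiome–disease analysis.

## What problem this solves

Cohort studies of the gut microbiome routinely fit one classifier of
health state to everyone. But the microbiome–disease relationship is often
*heterogeneous*: a taxon that predicts disease under one long-term dietary
pattern can be uninformative, or point the other way, under another.
`nutrimoe` is for researchers who suspect such diet-driven heterogeneity
and want to (i) discover the latent subcohorts ("nutritional ecotypes"),
(ii) fit a separate sparse microbiome classifier inside each one, and
(iii) read off which taxa are diet-specific signatures of disease.

## The model

A softmax **gating network** on the nutrient-intake vector
`w` assigns each sample latent-class probabilities
`π_k = exp(w'γ_k) / Σ_j exp(w'γ_j)`; within class `k`, a sparse logistic
**expert** on the transformed abundance profile `x^(l)` at taxonomic level
`l` models the outcome, giving the mixture

    P_l(Y = 1 | x, w) = Σ_k π_k(w) · σ(x' β_k^(l)).

Both networks carry elastic-net penalties
`φ(λ, α, β) = λ[α‖β‖₁ + ½(1−α)‖β‖₂²]`, and all taxonomic levels share one
gating network, so every sample has a coherent latent class across ranks.
The regularized log-likelihood (sum over levels of the penalized marginal
mixture log-likelihood) is maximized by an EM algorithm whose M-steps are
proximal-Newton solvers with coordinate-wise soft-thresholding, started
from a spectral pre-classification based on the diet × outcome-weighted
microbiome cross-moment matrix. Preprocessing (total-sum scaling,
core-taxon filtering, arcsine-square-root transform, z-scoring, derived
energy-ratio nutrition features), a synthetic multi-level data generator,
a naive two-stage baseline, bootstrap differential-abundance intervals,
ARI / LOOCV-AUC evaluation and five-way signature categorization are all
included. The methods vignette
(`vignettes/diet-gated-mixture-of-experts.Rmd`) documents the model,
algorithms and design choices in detail.

## Worked example

```r
library(nutrimoe)

sim <- simulate_ecotypes(sim_config(n = 250, p = 24, q = 8, eta = 0.3,
                                    levels = c(8, 24), n_signal_gating = 3,
                                    n_signal_expert = 10, seed = 12))
tr <- split_half(sim)$train

fit <- nutrimoe(tr$data$W, tr$data$X, tr$data$y, K = 2, seed = 21)
print(fit)
#> nutrimoe fit: K = 2 latent classes, 2 level(s)
#>   class sizes: 125.4 / 124.6
#>   selected expert coefficients per level: level1=10, level2=33
#>   final rLL = -227.4529 after 49 EM iterations (converged)

adjusted_rand_index(fit$cluster, tr$z)
#> [1] 0.8906972
```

The printout says the fit found two latent classes of roughly 125 samples
each (soft sizes), kept 10 + 33 nonzero expert coefficients across the
two taxonomic levels after elastic-net shrinkage, and converged in 49 EM
iterations. The adjusted Rand index of 0.89 measures agreement between the
estimated classes and the generator's true ones (1 = perfect, 0 = chance).
`categorize_signatures(fit)` then labels every taxon by its diet
specificity (same/different direction across classes, one class only, or
not selected), and `predict(fit, W_new, X_new)` scores new samples.

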