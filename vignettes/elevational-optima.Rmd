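---
title: "Modelling species elevational optima from traits on a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling species elevational optima from traits on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis

Mountain floras sort species along steep elevation gradients. A species'
*elevational optimum* — the elevation at which its occurrence probability
peaks — summarizes where it performs best, and interspecific variation in
optima can be explained by functional traits: stature, growth form, stem
anatomy, tissue chemistry. `elevtrait` implements that analysis as a chain
of well-defined stages:

1. **Optima from occurrence records.** Presence/absence records along the
   gradient are fitted with the Huisman–Olff–Fresco (HOF) hierarchy of
   response curves; the selected curve's maximum gives the optimum, and
   threshold crossings give range limits (`hof()`, `estimate_optima()`).
2. **Trait–optimum models on a phylogeny.** Because related species are
   not independent, trait effects are estimated by phylogenetic
   generalized least squares (PGLS) with Pagel's λ fitted by maximum
   likelihood (`pgls()`).
3. **Sequential exhaustive-AIC selection.** Trait predictors are grouped
   into morphology, anatomy and physiology; within each category every
   predictor subset is fitted, the best-AIC model is kept and its
   predictors become covariates for the next category
   (`sequential_selection()`).
4. **Single-predictor screens** per habitat pool with Holm–Bonferroni
   family-wise error control (`single_predictor_scan()`), and a
   **phylogenetic PCA** of traits together with optima, minima and maxima,
   with growth forms passively projected as centroids (`phylo_pca()`).

A synthetic-data module (`simulate_study()`) generates the whole chain's
inputs with known ground truth, so each stage is validated by parameter
recovery rather than by fixture files.

# The response model for occurrences

The five classical HOF shapes are built from products of logistic terms in
standardized elevation $x \in [0,1]$ (ceiling $M$):

* I (flat): $y = M/(1+e^{a})$
* II (monotone): $y = M/(1+e^{a+bx})$
* III (plateau): $y = M/[(1+e^{a+bx})(1+e^{c})]$
* IV (symmetric unimodal): $y = M/[(1+e^{a+bx})(1+e^{c-bx})]$
* V (skewed unimodal): $y = M/[(1+e^{a+bx})(1+e^{c-dx})]$

Each shape is fitted to one species' binary records by maximizing the
Bernoulli log-likelihood. Numerical choices:

* Elevations are standardized to $[0,1]$ for optimizer conditioning; every
  reported quantity is back-transformed to metres. A constant shift of all
  elevations therefore shifts the optimum by the same amount.
* $M$ is fixed at 1: with binary data the ceiling is not identifiable
  jointly with the intercept $a$, which absorbs prevalence.
* Optimization is deterministic multi-start Nelder–Mead with a BFGS polish
  of the winning start. Model II starts on the grid
  $a \in \{-2,0,2\} \times b \in \{\pm 5, \pm 20\}$; III, IV and V receive
  *nested warm starts* from the best simpler fit (e.g. IV seeded at the
  best II parameters with $c = -15$, V at the best IV with $d = b$), which
  guarantees the maximized log-likelihoods respect the nesting order
  $\ell_V \ge \ell_{IV} \ge \ell_{II} \ge \ell_I$ up to optimizer
  tolerance.
* **Model choice** uses a parsimony rule: among models whose AIC lies
  within 2 of the minimum — "similar fit" by the usual ΔAIC < 2 convention
  — the one with fewest parameters is selected. Plain minimum-AIC would
  pick a spuriously non-flat curve on pure-noise data roughly a quarter of
  the time (each extra parameter is accepted whenever twice the
  log-likelihood gain exceeds 2, which random noise achieves with
  probability ≈ 0.16); the parsimony rule keeps flat data on model I
  essentially always while leaving strongly unimodal data on IV/V.
* The model IV optimum has the closed form $x^* = (c-a)/(2b)$; model V is
  maximized on a 1-m grid refined by golden-section search. Monotone fits
  (II/III) attain their supremum at a gradient edge and are flagged
  `"boundary"`; flat fits have no optimum. Range limits are the outermost
  elevations where the curve reaches `threshold_frac` (default 0.05) of
  its peak — the criterion behind published minima/maxima is rarely
  stated, so the fraction is an explicit, documented assumption.
* Boundary-flagged optima are edge-biased; downstream trait regressions
  can and should exclude them (the flags column exists for exactly that).

# PGLS with maximum-likelihood Pagel's λ

For response $y$ (the optimum) and design $X$ across $n$ species,

$$y = X\beta + \varepsilon,\qquad
  \varepsilon \sim \mathcal{N}\!\big(0,\ \sigma^2 V(\lambda)\big),$$

where $C$ is the Brownian covariance implied by the tree (shared
root-to-MRCA path lengths) and $V(\lambda)$ multiplies the off-diagonal of
$C$ by $\lambda$, keeping the diagonal: $\lambda = 0$ is phylogenetic
independence, $\lambda = 1$ the full Brownian expectation. $\beta$ and
$\sigma^2$ are profiled analytically via a Cholesky-whitened QR solve;
$\lambda$ maximizes the profile likelihood on $[0,1]$ by golden-section /
parabolic search with explicit endpoint evaluation, so boundary estimates
are reported as exactly 0 or 1.

Conventions that matter for comparability:

* **ML, not REML**, throughout — AIC comparisons across different
  fixed-effect sets require ML.
* The AIC parameter count is $k = \mathrm{ncol}(X) + 2$ (coefficients plus
  λ and σ²). Since λ and σ² appear in every candidate, ΔAIC between
  designs reduces to the usual 2-per-coefficient penalty.
* $R^2$ is computed on the $\hat\lambda$-whitened scale against the
  intercept-only GLS refitted at the same $\hat\lambda$; adjusted $R^2$
  applies the standard $(n-1)/(n-p-1)$ penalty with $p$ the number of
  non-intercept coefficients. There is no single canonical $R^2$ under
  GLS, so published percentages under a different convention can differ
  by a little.
* Coefficient standard errors use the unbiased residual variance
  ($\mathrm{RSS}/(n-p_{\mathrm{coef}})$) with $t$ tests on
  $n - p_{\mathrm{coef}}$ degrees of freedom.

# Sequential exhaustive-AIC selection

Categories run in a fixed order — morphology (Height, growth form),
anatomy (bark/xylem ratio, longevity, mechanical tissue, storage tissue,
ring width), physiology (LNC, LPC, LCC, RNC, RPC, δ¹⁵N, δ¹³C, fructan,
starch, free sugar) — reflecting the view that morphology conditions
anatomy, which conditions physiology. Within a category all $2^p$ subsets
(always joined with the covariates inherited from earlier stages) are
fitted with λ re-estimated by ML in every candidate; the lowest-AIC design
wins, with ties broken toward fewer predictors and then lexicographically.
Growth form is one predictor: its indicator block enters and leaves as a
unit.

A selected predictor's **importance** is the AIC of the best model among
all subsets that exclude it (a re-search, not a single drop-one refit)
minus the best AIC; a `drop_one` variant is available. Under exhaustive
search this importance is nonnegative by construction, so the rule
"a predictor whose omission improves the fit is not retained" can only
bind through numerical tolerance — it is implemented regardless. Subsets
within ΔAIC < 2 of the best are reported as near-ties so that predictors
shadowed by correlated alternatives remain visible.

Two behaviors of this procedure are worth knowing:

* Under a pure-noise response, exhaustive min-AIC still admits each noise
  predictor with probability ≈ 0.16, so the final model is *not* empty in
  a majority of null runs (on average ~1–2 weakly supported extras across
  seven candidates). This is a property of AIC itself, not of the
  implementation; the near-tie report and the importance values (small,
  < 2) are the tools for reading such extras correctly. We deliberately
  did not impose a stricter inclusion threshold, because the procedure
  this package mirrors retains predictors with importance well below 2.
* The cumulative adjusted-$R^2$ staircase across stages is reported as-is
  and is not forced monotone (complete-case $n$ can differ by stage).

# The single-predictor screen and habitat contrasts

Each trait is tested alone against the optimum within one habitat pool
(PGLS, ML λ; growth form via a likelihood-ratio comparison against the
intercept-only model). Raw two-sided p-values are Holm–Bonferroni
corrected within the habitat's family of tested traits; direction arrows
accompany slopes with raw p below α. Skewed predictors can be
square-root or log transformed first; the log rule substitutes exact
zeros with half of the second-smallest distinct value (so zero-containing
percent traits admit a log) and records the substitution. Which trait
gets which rule is configuration, not hard-coding, since such assignments
are dataset-specific.

Habitat contrasts of a trait (steppe vs alpine) default to a PGLS on a
habitat indicator — a phylogenetic two-group contrast — with an ordinary
Welch test available as a non-phylogenetic sensitivity check; the method
used is recorded in the result.

# Phylogenetic PCA

The GLS-estimated ancestral mean under $V(\hat\lambda)$ is removed, the
evolutionary covariance
$(X-\mathbf{1}\hat a^\top)^\top V(\hat\lambda)^{-1}(X-\mathbf{1}\hat a^\top)/(n-1)$
is eigendecomposed, and species scores are the centered data projected on
the eigenvectors. λ comes from the multivariate ML profile. Correlation
mode (standardize by the evolutionary SDs) is the default because the
trait table mixes units (cm, %, ‰, years); covariance mode is available
and labelled. Component signs follow a deterministic convention (largest
loading positive), and growth-form centroids are passive: they are means
of member species' scores and do not influence the decomposition.

# What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: 310 species (steppe
and alpine pools split at 4,200 m), 4,062 localities uniform on
2,650–6,150 m, symmetric unimodal occurrence curves with 700 m full width
at half maximum and peak presence probability 0.3 (≈ 95,000–105,000
presences in total), traits evolved on a unit-height Yule tree with
signal λ = 0.5, and linear trait effects (Height −10 m/cm, storage tissue
+8 m/%, ring width −250 m/mm, RNC +250 m/%, δ¹³C +70 m/‰, fructan
+15 m/%, longevity +8 m/yr; intercept 5,500 m; residual SD 300 m) chosen
once so the simulated optima span roughly 2,650–5,850 m with a slight
steppe majority. Percent traits are generated through a logistic link so
they respect [0,100]; growth form is a latent Brownian trait cut into
seven bins, so categories carry phylogenetic signal; optima falling
outside the gradient are clipped *and logged*.

Not emulated: spatial autocorrelation among localities, abundance
(counts), climate covariates, trait measurement error, and correlated
trait evolution (latents are independent). Passing recovery tests on
these data therefore demonstrates the estimators' correctness under the
stated model, not robustness to field-data pathologies such as spatially
clustered sampling or collinear trait suites.

# Problem sizes used in the test suite

The validation ensembles run at the sizes the analyses are designed for:
λ recovery on 200-tip trees over 100 replicates; HOF optimum recovery on
5,000-record species over 50 replicates; sequential-selection recovery on
150-species studies over 50 replicates; family-wise error calibration of
the Holm scan over 500 null replicates of 17 traits. The full
pipeline-level recovery (records → optima → selection) runs at 150
species and 400 localities over 2 replicates, one at λ = 0 and one at
λ = 1 — the per-stage ensembles above carry the statistical weight, and
the pipeline test checks the plumbing end to end.

# A worked example

```{r example}
library(elevtrait)

cfg <- sim_config(n_species = 150, n_localities = 1000, seed = 42)
study <- simulate_study(cfg)

optima <- estimate_optima(study$occurrences)
data <- study$traits[optima$species, ]
data$optimum_m <- optima$optimum_m

# exclude species whose fitted curve peaks at a gradient edge
keep <- !is.na(data$optimum_m) & !grepl("boundary", optima$flags)
pool <- droplevels(data[keep, ])
tree_p <- ape::keep.tip(study$tree, rownames(pool))

ledger <- sequential_selection(pool, tree_p)
print(ledger)

scan <- single_predictor_scan(pool, tree_p, habitat = "alpine")
pca <- phylo_pca(pool[, sapply(pool, is.numeric)], tree_p)
```

# Known limitations

* Missing species are a validation error, not a grafting problem: taxa
  absent from the tree must be resolved upstream.
* No Ornstein–Uhlenbeck or κ/δ branch-length transforms; no measurement
  error in the response; no interaction terms, cross-validation, or model
  averaging in the selection stage; no bootstrap intervals on optima.
* The range-limit threshold and the transform assignments are assumptions
  surfaced as parameters, because the conventions behind published
  minima/maxima and transformations are usually unstated.
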