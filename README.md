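# elevtrait

Functional traits and species elevational optima on phylogenies.

`elevtrait` is an R package for asking *which plant traits determine where
on a mountain gradient a species does best*. It targets the common study
design in alpine ecology: thousands of floristic presence/absence records
along an elevation gradient, a species-level trait table (morphology,
stem anatomy, tissue chemistry), and a phylogeny of the species pool. It
is aimed at comparative ecologists who want the full chain — occurrence
records to species optima to phylogenetically corrected multi-trait
models — in one tested, scriptable toolchain.

## What it computes

**Species elevational optima.** For each species, presence/absence
records along elevation are fitted with the Huisman–Olff–Fresco (HOF)
hierarchy of response curves, built from products of logistic terms on
standardized elevation *x*:

| type | shape | response |
|------|-------|----------|
| I   | flat               | M/(1+e^a) |
| II  | monotone           | M/(1+e^(a+bx)) |
| III | plateau            | M/[(1+e^(a+bx))(1+e^c)] |
| IV  | symmetric unimodal | M/[(1+e^(a+bx))(1+e^(c−bx))] |
| V   | skewed unimodal    | M/[(1+e^(a+bx))(1+e^(c−dx))] |

Each shape is fitted by Bernoulli maximum likelihood; the most
parsimonious model within ΔAIC < 2 of the best is selected. The optimum
is the response maximum (closed form (c−a)/(2b) for type IV), and range
limits are threshold crossings of the fitted curve.

**Trait → optimum models.** Interspecific models are phylogenetic
generalized least squares, y = Xβ + ε with ε ~ N(0, σ²V(λ)), where V(λ)
scales the off-diagonal Brownian covariance of the tree by Pagel's λ
(0 = independence, 1 = Brownian motion), and λ is estimated by maximum
likelihood on [0,1].

**Sequential exhaustive-AIC selection.** Predictors are grouped into
morphology → anatomy → physiology. Within each category all 2^p subsets
are fitted (λ re-estimated per candidate), the best-AIC model is kept,
and its predictors are carried forward as covariates for the next
category. Each selected predictor gets a ΔAIC-when-omitted importance
(re-searched over all excluding subsets), and near-tie subsets
(ΔAIC < 2) are reported.

**Screens and ordination.** Single-predictor PGLS scans per habitat with
Holm–Bonferroni family-wise error control and direction arrows;
phylogenetic habitat contrasts; phylogenetic PCA of traits plus
optima/minima/maxima with growth forms passively projected as centroids.

**Synthetic studies.** `simulate_study()` generates the whole input set
with known ground truth — Yule tree, λ-structured traits, linear
trait→optimum effects, unimodal occurrence curves — so every estimator in
the chain is validated by parameter recovery.

## A worked example

```r
library(elevtrait)

cfg <- sim_config(n_species = 150, n_localities = 1000, seed = 42)
study <- simulate_study(cfg)

optima <- estimate_optima(study$occurrences)
data <- study$traits[optima$species, ]
data$optimum_m <- optima$optimum_m
keep <- !is.na(data$optimum_m) & !grepl("boundary", optima$flags)
pool <- droplevels(data[keep, ])
tree_p <- ape::keep.tip(study$tree, rownames(pool))

sequential_selection(pool, tree_p)
```

```
Sequential exhaustive-AIC selection on optimum_m 

[morphology] 4 designs, n = 147
  selected: Height 
    dAIC when Height omitted: 39 
  adj. R2 = 27.6 % ( + 27.6 %)  lambda = 0 

[anatomy] 32 designs, n = 147
  selected: Longevity, Mechanical_tissue, Storage_tissue 
    dAIC when Longevity omitted: 4.45 
    dAIC when Mechanical_tissue omitted: 1.9 
    dAIC when Storage_tissue omitted: 31 
  adj. R2 = 46.7 % ( + 19.1 %)  lambda = 0 

[physiology] 1024 designs, n = 147
  selected: d13C, Fructan, RNC, RPC, Starch 
    dAIC when d13C omitted: 15.3 
    dAIC when Fructan omitted: 14.5 
    dAIC when RNC omitted: 8.79 
    dAIC when RPC omitted: 2.52 
    dAIC when Starch omitted: 3.7 
  adj. R2 = 61.1 % ( + 14.4 %)  lambda = 0 
```

Reading: taller plants sit lower on the gradient (Height is selected at
the morphology stage; removing it costs 39 AIC units), storage tissue
dominates the anatomy stage (ΔAIC 31), and root nitrogen, δ13C and
fructan carry the physiology stage, for a final adjusted R² of 61% with
no residual phylogenetic signal (λ = 0) once the traits are in the model.
That is the planted structure: the generator's default effects include
Height −10 m/cm, storage tissue +8 m/%, RNC +250 m/%, δ13C +70 m/‰ and
fructan +15 m/%, and optimum-noise SD 300 m. Species whose fitted curve
peaked at a gradient edge (`boundary` flag) were excluded, since their
optima are edge-biased.

`single_predictor_scan(pool, tree_p, habitat = "alpine")` produces the
per-trait table (slope, raw and Holm-adjusted p, direction), and
`phylo_pca()` the ordination with growth-form centroids. `run_pipeline()`
chains validation, optima, selection, scan and PCA and writes CSV/JSON
artifacts.

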