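# PGLS engine: Brownian covariance, lambda transform, GLS likelihood,
# R-squared conventions, and equivariance properties.

test_that("Brownian covariance matches path arithmetic and an MRCA oracle", {
  Cs <- bm_covariance(star_tree(5))
  expect_equal(unname(Cs), diag(5))

  C <- bm_covariance(sister_tree())
  expect_equal(C["A", "B"], 0.6)
  expect_equal(unname(diag(C)), c(1, 1, 1))

  for (seed in 1:5) {
    tr <- simulate_yule_tree(10, 1, seed = seed)
    expect_equal(bm_covariance(tr), vcv_oracle(tr), tolerance = 1e-12)
  }

  expect_error(bm_covariance(sister_tree(), c("A", "Z")), "Z")
})

test_that("lambda transform scales off-diagonals only", {
  C <- bm_covariance(sister_tree())
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(unname(lambda_transform(C, 0)), diag(diag(C)))
  expect_equal(lambda_transform(C, 0.5)["A", "B"], 0.3)
  expect_error(lambda_transform(C, -0.1), "lambda")
})

test_that("PGLS at lambda = 0 reproduces ordinary least squares", {
  tr <- simulate_yule_tree(30, 1, seed = 3)
  set.seed(4)
  d <- data.frame(
    x1 = rnorm(30), x2 = rnorm(30),
    row.names = tr$tip.label
  )
  d$y <- 1 + 2 * d$x1 - 0.5 * d$x2 + rnorm(30)
  fit <- pgls(y ~ x1 + x2, d, tr, lambda = 0)
  ols <- lm(y ~ x1 + x2, d)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-8)
  expect_equal(fit$se, summary(ols)$coefficients[, 2], tolerance = 1e-8)
  expect_equal(fit$r2, summary(ols)$r.squared, tolerance = 1e-8)
  expect_equal(fit$adj_r2, summary(ols)$adj.r.squared, tolerance = 1e-8)
})

test_that("PGLS agrees with an independent GLS implementation", {
  tr <- simulate_yule_tree(40, 1, seed = 6)
  set.seed(7)
  d <- data.frame(x = rnorm(40), row.names = tr$tip.label)
  d$y <- 2 + 3 * d$x + simulate_lambda_traits(tr, 0.7, 4, seed = 8)[[1]]
  d$sp <- rownames(d)
  fit <- pgls(y ~ x, d, tr, lambda = 0.7)
  ref <- nlme::gls(y ~ x,
    data = d,
    correlation = ape::corPagel(0.7, tr, form = ~sp, fixed = TRUE),
    method = "ML"
  )
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("profile likelihood peaks at the returned lambda", {
  tr <- simulate_yule_tree(60, 1, seed = 9)
  d <- data.frame(
    y = simulate_lambda_traits(tr, 0.6, 1, seed = 10)[[1]],
    row.names = tr$tip.label
  )
  fit <- pgls(y ~ 1, d, tr)
  C <- bm_covariance(tr, fit$species)
  grid_ll <- vapply(
    seq(0, 1, length.out = 101),
    function(l) elevtrait:::gls_profile(fit$residuals + fit$fitted.values,
      matrix(1, fit$n, 1), C, l
    )$logL,
    numeric(1)
  )
  expect_gte(fit$logLik, max(grid_ll) - 1e-6)
})

test_that("PGLS is equivariant to response units and centering", {
  pl <- sim_planted(n = 60, seed = 13)
  d <- pl$data
  fit_m <- pgls(optimum_m ~ Height, d, pl$tree)
  d$optimum_km <- d$optimum_m / 1000
  fit_km <- pgls(optimum_km ~ Height, d, pl$tree)
  expect_equal(fit_km$lambda, fit_m$lambda, tolerance = 1e-4)
  expect_equal(coef(fit_km)[["Height"]] * 1000, coef(fit_m)[["Height"]],
    tolerance = 1e-6
  )

  # AIC invariant to predictor centering/scaling
  d$Height_c <- scale(d$Height)[, 1]
  fit_c <- pgls(optimum_m ~ Height_c, d, pl$tree)
  expect_equal(fit_c$aic, fit_m$aic, tolerance = 1e-3)
})

test_that("slope recovery and lambda recovery on Brownian data", {
  # y = 2 + 3x + BM noise: slope within 3 Ses in most replicates and
  # lambda-hat near 1 (scaled-down version of the full recovery study)
  hits <- 0
  lams <- numeric(10)
  for (r in 1:10) {
    tr <- simulate_yule_tree(100, 1, seed = 100 + r)
    set.seed(200 + r)
    d <- data.frame(x = rnorm(100), row.names = tr$tip.label)
    d$y <- 2 + 3 * d$x +
      simulate_lambda_traits(tr, 1, 1, seed = 300 + r)[[1]]
    fit <- pgls(y ~ x, d, tr)
    hits <- hits + (abs(coef(fit)[["x"]] - 3) < 3 * fit$se[["x"]])
    lams[r] <- fit$lambda
  }
  expect_gte(hits, 9)
  expect_gte(median(lams), 0.8)
})

test_that("degenerate designs and inputs are rejected informatively", {
  tr <- simulate_yule_tree(20, 1, seed = 15)
  set.seed(16)
  d <- data.frame(x = rnorm(20), row.names = tr$tip.label)
  d$x2 <- 2 * d$x
  d$y <- rnorm(20)
  expect_error(pgls(y ~ x + x2, d, tr), "singular")
  d$x2 <- NULL
  d$y[1] <- Inf
  expect_error(pgls(y ~ x, d, tr), "non-finite")
})

test_that("adjusted R-squared follows the penalized formula", {
  expect_equal(adjusted_r2(0.5, n = 101, p = 2), 1 - 0.5 * 100 / 98)
  expect_equal(adjusted_r2(1, n = 20, p = 3), 1)
  expect_lte(adjusted_r2(0, n = 50, p = 4), 0)
  expect_warning(out <- adjusted_r2(0.5, n = 4, p = 3), "undefined")
  expect_true(is.na(out))
})

test_that("simulate and predict methods round-trip the model", {
  pl <- sim_planted(n = 50, seed = 17)
  fit <- pgls(optimum_m ~ Height, pl$data, pl$tree)
  sims <- simulate(fit, nsim = 3, seed = 18)
  expect_equal(dim(sims), c(50, 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 18))
  expect_equal(
    predict(fit, pl$data[1:5, , drop = FALSE]),
    fit$fitted.values[1:5]
  )
})
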