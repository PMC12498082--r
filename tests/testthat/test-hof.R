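# HOF response-model hierarchy: curve shapes, likelihood fitting, model
# selection, optimum and range-limit extraction.

test_that("response curves evaluate to their closed forms", {
  expect_equal(hof_response(c(-3, 0, 7), "I", c(a = 0)), rep(0.5, 3))
  expect_equal(hof_response(2, "II", c(a = 2, b = -1)), 0.5)
  # type IV with a = c is symmetric about 0 and maximal there
  x <- seq(-2, 2, by = 0.05)
  y <- hof_response(x, "IV", c(a = 1, b = 3, c = 1))
  expect_equal(y, rev(y))
  expect_equal(which.max(y), which(x == 0))
  # V with d = b collapses to IV
  expect_equal(
    hof_response(x, "V", c(a = 1, b = 3, c = 0.5, d = 3)),
    hof_response(x, "IV", c(a = 1, b = 3, c = 0.5))
  )
  expect_true(all(y > 0 & y <= 1))
  expect_error(hof_response(0, "IV", c(a = 1, b = 2)), "needs parameters")
  expect_error(hof_response(0, "I", c(a = 1), M = 1.5), "M must")
})

test_that("fitting selects a unimodal model and recovers the optimum", {
  d <- sim_iv_records(4000, 4400, 800, 0.8, c(2650, 6150), seed = 1)
  fit <- hof(present ~ elevation_m, d)
  expect_true(fit$model_type %in% c("IV", "V"))
  expect_lt(abs(fit$optimum - 4400), 100)
  expect_equal(fit$n_records, 4000)
  # AIC bookkeeping: aic = -2 logL + 2k for the selected model
  k <- c(I = 1, II = 2, III = 3, IV = 3, V = 4)[[fit$model_type]]
  expect_equal(fit$aic, -2 * fit$logLik + 2 * k)
})

test_that("likelihoods respect the model nesting order", {
  d <- sim_iv_records(2000, 4800, 900, 0.6, c(2650, 6150), seed = 2)
  fit <- hof(present ~ elevation_m, d)
  ll <- setNames(fit$aic_table$logLik, fit$aic_table$model)
  expect_gte(ll[["II"]], ll[["I"]] - 1e-6)
  expect_gte(ll[["IV"]], ll[["II"]] - 1e-6)
  expect_gte(ll[["III"]], ll[["II"]] - 1e-6)
  expect_gte(ll[["V"]], ll[["IV"]] - 1e-6)
})

test_that("monotone prevalence selects II/III with a boundary optimum", {
  set.seed(3)
  x <- runif(3000, 2650, 6150)
  p <- plogis((x - 4400) / 400) * 0.8
  d <- data.frame(elevation_m = x, present = rbinom(3000, 1, p))
  fit <- hof(present ~ elevation_m, d)
  expect_true(fit$model_type %in% c("II", "III"))
  expect_true("boundary" %in% fit$flags)
  expect_equal(fit$optimum, max(d$elevation_m), tolerance = 1e-6)
})

test_that("degenerate and undersized inputs are handled explicitly", {
  set.seed(4)
  d <- data.frame(elevation_m = runif(50, 2650, 6150), present = 1)
  fit <- hof(present ~ elevation_m, d)
  expect_equal(fit$model_type, "I")
  expect_true("degenerate" %in% fit$flags)
  expect_true(is.na(fit$optimum))
  expect_error(
    hof(present ~ elevation_m, d[1:10, ]),
    "insufficient"
  )
})

test_that("shifting elevations shifts the optimum and preserves AIC gaps", {
  d <- sim_iv_records(3000, 4200, 800, 0.7, c(2650, 6150), seed = 5)
  f1 <- hof(present ~ elevation_m, d)
  d2 <- transform(d, elevation_m = elevation_m + 500)
  f2 <- hof(present ~ elevation_m, d2)
  expect_equal(f2$optimum - f1$optimum, 500, tolerance = 1)
  d1a <- f1$aic_table$aic - min(f1$aic_table$aic)
  d2a <- f2$aic_table$aic - min(f2$aic_table$aic)
  expect_equal(d1a, d2a, tolerance = 1e-3)
  # optimum lies inside the observed span
  expect_gte(f1$optimum, min(d$elevation_m))
  expect_lte(f1$optimum, max(d$elevation_m))
})

test_that("closed-form IV optimum matches the spec arithmetic", {
  fit <- structure(list(
    model_type = "IV", params = c(a = 1, b = 0.01, c = 3), M = 1,
    x_range = c(0, 1), flags = character(0)
  ), class = "hof")
  # (c - a) / (2b) = 100 standardized units -> clamps to the span edge
  expect_equal((3 - 1) / (2 * 0.01), 100)
  opt <- extract_optimum(fit)
  expect_equal(as.numeric(opt), 1)
  expect_true("boundary" %in% attr(opt, "flags"))

  # interior case: closed form equals a fine grid argmax
  fit$params <- c(a = -6, b = 14, c = 8)
  opt <- extract_optimum(fit)
  grid <- seq(0, 1, by = 1e-4)
  expect_equal(
    as.numeric(opt),
    grid[which.max(hof_response(grid, "IV", fit$params))],
    tolerance = 1e-3
  )
})

test_that("type V numeric optimum matches a brute-force grid scan", {
  set.seed(6)
  for (r in 1:25) {
    pars <- c(
      a = runif(1, -8, -2), b = runif(1, 5, 25),
      c = runif(1, 2, 12), d = runif(1, 3, 30)
    )
    fit <- structure(list(
      model_type = "V", params = pars, M = 1,
      x_range = c(2650, 6150), flags = character(0)
    ), class = "hof")
    grid <- seq(2650, 6150, by = 0.1)
    x <- (grid - 2650) / 3500
    oracle <- grid[which.max(hof_response(x, "V", pars))]
    expect_lt(abs(as.numeric(extract_optimum(fit)) - oracle), 1)
  }
})

test_that("range limits cross the threshold where the curve does", {
  fit <- structure(list(
    model_type = "IV", params = c(a = -6, b = 14, c = 8), M = 1,
    x_range = c(2650, 6150), flags = character(0)
  ), class = "hof")
  opt <- as.numeric(extract_optimum(fit))
  lim <- extract_range_limits(fit, 0.05)
  # symmetric curve: limits equidistant from the optimum
  expect_equal(opt - lim$range_min, lim$range_max - opt, tolerance = 2)
  # threshold -> 1: limits converge on the optimum
  lim99 <- extract_range_limits(fit, 0.999)
  expect_lt(lim99$range_max - lim99$range_min,
            lim$range_max - lim$range_min)
  expect_lt(abs((lim99$range_min + lim99$range_max) / 2 - opt), 20)
  # oracle: 1-m grid crossings
  grid <- seq(2650, 6150, by = 1)
  r <- hof_response((grid - 2650) / 3500, "IV", fit$params)
  inside <- r >= 0.05 * max(r)
  expect_lt(abs(lim$range_min - grid[which(inside)[1]]), 1.5)
  expect_lt(abs(lim$range_max - grid[rev(which(inside))[1]]), 1.5)
  expect_error(extract_range_limits(fit, 1.2), "threshold_frac")
})

test_that("estimate_optima aggregates per-species fits with flags", {
  opts <- c(spA = 3600, spB = 4800)
  occ <- simulate_occurrences(opts, 800, 0.6, 1500, c(2650, 6150), seed = 7)
  # add one species with too few records
  occ2 <- rbind(occ, data.frame(
    locality = "L1", elevation_m = 4000, species = "spC", present = 1
  ))
  res <- estimate_optima(occ2)
  expect_equal(nrow(res), 3)
  expect_lt(abs(res$optimum_m[res$species == "spA"] - 3600), 150)
  expect_lt(abs(res$optimum_m[res$species == "spB"] - 4800), 150)
  expect_true(is.na(res$optimum_m[res$species == "spC"]))
  expect_match(res$flags[res$species == "spC"], "insufficient")
  expect_true(all(res$min_m[1:2] < res$optimum_m[1:2]))
  expect_true(all(res$max_m[1:2] > res$optimum_m[1:2]))
})
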