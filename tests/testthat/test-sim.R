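# Synthetic-data generator: trees, lambda-structured traits, optimum
# composition and occurrence records.

test_that("Yule tree simulation gives valid, reproducible trees", {
  t2 <- simulate_yule_tree(2, 1, seed = 1)
  d <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(d[1], d[2])

  a <- simulate_yule_tree(50, 1, seed = 7)
  b <- simulate_yule_tree(50, 1, seed = 7)
  expect_identical(ape::write.tree(a), ape::write.tree(b))

  big <- simulate_yule_tree(310, 1, seed = 3)
  expect_length(big$tip.label, 310)
  # rooted binary tree: 2n - 1 nodes in total
  expect_equal(length(big$tip.label) + big$Nnode, 2 * 310 - 1)
  expect_false(any(duplicated(big$tip.label)))
  expect_true(all(big$edge.length > 0))

  expect_error(simulate_yule_tree(1), "n_species")
})

test_that("lambda-structured traits have the stated covariance", {
  expect_error(simulate_lambda_traits(sister_tree(), 1.5), "lambda")

  # lambda = 0: independent tips; empirical covariance ~ sigma^2 I
  tr <- simulate_yule_tree(8, 1, seed = 2)
  X0 <- t(as.matrix(simulate_lambda_traits(tr, 0, sigma2 = 1,
    n_traits = 3000, seed = 4
  )))
  S0 <- cov(X0)
  expect_lt(max(abs(S0[upper.tri(S0)])), 0.08)
  expect_equal(unname(diag(S0)), rep(1, 8), tolerance = 0.12)

  # lambda = 1, sister tips sharing fraction f of their depth: cor ~ f
  st <- sister_tree()
  X1 <- t(as.matrix(simulate_lambda_traits(st, 1, n_traits = 4000, seed = 5)))
  expect_equal(cor(X1[, "A"], X1[, "B"]), 0.6, tolerance = 0.05)

  # determinism under seed
  expect_identical(
    simulate_lambda_traits(st, 0.5, n_traits = 4, seed = 9),
    simulate_lambda_traits(st, 0.5, n_traits = 4, seed = 9)
  )
})

test_that("trait table respects scale invariants and carries growth form", {
  tr <- simulate_yule_tree(60, 1, seed = 11)
  tt <- simulate_trait_table(tr, 0.5, seed = 12)
  pct <- c(
    "Mechanical_tissue", "Storage_tissue", "Starch", "Fructan"
  )
  for (cn in pct) {
    expect_true(all(tt[[cn]] >= 0 & tt[[cn]] <= 100), label = cn)
  }
  expect_true(all(tt$Height > 0 & tt$Longevity > 0 & tt$Ring_width > 0))
  expect_true(all(levels(tt$growth_form) == growth_form_levels()))
  expect_false(any(duplicated(rownames(tt))))
})

test_that("optimum composition is linear with logged clipping", {
  tr <- simulate_yule_tree(20, 1, seed = 21)
  tt <- simulate_trait_table(tr, 0.5, seed = 22)

  o0 <- compose_optima(tt, c(Height = 0), 4500, 0)
  expect_equal(as.numeric(o0), rep(4500, 20))

  o1 <- compose_optima(tt, c(Height = -10), 4500, 0)
  expect_equal(as.numeric(o1), 4500 - 10 * tt$Height)

  expect_error(compose_optima(tt, c(NotATrait = 1), 4500, 0), "NotATrait")

  # noise SD recovered within the chi-square band stated for n = 141
  trn <- simulate_yule_tree(141, 1, seed = 23)
  ttn <- simulate_trait_table(trn, 0.5, seed = 24)
  on <- compose_optima(ttn, c(Height = -10), 4500, 300, seed = 25)
  eps <- as.numeric(on) - (4500 - 10 * ttn$Height)
  expect_gt(sd(eps), 200)
  expect_lt(sd(eps), 400)

  # clipping is applied and logged, not silent
  expect_message(
    oc <- compose_optima(tt, c(Height = 0), 7000, 0,
      elev_range = c(2650, 6150)
    ),
    "clipped"
  )
  expect_true(all(attr(oc, "clipped")))
  expect_equal(as.numeric(oc), rep(6150, 20))
})

test_that("occurrence records follow the stated unimodal curve", {
  expect_error(
    simulate_occurrences(c(sp1 = 4000), 700, 0.3, 10, c(5000, 5000)),
    "elev_range"
  )

  occ0 <- simulate_occurrences(c(sp1 = 4000), 700, 0, 500,
    c(2650, 6150),
    seed = 31
  )
  expect_equal(sum(occ0$present), 0)

  # peak presence frequency lands within one 100-m bin of the optimum
  occ <- simulate_occurrences(c(sp1 = 4400), 700, 0.8, 10000,
    c(2650, 6150),
    seed = 32
  )
  bins <- cut(occ$elevation_m, seq(2650, 6150, by = 100))
  freq <- tapply(occ$present, bins, mean)
  peak_bin <- which.max(freq)
  opt_bin <- findInterval(4400, seq(2650, 6150, by = 100))
  expect_lte(abs(peak_bin - opt_bin), 1)

  # total presences ~ n * mean curve height, within 3 binomial SDs
  grid <- seq(2650, 6150, length.out = 2000)
  b <- 2 * acosh(3) / 700
  pbar <- mean(0.8 * 4 * plogis(b * (grid - 4400)) * plogis(-b * (grid - 4400)))
  expect_lt(
    abs(sum(occ$present) - 10000 * pbar),
    3 * sqrt(10000 * pbar * (1 - pbar))
  )

  # determinism: identical tables under the same seed
  expect_identical(
    simulate_occurrences(c(sp1 = 4000, sp2 = 5000), 700, 0.3, 200,
      c(2650, 6150),
      seed = 33
    ),
    simulate_occurrences(c(sp1 = 4000, sp2 = 5000), 700, 0.3, 200,
      c(2650, 6150),
      seed = 33
    )
  )
})

test_that("a full simulated study is coherent and reproducible", {
  cfg <- sim_config(n_species = 30, n_localities = 150, seed = 41)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$occurrences, s2$occurrences)
  expect_setequal(rownames(s1$traits), s1$tree$tip.label)
  expect_true(all(s1$occurrences$elevation_m >= 2650 &
    s1$occurrences$elevation_m <= 6150))
  expect_true(all(table(s1$occurrences$locality) == 30))
  # habitat rule: steppe strictly below the split elevation
  expect_true(all(
    (s1$traits$habitat == "steppe") == (s1$traits$true_optimum < 4200)
  ))
})
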