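# Shared fixtures and independent oracles, all built in code.

two_tip_tree <- function() ape::read.tree(text = "(A:1,B:1);")

sister_tree <- function() ape::read.tree(text = "((A:0.4,B:0.4):0.6,C:1.0);")

star_tree <- function(n = 5) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", seq_len(n)), collapse = ","), ");"
  ))
}

# Independent Brownian-covariance oracle: pairwise MRCA depth by brute
# force from the tree's node depths.
vcv_oracle <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- if (i == j) depth[i] else depth[ape::getMRCA(tree, c(i, j))]
    }
  }
  C
}

# Brute-force multivariate-normal log density.
mvn_logdens <- function(y, mu, Sigma) {
  n <- length(y)
  r <- y - mu
  -0.5 * (n * log(2 * pi) + determinant(Sigma)$modulus[1] +
    drop(t(r) %*% solve(Sigma, r)))
}

# Manual Holm step-down oracle (sort, reject while p_(i) <= a/(m-i+1)).
holm_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  rej <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) rej[ord[i]] <- TRUE else break
  }
  rej
}

# Simulated presence/absence records from a symmetric unimodal (type IV)
# curve on the metre scale; peak height `max_prob` at `optimum`.
sim_iv_records <- function(n, optimum, width, max_prob, elev_range, seed) {
  set.seed(seed)
  x <- runif(n, elev_range[1], elev_range[2])
  b <- 2 * acosh(3) / width
  u <- b * (x - optimum)
  p <- max_prob * 4 * plogis(u) * plogis(-u)
  data.frame(elevation_m = x, present = rbinom(n, 1, p))
}

# Small comparative dataset with one planted linear effect.
sim_planted <- function(n = 80, beta = c(Height = -10), noise = 200,
                        seed = 1, lambda_true = 0.5) {
  tree <- simulate_yule_tree(n, 1, seed = seed)
  traits <- simulate_trait_table(tree, lambda_true, seed = seed + 1)
  # noise seed far from the trait/growth-form latent seeds
  opt <- compose_optima(traits, beta, 4500, noise, seed = seed + 7919)
  traits$optimum_m <- unname(opt)
  list(tree = tree, data = traits)
}
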