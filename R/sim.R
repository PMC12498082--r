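# Synthetic study generator: Yule trees, lambda-structured traits, known
# trait -> optimum effects, and unimodal presence/absence records along an
# elevation gradient. Designed so every downstream stage (HOF optima, PGLS,
# sequential selection) can be validated by parameter recovery.

#' Simulation configuration
#'
#' Assembles the full parameter set of the synthetic study. Defaults emulate
#' the study conditions the pipeline targets: 310 species split across a
#' steppe and an alpine pool, 4,062 survey localities on a 2,650--6,150 m
#' gradient, unimodal occurrence curves, and traits evolved on the tree with
#' tunable phylogenetic signal and known linear effects on the elevational
#' optimum.
#'
#' @param n_species number of species (tree tips).
#' @param habitat_split named counts for the two habitat pools (reference
#'   values; actual pool sizes follow from `habitat_split_elev`).
#' @param birth_rate per-lineage speciation rate of the pure-birth tree.
#' @param lambda_true phylogenetic signal of simulated traits, in \[0,1\].
#' @param sigma2 Brownian rate per latent trait.
#' @param beta_true named numeric vector mapping trait columns to their
#'   linear effect on the optimum (metres per trait unit).
#' @param optimum_intercept intercept of the optimum composition (m).
#' @param optimum_noise_sd residual SD of the optimum (m).
#' @param elev_range length-2 numeric, low and high end of the gradient (m).
#' @param n_localities number of survey localities.
#' @param curve_width full width at half maximum of the occurrence curve (m).
#' @param max_prob peak presence probability, in (0,1\].
#' @param habitat_split_elev species with true optimum below this elevation
#'   are labelled steppe, the rest alpine.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_species = 310,
                       habitat_split = c(steppe = 169, alpine = 141),
                       birth_rate = 1,
                       lambda_true = 0.5,
                       sigma2 = 1,
                       beta_true = c(
                         Height = -10, Storage_tissue = 8, Ring_width = -250,
                         RNC = 250, d13C = 70, Fructan = 15, Longevity = 8
                       ),
                       optimum_intercept = 5500,
                       optimum_noise_sd = 300,
                       elev_range = c(2650, 6150),
                       n_localities = 4062,
                       curve_width = 700,
                       max_prob = 0.3,
                       habitat_split_elev = 4200,
                       seed = 1L) {
  if (lambda_true < 0 || lambda_true > 1)
    stop_invalid("lambda_true must lie in [0, 1]")
  if (length(elev_range) != 2L || elev_range[1] >= elev_range[2])
    stop_invalid("elev_range must be (low, high) with low < high")
  if (max_prob < 0 || max_prob > 1)
    stop_invalid("max_prob must lie in (0, 1]")
  if (n_localities < 1) stop_invalid("n_localities must be >= 1")
  if (birth_rate <= 0 || sigma2 <= 0 || curve_width <= 0)
    stop_invalid("birth_rate, sigma2 and curve_width must be > 0")
  structure(list(
    n_species = as.integer(n_species), habitat_split = habitat_split,
    birth_rate = birth_rate, lambda_true = lambda_true, sigma2 = sigma2,
    beta_true = beta_true, optimum_intercept = optimum_intercept,
    optimum_noise_sd = optimum_noise_sd, elev_range = elev_range,
    n_localities = as.integer(n_localities), curve_width = curve_width,
    max_prob = max_prob, habitat_split_elev = habitat_split_elev,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Simulates a rooted binary tree with `n_species` tips under a constant
#' speciation rate and rescales it to unit height, giving all tips equal
#' root-to-tip depth. Tip labels are `sp001`, `sp002`, ...
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed RNG seed; fixed seed gives an identical tree.
#' @return an [ape::as.phylo] object.
#' @export
simulate_yule_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) stop_invalid("n_species must be >= 2")
  if (birth_rate <= 0) stop_invalid("birth_rate must be > 0")
  tree <- with_seed(seed, ape::rphylo(n_species, birth = birth_rate, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Simulate continuous traits with a given phylogenetic signal
#'
#' Draws `n_traits` independent traits, each multivariate normal across the
#' tips with covariance `sigma2 * V(lambda)`, where `V(lambda)` keeps the
#' Brownian diagonal and scales shared-branch off-diagonals by `lambda`
#' (Pagel's lambda as a generative model: 0 = star-like independence,
#' 1 = Brownian motion on the tree).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param lambda_true signal in \[0,1\].
#' @param sigma2 Brownian rate.
#' @param n_traits number of independent traits.
#' @param seed RNG seed.
#' @param trait_names optional column names.
#' @return data frame, one row per tip (rownames = tip labels).
#' @export
simulate_lambda_traits <- function(tree, lambda_true, sigma2 = 1,
                                   n_traits = 1, seed = NULL,
                                   trait_names = NULL) {
  if (lambda_true < 0 || lambda_true > 1)
    stop_invalid("lambda_true must lie in [0, 1]")
  C <- bm_covariance(tree)
  V <- sigma2 * lambda_transform(C, lambda_true)
  L <- chol(V)
  n <- nrow(V)
  Z <- with_seed(seed, matrix(stats::rnorm(n * n_traits), n, n_traits))
  X <- crossprod(L, Z)
  colnames(X) <- trait_names %||% paste0("trait", seq_len(n_traits))
  out <- as.data.frame(X)
  rownames(out) <- rownames(V)
  out
}

# Per-trait mappings from a ~N(0,1) latent to a realistic measurement scale.
# Percent-valued traits go through a logistic link so they respect [0,100];
# strictly positive traits are log-normal; isotope ratios are plain shifts.
.trait_maps <- list(
  Height            = function(z) exp(log(25) + 0.8 * z),
  Bark_xylem        = function(z) exp(log(0.8) + 0.7 * z),
  Mechanical_tissue = function(z) 100 * stats::plogis(stats::qlogis(0.28) + 0.9 * z),
  Storage_tissue    = function(z) 100 * stats::plogis(stats::qlogis(0.55) + 0.9 * z),
  Longevity         = function(z) exp(log(10) + 0.9 * z),
  Ring_width        = function(z) exp(log(0.3) + 0.8 * z),
  LNC               = function(z) exp(log(2.5) + 0.35 * z),
  LPC               = function(z) exp(log(0.18) + 0.4 * z),
  LCC               = function(z) 40 + 3 * z,
  RNC               = function(z) exp(log(1.1) + 0.4 * z),
  RPC               = function(z) exp(log(0.13) + 0.35 * z),
  d13C              = function(z) -27 + 1.5 * z,
  d15N              = function(z) 2.5 + 3 * z,
  Starch            = function(z) 100 * stats::plogis(stats::qlogis(0.05) + 1.0 * z),
  Fructan           = function(z) 100 * stats::plogis(stats::qlogis(0.05) + 1.0 * z),
  Free_sugar        = function(z) exp(log(5) + 0.7 * z)
)

#' Growth-form level set
#' @return the seven growth-form codes: annuals (A), cushions (C), long
#'   rhizomes (Lr), pleiocorms (P), short rhizomes (Sr), taproots (T),
#'   woody (W).
#' @export
growth_form_levels <- function() c("A", "C", "Lr", "P", "Sr", "T", "W")

#' Simulate a full species trait table
#'
#' Generates the 16 continuous traits on realistic measurement scales
#' (each driven by its own lambda-structured latent) plus a categorical
#' growth form obtained by thresholding a latent Brownian trait into seven
#' ordered bins, so categories carry phylogenetic signal.
#'
#' @param tree phylogeny.
#' @param lambda_true,sigma2 passed to [simulate_lambda_traits()].
#' @param seed RNG seed.
#' @param growth_form_probs bin widths (proportions) of the seven growth
#'   forms, in latent order woody -> taproot -> annual -> short rhizome ->
#'   long rhizome -> pleiocorm -> cushion.
#' @return data frame with rownames = species, 16 numeric columns plus
#'   factor `growth_form`.
#' @export
simulate_trait_table <- function(tree, lambda_true = 0.5, sigma2 = 1,
                                 seed = NULL,
                                 growth_form_probs = c(
                                   W = 0.10, T = 0.20, A = 0.15, Sr = 0.15,
                                   Lr = 0.15, P = 0.15, C = 0.10
                                 )) {
  nm <- names(.trait_maps)
  lat <- simulate_lambda_traits(tree, lambda_true, sigma2,
    n_traits = length(nm), seed = seed, trait_names = nm
  )
  out <- as.data.frame(Map(function(f, z) f(z), .trait_maps, lat))
  rownames(out) <- rownames(lat)
  # growth form: latent Brownian trait cut at quantile bin edges
  gf_lat <- simulate_lambda_traits(tree, 1, sigma2,
    n_traits = 1,
    seed = if (is.null(seed)) NULL else seed + 1L
  )[[1]]
  edges <- stats::quantile(gf_lat, cumsum(growth_form_probs)[-length(growth_form_probs)])
  codes <- names(growth_form_probs)[findInterval(gf_lat, edges) + 1L]
  out$growth_form <- factor(codes, levels = growth_form_levels())
  out
}

#' Compose true elevational optima from traits
#'
#' `optimum_i = intercept + sum_k beta_k * trait_ik + eps_i` with Gaussian
#' noise. If `elev_range` is supplied, optima are clipped to it and the
#' clipping events are recorded in the `"clipped"` attribute (and reported
#' via a message), so edge-effect analyses can exclude clipped species.
#'
#' @param traits trait table (rows = species).
#' @param beta_true named effects; every name must be a numeric trait column.
#' @param optimum_intercept intercept (m).
#' @param optimum_noise_sd residual SD (m).
#' @param seed RNG seed.
#' @param elev_range optional gradient bounds for clipping.
#' @return named numeric vector of optima (m), with attribute `clipped`.
#' @export
compose_optima <- function(traits, beta_true, optimum_intercept,
                           optimum_noise_sd = 0, seed = NULL,
                           elev_range = NULL) {
  missing_tr <- setdiff(names(beta_true), colnames(traits))
  if (length(missing_tr) > 0)
    stop_invalid(
      "beta_true names not found in traits: ",
      paste(missing_tr, collapse = ", ")
    )
  lin <- rep(optimum_intercept, nrow(traits))
  for (k in names(beta_true)) {
    if (!is.numeric(traits[[k]]))
      stop_invalid("trait '", k, "' is not numeric")
    lin <- lin + beta_true[[k]] * traits[[k]]
  }
  eps <- with_seed(seed, stats::rnorm(nrow(traits), 0, optimum_noise_sd))
  opt <- lin + eps
  names(opt) <- rownames(traits)
  clipped <- rep(FALSE, length(opt))
  if (!is.null(elev_range)) {
    clipped <- opt < elev_range[1] | opt > elev_range[2]
    if (any(clipped))
      message(sum(clipped), " optimum value(s) clipped to the gradient bounds")
    opt <- pmin(pmax(opt, elev_range[1]), elev_range[2])
  }
  attr(opt, "clipped") <- clipped
  opt
}

# Symmetric unimodal response used by the generator: a HOF type-IV curve
# normalized to peak height `max_prob`, with `curve_width` = full width at
# half maximum (b = 2*acosh(3)/width on the metre scale).
occurrence_curve <- function(x, optimum, curve_width, max_prob) {
  b <- 2 * acosh(3) / curve_width
  u <- b * (x - optimum)
  max_prob * 4 * stats::plogis(u) * stats::plogis(-u)
}

#' Simulate presence/absence records along the gradient
#'
#' Locality elevations are uniform over the gradient; each species is
#' present at a locality with probability given by a symmetric unimodal
#' (HOF type IV) curve peaking at its true optimum.
#'
#' @param true_optima named vector of optima (m), names = species.
#' @param curve_width full width at half maximum of the curve (m).
#' @param max_prob peak presence probability in \[0,1\].
#' @param n_localities number of localities.
#' @param elev_range gradient bounds (m).
#' @param seed RNG seed.
#' @return data frame with columns `locality`, `elevation_m`, `species`,
#'   `present`; one row per (locality, species) pair.
#' @export
simulate_occurrences <- function(true_optima, curve_width, max_prob,
                                 n_localities, elev_range, seed = NULL) {
  if (length(elev_range) != 2L || elev_range[1] >= elev_range[2])
    stop_invalid("elev_range must be (low, high) with low < high")
  if (curve_width <= 0) stop_invalid("curve_width must be > 0")
  if (is.null(names(true_optima)))
    names(true_optima) <- sprintf("sp%03d", seq_along(true_optima))
  with_seed(seed, {
    elev <- stats::runif(n_localities, elev_range[1], elev_range[2])
    loc <- sprintf("L%05d", seq_len(n_localities))
    nsp <- length(true_optima)
    p <- occurrence_curve(
      rep(elev, times = nsp),
      rep(unname(true_optima), each = n_localities),
      curve_width, max_prob
    )
    data.frame(
      locality = rep(loc, times = nsp),
      elevation_m = rep(elev, times = nsp),
      species = rep(names(true_optima), each = n_localities),
      present = stats::rbinom(n_localities * nsp, 1L, p),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a complete synthetic study
#'
#' Orchestrates tree, traits, optima, habitat labels and occurrence records
#' from one [sim_config()]. Habitats are assigned by thresholding the true
#' optimum at `habitat_split_elev` (steppe below, alpine above).
#'
#' @param config a [sim_config()].
#' @return list of class `elevtrait_sim` with elements `tree`, `traits`
#'   (including `growth_form`, `habitat`, `true_optimum`, `clipped`),
#'   `occurrences`, and the echoed `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_yule_tree(config$n_species, config$birth_rate,
    seed = child_seed(config$seed, "tree")
  )
  traits <- simulate_trait_table(tree, config$lambda_true, config$sigma2,
    seed = child_seed(config$seed, "traits")
  )
  opt <- compose_optima(traits, config$beta_true, config$optimum_intercept,
    config$optimum_noise_sd,
    seed = child_seed(config$seed, "optima"),
    elev_range = config$elev_range
  )
  traits$true_optimum <- unname(opt)
  traits$clipped <- attr(opt, "clipped")
  traits$habitat <- factor(
    ifelse(traits$true_optimum < config$habitat_split_elev, "steppe", "alpine"),
    levels = c("steppe", "alpine")
  )
  occ <- simulate_occurrences(opt, config$curve_width, config$max_prob,
    config$n_localities, config$elev_range,
    seed = child_seed(config$seed, "occurrences")
  )
  structure(
    list(tree = tree, traits = traits, occurrences = occ, config = config),
    class = "elevtrait_sim"
  )
}

#' @export
print.elevtrait_sim <- function(x, ...) {
  cat(
    "Synthetic elevational study:", nrow(x$traits), "species,",
    x$config$n_localities, "localities on",
    paste(x$config$elev_range, collapse = "-"), "m\n"
  )
  cat("  habitat pools:", paste(names(table(x$traits$habitat)),
    table(x$traits$habitat),
    collapse = ", ", sep = "="
  ), "\n")
  cat("  presences:", sum(x$occurrences$present), "of",
      nrow(x$occurrences), "records\n")
  invisible(x)
}
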