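# Huisman-Olff-Fresco (HOF) hierarchy of species response models along an
# elevation gradient: five nested shapes (flat, monotone, plateau, symmetric
# unimodal, skewed unimodal) built from products of logistic terms, fitted to
# presence/absence records by Bernoulli maximum likelihood and compared by
# AIC. The selected curve yields the species' elevational optimum and range
# limits.

# log(1 + exp(u)) without overflow
log1pexp <- function(u) ifelse(u > 33, u, log1p(exp(pmin(u, 33))))

.hof_pars <- list(
  I = "a", II = c("a", "b"), III = c("a", "b", "c"),
  IV = c("a", "b", "c"), V = c("a", "b", "c", "d")
)
.hof_k <- c(I = 1, II = 2, III = 3, IV = 3, V = 4)

#' HOF response curves
#'
#' Evaluates one of the five classical HOF model shapes at standardized
#' position `x`:
#' \describe{
#'   \item{I}{flat: `M / (1 + e^a)`}
#'   \item{II}{monotone: `M / (1 + e^(a+bx))`}
#'   \item{III}{plateau: `M / ((1 + e^(a+bx)) (1 + e^c))`}
#'   \item{IV}{symmetric unimodal: `M / ((1 + e^(a+bx)) (1 + e^(c-bx)))`}
#'   \item{V}{skewed unimodal: `M / ((1 + e^(a+bx)) (1 + e^(c-dx)))`}
#' }
#'
#' @param x numeric positions (standardized elevation).
#' @param model_type one of `"I"`..`"V"`.
#' @param params named vector with the parameters the shape requires
#'   (I: a; II: a,b; III/IV: a,b,c; V: a,b,c,d).
#' @param M response ceiling in (0,1\].
#' @return response values in (0, M\].
#' @export
hof_response <- function(x, model_type, params, M = 1) {
  model_type <- match.arg(model_type, names(.hof_pars))
  need <- .hof_pars[[model_type]]
  if (!all(need %in% names(params)))
    stop_invalid(
      "model ", model_type, " needs parameters ",
      paste(need, collapse = ", ")
    )
  if (M <= 0 || M > 1) stop_invalid("M must lie in (0, 1]")
  p <- as.list(params)
  lognum <- switch(model_type,
    I = log1pexp(rep(p$a, length(x))),
    II = log1pexp(p$a + p$b * x),
    III = log1pexp(p$a + p$b * x) + log1pexp(rep(p$c, length(x))),
    IV = log1pexp(p$a + p$b * x) + log1pexp(p$c - p$b * x),
    V = log1pexp(p$a + p$b * x) + log1pexp(p$c - p$d * x)
  )
  M * exp(-lognum)
}

# Bernoulli negative log-likelihood of a HOF curve on standardized data.
hof_nll <- function(par, x, y, model_type) {
  if (any(!is.finite(par))) return(1e10) # keep optimizers on finite ground
  names(par) <- .hof_pars[[model_type]]
  p <- hof_response(x, model_type, par)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log1p(-p))
}

# Deterministic multi-start optimization of one HOF shape. `starts` is a
# list of numeric start vectors; nested warm starts passed in by the caller
# guarantee the likelihood ordering I <= II <= {III, IV} <= V.
hof_optim <- function(x, y, model_type, starts) {
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, hof_nll,
      x = x, y = y, model_type = model_type,
      method = "Nelder-Mead",
      control = list(maxit = 400, reltol = 1e-8)
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # quasi-Newton polish of the winning start only
  pol <- tryCatch(
    stats::optim(best$par, hof_nll,
      x = x, y = y, model_type = model_type,
      method = "BFGS", control = list(maxit = 200, reltol = 1e-12)
    ),
    error = function(e) best
  )
  if (pol$value < best$value) best <- pol
  names(best$par) <- .hof_pars[[model_type]]
  best
}

#' Fit the HOF model hierarchy to one species
#'
#' Fits models I--V to presence/absence records along elevation by
#' maximizing the Bernoulli log-likelihood (elevations standardized to
#' \[0,1\] internally; multi-start deterministic optimization with nested
#' warm starts) and selects the fit with lowest AIC, preferring the simpler
#' model at ties. The response ceiling is fixed at `M = 1`: with binary
#' data the ceiling is not identifiable jointly with the intercept, which
#' absorbs prevalence.
#'
#' @param formula `present ~ elevation`, both sides columns of `data`.
#' @param data data frame of one species' records.
#' @param threshold_frac response fraction of the peak that defines the
#'   range limits (default 0.05).
#' @param min_records minimum record count (default 30).
#' @return object of class `hof` with the selected model type, parameters,
#'   log-likelihood, AIC, the derived `optimum`, `range_min`, `range_max`
#'   (metres), per-model AIC table, and flags (`"degenerate"`,
#'   `"boundary"`).
#' @export
hof <- function(formula, data, threshold_frac = 0.05, min_records = 30) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  elev <- mf[[2L]]
  if (!all(y %in% c(0, 1))) stop_invalid("response must be binary 0/1")
  n <- length(y)
  if (n < min_records)
    stop_invalid("insufficient data: ", n, " records < ", min_records)
  x_range <- range(elev)
  degenerate <- length(unique(y)) < 2L || diff(x_range) == 0
  x <- if (diff(x_range) > 0) (elev - x_range[1]) / diff(x_range) else elev * 0

  pbar <- mean(y)
  a1 <- log((1 - min(max(pbar, 1e-9), 1 - 1e-9)) /
    min(max(pbar, 1e-9), 1 - 1e-9))
  fits <- list(I = list(par = c(a = a1), value = hof_nll(a1, x, y, "I")))

  if (!degenerate) {
    starts2 <- lapply(
      seq_len(12),
      function(i) {
        c(
          a = c(-2, 0, 2)[(i - 1) %% 3 + 1],
          b = c(-20, -5, 5, 20)[(i - 1) %/% 3 + 1]
        )
      }
    )
    fits$II <- hof_optim(x, y, "II", starts2)
    ab <- fits$II$par
    fits$III <- hof_optim(x, y, "III", list(
      c(ab, c = -15), c(ab, c = -1), c(ab, c = 1),
      c(a = 0, b = 5, c = 0), c(a = 0, b = -5, c = 0)
    ))
    starts4 <- list(c(ab, c = -15))
    for (b0 in c(10, 25)) {
      for (xo in c(0.25, 0.5, 0.75)) {
        starts4 <- c(starts4, list(c(a = -2, b = b0, c = -2 + 2 * b0 * xo)))
      }
    }
    fits$IV <- hof_optim(x, y, "IV", starts4)
    p4 <- fits$IV$par
    fits$V <- hof_optim(x, y, "V", list(
      c(p4, d = unname(p4["b"])),
      c(p4, d = unname(p4["b"]) / 2),
      c(p4, d = unname(p4["b"]) * 2),
      c(ab, c = -15, d = 1)
    ))
  }

  logL <- vapply(fits, function(f) -f$value, numeric(1))
  aic <- -2 * logL + 2 * .hof_k[names(fits)]
  # parsimony rule: among models with similar fit (delta AIC < 2 of the
  # minimum) take the one with fewest parameters; exact ties go to the
  # earlier (simpler) member of the hierarchy
  cand <- which(aic < min(aic) + 2)
  sel <- names(fits)[cand[which.min(.hof_k[names(fits)][cand])]]

  obj <- structure(list(
    model_type = sel, params = fits[[sel]]$par, M = 1,
    logLik = logL[[sel]], aic = unname(aic[sel]), n_records = n,
    x_range = x_range, aic_table = data.frame(
      model = names(fits), logLik = unname(logL), aic = unname(aic),
      k = unname(.hof_k[names(fits)]), row.names = NULL
    ),
    threshold_frac = threshold_frac,
    flags = if (degenerate) "degenerate" else character(0),
    call = match.call()
  ), class = "hof")
  opt <- extract_optimum(obj)
  obj$flags <- attr(opt, "flags") %||% obj$flags
  obj$optimum <- as.numeric(opt)
  lim <- extract_range_limits(obj, threshold_frac)
  obj$range_min <- lim[[1]]
  obj$range_max <- lim[[2]]
  obj
}

# Map a standardized position back to metres.
hof_back <- function(fit, x) fit$x_range[1] + x * diff(fit$x_range)

# Predicted response on the metre scale.
hof_curve <- function(fit, elev_m) {
  x <- (elev_m - fit$x_range[1]) / diff(fit$x_range)
  hof_response(x, fit$model_type, fit$params, fit$M)
}

#' Elevational optimum of a fitted HOF model
#'
#' Model IV has the closed form `x* = (c - a) / (2b)` on the standardized
#' axis; model V is maximized numerically (1-m grid refined by
#' golden-section search); model I has no optimum (NA); monotone models
#' II/III attain their supremum at a gradient boundary, which is returned
#' with a `"boundary"` flag. Optima are clamped to the observed span.
#'
#' @param fit a `hof` object.
#' @return optimum elevation in metres (NA for model I), with attribute
#'   `flags`.
#' @export
extract_optimum <- function(fit) {
  stopifnot(inherits(fit, "hof"))
  flags <- fit$flags
  mt <- fit$model_type
  p <- fit$params
  if (mt == "I" || "degenerate" %in% flags) {
    return(structure(NA_real_, flags = unique(c(flags))))
  }
  if (mt %in% c("II", "III")) {
    # response is monotone: decreasing in x when b > 0
    xs <- if (p[["b"]] > 0) 0 else 1
    flags <- c(flags, "boundary")
  } else if (mt == "IV") {
    xs <- (p[["c"]] - p[["a"]]) / (2 * p[["b"]])
  } else { # V: numeric argmax, metre grid then refine
    grid_m <- seq(fit$x_range[1], fit$x_range[2], by = 1)
    r <- hof_curve(fit, grid_m)
    i <- which.max(r)
    lo <- grid_m[max(1L, i - 1L)]
    hi <- grid_m[min(length(grid_m), i + 1L)]
    opt <- stats::optimize(function(m) hof_curve(fit, m), c(lo, hi),
      maximum = TRUE, tol = 1e-4
    )
    xs <- (opt$maximum - fit$x_range[1]) / diff(fit$x_range)
  }
  if (xs < 0 || xs > 1) {
    xs <- min(max(xs, 0), 1)
    flags <- c(flags, "boundary")
  }
  structure(hof_back(fit, xs), flags = unique(flags))
}

#' Range limits of a fitted HOF model
#'
#' Outermost elevations at which the predicted response equals
#' `threshold_frac` times the peak response, located on a 1-m grid with
#' linear interpolation at the crossings and clipped to the observed
#' gradient. For monotone fits one side is the gradient edge; for the flat
#' model I the limits are undefined.
#'
#' @param fit a `hof` object.
#' @param threshold_frac fraction of the peak in (0,1).
#' @return list `(range_min, range_max)` in metres.
#' @export
extract_range_limits <- function(fit, threshold_frac = 0.05) {
  stopifnot(inherits(fit, "hof"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop_invalid("threshold_frac must lie in (0, 1)")
  if (fit$model_type == "I" || "degenerate" %in% fit$flags)
    return(list(range_min = NA_real_, range_max = NA_real_))
  grid_m <- seq(fit$x_range[1], fit$x_range[2], by = 1)
  r <- hof_curve(fit, grid_m)
  thr <- threshold_frac * max(r)
  inside <- r >= thr
  if (!any(inside))
    return(list(range_min = NA_real_, range_max = NA_real_))
  i1 <- which(inside)[1]
  i2 <- rev(which(inside))[1]
  cross <- function(i_out, i_in) {
    # linear interpolation between the grid point outside and inside
    if (i_out < 1 || i_out > length(r)) return(grid_m[i_in])
    grid_m[i_out] + (thr - r[i_out]) / (r[i_in] - r[i_out]) *
      (grid_m[i_in] - grid_m[i_out])
  }
  lo <- if (i1 == 1L) grid_m[1] else cross(i1 - 1L, i1)
  hi <- if (i2 == length(r)) grid_m[length(r)] else cross(i2 + 1L, i2)
  list(range_min = lo, range_max = hi)
}

#' @export
print.hof <- function(x, digits = 4, ...) {
  cat("HOF response model (type ", x$model_type, "), n = ", x$n_records,
    "\n",
    sep = ""
  )
  cat("  params:", paste(names(x$params),
    round(x$params, digits),
    sep = "=", collapse = " "
  ), "\n")
  cat(
    "  logLik =", format(x$logLik, digits = digits),
    " AIC =", format(x$aic, digits = digits), "\n"
  )
  cat(
    "  optimum =", round(x$optimum, 1), "m; range",
    round(x$range_min, 1), "-", round(x$range_max, 1), "m\n"
  )
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hof <- function(object, ...) {
  cat("Model comparison (Bernoulli likelihood):\n")
  tab <- object$aic_table
  tab$delta_aic <- tab$aic - min(tab$aic)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.hof <- function(object, ...) object$params

#' @export
logLik.hof <- function(object, ...) {
  structure(object$logLik,
    df = unname(.hof_k[object$model_type]),
    nobs = object$n_records, class = "logLik"
  )
}

#' @export
predict.hof <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- seq(object$x_range[1], object$x_range[2], length.out = 101)
  }
  elev <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  hof_curve(object, elev)
}

#' @export
plot.hof <- function(x, n_grid = 200, ...) {
  elev <- seq(x$x_range[1], x$x_range[2], length.out = n_grid)
  graphics::plot(elev, hof_curve(x, elev),
    type = "l",
    xlab = "Elevation (m)", ylab = "P(presence)",
    main = paste("HOF type", x$model_type), ...
  )
  if (is.finite(x$optimum)) graphics::abline(v = x$optimum, lty = 2)
  invisible(x)
}

#' Estimate elevational optima for every species in an occurrence table
#'
#' Runs the HOF hierarchy species by species and collects the selected
#' model, optimum and range limits. Species with too few records, or with
#' all-present/all-absent records, are returned with NA estimates and an
#' explanatory flag rather than dropped silently.
#'
#' @param occurrences data frame with columns `species`, `elevation_m`,
#'   `present`.
#' @param threshold_frac passed to [extract_range_limits()].
#' @param min_records minimum records per species (default 30).
#' @return data frame: `species`, `model_type`, `optimum_m`, `min_m`,
#'   `max_m`, `aic`, `n_records`, `flags`.
#' @export
estimate_optima <- function(occurrences, threshold_frac = 0.05,
                            min_records = 30) {
  need <- c("species", "elevation_m", "present")
  if (!all(need %in% names(occurrences)))
    stop_invalid(
      "occurrences must have columns ",
      paste(need, collapse = ", ")
    )
  sp_list <- unique(occurrences$species)
  rows <- lapply(sp_list, function(sp) {
    d <- occurrences[occurrences$species == sp, ]
    fit <- tryCatch(
      hof(present ~ elevation_m, d,
        threshold_frac = threshold_frac,
        min_records = min_records
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(data.frame(
        species = sp, model_type = NA_character_, optimum_m = NA_real_,
        min_m = NA_real_, max_m = NA_real_, aic = NA_real_,
        n_records = nrow(d), flags = conditionMessage(fit),
        stringsAsFactors = FALSE
      ))
    }
    data.frame(
      species = sp, model_type = fit$model_type,
      optimum_m = as.numeric(fit$optimum), min_m = fit$range_min,
      max_m = fit$range_max, aic = fit$aic, n_records = fit$n_records,
      flags = paste(fit$flags, collapse = ";"), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
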