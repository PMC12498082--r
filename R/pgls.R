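# Phylogenetic generalized least squares with maximum-likelihood Pagel's
# lambda. This is the statistical engine behind every trait-optimum model
# in the package; it is self-contained (no comparative-methods package is
# called) so that AIC and R^2 conventions are fully under our control.

#' Brownian expected covariance among tips
#'
#' `C[i,j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param species_order optional character vector giving the row/column
#'   order; defaults to the tree's tip order.
#' @return symmetric positive semi-definite matrix with dimnames.
#' @export
bm_covariance <- function(tree, species_order = NULL) {
  C <- ape::vcv.phylo(tree)
  if (!is.null(species_order)) {
    missing_sp <- setdiff(species_order, rownames(C))
    if (length(missing_sp) > 0)
      stop_invalid(
        "species not in tree: ",
        paste(missing_sp, collapse = ", ")
      )
    C <- C[species_order, species_order, drop = FALSE]
  }
  C
}

#' Pagel's lambda branch-length transform of a covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `V(0)` is diagonal (star-like independence), `V(1) = C`
#' (full Brownian expectation).
#'
#' @param C Brownian covariance from [bm_covariance()].
#' @param lambda value in \[0,1\].
#' @return transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (lambda < 0 || lambda > 1) stop_invalid("lambda must lie in [0, 1]")
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

# Core GLS computations for a fixed lambda. Returns the profiled ML fit:
# beta-hat, ML sigma^2 = RSS/n, logL, plus pieces reused by summaries.
gls_profile <- function(y, X, C, lambda) {
  V <- lambda_transform(C, lambda)
  L <- chol(V) # V = t(L) %*% L, L upper-triangular
  w <- function(M) backsolve(L, M, transpose = TRUE) # L^{-T} M, whitening
  yw <- w(y)
  Xw <- w(X)
  qr_x <- qr(Xw)
  if (qr_x$rank < ncol(Xw)) {
    cols <- colnames(X)[qr_x$pivot[seq_len(qr_x$rank)]]
    stop_invalid(
      "singular design; columns beyond rank: ",
      paste(setdiff(colnames(X), cols), collapse = ", ")
    )
  }
  beta <- qr.coef(qr_x, yw)
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  n <- length(y)
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  logL <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  list(
    beta = beta, rss = rss, sigma2_ml = sigma2_ml, logL = logL,
    Xw = Xw, yw = yw, qr_x = qr_x, logdetV = logdetV
  )
}

# Whitened residual sum of squares of the intercept-only GLS at lambda.
gls_null_rss <- function(y, C, lambda) {
  X0 <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  gls_profile(y, X0, C, lambda)$rss
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = X beta + eps`, `eps ~ N(0, sigma^2 V(lambda))`, where
#' `V(lambda)` scales the off-diagonal Brownian covariance by lambda.
#' `beta` and `sigma^2` are profiled analytically; lambda is estimated by
#' maximum likelihood on \[0,1\] (golden-section/parabolic search plus
#' explicit endpoint checks, so a boundary optimum is reported as exactly
#' 0 or 1), or held fixed.
#'
#' Species are matched to tree tips through the data's row names. R-squared
#' is defined on the lambda-hat-whitened scale against the intercept-only
#' GLS refitted at the same lambda-hat. The AIC parameter count is
#' `k = ncol(X) + 2` (coefficients plus lambda and sigma^2).
#'
#' @param formula model formula; categorical predictors expand to
#'   reference-coded indicators.
#' @param data data frame with species row names matching tip labels.
#' @param tree rooted `phylo` covering all species in `data`.
#' @param lambda `"ML"` (default) or a fixed value in \[0,1\].
#' @param vcv optional precomputed Brownian covariance (rows/cols named by
#'   species); overrides `tree`. Useful when fitting many models on one
#'   phylogeny.
#' @return object of class `pgls` with methods `print`, `summary`, `coef`,
#'   `logLik`, `AIC`, `vcov`, `fitted`, `residuals`, `predict`, `simulate`,
#'   `nobs`.
#' @export
pgls <- function(formula, data, tree = NULL, lambda = "ML", vcv = NULL) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!all(is.finite(y)) || !all(is.finite(X)))
    stop_invalid("non-finite values in response or design")
  sp <- rownames(mf)
  n <- length(y)
  if (n < ncol(X) + 2)
    stop_invalid("need at least ", ncol(X) + 2, " species, got ", n)
  if (is.null(vcv)) {
    if (is.null(tree)) stop_invalid("supply either tree or vcv")
    C <- bm_covariance(tree, sp)
  } else {
    missing_sp <- setdiff(sp, rownames(vcv))
    if (length(missing_sp) > 0)
      stop_invalid("species not in vcv: ", paste(missing_sp, collapse = ", "))
    C <- vcv[sp, sp, drop = FALSE]
  }

  prof <- function(lam) gls_profile(y, X, C, lam)$logL
  if (identical(lambda, "ML")) {
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    ll <- c(prof(0), opt$objective, prof(1))
    lambda_hat <- cand[which.max(ll)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop_invalid("lambda must be 'ML' or a number in [0, 1]")
    lambda_hat <- lambda
  }
  fit <- gls_profile(y, X, C, lambda_hat)

  p_coef <- ncol(X)
  k <- p_coef + 2 # coefficients + lambda + sigma^2
  aic <- -2 * fit$logL + 2 * k
  # unbiased residual variance for coefficient SEs and t tests
  sigma2_unb <- fit$rss / (n - p_coef)
  XtX_inv <- chol2inv(qr.R(fit$qr_x))[order(fit$qr_x$pivot),
    order(fit$qr_x$pivot),
    drop = FALSE
  ]
  vcov_beta <- sigma2_unb * XtX_inv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov_beta))
  tval <- drop(fit$beta) / se
  pval <- 2 * stats::pt(abs(tval), df = n - p_coef, lower.tail = FALSE)

  rss0 <- gls_null_rss(y, C, lambda_hat)
  has_icept <- "(Intercept)" %in% colnames(X)
  r2 <- if (has_icept) 1 - fit$rss / rss0 else NA_real_
  p_slopes <- p_coef - as.integer(has_icept)
  adj <- if (has_icept && n > p_slopes + 1) {
    1 - (1 - r2) * (n - 1) / (n - p_slopes - 1)
  } else {
    NA_real_
  }

  coefs <- drop(fit$beta)
  names(coefs) <- colnames(X)
  structure(list(
    coefficients = coefs, se = se, tvalue = tval, pvalue = pval,
    vcov = vcov_beta, lambda = lambda_hat,
    lambda_mode = if (identical(lambda, "ML")) "ML" else "fixed",
    sigma2 = fit$sigma2_ml, logLik = fit$logL, aic = aic,
    r2 = r2, adj_r2 = adj, n = n, k = k, p = p_slopes,
    rss = fit$rss, null_rss = rss0,
    fitted.values = drop(X %*% fit$beta),
    residuals = y - drop(X %*% fit$beta),
    species = sp, terms = attr(mf, "terms"), xlevels = stats::.getXlevels(
      attr(mf, "terms"), mf
    ),
    C = C, call = match.call(), formula = formula
  ), class = "pgls")
}

#' Adjusted R-squared of a PGLS fit
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)` with `p` the number of
#' non-intercept coefficients. Also callable with raw numbers.
#'
#' @param fit a `pgls` object, or the R-squared value.
#' @param n,p species count and slope count when `fit` is numeric.
#' @return the adjusted R-squared (NA with a warning when `n <= p + 1`).
#' @export
adjusted_r2 <- function(fit, n = NULL, p = NULL) {
  if (inherits(fit, "pgls")) {
    r2 <- fit$r2
    n <- fit$n
    p <- fit$p
  } else {
    r2 <- fit
  }
  if (n <= p + 1) {
    warning("adjusted R-squared undefined: n <= p + 1")
    return(NA_real_)
  }
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' @export
print.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS (Pagel's lambda,", x$lambda_mode, "fit)\n")
  cat("  n =", x$n, " lambda =", format(x$lambda, digits = digits),
      " logLik =", format(x$logLik, digits = digits),
      " AIC =", format(x$aic, digits = digits), "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(
    Estimate = object$coefficients, `Std. Error` = object$se,
    `t value` = object$tvalue, `Pr(>|t|)` = object$pvalue
  )
  structure(list(
    call = object$call, coefficients = tab, lambda = object$lambda,
    sigma2 = object$sigma2, logLik = object$logLik, aic = object$aic,
    r2 = object$r2, adj_r2 = object$adj_r2, n = object$n
  ), class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS fit\n\nCall: ")
  print(x$call)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(
    "\nlambda =", format(x$lambda, digits = digits),
    " sigma2 =", format(x$sigma2, digits = digits),
    "\nlogLik =", format(x$logLik, digits = digits),
    " AIC =", format(x$aic, digits = digits),
    "\nR2 =", format(x$r2, digits = digits),
    " adj. R2 =", format(x$adj_r2, digits = digits),
    " n =", x$n, "\n"
  )
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik,
    df = object$k, nobs = object$n,
    class = "logLik"
  )
}

#' @export
nobs.pgls <- function(object, ...) object$n

#' @export
fitted.pgls <- function(object, ...) object$fitted.values

#' @export
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "response") return(r)
  V <- lambda_transform(object$C, object$lambda) * object$sigma2
  drop(backsolve(chol(V), r, transpose = TRUE))
}

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  drop(X %*% object$coefficients)
}

#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  V <- lambda_transform(object$C, object$lambda) * object$sigma2
  L <- chol(V)
  mu <- object$fitted.values
  sims <- with_seed(seed, {
    Z <- matrix(stats::rnorm(object$n * nsim), object$n, nsim)
    mu + crossprod(L, Z)
  })
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$species
  out
}
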