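# Phylogenetic principal component analysis: eigendecomposition of the
# evolutionary (phylogenetically whitened) covariance or correlation matrix
# with a GLS-estimated ancestral mean, lambda fitted by multivariate ML,
# and growth-form categories passively projected as score centroids.

# Multivariate profile log-likelihood of lambda for data X on covariance C.
ppca_loglik <- function(X, C, lambda) {
  V <- lambda_transform(C, lambda)
  L <- chol(V)
  n <- nrow(X)
  p <- ncol(X)
  one <- matrix(1, n, 1)
  w <- function(M) backsolve(L, M, transpose = TRUE)
  ones_w <- w(one)
  Xw <- w(X)
  a <- drop(crossprod(ones_w, Xw)) / sum(ones_w^2) # GLS ancestral mean
  Rw <- Xw - ones_w %*% t(a)
  S <- crossprod(Rw) / n # ML scatter
  eS <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(eS <= 1e-300)) return(-1e10) # rank-deficient scatter

  logdetV <- 2 * sum(log(diag(L)))
  -0.5 * (n * p * log(2 * pi) + p * logdetV + n * sum(log(eS)) + n * p)
}

#' Phylogenetic PCA
#'
#' Removes the GLS-estimated ancestral mean under `V(lambda-hat)`,
#' eigendecomposes the evolutionary covariance
#' `t(X - mu) V(lambda-hat)^{-1} (X - mu) / (n - 1)` (or its correlation
#' rescaling), and projects the centered data onto the eigenvectors.
#' Lambda is estimated by multivariate ML on \[0,1\] (with endpoint
#' checks) or held fixed. Correlation mode is the default because trait
#' tables mix units (cm, %, per-mil, years). Component signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param X numeric matrix or data frame, species as row names; complete
#'   cases of at least 3 species required.
#' @param tree phylogeny covering the species.
#' @param lambda `"ML"` (default) or a fixed value in \[0,1\].
#' @param mode `"correlation"` (standardized variables) or `"covariance"`.
#' @return object of class `phylo_pca` with `loadings`, `scores`,
#'   `eigenvalues`, `percent_variance`, `lambda`, `center` (ancestral
#'   means), `scale` (evolutionary SDs in correlation mode).
#' @export
phylo_pca <- function(X, tree, lambda = "ML",
                      mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (!is.numeric(X)) stop_invalid("X must be numeric")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) stop_invalid("need at least 3 complete species")
  C <- bm_covariance(tree, rownames(X))

  if (identical(lambda, "ML")) {
    opt <- stats::optimize(function(l) ppca_loglik(X, C, l), c(0, 1),
      maximum = TRUE, tol = 1e-6
    )
    cand <- c(0, opt$maximum, 1)
    ll <- c(ppca_loglik(X, C, 0), opt$objective, ppca_loglik(X, C, 1))
    lambda_hat <- cand[which.max(ll)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop_invalid("lambda must be 'ML' or a number in [0, 1]")
    lambda_hat <- lambda
  }

  V <- lambda_transform(C, lambda_hat)
  L <- chol(V)
  one <- matrix(1, n, 1)
  w <- function(M) backsolve(L, M, transpose = TRUE)
  ones_w <- w(one)
  Xw <- w(X)
  a <- drop(crossprod(ones_w, Xw)) / sum(ones_w^2)
  Xc <- X - one %*% t(a)
  R <- crossprod(w(Xc)) / (n - 1) # evolutionary covariance
  scale_sd <- rep(1, p)
  if (mode == "correlation") {
    scale_sd <- sqrt(diag(R))
    if (any(scale_sd == 0)) stop_invalid("zero-variance column in X")
    R <- R / tcrossprod(scale_sd)
    Xc <- sweep(Xc, 2, scale_sd, "/")
  }
  eig <- eigen(R, symmetric = TRUE)
  n_comp <- min(n - 1, p)
  if (any(eig$values[seq_len(n_comp)] < -1e-8))
    warning("rank-deficient matrix: negative eigenvalues truncated")
  vals <- pmax(eig$values[seq_len(n_comp)], 0)
  vecs <- eig$vectors[, seq_len(n_comp), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(n_comp)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(X), paste0("PC", seq_len(n_comp)))
  scores <- Xc %*% vecs
  structure(list(
    loadings = vecs, scores = scores, eigenvalues = vals,
    percent_variance = 100 * vals / sum(eig$values[seq_len(n_comp)]),
    lambda = lambda_hat, mode = mode, center = a, scale = scale_sd,
    n = n
  ), class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, digits = 3, ...) {
  cat("Phylogenetic PCA (", x$mode, " mode), n = ", x$n,
    ", lambda = ", format(x$lambda, digits = digits), "\n",
    sep = ""
  )
  pv <- round(x$percent_variance, 1)
  cat("  variance explained:", paste0(
    colnames(x$loadings), "=", pv, "%",
    collapse = " "
  ), "\n")
  invisible(x)
}

#' Passive projection of growth-form categories
#'
#' Centroid (mean score) of each category's member species on the first
#' two components; categories with fewer than 2 members are flagged.
#'
#' @param scores species-by-component score matrix (a `phylo_pca` object
#'   is also accepted).
#' @param categories factor or character vector of category labels, named
#'   by species or aligned with the score rows.
#' @return data frame: `category`, `n`, `PC1`, `PC2`, `flagged`.
#' @export
project_categories <- function(scores, categories) {
  if (inherits(scores, "phylo_pca")) scores <- scores$scores
  if (length(categories) == 0 || all(is.na(categories)))
    stop_invalid("empty category set")
  if (!is.null(names(categories))) {
    categories <- categories[rownames(scores)]
  }
  if (length(categories) != nrow(scores))
    stop_invalid("categories must align with score rows")
  f <- droplevels(factor(categories))
  cent <- t(vapply(
    levels(f),
    function(l) colMeans(scores[f == l, 1:2, drop = FALSE]),
    numeric(2)
  ))
  out <- data.frame(
    category = levels(f), n = as.integer(table(f)),
    PC1 = cent[, 1], PC2 = cent[, 2],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$flagged <- out$n < 2
  out
}
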