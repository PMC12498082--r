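# Sequential, category-wise exhaustive-AIC model selection: all predictor
# subsets within each trait category are fitted as PGLS models (lambda
# re-estimated by ML in every candidate), the best-AIC model is kept, its
# predictors become covariates for the next category, and each selected
# predictor's importance is the AIC penalty of the best model that excludes
# it. Categories run morphology -> anatomy -> physiology by default,
# reflecting the levels-of-adaptation ordering.

#' Default trait categories
#'
#' The three predictor categories used in the sequential search. Growth
#' form counts as one predictor: its indicator columns enter and leave the
#' design as a block.
#'
#' @return named list of character vectors.
#' @export
default_categories <- function() {
  list(
    morphology = c("Height", "growth_form"),
    anatomy = c(
      "Bark_xylem", "Longevity", "Mechanical_tissue",
      "Storage_tissue", "Ring_width"
    ),
    physiology = c(
      "LNC", "LPC", "LCC", "RNC", "RPC", "d15N", "d13C",
      "Fructan", "Starch", "Free_sugar"
    )
  )
}

#' Enumerate all predictor subsets of a category
#'
#' Generates the `2^p` candidate designs (every subset of the predictors,
#' each united with the fixed covariates, including the covariates-only
#' design) in deterministic order: by subset size, then lexicographically.
#'
#' @param predictors character vector of candidate predictors (at most 12).
#' @param covariates character vector carried into every design.
#' @return list of lists with elements `subset` and `terms`.
#' @export
enumerate_subsets <- function(predictors, covariates = character(0)) {
  if (length(predictors) > 12)
    stop_invalid("more than 12 predictors (", length(predictors),
                 "): exhaustive search refused")
  if (any(duplicated(c(predictors, covariates))))
    stop_invalid("duplicate names between predictors and covariates")
  out <- list()
  for (s in 0:length(predictors)) {
    combos <- if (s == 0) list(character(0)) else
      utils::combn(sort(predictors), s, simplify = FALSE)
    combos <- combos[order(vapply(combos, paste, "", collapse = "\r"))]
    out <- c(out, lapply(combos, function(sub) {
      list(subset = sub, terms = c(covariates, sub))
    }))
  }
  out
}

design_formula <- function(response, terms) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

#' Exhaustive AIC selection within one trait category
#'
#' Fits every subset of `predictors` (always together with `covariates`)
#' as a PGLS model with ML lambda, picks the lowest-AIC design (ties go to
#' fewer predictors, then lexicographic order), and computes each selected
#' predictor's importance as the AIC of the best design excluding that
#' predictor (re-searched over all such designs) minus the best AIC.
#' Predictors whose omission does not worsen the fit (importance <= 0)
#' are not retained. Designs with more parameters than the data support
#' are skipped and logged. Near-ties (delta AIC < 2) are recorded.
#'
#' @param data data frame, species as row names; complete cases over the
#'   response, predictors and covariates are used.
#' @param tree phylogeny (or pass `vcv`).
#' @param response response column name.
#' @param predictors candidate predictors of this category.
#' @param covariates fixed covariates from earlier stages.
#' @param category label stored in the result.
#' @param importance `"research"` (default; best model over all subsets
#'   excluding the predictor) or `"drop_one"` (best subset minus that
#'   single term).
#' @param vcv optional precomputed Brownian covariance.
#' @return list describing the stage (best subset, fit, importances,
#'   near-ties, skipped designs, adjusted R-squared, lambda).
#' @export
select_category <- function(data, tree = NULL, response, predictors,
                            covariates = character(0),
                            category = "category",
                            importance = c("research", "drop_one"),
                            vcv = NULL) {
  importance <- match.arg(importance)
  vars <- c(response, predictors, covariates)
  missing_cols <- setdiff(vars, colnames(data))
  if (length(missing_cols) > 0)
    stop_invalid("columns not in data: ", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  if (is.null(vcv)) {
    if (is.null(tree)) stop_invalid("supply either tree or vcv")
    vcv <- bm_covariance(tree, rownames(d))
  }
  designs <- enumerate_subsets(predictors, covariates)
  fits <- vector("list", length(designs))
  aics <- rep(NA_real_, length(designs))
  skipped <- character(0)
  for (i in seq_along(designs)) {
    f <- design_formula(response, designs[[i]]$terms)
    fit <- tryCatch(pgls(f, d, lambda = "ML", vcv = vcv),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      skipped <- c(skipped, paste0(
        "{", paste(designs[[i]]$terms, collapse = ","), "}: ",
        conditionMessage(fit)
      ))
    } else {
      fits[[i]] <- fit
      aics[i] <- fit$aic
    }
  }
  if (all(is.na(aics))) stop_invalid("all candidate designs failed")

  # best design: lowest AIC; ties -> fewer predictors, then lexicographic
  ok <- which(!is.na(aics))
  tied <- ok[aics[ok] <= min(aics[ok]) + 1e-9]
  sizes <- vapply(designs[tied], function(x) length(x$subset), integer(1))
  tied <- tied[sizes == min(sizes)]
  keys <- vapply(designs[tied], function(x) paste(x$subset, collapse = "\r"), "")
  best_i <- tied[order(keys)[1]]
  best_aic <- aics[best_i]
  best_subset <- designs[[best_i]]$subset

  imp <- numeric(0)
  if (length(best_subset) > 0) {
    imp <- vapply(best_subset, function(pr) {
      if (importance == "research") {
        without <- which(!vapply(
          designs, function(x) pr %in% x$subset, logical(1)
        ) & !is.na(aics))
        min(aics[without]) - best_aic
      } else {
        sub <- setdiff(best_subset, pr)
        j <- which(vapply(designs, function(x) setequal(x$subset, sub),
                          logical(1)))[1]
        aics[j] - best_aic
      }
    }, numeric(1))
  }
  # the exclusion rule: a predictor whose omission improves (or leaves
  # unchanged) the fit is not considered to influence the response
  selected <- names(imp)[imp > 1e-9]
  if (!setequal(selected, best_subset)) {
    f <- design_formula(response, c(covariates, selected))
    final_fit <- pgls(f, d, lambda = "ML", vcv = vcv)
  } else {
    selected <- best_subset
    final_fit <- fits[[best_i]]
  }

  nt <- which(!is.na(aics) & aics - best_aic < 2)
  near_ties <- data.frame(
    subset = vapply(designs[nt], function(x) {
      paste(x$subset, collapse = "+")
    }, ""),
    delta_aic = aics[nt] - best_aic, stringsAsFactors = FALSE
  )
  near_ties <- near_ties[order(near_ties$delta_aic, near_ties$subset), ]
  rownames(near_ties) <- NULL

  list(
    category = category, response = response, predictors = predictors,
    covariates = covariates, n = nrow(d),
    candidate_count = length(designs), n_fitted = sum(!is.na(aics)),
    skipped = skipped, best_subset = best_subset, selected = selected,
    importance = imp, near_ties = near_ties, best_aic = best_aic,
    fit = final_fit, adj_r2 = final_fit$adj_r2, lambda = final_fit$lambda
  )
}

#' Sequential category-wise model selection
#'
#' Runs [select_category()] over the trait categories in order; the
#' predictors selected at each stage are carried forward as covariates for
#' all later stages. The resulting ledger records, per stage, the best
#' subset, each selected predictor's delta-AIC importance, near-tie
#' subsets, and the cumulative adjusted R-squared with its increment over
#' the previous stage (the sequence is reported as-is, not forced
#' monotone).
#'
#' @param data data frame, species as row names.
#' @param tree phylogeny.
#' @param categories named list of predictor vectors, in stage order.
#' @param response response column name.
#' @param importance importance variant, see [select_category()].
#' @return object of class `selection_ledger`.
#' @export
sequential_selection <- function(data, tree, categories = default_categories(),
                                 response = "optimum_m",
                                 importance = "research") {
  if (any(duplicated(unlist(categories))))
    stop_invalid("categories must be disjoint")
  vcv <- bm_covariance(tree, intersect(rownames(data), tree$tip.label))
  covariates <- character(0)
  stages <- list()
  prev_adj <- 0
  for (nm in names(categories)) {
    st <- select_category(data,
      response = response,
      predictors = categories[[nm]], covariates = covariates,
      category = nm, importance = importance, vcv = vcv
    )
    st$cum_adj_r2 <- st$adj_r2
    st$adj_r2_increment <- st$adj_r2 - prev_adj
    prev_adj <- st$adj_r2
    stages[[nm]] <- st
    covariates <- c(covariates, st$selected)
  }
  structure(
    list(stages = stages, response = response, categories = categories,
         final_predictors = covariates),
    class = "selection_ledger"
  )
}

#' @export
print.selection_ledger <- function(x, digits = 3, ...) {
  cat("Sequential exhaustive-AIC selection on", x$response, "\n")
  for (st in x$stages) {
    cat("\n[", st$category, "] ", st$candidate_count, " designs, n = ",
      st$n, "\n",
      sep = ""
    )
    if (length(st$selected) == 0) {
      cat("  selected: (covariates only)\n")
    } else {
      cat("  selected:", paste(st$selected, collapse = ", "), "\n")
      for (pr in names(st$importance)) {
        cat("    dAIC when", pr, "omitted:",
            format(st$importance[[pr]], digits = digits), "\n")
      }
    }
    cat(
      "  adj. R2 =", format(100 * st$cum_adj_r2, digits = digits),
      "% (", ifelse(st$adj_r2_increment >= 0, "+", ""),
      format(100 * st$adj_r2_increment, digits = digits), "%)",
      " lambda =", format(st$lambda, digits = digits), "\n"
    )
    if (nrow(st$near_ties) > 1) {
      cat("  near-ties (dAIC < 2):",
          paste0("{", st$near_ties$subset, "}", collapse = " "), "\n")
    }
  }
  invisible(x)
}

# Canonical plain-list representation of a ledger (JSON-serializable).
ledger_summary <- function(ledger) {
  stopifnot(inherits(ledger, "selection_ledger"))
  list(
    response = ledger$response,
    final_predictors = as.list(ledger$final_predictors),
    stages = lapply(ledger$stages, function(st) {
      list(
        category = st$category,
        predictors = as.list(st$predictors),
        covariates = as.list(st$covariates),
        n = st$n, candidate_count = st$candidate_count,
        best_subset = as.list(st$best_subset),
        selected = as.list(st$selected),
        importance = as.list(st$importance),
        near_ties = list(
          subset = as.list(st$near_ties$subset),
          delta_aic = as.list(st$near_ties$delta_aic)
        ),
        best_aic = st$best_aic, adj_r2 = st$adj_r2,
        cum_adj_r2 = st$cum_adj_r2,
        adj_r2_increment = st$adj_r2_increment,
        lambda = st$lambda,
        coefficients = as.list(stats::coef(st$fit))
      )
    })
  )
}

#' Write a selection ledger to JSON
#'
#' Serializes the ledger summary (subsets, importances, near-ties, AICs,
#' adjusted R-squared staircase, coefficients) at full numeric precision,
#' so that write -> read -> write round-trips losslessly.
#'
#' @param ledger a `selection_ledger`, or a summary list as returned by
#'   [read_ledger()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  if (inherits(ledger, "selection_ledger")) ledger <- ledger_summary(ledger)
  jsonlite::write_json(ledger, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a selection ledger summary from JSON
#'
#' @param path file written by [write_ledger()].
#' @return the ledger summary list.
#' @export
read_ledger <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
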