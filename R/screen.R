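# Single-predictor trait-optimum screens per habitat, phylogenetic habitat
# contrasts, skewness-motivated predictor transformations, and
# Holm-Bonferroni family-wise error control.

#' Transform a skewed predictor
#'
#' `"log"` first replaces exact zeros by half of the second-smallest
#' distinct value (so zero-containing traits admit a log), then takes the
#' natural logarithm; `"sqrt"` requires nonnegative values; `"none"` is the
#' identity. The rule applied and any zero substitution are recorded as
#' attributes for provenance.
#'
#' @param values numeric vector.
#' @param rule one of `"none"`, `"sqrt"`, `"log"`.
#' @param name trait name used in error messages.
#' @return transformed vector with attributes `transform` and
#'   `zero_substituted`.
#' @export
transform_predictor <- function(values, rule = c("none", "sqrt", "log"),
                                name = "trait") {
  rule <- match.arg(rule)
  out <- values
  n_sub <- 0L
  if (rule == "sqrt") {
    if (any(values < 0, na.rm = TRUE))
      stop_invalid("negative values in '", name, "' under sqrt transform")
    out <- sqrt(values)
  } else if (rule == "log") {
    if (any(values < 0, na.rm = TRUE))
      stop_invalid("negative values in '", name, "' under log transform")
    zero <- !is.na(values) & values == 0
    if (any(zero)) {
      distinct <- sort(unique(values[!is.na(values)]))
      if (length(distinct) < 2)
        stop_invalid("cannot substitute zeros in '", name,
                     "': fewer than two distinct values")
      out[zero] <- distinct[2] / 2
      n_sub <- sum(zero)
    }
    out <- log(out)
  }
  attr(out, "transform") <- rule
  attr(out, "zero_substituted") <- n_sub
  out
}

#' Holm-Bonferroni step-down decisions
#'
#' Controls the family-wise error rate at `alpha`: p-values are sorted
#' ascending and `p_(i)` is rejected while `p_(i) <= alpha / (m - i + 1)`,
#' stopping at the first failure. Decisions are returned in input order
#' (invariant to it), with the Holm-adjusted p-values attached.
#'
#' @param pvalues numeric vector in \[0,1\] (names kept).
#' @param alpha family-wise error rate.
#' @return logical rejection vector with attribute `adjusted`.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_invalid("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "holm")
  out <- adj <= alpha
  names(out) <- names(pvalues)
  attr(out, "adjusted") <- adj
  out
}

#' Single-predictor trait-optimum scan within one habitat
#'
#' Fits one PGLS (ML lambda) per trait with the elevational optimum as
#' response, within the species pool of one habitat. Continuous traits are
#' optionally transformed first ([transform_predictor()]); their slope is
#' tested with a two-sided t test. The categorical growth form is tested as
#' a block with a likelihood-ratio comparison against the intercept-only
#' PGLS. Holm-Bonferroni is applied across the habitat's family of tested
#' traits. Direction arrows accompany slopes whose raw p-value is below
#' `alpha` (mirroring up/down annotation conventions for trait tables).
#'
#' @param data data frame with species row names containing the response,
#'   the traits and a `habitat` column.
#' @param tree phylogeny.
#' @param habitat habitat level to scan (e.g. `"steppe"` or `"alpine"`).
#' @param traits trait columns to test; default: all 16 continuous traits
#'   plus `growth_form` that are present in `data`.
#' @param response response column (default `"optimum_m"`).
#' @param transforms optional named list/vector of transform rules per
#'   trait (`"none"`, `"sqrt"`, `"log"`).
#' @param alpha significance level (default 0.05).
#' @param habitat_col habitat column name.
#' @return data frame with one row per tested trait: `trait`, `habitat`,
#'   `n`, `slope`, `p_raw`, `p_holm`, `significant`, `direction`,
#'   `transform`. Traits skipped (zero variance) are reported with NA
#'   p-values and a note.
#' @export
single_predictor_scan <- function(data, tree, habitat, traits = NULL,
                                  response = "optimum_m", transforms = NULL,
                                  alpha = 0.05, habitat_col = "habitat") {
  if (!habitat %in% data[[habitat_col]])
    stop_invalid("no species with habitat '", habitat, "'")
  d <- droplevels(data[data[[habitat_col]] == habitat, , drop = FALSE])
  if (is.null(traits)) {
    traits <- intersect(
      c(names(.trait_maps), "growth_form"),
      colnames(d)
    )
  }
  vcv <- bm_covariance(tree, intersect(rownames(d), tree$tip.label))
  rows <- lapply(traits, function(tr) {
    di <- d[stats::complete.cases(d[, c(response, tr)]), , drop = FALSE]
    base <- data.frame(
      trait = tr, habitat = habitat, n = nrow(di), slope = NA_real_,
      p_raw = NA_real_, transform = "none", note = "",
      stringsAsFactors = FALSE
    )
    if (is.factor(di[[tr]]) || is.character(di[[tr]])) {
      di[[tr]] <- droplevels(factor(di[[tr]]))
      if (nlevels(di[[tr]]) < 2) {
        base$note <- "single level; skipped"
        return(base)
      }
      full <- pgls(design_formula(response, tr), di, vcv = vcv)
      null <- pgls(design_formula(response, character(0)), di, vcv = vcv)
      lr <- max(0, 2 * (full$logLik - null$logLik))
      base$p_raw <- stats::pchisq(lr, df = nlevels(di[[tr]]) - 1,
                                  lower.tail = FALSE)
      return(base)
    }
    rule <- if (!is.null(transforms) && tr %in% names(transforms))
      transforms[[tr]] else "none"
    di[[tr]] <- transform_predictor(di[[tr]], rule, name = tr)
    base$transform <- rule
    if (stats::var(di[[tr]]) == 0) {
      base$note <- "zero variance; skipped"
      return(base)
    }
    fit <- pgls(design_formula(response, tr), di, vcv = vcv)
    base$slope <- unname(stats::coef(fit)[2])
    base$p_raw <- unname(fit$pvalue[2])
    base
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p_raw)
  out$p_holm <- NA_real_
  out$significant <- NA
  if (any(tested)) {
    dec <- holm_bonferroni(out$p_raw[tested], alpha)
    out$p_holm[tested] <- attr(dec, "adjusted")
    out$significant[tested] <- unname(dec)
  }
  out$direction <- ifelse(
    tested & !is.na(out$slope) & out$p_raw < alpha,
    ifelse(out$slope > 0, "up", "down"), ""
  )
  out[, c(
    "trait", "habitat", "n", "slope", "p_raw", "p_holm",
    "significant", "direction", "transform", "note"
  )]
}

#' Phylogenetic habitat contrast of one trait
#'
#' Tests whether a trait differs between the steppe and alpine pools.
#' Default: PGLS (ML lambda) of the trait on a habitat indicator, i.e. a
#' phylogenetic two-group contrast; `method = "welch"` gives the ordinary
#' Welch two-sample test as a non-phylogenetic sensitivity check.
#'
#' @param trait trait column name.
#' @param data data frame with species row names and a `habitat` column
#'   containing both habitats.
#' @param tree phylogeny (ignored for `"welch"`).
#' @param method `"pgls"` or `"welch"`.
#' @param habitat_col habitat column name.
#' @return list with `p_value`, `estimate` (group difference), `method`.
#' @export
habitat_contrast <- function(trait, data, tree = NULL,
                             method = c("pgls", "welch"),
                             habitat_col = "habitat") {
  method <- match.arg(method)
  d <- data[stats::complete.cases(data[, c(trait, habitat_col)]), ,
    drop = FALSE
  ]
  hab <- droplevels(factor(d[[habitat_col]]))
  if (nlevels(hab) < 2) stop_invalid("both habitats must be represented")
  if (method == "welch") {
    tt <- stats::t.test(d[[trait]] ~ hab)
    return(list(
      p_value = tt$p.value,
      estimate = unname(diff(rev(tt$estimate))), method = "welch"
    ))
  }
  d[[habitat_col]] <- hab
  fit <- pgls(design_formula(trait, habitat_col), d, tree = tree)
  list(
    p_value = unname(fit$pvalue[2]),
    estimate = unname(stats::coef(fit)[2]), method = "pgls"
  )
}
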