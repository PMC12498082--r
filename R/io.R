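# Readers/writers, input validation, and the end-to-end pipeline:
# occurrences -> HOF optima -> per-habitat sequential selection, trait
# screen and phylogenetic PCA, with deterministic seeding and provenance.

#' Read a rooted phylogeny from Newick
#'
#' Thin wrapper over [ape::read.tree()] that normalizes tip labels
#' (whitespace to underscores, quotes stripped), accepts polytomies and
#' rejects zero-length terminal branches with a clear message.
#'
#' @param path Newick file.
#' @return a `phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop_invalid("tree file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
    error = function(e) e
  )
  if (inherits(tree, "error") || is.null(tree))
    stop_invalid(
      "malformed Newick in ", path, ": ",
      if (inherits(tree, "error")) conditionMessage(tree) else "parse failed"
    )
  tree$tip.label <- gsub("[\"']", "", gsub("\\s+", "_", tree$tip.label))
  if (is.null(tree$edge.length))
    stop_invalid("tree has no branch lengths")
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] <= 0))
    stop_invalid(
      "zero- or negative-length terminal branches for tips: ",
      paste(tree$tip.label[tree$edge[term, 2][
        tree$edge.length[term] <= 0
      ]], collapse = ", ")
    )
  tree
}

#' Write a phylogeny to Newick
#' @param tree `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write a species trait table (CSV)
#'
#' The CSV uses one row per species with a `species` column plus trait
#' columns; row names carry the species on the R side. Duplicate species
#' rows are rejected.
#'
#' @param path CSV file.
#' @return data frame with species row names; `growth_form` and `habitat`
#'   become factors when present.
#' @export
read_trait_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species" %in% names(d)) stop_invalid("traits CSV needs a 'species' column")
  d$species <- gsub("\\s+", "_", d$species)
  if (any(duplicated(d$species)))
    stop_invalid(
      "duplicate species rows: ",
      paste(unique(d$species[duplicated(d$species)]), collapse = ", ")
    )
  rownames(d) <- d$species
  d$species <- NULL
  if ("growth_form" %in% names(d))
    d$growth_form <- factor(d$growth_form, levels = growth_form_levels())
  if ("habitat" %in% names(d))
    d$habitat <- factor(d$habitat, levels = c("steppe", "alpine"))
  d
}

#' @rdname read_trait_table
#' @param traits data frame with species row names.
#' @export
write_trait_table <- function(traits, path) {
  out <- cbind(species = rownames(traits), traits)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write an occurrence table (CSV)
#'
#' Columns `locality`, `elevation_m`, `species`, `present` (binary).
#' Duplicate (locality, species) records are rejected.
#'
#' @param path CSV file.
#' @return data frame.
#' @export
read_occurrence_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locality", "elevation_m", "species", "present")
  if (!all(need %in% names(d)))
    stop_invalid("occurrences CSV needs columns ", paste(need, collapse = ", "))
  if (!all(d$present %in% c(0L, 1L)))
    stop_invalid("present must be binary 0/1")
  if (any(duplicated(d[, c("locality", "species")])))
    stop_invalid("duplicate (locality, species) records")
  d$species <- gsub("\\s+", "_", d$species)
  d
}

#' @rdname read_occurrence_table
#' @param occurrences data frame.
#' @export
write_occurrence_table <- function(occurrences, path) {
  utils::write.csv(occurrences, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Cross-validate the pipeline inputs
#'
#' Checks species sets (tree vs traits vs occurrences), trait-range
#' invariants (percent traits in \[0,100\]; Height, Longevity, Ring width
#' nonnegative; growth form and habitat drawn from their level sets) and
#' elevation bounds. Always returns a report; `hard = TRUE` issues should
#' halt a pipeline, warnings should not.
#'
#' @param tree phylogeny (or NULL to skip tree checks).
#' @param traits trait table with species row names.
#' @param occurrences occurrence table (or NULL).
#' @param elev_range optional configured gradient bounds; elevations
#'   outside them raise warnings.
#' @return data frame with columns `hard`, `issue`.
#' @export
validate_inputs <- function(tree = NULL, traits = NULL, occurrences = NULL,
                            elev_range = NULL) {
  issues <- data.frame(hard = logical(0), issue = character(0))
  add <- function(hard, msg) rbind(issues, data.frame(hard = hard, issue = msg))
  if (!is.null(traits)) {
    if (any(duplicated(rownames(traits))))
      issues <- add(TRUE, "duplicate species in traits")
    if (!is.null(tree)) {
      extra <- setdiff(rownames(traits), tree$tip.label)
      if (length(extra) > 0)
        issues <- add(TRUE, paste(
          "species in traits but not tree:",
          paste(extra, collapse = ", ")
        ))
    }
    pct <- intersect(c(
      "Mechanical_tissue", "Storage_tissue", "LNC", "LPC", "LCC",
      "RNC", "RPC", "Starch", "Fructan", "Free_sugar"
    ), colnames(traits))
    for (cn in pct) {
      v <- traits[[cn]]
      if (any(v < 0 | v > 100, na.rm = TRUE))
        issues <- add(TRUE, paste0(cn, " outside [0, 100]"))
    }
    for (cn in intersect(c("Height", "Longevity", "Ring_width"),
                         colnames(traits))) {
      if (any(traits[[cn]] < 0, na.rm = TRUE))
        issues <- add(TRUE, paste0(cn, " negative"))
    }
    if ("growth_form" %in% colnames(traits)) {
      bad <- !is.na(traits$growth_form) &
        !as.character(traits$growth_form) %in% growth_form_levels()
      if (any(bad)) issues <- add(TRUE, "growth_form outside level set")
    }
    if ("habitat" %in% colnames(traits)) {
      bad <- !is.na(traits$habitat) &
        !as.character(traits$habitat) %in% c("steppe", "alpine")
      if (any(bad)) issues <- add(TRUE, "habitat outside {steppe, alpine}")
    }
  }
  if (!is.null(occurrences)) {
    if (!all(occurrences$present %in% c(0, 1)))
      issues <- add(TRUE, "non-binary presence values")
    if (!is.null(elev_range)) {
      out_of_range <- occurrences$elevation_m < elev_range[1] |
        occurrences$elevation_m > elev_range[2]
      if (any(out_of_range))
        issues <- add(FALSE, paste(
          sum(out_of_range),
          "elevation(s) outside the configured gradient"
        ))
    }
    if (!is.null(tree)) {
      extra <- setdiff(unique(occurrences$species), tree$tip.label)
      if (length(extra) > 0)
        issues <- add(FALSE, paste(
          "species in occurrences but not tree:",
          paste(extra, collapse = ", ")
        ))
    }
  }
  issues
}

#' Run the full trait-optimum pipeline
#'
#' Validates the inputs, estimates species elevational optima with the HOF
#' hierarchy, then per habitat runs the sequential exhaustive-AIC trait
#' selection, the single-predictor Holm screen, and the phylogenetic PCA
#' over traits plus optima/minima/maxima. Deterministic given the config.
#'
#' @param tree phylogeny.
#' @param traits trait table with species row names, `growth_form` and
#'   `habitat` columns.
#' @param occurrences occurrence table.
#' @param categories stage list for the sequential selection.
#' @param threshold_frac HOF range-limit threshold.
#' @param transforms optional transform map for the screen.
#' @param alpha screen significance level.
#' @param out_dir optional directory; when given, artifacts are written
#'   (optima CSV, per-habitat ledger JSON and scan CSV, PPCA JSON, config
#'   echo YAML).
#' @param habitats habitat levels to analyze.
#' @return list with `validation`, `optima`, and per-habitat `selection`,
#'   `scan`, `ppca` results.
#' @export
run_pipeline <- function(tree, traits, occurrences,
                         categories = default_categories(),
                         threshold_frac = 0.05, transforms = NULL,
                         alpha = 0.05, out_dir = NULL,
                         habitats = c("steppe", "alpine")) {
  report <- validate_inputs(tree, traits, occurrences)
  if (any(report$hard))
    stop_invalid(
      "input validation failed:\n  ",
      paste(report$issue[report$hard], collapse = "\n  ")
    )
  optima <- estimate_optima(occurrences, threshold_frac = threshold_frac)
  usable <- optima[!is.na(optima$optimum_m), ]
  data <- traits[rownames(traits) %in% usable$species, , drop = FALSE]
  data$optimum_m <- usable$optimum_m[match(rownames(data), usable$species)]
  data$min_m <- usable$min_m[match(rownames(data), usable$species)]
  data$max_m <- usable$max_m[match(rownames(data), usable$species)]

  per_habitat <- lapply(habitats, function(h) {
    dh <- droplevels(data[data$habitat == h, , drop = FALSE])
    keep <- intersect(rownames(dh), tree$tip.label)
    th <- ape::keep.tip(tree, keep)
    dh <- dh[keep, , drop = FALSE]
    sel <- sequential_selection(dh, th, categories, response = "optimum_m")
    scan <- single_predictor_scan(dh, th,
      habitat = h, transforms = transforms,
      alpha = alpha
    )
    num <- vapply(dh, is.numeric, logical(1))
    pca_cols <- setdiff(names(dh)[num], c("true_optimum", "clipped"))
    pca <- phylo_pca(dh[, pca_cols, drop = FALSE], th)
    centroids <- if ("growth_form" %in% names(dh)) {
      project_categories(pca, stats::setNames(dh$growth_form, rownames(dh)))
    } else {
      NULL
    }
    list(
      habitat = h, n = nrow(dh), selection = sel, scan = scan,
      ppca = pca, centroids = centroids
    )
  })
  names(per_habitat) <- habitats

  res <- list(
    validation = report, optima = optima, habitats = per_habitat
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(optima, file.path(out_dir, "optima.csv"),
      row.names = FALSE
    )
    for (h in habitats) {
      ph <- per_habitat[[h]]
      write_ledger(ph$selection, file.path(out_dir, paste0("ledger_", h, ".json")))
      utils::write.csv(ph$scan, file.path(out_dir, paste0("scan_", h, ".csv")),
        row.names = FALSE
      )
      jsonlite::write_json(
        list(
          lambda = ph$ppca$lambda,
          percent_variance = ph$ppca$percent_variance,
          loadings = as.data.frame(ph$ppca$loadings),
          centroids = ph$centroids
        ),
        file.path(out_dir, paste0("ppca_", h, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns"
      )
    }
    yaml::write_yaml(
      list(
        habitats = habitats, threshold_frac = threshold_frac,
        alpha = alpha, categories = categories,
        version = as.character(utils::packageVersion("elevtrait"))
      ),
      file.path(out_dir, "config_echo.yaml")
    )
  }
  res
}
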