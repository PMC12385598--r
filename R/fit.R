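#' Fit consumer sensory attribute weights from questionnaire ratings
#'
#' The package's central estimator. For every drinking-frequency cohort and
#' every hierarchy level (the four primary dimensions, and the sub-attributes
#' within each dimension) it derives:
#'
#' * subjective AHP weights — cohort attribute means are min-max mapped onto
#'   the Saaty 1-9 scale and converted to priorities of the induced ratio
#'   pairwise matrix ([minmax_to_saaty()], [ahp_weights()]);
#' * objective entropy weights from the dispersion of the raw ratings
#'   ([entropy_weights()]);
#' * composite weights, the 7:3 (by default) fusion of the two
#'   ([fuse_weights()]).
#'
#' Cohorts are then blended into market-wide comprehensive weights with
#' population coefficients `C_i = f_i N_i / sum(f N)` ([cohort_coefficients()],
#' [aggregate_cohorts()]). By default the AHP layer is aggregated (see
#' `aggregate_layer`): aggregating the composite layer is the formula as
#' usually written, but aggregating the subjective layer keeps the
#' comprehensive weights interpretable as stated importance and is the
#' package default; the choice is recorded on the fitted object.
#'
#' @param ratings A `ratings_table` (see [ratings_table()], [read_ratings()]).
#' @param cohorts Cohort definitions with `cohort` and `frequency_factor`
#'   columns; default [pale_lager_cohorts()].
#' @param alpha Subjective share of the AHP:EWM fusion, default 0.7.
#' @param aggregate_layer Which per-cohort layer feeds the comprehensive
#'   aggregation: `"ahp"` (default) or `"composite"`.
#' @return An object of class `sensory_weights` with components
#'   `weights` (long data.frame: cohort, level, dimension, attribute, ahp,
#'   ewm, composite), `comprehensive` (data.frame: level, dimension,
#'   attribute, weight), `coefficients` (a `cohort_coefficients`),
#'   `means` (per-cohort attribute summaries), `alpha`, `aggregate_layer`,
#'   `hierarchy`, `call`.
#' @seealso [coef.sensory_weights()], [build_scale()]
#' @examples
#' h <- pale_lager_hierarchy()
#' r <- simulate_survey(n = 300, hierarchy = h, seed = 1)
#' fit <- sensory_weights(r)
#' coef(fit, level = "dimension")
#' @export
sensory_weights <- function(ratings, cohorts = pale_lager_cohorts(),
                            alpha = 0.7,
                            aggregate_layer = c("ahp", "composite")) {
  aggregate_layer <- match.arg(aggregate_layer)
  stopifnot(inherits(ratings, "ratings_table"))
  hierarchy <- attr(ratings, "hierarchy")
  labels <- cohorts$cohort
  sizes <- vapply(labels, function(cc) sum(ratings$cohort == cc), integer(1))
  if (any(sizes < 2L))
    stop("every cohort needs at least 2 respondents; short: ",
         paste(labels[sizes < 2L], collapse = ", "), call. = FALSE)

  mean_sub <- attribute_means(ratings, "subattribute")
  mean_dim <- attribute_means(ratings, "dimension")

  # one level per dimension (its sub-attributes) plus the dimension level
  levels <- c(list(dimension = hierarchy$dimensions),
              setNames(hierarchy$children, hierarchy$dimensions))
  levels <- Filter(function(a) length(a) >= 2L, levels)

  msub <- rating_matrix(ratings, "subattribute")
  mdim <- rating_matrix(ratings, "dimension")

  per_cohort <- list()
  rows <- list()
  for (cc in labels) {
    sel <- ratings$cohort == cc
    for (lv in names(levels)) {
      attrs <- levels[[lv]]
      msum <- if (lv == "dimension") mean_dim else mean_sub
      msum <- msum[msum$cohort == cc & msum$attribute %in% attrs, ]
      means <- setNames(msum$mean, msum$attribute)[attrs]
      x <- if (lv == "dimension") mdim[sel, attrs, drop = FALSE]
           else msub[sel, attrs, drop = FALSE]
      x <- x[stats::complete.cases(x), , drop = FALSE]
      ahp <- ahp_weights(minmax_to_saaty(means), level = lv, cohort = cc)
      ewm <- entropy_weights(x, level = lv, cohort = cc)
      comp <- fuse_weights(ahp$weights, ewm, alpha = alpha)
      per_cohort[[cc]][[lv]] <- list(ahp = ahp$weights, ewm = ewm,
                                     composite = comp)
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = cc,
        level = if (lv == "dimension") "dimension" else "subattribute",
        dimension = if (lv == "dimension") attrs else lv,
        attribute = attrs,
        ahp = as.numeric(ahp$weights),
        ewm = as.numeric(ewm),
        composite = as.numeric(comp),
        stringsAsFactors = FALSE
      )
    }
  }

  coefs <- cohort_coefficients(cohorts$frequency_factor, sizes,
                               cohort = labels)
  comp_rows <- list()
  for (lv in names(levels)) {
    wk <- lapply(labels, function(cc) per_cohort[[cc]][[lv]][[aggregate_layer]])
    agg <- aggregate_cohorts(wk, coefs)
    comp_rows[[lv]] <- data.frame(
      level = if (lv == "dimension") "dimension" else "subattribute",
      dimension = if (lv == "dimension") names(agg) else lv,
      attribute = names(agg),
      weight = as.numeric(agg),
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(weights = do.call(rbind, rows),
         comprehensive = do.call(rbind, c(comp_rows,
                                          list(make.row.names = FALSE))),
         coefficients = coefs,
         means = list(subattribute = mean_sub, dimension = mean_dim),
         alpha = alpha, aggregate_layer = aggregate_layer,
         hierarchy = hierarchy, n = sum(sizes), call = match.call()),
    class = "sensory_weights"
  )
}

#' Extract comprehensive weights from a fitted weighting
#'
#' @param object A `sensory_weights` fit.
#' @param level `"all"` (default: dimension and sub-attribute rows),
#'   `"dimension"`, or `"subattribute"`.
#' @param ... Unused.
#' @return A data.frame with columns `level`, `dimension`, `attribute`,
#'   `weight` (fractions; each level/dimension block sums to 1). This is the
#'   input format expected by [build_scale()].
#' @export
coef.sensory_weights <- function(object,
                                 level = c("all", "dimension",
                                           "subattribute"), ...) {
  level <- match.arg(level)
  cw <- object$comprehensive
  if (level != "all") cw <- cw[cw$level == level, ]
  rownames(cw) <- NULL
  cw
}

#' @export
print.sensory_weights <- function(x, ...) {
  cat("Consumer sensory weighting (AHP + entropy fusion)\n")
  cat(sprintf("  %d respondents in %d cohorts; alpha = %.2f; aggregated layer: %s\n",
              x$n, nrow(x$coefficients), x$alpha, x$aggregate_layer))
  cat("Comprehensive dimension weights:\n")
  dw <- x$comprehensive[x$comprehensive$level == "dimension", ]
  for (i in seq_len(nrow(dw)))
    cat(sprintf("  %-20s %6.2f%%\n", dw$attribute[i], 100 * dw$weight[i]))
  invisible(x)
}

#' @export
summary.sensory_weights <- function(object, ...) {
  structure(list(fit = object), class = "summary.sensory_weights")
}

#' @export
print.summary.sensory_weights <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nCohort coefficients (C_i = f_i N_i / sum M):\n")
  cf <- fit$coefficients
  for (i in seq_len(nrow(cf)))
    cat(sprintf("  %-6s f=%2g  n=%5d  C=%.4f\n", cf$cohort[i],
                cf$frequency_factor[i], cf$n[i], cf$coefficient[i]))
  cat("\nPer-cohort dimension weights (percent):\n")
  w <- fit$weights[fit$weights$level == "dimension", ]
  for (cc in unique(w$cohort)) {
    cat(" ", cc, "\n")
    wc <- w[w$cohort == cc, ]
    for (i in seq_len(nrow(wc)))
      cat(sprintf("    %-20s ahp %6.2f  ewm %6.2f  composite %6.2f\n",
                  wc$attribute[i], 100 * wc$ahp[i], 100 * wc$ewm[i],
                  100 * wc$composite[i]))
  }
  invisible(x)
}
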