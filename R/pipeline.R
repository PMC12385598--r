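#' Read a pipeline configuration file
#'
#' One YAML file reproduces the whole analysis: the attribute hierarchy
#' (dimensions, sub-attributes, merge map, exclusions), cohort definitions
#' (label, occasion band, frequency factor, population share), the AHP:EWM
#' fusion ratio, the aggregation layer, top-k, scale bounds and the seed.
#' See `system.file("extdata", "pale_lager.yml", package = "lagerscale")`
#' for the default configuration.
#'
#' @param path Path to the YAML config.
#' @return A list of class `pipeline_config`: `hierarchy`
#'   (an [attribute_hierarchy()]), `cohorts` (data.frame), `alpha`,
#'   `aggregate_layer`, `top_k`, `survey_bounds`, `tasting_bounds`, `seed`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  h <- cfg$hierarchy
  hierarchy <- attribute_hierarchy(
    dimensions = h$dimensions,
    children = h$children,
    merge_map = h$merge_map %||% list(),
    exclusions = h$exclusions %||% character()
  )
  co <- do.call(rbind, lapply(cfg$cohorts, function(x)
    data.frame(cohort = x$label,
               min_occasions = x$min_occasions,
               max_occasions = if (is.null(x$max_occasions)) Inf
                               else x$max_occasions,
               frequency_factor = x$frequency_factor,
               share = x$share %||% NA_real_,
               stringsAsFactors = FALSE)))
  alpha <- cfg$alpha %||% 0.7
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  top_k <- cfg$top_k %||% 3L
  if (top_k < 1L) stop("top_k must be at least 1", call. = FALSE)
  structure(
    list(hierarchy = hierarchy, cohorts = co, alpha = alpha,
         aggregate_layer = cfg$aggregate_layer %||% "ahp",
         top_k = top_k,
         survey_bounds = as.integer(cfg$survey_bounds %||% c(1L, 5L)),
         tasting_bounds = as.integer(cfg$tasting_bounds %||% c(1L, 9L)),
         seed = as.integer(cfg$seed %||% 1L)),
    class = "pipeline_config"
  )
}

#' Default pale-lager pipeline configuration
#' @return A `pipeline_config` built from the bundled YAML file.
#' @export
pale_lager_config <- function() {
  read_pipeline_config(system.file("extdata", "pale_lager.yml",
                                   package = "lagerscale"))
}

# small stable polynomial hash so runs can be stamped without extra deps
config_hash <- function(config) {
  s <- utf8ToInt(paste(utils::capture.output(utils::str(config)),
                       collapse = "\n"))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full weighting-and-scale pipeline
#'
#' Orchestrates every stage: reliability screening, per-cohort AHP/EWM/
#' composite weighting, cohort aggregation, scale construction, and (when a
#' tasting session is supplied) validation against consumer rankings. Two
#' entry modes are supported: from raw questionnaire ratings (full
#' computation via [sensory_weights()]) or from an already-computed
#' comprehensive-weight table (e.g. a published table; scale construction
#' and validation only). Outputs are deterministic given config plus inputs.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]); default
#'   the bundled pale-lager configuration.
#' @param ratings A `ratings_table`, a ratings CSV path, or `NULL`.
#' @param weights A comprehensive-weight data.frame (`level`, `dimension`,
#'   `attribute`, `weight`) or CSV path; used when `ratings` is `NULL`.
#' @param tasting_new,tasting_old Optional `tasting_session`s (or CSV paths)
#'   for validation.
#' @param out_dir Optional directory; when given, writes
#'   `comprehensive_weights.csv`, `cohort_weights.csv` (ratings mode),
#'   `reliability.csv` (ratings mode), `scale.json`, `validation.json`
#'   (when validated) and `run_log.txt`.
#' @return A list of class `pipeline_result`: `fit` (or `NULL`),
#'   `reliability` (or `NULL`), `comprehensive`, `scale`, `validation`
#'   (or `NULL`), `log` (character).
#' @export
run_pipeline <- function(config = pale_lager_config(), ratings = NULL,
                         weights = NULL, tasting_new = NULL,
                         tasting_old = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- c(sprintf("lagerscale %s  config %s",
                   as.character(utils::packageVersion("lagerscale")),
                   config_hash(config)),
           sprintf(paste0("fusion alpha = %g; aggregated layer = %s ",
                          "(ahp = subjective stated-importance layer, ",
                          "composite = fused layer); top_k = %d"),
                   config$alpha, config$aggregate_layer, config$top_k))
  say <- function(...) log <<- c(log, sprintf(...))

  fit <- NULL
  rel <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\n  hint: check the corresponding input file/config block",
           call. = FALSE))
  }

  if (!is.null(ratings)) {
    if (is.character(ratings))
      ratings <- stage("load_ratings",
                       read_ratings(ratings, config$hierarchy,
                                    cohorts = config$cohorts,
                                    bounds = config$survey_bounds))
    rel <- stage("reliability", reliability_report(ratings))
    say("reliability: alpha in [%.3f, %.3f], KMO in [%.3f, %.3f]",
        min(rel$alpha), max(rel$alpha), min(rel$kmo), max(rel$kmo))
    fit <- stage("weighting",
                 sensory_weights(ratings, cohorts = config$cohorts,
                                 alpha = config$alpha,
                                 aggregate_layer = config$aggregate_layer))
    comprehensive <- coef(fit)
    say("weighting: %d respondents, coefficients %s", fit$n,
        paste(sprintf("%.4f", fit$coefficients$coefficient), collapse = "/"))
  } else if (!is.null(weights)) {
    if (is.character(weights))
      weights <- stage("load_weights",
                       read.csv(weights, stringsAsFactors = FALSE))
    comprehensive <- weights
    say("weighting: skipped; using supplied comprehensive-weight table")
  } else {
    stop("supply either 'ratings' or a comprehensive 'weights' table",
         call. = FALSE)
  }

  scale <- stage("scale_construction",
                 build_scale(comprehensive, hierarchy = config$hierarchy,
                             top_k = config$top_k,
                             anchors = config$tasting_bounds))
  say("scale: %d attributes, integer weights sum %d", nrow(scale),
      sum(scale$integer_weight))

  validation <- NULL
  if (!is.null(tasting_new)) {
    if (is.character(tasting_new))
      tasting_new <- stage("load_tasting",
                           read_tasting(tasting_new, scale_id = "new",
                                        bounds = config$tasting_bounds))
    if (is.character(tasting_old))
      tasting_old <- stage("load_tasting",
                           read_tasting(tasting_old, scale_id = "existing",
                                        bounds = config$tasting_bounds))
    validation <- stage("validation",
                        validate_scale(tasting_new, tasting_old, scale))
    say("validation [new]: tau = %.3f, rho = %.3f",
        validation$new$kendall_tau, validation$new$spearman_rho)
    if (!is.null(validation$old))
      say("validation [existing]: tau = %.3f, rho = %.3f",
          validation$old$kendall_tau, validation$old$spearman_rho)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(comprehensive, file.path(out_dir, "comprehensive_weights.csv"),
              row.names = FALSE)
    if (!is.null(fit))
      write.csv(fit$weights, file.path(out_dir, "cohort_weights.csv"),
                row.names = FALSE)
    if (!is.null(rel))
      write.csv(rel, file.path(out_dir, "reliability.csv"),
                row.names = FALSE)
    write_scale(scale, file.path(out_dir, "scale.json"))
    if (!is.null(validation)) {
      rep_list <- function(r) list(samples = r$samples,
                                   kendall_tau = r$kendall_tau,
                                   spearman_rho = r$spearman_rho,
                                   scale_id = r$scale_id)
      jsonlite::write_json(
        list(new = rep_list(validation$new),
             old = if (!is.null(validation$old)) rep_list(validation$old)),
        file.path(out_dir, "validation.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }

  structure(list(fit = fit, reliability = rel,
                 comprehensive = comprehensive, scale = scale,
                 validation = validation, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(x$log, sep = "\n")
  cat("\n")
  print(x$scale)
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}
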