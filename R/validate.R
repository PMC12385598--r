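#' Construct a tasting session
#'
#' Holds a complete-block tasting: every panel assessor scores every sample
#' (either per attribute for a weighted scale, or a single `"overall"` score
#' for a holistic scale), and every consumer gives each sample a 9-point
#' hedonic liking score.
#'
#' @param panel data.frame with columns `assessor`, `sample`, `attribute`,
#'   `score` (integer, `bounds`).
#' @param hedonic data.frame with columns `consumer`, `sample`, `score`.
#' @param scale_id Label of the scale the panel used.
#' @param bounds Score bounds, default `c(1, 9)`.
#' @return A list of class `tasting_session`.
#' @export
tasting_session <- function(panel, hedonic, scale_id = "scale",
                            bounds = c(1L, 9L)) {
  for (nm in c("assessor", "sample", "attribute", "score"))
    if (!nm %in% names(panel))
      stop("panel scores need column '", nm, "'", call. = FALSE)
  for (nm in c("consumer", "sample", "score"))
    if (!nm %in% names(hedonic))
      stop("hedonic scores need column '", nm, "'", call. = FALSE)
  chk <- function(x, what) {
    bad <- is.na(x) | x < bounds[1] | x > bounds[2] | x != round(x)
    if (any(bad))
      stop(what, " outside [", bounds[1], ",", bounds[2],
           "] or non-integer on row(s) ", paste(which(bad), collapse = ", "),
           call. = FALSE)
  }
  chk(panel$score, "panel score")
  chk(hedonic$score, "hedonic score")
  samples <- unique(as.character(panel$sample))
  # complete block: every assessor scores every (sample, attribute) cell
  tab <- table(panel$assessor, panel$sample)
  if (any(tab == 0))
    stop("incomplete block: every assessor must score every sample",
         call. = FALSE)
  structure(list(panel = panel, hedonic = hedonic, samples = samples,
                 scale_id = scale_id, bounds = as.integer(bounds)),
            class = "tasting_session")
}

#' Read a tasting CSV (long form)
#'
#' Columns: `assessor_id`, `role` (`"panel"` or `"consumer"`), `sample`,
#' `attribute` (`"hedonic"` for consumer liking rows), `score`.
#'
#' @param path CSV path.
#' @param scale_id Label of the scale the panel used.
#' @param bounds Score bounds, default `c(1, 9)`.
#' @return A `tasting_session`.
#' @export
read_tasting <- function(path, scale_id = "scale", bounds = c(1L, 9L)) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("assessor_id", "role", "sample", "attribute", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("tasting CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pan <- df[df$role == "panel", ]
  con <- df[df$role == "consumer", ]
  tasting_session(
    panel = data.frame(assessor = pan$assessor_id, sample = pan$sample,
                       attribute = pan$attribute, score = pan$score,
                       stringsAsFactors = FALSE),
    hedonic = data.frame(consumer = con$assessor_id, sample = con$sample,
                         score = con$score, stringsAsFactors = FALSE),
    scale_id = scale_id, bounds = bounds
  )
}

#' Write a tasting session to CSV (long form)
#' @param session A `tasting_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tasting <- function(session, path) {
  pan <- data.frame(assessor_id = session$panel$assessor, role = "panel",
                    sample = session$panel$sample,
                    attribute = session$panel$attribute,
                    score = session$panel$score, stringsAsFactors = FALSE)
  con <- data.frame(assessor_id = session$hedonic$consumer, role = "consumer",
                    sample = session$hedonic$sample, attribute = "hedonic",
                    score = session$hedonic$score, stringsAsFactors = FALSE)
  write.csv(rbind(pan, con), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Weighted composite score of each sample under a scale
#'
#' Per assessor and sample, the composite is the weighted average
#' `sum(w_a * score_a)` over the scale's attributes (fractional weights, sum
#' 1); the sample composite is the mean over assessors. A session whose panel
#' scored a single `"overall"` attribute (an existing holistic scale) is
#' averaged directly.
#'
#' @param session A `tasting_session`.
#' @param scale A `sensory_scale`, or `NULL` for a holistic
#'   one-score-per-sample session.
#' @return Named numeric: composite score per sample.
#' @export
weighted_score <- function(session, scale = NULL) {
  pan <- session$panel
  if (is.null(scale) || identical(unique(pan$attribute), "overall")) {
    return(tapply_mean(pan$score, pan$sample, session$samples))
  }
  w <- setNames(scale$weight, scale$attribute)
  per_assessor <- vapply(session$samples, function(s) {
    ps <- pan[pan$sample == s, ]
    comps <- vapply(unique(ps$assessor), function(aid) {
      rows <- ps[ps$assessor == aid, ]
      sc <- setNames(rows$score, rows$attribute)
      miss <- setdiff(names(w), names(sc))
      if (length(miss))
        stop("assessor '", aid, "' did not score attribute(s) ",
             paste(miss, collapse = ", "), " on sample '", s, "'",
             call. = FALSE)
      sum(w * sc[names(w)])
    }, numeric(1))
    mean(comps)
  }, numeric(1))
  per_assessor
}

tapply_mean <- function(x, g, levels) {
  vapply(levels, function(s) mean(x[g == s]), numeric(1))
}

#' Mean consumer hedonic score per sample
#' @param session A `tasting_session` (or a data.frame with `consumer`,
#'   `sample`, `score`).
#' @return Named numeric: mean liking per sample.
#' @export
mean_hedonic <- function(session) {
  hed <- if (inherits(session, "tasting_session")) session$hedonic else session
  samples <- unique(as.character(hed$sample))
  n <- table(hed$sample)
  if (any(n == 0) || !length(samples))
    stop("every sample needs at least one consumer score", call. = FALSE)
  tapply_mean(hed$score, hed$sample, samples)
}

#' Rank samples by descending score
#'
#' Rank 1 is the best (highest) score; ties receive the average of the tied
#' rank positions.
#'
#' @param scores Named numeric vector, length >= 2.
#' @return Named numeric ranks.
#' @export
rank_descending <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 samples", call. = FALSE)
  rank(-as.numeric(scores), ties.method = "average") |>
    setNames(names(scores))
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected tau: concordant minus discordant pairs over the geometric
#' mean of tie-adjusted pair counts; equals tau-a when there are no ties.
#'
#' @param x,y Numeric vectors of equal length (scores or ranks).
#' @return tau in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  check_corr_input(x, y)
  stats::cor(x, y, method = "kendall")
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks; equals
#' `1 - 6 sum(d^2) / (n (n^2 - 1))` when there are no ties.
#'
#' @param x,y Numeric vectors of equal length.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  check_corr_input(x, y)
  stats::cor(x, y, method = "spearman")
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("rank correlation undefined: zero variance input", call. = FALSE)
  invisible(TRUE)
}

#' Concordance between professional and consumer scores
#'
#' @param professional Named numeric professional composite scores per sample.
#' @param consumer Named numeric consumer mean hedonic scores, same samples.
#' @param scale_id Label carried into the report.
#' @return A list of class `validation_report`: per-sample scores and
#'   rankings, `kendall_tau`, `spearman_rho`.
#' @export
rank_concordance <- function(professional, consumer, scale_id = "scale") {
  if (!setequal(names(professional), names(consumer)))
    stop("professional and consumer scores cover different samples",
         call. = FALSE)
  consumer <- consumer[names(professional)]
  pr <- rank_descending(professional)
  cr <- rank_descending(consumer)
  structure(
    list(samples = data.frame(sample = names(professional),
                              professional = as.numeric(professional),
                              consumer = as.numeric(consumer),
                              professional_rank = as.numeric(pr),
                              consumer_rank = as.numeric(cr),
                              stringsAsFactors = FALSE),
         kendall_tau = kendall_tau(pr, cr),
         spearman_rho = spearman_rho(pr, cr),
         scale_id = scale_id),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Scale validation [%s]\n", x$scale_id))
  s <- x$samples
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s professional %5.2f (rank %g)   consumer %5.2f (rank %g)\n",
                s$sample[i], s$professional[i], s$professional_rank[i],
                s$consumer[i], s$consumer_rank[i]))
  cat(sprintf("  Kendall tau = %.3f   Spearman rho = %.3f\n",
              x$kendall_tau, x$spearman_rho))
  invisible(x)
}

#' Validate a new scale against an existing one on the same tasting
#'
#' Scores the new-scale session with [weighted_score()] under `scale`, takes
#' the existing-scale session's single overall score per assessor, aggregates
#' the shared consumer panel with [mean_hedonic()], and reports rank
#' concordance for both.
#'
#' @param session_new `tasting_session` scored attribute-by-attribute with the
#'   new scale.
#' @param session_old `tasting_session` scored with a single `"overall"`
#'   attribute (the existing holistic scale). May be `NULL` to validate only
#'   the new scale.
#' @param scale The `sensory_scale` used by `session_new`.
#' @return A list of class `scale_validation` with elements `new` and `old`
#'   (each a `validation_report`).
#' @export
validate_scale <- function(session_new, session_old = NULL, scale) {
  if (!is.null(session_old) &&
      !setequal(session_new$samples, session_old$samples))
    stop("sessions cover different sample sets", call. = FALSE)
  consumer <- mean_hedonic(session_new)
  new_rep <- rank_concordance(weighted_score(session_new, scale),
                              consumer[session_new$samples],
                              scale_id = session_new$scale_id)
  old_rep <- NULL
  if (!is.null(session_old)) {
    old_consumer <- if (nrow(session_old$hedonic)) mean_hedonic(session_old)
                    else consumer
    old_rep <- rank_concordance(weighted_score(session_old, NULL),
                                old_consumer[session_old$samples],
                                scale_id = session_old$scale_id)
  }
  structure(list(new = new_rep, old = old_rep), class = "scale_validation")
}

#' @export
print.scale_validation <- function(x, ...) {
  print(x$new)
  if (!is.null(x$old)) print(x$old)
  invisible(x)
}
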