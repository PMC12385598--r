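#' Largest-remainder integer allocation
#'
#' Apportions `n` units to groups proportionally to `shares`: floor each
#' `share * n`, then give the remaining units to the largest fractional
#' remainders (ties by larger share, then position).
#'
#' @param shares Nonnegative numeric shares summing to 1 (within 1e-9).
#' @param n Total count to allocate.
#' @return Integer vector summing to `n`.
#' @export
largest_remainder <- function(shares, n) {
  if (any(shares < 0)) stop("shares must be nonnegative", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-9)
    stop("shares must sum to 1", call. = FALSE)
  raw <- shares * n
  fl <- floor(raw)
  short <- as.integer(n - sum(fl))
  ord <- order(-(raw - fl), -shares, seq_along(shares))
  out <- as.integer(fl)
  if (short > 0L) out[ord[seq_len(short)]] <- out[ord[seq_len(short)]] + 1L
  setNames(out, names(shares))
}

# latent normal, rounded to the nearest integer, clamped to bounds
draw_likert <- function(n, mu, sigma, bounds) {
  pmin(pmax(round(rnorm(n, mu, sigma)), bounds[1]), bounds[2])
}

#' Exact mean/SD of a discretized, clamped normal rating
#'
#' The generator's Likert model draws a latent normal(mu, sigma), rounds to
#' the nearest integer and clamps to the scale bounds. This helper computes
#' the implied exact bin probabilities and the resulting mean and SD — the
#' oracle used to test planted-parameter recovery.
#'
#' @param mu,sigma Latent normal parameters.
#' @param bounds Integer scale bounds, default `c(1, 5)`.
#' @return A list: `probs` (named bin probabilities), `mean`, `sd`
#'   (population SD of the discrete distribution).
#' @export
likert_moments <- function(mu, sigma, bounds = c(1L, 5L)) {
  ks <- seq(bounds[1], bounds[2])
  cuts <- c(-Inf, ks[-length(ks)] + 0.5, Inf)
  p <- pnorm(cuts[-1], mu, sigma) - pnorm(cuts[-length(cuts)], mu, sigma)
  m <- sum(ks * p)
  v <- sum((ks - m)^2 * p)
  list(probs = setNames(p, ks), mean = m, sd = sqrt(v))
}

#' Generate a synthetic consumer survey
#'
#' Emulates the statistical structure of a large pale-lager questionnaire:
#' respondents are allocated to drinking-frequency cohorts by
#' largest-remainder on the cohort shares, and each (cohort, attribute) cell
#' draws integer 1-5 Likert ratings from a rounded, clamped latent normal.
#' Default targets are means in `[3.6, 4.0]` and SDs in `[1.0, 1.25]` —
#' mid-to-upper scale ratings with the dispersion typical of consumer
#' importance surveys.
#'
#' @param n Number of respondents (default 1837).
#' @param hierarchy An [attribute_hierarchy()].
#' @param cohorts Cohort definitions with `cohort` and `share` columns.
#' @param mu Optional cohort-by-attribute matrix of latent means (rownames =
#'   cohort labels, colnames = sub-attributes). Drawn uniformly in `mu_range`
#'   when `NULL`.
#' @param sigma Optional matrix of latent SDs, like `mu`; drawn in
#'   `sigma_range` when `NULL`.
#' @param dimension_means Optional named numeric: a planted latent mean per
#'   dimension, applied to all its sub-attributes in every cohort (overrides
#'   `mu`). Used to plant a known dimension-importance ordering.
#' @param mu_range,sigma_range Ranges for randomly drawn targets.
#' @param seed Integer seed; fully determines the output.
#' @param bounds Likert bounds, default `c(1, 5)`.
#' @return A `ratings_table`.
#' @examples
#' r <- simulate_survey(n = 200, seed = 7)
#' table(r$cohort)
#' @export
simulate_survey <- function(n = 1837, hierarchy = pale_lager_hierarchy(),
                            cohorts = pale_lager_cohorts(),
                            mu = NULL, sigma = NULL, dimension_means = NULL,
                            mu_range = c(3.6, 4.0),
                            sigma_range = c(1.0, 1.25),
                            seed = 1L, bounds = c(1L, 5L)) {
  attrs <- all_attributes(hierarchy)
  labels <- cohorts$cohort
  sizes <- largest_remainder(setNames(cohorts$share, labels), n)
  if (any(sizes < 2L))
    stop("cohort shares leave a cohort with fewer than 2 respondents",
         call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(mu))
    mu <- matrix(runif(length(labels) * length(attrs),
                       mu_range[1], mu_range[2]),
                 nrow = length(labels),
                 dimnames = list(labels, attrs))
  if (!is.null(dimension_means)) {
    for (d in names(dimension_means))
      mu[, hierarchy$children[[d]]] <- dimension_means[[d]]
  }
  if (is.null(sigma))
    sigma <- matrix(runif(length(labels) * length(attrs),
                          sigma_range[1], sigma_range[2]),
                    nrow = length(labels),
                    dimnames = list(labels, attrs))
  if (any(mu < bounds[1] | mu > bounds[2]))
    stop("latent means must lie within the rating bounds", call. = FALSE)
  if (any(sigma <= 0)) stop("latent SDs must be positive", call. = FALSE)

  blocks <- lapply(labels, function(cc) {
    m <- sapply(attrs, function(a)
      draw_likert(sizes[[cc]], mu[cc, a], sigma[cc, a], bounds))
    df <- as.data.frame(m)
    df$cohort <- cc
    df
  })
  df <- do.call(rbind, blocks)
  df$respondent_id <- sprintf("R%04d", seq_len(nrow(df)))
  ratings_table(df, hierarchy, cohorts = cohorts, bounds = bounds)
}

#' Generate a synthetic tasting session
#'
#' Emulates a blind tasting: a professional panel scores each sample on each
#' scale attribute around a planted true intensity, and a consumer panel
#' gives 9-point hedonic liking scores around a planted true mean; all scores
#' are rounded and clamped to `[1, 9]`, and every assessor scores every
#' sample (complete block). With `noise_sd = 0` every assessor reproduces the
#' planted values exactly.
#'
#' @param intensities Sample-by-attribute numeric matrix of true intensities
#'   in `[1, 9]` (rownames = sample codes, colnames = attributes).
#' @param hedonic_mu Named numeric: true hedonic mean per sample.
#' @param n_panel Professional panel size, default 10.
#' @param n_consumers Consumer panel size, default 30.
#' @param noise_sd Latent score noise SD, default 0.5.
#' @param seed Integer seed.
#' @param scale_id Label carried on the session.
#' @return A `tasting_session`.
#' @export
simulate_tasting <- function(intensities, hedonic_mu, n_panel = 10,
                             n_consumers = 30, noise_sd = 0.5, seed = 1L,
                             scale_id = "synthetic") {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("intensities need sample rownames and attribute colnames",
         call. = FALSE)
  if (any(intensities < 1 | intensities > 9))
    stop("true intensities must lie in [1, 9]", call. = FALSE)
  if (!setequal(names(hedonic_mu), rownames(intensities)))
    stop("hedonic means must cover exactly the sample set", call. = FALSE)
  if (n_panel < 2 || n_consumers < 2)
    stop("panel and consumer counts must be at least 2", call. = FALSE)
  if (noise_sd < 0) stop("noise SD must be nonnegative", call. = FALSE)
  set.seed(as.integer(seed))
  samples <- rownames(intensities)
  bounds <- c(1L, 9L)

  panel <- do.call(rbind, lapply(seq_len(n_panel), function(i) {
    do.call(rbind, lapply(samples, function(s) {
      data.frame(assessor = sprintf("E%02d", i), sample = s,
                 attribute = colnames(intensities),
                 score = draw_likert(ncol(intensities), intensities[s, ],
                                     noise_sd, bounds),
                 stringsAsFactors = FALSE)
    }))
  }))
  hedonic <- do.call(rbind, lapply(seq_len(n_consumers), function(i) {
    data.frame(consumer = sprintf("C%02d", i), sample = samples,
               score = draw_likert(length(samples), hedonic_mu[samples],
                                   noise_sd, bounds),
               stringsAsFactors = FALSE)
  }))
  tasting_session(panel, hedonic, scale_id = scale_id, bounds = bounds)
}
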