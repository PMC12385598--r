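#' Construct a weight vector
#'
#' A named, nonnegative weight vector over the attributes of one hierarchy
#' level, normalized to sum to 1, tagged with the weighting layer it came
#' from, the level it lives on and the cohort it describes.
#'
#' @param w Named nonnegative numeric vector; must sum to 1 within `tol`.
#' @param layer One of `"ahp"`, `"ewm"`, `"composite"`, `"comprehensive"`.
#' @param level `"dimension"` or the name of the dimension whose
#'   sub-attributes the vector spans.
#' @param cohort Cohort label, or `"all"`.
#' @param tol Normalization tolerance (printed 2-dp tables drift by up to
#'   about 1e-4 in fraction units; the default accommodates them).
#' @return A numeric vector of class `weight_vector`.
#' @export
weight_vector <- function(w, layer = c("ahp", "ewm", "composite",
                                       "comprehensive"),
                          level = "dimension", cohort = "all", tol = 5e-3) {
  layer <- match.arg(layer)
  if (is.null(names(w)) || anyDuplicated(names(w)))
    stop("weights must have unique names", call. = FALSE)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(w) - 1) > tol)
    stop("weights must sum to 1 (got ", format(sum(w)), ")", call. = FALSE)
  structure(as.numeric(w), names = names(w), layer = layer, level = level,
            cohort = cohort, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat(sprintf("<weight_vector layer=%s level=%s cohort=%s>\n",
              attr(x, "layer"), attr(x, "level"), attr(x, "cohort")))
  print(round(setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

#' Map attribute means onto the Saaty 1-9 scale
#'
#' Min-max normalizes a vector of Likert means and maps it linearly onto
#' `[1, 9]`: `v = 1 + 8 * (m - min) / (max - min)`. When all means are equal
#' the map is degenerate and every attribute is sent to the scale midpoint 5
#' (with a warning), which yields uniform AHP weights downstream.
#'
#' @param means Named numeric vector of attribute means (scale points).
#' @return A list of class `saaty_mapping`: `means`, `values` (the mapped
#'   1-9 values), `min`, `max`.
#' @export
minmax_to_saaty <- function(means) {
  if (length(means) < 2L)
    stop("need at least 2 attributes to map onto the Saaty scale",
         call. = FALSE)
  if (is.null(names(means))) stop("means must be named", call. = FALSE)
  lo <- min(means); hi <- max(means)
  if (hi > lo) {
    v <- 1 + 8 * (means - lo) / (hi - lo)
  } else {
    warning("all means equal; mapping every attribute to mid-scale 5",
            call. = FALSE)
    v <- setNames(rep(5, length(means)), names(means))
  }
  structure(list(means = means, values = v, min = lo, max = hi),
            class = "saaty_mapping")
}

#' Ratings-driven AHP weights
#'
#' Builds the pairwise comparison matrix `a_ij = v_i / v_j` from the mapped
#' Saaty values and derives the priority vector. Ratio matrices are perfectly
#' consistent, so the priorities reduce to `w_i = v_i / sum(v)` and the
#' consistency ratio is 0 by construction.
#'
#' @param mapping A `saaty_mapping` from [minmax_to_saaty()], or a named
#'   numeric vector of 1-9 values.
#' @param level,cohort Tags passed to [weight_vector()].
#' @return A list: `weights` (a `weight_vector`, layer `"ahp"`), `matrix`
#'   (the reciprocal pairwise matrix), `cr` (consistency ratio).
#' @export
ahp_weights <- function(mapping, level = "dimension", cohort = "all") {
  v <- if (inherits(mapping, "saaty_mapping")) mapping$values else mapping
  if (is.null(names(v))) stop("values must be named", call. = FALSE)
  if (any(v < 1 | v > 9))
    stop("mapped values must lie in [1, 9]", call. = FALSE)
  a <- outer(v, v, "/")
  a <- pmin(pmax(a, 1 / 9), 9)
  dimnames(a) <- list(names(v), names(v))
  w <- weight_vector(v / sum(v), layer = "ahp", level = level,
                     cohort = cohort)
  list(weights = w, matrix = a, cr = consistency_ratio(a))
}

# Saaty random indices for n = 1..10
.saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' AHP consistency ratio of a reciprocal pairwise matrix
#'
#' `CI = (lambda_max - n) / (n - 1)` from the principal eigenvalue, divided
#' by Saaty's random index for the matrix size. Matrices built as ratio
#' matrices `v_i/v_j` have CR = 0; the conventional acceptance threshold for
#' judgement matrices is CR < 0.1 (reported, not enforced here).
#'
#' @param a Square reciprocal matrix with entries in `[1/9, 9]`.
#' @param tol Reciprocity tolerance.
#' @return The consistency ratio (0 for `n <= 2`).
#' @export
consistency_ratio <- function(a, tol = 1e-8) {
  a <- as.matrix(a)
  n <- nrow(a)
  if (n != ncol(a) || n < 2L || n > 10L)
    stop("need a square reciprocal matrix with 2 <= n <= 10", call. = FALSE)
  if (max(abs(a * t(a) - 1)) > tol || max(abs(diag(a) - 1)) > tol)
    stop("matrix is not reciprocal (a_ij * a_ji must equal 1)", call. = FALSE)
  if (n <= 2L) return(0)
  lambda <- max(Re(eigen(a, only.values = TRUE)$values))
  ci <- (lambda - n) / (n - 1)
  ci / .saaty_ri[n]
}

#' Entropy weights from a ratings matrix
#'
#' The entropy weight method assigns larger weights to attributes whose
#' scores are more dispersed across respondents. Each column is normalized to
#' a distribution `p_ij = x_ij / sum_i(x_ij)`, its Shannon entropy
#' `e_j = -sum(p log p) / log(n)` computed (with `0 log 0 = 0`), and weights
#' are the normalized divergences `w_j = (1 - e_j) / sum(1 - e)`. A constant
#' column has entropy 1 and weight 0; if every column is constant the weights
#' fall back to uniform with a warning.
#'
#' @param x Respondent-by-attribute numeric matrix of nonnegative scores with
#'   column names.
#' @param level,cohort Tags passed to [weight_vector()].
#' @return A `weight_vector` with layer `"ewm"`.
#' @export
entropy_weights <- function(x, level = "dimension", cohort = "all") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("matrix must have column names", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 respondents", call. = FALSE)
  if (anyNA(x)) stop("entropy weights require complete data", call. = FALSE)
  if (any(x < 0)) stop("scores must be nonnegative", call. = FALSE)
  n <- nrow(x)
  e <- apply(x, 2, function(col) {
    s <- sum(col)
    if (s == 0) return(1)  # all-zero column: no information
    p <- col / s
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  })
  d <- pmax(1 - e, 0)  # clamp float noise on constant columns
  if (sum(d) <= .Machine$double.eps * length(d)) {
    warning("no score dispersion in any column; falling back to uniform ",
            "entropy weights", call. = FALSE)
    w <- setNames(rep(1 / ncol(x), ncol(x)), colnames(x))
  } else {
    w <- d / sum(d)
  }
  weight_vector(w, layer = "ewm", level = level, cohort = cohort)
}

#' Fuse subjective and objective weights
#'
#' Convex combination `w = alpha * w_subj + (1 - alpha) * w_obj` of an AHP
#' (subjective) and an EWM (objective) weight vector over the same attribute
#' set. The default ratio 7:3 gives primacy to stated consumer importance
#' while letting score dispersion adjust it.
#'
#' @param w_subj,w_obj `weight_vector`s (or named numerics) over the same
#'   attributes.
#' @param alpha Subjective share, in `[0, 1]`; default 0.7.
#' @return A `weight_vector` with layer `"composite"`.
#' @export
fuse_weights <- function(w_subj, w_obj, alpha = 0.7) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (!setequal(names(w_subj), names(w_obj)))
    stop("subjective and objective weights cover different attributes",
         call. = FALSE)
  wo <- as.numeric(w_obj)[match(names(w_subj), names(w_obj))]
  w <- alpha * as.numeric(w_subj) + (1 - alpha) * wo
  weight_vector(setNames(w, names(w_subj)), layer = "composite",
                level = attr(w_subj, "level") %||% "dimension",
                cohort = attr(w_subj, "cohort") %||% "all")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population coefficients for drinking-frequency cohorts
#'
#' Each cohort contributes `M_i = f_i * N_i` (representative monthly
#' occasions times cohort size); normalized coefficients `C_i = M_i / sum(M)`
#' weight the cohorts in the market-wide aggregation.
#'
#' @param frequency_factor Positive numeric vector of representative
#'   occasions/month (defaults 2, 6, 14 for low/mid/high).
#' @param n Positive integer vector of cohort sizes, same length and order.
#' @param cohort Optional cohort labels.
#' @return A data.frame of class `cohort_coefficients` with columns `cohort`,
#'   `frequency_factor`, `n`, `contribution`, `coefficient`.
#' @export
cohort_coefficients <- function(frequency_factor, n,
                                cohort = names(frequency_factor) %||%
                                  paste0("cohort", seq_along(frequency_factor))) {
  if (length(frequency_factor) != length(n))
    stop("frequency factors and cohort sizes differ in length", call. = FALSE)
  if (any(frequency_factor <= 0)) stop("frequency factors must be positive",
                                       call. = FALSE)
  if (any(n <= 0)) stop("every cohort must be non-empty", call. = FALSE)
  m <- frequency_factor * n
  out <- data.frame(cohort = cohort, frequency_factor = frequency_factor,
                    n = n, contribution = m, coefficient = m / sum(m),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_coefficients", "data.frame")
  out
}

#' Aggregate per-cohort weights into a comprehensive weight vector
#'
#' Market-wide weights `W_a = sum_k C_k * W_k,a`: a convex combination of the
#' cohort weight vectors with the population coefficients. All cohorts must
#' supply the same attribute set from the same weighting layer (mixing, say,
#' an AHP vector with a composite vector would silently change the meaning of
#' the aggregate). Rounding drift beyond 1e-9 is renormalized away.
#'
#' @param weights Named list of `weight_vector`s, one per cohort, in the same
#'   order as `coefficients`.
#' @param coefficients A `cohort_coefficients` data.frame, or a numeric
#'   vector of coefficients summing to 1.
#' @return A `weight_vector` with layer `"comprehensive"`, cohort `"all"`.
#' @export
aggregate_cohorts <- function(weights, coefficients) {
  cc <- if (inherits(coefficients, "data.frame")) coefficients$coefficient
        else as.numeric(coefficients)
  if (length(weights) != length(cc))
    stop("one weight vector per cohort coefficient required", call. = FALSE)
  if (abs(sum(cc) - 1) > 1e-6)
    stop("cohort coefficients must sum to 1", call. = FALSE)
  layers <- unique(vapply(weights, function(w)
    attr(w, "layer") %||% "unknown", character(1)))
  if (length(layers) > 1L)
    stop("cohort weight vectors come from different layers (",
         paste(layers, collapse = ", "), "); refusing to mix them",
         call. = FALSE)
  nm <- names(weights[[1L]])
  agg <- setNames(rep(0, length(nm)), nm)
  for (k in seq_along(weights)) {
    wk <- weights[[k]]
    if (!setequal(names(wk), nm))
      stop("cohort weight vectors cover different attributes", call. = FALSE)
    agg <- agg + cc[k] * as.numeric(wk)[match(nm, names(wk))]
  }
  if (abs(sum(agg) - 1) > 1e-9) agg <- agg / sum(agg)
  weight_vector(agg, layer = "comprehensive",
                level = attr(weights[[1L]], "level") %||% "dimension",
                cohort = "all")
}
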