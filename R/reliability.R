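#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`, with
#' sample variances over complete cases. Values above 0.70 are conventionally
#' considered satisfactory; alpha can be negative for incoherent item sets.
#'
#' @param items Respondent-by-item numeric matrix or data.frame, k >= 2
#'   items; rows with any missing item are dropped (complete-case analysis,
#'   no imputation).
#' @return alpha (<= 1).
#' @export
cronbach_alpha <- function(items) {
  x <- complete_items(items, min_n = 3L)
  k <- ncol(x)
  total_var <- var(rowSums(x))
  if (total_var == 0)
    stop("total score has zero variance; alpha undefined", call. = FALSE)
  (k / (k - 1)) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal pairs, where
#' `r` are Pearson correlations and `q` the anti-image partial correlations
#' obtained from the inverted correlation matrix. Per-item MSA values use the
#' same ratio restricted to each item's row. Values near 1 indicate compact
#' correlation structure suitable for factoring; above 0.70 is conventionally
#' good.
#'
#' @inheritParams cronbach_alpha
#' @return A list: `overall`, `per_item` (named numeric).
#' @export
kmo_statistic <- function(items) {
  x <- complete_items(items, min_n = ncol(as.matrix(items)) + 1L)
  r <- cor(x)
  inv <- tryCatch(solve(r), error = function(e)
    stop("correlation matrix is singular; remove redundant items",
         call. = FALSE))
  q <- -inv / sqrt(outer(diag(inv), diag(inv)))
  diag(q) <- 0
  diag(r) <- 0
  r2 <- r^2
  q2 <- q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per_item <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  list(overall = overall, per_item = setNames(per_item, colnames(x)))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is an identity (items uncorrelated):
#' `chi2 = -(n - 1 - (2k + 5)/6) * ln det(R)` on `k(k-1)/2` degrees of
#' freedom. p < 0.05 conventionally indicates the data are suitable for
#' structure detection.
#'
#' @inheritParams cronbach_alpha
#' @return A list: `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(items) {
  x <- complete_items(items, min_n = ncol(as.matrix(items)) + 1L)
  n <- nrow(x)
  k <- ncol(x)
  d <- det(cor(x))
  if (d <= 0)
    stop("correlation matrix has non-positive determinant", call. = FALSE)
  chi2 <- -(n - 1 - (2 * k + 5) / 6) * log(d)
  df <- k * (k - 1) / 2
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Reliability report for item scales
#'
#' Convenience wrapper computing Cronbach's alpha, overall KMO and Bartlett's
#' sphericity for one or more item sets.
#'
#' @param ratings A `ratings_table` (or plain data.frame of items).
#' @param scales Named list of character vectors: scale name -> item columns.
#'   Defaults to one scale per hierarchy dimension when `ratings` is a
#'   `ratings_table`.
#' @return A data.frame of class `reliability_report`: one row per scale with
#'   `scale`, `alpha`, `kmo`, `bartlett_chi2`, `bartlett_df`, `bartlett_p`,
#'   `n`, `k`.
#' @export
reliability_report <- function(ratings, scales = NULL) {
  if (is.null(scales)) {
    h <- attr(ratings, "hierarchy")
    if (is.null(h))
      stop("supply 'scales' when ratings carry no hierarchy", call. = FALSE)
    scales <- Filter(function(a) length(a) >= 2L, h$children)
  }
  out <- do.call(rbind, lapply(names(scales), function(s) {
    x <- as.data.frame(ratings)[, scales[[s]], drop = FALSE]
    cc <- x[stats::complete.cases(x), , drop = FALSE]
    b <- bartlett_sphericity(cc)
    data.frame(scale = s, alpha = cronbach_alpha(cc),
               kmo = kmo_statistic(cc)$overall,
               bartlett_chi2 = b$chi2, bartlett_df = b$df, bartlett_p = b$p,
               n = nrow(cc), k = ncol(cc), stringsAsFactors = FALSE)
  }))
  class(out) <- c("reliability_report", "data.frame")
  out
}

complete_items <- function(items, min_n) {
  x <- as.matrix(as.data.frame(items))
  storage.mode(x) <- "double"
  if (ncol(x) < 2L) stop("need at least 2 items", call. = FALSE)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < min_n)
    stop("too few complete cases (", nrow(x), ")", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  x
}
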