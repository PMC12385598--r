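#' @importFrom stats sd var cor pchisq rnorm runif pnorm setNames
#' @importFrom utils read.csv write.csv
NULL

.demographic_cols <- c("sex", "age_band", "education", "spending_band")

#' Construct a validated ratings table
#'
#' One row per respondent: an identifier, a drinking-frequency cohort label,
#' one integer Likert column per sub-attribute of the hierarchy, and optional
#' demographic columns. Missing ratings are `NA`, never zero.
#'
#' @param df A data.frame with columns `respondent_id`, `cohort` and one
#'   column per sub-attribute of `hierarchy`.
#' @param hierarchy An [attribute_hierarchy()].
#' @param cohorts Cohort definition data.frame (see [pale_lager_cohorts()]);
#'   its `cohort` column is the set of admissible labels.
#' @param bounds Integer rating bounds, default the 1-5 Likert survey scale.
#' @return A data.frame of class `ratings_table` with the hierarchy attached
#'   as attribute `"hierarchy"`.
#' @export
ratings_table <- function(df, hierarchy, cohorts = pale_lager_cohorts(),
                          bounds = c(1L, 5L)) {
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  attrs <- all_attributes(hierarchy)
  need <- c("respondent_id", "cohort")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ratings are missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss_attr <- setdiff(attrs, names(df))
  if (length(miss_attr))
    stop("ratings are missing attribute columns: ",
         paste(miss_attr, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), c(need, attrs, .demographic_cols))
  if (length(extra))
    stop("unknown attribute columns: ", paste(extra, collapse = ", "),
         call. = FALSE)

  bad_cohort <- !(df$cohort %in% cohorts$cohort)
  if (any(bad_cohort))
    stop("unknown cohort label(s) ",
         paste(unique(df$cohort[bad_cohort]), collapse = ", "),
         " on row(s) ", paste(which(bad_cohort), collapse = ", "),
         call. = FALSE)

  for (a in attrs) {
    x <- df[[a]]
    if (!is.numeric(x)) x <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & (x < bounds[1] | x > bounds[2] | x != round(x))
    if (any(bad))
      stop("ratings for '", a, "' outside [", bounds[1], ",", bounds[2],
           "] or non-integer on row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    df[[a]] <- as.integer(x)
  }
  df <- df[, c(need, intersect(.demographic_cols, names(df)), attrs)]
  structure(df, hierarchy = hierarchy, bounds = as.integer(bounds),
            class = c("ratings_table", "data.frame"))
}

#' Read a ratings CSV
#'
#' Expects a UTF-8, comma-separated file with a header row naming
#' `respondent_id`, `cohort`, and one column per sub-attribute; `NA` marks a
#' missing rating. Validation failures report the offending rows.
#'
#' @inheritParams ratings_table
#' @param path Path to the CSV file.
#' @return A `ratings_table`.
#' @export
read_ratings <- function(path, hierarchy, cohorts = pale_lager_cohorts(),
                         bounds = c(1L, 5L)) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  ratings_table(df, hierarchy, cohorts = cohorts, bounds = bounds)
}

#' Write a ratings table to CSV
#' @param ratings A `ratings_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  write.csv(as.data.frame(ratings), path, row.names = FALSE,
            fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' Per-attribute mean, SD and count by cohort
#'
#' Summarizes ratings per (cohort, attribute) and pooled over all cohorts
#' (`cohort = "all"`). At `level = "dimension"`, each respondent's dimension
#' score is the mean of their non-missing sub-attribute ratings in that
#' dimension; the summary then describes those per-respondent scores. Missing
#' values are excluded pairwise; an attribute with fewer than 2 non-missing
#' ratings in a cohort is an error (no imputation is ever performed).
#'
#' @param ratings A `ratings_table`.
#' @param level `"subattribute"` (default) or `"dimension"`.
#' @return A data.frame with columns `cohort`, `attribute`, `mean`, `sd`, `n`.
#'   SDs use the sample (n-1) denominator.
#' @export
attribute_means <- function(ratings, level = c("subattribute", "dimension")) {
  level <- match.arg(level)
  hierarchy <- attr(ratings, "hierarchy")
  m <- rating_matrix(ratings, level)
  cohorts <- c(unique(as.character(ratings$cohort)), "all")
  out <- do.call(rbind, lapply(cohorts, function(cc) {
    rows <- if (cc == "all") rep(TRUE, nrow(m)) else ratings$cohort == cc
    mm <- m[rows, , drop = FALSE]
    do.call(rbind, lapply(colnames(mm), function(a) {
      x <- mm[, a]
      x <- x[!is.na(x)]
      if (length(x) < 2L)
        stop("attribute '", a, "' has fewer than 2 ratings in cohort '",
             cc, "'", call. = FALSE)
      data.frame(cohort = cc, attribute = a, mean = mean(x), sd = sd(x),
                 n = length(x), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# numeric respondent x attribute matrix at the requested level
rating_matrix <- function(ratings, level = c("subattribute", "dimension")) {
  level <- match.arg(level)
  hierarchy <- attr(ratings, "hierarchy")
  attrs <- all_attributes(hierarchy)
  m <- as.matrix(as.data.frame(ratings)[, attrs, drop = FALSE])
  storage.mode(m) <- "double"
  if (level == "subattribute") return(m)
  dm <- sapply(hierarchy$dimensions, function(d) {
    cols <- hierarchy$children[[d]]
    if (!length(cols)) return(rep(NA_real_, nrow(m)))
    rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
  })
  dm[is.nan(dm)] <- NA_real_
  dm
}
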