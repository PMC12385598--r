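#' Merge perceptually similar attributes
#'
#' Replaces each merge group by a single attribute whose weight is the sum of
#' its sources — weight mass is conserved. The merged attribute takes the
#' position of its first source; unmerged attributes pass through unchanged.
#'
#' @param w Named numeric weight vector (fractions or percent).
#' @param merge_map Named list: merged name -> character vector of sources.
#' @return Named numeric vector with merged attributes, same total weight.
#' @export
merge_attributes <- function(w, merge_map) {
  if (!length(merge_map)) return(w)
  for (m in names(merge_map)) {
    src <- merge_map[[m]]
    miss <- setdiff(src, names(w))
    if (length(miss))
      stop("merge sources missing from weights: ",
           paste(miss, collapse = ", "), call. = FALSE)
    merged <- sum(w[src])
    # rebuild preserving order, merged attribute at the first source position
    nm <- names(w)
    nm[nm == src[1L]] <- m
    nm <- nm[!nm %in% src]
    w2 <- setNames(numeric(length(nm)), nm)
    w2[setdiff(nm, m)] <- w[setdiff(nm, m)]
    w2[m] <- merged
    w <- w2
  }
  w
}

#' Drop excluded attributes from a weight vector
#'
#' Removal without renormalization: the three-step standardization normalizes
#' later, so remaining weights are left untouched here. Excluding a name not
#' present is a warning, not an error.
#'
#' @param w Named numeric weight vector.
#' @param exclusions Character vector of attribute names to drop.
#' @return `w` without the excluded attributes.
#' @export
apply_exclusions <- function(w, exclusions) {
  if (!length(exclusions)) return(w)
  absent <- setdiff(exclusions, names(w))
  if (length(absent))
    warning("exclusion(s) not present, ignored: ",
            paste(absent, collapse = ", "), call. = FALSE)
  w[!names(w) %in% exclusions]
}

#' Select the top-k attributes of a dimension and normalize locally
#'
#' Keeps the `k` largest weights and divides by their sum so the retained
#' attributes sum to 1 within the dimension. Ties at rank `k` are broken by
#' the larger pre-merge source weight (`tiebreak`), then lexicographically —
#' a deterministic rule.
#'
#' @param w Named numeric weights of one dimension's (merged, filtered)
#'   attributes.
#' @param k Number of attributes to keep, default 3.
#' @param tiebreak Optional named numeric: for each attribute, the largest
#'   pre-merge source weight backing it; defaults to `w` itself.
#' @param dimension Dimension name, used in error messages.
#' @return Named numeric local weights of length `k`, summing to 1, in
#'   decreasing order.
#' @export
top_k_local_normalize <- function(w, k = 3, tiebreak = NULL,
                                  dimension = "dimension") {
  if (length(w) < k)
    stop("dimension '", dimension, "' has only ", length(w),
         " attributes after merging/exclusion; need at least ", k,
         call. = FALSE)
  if (is.null(tiebreak)) tiebreak <- w
  tb <- as.numeric(tiebreak)[match(names(w), names(tiebreak))]
  tb[is.na(tb)] <- -Inf
  ord <- order(-as.numeric(w), -tb, names(w))
  top <- w[ord[seq_len(k)]]
  top / sum(top)
}

#' Globalize locally normalized weights by the dimension weights
#'
#' Step two and three of the standardization: each local weight is multiplied
#' by its dimension's comprehensive weight, then all products are normalized
#' globally so the scale sums to 100%.
#'
#' @param locals Named list: dimension -> named numeric local weights
#'   (each summing to 1).
#' @param dim_weights Named numeric comprehensive dimension weights
#'   (fractions or percent; only ratios matter after global normalization).
#' @return Named numeric fractional scale weights over all retained
#'   attributes, summing to 1.
#' @export
integrate_and_globalize <- function(locals, dim_weights) {
  miss <- setdiff(names(locals), names(dim_weights))
  if (length(miss))
    stop("no dimension weight for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  g <- unlist(lapply(names(locals), function(d)
    locals[[d]] * dim_weights[[d]]))
  g / sum(g)
}

#' Convert fractional weights to integer percentages summing to 100
#'
#' Largest-remainder apportionment: floor each `100 * f`, then hand the
#' remaining points to the largest fractional remainders. Remainder ties are
#' broken by the larger fraction, then lexicographically by name.
#'
#' @param fractions Named numeric vector summing to 1 (within 1e-3; printed
#'   tables rounded to 4 decimals drift by up to that much).
#' @return Named integer vector summing to exactly 100.
#' @export
integerize <- function(fractions) {
  if (abs(sum(fractions) - 1) > 1e-3)
    stop("fractions must sum to 1", call. = FALSE)
  raw <- 100 * fractions / sum(fractions)
  fl <- floor(raw)
  rem <- raw - fl
  short <- 100L - as.integer(round(sum(fl)))
  nm <- names(fractions) %||% as.character(seq_along(fractions))
  ord <- order(-rem, -raw, nm)
  out <- as.integer(fl)
  if (short > 0L) out[ord[seq_len(short)]] <- out[ord[seq_len(short)]] + 1L
  setNames(out, names(fractions))
}

#' Build a consumer-oriented sensory evaluation scale
#'
#' Runs the full three-step standardization on comprehensive weights:
#' within every retained dimension, merge perceptually similar attributes
#' (weights summed), drop excluded attributes, keep the top `k` and normalize
#' them locally; then multiply each local weight by its dimension's
#' comprehensive weight and normalize globally to 100%; finally convert to
#' integer percentages by largest remainder. Dimensions named in the
#' hierarchy's exclusion list (appearance, by default) are dropped whole,
#' with a message in the scale's provenance.
#'
#' @param weights A fitted [sensory_weights()] object, or a data.frame with
#'   columns `level` (`"dimension"` / `"subattribute"`), `dimension`,
#'   `attribute`, `weight` (fractions or percent; each block is renormalized).
#' @param hierarchy An [attribute_hierarchy()] supplying the merge map and
#'   exclusions; defaults to the hierarchy attached to a fitted object, or
#'   [pale_lager_hierarchy()].
#' @param top_k Attributes retained per dimension, default 3.
#' @param anchors Score anchor bounds of the resulting scorecard, default
#'   `c(1, 9)` (1 = extremely weak, 9 = extremely strong).
#' @return An object of class `sensory_scale`: a data.frame with one row per
#'   scale attribute (`attribute`, `dimension`, `weight` fraction, `percent`,
#'   `integer_weight`, `sources`) ordered by decreasing weight, plus
#'   attributes `anchors`, `top_k`, `dimension_weights`.
#' @examples
#' # reproduce a scale from a printed comprehensive-weight table
#' cw <- read.csv(system.file("extdata", "comprehensive_weights.csv",
#'                            package = "lagerscale"))
#' sc <- build_scale(cw)
#' sc
#' @export
build_scale <- function(weights, hierarchy = NULL, top_k = 3,
                        anchors = c(1, 9)) {
  if (inherits(weights, "sensory_weights")) {
    if (is.null(hierarchy)) hierarchy <- weights$hierarchy
    weights <- coef(weights)
  }
  if (is.null(hierarchy)) hierarchy <- pale_lager_hierarchy()
  need <- c("level", "dimension", "attribute", "weight")
  if (!all(need %in% names(weights)))
    stop("weights need columns ", paste(need, collapse = ", "), call. = FALSE)

  dimw <- weights[weights$level == "dimension", ]
  dim_weights <- setNames(dimw$weight, dimw$attribute)
  dim_weights <- dim_weights / sum(dim_weights)

  excl <- hierarchy$exclusions
  excl_dims <- intersect(excl, hierarchy$dimensions)
  excl_attrs <- setdiff(excl, excl_dims)

  sub <- weights[weights$level == "subattribute", ]
  have_dims <- intersect(hierarchy$dimensions, unique(sub$dimension))
  retained <- setdiff(have_dims, excl_dims)
  if (!length(retained))
    stop("no dimensions left after exclusions", call. = FALSE)

  locals <- list()
  provenance <- list()
  for (d in retained) {
    wd <- sub[sub$dimension == d, ]
    w <- setNames(wd$weight, wd$attribute)
    w <- w / sum(w)
    pre <- w
    mm <- Filter(function(src) all(src %in% names(w)), hierarchy$merge_map)
    w <- merge_attributes(w, mm)
    w <- apply_exclusions(w, intersect(excl_attrs, names(w)))
    if (!length(w)) {
      warning("all attributes of dimension '", d, "' excluded; dropping it",
              call. = FALSE)
      next
    }
    # tie-break on the largest pre-merge source weight
    tb <- vapply(names(w), function(a) {
      src <- if (a %in% names(mm)) mm[[a]] else a
      max(pre[src])
    }, numeric(1))
    locals[[d]] <- top_k_local_normalize(w, k = top_k, tiebreak = tb,
                                         dimension = d)
    provenance[[d]] <- mm
  }

  final <- integrate_and_globalize(locals, dim_weights)
  final <- final[order(-final, names(final))]
  ints <- integerize(final)

  src_of <- function(a) {
    for (d in names(provenance))
      if (a %in% names(provenance[[d]]))
        return(paste(provenance[[d]][[a]], collapse = "+"))
    a
  }
  out <- data.frame(
    attribute = names(final),
    dimension = unname(attribute_dimension(hierarchy, names(final))),
    weight = as.numeric(final),
    percent = 100 * as.numeric(final),
    integer_weight = as.integer(ints[names(final)]),
    sources = vapply(names(final), src_of, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, anchors = anchors, top_k = top_k,
            dimension_weights = dim_weights,
            excluded = list(dimensions = excl_dims, attributes = excl_attrs),
            class = c("sensory_scale", "data.frame"))
}

#' @export
print.sensory_scale <- function(x, ...) {
  a <- attr(x, "anchors")
  cat(sprintf(
    "Consumer-oriented sensory scale: %d attributes, anchors %g-%g\n",
    nrow(x), a[1], a[2]))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-24s %-20s %6.2f%%  -> %3d\n", x$attribute[i],
                paste0("(", x$dimension[i], ")"), x$percent[i],
                x$integer_weight[i]))
  cat(sprintf("  integer weights sum to %d\n", sum(x$integer_weight)))
  invisible(x)
}

#' Write a scale definition to JSON
#' @param scale A `sensory_scale`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scale <- function(scale, path) {
  obj <- list(
    attributes = as.data.frame(scale),
    anchors = attr(scale, "anchors"),
    top_k = attr(scale, "top_k"),
    dimension_weights = as.list(attr(scale, "dimension_weights")),
    excluded = attr(scale, "excluded")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scale definition from JSON
#' @param path Path written by [write_scale()].
#' @return A `sensory_scale`.
#' @export
read_scale <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- obj$attributes
  out$integer_weight <- as.integer(out$integer_weight)
  structure(out, anchors = as.numeric(obj$anchors), top_k = obj$top_k,
            dimension_weights = unlist(obj$dimension_weights),
            excluded = obj$excluded,
            class = c("sensory_scale", "data.frame"))
}
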