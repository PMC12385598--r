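#' Define a sensory attribute hierarchy
#'
#' An attribute hierarchy is the coordinate system of every weight vector in
#' the package: an ordered set of primary sensory dimensions, each carrying an
#' ordered set of sub-attributes, plus the merge map and exclusion list used
#' during scale construction.
#'
#' @param dimensions Character vector of dimension names, in display order.
#' @param children Named list mapping every dimension to a character vector of
#'   sub-attribute names. A dimension may have no sub-attributes (empty
#'   vector) if it only ever receives a dimension-level weight.
#' @param merge_map Named list mapping a merged attribute name to the
#'   character vector of source sub-attributes it absorbs. A source may appear
#'   in at most one merge group.
#' @param exclusions Character vector of attribute or dimension names dropped
#'   during scale construction (before top-k selection).
#' @return An object of class `attribute_hierarchy`.
#' @examples
#' h <- attribute_hierarchy(
#'   dimensions = c("aroma", "taste"),
#'   children = list(aroma = c("malt", "hop"), taste = c("sweetness")),
#'   merge_map = list(), exclusions = character()
#' )
#' all_attributes(h)
#' @export
attribute_hierarchy <- function(dimensions, children,
                                merge_map = list(),
                                exclusions = character()) {
  dimensions <- as.character(dimensions)
  if (anyDuplicated(dimensions))
    stop("dimension names must be unique", call. = FALSE)
  if (!setequal(names(children), dimensions))
    stop("'children' must have exactly one entry per dimension", call. = FALSE)
  children <- lapply(children[dimensions], as.character)
  subs <- unlist(children, use.names = FALSE)
  if (anyDuplicated(subs))
    stop("sub-attribute names must be unique across dimensions: ",
         paste(unique(subs[duplicated(subs)]), collapse = ", "), call. = FALSE)
  if (any(subs %in% dimensions))
    stop("a sub-attribute may not share a name with a dimension", call. = FALSE)

  merge_map <- lapply(merge_map, as.character)
  srcs <- unlist(merge_map, use.names = FALSE)
  if (anyDuplicated(srcs))
    stop("a merge source may appear in at most one merge group", call. = FALSE)
  missing_src <- setdiff(srcs, subs)
  if (length(missing_src))
    stop("merge sources not in the hierarchy: ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  # every merge group must sit inside one dimension, and merged names must
  # stay unique after replacement
  for (m in names(merge_map)) {
    d <- unique(vapply(merge_map[[m]], function(a) dimension_of(subs, children, a),
                       character(1)))
    if (length(d) != 1L)
      stop("merge group '", m, "' spans more than one dimension", call. = FALSE)
  }
  post <- c(setdiff(subs, srcs), names(merge_map))
  if (anyDuplicated(post))
    stop("attribute names are not unique after merging", call. = FALSE)

  exclusions <- as.character(exclusions)
  structure(
    list(dimensions = dimensions, children = children,
         merge_map = merge_map, exclusions = exclusions),
    class = "attribute_hierarchy"
  )
}

dimension_of <- function(subs, children, a) {
  for (d in names(children)) if (a %in% children[[d]]) return(d)
  stop("attribute '", a, "' not found in hierarchy", call. = FALSE)
}

#' All sub-attribute names of a hierarchy
#' @param hierarchy An [attribute_hierarchy()].
#' @return Character vector of all sub-attributes, in hierarchy order.
#' @export
all_attributes <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  unlist(hierarchy$children, use.names = FALSE)
}

#' Look up the parent dimension of sub-attributes
#' @param hierarchy An [attribute_hierarchy()].
#' @param attributes Character vector of sub-attribute (or merged) names.
#' @return Character vector of dimension names.
#' @export
attribute_dimension <- function(hierarchy, attributes) {
  stopifnot(inherits(hierarchy, "attribute_hierarchy"))
  vapply(attributes, function(a) {
    if (a %in% names(hierarchy$merge_map)) a <- hierarchy$merge_map[[a]][1L]
    dimension_of(all_attributes(hierarchy), hierarchy$children, a)
  }, character(1))
}

#' @export
print.attribute_hierarchy <- function(x, ...) {
  cat("Attribute hierarchy:", length(x$dimensions), "dimensions,",
      length(all_attributes(x)), "sub-attributes\n")
  for (d in x$dimensions)
    cat("  ", d, ": ", paste(x$children[[d]], collapse = ", "), "\n", sep = "")
  if (length(x$merge_map)) {
    cat("Merges:\n")
    for (m in names(x$merge_map))
      cat("  ", m, " <- ", paste(x$merge_map[[m]], collapse = " + "), "\n",
          sep = "")
  }
  if (length(x$exclusions))
    cat("Excluded from scale construction:",
        paste(x$exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' Default pale-lager attribute hierarchy
#'
#' Four primary dimensions (appearance, aroma, taste, drinking sensation) with
#' the sub-attribute sets used throughout the package's worked examples.
#' Appearance carries visual sub-attributes but, by default, is excluded from
#' scale construction together with alcohol warmth; hop+floral,
#' fruit+fermentation and aftertaste+persistence are merged, reflecting
#' perceptual similarity of those pairs for ordinary consumers.
#'
#' @return An [attribute_hierarchy()].
#' @export
pale_lager_hierarchy <- function() {
  attribute_hierarchy(
    dimensions = c("appearance", "aroma", "taste", "drinking_sensation"),
    children = list(
      appearance = c("beer_color", "clarity", "foam_abundance"),
      aroma = c("malt", "hop", "fruit", "floral", "sweet", "fermentation"),
      taste = c("sweetness", "sourness", "bitterness", "umami", "astringency"),
      drinking_sensation = c("smoothness", "fullness", "refreshment",
                             "body_coordination", "alcohol_warmth",
                             "persistence", "prickliness", "aftertaste",
                             "foam_fineness")
    ),
    merge_map = list(
      hop_flower = c("hop", "floral"),
      fruity_fermentation = c("fruit", "fermentation"),
      aftertaste_persistence = c("aftertaste", "persistence")
    ),
    exclusions = c("alcohol_warmth", "appearance")
  )
}

#' Default drinking-frequency cohort definitions
#'
#' Three cohorts defined by monthly drinking occasions: low (1-3), mid (4-8)
#' and high (9+). Each carries a representative frequency factor (2, 6, 14
#' occasions/month) used to form population coefficients, and the population
#' share used by the synthetic survey generator (38.54% / 42.49% / remainder).
#'
#' @return A data.frame with columns `cohort`, `min_occasions`,
#'   `max_occasions`, `frequency_factor`, `share`.
#' @export
pale_lager_cohorts <- function() {
  data.frame(
    cohort = c("low", "mid", "high"),
    min_occasions = c(1, 4, 9),
    max_occasions = c(3, 8, Inf),
    frequency_factor = c(2, 6, 14),
    share = c(0.3854, 0.4249, 1 - 0.3854 - 0.4249),
    stringsAsFactors = FALSE
  )
}
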