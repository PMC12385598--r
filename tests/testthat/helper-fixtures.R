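# Shared fixtures: a tiny two-dimension hierarchy, small ratings builders,
# and the published weight tables used by the desk-scale reproduction tests.

tiny_hierarchy <- function() {
  attribute_hierarchy(
    dimensions = c("aroma", "taste"),
    children = list(aroma = c("malt", "hop"),
                    taste = c("sweetness", "bitterness")),
    merge_map = list(),
    exclusions = character()
  )
}

tiny_cohorts <- function() {
  data.frame(cohort = c("low", "high"),
             min_occasions = c(1, 9), max_occasions = c(8, Inf),
             frequency_factor = c(2, 14), share = c(0.5, 0.5),
             stringsAsFactors = FALSE)
}

tiny_ratings <- function(df = NULL) {
  if (is.null(df))
    df <- data.frame(
      respondent_id = c("r1", "r2", "r3", "r4"),
      cohort = c("low", "low", "high", "high"),
      malt = c(3L, 4L, 5L, 2L), hop = c(2L, 2L, 3L, 4L),
      sweetness = c(5L, 4L, 4L, 3L), bitterness = c(1L, 2L, 3L, 2L),
      stringsAsFactors = FALSE
    )
  ratings_table(df, tiny_hierarchy(), cohorts = tiny_cohorts())
}

# Published comprehensive weight table (percent), the desk-scale input for
# scale construction. Dimension weights plus sub-attribute weights for the
# three non-visual dimensions; appearance carries no sub-attribute weights.
published_comprehensive <- function() {
  read.csv(system.file("extdata", "comprehensive_weights.csv",
                       package = "lagerscale"),
           stringsAsFactors = FALSE)
}

# Published per-cohort dimension-level AHP and EWM weight vectors (percent).
# Entries marked with a trailing comment were never printed and are
# back-solved from the published composite/comprehensive tables; they close
# each vector to a 100% total and are used as inputs only, never asserted.
published_cohort_ahp <- function() {
  list(
    low = c(appearance = 13.645,              # back-solved
            aroma = 7.26, taste = 13.775,     # taste back-solved
            drinking_sensation = 65.32),
    mid = c(appearance = 31.65, aroma = 4.30, # aroma back-solved
            taste = 25.46,                    # back-solved
            drinking_sensation = 38.59),
    high = c(appearance = 5.50, aroma = 49.49, taste = 31.40,
             drinking_sensation = 13.61)
  )
}

published_cohort_ewm <- function() {
  list(
    low = c(appearance = 21.528,              # back-solved
            aroma = 28.58, taste = 24.725,    # taste back-solved
            drinking_sensation = 25.19),
    high = c(appearance = 27.11, aroma = 24.76, taste = 22.52,
             drinking_sensation = 25.61)
  )
}

published_coefficients <- c(low = 0.1285, mid = 0.4269, high = 0.4446)

# Published four-sample validation scores (professional composites under the
# new and existing scales, consumer hedonic means).
published_validation <- function() {
  read.csv(system.file("extdata", "validation_scores.csv",
                       package = "lagerscale"),
           stringsAsFactors = FALSE)
}

as_wv <- function(x, layer = "ahp", cohort = "all", level = "dimension") {
  weight_vector(x / sum(x), layer = layer, level = level, cohort = cohort)
}

# independent brute-force Kendall tau: concordant minus discordant pair count
brute_force_tau <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
  s / choose(n, 2)
}

# independent largest-remainder apportionment (seats to largest remainders)
brute_force_largest_remainder <- function(shares, n) {
  raw <- shares * n
  out <- floor(raw)
  while (sum(out) < n) {
    rem <- raw - out
    i <- which(rem == max(rem))[1]
    out[i] <- out[i] + 1
  }
  as.integer(out)
}

# independent entropy-weight oracle, straight from the defining formula
brute_force_entropy <- function(x) {
  n <- nrow(x)
  d <- apply(x, 2, function(col) {
    p <- col / sum(col)
    e <- -sum(ifelse(p > 0, p * log(p), 0)) / log(n)
    1 - e
  })
  d / sum(d)
}
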