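test_that("min-max Saaty mapping hits the endpoints and midpoints", {
  expect_equal(minmax_to_saaty(c(a = 1, b = 5))$values, c(a = 1, b = 9))
  expect_equal(minmax_to_saaty(c(a = 2, b = 3, c = 4))$values,
               c(a = 1, b = 5, c = 9))
  expect_warning(
    mp <- minmax_to_saaty(c(a = 3.7, b = 3.7, c = 3.7)),
    "all means equal")
  expect_equal(mp$values, c(a = 5, b = 5, c = 5))
  expect_error(minmax_to_saaty(c(a = 3)), "at least 2")
  # order preservation
  set.seed(1)
  m <- setNames(runif(6, 1, 5), letters[1:6])
  v <- minmax_to_saaty(m)$values
  expect_identical(order(v), order(m))
})

test_that("ratio-built AHP weights are v/sum(v) with zero inconsistency", {
  a <- ahp_weights(setNames(c(9, 1, 1, 1), letters[1:4]))
  expect_equal(as.numeric(a$weights), c(0.75, 1 / 12, 1 / 12, 1 / 12))
  expect_lt(abs(a$cr), 1e-9)
  expect_true(all(a$matrix >= 1 / 9 & a$matrix <= 9))
  expect_equal(max(abs(a$matrix * t(a$matrix) - 1)), 0, tolerance = 1e-12)

  u <- ahp_weights(setNames(rep(5, 4), letters[1:4]))
  expect_equal(as.numeric(u$weights), rep(0.25, 4))

  # monotone: larger mean => mapped value => weight
  m <- setNames(c(3.2, 3.9, 3.5, 3.4), letters[1:4])
  w <- ahp_weights(minmax_to_saaty(m))$weights
  expect_identical(order(as.numeric(w)), order(m))
})

test_that("consistency ratio flags perturbed matrices and matches power iteration", {
  v <- c(2, 5, 7)
  a <- outer(v, v, "/")
  expect_lt(consistency_ratio(a), 1e-9)
  a2 <- a
  a2[1, 2] <- a2[1, 2] * 2
  a2[2, 1] <- 1 / a2[1, 2]
  expect_gt(consistency_ratio(a2), 0)
  expect_error(consistency_ratio(matrix(1, 3, 3) + diag(3)),
               "not reciprocal")

  # random reciprocal 4x4: principal eigenvalue via an independent power
  # iteration oracle
  set.seed(17)
  b <- diag(4)
  for (i in 1:3) for (j in (i + 1):4) {
    b[i, j] <- sample(c(1/5, 1/3, 1, 3, 5, 7), 1)
    b[j, i] <- 1 / b[i, j]
  }
  x <- rep(1, 4)
  for (it in 1:500) x <- b %*% x / sqrt(sum((b %*% x)^2))
  lambda <- as.numeric(t(x) %*% b %*% x / sum(x^2))
  ri4 <- 0.90
  expect_equal(consistency_ratio(b), ((lambda - 4) / 3) / ri4,
               tolerance = 1e-8)
})

test_that("entropy weights match the formula oracle and handle degeneracy", {
  m <- matrix(c(1, 1, 4, 2, 2, 2), ncol = 2,
              dimnames = list(NULL, c("varying", "constant")))
  w <- entropy_weights(m)
  # constant column carries no information: e = 1, d = 0, weight 0
  expect_equal(as.numeric(w), c(1, 0))

  expect_warning(
    wu <- entropy_weights(matrix(3, 4, 2, dimnames = list(NULL, c("a", "b")))),
    "uniform")
  expect_equal(as.numeric(wu), c(0.5, 0.5))

  expect_error(entropy_weights(matrix(c(-1, 1, 2, 2), 2,
                                      dimnames = list(NULL, c("a", "b")))),
               "nonnegative")

  # invariance to positive rescaling of a single column
  set.seed(3)
  x <- matrix(sample(1:5, 40, replace = TRUE), ncol = 4,
              dimnames = list(NULL, letters[1:4]))
  w1 <- entropy_weights(x)
  x2 <- x; x2[, 2] <- x2[, 2] * 7
  expect_equal(as.numeric(entropy_weights(x2)), as.numeric(w1),
               tolerance = 1e-12)
})

test_that("fusion is the stated convex combination of AHP and EWM layers", {
  # published low-cohort drinking-sensation component: 0.7*65.32 + 0.3*25.19
  ws <- as_wv(published_cohort_ahp()$low, layer = "ahp")
  wo <- as_wv(published_cohort_ewm()$low, layer = "ewm")
  fused <- fuse_weights(ws, wo, alpha = 0.7)
  expect_equal(100 * fused[["drinking_sensation"]], 53.28, tolerance = 0.005)

  # fixed point and attribute-set check
  expect_equal(as.numeric(fuse_weights(ws, ws)), as.numeric(ws))
  bad <- weight_vector(c(x = 0.5, y = 0.5), layer = "ewm")
  expect_error(fuse_weights(ws, bad), "different attributes")
  expect_error(fuse_weights(ws, wo, alpha = 1.2), "\\[0, 1\\]")

  # convexity: output bounded by per-attribute min/max of the inputs
  lo <- pmin(as.numeric(ws), as.numeric(wo)[match(names(ws), names(wo))])
  hi <- pmax(as.numeric(ws), as.numeric(wo)[match(names(ws), names(wo))])
  expect_true(all(as.numeric(fused) >= lo - 1e-12 &
                  as.numeric(fused) <= hi + 1e-12))
})

test_that("cohort coefficients normalize frequency-weighted sizes", {
  cc <- cohort_coefficients(c(2, 6, 14), c(1, 1, 1))
  expect_equal(cc$coefficient, c(1, 3, 7) / 11)
  expect_equal(sum(cc$coefficient), 1, tolerance = 1e-12)
  expect_error(cohort_coefficients(c(2, 6), c(5, 0)), "non-empty")
  expect_error(cohort_coefficients(c(2, 6, 14), c(5, 5)), "length")
})

test_that("cohort aggregation is a layer-checked convex combination", {
  ahp <- published_cohort_ahp()
  wl <- lapply(names(ahp), function(cc) as_wv(ahp[[cc]], cohort = cc))
  agg <- aggregate_cohorts(wl, published_coefficients)
  expect_equal(sum(agg), 1, tolerance = 1e-9)
  # identical vectors: fixed point
  same <- lapply(1:3, function(i) as_wv(c(a = 2, b = 3, c = 5)))
  expect_equal(as.numeric(aggregate_cohorts(same, c(0.2, 0.3, 0.5))),
               c(0.2, 0.3, 0.5))
  # refuse to mix layers silently
  mixed <- wl
  mixed[[2]] <- as_wv(ahp$mid, layer = "composite", cohort = "mid")
  expect_error(aggregate_cohorts(mixed, published_coefficients),
               "different layers")
  # convexity bounds per attribute
  mat <- do.call(rbind, lapply(wl, as.numeric))
  expect_true(all(as.numeric(agg) >= apply(mat, 2, min) - 1e-12 &
                  as.numeric(agg) <= apply(mat, 2, max) + 1e-12))
})

test_that("a dominant dimension yields a dominant fitted AHP share", {
  # planted low-cohort-style pattern: one dimension's means far above the rest
  h <- pale_lager_hierarchy()
  r <- simulate_survey(
    n = 1200, hierarchy = h, seed = 19,
    dimension_means = c(appearance = 3.25, aroma = 3.2, taste = 3.3,
                        drinking_sensation = 3.9))
  fit <- sensory_weights(r)
  w <- fit$weights
  lead <- w[w$level == "dimension" & w$attribute == "drinking_sensation",
            "ahp"]
  expect_true(all(lead > 0.5))
  for (cc in unique(w$cohort)) {
    wd <- w[w$level == "dimension" & w$cohort == cc, ]
    expect_identical(wd$attribute[which.max(wd$ahp)], "drinking_sensation")
  }
})

test_that("every fitted weight vector is normalized and nonnegative", {
  r <- simulate_survey(n = 240, seed = 23)
  fit <- sensory_weights(r)
  w <- fit$weights
  for (cc in unique(w$cohort)) for (lv in unique(w$level)) {
    blocks <- if (lv == "dimension") "dimension"
              else unique(w$dimension[w$level == lv])
    for (b in blocks) {
      sel <- w$cohort == cc & w$level == lv &
        (lv == "dimension" | w$dimension == b)
      for (col in c("ahp", "ewm", "composite")) {
        expect_equal(sum(w[sel, col]), 1, tolerance = 1e-9)
        expect_true(all(w[sel, col] >= 0))
      }
    }
  }
  cw <- coef(fit)
  expect_equal(sum(cw$weight[cw$level == "dimension"]), 1, tolerance = 1e-9)
})
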