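test_that("attribute merging sums source weights and conserves mass", {
  w <- c(malt = 0.2588, hop = 0.0483, fruit = 0.1035, floral = 0.2002,
         sweet = 0.1861, fermentation = 0.2031)
  mm <- list(hop_flower = c("hop", "floral"),
             fruity_fermentation = c("fruit", "fermentation"))
  m <- merge_attributes(w, mm)
  expect_equal(m[["hop_flower"]], 0.2485)
  expect_equal(m[["fruity_fermentation"]], 0.3066)
  expect_equal(sum(m), sum(w), tolerance = 1e-12)
  expect_identical(merge_attributes(w, list()), w)
  expect_error(merge_attributes(w, list(x = c("hop", "ghost"))), "missing")
  # mass conservation on random vectors
  set.seed(6)
  for (i in 1:10) {
    v <- setNames(runif(6), letters[1:6])
    mm2 <- list(g1 = c("a", "c"), g2 = c("e", "f"))
    expect_equal(sum(merge_attributes(v, mm2)), sum(v), tolerance = 1e-12)
  }
})

test_that("exclusions remove without renormalizing and warn on unknowns", {
  w <- c(smoothness = 0.1283, alcohol_warmth = 0.1545, aftertaste = 0.1181)
  out <- apply_exclusions(w, "alcohol_warmth")
  expect_identical(out, w[c("smoothness", "aftertaste")])
  expect_identical(apply_exclusions(w, character()), w)
  expect_warning(out2 <- apply_exclusions(w, "ghost"), "ghost")
  expect_identical(out2, w)
})

test_that("top-k selection renormalizes locally with a deterministic tie-break", {
  taste <- c(astringency = 0.2759, sweetness = 0.2670, bitterness = 0.2192,
             umami = 0.1347, sourness = 0.1033)
  loc <- top_k_local_normalize(taste, k = 3)
  expect_equal(as.numeric(loc),
               c(0.2759, 0.2670, 0.2192) / (0.2759 + 0.2670 + 0.2192),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(loc), 4), c(0.3620, 0.3503, 0.2876))
  # exactly k attributes: pure renormalization
  expect_equal(as.numeric(top_k_local_normalize(taste[1:3], k = 3)),
               as.numeric(taste[1:3] / sum(taste[1:3])))
  # tie at rank k: larger pre-merge backing weight wins, then name
  w <- c(a = 0.4, b = 0.3, c = 0.15, d = 0.15)
  keep <- top_k_local_normalize(w, k = 3, tiebreak = c(a = 0.4, b = 0.3,
                                                       c = 0.10, d = 0.12))
  expect_setequal(names(keep), c("a", "b", "d"))
  keep2 <- top_k_local_normalize(w, k = 3)  # equal backing: lexicographic
  expect_setequal(names(keep2), c("a", "b", "c"))
  expect_error(top_k_local_normalize(w[1:2], k = 3, dimension = "taste"),
               "taste")
})

test_that("integerization is largest-remainder and sums to exactly 100", {
  f <- c(ap = 0.1884, as = 0.1170, ff = 0.1134, sw = 0.1132, bc = 0.0989,
         ma = 0.0957, bi = 0.0930, hf = 0.0919, sm = 0.0884)
  expect_identical(unname(integerize(f)),
                   c(19L, 12L, 11L, 11L, 10L, 10L, 9L, 9L, 9L))
  expect_identical(unname(integerize(c(0.5, 0.5))), c(50L, 50L))
  expect_identical(unname(integerize(setNames(rep(1, 3) / 3, c("a", "b", "c")))),
                   c(34L, 33L, 33L))
  # random fractions against an independent brute-force apportionment
  set.seed(9)
  for (i in 1:20) {
    v <- runif(sample(3:9, 1)); v <- v / sum(v)
    names(v) <- paste0("x", seq_along(v))
    got <- integerize(v)
    expect_identical(sum(got), 100L)
    expect_true(all(abs(got - 100 * v) < 1))
    raw <- 100 * v
    oracle <- floor(raw)
    while (sum(oracle) < 100) {
      rem <- raw - oracle
      j <- which(rem == max(rem))[1]
      oracle[j] <- oracle[j] + 1
    }
    expect_identical(unname(got), as.integer(oracle))
  }
})

test_that("globalization multiplies locals by dimension weights and normalizes", {
  locals <- list(taste = c(a = 0.5, b = 0.5), aroma = c(c = 1))
  dw <- c(taste = 0.3, aroma = 0.2, appearance = 0.5)
  g <- integrate_and_globalize(locals, dw)
  expect_equal(sum(g), 1, tolerance = 1e-12)
  expect_equal(as.numeric(g), c(0.15, 0.15, 0.2) / 0.5)
  expect_error(integrate_and_globalize(list(ghost = c(a = 1)), dw),
               "ghost")
  # single dimension, single attribute: weight 1
  expect_equal(as.numeric(integrate_and_globalize(list(taste = c(a = 1)),
                                                  c(taste = 0.3))), 1)
})

test_that("the full three-step construction reproduces the published scale", {
  sc <- build_scale(published_comprehensive())
  expect_identical(
    sc$attribute,
    c("aftertaste_persistence", "astringency", "fruity_fermentation",
      "sweetness", "body_coordination", "malt", "bitterness", "hop_flower",
      "smoothness"))
  published <- c(18.84, 11.70, 11.34, 11.32, 9.89, 9.57, 9.30, 9.19, 8.84)
  expect_equal(sc$percent, published, tolerance = 0.01 / mean(published))
  expect_true(all(abs(sc$percent - published) <= 0.01))
  expect_identical(sc$integer_weight,
                   c(19L, 12L, 11L, 11L, 10L, 10L, 9L, 9L, 9L))
  expect_equal(sum(sc$weight), 1, tolerance = 1e-9)
  # provenance: merged attributes trace to their sources
  expect_identical(sc$sources[sc$attribute == "aftertaste_persistence"],
                   "aftertaste+persistence")
  expect_identical(sc$sources[sc$attribute == "hop_flower"], "hop+floral")
  # no appearance attribute survives the dimension exclusion
  expect_false("appearance" %in% sc$dimension)
})

test_that("uniform inputs with no merges or exclusions give a uniform scale", {
  h <- attribute_hierarchy(
    dimensions = c("d1", "d2"),
    children = list(d1 = c("a", "b", "c"), d2 = c("x", "y", "z")))
  cw <- rbind(
    data.frame(level = "dimension", dimension = c("d1", "d2"),
               attribute = c("d1", "d2"), weight = 0.5),
    data.frame(level = "subattribute",
               dimension = rep(c("d1", "d2"), each = 3),
               attribute = c("a", "b", "c", "x", "y", "z"), weight = 1 / 3))
  sc <- build_scale(cw, hierarchy = h)
  expect_equal(sc$weight, rep(1 / 6, 6))
})

test_that("raising a retained attribute's weight never lowers its scale weight", {
  base <- published_comprehensive()
  sc0 <- build_scale(base)
  w0 <- sc0$weight[sc0$attribute == "astringency"]
  up <- base
  i <- up$attribute == "astringency"
  up$weight[i] <- up$weight[i] + 5
  sc1 <- build_scale(up)
  expect_gte(sc1$weight[sc1$attribute == "astringency"], w0)
})

test_that("scale definitions survive a JSON round trip", {
  sc <- build_scale(published_comprehensive())
  path <- withr::local_tempfile(fileext = ".json")
  write_scale(sc, path)
  sc2 <- read_scale(path)
  expect_equal(sc2$weight, sc$weight, tolerance = 1e-12)
  expect_identical(sc2$integer_weight, sc$integer_weight)
  expect_identical(sc2$attribute, sc$attribute)
  expect_equal(attr(sc2, "anchors"), attr(sc, "anchors"))
})
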