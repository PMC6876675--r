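# Composite indicators: knowledge weights and scores, dietary diversity
# schemes, FCS, vitamin A frequency, food security, and their invariants.

test_that("knowledge weights are inverse reference correct-rates", {
  resp <- cbind(easy = rep(1, 200),
                hard = rep(c(1, 0), c(50, 150)),
                never = rep(0, 200))
  expect_warning(w <- fit_knowledge_weights(resp), "never")
  expect_equal(unname(w$weights["easy"]), 1)
  expect_equal(unname(w$weights["hard"]), 4)
  expect_identical(w$excluded, "never")

  w2 <- fit_knowledge_weights(cbind(a = rep(1, 8), b = rep(c(1, 0), 4)))
  expect_equal(unname(w2$weights), c(1, 2))
})

test_that("knowledge scores are weighted sums and additive over subsets", {
  resp <- cbind(a = c(1, 0, 1), b = c(1, 0, 0))
  w <- fit_knowledge_weights(cbind(a = rep(c(1, 0), c(4, 0)),
                                   b = rep(c(1, 0), c(1, 3))))
  expect_equal(unname(w$weights), c(1, 4))
  expect_equal(knowledge_score(resp, w), c(5, 0, 1))

  set.seed(1)
  m <- matrix(rbinom(200, 1, 0.6), 20, dimnames = list(NULL, letters[1:10]))
  wt <- fit_knowledge_weights(m)
  sub1 <- letters[1:6]; sub2 <- letters[7:10]
  expect_equal(knowledge_score(m, wt, sub1) + knowledge_score(m, wt, sub2),
               knowledge_score(m, wt))

  # missing responses scored as incorrect by default, error on request
  mm <- m; mm[1, 1] <- NA
  expect_equal(knowledge_score(mm, wt)[-1], knowledge_score(m, wt)[-1])
  expect_error(knowledge_score(mm, wt, missing = "error"), "missing",
               class = "ipwdid_error")
})

test_that("standardization has mean 0 / SD 1 and is affine-invariant", {
  set.seed(2)
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(as.numeric(standardize(mean(x), x)), 0)
  expect_equal(as.numeric(standardize(mean(x) + 2 * sd(x), x)), 2)
  # affine rescaling of the raw score leaves the standardized index unchanged
  expect_equal(as.numeric(standardize(3 * x + 7)), as.numeric(z))
  expect_error(standardize(x, rep(1, 5)), "zero", class = "ipwdid_error")
})

test_that("diversity schemes respect their bounds and group listings", {
  map <- food_group_map()
  zero <- recall_vec()
  all1 <- recall_vec(map$map$category)
  expect_equal(c(hdds(zero), cdds(zero), fgds(zero), vita_diversity(zero)),
               c(0L, 0L, 0L, 0L))
  expect_equal(c(hdds(all1), cdds(all1), fgds(all1), vita_diversity(all1)),
               c(8L, 8L, 10L, 6L))
  # green leafy vegetables: one group under each scheme that includes them
  glv <- recall_vec("vita_vegetables")
  expect_equal(fgds(glv), 1L)
  expect_equal(vita_diversity(glv), 1L)
  expect_equal(hdds(glv), 1L)
  expect_error(hdds(recall_vec() + 2), "0/1", class = "ipwdid_error")
})

test_that("scheme group counts match the documented enumerations", {
  m <- food_group_map()$map
  groups <- function(s) setdiff(unique(m[[s]]), "")
  expect_length(groups("hdds"), 8)
  expect_length(groups("cdds"), 8)
  expect_length(groups("fgds"), 10)
  expect_length(groups("vita"), 6)
  expect_length(groups("fcs"), 7)
  expect_setequal(groups("fgds"),
                  c("starchy_staples", "legumes_nuts", "dairy", "organ_meats",
                    "eggs", "flesh_foods", "vita_fruits", "vita_vegetables",
                    "other_fruit_veg", "oil"))
  expect_setequal(groups("vita"),
                  c("vita_fruits", "vita_vegetables", "eggs", "dairy",
                    "flesh_meat", "organ_meat"))
  # child scheme separates organ meat and vitamin-A-rich produce, drops oil
  expect_true("organ_meat" %in% groups("cdds"))
  expect_true("vita_fruit_veg" %in% groups("cdds"))
  expect_false("oil" %in% groups("cdds"))
})

test_that("adding a consumed category never decreases a diversity score", {
  map <- food_group_map()
  set.seed(3)
  for (i in 1:25) {
    r <- rbinom(12, 1, 0.4)
    off <- which(r == 0)
    if (!length(off)) next
    r2 <- r; r2[sample(off, 1)] <- 1
    for (f in list(hdds, cdds, fgds, vita_diversity))
      expect_gte(f(r2, map), f(r, map))
  }
})

test_that("FCS applies group-sum, cap and weights as documented", {
  map <- food_group_map()
  expect_equal(fcs(freq_vec()), 0)
  # every category at 7 days: each group capped at 7 -> 7 * sum(weights)
  expect_equal(fcs(freq_vec(setNames(as.list(rep(7, 12)),
                                     map$map$category))),
               7 * sum(map$fcs_weights))
  # two staple items at 5 and 4 days: group sum 9 capped at 7, weight 2 -> 14
  f <- freq_vec(list(cereals = 5, roots_tubers = 4))
  expect_equal(fcs(f), min(5 + 4, 7) * 2)
  expect_error(fcs(freq_vec(list(cereals = -1))), "non-negative",
               class = "ipwdid_error")
  # capping keeps FCS non-decreasing and bounded
  f1 <- freq_vec(list(cereals = 6)); f2 <- freq_vec(list(cereals = 7))
  expect_lte(fcs(f1), fcs(f2))
  expect_lte(fcs(freq_vec(setNames(as.list(rep(7, 12)), map$map$category))),
             7 * sum(map$fcs_weights))
})

test_that("vitamin A frequency is the capped day-union", {
  expect_equal(vita_freq(freq_vec()), 0)
  expect_equal(vita_freq(freq_vec(list(vita_vegetables = 7))), 7)
  expect_equal(vita_freq(freq_vec(list(vita_vegetables = 2,
                                       vita_fruits = 3))), 5)
  expect_equal(vita_freq(freq_vec(list(vita_vegetables = 6,
                                       vita_fruits = 6))), 7)
  # non-vitamin-A items do not count
  expect_equal(vita_freq(freq_vec(list(cereals = 7))), 0)
})

test_that("food security indicators sum calendars and validate inputs", {
  z <- rep(0, 12)
  out <- food_security(z, z, 0, 0)
  expect_equal(unlist(out), c(mihfp = 0, relief_months = 0, sold_asset = 0,
                              food_insecurity_score = 0))
  expect_equal(food_security(rep(1, 12), z, 1, 3)$mihfp, 12L)
  expect_equal(food_security(c(rep(1, 3), rep(0, 9)), z, 0, 0)$mihfp, 3L)
  expect_error(food_security(rep(0, 11), z, 0, 0), "12",
               class = "ipwdid_error")
  expect_error(food_security(z, z, 0, -1), "non-negative",
               class = "ipwdid_error")
})

test_that("indicator table is keyed by household x wave with identities", {
  p <- generate_panel(small_config(seed = 10))
  ind <- indicator_table(p)
  expect_equal(nrow(ind), nrow(p$data))
  expect_equal(ind$knowledge_combined,
               ind$knowledge_production + ind$knowledge_vitamina)
  expect_true(all(ind$hdds >= 0 & ind$hdds <= 8))
  expect_true(all(ind$fgds <= 10))
  expect_true(all(ind$vita_diversity <= 6))
  expect_true(all(ind$mihfp >= 0 & ind$mihfp <= 12))
  base <- ind$wave == 0
  expect_equal(mean(ind$knowledge_production_std[base]), 0, tolerance = 1e-10)
  expect_equal(sd(ind$knowledge_production_std[base]), 1, tolerance = 1e-10)
})
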