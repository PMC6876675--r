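# IPW weights, the weighted DID estimator and its closed-form oracles,
# cluster-robust covariance, and placebo regressions.

test_that("IPW weights follow the 1/p and 1/(1-p) definitions", {
  expect_equal(ipw_weights(c(0.5, 0.5), c(1, 0)), c(2, 2))
  expect_equal(ipw_weights(0.25, 1), 4)
  expect_equal(ipw_weights(0.25, 0), 4 / 3)
  expect_true(all(ipw_weights(runif(50, 0.01, 0.99),
                              rbinom(50, 1, 0.5)) >= 1))
  wn <- ipw_weights(c(0.2, 0.4, 0.6, 0.8), c(1, 1, 0, 0), normalize = TRUE)
  expect_equal(sum(wn[1:2]), 2)
  expect_equal(sum(wn[3:4]), 2)
  expect_error(ipw_weights(c(0, 0.5), c(1, 0)), "strictly",
               class = "ipwdid_error")
})

test_that("unweighted no-controls DID equals the four-group closed form", {
  p <- toy_panel(cells = c(1, 4, 2, 3))
  r <- did_estimate(p, "y")
  expect_equal(r$theta, (4 - 1) - (3 - 2), tolerance = 1e-10)
  expect_equal(r$n, 24)

  # random cell means, noisy: still the four-means closed form
  set.seed(10)
  for (i in 1:5) {
    cells <- rnorm(4, 0, 3)
    p2 <- toy_panel(n_treated = 11, n_control = 9, cells = cells,
                    noise = 1, seed = i)
    d <- p2$data
    cf <- with(d, (mean(y[treated == 1 & wave == 1]) -
                   mean(y[treated == 1 & wave == 0])) -
                  (mean(y[treated == 0 & wave == 1]) -
                   mean(y[treated == 0 & wave == 0])))
    expect_equal(did_estimate(p2, "y")$theta, cf, tolerance = 1e-10)
  }
})

test_that("DID is linear in the outcome and affine-equivariant", {
  set.seed(11)
  p <- toy_panel(n_treated = 10, n_control = 10, cells = c(1, 4, 2, 3),
                 noise = 1)
  d <- p$data
  p$data$y2 <- rnorm(nrow(d), 5, 2)
  p$outcome_names <- c("y", "y2")
  p$data$ysum <- 2 * p$data$y + 3 * p$data$y2
  p$outcome_names <- c(p$outcome_names, "ysum")
  w <- setNames(runif(p$n_households, 0.5, 2), seq_len(p$n_households))
  t1 <- did_estimate(p, "y", weights = w)$theta
  t2 <- did_estimate(p, "y2", weights = w)$theta
  ts <- did_estimate(p, "ysum", weights = w)$theta
  expect_equal(ts, 2 * t1 + 3 * t2, tolerance = 1e-10)

  # shift invariance and scale equivariance
  p$data$yshift <- p$data$y + 100
  p$data$yscale <- 10 * p$data$y
  p$outcome_names <- c(p$outcome_names, "yshift", "yscale")
  expect_equal(did_estimate(p, "yshift", weights = w)$theta, t1,
               tolerance = 1e-9)
  expect_equal(did_estimate(p, "yscale", weights = w)$theta, 10 * t1,
               tolerance = 1e-9)
})

test_that("cluster covariance limits: singleton clusters match HC", {
  set.seed(12)
  n <- 40
  X <- cbind(1, rnorm(n))
  e <- rnorm(n)
  w <- runif(n, 0.5, 2)
  v_cl <- cluster_vcov(X, e, w, cluster = seq_len(n), type = "CR0")
  bread <- solve(crossprod(X * sqrt(w)))
  meat <- crossprod(X * (w * e))
  expect_equal(v_cl, bread %*% meat %*% bread, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(cluster_vcov(X, e, w, cluster = rep(1, n)), "2 clusters",
               class = "ipwdid_error")
})

test_that("duplicating every cluster leaves the estimate unchanged", {
  p <- toy_panel(n_treated = 8, n_control = 8, cells = c(1, 5, 2, 3),
                 noise = 0.5, seed = 13)
  r1 <- did_estimate(p, "y")
  d2 <- p$data
  d2$household_id <- d2$household_id + 1000
  d2$village_id <- d2$village_id + 100
  p2 <- p
  p2$data <- rbind(p$data, d2)
  p2$n_households <- 2 * p$n_households
  r2 <- did_estimate(p2, "y")
  expect_equal(r2$theta, r1$theta, tolerance = 1e-10)
  expect_equal(r2$n, 2 * r1$n)
})

test_that("with many equal independent clusters, clustered SE tracks classical SE", {
  set.seed(14)
  G <- 150; m <- 4; n <- G * m
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x)
  beta <- solve(crossprod(X), crossprod(X, y))
  e <- y - drop(X %*% beta)
  v_cl <- cluster_vcov(X, e, rep(1, n), cluster = rep(seq_len(G), each = m))
  s2 <- sum(e^2) / (n - 2)
  v_ols <- s2 * solve(crossprod(X))
  expect_equal(sqrt(v_cl[2, 2]) / sqrt(v_ols[2, 2]), 1, tolerance = 0.1)
})

test_that("null effects are recovered on average under a null DGP", {
  thetas <- vapply(1:40, function(s) {
    cfg <- dgp_config(n_households = 200, n_villages = 10,
                      true_effects = c(hdds = 0), seed = s)
    p <- generate_panel(cfg, instruments = FALSE)
    fit <- fit_probit(p)
    w <- setNames(ipw_weights(fit$scores, fit$treated), fit$household_id)
    did_estimate(p, "hdds", weights = w,
                 controls = p$covariates$name)$theta
  }, numeric(1))
  expect_lt(abs(mean(thetas)), 3 * sd(thetas) / sqrt(length(thetas)))
})

test_that("placebo recovers a constructed baseline signal", {
  set.seed(15)
  n <- 200
  tr <- rep(c(1L, 0L), each = n / 2)
  village <- rep_len(1:10, n)
  base_y <- rnorm(n) + 1 * tr   # baseline outcome shifted +1 for treated
  d <- rbind(
    data.frame(household_id = 1:n, village_id = village, wave = 0,
               treated = tr, y = base_y),
    data.frame(household_id = 1:n, village_id = village, wave = 1,
               treated = tr, y = rnorm(n)))
  p <- structure(list(data = d[order(d$household_id, d$wave), ],
                      covariates = data.frame(name = character(),
                                              kind = character()),
                      outcome_names = "y", exam_items = NULL,
                      n_households = n, n_villages = 10, config = NULL),
                 class = "household_panel")
  r <- placebo_test(p, "y")
  expect_equal(r$coefficient, mean(base_y[tr == 1]) - mean(base_y[tr == 0]),
               tolerance = 1e-10)
  expect_equal(r$coefficient, 1, tolerance = 3 * r$se)
  expect_equal(r$n, n)
})

test_that("placebo is null when selection ignores baseline outcomes", {
  coefs <- vapply(1:40, function(s) {
    cfg <- dgp_config(n_households = 200, n_villages = 10, seed = s)
    # rho = 0: no baseline gap for hdds
    cfg$outcome_spec$rho[cfg$outcome_spec$name == "hdds"] <- 0
    att <- attr(cfg$outcome_spec, "gamma")
    att$hdds <- NULL                      # and no covariate confounding
    attr(cfg$outcome_spec, "gamma") <- att
    p <- generate_panel(cfg, instruments = FALSE)
    placebo_test(p, "hdds")$coefficient
  }, numeric(1))
  expect_lt(abs(mean(coefs)), 3 * sd(coefs) / sqrt(length(coefs)))
})

test_that("collinear controls are dropped, not fatal", {
  set.seed(16)
  p <- generate_panel(small_config(seed = 17), instruments = FALSE)
  p$data$dup <- p$data$male       # duplicate of an existing covariate
  p$covariates <- rbind(p$covariates, data.frame(name = "dup",
                                                 kind = "binary"))
  r <- did_estimate(p, "hdds", controls = c("male", "dup"))
  expect_true("dup" %in% r$aliased || "male" %in% r$aliased)
  expect_true(is.finite(r$theta))
})

test_that("estimation errors name their cause", {
  p <- toy_panel()
  p$data$const <- 1
  p$outcome_names <- c(p$outcome_names, "const")
  expect_error(did_estimate(p, "const"), "constant", class = "ipwdid_error")
  expect_error(did_estimate(p, "nope"), "not in panel",
               class = "ipwdid_error")
  p1 <- toy_panel(n_villages = 1)
  expect_error(did_estimate(p1, "y"), "clusters", class = "ipwdid_error")
})
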