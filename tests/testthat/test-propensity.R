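# Participation probit: closed-form oracles, grid-search oracle, an
# independent glm cross-check, marginal effects, and common support.

test_that("intercept-only probit recovers the probit of the treated share", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- probit_mle(matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")),
                    y)
  expect_equal(unname(fit$coefficients), qnorm(0.3), tolerance = 1e-7)
  expect_equal(fit$pseudo_r2, 0, tolerance = 1e-9)
})

test_that("single binary covariate matches the two-cell closed form", {
  # cell shares: s0 = 10/40 among x=0, s1 = 30/40 among x=1
  x <- rep(c(0, 1), each = 40)
  y <- c(rep(c(1, 0), c(10, 30)), rep(c(1, 0), c(30, 10)))
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- probit_mle(X, y)
  expect_equal(unname(fit$coefficients["(Intercept)"]), qnorm(0.25),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["x"]), qnorm(0.75) - qnorm(0.25),
               tolerance = 1e-6)
})

test_that("MLE matches a brute-force grid search on a two-parameter toy", {
  set.seed(4)
  x <- rnorm(60)
  y <- as.integer(0.4 + 0.8 * x + rnorm(60) > 0)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- probit_mle(X, y)
  b <- fit$coefficients
  # exhaustive grid at step 1e-3 around the MLE: no grid point beats it
  g0 <- seq(b[1] - 0.05, b[1] + 0.05, by = 1e-3)
  g1 <- seq(b[2] - 0.05, b[2] + 0.05, by = 1e-3)
  ll <- outer(g0, g1, Vectorize(function(a, c)
    ipwdid:::probit_loglik(c(a, c), X, y, rep(1, 60))))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  ll_mle <- ipwdid:::probit_loglik(b, X, y, rep(1, 60))
  expect_gte(ll_mle, max(ll))
  expect_equal(unname(b[1]), g0[best[1]], tolerance = 2e-3)
  expect_equal(unname(b[2]), g1[best[2]], tolerance = 2e-3)
})

test_that("probit agrees with glm on a multivariate fixture", {
  set.seed(5)
  n <- 400
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- as.integer(drop(X %*% c(-0.2, 0.7, -0.5)) + rnorm(n) > 0)
  fit <- probit_mle(X, y)
  ref <- glm(y ~ a + b, family = binomial("probit"),
             data = data.frame(y, a = X[, "a"], b = X[, "b"]))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_gte(fit$pseudo_r2, 0)
  expect_lt(fit$pseudo_r2, 1)
})

test_that("panel probit recovers generating coefficients at large n", {
  cfg <- dgp_config(n_households = 10000, n_villages = 40, seed = 12)
  p <- generate_panel(cfg, instruments = FALSE)
  fit <- fit_probit(p)
  beta <- cfg$selection_coefficients
  est <- fit$coefficients[names(beta)]
  se <- sqrt(diag(fit$vcov))[names(beta)]
  expect_true(all(abs(est - beta) <= 3 * se))
  expect_true(all(fit$scores > 0 & fit$scores < 1))
})

test_that("treated scores stochastically dominate control scores", {
  p <- generate_panel(dgp_config(seed = 13), instruments = FALSE)
  fit <- fit_probit(p)
  pt <- fit$scores[fit$treated == 1]
  pc <- fit$scores[fit$treated == 0]
  qs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(quantile(pt, qs) >= quantile(pc, qs)))
})

test_that("perfect separation fails naming the covariate", {
  x <- rep(c(0, 1), each = 25)
  X <- cbind(`(Intercept)` = 1, sep = x)
  expect_error(probit_mle(X, x), "sep", class = "ipwdid_separation")
})

test_that("derivative AME has a constant ratio to the coefficients", {
  p <- generate_panel(small_config(seed = 14), instruments = FALSE)
  fit <- fit_probit(p)
  ame <- fit$ame
  b <- fit$coefficients[ame$term]
  ratio <- ame$ame / b
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-10)
  expect_equal(unname(ratio[1]),
               mean(dnorm(drop(fit$design %*% fit$coefficients))),
               tolerance = 1e-10)
  # zero coefficient -> zero AME
  fit0 <- fit
  fit0$coefficients["male"] <- 0
  ame0 <- marginal_effects(fit0)
  expect_equal(ame0$ame[ame0$term == "male"], 0)

  disc <- marginal_effects(fit, method = "discrete")
  expect_false(isTRUE(all.equal(disc$ame, ame$ame)))
  expect_error(marginal_effects(fit, method = "bogus"))
})

test_that("rescaling a covariate rescales beta and AME inversely", {
  set.seed(6)
  n <- 300
  a <- rnorm(n)
  y <- as.integer(0.5 * a + rnorm(n) > 0)
  f1 <- probit_mle(cbind(`(Intercept)` = 1, a = a), y)
  f2 <- probit_mle(cbind(`(Intercept)` = 1, a = 2 * a), y)
  expect_equal(unname(f2$coefficients["a"]),
               unname(f1$coefficients["a"]) / 2, tolerance = 1e-6)
  expect_equal(pnorm(drop(cbind(1, a) %*% f1$coefficients)),
               pnorm(drop(cbind(1, 2 * a) %*% f2$coefficients)),
               tolerance = 1e-6)
})

test_that("common support conventions trim as documented", {
  s <- c(0.2, 0.5, 0.8, 0.1, 0.5, 0.9)
  tr <- c(1, 1, 1, 0, 0, 0)
  cs <- common_support(s, tr)
  expect_equal(c(cs$lo, cs$hi), c(0.2, 0.8))
  expect_equal(cs$n_trimmed_treated, 0)
  expect_equal(cs$n_trimmed_control, 2)

  # identical score sets: full range, nothing trimmed
  cs2 <- common_support(c(0.3, 0.6, 0.3, 0.6), c(1, 1, 0, 0))
  expect_equal(c(cs2$lo, cs2$hi), c(0.3, 0.6))
  expect_true(all(cs2$keep))

  # treated-preserving keeps every treated observation
  cs3 <- common_support(s, tr, convention = "treated_preserving")
  expect_true(all(cs3$keep[tr == 1]))
  expect_equal(cs3$n_trimmed_control, 2)

  expect_error(common_support(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)),
               "disjoint", class = "ipwdid_error")
  expect_error(common_support(c(0.5, 0.6), c(1, 1)), "non-empty",
               class = "ipwdid_error")
})
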