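# Synthetic two-wave household panel generator.
#
# The generator emulates the design of a voucher-based seed-system
# intervention study in the Lake zone of Tanzania: 434 households observed at
# baseline and endline, village clustering, self-selection into treatment on
# observable baseline characteristics via a latent-index probit, and outcomes
# that follow a two-period difference-in-differences data-generating process
#   y_it = alpha + lambda * t + theta * W_i * t + rho * W_i + gamma' x_i
#          + v_village + e_it
# with known treatment effects theta, so that every downstream estimator can
# be tested for parameter recovery without any survey microdata.

# Covariate specification constructors ---------------------------------------

#' Covariate specification entries
#'
#' A covariate specification is a list of entries, one per baseline covariate,
#' each created by one of these constructors. `cov_binary()` draws a Bernoulli
#' indicator, `cov_lognormal()` a lognormal positive variable,
#' `cov_beta()` a proportion in (0,1), `cov_poisson()` a count, and
#' `cov_categorical()` a mutually exclusive dummy block (e.g. road type) in
#' which at most one dummy is 1.
#'
#' @param name Column name of the covariate (for `cov_categorical()`, a stem;
#'   `dummies` are the generated column names).
#' @param p,meanlog,sdlog,shape1,shape2,lambda Distribution parameters.
#' @param dummies,probs For `cov_categorical()`: dummy column names and their
#'   probabilities (remaining mass is the omitted base level).
#' @return A list with class `"cov_spec"`.
#' @export
cov_binary <- function(name, p) {
  stopifnot(p > 0, p < 1)
  structure(list(name = name, kind = "binary", p = p), class = "cov_spec")
}

#' @rdname cov_binary
#' @export
cov_lognormal <- function(name, meanlog, sdlog) {
  stopifnot(sdlog > 0)
  structure(list(name = name, kind = "continuous", dist = "lognormal",
                 meanlog = meanlog, sdlog = sdlog), class = "cov_spec")
}

#' @rdname cov_binary
#' @export
cov_beta <- function(name, shape1, shape2) {
  stopifnot(shape1 > 0, shape2 > 0)
  structure(list(name = name, kind = "continuous", dist = "beta",
                 shape1 = shape1, shape2 = shape2), class = "cov_spec")
}

#' @rdname cov_binary
#' @export
cov_poisson <- function(name, lambda) {
  stopifnot(lambda >= 0)
  structure(list(name = name, kind = "continuous", dist = "poisson",
                 lambda = lambda), class = "cov_spec")
}

#' @rdname cov_binary
#' @export
cov_categorical <- function(name, dummies, probs) {
  stopifnot(length(dummies) == length(probs), all(probs > 0), sum(probs) < 1)
  structure(list(name = name, kind = "categorical", dummies = dummies,
                 probs = probs), class = "cov_spec")
}

#' Default baseline covariate specification
#'
#' Fourteen pre-treatment covariates with marginal distributions matched to
#' the pooled summary statistics of the motivating survey: household-head sex,
#' age, livelihood, casual labour, education share, dependency ratio, infants,
#' cultivated land, cassava-disease experience, valley-bottom access, road
#' type, asset value and region. Continuous scale variables (age, land,
#' assets) are lognormal; proportions are beta; binaries are Bernoulli.
#'
#' @return List of `cov_spec` entries.
#' @export
default_covariate_spec <- function() {
  list(
    cov_binary("male", 0.779),
    cov_lognormal("age", meanlog = 3.822, sdlog = 0.27),
    cov_binary("farming", 0.949),
    cov_binary("casual", 0.251),
    cov_beta("educ_share", 0.6, 6.8),
    cov_beta("dependency", 2.4, 3.5),
    cov_poisson("infants", 1.364),
    cov_lognormal("land_ha", meanlog = 0.79, sdlog = 0.65),
    cov_binary("cassava", 0.407),
    cov_binary("valley", 0.698),
    cov_categorical("road", dummies = c("road_earth", "road_tarmac"),
                    probs = c(0.539, 0.117)),
    cov_lognormal("assets_usd", meanlog = 2.77, sdlog = 1.11),
    cov_binary("mwanza", 0.610)
  )
}

#' Default selection (participation) coefficients
#'
#' Probit coefficients of the latent participation index, matched to the
#' first-stage participation regression of the motivating study. Names refer
#' to columns of the selection design matrix; `log_` prefixed names denote
#' natural-log transforms applied before fitting (age, asset value).
#'
#' @return Named numeric vector including `"(Intercept)"`.
#' @export
default_selection_coefficients <- function() {
  c(`(Intercept)` = 1.379,
    male = -0.464, log_age = -0.457, farming = 0.022, casual = -0.098,
    educ_share = 0.881, dependency = -0.691, infants = 0.079,
    land_ha = 0.015, cassava = 0.082, valley = 0.246,
    road_earth = 0.208, road_tarmac = 0.102, log_assets_usd = 0.015,
    mwanza = 0.640)
}

#' Default outcome equation specification
#'
#' One row per outcome with the parameters of the two-period DID
#' data-generating process: baseline control level `alpha`, secular time
#' effect `lambda`, time-invariant treated-group gap `rho`, true treatment
#' effect `theta`, idiosyncratic noise SD, village random-intercept SD, and
#' outcome kind (`"continuous"` or `"binary"`). Levels, gaps and effects
#' follow the published group means and DID estimates of the motivating
#' study; noise SDs are set so the implied effect sizes (in SD units) match
#' the published standardized effects.
#'
#' @return `data.frame` with attribute `"gamma"`: a named list of
#'   covariate loadings (on the selection design columns) per outcome.
#' @export
default_outcome_spec <- function() {
  out <- data.frame(
    name = c("knowledge_production", "knowledge_vitamina", "grow_ofsp",
             "hdds", "fcs", "mihfp", "relief_months", "sold_asset",
             "food_insecurity"),
    alpha = c(14.802, 1.995, 0.00, 4.303, 35.211, 1.005, 0.596, 0.560, 3.431),
    lambda = c(0.786, 0.520, 0.00, -1.142, -17.447, 2.298, -0.009, 0.027,
               -0.114),
    rho = c(2.625, 2.086, 0.057, 0.247, 1.916, 0.110, 0.031, -0.029, 0.339),
    theta = c(2.154, 0.844, 0.743, 0.172, 1.639, -0.038, -0.211, -0.048,
              0.580),
    noise_sd = c(11.0, 5.0, NA, 1.8, 15.0, 2.2, 1.2, NA, 2.0),
    village_sd = c(2.0, 1.0, 0.05, 0.3, 3.0, 0.4, 0.2, 0.05, 0.4),
    kind = c("continuous", "continuous", "binary", "continuous", "continuous",
             "continuous", "continuous", "binary", "continuous"),
    stringsAsFactors = FALSE
  )
  attr(out, "gamma") <- list(
    knowledge_production = c(educ_share = 6, dependency = -2, male = 1.5,
                             mwanza = 2),
    knowledge_vitamina = c(educ_share = 3, dependency = -1, mwanza = 1),
    grow_ofsp = c(valley = 0.05, mwanza = 0.05),
    hdds = c(log_assets_usd = 0.4, land_ha = 0.05, dependency = -0.5),
    fcs = c(log_assets_usd = 3, land_ha = 0.4, dependency = -4),
    mihfp = c(log_assets_usd = -0.5, land_ha = -0.1, dependency = 1.0),
    relief_months = c(log_assets_usd = -0.2, dependency = 0.5),
    sold_asset = c(log_assets_usd = -0.05, dependency = 0.1),
    food_insecurity = c(log_assets_usd = -0.4, dependency = 0.8)
  )
  out
}

#' Default knowledge-exam item banks
#'
#' Two blocks of binary exam items (sweetpotato production agronomy and
#' vitamin A nutrition) with per-item difficulties on the logit scale spread
#' from easy to hard, and the treatment-induced shift of latent ability (in
#' SD units, applied at endline to treated households).
#'
#' @return List with elements `production` and `vitamina`, each a list with
#'   `difficulty` (numeric vector in (0,1) of reference correct-response
#'   probabilities) and `effect` (ability shift).
#' @export
default_exam_items <- function() {
  list(
    production = list(difficulty = seq(0.90, 0.30, length.out = 20),
                      effect = 0.5),
    vitamina = list(difficulty = seq(0.75, 0.10, length.out = 8),
                    effect = 0.4)
  )
}

# DGP configuration -----------------------------------------------------------

#' Configure the synthetic panel data-generating process
#'
#' @param n_households Number of households (each observed in both waves).
#' @param n_villages Number of villages; households are assigned uniformly at
#'   random. The motivating study clusters standard errors at village level
#'   but does not report a village count; 30 is the package default.
#' @param covariate_spec List of [cov_binary()]-family entries.
#' @param selection_coefficients Named probit coefficients of the latent
#'   participation index (see [default_selection_coefficients()]).
#' @param outcome_spec Outcome equation table (see [default_outcome_spec()]).
#' @param true_effects Optional named vector overriding `theta` per outcome.
#' @param village_sd,noise_sd Optional scalars overriding the per-outcome
#'   village random-intercept SD / idiosyncratic noise SD for all outcomes.
#' @param exam_items Knowledge-exam item banks (see [default_exam_items()]).
#' @param transforms Named character vector of covariate transforms applied in
#'   the selection design (currently only `"log"`), e.g.
#'   `c(age = "log", assets_usd = "log")`.
#' @param seed Master seed; expanded into per-stage substreams.
#' @return Object of class `"dgp_config"`.
#' @export
dgp_config <- function(n_households = 434L,
                       n_villages = 30L,
                       covariate_spec = default_covariate_spec(),
                       selection_coefficients = default_selection_coefficients(),
                       outcome_spec = default_outcome_spec(),
                       true_effects = NULL,
                       village_sd = NULL,
                       noise_sd = NULL,
                       exam_items = default_exam_items(),
                       transforms = c(age = "log", assets_usd = "log"),
                       seed = 1L) {
  if (n_households < 4) ipw_stop("n_households must be at least 4")
  if (n_villages < 2) ipw_stop("n_villages must be at least 2")
  cov_names <- unlist(lapply(covariate_spec, function(s) {
    if (s$kind == "categorical") s$dummies else s$name
  }))
  if (anyDuplicated(cov_names))
    ipw_stop("duplicate covariate names: ",
             paste(unique(cov_names[duplicated(cov_names)]), collapse = ", "))
  ref <- setdiff(names(selection_coefficients), "(Intercept)")
  base_ref <- sub("^log_", "", ref)
  missing <- base_ref[!base_ref %in% cov_names]
  if (length(missing))
    ipw_stop("selection_coefficients reference unknown covariates: ",
             paste(missing, collapse = ", "))
  if (!"(Intercept)" %in% names(selection_coefficients))
    ipw_stop("selection_coefficients must include an \"(Intercept)\" term")
  if (!is.null(true_effects)) {
    bad <- setdiff(names(true_effects), outcome_spec$name)
    if (length(bad))
      ipw_stop("true_effects for unknown outcomes: ",
               paste(bad, collapse = ", "))
    outcome_spec$theta[match(names(true_effects), outcome_spec$name)] <-
      as.numeric(true_effects)
  }
  if (!is.null(village_sd)) outcome_spec$village_sd[] <- village_sd
  if (!is.null(noise_sd)) {
    # a scalar override applies to every outcome; for binary outcomes a zero
    # disables the Bernoulli draw (degenerate deterministic mode, used by the
    # zero-noise determinism contract)
    outcome_spec$noise_sd[] <- noise_sd
  }
  for (blk in names(exam_items)) {
    d <- exam_items[[blk]]$difficulty
    if (any(d <= 0 | d >= 1))
      ipw_stop("exam item difficulties must lie in (0,1)")
  }
  structure(list(
    n_households = as.integer(n_households),
    n_villages = as.integer(n_villages),
    covariate_spec = covariate_spec,
    selection_coefficients = selection_coefficients,
    outcome_spec = outcome_spec,
    exam_items = exam_items,
    transforms = transforms,
    seed = as.integer(seed)
  ), class = "dgp_config")
}

# Internal generation stages ---------------------------------------------------

draw_covariates <- function(spec, n) {
  cols <- list()
  for (s in spec) {
    if (s$kind == "binary") {
      cols[[s$name]] <- rbinom(n, 1L, s$p)
    } else if (s$kind == "categorical") {
      probs <- c(s$probs, 1 - sum(s$probs))
      lev <- sample.int(length(probs), n, replace = TRUE, prob = probs)
      for (j in seq_along(s$dummies))
        cols[[s$dummies[j]]] <- as.integer(lev == j)
    } else {
      cols[[s$name]] <- switch(s$dist,
        lognormal = rlnorm(n, s$meanlog, s$sdlog),
        beta = rbeta(n, s$shape1, s$shape2),
        poisson = rpois(n, s$lambda),
        ipw_stop("unknown covariate distribution: ", s$dist))
    }
  }
  as.data.frame(cols)
}

covariate_kinds <- function(spec) {
  do.call(rbind, lapply(spec, function(s) {
    if (s$kind == "categorical")
      data.frame(name = s$dummies, kind = "binary")
    else
      data.frame(name = s$name, kind = s$kind)
  }))
}

#' Build the selection / control design matrix from raw covariates
#'
#' Applies the configured transforms (natural log for scale variables, with
#' names prefixed `log_`) and returns a numeric matrix whose columns can be
#' addressed by selection coefficients and outcome loadings.
#' @param covariates Data frame of raw baseline covariates.
#' @param transforms Named character vector, values `"log"`.
#' @return Numeric matrix (no intercept column).
#' @export
selection_design <- function(covariates,
                             transforms = c(age = "log", assets_usd = "log")) {
  X <- covariates
  for (nm in names(transforms)) {
    if (!nm %in% names(X)) next
    if (transforms[[nm]] != "log")
      ipw_stop("unknown transform: ", transforms[[nm]])
    if (any(X[[nm]] <= 0))
      ipw_stop("cannot log-transform non-positive covariate: ", nm)
    X[[paste0("log_", nm)]] <- log(X[[nm]])
    X[[nm]] <- NULL
  }
  as.matrix(X)
}

#' Deterministic outcome means of the generating process
#'
#' Returns the noiseless mean of every outcome for given covariates,
#' treatment and wave: `alpha + lambda t + theta W t + rho W + gamma'(x - xbar)`.
#' Covariate loadings are applied to columns centered at their sample means so
#' `alpha` remains the baseline control level.
#'
#' @param config A [dgp_config()].
#' @param design Selection design matrix from [selection_design()].
#' @param treated 0/1 vector per household.
#' @param wave Scalar 0 or 1, or vector.
#' @return Matrix (rows = households, columns = outcomes).
#' @export
expected_outcomes <- function(config, design, treated, wave) {
  os <- config$outcome_spec
  gammas <- attr(os, "gamma")
  Xc <- scale(design, center = TRUE, scale = FALSE)
  n <- nrow(design)
  wave <- rep_len(wave, n)
  mu <- matrix(0, n, nrow(os), dimnames = list(NULL, os$name))
  for (i in seq_len(nrow(os))) {
    g <- gammas[[os$name[i]]]
    gx <- if (is.null(g)) 0 else {
      bad <- setdiff(names(g), colnames(Xc))
      if (length(bad))
        ipw_stop("outcome loading on unknown design column: ",
                 paste(bad, collapse = ", "))
      as.vector(Xc[, names(g), drop = FALSE] %*% g)
    }
    mu[, i] <- os$alpha[i] + os$lambda[i] * wave +
      os$rho[i] * treated + os$theta[i] * treated * wave + gx
    # binary outcomes are generated from the mean as a probability
    if (os$kind[i] == "binary") mu[, i] <- pmin(pmax(mu[, i], 0), 1)
  }
  mu
}

# 12 survey food categories used by the recall instruments (see the food
# group map shipped in extdata); baseline consumption prevalences chosen as
# realistic for a rural East African setting.
survey_categories <- function() {
  c(cereals = 0.95, roots_tubers = 0.60, vita_vegetables = 0.50,
    other_vegetables = 0.60, vita_fruits = 0.25, other_fruits = 0.30,
    organ_meat = 0.05, flesh_meat_fish = 0.40, eggs = 0.12,
    legumes_nuts = 0.45, milk_dairy = 0.20, oils_fats = 0.50)
}

draw_instruments <- function(config, mu0, mu1, treated) {
  n <- config$n_households
  os <- config$outcome_spec
  std <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0

  res <- list()
  # Knowledge exams: one-parameter item-response model. Latent ability tracks
  # the standardized deterministic mean of the matching knowledge outcome, so
  # exam-derived scores move with the outcome-level DGP.
  for (blk in names(config$exam_items)) {
    it <- config$exam_items[[blk]]
    K <- length(it$difficulty)
    onm <- paste0("knowledge_",
                  if (blk == "production") "production" else "vitamina")
    latent <- if (onm %in% colnames(mu0)) cbind(std(mu0[, onm]), std(mu1[, onm]))
              else matrix(0, n, 2)
    pers <- rnorm(n)
    thr <- qlogis(it$difficulty)   # logit of reference correct probability
    for (w in 1:2) {
      ability <- latent[, w] + pers + if (w == 2) it$effect * treated else 0
      p <- plogis(outer(ability, thr, "+"))
      m <- matrix(rbinom(n * K, 1L, p), n, K)
      colnames(m) <- sprintf("exam_%s_%02d",
                             ifelse(blk == "production", "prod", "vita"),
                             seq_len(K))
      res[[paste0("exam_", blk, "_w", w - 1)]] <- m
    }
  }
  # 24-hour recall and 7-day frequency instruments, shifted on the logit
  # scale by the standardized dietary latent (hdds / fcs means).
  cats <- survey_categories()
  dlat <- if ("hdds" %in% colnames(mu0)) cbind(std(mu0[, "hdds"]), std(mu1[, "hdds"]))
          else matrix(0, n, 2)
  flat <- if ("fcs" %in% colnames(mu0)) cbind(std(mu0[, "fcs"]), std(mu1[, "fcs"]))
          else matrix(0, n, 2)
  for (w in 1:2) {
    p <- plogis(outer(0.5 * dlat[, w], qlogis(cats), "+"))
    m <- matrix(rbinom(n * length(cats), 1L, p), n)
    colnames(m) <- sprintf("recall_g%02d", seq_along(cats))
    res[[paste0("recall_w", w - 1)]] <- m
    pf <- plogis(outer(0.5 * flat[, w], qlogis(cats), "+"))
    f <- matrix(rbinom(n * length(cats), 7L, pf), n)
    colnames(f) <- sprintf("freq_f%02d", seq_along(cats))
    res[[paste0("freq_w", w - 1)]] <- f
  }
  # Food-security month calendars and coping strategies.
  for (w in 1:2) {
    muw <- if (w == 1) mu0 else mu1
    pl <- if ("mihfp" %in% colnames(muw))
      pmin(pmax(muw[, "mihfp"] / 12, 0.005), 0.995) else rep(0.1, n)
    ml <- matrix(rbinom(n * 12, 1L, rep(pl, 12)), n)
    colnames(ml) <- sprintf("month_low_%02d", 1:12)
    pr <- if ("relief_months" %in% colnames(muw))
      pmin(pmax(muw[, "relief_months"] / 12, 0.002), 0.995) else rep(0.05, n)
    mr <- matrix(rbinom(n * 12, 1L, rep(pr, 12)), n)
    colnames(mr) <- sprintf("month_relief_%02d", 1:12)
    lam <- if ("food_insecurity" %in% colnames(muw))
      pmax(muw[, "food_insecurity"], 0.05) else rep(1, n)
    res[[paste0("months_w", w - 1)]] <-
      cbind(ml, mr, strategies_count = rpois(n, lam))
  }
  res
}

# Panel generation -------------------------------------------------------------

#' Generate a synthetic two-wave household panel
#'
#' Draws baseline covariates, assigns villages uniformly at random, realizes
#' treatment by the latent-index rule `W = 1{beta'z + e > 0}` with standard
#' normal `e`, generates outcomes from the two-period DID process with village
#' random intercepts, and generates raw survey instruments (knowledge exam
#' items, 24-hour recall indicators, 7-day frequencies, food-security month
#' calendars) consistently with the outcome-level latent means.
#'
#' @param config A [dgp_config()].
#' @param instruments Generate raw instrument columns (default `TRUE`);
#'   disable for speed in Monte-Carlo studies that only use the outcome
#'   columns.
#' @return Object of class `"household_panel"`: list with `data` (one row per
#'   household x wave), `covariates` (name/kind table), `outcome_names`,
#'   `exam_items`, and the generating `config`.
#' @export
generate_panel <- function(config, instruments = TRUE) {
  stopifnot(inherits(config, "dgp_config"))
  seeds <- derive_seeds(config$seed,
                        c("covariates", "selection", "outcomes", "instruments"))
  n <- config$n_households

  set.seed(seeds[["covariates"]])
  cov <- draw_covariates(config$covariate_spec, n)
  village <- sample.int(config$n_villages, n, replace = TRUE)
  if (length(unique(village)) < 2)
    village[1:2] <- 1:2

  set.seed(seeds[["selection"]])
  X <- selection_design(cov, config$transforms)
  beta <- config$selection_coefficients
  slope <- setdiff(names(beta), "(Intercept)")
  bad <- setdiff(slope, colnames(X))
  if (length(bad))
    ipw_stop("selection coefficients without design column: ",
             paste(bad, collapse = ", "))
  latent <- beta[["(Intercept)"]] +
    as.vector(X[, slope, drop = FALSE] %*% beta[slope]) + rnorm(n)
  treated <- as.integer(latent > 0)
  share <- mean(treated)
  if (sum(treated) < 2 || sum(1 - treated) < 2)
    ipw_stop(sprintf(
      "degenerate treatment assignment: realized treated share %.3f", share))

  set.seed(seeds[["outcomes"]])
  mu0 <- expected_outcomes(config, X, treated, wave = 0)
  mu1 <- expected_outcomes(config, X, treated, wave = 1)
  # village intercepts must be common to both waves: draw per outcome once
  os <- config$outcome_spec
  veff <- sapply(seq_len(nrow(os)), function(i)
    if (os$village_sd[i] > 0) rnorm(config$n_villages, 0, os$village_sd[i])
    else rep(0, config$n_villages))
  y0 <- mu0; y1 <- mu1
  for (i in seq_len(nrow(os))) {
    v <- veff[village, i]
    for (w in 1:2) {
      muw <- if (w == 1) mu0[, i] else mu1[, i]
      if (os$kind[i] == "binary") {
        p <- pmin(pmax(muw + v, 0), 1)
        nsd <- os$noise_sd[i]
        draw <- if (!is.na(nsd) && nsd == 0) p else rbinom(n, 1L, p)
      } else {
        nsd <- os$noise_sd[i]
        draw <- muw + v + if (!is.na(nsd) && nsd > 0) rnorm(n, 0, nsd) else 0
      }
      if (w == 1) y0[, i] <- draw else y1[, i] <- draw
    }
  }

  inst <- NULL
  if (instruments) {
    set.seed(seeds[["instruments"]])
    inst <- draw_instruments(config, mu0, mu1, treated)
  }

  rows <- function(w) {
    df <- data.frame(household_id = seq_len(n), village_id = village,
                     wave = w, treated = treated)
    df <- cbind(df, cov)
    if (instruments) {
      df <- cbind(df,
        inst[[paste0("exam_production_w", w)]],
        inst[[paste0("exam_vitamina_w", w)]],
        inst[[paste0("recall_w", w)]],
        inst[[paste0("freq_w", w)]],
        inst[[paste0("months_w", w)]])
    }
    yw <- if (w == 0) y0 else y1
    cbind(df, as.data.frame(yw))
  }
  data <- rbind(rows(0), rows(1))
  data <- data[order(data$household_id, data$wave), ]
  rownames(data) <- NULL

  structure(list(
    data = data,
    covariates = covariate_kinds(config$covariate_spec),
    outcome_names = os$name,
    exam_items = if (instruments) list(
      production = sprintf("exam_prod_%02d",
                           seq_along(config$exam_items$production$difficulty)),
      vitamina = sprintf("exam_vita_%02d",
                         seq_along(config$exam_items$vitamina$difficulty))
    ) else NULL,
    n_households = n,
    n_villages = config$n_villages,
    config = config
  ), class = "household_panel")
}

#' @export
print.household_panel <- function(x, ...) {
  cat("<household_panel>\n")
  cat("  households:", x$n_households, " villages:", x$n_villages, "\n")
  b <- x$data[x$data$wave == 0, ]
  cat("  treated:", sum(b$treated), " control:", sum(1 - b$treated), "\n")
  cat("  covariates:", paste(x$covariates$name, collapse = ", "), "\n")
  cat("  outcomes:", paste(x$outcome_names, collapse = ", "), "\n")
  invisible(x)
}

# Panel I/O ---------------------------------------------------------------------

#' Write / read a household panel as CSV
#'
#' `write_panel()` writes one row per household x wave. `read_panel()` reads a
#' panel CSV back, validates the schema (required id columns, balanced waves,
#' treatment constant within household, 12-entry recall and month blocks) and
#' reconstructs the panel object; covariate kind (binary vs continuous) is
#' inferred from the observed values.
#'
#' @param panel A `"household_panel"`.
#' @param path File path.
#' @return `read_panel()` returns a `"household_panel"`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "household_panel"))
  write.csv(panel$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) ipw_stop("no such file: ", path)
  data <- read.csv(path, check.names = FALSE)
  required <- c("household_id", "village_id", "wave", "treated")
  missing <- setdiff(required, names(data))
  if (length(missing))
    ipw_stop("panel file missing required columns: ",
             paste(missing, collapse = ", "))
  if (!all(data$wave %in% c(0, 1)))
    ipw_stop("wave must be 0 (baseline) or 1 (endline)")
  tab <- table(data$household_id, data$wave)
  if (!all(dim(tab) == c(length(unique(data$household_id)), 2)) ||
      !all(tab == 1))
    ipw_stop("panel is not balanced: every household needs exactly one row ",
             "per wave")
  tcheck <- tapply(data$treated, data$household_id,
                   function(z) length(unique(z)))
  if (any(tcheck != 1))
    ipw_stop("treatment status not constant within household: ",
             paste(utils::head(names(tcheck)[tcheck != 1], 5), collapse = ", "))

  nm <- names(data)
  inst_pat <- "^(exam_(prod|vita)_|recall_g|freq_f|month_(low|relief)_)"
  inst_cols <- grep(inst_pat, nm, value = TRUE)
  n_recall <- sum(grepl("^recall_g", nm))
  if (n_recall > 0 && n_recall != 12)
    ipw_stop("recall block must have exactly 12 categories, found ", n_recall)
  for (blk in c("month_low_", "month_relief_")) {
    k <- sum(startsWith(nm, blk))
    if (k > 0 && k != 12)
      ipw_stop(blk, "block must have exactly 12 months, found ", k)
  }
  special <- c(required, inst_cols, "sold_asset", "strategies_count")
  first_inst <- if (length(inst_cols)) min(match(inst_cols, nm)) else NA
  rest <- setdiff(nm, special)
  # columns before the instrument block are covariates, after are outcomes
  if (!is.na(first_inst)) {
    cov_cols <- rest[match(rest, nm) < first_inst]
    out_cols <- rest[match(rest, nm) > max(match(inst_cols, nm))]
  } else {
    # no instruments: covariates are constant within household across waves
    const <- vapply(rest, function(cn)
      all(tapply(data[[cn]], data$household_id,
                 function(z) length(unique(z))) == 1), logical(1))
    cov_cols <- rest[const]
    out_cols <- rest[!const]
  }
  if ("sold_asset" %in% nm) out_cols <- union(out_cols, "sold_asset")
  kinds <- vapply(cov_cols, function(cn)
    if (all(data[[cn]] %in% c(0, 1))) "binary" else "continuous", character(1))

  data <- data[order(data$household_id, data$wave), ]
  rownames(data) <- NULL
  structure(list(
    data = data,
    covariates = data.frame(name = cov_cols, kind = unname(kinds)),
    outcome_names = out_cols,
    exam_items = if (any(startsWith(nm, "exam_"))) list(
      production = grep("^exam_prod_", nm, value = TRUE),
      vitamina = grep("^exam_vita_", nm, value = TRUE)
    ) else NULL,
    n_households = length(unique(data$household_id)),
    n_villages = length(unique(data$village_id)),
    config = NULL
  ), class = "household_panel")
}

#' Baseline rows of a panel
#' @param panel A `"household_panel"`.
#' @param wave Wave to extract (0 = baseline).
#' @return Data frame, one row per household.
#' @export
panel_wave <- function(panel, wave = 0) {
  stopifnot(inherits(panel, "household_panel"))
  out <- panel$data[panel$data$wave == wave, , drop = FALSE]
  rownames(out) <- NULL
  out
}
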