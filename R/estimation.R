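# Treatment-effect estimation: inverse-probability weights from the
# propensity scores, weighted least squares for the two-period DID equation
#   y_it = alpha + lambda t + theta W_i t + rho W_i + gamma' x_it + e_it
# with village-clustered sandwich standard errors, and placebo regressions of
# baseline outcomes on endline participation.

#' Inverse-probability-of-treatment weights
#'
#' Treated households get `1/p`, controls `1/(1-p)`, with `p` the estimated
#' propensity score; both waves of a household share its weight.
#'
#' @param scores Propensity scores in (0, 1).
#' @param treated 0/1 flags aligned with `scores`.
#' @param normalize Normalize weights within arm to sum to the arm size
#'   (default `FALSE`: weights used as given).
#' @return Numeric weight vector (each weight is at least 1 when
#'   `normalize = FALSE`).
#' @export
ipw_weights <- function(scores, treated, normalize = FALSE) {
  if (any(scores <= 0 | scores >= 1))
    ipw_stop("propensity scores must lie strictly in (0, 1)")
  treated <- as.integer(treated)
  phi <- ifelse(treated == 1, 1 / scores, 1 / (1 - scores))
  if (normalize) {
    for (a in 0:1) {
      i <- treated == a
      phi[i] <- phi[i] * sum(i) / sum(phi[i])
    }
  }
  phi
}

#' Cluster-robust sandwich covariance for weighted least squares
#'
#' `vcov = c (X'WX)^{-1} (sum_g u_g u_g') (X'WX)^{-1}` with cluster score
#' sums `u_g = sum_{i in g} w_i e_i x_i`. The small-sample factor `c` is
#' `G/(G-1) * (n-1)/(n-k)` for `type = "CR1"` (default) and 1 for `"CR0"`.
#'
#' @param X Design matrix (the columns actually used in the fit).
#' @param residuals WLS residuals.
#' @param weights Case weights.
#' @param cluster Cluster id per row (at least 2 distinct values).
#' @param type `"CR1"` or `"CR0"`.
#' @return Covariance matrix.
#' @export
cluster_vcov <- function(X, residuals, weights, cluster,
                         type = c("CR1", "CR0")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  cluster <- as.character(cluster)
  G <- length(unique(cluster))
  if (G < 2) ipw_stop("clustered covariance needs at least 2 clusters")
  n <- nrow(X); k <- ncol(X)
  bread <- solve(crossprod(X * sqrt(weights)))
  S <- X * (weights * residuals)
  U <- rowsum(S, cluster)
  meat <- crossprod(U)
  corr <- if (type == "CR1") G / (G - 1) * (n - 1) / (n - k) else 1
  v <- corr * bread %*% meat %*% bread
  dimnames(v) <- list(colnames(X), colnames(X))
  v
}

build_controls <- function(panel, controls, transforms) {
  if (!length(controls)) return(NULL)
  base <- panel_wave(panel, 0)
  missing <- setdiff(controls, names(base))
  if (length(missing))
    ipw_stop("control covariates not in panel: ",
             paste(missing, collapse = ", "))
  # baseline values replicated across both waves (the conditioning set is
  # pre-treatment by construction)
  Z <- selection_design(base[, controls, drop = FALSE],
                        transforms[names(transforms) %in% controls])
  Z[match(panel$data$household_id, base$household_id), , drop = FALSE]
}

wls_fit <- function(X, y, w, cluster, se_type) {
  qr_x <- qr(X * sqrt(w))
  aliased <- rep(FALSE, ncol(X))
  if (qr_x$rank < ncol(X)) {
    drop_cols <- qr_x$pivot[(qr_x$rank + 1):ncol(X)]
    aliased[drop_cols] <- TRUE
    X_use <- X[, !aliased, drop = FALSE]
  } else X_use <- X
  beta <- solve(crossprod(X_use * sqrt(w)), crossprod(X_use, w * y))
  fitted <- drop(X_use %*% beta)
  e <- y - fitted
  vc <- cluster_vcov(X_use, e, w, cluster, type = se_type)
  ybar <- wmean(y, w)
  r2 <- 1 - sum(w * e^2) / sum(w * (y - ybar)^2)
  list(coefficients = setNames(drop(beta), colnames(X_use)),
       vcov = vc, residuals = e, r2 = r2, aliased = colnames(X)[aliased])
}

#' Weighted difference-in-differences estimate on a two-wave panel
#'
#' Weighted least squares of the outcome on intercept, time dummy, treatment
#' indicator, their interaction, and baseline controls. The interaction
#' coefficient is the average DID effect of participation. Standard errors
#' are clustered (village level by default) with a CR1 small-sample
#' correction; confidence intervals use t critical values with G-1 degrees
#' of freedom.
#'
#' @param panel A `"household_panel"`.
#' @param outcome Outcome column name.
#' @param weights Optional per-household weights, either a numeric vector
#'   named by household id or a data frame with columns `id` and `weight`
#'   (e.g. from [ipw_weights()] or a match result). Default: unweighted.
#' @param controls Character vector of baseline covariate names (transformed
#'   per `transforms`).
#' @param keep Optional household ids to retain (e.g. the common-support
#'   sample).
#' @param cluster Cluster column (default `"village_id"`).
#' @param transforms Log-transform map applied to controls.
#' @param se_type `"CR1"` (default) or `"CR0"`.
#' @param conf_level Confidence level for the reported interval.
#' @return Object of class `"did_result"` with the coefficient table
#'   (`table`), the DID effect (`theta`, `se`, `conf_int`, `p_value`),
#'   `r2`, `n`, `n_clusters`, and metadata.
#' @export
did_estimate <- function(panel, outcome, weights = NULL,
                         controls = character(), keep = NULL,
                         cluster = "village_id",
                         transforms = c(age = "log", assets_usd = "log"),
                         se_type = c("CR1", "CR0"), conf_level = 0.95) {
  se_type <- match.arg(se_type)
  stopifnot(inherits(panel, "household_panel"))
  d <- panel$data
  if (!outcome %in% names(d)) ipw_stop("outcome not in panel: ", outcome)
  Z <- build_controls(panel, controls, transforms)
  hh_w <- resolve_weights(weights, d$household_id)
  rows <- if (is.null(keep)) rep(TRUE, nrow(d)) else d$household_id %in% keep
  rows <- rows & hh_w > 0
  y <- d[[outcome]][rows]
  if (var(y) == 0) ipw_stop("outcome is constant: ", outcome)
  X <- cbind(`(Intercept)` = 1, wave = d$wave, treated = d$treated,
             `treated:wave` = d$treated * d$wave)
  if (!is.null(Z)) X <- cbind(X, Z)
  X <- X[rows, , drop = FALSE]
  w <- hh_w[rows]
  cl <- d[[cluster]][rows]
  G <- length(unique(cl))
  if (G < 2) ipw_stop("need at least 2 clusters, got ", G)
  fit <- wls_fit(X, y, w, cl, se_type)
  se <- sqrt(diag(fit$vcov))
  est <- fit$coefficients
  tcrit <- qt(1 - (1 - conf_level) / 2, df = G - 1)
  table <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se))
  table$statistic <- table$estimate / table$se
  table$p_value <- 2 * pt(-abs(table$statistic), df = G - 1)
  th <- est[["treated:wave"]]
  th_se <- se[["treated:wave"]]
  structure(list(
    table = table,
    theta = th, se = th_se,
    conf_int = c(th - tcrit * th_se, th + tcrit * th_se),
    p_value = 2 * pt(-abs(th / th_se), df = G - 1),
    r2 = fit$r2, n = sum(rows), n_clusters = G,
    outcome = outcome, controls = controls, se_type = se_type,
    aliased = fit$aliased, weighted = !is.null(weights)
  ), class = "did_result")
}

resolve_weights <- function(weights, household_id) {
  if (is.null(weights)) return(rep(1, length(household_id)))
  if (inherits(weights, "match_result")) weights <- weights$weights
  if (is.data.frame(weights)) {
    if (!all(c("id", "weight") %in% names(weights)))
      ipw_stop("weight data frame needs columns id, weight")
    w <- setNames(weights$weight, weights$id)
  } else if (!is.null(names(weights))) {
    w <- weights
  } else {
    ids <- unique(household_id)
    if (length(weights) != length(ids))
      ipw_stop("unnamed weights must have one entry per household")
    w <- setNames(weights, ids)
  }
  out <- w[as.character(household_id)]
  out[is.na(out)] <- 0
  unname(out)
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf("<did_result> outcome %s (%s%s)\n", x$outcome,
              if (x$weighted) "IPW-weighted, " else "unweighted, ",
              x$se_type))
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("DID effect %.4f (SE %.4f), 95%% CI [%.4f, %.4f], R2 %.3f, n %d, clusters %d\n",
              x$theta, x$se, x$conf_int[1], x$conf_int[2], x$r2, x$n,
              x$n_clusters))
  invisible(x)
}

#' Placebo regression of a baseline outcome on endline participation
#'
#' Cross-sectional weighted regression of the baseline (pre-intervention)
#' outcome on the endline treatment indicator and controls, with clustered
#' standard errors. A significant coefficient signals selection on baseline
#' outcomes.
#'
#' @inheritParams did_estimate
#' @return Object of class `"placebo_result"` with `coefficient` (on
#'   treatment), `se`, `p_value`, `table`, `r2`, `n`, `n_clusters`.
#' @export
placebo_test <- function(panel, outcome, weights = NULL,
                         controls = character(), keep = NULL,
                         cluster = "village_id",
                         transforms = c(age = "log", assets_usd = "log"),
                         se_type = c("CR1", "CR0")) {
  se_type <- match.arg(se_type)
  stopifnot(inherits(panel, "household_panel"))
  base <- panel_wave(panel, 0)
  if (!outcome %in% names(base)) ipw_stop("outcome not in panel: ", outcome)
  Zfull <- build_controls(panel, controls, transforms)
  bidx <- panel$data$wave == 0
  Z <- if (is.null(Zfull)) NULL else Zfull[bidx, , drop = FALSE]
  hh_w <- resolve_weights(weights, base$household_id)
  rows <- if (is.null(keep)) rep(TRUE, nrow(base))
          else base$household_id %in% keep
  rows <- rows & hh_w > 0
  y <- base[[outcome]][rows]
  if (var(y) == 0) ipw_stop("outcome is constant: ", outcome)
  X <- cbind(`(Intercept)` = 1, treated = base$treated)
  if (!is.null(Z)) X <- cbind(X, Z)
  X <- X[rows, , drop = FALSE]
  cl <- base[[cluster]][rows]
  G <- length(unique(cl))
  if (G < 2) ipw_stop("need at least 2 clusters, got ", G)
  fit <- wls_fit(X, y, hh_w[rows], cl, se_type)
  se <- sqrt(diag(fit$vcov))
  est <- fit$coefficients
  table <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se))
  table$statistic <- table$estimate / table$se
  table$p_value <- 2 * pt(-abs(table$statistic), df = G - 1)
  structure(list(
    table = table,
    coefficient = est[["treated"]], se = se[["treated"]],
    p_value = 2 * pt(-abs(est[["treated"]] / se[["treated"]]), df = G - 1),
    r2 = fit$r2, n = sum(rows), n_clusters = G,
    outcome = outcome, aliased = fit$aliased
  ), class = "placebo_result")
}

#' @export
print.placebo_result <- function(x, ...) {
  cat(sprintf("<placebo_result> baseline %s on endline participation\n",
              x$outcome))
  cat(sprintf("coefficient %.4f (SE %.4f, p %.3f), R2 %.3f, n %d, clusters %d\n",
              x$coefficient, x$se, x$p_value, x$r2, x$n, x$n_clusters))
  invisible(x)
}

#' Naive endline contrast in means
#'
#' The unadjusted treated-minus-control difference in endline means: the
#' estimator that ignores both selection and baseline differences. Exposed
#' as the benchmark that the IPW-DID validity simulations compare against.
#'
#' @param panel A `"household_panel"`.
#' @param outcome Outcome column name.
#' @return Numeric difference in means.
#' @export
naive_contrast <- function(panel, outcome) {
  e <- panel_wave(panel, 1)
  mean(e[[outcome]][e$treated == 1]) - mean(e[[outcome]][e$treated == 0])
}
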