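# Propensity-score matching (nearest neighbour, radius, Epanechnikov kernel)
# and covariate balance diagnostics (standardized bias, post-matching probit
# refit, likelihood-ratio balance test).

#' Match control to treated households on the propensity score
#'
#' Each matched treated household carries weight 1 and distributes one unit
#' of mass over its matched controls: nearest neighbour (with replacement,
#' ties broken by lowest household id) gives its control weight 1; radius
#' matching splits the unit equally over all controls within the radius;
#' kernel matching distributes it proportionally to Epanechnikov kernel
#' weights `K((p_i - p_j)/h)`. Control weights therefore sum to the number of
#' matched treated households. Treated households with no admissible control
#' are dropped with a warning.
#'
#' @param scores Propensity scores.
#' @param treated 0/1 flags aligned with `scores`.
#' @param ids Household ids (used for tie-breaking and reporting); default
#'   positional.
#' @param algorithm `"radius"` (default), `"nearest_neighbour"` or
#'   `"kernel"`.
#' @param radius Radius for radius matching (default 0.05).
#' @param bandwidth Kernel bandwidth (default 0.06).
#' @return Object of class `"match_result"`: data frame `weights` with
#'   columns `id`, `treated`, `score`, `weight`, `matched`, plus algorithm
#'   metadata and per-arm effective sample sizes.
#' @export
match_households <- function(scores, treated, ids = seq_along(scores),
                             algorithm = c("radius", "nearest_neighbour",
                                           "kernel"),
                             radius = 0.05, bandwidth = 0.06) {
  algorithm <- match.arg(algorithm)
  treated <- as.integer(treated)
  if (!any(treated == 1) || !any(treated == 0))
    ipw_stop("both arms must be non-empty")
  it <- which(treated == 1)
  ic <- which(treated == 0)
  # order controls by id so which.min tie-breaks to the lowest id
  ic <- ic[order(ids[ic])]
  w_control <- setNames(numeric(length(ic)), ids[ic])
  matched_t <- logical(length(it))
  D <- abs(outer(scores[it], scores[ic], "-"))   # treated x control distances
  for (r in seq_along(it)) {
    d <- D[r, ]
    if (algorithm == "nearest_neighbour") {
      j <- which.min(d)
      w_control[j] <- w_control[j] + 1
      matched_t[r] <- TRUE
    } else if (algorithm == "radius") {
      j <- which(d <= radius)
      if (length(j)) {
        w_control[j] <- w_control[j] + 1 / length(j)
        matched_t[r] <- TRUE
      }
    } else {
      k <- pmax(0, 1 - (d / bandwidth)^2)       # Epanechnikov, constant dropped
      if (sum(k) > 0) {
        w_control <- w_control + k / sum(k)
        matched_t[r] <- TRUE
      }
    }
  }
  n_dropped <- sum(!matched_t)
  if (n_dropped > 0)
    warning(n_dropped, " treated household(s) had no admissible control and ",
            "were dropped", call. = FALSE)
  weights <- data.frame(
    id = c(ids[it], ids[ic]),
    treated = c(rep(1L, length(it)), rep(0L, length(ic))),
    score = c(scores[it], scores[ic]),
    weight = c(as.numeric(matched_t), unname(w_control)))
  weights$matched <- weights$weight > 0
  weights <- weights[order(weights$id), ]
  rownames(weights) <- NULL
  structure(list(
    weights = weights,
    algorithm = algorithm,
    params = switch(algorithm,
      radius = list(radius = radius),
      kernel = list(bandwidth = bandwidth, kernel = "epanechnikov"),
      nearest_neighbour = list(k = 1L, replacement = TRUE)),
    n_treated_matched = sum(matched_t),
    n_treated_dropped = n_dropped,
    n_control_used = sum(w_control > 0),
    ess_control = n_eff(w_control[w_control > 0])
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s; %d treated matched (%d dropped), %d controls used (ESS %.1f)\n",
              x$algorithm, x$n_treated_matched, x$n_treated_dropped,
              x$n_control_used, x$ess_control))
  invisible(x)
}

#' Standardized bias (standardized mean difference, percent)
#'
#' The Rosenbaum-Rubin form: `100 (mean_T - mean_C) / sqrt((var_T + var_C)/2)`.
#' For binary covariates the variances should be the Bernoulli variances
#' `p (1 - p)`; [binary_variance()] is provided for this.
#'
#' @param mean_t,mean_c Group means (vectorized).
#' @param var_t,var_c Group variances.
#' @return Bias in percent.
#' @export
standardized_bias <- function(mean_t, mean_c, var_t, var_c) {
  if (any(var_t < 0 | var_c < 0)) ipw_stop("variances must be non-negative")
  denom <- sqrt((var_t + var_c) / 2)
  zero <- denom == 0
  if (any(zero & mean_t != mean_c))
    ipw_stop("both variances zero with unequal means: bias undefined")
  out <- numeric(length(denom))
  out[!zero] <- 100 * (mean_t[!zero] - mean_c[!zero]) / denom[!zero]
  out
}

#' @rdname standardized_bias
#' @param p Proportion of a binary covariate.
#' @export
binary_variance <- function(p) p * (1 - p)

#' Two-sample t statistic from group summaries
#'
#' Welch (unpooled, default) or pooled-variance t statistic for a difference
#' in group means, computed from summary statistics. For a binary covariate
#' pass the Bernoulli sample variance `p(1-p) n/(n-1)`.
#'
#' @param mean_t,mean_c Group means.
#' @param var_t,var_c Group sample variances.
#' @param n_t,n_c Group sizes (effective sizes for weighted samples).
#' @param variance `"welch"` or `"pooled"`.
#' @return t statistic.
#' @export
two_sample_t <- function(mean_t, mean_c, var_t, var_c, n_t, n_c,
                         variance = c("welch", "pooled")) {
  variance <- match.arg(variance)
  se <- if (variance == "welch") sqrt(var_t / n_t + var_c / n_c)
        else {
          sp <- ((n_t - 1) * var_t + (n_c - 1) * var_c) / (n_t + n_c - 2)
          sqrt(sp * (1 / n_t + 1 / n_c))
        }
  (mean_t - mean_c) / se
}

#' Covariate balance report before and after matching/weighting
#'
#' For every covariate: raw and weighted means by arm, standardized bias
#' before and after (both computed against the unmatched group variances,
#' the usual convention for matching diagnostics), and two-sample
#' t-statistics (Welch by default). Overall: mean absolute standardized
#' bias, and a probit re-fit of treatment on the covariates in the weighted
#' sample giving the post-matching pseudo-R-squared and the likelihood-ratio
#' test of joint covariate significance.
#'
#' @param X Matrix/data frame of baseline covariates (one row per
#'   household, already transformed as used in the propensity model).
#' @param treated 0/1 flags.
#' @param weights Per-household weights from a [match_households()] result
#'   (`$weights$weight` aligned by id) or IPW weights; `NULL` compares raw
#'   samples only.
#' @param binary Optional logical vector flagging binary covariates; default
#'   auto-detected (values in {0,1}).
#' @param t_variance `"welch"` (default) or `"pooled"`.
#' @return Object of class `"balance_report"` with elements `covariates`
#'   (per-covariate table) and `summary`.
#' @export
balance_report <- function(X, treated, weights = NULL, binary = NULL,
                           t_variance = c("welch", "pooled")) {
  t_variance <- match.arg(t_variance)
  X <- as.matrix(X)
  treated <- as.integer(treated)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (length(weights) != nrow(X))
    ipw_stop("weights must align with rows of X")
  if (sum(weights[treated == 1]) == 0 || sum(weights[treated == 0]) == 0)
    ipw_stop("empty matched sample in one arm")
  binary <- binary %||% apply(X, 2, function(v) all(v %in% c(0, 1)))
  ti <- treated == 1; ci <- !ti

  per_cov <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    m_t <- mean(x[ti]); m_c <- mean(x[ci])
    v_t <- if (binary[j]) binary_variance(m_t) else var(x[ti])
    v_c <- if (binary[j]) binary_variance(m_c) else var(x[ci])
    wm_t <- wmean(x[ti], weights[ti]); wm_c <- wmean(x[ci], weights[ci])
    bias_before <- standardized_bias(m_t, m_c, v_t, v_c)
    # post-matching bias uses the unmatched variances in the denominator
    bias_after <- standardized_bias(wm_t, wm_c, v_t, v_c)
    sv_t <- var(x[ti]); sv_c <- var(x[ci])
    t_before <- two_sample_t(m_t, m_c, sv_t, sv_c, sum(ti), sum(ci),
                             variance = t_variance)
    wv_t <- wvar(x[ti], weights[ti]); wv_c <- wvar(x[ci], weights[ci])
    t_after <- two_sample_t(wm_t, wm_c, wv_t, wv_c,
                            n_eff(weights[ti]), n_eff(weights[ci]),
                            variance = t_variance)
    data.frame(covariate = colnames(X)[j],
               mean_t = m_t, mean_c = m_c,
               wmean_t = wm_t, wmean_c = wm_c,
               bias_before = bias_before, bias_after = bias_after,
               t_before = t_before, t_after = t_after)
  })
  per_cov <- do.call(rbind, per_cov)

  refit <- function(w) {
    Xd <- cbind(`(Intercept)` = 1, X)
    fit <- probit_mle(Xd, treated, weights = w)
    lr <- 2 * (fit$loglik - fit$loglik_null)
    list(pseudo_r2 = fit$pseudo_r2, lr = lr,
         p = pchisq(lr, df = ncol(X), lower.tail = FALSE))
  }
  before <- refit(rep(1, nrow(X)))
  after <- refit(weights)
  summary <- data.frame(
    sample = c("unmatched", "matched"),
    mean_abs_bias = c(mean(abs(per_cov$bias_before)),
                      mean(abs(per_cov$bias_after))),
    pseudo_r2 = c(before$pseudo_r2, after$pseudo_r2),
    lr_chi2 = c(before$lr, after$lr),
    lr_p = c(before$p, after$p),
    n_treated = c(sum(ti), round(n_eff(weights[ti]), 1)),
    n_control = c(sum(ci), round(n_eff(weights[ci]), 1)))
  structure(list(covariates = per_cov, summary = summary,
                 t_variance = t_variance),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report>\n")
  print(x$covariates, digits = 3, row.names = FALSE)
  cat("\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
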