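# Participation (selection) model: probit maximum likelihood with robust
# covariance, average marginal effects, and common-support trimming of the
# estimated propensity scores.

probit_loglik <- function(beta, X, y, w) {
  xb <- drop(X %*% beta)
  sum(w * (y * pnorm(xb, log.p = TRUE) + (1 - y) * pnorm(-xb, log.p = TRUE)))
}

# per-observation score factor lambda_i such that gradient = X' (w * lambda)
probit_lambda <- function(xb, y) {
  p <- pmin(pmax(pnorm(xb), 1e-12), 1 - 1e-12)
  dnorm(xb) * (y - p) / (p * (1 - p))
}

#' Probit maximum likelihood on a design matrix
#'
#' Fisher scoring with analytic gradient and expected information, zero
#' starting values, and a hard convergence contract: the gradient max-norm
#' must reach `tol` (default 1e-6) or the fit fails with an explicit
#' non-convergence error. Runaway coefficients trigger a perfect-separation
#' error naming the suspect column.
#'
#' @param X Design matrix including an intercept column.
#' @param y 0/1 response.
#' @param weights Optional non-negative case weights (used by the balance
#'   diagnostics to re-fit on weighted matched samples).
#' @param tol Gradient max-norm tolerance.
#' @param max_iter Iteration cap.
#' @return List with `coefficients`, `vcov` (robust sandwich), `se`,
#'   `fitted` (probabilities), `loglik`, `loglik_null`, `pseudo_r2`
#'   (McFadden), `iterations`.
#' @export
probit_mle <- function(X, y, weights = NULL, tol = 1e-6, max_iter = 100L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) ipw_stop("response must be 0/1")
  w <- weights %||% rep(1, length(y))
  if (any(w < 0)) ipw_stop("case weights must be non-negative")
  keep <- w > 0
  X <- X[keep, , drop = FALSE]; y <- y[keep]; w <- w[keep]
  k <- ncol(X)
  slope_cols <- setdiff(seq_len(k), which(colnames(X) == "(Intercept)"))
  for (j in slope_cols) {
    if (var(X[, j]) == 0)
      ipw_stop("covariate constant in sample: ", colnames(X)[j])
  }
  beta <- rep(0, k)
  ll <- probit_loglik(beta, X, y, w)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    xb <- drop(X %*% beta)
    lam <- probit_lambda(xb, y)
    grad <- drop(crossprod(X, w * lam))
    if (max(abs(grad)) <= tol) break
    p <- pmin(pmax(pnorm(xb), 1e-12), 1 - 1e-12)
    fisher_w <- w * dnorm(xb)^2 / (p * (1 - p))
    info <- crossprod(X * sqrt(fisher_w))
    step <- tryCatch(solve(info, grad), error = function(e)
      ipw_stop("singular information matrix in probit fit"))
    # step halving to guarantee likelihood ascent
    s <- 1
    repeat {
      cand <- beta + s * step
      llc <- probit_loglik(cand, X, y, w)
      if (llc >= ll - 1e-10 || s < 1e-6) break
      s <- s / 2
    }
    beta <- cand; ll <- llc
    trace <- c(trace, ll)
    if (length(slope_cols) && max(abs(beta[slope_cols])) > 30) {
      sdx <- apply(X[, slope_cols, drop = FALSE], 2, sd)
      worst <- slope_cols[which.max(abs(beta[slope_cols]) * sdx)]
      ipw_stop("perfect separation suspected on covariate: ",
               colnames(X)[worst], class = "ipwdid_separation")
    }
    if (it == max_iter) {
      xb <- drop(X %*% beta)
      grad <- drop(crossprod(X, w * probit_lambda(xb, y)))
      if (max(abs(grad)) > tol)
        ipw_stop("probit did not converge in ", max_iter,
                 " iterations; gradient max-norm ",
                 format(max(abs(grad))), "; log-likelihood trace: ",
                 paste(format(utils::tail(trace, 5)), collapse = " -> "))
    }
  }
  xb <- drop(X %*% beta)
  p <- pnorm(xb)
  # a gradient that vanishes while every observation is classified with
  # near-certainty is the signature of perfect separation (the true MLE is
  # at infinity); name the dominant covariate
  if (length(slope_cols) && all(y == (p > 0.5)) && min(abs(xb)) > 3) {
    sdx <- apply(X[, slope_cols, drop = FALSE], 2, sd)
    worst <- slope_cols[which.max(abs(beta[slope_cols]) * sdx)]
    ipw_stop("perfect separation suspected on covariate: ",
             colnames(X)[worst], class = "ipwdid_separation")
  }
  lam <- probit_lambda(xb, y)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  fisher_w <- w * dnorm(xb)^2 / (pc * (1 - pc))
  A <- crossprod(X * sqrt(fisher_w))
  scores <- X * (w * lam)
  B <- crossprod(scores)
  Ainv <- solve(A)
  vcov <- Ainv %*% B %*% Ainv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  pbar <- wmean(y, w)
  ll0 <- sum(w * (y * log(pbar) + (1 - y) * log(1 - pbar)))
  list(coefficients = setNames(drop(beta), colnames(X)),
       vcov = vcov, se = sqrt(diag(vcov)),
       fitted = p, linear_predictor = xb,
       loglik = ll, loglik_null = ll0,
       pseudo_r2 = 1 - ll / ll0, iterations = it,
       weights = w, X = X, y = y)
}

#' Fit the participation probit on a panel's baseline covariates
#'
#' Regresses the treatment indicator on the baseline (pre-treatment)
#' covariates by probit maximum likelihood and returns propensity scores
#' `p = Phi(z'beta)`, a robust coefficient table, average marginal effects
#' and fit diagnostics. Scale covariates are log-transformed per
#' `transforms` before fitting (natural log of age and asset value by
#' default, matching the conventional specification).
#'
#' @param panel A `"household_panel"`.
#' @param covariates Covariate names to use (default: all panel covariates).
#' @param transforms Named character vector of `"log"` transforms (see
#'   [selection_design()]).
#' @param clamp Scores are defensively clamped to `[clamp, 1 - clamp]`
#'   before any inverse weighting; clamped households are counted in
#'   `n_clamped`.
#' @return Object of class `"propensity_fit"`.
#' @export
fit_probit <- function(panel, covariates = NULL,
                       transforms = c(age = "log", assets_usd = "log"),
                       clamp = 1e-6) {
  stopifnot(inherits(panel, "household_panel"))
  base <- panel_wave(panel, 0)
  covariates <- covariates %||% panel$covariates$name
  missing <- setdiff(covariates, names(base))
  if (length(missing))
    ipw_stop("covariates not in panel: ", paste(missing, collapse = ", "))
  Z <- selection_design(base[, covariates, drop = FALSE],
                        transforms[names(transforms) %in% covariates])
  X <- cbind(`(Intercept)` = 1, Z)
  fit <- probit_mle(X, base$treated)
  p_raw <- fit$fitted
  p <- pmin(pmax(p_raw, clamp), 1 - clamp)
  table <- data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    robust_se = unname(fit$se))
  table$z <- table$estimate / table$robust_se
  table$p_value <- 2 * pnorm(-abs(table$z))
  out <- structure(list(
    coefficients = fit$coefficients,
    vcov = fit$vcov,
    table = table,
    scores = setNames(p, base$household_id),
    household_id = base$household_id,
    treated = base$treated,
    design = X,
    loglik = fit$loglik, loglik_null = fit$loglik_null,
    pseudo_r2 = fit$pseudo_r2, iterations = fit$iterations,
    n = nrow(base), n_clamped = sum(p != p_raw),
    transforms = transforms, covariate_names = colnames(Z)
  ), class = "propensity_fit")
  out$ame <- marginal_effects(out)
  out
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> probit, n =", x$n, "\n")
  tab <- merge(x$table, x$ame, by = "term", all.x = TRUE, sort = FALSE)
  print(tab, digits = 3, row.names = FALSE)
  cat(sprintf("log-likelihood %.3f (null %.3f), McFadden pseudo-R2 %.4f\n",
              x$loglik, x$loglik_null, x$pseudo_r2))
  invisible(x)
}

#' Average marginal effects of a fitted participation probit
#'
#' `method = "derivative"` (default) reports the sample mean of
#' `phi(z'beta) * beta_k` for every covariate, binary included — so the
#' ratio AME/coefficient is the mean density, identical across covariates.
#' `method = "discrete"` reports the average discrete change
#' `Phi(z'beta | x = 1) - Phi(z'beta | x = 0)` for binary covariates.
#'
#' @param fit A `"propensity_fit"`.
#' @param method `"derivative"` or `"discrete"`.
#' @return Data frame with columns `term` and `ame`.
#' @export
marginal_effects <- function(fit, method = c("derivative", "discrete")) {
  method <- match.arg(method)
  X <- fit$design
  beta <- fit$coefficients
  xb <- drop(X %*% beta)
  mean_dens <- mean(dnorm(xb))
  terms <- setdiff(names(beta), "(Intercept)")
  ame <- mean_dens * beta[terms]
  if (method == "discrete") {
    for (tm in terms) {
      v <- X[, tm]
      if (all(v %in% c(0, 1))) {
        X1 <- X; X1[, tm] <- 1
        X0 <- X; X0[, tm] <- 0
        ame[tm] <- mean(pnorm(drop(X1 %*% beta)) - pnorm(drop(X0 %*% beta)))
      }
    }
  }
  data.frame(term = terms, ame = unname(ame))
}

#' Common-support region of the propensity scores
#'
#' `convention = "intersection"` (default) keeps scores inside
#' `[max(min_T, min_C), min(max_T, max_C)]` and trims both arms.
#' `convention = "treated_preserving"` trims only controls lying outside the
#' treated score range, so no treated observation is lost.
#'
#' @param scores Propensity scores.
#' @param treated 0/1 treatment flags aligned with `scores`.
#' @param convention Trimming convention.
#' @return Object of class `"common_support"`: list with `lo`, `hi`, `keep`
#'   (logical per observation), and trim counts per arm.
#' @export
common_support <- function(scores, treated,
                           convention = c("intersection",
                                          "treated_preserving")) {
  convention <- match.arg(convention)
  treated <- as.logical(treated)
  if (!any(treated) || !any(!treated))
    ipw_stop("both arms must be non-empty")
  pt <- scores[treated]; pc <- scores[!treated]
  if (convention == "intersection") {
    lo <- max(min(pt), min(pc)); hi <- min(max(pt), max(pc))
    if (lo > hi) ipw_stop("disjoint propensity-score supports")
    keep <- scores >= lo & scores <= hi
  } else {
    lo <- min(pt); hi <- max(pt)
    if (max(pc) < lo || min(pc) > hi)
      ipw_stop("disjoint propensity-score supports")
    keep <- treated | (scores >= lo & scores <= hi)
  }
  structure(list(lo = lo, hi = hi, keep = keep,
                 convention = convention,
                 n_trimmed_treated = sum(!keep & treated),
                 n_trimmed_control = sum(!keep & !treated)),
            class = "common_support")
}

#' @export
print.common_support <- function(x, ...) {
  cat(sprintf("<common_support> [%.4f, %.4f] (%s); trimmed %d treated, %d control\n",
              x$lo, x$hi, x$convention,
              x$n_trimmed_treated, x$n_trimmed_control))
  invisible(x)
}
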