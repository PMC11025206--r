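#' Control parameters for Gaussian-mixture fitting
#'
#' @param mode `"map"` for MAP-EM under weak conjugate priors (a Dirichlet
#'   prior on the weights and a Normal-Inverse-Gamma prior on each
#'   component's mean and variance, centred on the sample moments) or
#'   `"ml"` for plain maximum-likelihood EM.  The default priors are weak
#'   enough that MAP estimates track the ML solution while keeping the
#'   M-step closed form and the fit away from degenerate solutions.
#' @param tol Convergence tolerance on the relative change of the
#'   objective (log-likelihood or log-posterior) between iterations.
#' @param max_iter Maximum EM iterations.
#' @param init `"quantile"` places initial component means at the
#'   (2i-1)/(2k) sample quantiles (deterministic); `"random"` draws k
#'   distinct observations as initial means (use `seed`).
#' @param seed RNG seed, used only by random initialization.
#' @param var_floor_frac Variance floor as a fraction of the sample
#'   variance; component variances are clamped to this floor.
#' @param dirichlet_alpha Dirichlet concentration for the weight prior
#'   (MAP mode); must be > 1 for a proper MAP weight update.
#' @param kappa0 Prior pseudo-count tying each component mean to the
#'   sample mean (MAP mode).
#' @param a0,b0_frac Inverse-Gamma shape and scale (the latter as a
#'   fraction of the sample variance) for the variance prior (MAP mode).
#' @return A list of class `gmm_control`.
#' @export
gmm_control <- function(mode = c("map", "ml"), tol = 1e-6, max_iter = 500L,
                        init = c("quantile", "random"), seed = NULL,
                        var_floor_frac = 1e-6, dirichlet_alpha = 1 + 1e-3,
                        kappa0 = 1e-3, a0 = 1 + 1e-3, b0_frac = 1e-3) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  if (tol <= 0 || max_iter < 1L)
    stop("`tol` must be > 0 and `max_iter` >= 1", call. = FALSE)
  if (mode == "map" && dirichlet_alpha <= 1)
    stop("`dirichlet_alpha` must exceed 1 in MAP mode", call. = FALSE)
  structure(list(mode = mode, tol = tol, max_iter = as.integer(max_iter),
                 init = init, seed = seed, var_floor_frac = var_floor_frac,
                 dirichlet_alpha = dirichlet_alpha, kappa0 = kappa0,
                 a0 = a0, b0_frac = b0_frac),
            class = "gmm_control")
}

# log density of the mixture per observation x component, n x k
gmm_log_comp <- function(x, w, mu, s2) {
  k <- length(w)
  lp <- matrix(0, length(x), k)
  for (j in seq_len(k))
    lp[, j] <- log(w[j]) + dnorm(x, mu[j], sqrt(s2[j]), log = TRUE)
  lp
}

row_log_sum_exp <- function(lp) {
  m <- apply(lp, 1L, max)
  m + log(rowSums(exp(lp - m)))
}

# log prior for the MAP objective (Dirichlet on weights, NIG on mean/var)
gmm_log_prior <- function(w, mu, s2, m0, kappa0, a0, b0, alpha) {
  k <- length(w)
  ldir <- lgamma(k * alpha) - k * lgamma(alpha) + (alpha - 1) * sum(log(w))
  lnig <- sum(dnorm(mu, m0, sqrt(s2 / kappa0), log = TRUE) +
                a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(s2) - b0 / s2)
  ldir + lnig
}

#' Fit a univariate Gaussian mixture by EM or MAP-EM
#'
#' Expectation-maximization for a k-component univariate Gaussian mixture
#' on a vector of intensities, either maximum likelihood (`mode = "ml"`)
#' or maximum a posteriori under weak conjugate priors (`mode = "map"`,
#' the default), with closed-form M-steps in both modes.  Iteration stops
#' when the relative change of the objective falls below `tol` or after
#' `max_iter` iterations.  With the default deterministic quantile
#' initialization the fit is fully reproducible.
#'
#' The objective trace (log-likelihood, or log-posterior in MAP mode) is
#' recorded per iteration; EM theory guarantees it is non-decreasing,
#' except in rare degenerate samples where the variance floor engages
#' (flagged by `variance_floored`).
#'
#' @param values Numeric vector of observations (finite, length >= 10 k).
#' @param k Number of mixture components.
#' @param control A [gmm_control()].
#' @return An object of class `gmm_fit`: `k`, `weights`, `means`,
#'   `variances`, `responsibilities` (n x k), `log_objective_trace`,
#'   `converged`, `n_iter`, `variance_floored`, `mode`, `seed`.
#' @export
#' @examples
#' x <- c(rnorm(200, 0), rnorm(200, 10))
#' fit <- fit_gmm(x, 2)
#' sort(fit$means)
fit_gmm <- function(values, k, control = gmm_control()) {
  values <- as.numeric(values)
  k <- as.integer(k)
  n <- length(values)
  if (any(!is.finite(values)))
    stop("gmm fit error: non-finite values in sample", call. = FALSE)
  if (n < 10L * k)
    stop("gmm fit error: need at least ", 10L * k,
         " observations for k = ", k, " (got ", n, ")", call. = FALSE)
  s2_all <- var(values)
  if (!is.finite(s2_all) || s2_all <= 1e-12 * max(1, mean(values)^2))
    stop("gmm fit error: sample variance is (near) zero; ",
         "mixture components cannot be resolved", call. = FALSE)
  floor_s2 <- control$var_floor_frac * s2_all
  m0 <- mean(values)
  b0 <- control$b0_frac * s2_all

  mu <- switch(control$init,
    quantile = as.numeric(quantile(values, probs = (2 * seq_len(k) - 1) /
                                     (2 * k), names = FALSE, type = 7)),
    random = with_seed(control$seed,
                       sample(values, k, replace = FALSE)))
  # separate coincident initial means so components can differentiate
  if (anyDuplicated(mu))
    mu <- mu + (seq_len(k) - (k + 1) / 2) * 1e-6 * sqrt(s2_all)
  s2 <- rep(s2_all, k)
  w <- rep(1 / k, k)

  trace <- numeric(0)
  converged <- FALSE
  floored <- FALSE
  resp <- NULL
  obj_prev <- -Inf
  for (it in seq_len(control$max_iter)) {
    lp <- gmm_log_comp(values, w, mu, s2)
    lse <- row_log_sum_exp(lp)
    resp <- exp(lp - lse)
    obj <- sum(lse)
    if (control$mode == "map")
      obj <- obj + gmm_log_prior(w, mu, s2, m0, control$kappa0,
                                 control$a0, b0, control$dirichlet_alpha)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        abs(obj - obj_prev) < control$tol * (abs(obj_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj

    nk <- colSums(resp)
    xbar <- colSums(resp * values) / nk
    ss <- colSums(resp * outer(values, xbar, "-")^2)
    if (control$mode == "ml") {
      w <- nk / n
      mu <- xbar
      s2 <- ss / nk
    } else {
      a <- control$dirichlet_alpha
      w <- (nk + a - 1) / (n + k * (a - 1))
      kap <- control$kappa0
      mu <- (nk * xbar + kap * m0) / (nk + kap)
      s2 <- (2 * b0 + ss + kap * nk / (kap + nk) * (xbar - m0)^2) /
        (nk + 2 * control$a0 + 3)
    }
    if (any(s2 < floor_s2)) {
      floored <- TRUE
      s2 <- pmax(s2, floor_s2)
    }
  }

  structure(list(k = k, weights = w, means = mu, variances = s2,
                 responsibilities = resp, log_objective_trace = trace,
                 converged = converged, n_iter = length(trace),
                 variance_floored = floored, mode = control$mode,
                 seed = control$seed),
            class = "gmm_fit")
}

#' Hard-assign observations to mixture components
#'
#' Each observation goes to its maximum-responsibility component.  Exact
#' responsibility ties are broken toward the component with the larger
#' mean, then toward the lower component index; assignment therefore
#' depends only on the fitted parameters, not on component ordering.
#'
#' @param fit A [fit_gmm()] result.
#' @return Integer vector of component indices, one per observation.
#' @export
gmm_assign <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  r <- fit$responsibilities
  # rank components so that ties resolve to larger mean, then lower index
  pref <- order(-fit$means, seq_len(fit$k))
  r_pref <- r[, pref, drop = FALSE]
  apply(r_pref, 1L, which.max) -> best
  pref[best]
}

# index of the component with the largest mean; ties by larger variance,
# then lower index
select_high_component <- function(means, variances) {
  ord <- order(-means, -variances, seq_along(means))
  ord[1L]
}

# permute component labels of a fit (used to verify relabeling invariance)
permute_components <- function(fit, perm) {
  stopifnot(inherits(fit, "gmm_fit"), length(perm) == fit$k)
  fit$weights <- fit$weights[perm]
  fit$means <- fit$means[perm]
  fit$variances <- fit$variances[perm]
  fit$responsibilities <- fit$responsibilities[, perm, drop = FALSE]
  fit
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit> k = ", x$k, " (", x$mode, "), ",
      x$n_iter, " iterations, ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  ord <- order(x$means)
  for (j in ord)
    cat(sprintf("  comp %d: weight %.3f  mean %.3f  sd %.3f\n",
                j, x$weights[j], x$means[j], sqrt(x$variances[j])))
  invisible(x)
}
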