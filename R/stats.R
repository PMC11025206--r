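#' Covariate-adjusted general linear model group comparison
#'
#' Least-squares fit of an outcome on a group factor plus nuisance
#' covariates (by default age, sex and total intracranial volume, the
#' standard adjustment set for head-size-dependent brain volumes).  The
#' omnibus group effect is tested by comparing the full model against the
#' covariate-only model (partial F test); all pairwise group contrasts
#' are then tested on the full model and corrected for family-wise error
#' across the pairwise family (Bonferroni by default, Holm optional).
#' Sex is coded 0/1 (F/M) in the design matrix.
#'
#' @param cohort Data frame with a `group` column (factor or character)
#'   and the outcome/covariate columns.  Rows with missing values in any
#'   used column are dropped (complete-case analysis).
#' @param outcome Name of the outcome column (default `"cp_volume"`).
#' @param covariates Character vector of covariate column names.
#' @param fwe `"bonferroni"` or `"holm"`.
#' @return An object of class `glm_group_result`: `coefficients`,
#'   `omnibus` (F, df1, df2, p), `contrasts` (data frame of pairwise
#'   differences with raw and FWE-adjusted p), `n`, `fwe`.
#' @export
glm_group_comparison <- function(cohort, outcome = "cp_volume",
                                 covariates = c("age", "sex", "tiv"),
                                 fwe = c("bonferroni", "holm")) {
  fwe <- match.arg(fwe)
  cols <- c("group", outcome, covariates)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- cohort[cols]
  if ("sex" %in% covariates && !is.numeric(d$sex))
    d$sex <- as.numeric(d$sex %in% c("M", "male", "Male", "1"))
  d <- d[complete.cases(d), , drop = FALSE]
  d$group <- droplevels(factor(d$group))
  g <- levels(d$group)
  if (length(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- nrow(d)
  p_full <- length(g) + length(covariates)
  if (n <= p_full)
    stop("fewer subjects (", n, ") than model parameters (", p_full, ")",
         call. = FALSE)

  rhs <- paste(c("group", covariates), collapse = " + ")
  f_full <- stats::as.formula(paste(outcome, "~", rhs))
  f_null <- stats::as.formula(paste(
    outcome, "~", if (length(covariates))
      paste(covariates, collapse = " + ") else "1"))
  fit_full <- lm(f_full, data = d)
  X <- model.matrix(fit_full)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  fit_null <- lm(f_null, data = d)

  rss1 <- sum(resid(fit_full)^2)
  rss0 <- sum(resid(fit_null)^2)
  df1 <- length(g) - 1L
  df2 <- n - ncol(X)
  # an (effectively) exact fit of the covariate-only model means the
  # outcome carries no group information: F = 0 rather than 0/0 noise
  scale2 <- max(1, mean(d[[outcome]]^2)) * n
  exact <- rss1 <= .Machine$double.eps^0.75 * scale2
  F_stat <- if (exact) {
    if (rss0 - rss1 <= .Machine$double.eps^0.75 * scale2) 0 else Inf
  } else ((rss0 - rss1) / df1) / (rss1 / df2)
  p_omni <- pf(F_stat, df1, df2, lower.tail = FALSE)
  exact_null <- exact && F_stat == 0

  # pairwise contrasts on the full model via the coefficient covariance
  beta <- coef(fit_full)
  V <- suppressWarnings(vcov(fit_full))
  dummy <- function(lev) if (lev == g[1]) NULL else paste0("group", lev)
  pairs <- utils::combn(g, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    cvec <- setNames(numeric(length(beta)), names(beta))
    d1 <- dummy(pr[1]); d2 <- dummy(pr[2])
    if (!is.null(d1)) cvec[d1] <- 1
    if (!is.null(d2)) cvec[d2] <- -1
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tt <- if (se > 0 && !exact_null) est / se else 0
    data.frame(contrast = paste(pr[1], "-", pr[2]), estimate = est,
               se = se, t = tt, df = df2,
               p = 2 * pt(abs(tt), df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  contrasts <- do.call(rbind, rows)
  contrasts$p_fwe <- p.adjust(contrasts$p, method = fwe)

  structure(list(coefficients = beta,
                 omnibus = list(F = F_stat, df1 = df1, df2 = df2,
                                p = p_omni),
                 contrasts = contrasts, n = n, groups = g, fwe = fwe,
                 model = fit_full),
            class = "glm_group_result")
}

#' @export
print.glm_group_result <- function(x, ...) {
  cat("<glm_group_result> n =", x$n, " groups:",
      paste(x$groups, collapse = ", "), "\n")
  cat(sprintf("  omnibus F(%d, %d) = %.3f, p = %.3g\n", x$omnibus$df1,
              x$omnibus$df2, x$omnibus$F, x$omnibus$p))
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation between the least-squares residuals of `x` and `y`
#' after regressing each on the covariates plus an intercept; the p-value
#' comes from `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k`
#' covariates, two-sided.  Rows with any missing value are dropped.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix or data frame of covariates (may have
#'   zero columns for a plain Pearson correlation).
#' @return An object of class `partial_corr_result`: `r`, `df`, `p`, `n`,
#'   `covariates` (names).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) covariates <- matrix(numeric(0), length(x), 0)
  Z <- as.matrix(as.data.frame(covariates))
  if (is.character(Z)) stop("covariates must be numeric", call. = FALSE)
  storage.mode(Z) <- "double"
  ok <- is.finite(x) & is.finite(y) &
    (if (ncol(Z)) rowSums(!is.finite(Z)) == 0 else TRUE)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n <= k + 3L)
    stop("need n > number of covariates + 3 (got n = ", n, ", k = ", k,
         ")", call. = FALSE)
  M <- cbind(1, Z)
  rx <- resid(stats::lm.fit(M, x))
  ry <- resid(stats::lm.fit(M, y))
  if (sd(rx) <= 1e-10 * max(1, sqrt(mean(x^2))) ||
      sd(ry) <= 1e-10 * max(1, sqrt(mean(y^2))))
    stop("zero-variance residuals after covariate adjustment",
         call. = FALSE)
  r <- cor(rx, ry)
  df <- n - 2L - k
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  structure(list(r = r, df = df, p = p, n = n,
                 covariates = colnames(Z)),
            class = "partial_corr_result")
}

#' @export
print.partial_corr_result <- function(x, ...) {
  cat(sprintf("partial r = %.3f (df = %d, p = %.3g, n = %d)\n",
              x$r, x$df, x$p, x$n))
  invisible(x)
}

check_summaries <- function(n, mean, sd) {
  if (length(n) != length(mean) || length(n) != length(sd))
    stop("summary vectors must have equal length", call. = FALSE)
  if (any(n < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd < 0))
    stop("invalid group summaries", call. = FALSE)
}

#' One-way ANOVA from per-group summary statistics
#'
#' Reconstructs the one-way ANOVA F statistic from (n, mean, sd) per
#' group, the form published in cohort tables: between-group sum of
#' squares from the group means about the grand mean, within-group sum of
#' squares as `sum((n_i - 1) * sd_i^2)`.  Identical to raw-data ANOVA
#' whenever raw data match the summaries exactly.
#'
#' @param n,mean,sd Numeric vectors, one entry per group (>= 2 groups).
#' @return List `F`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' anova_from_summary(n = c(12, 143, 105),
#'                    mean = c(3161.8, 2911.3, 2454.5),
#'                    sd = c(735.1, 735.1, 781.3))
anova_from_summary <- function(n, mean, sd) {
  check_summaries(n, mean, sd)
  if (length(n) < 2L) stop("need >= 2 groups", call. = FALSE)
  N <- sum(n)
  grand <- sum(n * mean) / N
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- length(n) - 1L
  df2 <- N - length(n)
  F_stat <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / df1) / (ssw / df2)
  list(F = F_stat, df1 = df1, df2 = df2,
       p = pf(F_stat, df1, df2, lower.tail = FALSE))
}

#' Two-sample t test from summary statistics
#'
#' Student's pooled-variance t (default) or Welch's t from per-group
#' (n, mean, sd).
#'
#' @param n1,mean1,sd1 Summaries for the first group.
#' @param n2,mean2,sd2 Summaries for the second group.
#' @param pooled `TRUE` for Student's pooled-variance test, `FALSE` for
#'   Welch.
#' @return List `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' ttest_from_summary(12, 38.1, 6.1, 143, 40.5, 3.4)
ttest_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                               pooled = TRUE) {
  check_summaries(c(n1, n2), c(mean1, mean2), c(sd1, sd2))
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tt <- if (se == 0) {
    if (mean1 == mean2) 0 else Inf * sign(mean1 - mean2)
  } else (mean1 - mean2) / se
  list(t = tt, df = df, p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson's chi-squared without continuity correction, as used for
#' categorical cohort-table comparisons (for instance sex by group).
#'
#' @param counts Numeric matrix of non-negative counts with positive row
#'   and column margins.
#' @return List `chisq`, `df`, `p`.
#' @export
#' @examples
#' chisq_contingency(rbind(c(9, 3), c(85, 58), c(55, 50)))
chisq_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has a zero margin", call. = FALSE)
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}
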