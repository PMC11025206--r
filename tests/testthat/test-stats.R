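test_that("albumin quotient and progression rate follow their formulas", {
  expect_equal(qalb(236, 40), 5.9)
  expect_equal(qalb(60, 60), 1)
  expect_error(qalb(0, 40), "positive")
  expect_error(qalb(200, -1), "positive")
  expect_equal(bpr(48, 10), 0)
  expect_equal(bpr(40.3, 13.6), (48 - 40.3) / 13.6)
  expect_equal(bpr(36, 12), 1)
  expect_error(bpr(36, 0), "positive")
  expect_error(bpr(50, 12), "\\[0, 48\\]")
})

test_that("group GLM handles constant outcomes and controls FWE", {
  set.seed(1)
  coh <- data.frame(group = rep(c("a", "b", "c"), each = 20),
                    cp_volume = 5,
                    age = rnorm(60, 50, 8), sex = rep(c("M", "F"), 30),
                    tiv = rnorm(60, 1.4e6, 1e5))
  res <- glm_group_comparison(coh)
  expect_equal(res$omnibus$F, 0)
  expect_equal(res$contrasts$p_fwe, rep(1, 3))
  # adjusted p never below raw p, never above 1
  coh$cp_volume <- rnorm(60, 100, 10) + 10 * (coh$group == "b")
  res2 <- glm_group_comparison(coh)
  expect_true(all(res2$contrasts$p_fwe >= res2$contrasts$p))
  expect_true(all(res2$contrasts$p_fwe <= 1))
  expect_equal(nrow(res2$contrasts), 3L)
  # Bonferroni on 3 contrasts is min(1, 3p); Holm is never larger
  expect_equal(res2$contrasts$p_fwe, pmin(1, 3 * res2$contrasts$p))
  holm <- glm_group_comparison(coh, fwe = "holm")
  expect_true(all(holm$contrasts$p_fwe <= res2$contrasts$p_fwe + 1e-12))
})

test_that("covariate-free two-group omnibus F equals the squared pooled t", {
  set.seed(2)
  coh <- data.frame(group = rep(c("a", "b"), c(14, 17)),
                    cp_volume = c(rnorm(14, 10, 2), rnorm(17, 12, 2)))
  res <- glm_group_comparison(coh, covariates = character(0))
  tt <- t.test(cp_volume ~ group, coh, var.equal = TRUE)
  expect_equal(res$omnibus$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$omnibus$p, tt$p.value, tolerance = 1e-10)
})

test_that("GLM rejects deficient designs", {
  coh <- data.frame(group = rep(c("a", "b"), each = 3),
                    cp_volume = rnorm(6), age = 50, sex = "M",
                    tiv = rnorm(6))
  # constant age and sex make the design rank deficient / overparameterized
  expect_error(glm_group_comparison(coh), "parameters|rank")
  expect_error(glm_group_comparison(data.frame(group = "a",
                                               cp_volume = 1)),
               "2 groups|columns")
})

test_that("partial correlation matches the one-covariate closed form", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 60
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + 0.4 * x + rnorm(n)
    res <- partial_correlation(x, y, data.frame(z = z))
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(res$r, closed, tolerance = 1e-10)
    expect_equal(res$df, n - 3L)
  }
})

test_that("partial correlation degenerates gracefully and correctly", {
  set.seed(4)
  x <- rnorm(50)
  expect_equal(partial_correlation(x, x, data.frame(z = rnorm(50)))$r, 1)
  expect_error(partial_correlation(x, rep(1, 50),
                                   data.frame(z = rnorm(50))),
               "zero-variance")
  # independent covariates at large n: partial r converges to plain r
  n <- 10000
  x <- rnorm(n); y <- 0.3 * x + rnorm(n)
  z <- matrix(rnorm(3 * n), n, 3)
  expect_lt(abs(partial_correlation(x, y, z)$r - cor(x, y)), 0.02)
})

test_that("summary-statistic tests agree with raw-data computations", {
  # raw data reconstructed to match the summaries exactly
  make_group <- function(n, m, s) {
    v <- scale(rnorm(n))[, 1]
    m + s * v
  }
  set.seed(5)
  gs <- list(list(n = 12, m = 3161.8, s = 735.1),
             list(n = 143, m = 2911.3, s = 735.1),
             list(n = 105, m = 2454.5, s = 781.3))
  raw <- lapply(gs, function(g) make_group(g$n, g$m, g$s))
  d <- data.frame(y = unlist(raw),
                  g = factor(rep(seq_along(gs), vapply(gs, `[[`,
                                                       numeric(1), "n"))))
  ref <- anova(lm(y ~ g, d))
  res <- anova_from_summary(vapply(gs, `[[`, numeric(1), "n"),
                            vapply(gs, `[[`, numeric(1), "m"),
                            vapply(gs, `[[`, numeric(1), "s"))
  expect_equal(res$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  # two-group summary ANOVA equals the squared pooled t
  res2 <- anova_from_summary(c(12, 143), c(38.1, 40.5), c(6.1, 3.4))
  tt <- ttest_from_summary(12, 38.1, 6.1, 143, 40.5, 3.4)
  expect_equal(res2$F, tt$t^2, tolerance = 1e-12)
  # identical means give F = 0
  expect_equal(anova_from_summary(c(10, 10), c(5, 5), c(1, 2))$F, 0)
})

test_that("summary t test agrees with t.test on reconstructed data", {
  set.seed(6)
  a <- 10 + 2 * scale(rnorm(20))[, 1]
  b <- 12 + 3 * scale(rnorm(25))[, 1]
  pooled <- ttest_from_summary(20, 10, 2, 25, 12, 3)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(pooled$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(pooled$p, ref$p.value, tolerance = 1e-10)
  welch <- ttest_from_summary(20, 10, 2, 25, 12, 3, pooled = FALSE)
  refw <- t.test(a, b)
  expect_equal(welch$t, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-10)
  expect_equal(ttest_from_summary(5, 3, 1, 8, 3, 2)$t, 0)
  expect_error(ttest_from_summary(1, 3, 1, 8, 3, 2), "n >= 2")
})

test_that("Pearson chi-squared matches hand computation", {
  expect_equal(chisq_contingency(rbind(c(10, 0), c(0, 10)))$chisq, 20)
  res <- chisq_contingency(rbind(c(9, 3), c(85, 58), c(55, 50)))
  expect_equal(res$df, 2L)
  # a table proportional to its margins has no association
  expect_equal(chisq_contingency(outer(c(2, 3), c(5, 10)))$chisq, 0)
  expect_error(chisq_contingency(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chisq_contingency(rbind(c(-1, 2), c(1, 2))),
               "non-negative")
})
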