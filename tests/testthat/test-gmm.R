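test_that("well-separated populations are recovered to the sample moments", {
  set.seed(7)
  x <- c(rnorm(500, 0, 1), rnorm(500, 100, 1))
  truth <- c(mean(x[1:500]), mean(x[501:1000]))
  for (mode in c("ml", "map")) {
    fit <- fit_gmm(x, 2, gmm_control(mode = mode))
    expect_true(fit$converged)
    expect_lt(max(abs(sort(fit$means) - sort(truth))), 0.2)
  }
})

test_that("degenerate and undersized samples raise fit errors", {
  expect_error(fit_gmm(rep(5, 100), 2), "variance")
  expect_error(fit_gmm(rnorm(19), 2), "at least 20")
  expect_error(fit_gmm(c(rnorm(50), NA), 2), "non-finite")
})

test_that("single-component ML objective equals the closed-form likelihood", {
  set.seed(3)
  y <- rnorm(100, 5, 2)
  fit <- fit_gmm(y, 1, gmm_control(mode = "ml", tol = 1e-12))
  s2_mle <- mean((y - mean(y))^2)
  ll <- sum(dnorm(y, mean(y), sqrt(s2_mle), log = TRUE))
  expect_equal(tail(fit$log_objective_trace, 1), ll, tolerance = 1e-8)
})

test_that("objective trace is non-decreasing in both modes", {
  for (s in 1:10) {
    set.seed(s)
    z <- c(rnorm(150, 0), rnorm(100, 3), rnorm(80, 7))
    for (mode in c("ml", "map")) {
      tr <- fit_gmm(z, 3, gmm_control(mode = mode))$log_objective_trace
      expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])),
                  info = paste("seed", s, mode))
    }
  }
})

test_that("weights and responsibilities are proper and fits deterministic", {
  set.seed(9)
  x <- c(rnorm(200, 0), rnorm(200, 4))
  fit <- fit_gmm(x, 2)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
  expect_equal(rowSums(fit$responsibilities), rep(1, length(x)),
               tolerance = 1e-10)
  floor_s2 <- 1e-6 * var(x)
  expect_true(all(fit$variances >= floor_s2 * (1 - 1e-12)))
  expect_identical(fit_gmm(x, 2), fit)  # quantile init is deterministic
})

test_that("ML fit matches an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(7)
  x <- c(rnorm(500, 0, 1), rnorm(500, 100, 1))
  fit <- fit_gmm(x, 2, gmm_control(mode = "ml", tol = 1e-10))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(unname(mc$parameters$mean)),
               tolerance = 1e-4)
  expect_equal(sort(fit$weights), sort(unname(mc$parameters$pro)),
               tolerance = 1e-4)
})

test_that("hard assignment prefers the higher mean on ties", {
  fit <- structure(list(
    k = 2L, weights = c(0.5, 0.5), means = c(10, 0), variances = c(1, 1),
    responsibilities = matrix(0.5, 3, 2)), class = "gmm_fit")
  expect_identical(gmm_assign(fit), rep(1L, 3))
  # equal means: larger variance wins, then lower index
  expect_identical(cpseg:::select_high_component(c(1, 1), c(1, 2)), 2L)
  expect_identical(cpseg:::select_high_component(c(1, 1), c(2, 2)), 1L)
  expect_identical(cpseg:::select_high_component(c(0, 5, 5), c(1, 3, 2)),
                   2L)
})
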