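signal_data <- function(n = 300, sd = 0.1, seed = 41) {
  withr::local_seed(seed, .local_envir = parent.frame())
  tibble::tibble(
    year = rep(2000:2009, length.out = n),
    a = stats::runif(n, 0, 10),
    b = stats::rnorm(n, 5, 2),
    c = stats::runif(n, -1, 1),
    ucu = 1 + 2 * a + 3 * b + stats::rnorm(n, 0, sd)
  )
}

test_that("subset enumeration covers all models and finds the true one", {
  d <- signal_data()
  ranking <- enumerate_ucu_models(d, c("a", "b", "c"))
  expect_identical(nrow(ranking), 8L) # 2^3 subsets incl. the null
  expect_true(all(c("a", "b") %in% attr(ranking, "best")))
  null_aic <- ranking$aic[ranking$formula == "ucu ~ 1"]
  expect_gt(null_aic - min(ranking$aic), 100)
  expect_true(all(diff(ranking$aic) >= 0))
})

test_that("the AIC ranking does not depend on covariate enumeration order", {
  d <- signal_data(seed = 42)
  r1 <- enumerate_ucu_models(d, c("a", "b", "c"))
  r2 <- enumerate_ucu_models(d, c("c", "b", "a"))
  expect_equal(sort(r1$aic), sort(r2$aic), tolerance = 1e-12)
  expect_setequal(attr(r1, "best"), attr(r2, "best"))
})

test_that("ordinary least squares matches the closed-form solution", {
  # exact line: slope recovered perfectly
  d0 <- tibble::tibble(year = 2000:2009, x = 1:10, ucu = 2 * (1:10))
  f0 <- fit_ucu_ols(d0, "x")
  expect_equal(unname(stats::coef(f0$fit)), c(0, 2), tolerance = 1e-12)
  expect_equal(suppressWarnings(glance(f0)$r_squared), 1,
               tolerance = 1e-12)

  # intercept-only returns the response mean
  fm <- fit_ucu_ols(d0, character(0))
  expect_equal(unname(stats::coef(fm$fit)), mean(d0$ucu))

  # random design vs normal equations
  withr::local_seed(43)
  d <- signal_data(n = 120, sd = 0.5)
  fit <- fit_ucu_ols(d, c("a", "b", "c"))
  X <- cbind(1, d$a, d$b, d$c)
  expect_equal(unname(stats::coef(fit$fit)), ols_oracle(X, d$ucu),
               tolerance = 1e-10)
})

test_that("collinear designs are refused with the offending column named", {
  d <- signal_data(n = 50, seed = 44)
  d$a2 <- 2 * d$a
  expect_error(fit_ucu_ols(d, c("a", "a2")), "a2")
})

test_that("bootstrap bias vanishes on noise-free data and is reproducible", {
  d0 <- tibble::tibble(year = rep(2000:2009, 5),
                       x = stats::runif(50, 0, 10))
  d0$ucu <- 1 + 0.5 * d0$x
  fit <- fit_ucu_ols(d0, "x")
  bt <- bootstrap_ucu(fit, B = 200, seed = 7)
  expect_true(all(abs(bt$coefficients$bias) < 1e-10))
  bt2 <- bootstrap_ucu(fit, B = 200, seed = 7)
  expect_identical(bt$coefficients, bt2$coefficients)
  bt3 <- bootstrap_ucu(fit, B = 200, seed = 8)
  expect_false(identical(bt$coefficients$std_error,
                         bt3$coefficients$std_error))
})

test_that("the bias-corrected estimate is 2b minus the bootstrap mean", {
  d <- signal_data(n = 150, sd = 1, seed = 45)
  bt <- bootstrap_ucu(fit_ucu_ols(d, c("a", "b")), B = 150, seed = 3)
  expect_equal(bt$coefficients$corrected,
               2 * bt$coefficients$estimate - colMeans(bt$boot_estimates),
               tolerance = 1e-12, ignore_attr = TRUE)
  # strong signal: slopes flagged at the strictest percentile level
  sig <- bt$coefficients$significance[bt$coefficients$term %in% c("a", "b")]
  expect_true(all(sig == "***"))
})

test_that("vessel-cluster resampling is available and reproducible", {
  d <- signal_data(n = 120, sd = 0.5, seed = 46)
  d$vessel_id <- rep(sprintf("V%02d", 1:12), each = 10)
  fit <- fit_ucu_ols(d, c("a", "b"))
  bt <- bootstrap_ucu(fit, B = 120, seed = 5, resample = "vessel")
  expect_identical(bt$resample, "vessel")
  expect_identical(
    bt$coefficients,
    bootstrap_ucu(fit, B = 120, seed = 5, resample = "vessel")$coefficients)
})

test_that("elasticities scale coefficients by relative average annual changes", {
  # deterministic two-covariate design with controlled annual trends:
  # mean annual change of x1 is 1, of x2 is 0.7, and the response
  # y = 0.5 + 0.3 x1 + 1.0 x2 exactly, so dy = 0.3 + 0.7 = 1 = dx1.
  years <- 2000:2009
  wiggle <- c(0, 0.3, -0.2, 0.4, -0.5, 0.2, 0.1, -0.3, 0.25, 0)
  x1 <- seq_along(years)               # diffs all 1
  x2 <- cumsum(c(2, rep(0.7, 9))) + wiggle
  d <- tibble::tibble(year = years, x1 = x1, x2 = x2,
                      ucu = 0.5 + 0.3 * x1 + 1.0 * x2)
  fit <- fit_ucu_ols(d, c("x1", "x2"))
  el <- ucu_elasticities(fit)
  expect_equal(el$dy, c(1, 1), tolerance = 1e-9)
  # dx/dy = 1 for x1, so its elasticity equals its coefficient
  e1 <- el[el$term == "x1", ]
  expect_equal(e1$elasticity, e1$b, tolerance = 1e-9)
  expect_equal(e1$elasticity, 0.3, tolerance = 1e-9)
  # general arithmetic for x2: E = b * dx / dy = 1 * 0.7 / 1
  mean_dx2 <- mean(diff(x2))
  e2 <- el[el$term == "x2", ]
  expect_equal(e2$elasticity, 1 * mean_dx2 / 1, tolerance = 1e-9)
  # endpoint mode replaces means of first differences by the endpoint slope
  el_end <- ucu_elasticities(fit, mode = "endpoint")
  end_dx2 <- (x2[10] - x2[1]) / 9
  expect_equal(el_end$elasticity[el_end$term == "x2"],
               end_dx2 / 1, tolerance = 1e-9)
})

test_that("a zero coefficient has zero elasticity", {
  years <- 2000:2009
  x1 <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  x2 <- seq_along(years)^1.5
  d <- tibble::tibble(year = years, x1 = x1, x2 = x2, ucu = x2)
  el <- ucu_elasticities(fit_ucu_ols(d, c("x1", "x2")))
  expect_equal(el$elasticity[el$term == "x1"], 0, tolerance = 1e-9)
})

test_that("a flat response makes elasticities undefined, not infinite", {
  d <- tibble::tibble(year = 2000:2009, x = (1:10)^1.3, ucu = 0.8)
  el <- ucu_elasticities(fit_ucu_ols(d, "x"))
  expect_false(el$defined)
  expect_true(is.na(el$elasticity))
})

test_that("residual diagnostics discriminate hetero- from homoskedastic errors", {
  run_bp <- function(het, n, seed) {
    withr::local_seed(seed)
    vapply(1:60, function(i) {
      x <- stats::runif(n, 0, 10)
      sd <- if (het) 0.2 + 0.4 * x else 1.5
      d <- tibble::tibble(year = rep(2000:2009, length.out = n), x = x,
                          ucu = 1 + x + stats::rnorm(n, 0, sd))
      ucu_diagnostics(fit_ucu_ols(d, "x"))$flag[2]
    }, logical(1))
  }
  expect_gte(mean(!run_bp(het = FALSE, n = 300, seed = 47)), 0.9)
  expect_gte(mean(run_bp(het = TRUE, n = 500, seed = 48)), 0.9)
})

test_that("white-noise residuals rarely trip the autocorrelation flag", {
  withr::local_seed(49)
  flags <- vapply(1:60, function(i) {
    d <- tibble::tibble(year = rep(2000:2009, 30),
                        x = stats::runif(300, 0, 10))
    d$ucu <- 1 + 0.2 * d$x + stats::rnorm(300, 0, 1)
    ucu_diagnostics(fit_ucu_ols(d, "x"))$flag[1]
  }, logical(1))
  expect_gte(mean(!flags), 0.9)
})

test_that("tidy and glance expose the usual model summaries", {
  d <- signal_data(n = 100, seed = 50)
  fit <- fit_ucu_ols(d, c("a", "b"))
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "a", "b"))
  gl <- glance(fit)
  expect_true(all(c("r_squared", "aic", "n") %in% names(gl)))
  expect_identical(gl$n, 100L)
  bt <- bootstrap_ucu(fit, B = 100, seed = 1)
  expect_identical(glance(bt)$B, 100)
  expect_setequal(names(tidy(bt)),
                  c("term", "estimate", "bias", "corrected", "std_error",
                    "conf_low", "conf_high", "significance"))
})
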