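#' Exhaustive subset model selection by AIC
#'
#' Fits every subset of the candidate covariates (including the
#' intercept-only null model) by ordinary least squares and ranks the
#' models by the Akaike Information Criterion, the standard screen for a
#' parsimonious model of capacity-utilisation scores. Ties in AIC are
#' broken in favour of fewer parameters; rank-deficient designs are
#' flagged and excluded from the ranking.
#'
#' @param data Tibble with the response and covariate columns (vessel-year
#'   rows; typically [dea_scores()] joined back to the panel covariates).
#' @param covariates Character vector of candidate covariate columns
#'   (at least 2).
#' @param response Response column name (default `"ucu"`).
#' @param top_k How many leading models to keep in the `"top"` attribute
#'   (default 5, the usual candidate-table size).
#' @return Tibble ranked by AIC: `formula`, `df` (estimated parameters,
#'   including the residual variance), `aic`, `delta_aic`. The best
#'   model's covariates are in attribute `"best"`.
#' @export
enumerate_ucu_models <- function(data, covariates, response = "ucu",
                                 top_k = 5) {
  stopifnot(length(covariates) >= 2)
  if (nrow(data) <= length(covariates) + 2)
    stop("too few rows (", nrow(data), ") to fit ",
         length(covariates), " covariates", call. = FALSE)
  subsets <- unlist(lapply(0:length(covariates), function(k) {
    utils::combn(covariates, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- purrr::map(subsets, function(vars) {
    fml <- if (length(vars)) stats::reformulate(vars, response)
           else stats::as.formula(paste(response, "~ 1"))
    fit <- stats::lm(fml, data = data)
    if (fit$rank < length(vars) + 1)
      return(tibble::tibble(formula = deparse1(fml), df = NA_integer_,
                            aic = NA_real_, rank_deficient = TRUE))
    tibble::tibble(formula = deparse1(fml),
                   df = length(vars) + 2L,  # coefficients + sigma
                   aic = stats::AIC(fit), rank_deficient = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  dropped <- out[out$rank_deficient, , drop = FALSE]
  out <- out[!out$rank_deficient, , drop = FALSE]
  out <- dplyr::arrange(out, .data$aic, .data$df)
  out$delta_aic <- out$aic - out$aic[1]
  out$rank_deficient <- NULL
  attr(out, "top") <- utils::head(out, top_k)
  attr(out, "dropped") <- dropped$formula
  attr(out, "best") <- all.vars(stats::as.formula(out$formula[1]))[-1]
  out
}

#' Fit an ordinary least squares model for capacity-utilisation scores
#'
#' Plain OLS of a score on covariates, the second-stage model of choice
#' for DEA efficiency scores. Returns a lightweight fitted object that
#' [bootstrap_ucu()], [ucu_elasticities()] and [ucu_diagnostics()] build
#' on; `tidy()` and `glance()` methods give the usual summaries.
#'
#' @inheritParams enumerate_ucu_models
#' @param covariates Covariate column names (may be empty for the null
#'   model).
#' @return A `ucu_fit` object wrapping the `lm` fit, the data and the
#'   model specification.
#' @export
fit_ucu_ols <- function(data, covariates, response = "ucu") {
  fml <- if (length(covariates)) stats::reformulate(covariates, response)
         else stats::as.formula(paste(response, "~ 1"))
  fit <- stats::lm(fml, data = data)
  if (fit$rank < length(covariates) + 1) {
    bad <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(fit = fit, data = data, response = response,
                 covariates = covariates),
            class = "ucu_fit")
}

#' @export
print.ucu_fit <- function(x, ...) {
  cat("OLS second-stage model:", deparse1(stats::formula(x$fit)), "\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @rdname fit_ucu_ols
#' @param x A `ucu_fit`.
#' @param ... Unused.
#' @export
tidy.ucu_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std_error = sm[, 2], statistic = sm[, 3],
                 p_value = sm[, 4])
}

#' @rdname fit_ucu_ols
#' @export
glance.ucu_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 sigma = sm$sigma,
                 aic = stats::AIC(x$fit),
                 df = length(stats::coef(x$fit)) + 1L,
                 n = stats::nobs(x$fit))
}

boot_stars <- function(lo_hi_fun) {
  # smallest two-sided percentile level at which 0 is excluded
  levels <- c(0.001, 0.01, 0.05, 0.1)
  stars <- c("***", "**", "*", ".")
  for (i in seq_along(levels)) {
    ci <- lo_hi_fun(levels[i])
    if (ci[1] > 0 || ci[2] < 0) return(stars[i])
  }
  ""
}

#' Bootstrap bias correction for a second-stage model
#'
#' Case-resampling bootstrap of the fitted OLS model: rows (or whole
#' vessels, for cluster resampling) are drawn with replacement `B` times
#' and the model refitted. Reported per covariate are the original
#' estimate, the bootstrap bias `mean(b*) - b`, the bias-corrected
#' estimate `2b - mean(b*)`, the bootstrap standard error, the percentile
#' confidence interval and a significance code from the smallest
#' two-sided percentile level excluding zero. Bootstrapping is the
#' standard guard when the residuals are heteroskedastic, as
#' efficiency-score regressions usually are. Deterministic given `seed`.
#'
#' @param fit A [fit_ucu_ols()] object.
#' @param B Number of bootstrap replicates (>= 100; 1000 in routine use).
#' @param seed Integer seed.
#' @param resample `"rows"` for vessel-year case resampling (default) or
#'   `"vessel"` to resample whole vessels (requires a `vessel_id` column).
#' @param ci_level Level of the reported percentile interval (default
#'   0.95).
#' @return A `ucu_boot` object; `tidy()` returns the coefficient table,
#'   `glance()` the model summary.
#' @export
bootstrap_ucu <- function(fit, B = 1000, seed = 1,
                          resample = c("rows", "vessel"),
                          ci_level = 0.95) {
  stopifnot(inherits(fit, "ucu_fit"), B >= 100)
  resample <- match.arg(resample)
  set.seed(as.integer(seed))
  X <- stats::model.matrix(fit$fit)
  y <- stats::model.response(stats::model.frame(fit$fit))
  n <- nrow(X)
  p <- ncol(X)
  if (resample == "vessel") {
    if (!"vessel_id" %in% names(fit$data))
      stop("vessel resampling needs a vessel_id column", call. = FALSE)
    cluster <- split(seq_len(n), fit$data$vessel_id)
  }
  est <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(X)))
  n_redraw <- 0L
  for (b in seq_len(B)) {
    for (attempt in 1:50) {
      idx <- if (resample == "rows") sample.int(n, n, replace = TRUE)
             else unlist(cluster[sample.int(length(cluster),
                                            length(cluster),
                                            replace = TRUE)],
                         use.names = FALSE)
      Xb <- X[idx, , drop = FALSE]
      if (qr(Xb)$rank == p) break
      n_redraw <- n_redraw + 1L
      if (attempt == 50)
        stop("bootstrap: could not draw a full-rank design in 50 attempts",
             call. = FALSE)
    }
    est[b, ] <- stats::.lm.fit(Xb, y[idx])$coefficients
  }
  b0 <- stats::coef(fit$fit)
  bias <- colMeans(est) - b0
  alpha <- 1 - ci_level
  ci <- apply(est, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  sig <- vapply(seq_len(p), function(j) {
    boot_stars(function(a) stats::quantile(est[, j],
                                           c(a / 2, 1 - a / 2),
                                           names = FALSE))
  }, character(1))
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = unname(b0),
    bias = unname(bias),
    corrected = unname(b0 - bias),
    std_error = apply(est, 2, stats::sd),
    conf_low = ci[1, ],
    conf_high = ci[2, ],
    significance = sig
  )
  structure(list(fit = fit, B = B, seed = as.integer(seed),
                 resample = resample, ci_level = ci_level,
                 coefficients = coefs, boot_estimates = est,
                 n_redraw = n_redraw),
            class = "ucu_boot")
}

#' @export
print.ucu_boot <- function(x, ...) {
  cat("Bootstrapped OLS (B =", x$B, ", resample =", x$resample, ")\n")
  print(x$coefficients)
  invisible(x)
}

#' @rdname bootstrap_ucu
#' @param x A `ucu_boot`.
#' @param ... Unused.
#' @export
tidy.ucu_boot <- function(x, ...) x$coefficients

#' @rdname bootstrap_ucu
#' @export
glance.ucu_boot <- function(x, ...) {
  dplyr::mutate(glance(x$fit), B = x$B, seed = x$seed)
}

annual_mean_series <- function(data, var, period) {
  d <- data[data$year >= period[1] & data$year <= period[2], , drop = FALSE]
  s <- dplyr::summarise(dplyr::group_by(d, .data$year),
                        v = mean(.data[[var]], na.rm = TRUE),
                        .groups = "drop")
  s <- dplyr::arrange(s, .data$year)
  s$v
}

#' Covariate elasticities of a second-stage model
#'
#' The elasticity of the response to a covariate is `E = b * (dx / dy)`,
#' the coefficient scaled by the average annual change of the covariate
#' over the average annual change of the response across the analysis
#' period: the expected percent change in the response per 1 percent
#' change in the covariate. By default both average changes are means of
#' first differences of the annual fleet-mean series
#' (`mode = "mean_diff"`); `mode = "endpoint"` uses the endpoint
#' difference divided by the number of year steps instead. Coefficients
#' come from the bias-corrected bootstrap estimates when `object` is a
#' `ucu_boot`, otherwise from the OLS fit.
#'
#' @param object A `ucu_fit` or `ucu_boot`.
#' @param period Length-2 year range (default: full range of the data).
#' @param mode `"mean_diff"` or `"endpoint"`.
#' @return Tibble `term`, `b`, `dx`, `dy`, `elasticity`, `defined`; the
#'   elasticity is `NA` with `defined = FALSE` when the average response
#'   change is zero.
#' @export
ucu_elasticities <- function(object, period = NULL,
                             mode = c("mean_diff", "endpoint")) {
  mode <- match.arg(mode)
  fit <- if (inherits(object, "ucu_boot")) object$fit else object
  stopifnot(inherits(fit, "ucu_fit"))
  data <- fit$data
  if (!"year" %in% names(data))
    stop("elasticities need a year column in the model data", call. = FALSE)
  period <- period %||% range(data$year)
  coefs <- if (inherits(object, "ucu_boot")) {
    stats::setNames(object$coefficients$corrected,
                    object$coefficients$term)
  } else stats::coef(fit$fit)
  coefs <- coefs[names(coefs) != "(Intercept)"]
  avg_change <- function(var) {
    s <- annual_mean_series(data, var, period)
    if (length(s) < 2)
      stop("period ", period[1], "-", period[2],
           " spans fewer than two years", call. = FALSE)
    if (mode == "mean_diff") mean(diff(s))
    else (s[length(s)] - s[1]) / (length(s) - 1)
  }
  dy <- avg_change(fit$response)
  out <- purrr::map(names(coefs), function(v) {
    dx <- avg_change(v)
    tibble::tibble(term = v, b = unname(coefs[v]), dx = dx, dy = dy,
                   elasticity = if (dy == 0) NA_real_
                                else unname(coefs[v]) * dx / dy,
                   defined = dy != 0)
  })
  dplyr::bind_rows(out)
}

#' Residual diagnostics for a second-stage model
#'
#' First-order autocorrelation (Durbin-Watson) and heteroskedasticity
#' (Breusch-Pagan) tests on the OLS residuals, with pass/fail flags at
#' the 5\% level. A flagged heteroskedasticity test is the usual cue to
#' report the bootstrap bias-corrected estimates.
#'
#' @param fit A [fit_ucu_ols()] object.
#' @return Tibble `test`, `statistic`, `p_value`, `flag` (TRUE when the
#'   null of well-behaved residuals is rejected at 5\%).
#' @export
ucu_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "ucu_fit"))
  dw <- lmtest::dwtest(fit$fit)
  bp <- lmtest::bptest(fit$fit)
  tibble::tibble(
    test = c("autocorrelation_dw", "heteroskedasticity_bp"),
    statistic = c(unname(dw$statistic), unname(bp$statistic)),
    p_value = c(dw$p.value, bp$p.value),
    flag = c(dw$p.value < 0.05, bp$p.value < 0.05)
  )
}
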