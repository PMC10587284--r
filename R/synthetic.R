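#' Configure a synthetic fleet simulation
#'
#' Builds and validates the configuration for [simulate_fleet()]. The
#' generator emulates a purse-seine vessel-year panel: a fixed capital input
#' (vessel length), variable effort inputs (days fished, number of sets),
#' two species outputs expressed as exploitation rates (catch divided by
#' spawning stock biomass), a concave variable-returns-to-scale production
#' frontier drifting upward at a constant annual rate, vessel-level
#' inefficiency draws, and a linear covariate model for true unbiased
#' capacity utilisation. Every stochastic element is governed by `seed`, so
#' identical configurations reproduce identical panels.
#'
#' @param n_vessels Number of vessels in the fleet.
#' @param years Integer vector of calendar years (inclusive panel span).
#' @param strategy Fishing strategy the panel describes, `"FOB"` (floating
#'   object) or `"FSC"` (free swimming school).
#' @param drift_rate Annual frontier drift: potential output in year `t` is
#'   the base-year frontier times `(1 + drift_rate)^(t - base)`. Must exceed
#'   -1. Default 0.036 (3.6\% per year, a realistic effort-creep rate for a
#'   tropical tuna purse-seine fleet).
#' @param frontier Named list of frontier parameters: `scale`, a named
#'   numeric of per-species multipliers on the input aggregate; `exponents`,
#'   a named numeric of Cobb-Douglas exponents for `length_m`,
#'   `days_fished` and `n_sets` summing to less than 1 so the frontier is
#'   concave (variable returns to scale with an interior optimum).
#' @param inefficiency Named list describing the distribution of true
#'   technical efficiency on (0, 1]: `family` is `"beta"` (draws from
#'   `rbeta(shape1, shape2)`) or `"degenerate"` (all draws equal `at`,
#'   default 1).
#' @param entry_exit_prob Per-vessel per-year probability of being absent
#'   from the fishery. 0 gives a fully balanced panel.
#' @param covariate_model Named list with `beta` (named coefficient vector,
#'   `(Intercept)` plus any of the covariate columns produced by the
#'   generator) linking covariates to true unbiased capacity utilisation,
#'   `noise_sd` (Gaussian error standard deviation, >= 0) and optional
#'   `het_covariate` (name of a covariate whose scaled magnitude multiplies
#'   the error standard deviation, producing heteroskedastic scores).
#' @param ssb Named list of constant spawning stock biomass levels in
#'   tonnes: `yft` (yellowfin) and `skj` (skipjack), used to convert
#'   frontier exploitation rates back into catches.
#' @param tac_year First year of the total-allowable-catch regime; the `tac`
#'   covariate dummy is 1 from this year on (default 2017).
#' @param seed Integer seed controlling all draws.
#'
#' @return A `fleet_config` list, validated.
#' @export
#' @examples
#' cfg <- fleet_config(n_vessels = 10, years = 2000:2005, seed = 1)
#' sim <- simulate_fleet(cfg)
#' head(sim$panel)
fleet_config <- function(n_vessels = 30,
                         years = 1992:2019,
                         strategy = c("FOB", "FSC"),
                         drift_rate = 0.036,
                         frontier = list(
                           scale = c(yft = 8e-6, skj = 6e-6),
                           exponents = c(length_m = 0.30,
                                         days_fished = 0.25,
                                         n_sets = 0.25)
                         ),
                         inefficiency = list(family = "beta",
                                             shape1 = 6, shape2 = 2),
                         entry_exit_prob = 0,
                         covariate_model = list(
                           beta = c(`(Intercept)` = 0.70,
                                    n_sets = 0.0020,
                                    fuel = 0.0005,
                                    events = -0.0030,
                                    dmi = 0.05),
                           noise_sd = 0.05,
                           het_covariate = NULL
                         ),
                         ssb = list(yft = 1.0e6, skj = 2.0e6),
                         tac_year = 2017,
                         seed = 1L) {
  strategy <- match.arg(strategy)
  cfg <- list(n_vessels = as.integer(n_vessels), years = as.integer(years),
              strategy = strategy, drift_rate = drift_rate,
              frontier = frontier, inefficiency = inefficiency,
              entry_exit_prob = entry_exit_prob,
              covariate_model = covariate_model, ssb = ssb,
              tac_year = as.integer(tac_year), seed = as.integer(seed))
  validate_fleet_config(cfg)
  structure(cfg, class = "fleet_config")
}

validate_fleet_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid fleet configuration field `", field, "`: ", msg,
         call. = FALSE)
  }
  if (cfg$n_vessels < 1) fail("n_vessels", "must be >= 1")
  if (length(cfg$years) < 1) fail("years", "must span at least one year")
  if (!is.numeric(cfg$drift_rate) || cfg$drift_rate <= -1)
    fail("drift_rate", "must be a number > -1")
  ex <- cfg$frontier$exponents
  if (is.null(ex) || any(ex <= 0) || sum(ex) >= 1)
    fail("frontier$exponents",
         "must be positive and sum to < 1 (concave frontier)")
  if (is.null(cfg$frontier$scale) || any(cfg$frontier$scale <= 0))
    fail("frontier$scale", "must be positive per species")
  inef <- cfg$inefficiency
  if (!inef$family %in% c("beta", "degenerate"))
    fail("inefficiency$family", "must be 'beta' or 'degenerate'")
  if (inef$family == "beta" &&
      (is.null(inef$shape1) || is.null(inef$shape2) ||
       inef$shape1 <= 0 || inef$shape2 <= 0))
    fail("inefficiency$shape1/shape2", "beta shapes must be positive")
  if (inef$family == "degenerate") {
    at <- inef$at %||% 1
    if (at <= 0 || at > 1) fail("inefficiency$at", "must lie in (0, 1]")
  }
  if (cfg$entry_exit_prob < 0 || cfg$entry_exit_prob >= 1)
    fail("entry_exit_prob", "must lie in [0, 1)")
  cm <- cfg$covariate_model
  if (is.null(cm$beta) || is.null(names(cm$beta)))
    fail("covariate_model$beta", "must be a named coefficient vector")
  if (cm$noise_sd < 0) fail("covariate_model$noise_sd", "must be >= 0")
  if (any(unlist(cfg$ssb) <= 0)) fail("ssb", "biomass must be positive")
  invisible(cfg)
}

#' Read a fleet configuration from a YAML file
#'
#' Every field of [fleet_config()] is addressable from the file; omitted
#' fields fall back to the defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `fleet_config`.
#' @export
read_fleet_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$years) && length(raw$years) == 2)
    raw$years <- raw$years[1]:raw$years[2]
  for (fld in c("frontier", "inefficiency", "covariate_model", "ssb")) {
    if (!is.null(raw[[fld]]))
      raw[[fld]] <- utils::modifyList(formals(fleet_config)[[fld]] |>
                                        eval(), lapply(raw[[fld]], unlist))
  }
  do.call(fleet_config, raw)
}

frontier_output <- function(cfg, length_m, days_fished, n_sets, year) {
  ex <- cfg$frontier$exponents
  agg <- length_m^ex[["length_m"]] *
    days_fished^ex[["days_fished"]] *
    n_sets^ex[["n_sets"]]
  drift <- (1 + cfg$drift_rate)^(year - min(cfg$years))
  vapply(names(cfg$frontier$scale),
         function(sp) cfg$frontier$scale[[sp]] * agg * drift,
         numeric(length(agg)))
}

draw_te <- function(cfg, n) {
  inef <- cfg$inefficiency
  if (inef$family == "degenerate") rep(inef$at %||% 1, n)
  else pmax(stats::rbeta(n, inef$shape1, inef$shape2), 1e-6)
}

#' Simulate a synthetic fleet panel with known ground truth
#'
#' Generates a vessel-year panel on the schema consumed by
#' [read_fleet_panel()], together with a truth table holding the latent
#' quantities the downstream stages are meant to recover: per vessel-year
#' true technical efficiency and true unbiased capacity utilisation, and
#' the constant frontier-drift factor. Observed outputs are constructed as
#' `true_te` times the frontier output at the vessel's own inputs times the
#' drift multiplier, so no vessel-year ever lies above its year's frontier,
#' and catches are recovered by multiplying exploitation rates by spawning
#' stock biomass.
#'
#' @param config A [fleet_config()].
#' @return A list of class `fleet_sim`:
#' \describe{
#'   \item{panel}{vessel-year tibble with inputs, catches and covariates.}
#'   \item{truth}{tibble `vessel_id`, `year`, `true_te`, `true_ucu`.}
#'   \item{ssb}{year-level spawning-stock-biomass tibble.}
#'   \item{true_tc}{the constant per-pair technical-change factor
#'     `1 + drift_rate`.}
#'   \item{true_beta}{the covariate coefficient vector.}
#' }
#' @export
simulate_fleet <- function(config) {
  stopifnot(inherits(config, "fleet_config"))
  validate_fleet_config(config)
  cfg <- config
  set.seed(cfg$seed)
  years <- cfg$years
  nV <- cfg$n_vessels
  vessel_id <- sprintf("V%02d", seq_len(nV))

  # static vessel attributes: length in metres, engine power correlated
  # with length (typical large tropical purse seiners)
  length_m <- stats::runif(nV, 60, 95)
  kw <- round(45 * length_m + stats::rnorm(nV, 0, 150))

  cov_year <- generate_covariates(cfg)

  grid <- tidyr::expand_grid(vessel_id = vessel_id, year = years)
  grid$length_m <- length_m[match(grid$vessel_id, vessel_id)]
  grid$kw <- kw[match(grid$vessel_id, vessel_id)]
  n <- nrow(grid)

  present <- stats::runif(n) >= cfg$entry_exit_prob
  days_fished <- round(stats::runif(n, 120, 240))
  n_sets <- round(days_fished * stats::runif(n, 0.30, 0.60))
  buoys <- stats::rpois(n, 150)
  true_te <- draw_te(cfg, n)

  pot <- frontier_output(cfg, grid$length_m, days_fished, n_sets, grid$year)
  rate <- pot * true_te  # exploitation rates, one column per species

  panel <- tibble::tibble(
    vessel_id = grid$vessel_id,
    year = grid$year,
    strategy = cfg$strategy,
    length_m = grid$length_m,
    kw = grid$kw,
    gt = round(grid$length_m^2 * 0.35),
    days_fished = days_fished,
    n_sets = n_sets,
    catch_yft_t = rate[, "yft"] * cfg$ssb$yft,
    catch_skj_t = rate[, "skj"] * cfg$ssb$skj,
    buoys = buoys
  )
  panel <- dplyr::left_join(panel, cov_year, by = "year")

  # true covariate -> UCU link (score-level response used to validate the
  # second stage; clipped into (0, 1])
  cm <- cfg$covariate_model
  bt <- cm$beta
  xmat <- cbind(`(Intercept)` = 1,
                as.matrix(panel[setdiff(names(bt), "(Intercept)")]))
  mu <- drop(xmat[, names(bt), drop = FALSE] %*% bt)
  sd_vec <- rep(cm$noise_sd, n)
  if (!is.null(cm$het_covariate)) {
    h <- panel[[cm$het_covariate]]
    sd_vec <- cm$noise_sd * (0.25 + 1.5 * abs(h) / (mean(abs(h)) + 1e-12))
  }
  true_ucu <- pmin(pmax(mu + stats::rnorm(n, 0, sd_vec), 0.02), 1)

  truth <- tibble::tibble(vessel_id = grid$vessel_id, year = grid$year,
                          true_te = true_te, true_ucu = true_ucu)
  panel <- panel[present, , drop = FALSE]
  truth <- truth[present, , drop = FALSE]

  ssb <- tibble::tibble(year = years,
                        yft_ssb_t = cfg$ssb$yft,
                        skj_ssb_t = cfg$ssb$skj)

  structure(list(panel = panel, truth = truth, ssb = ssb,
                 true_tc = 1 + cfg$drift_rate,
                 true_beta = bt, config = cfg),
            class = "fleet_sim")
}

#' Generate year-level covariates for a synthetic fleet
#'
#' Year-level series emulating the covariates used to explain capacity
#' utilisation: real fuel price, real yellowfin and skipjack prices (slow
#' random walks), piracy event counts (Poisson), the Indian Ocean Dipole
#' index (zero-mean Gaussian) and the total-allowable-catch dummy (1 from
#' `tac_year` on). Vessel-level covariates (engine power, buoy deployments)
#' are drawn inside [simulate_fleet()].
#'
#' @param config A [fleet_config()].
#' @return A year-keyed tibble with columns `year`, `tac`, `fuel`, `yftpr`,
#'   `skjpr`, `events`, `dmi`.
#' @export
generate_covariates <- function(config) {
  cfg <- config
  set.seed(cfg$seed + 1000003L)
  nY <- length(cfg$years)
  rw <- function(start, sd, lo, hi) {
    x <- cumsum(c(start, stats::rnorm(nY - 1, 0, sd)))
    pmin(pmax(x, lo), hi)
  }
  tibble::tibble(
    year = cfg$years,
    tac = as.integer(cfg$years >= cfg$tac_year),
    fuel = rw(60, 8, 25, 120),
    yftpr = rw(1800, 90, 1000, 3000),
    skjpr = rw(1300, 70, 700, 2200),
    events = stats::rpois(nY, 15),
    dmi = round(stats::rnorm(nY, 0, 0.35), 3)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
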