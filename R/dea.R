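#' Build a within-year, within-strategy DEA reference set
#'
#' Assembles the input matrix X and output matrix Y that define the
#' best-practice frontier for one comparison group: all active vessels of
#' one fishing strategy in one calendar year. A vessel-year is active when
#' it recorded at least one set and at least one positive variable input;
#' inactive rows and rows with no positive output stay in the panel but are
#' excluded from the frontier, and the exclusions are reported.
#'
#' @param panel Vessel-year tibble with exploitation-rate outputs already
#'   joined (see [join_ssb()]).
#' @param year Calendar year of the comparison group.
#' @param strategy `"FOB"` or `"FSC"`.
#' @param fixed_input Column name of the capital input held fixed in the
#'   capacity model (`"length_m"`, `"kw"` or `"gt"`).
#' @param variable_inputs Character vector of variable-input columns, a
#'   subset of `c("days_fished", "n_sets")`.
#' @return A `dea_refset`: list with `year`, `strategy`, `dmu_ids`, `X`
#'   (J x N inputs, fixed column first), `Y` (J x 2 exploitation rates),
#'   `fixed_idx`, `variable_idx`, and an `excluded` tibble.
#' @export
build_reference_set <- function(panel, year, strategy,
                                fixed_input = "length_m",
                                variable_inputs = c("days_fished", "n_sets")) {
  stopifnot(length(fixed_input) == 1, length(variable_inputs) >= 1)
  if (!all(c("y_yft", "y_skj") %in% names(panel)))
    stop("panel has no exploitation-rate outputs; call join_ssb() first",
         call. = FALSE)
  rows <- panel[panel$year == year & panel$strategy == strategy, ,
                drop = FALSE]
  if (!nrow(rows))
    stop("no vessels for strategy ", strategy, " in year ", year,
         call. = FALSE)

  vi <- as.matrix(rows[variable_inputs])
  inactive <- rows$n_sets <= 0 | rowSums(vi > 0) == 0
  no_output <- rows$y_yft <= 0 & rows$y_skj <= 0
  keep <- !inactive & !no_output
  excluded <- tibble::tibble(
    vessel_id = rows$vessel_id[!keep],
    reason = ifelse(inactive[!keep], "no positive sets", "no positive output")
  )
  rows <- rows[keep, , drop = FALSE]
  if (!nrow(rows))
    stop("no active vessels for strategy ", strategy, " in year ", year,
         call. = FALSE)

  X <- as.matrix(rows[c(fixed_input, variable_inputs)])
  Y <- as.matrix(rows[c("y_yft", "y_skj")])
  structure(list(year = year, strategy = strategy,
                 dmu_ids = rows$vessel_id,
                 X = X, Y = Y,
                 fixed_idx = 1L,
                 variable_idx = seq_along(variable_inputs) + 1L,
                 excluded = excluded),
            class = "dea_refset")
}

# Solve the batched output-oriented VRS expansion LPs for observations
# (X0, Y0) against the frontier of `refset`. `model` chooses which input
# constraints bind: "te" keeps them all, "cu" keeps only the fixed input
# (the variable-input utilisation multipliers are free above zero, so those
# constraints can never bind and are omitted; the implied utilisation rates
# are recovered from the optimal weights afterwards).
dea_expand <- function(refset, X0 = refset$X, Y0 = refset$Y,
                       model = c("te", "cu")) {
  model <- match.arg(model)
  constrained <- if (model == "te") seq_len(ncol(refset$X)) else refset$fixed_idx
  res <- .dea_solve_batch_cpp(refset$X, refset$Y,
                              X0, Y0, as.integer(constrained))
  res$status <- c("optimal", "infeasible", "unbounded")[res$status + 1L]
  res
}

snap_theta <- function(theta, tol = 1e-6) {
  ifelse(!is.na(theta) & abs(theta - 1) < tol, 1, theta)
}

#' Solve the technical-efficiency program for a reference set
#'
#' Output-oriented distance program under variable returns to scale: for
#' each vessel j the maximal proportional output expansion theta1 feasible
#' inside the convex hull of the group's observed input-output bundles,
#' with all inputs bound at the vessel's own levels. Technical efficiency
#' is `te = 1/theta1`.
#'
#' @param refset A [build_reference_set()] object.
#' @return Tibble `dmu_id`, `theta1`, `te`, `lp_status`, with the optimal
#'   intensity weights in the `"z"` attribute (one row per scored vessel).
#' @export
solve_te <- function(refset) {
  res <- dea_expand(refset, model = "te")
  theta <- snap_theta(res$theta)
  out <- tibble::tibble(dmu_id = refset$dmu_ids, theta1 = theta,
                        te = 1 / theta, lp_status = res$status)
  attr(out, "z") <- res$z
  out
}

#' Solve the capacity (sub-vector) program for a reference set
#'
#' Same expansion program as [solve_te()] except that the variable-input
#' constraints are relaxed: each vessel may use any non-negative amount of
#' days and sets, while the fixed capital input still binds. The resulting
#' theta2 >= theta1 and capacity utilisation is `cu = 1/theta2`. The
#' implied utilisation multipliers of the variable inputs (the ratio of
#' the frontier-combination input use to the vessel's own) are returned in
#' the `"lambda"` attribute.
#'
#' @inheritParams solve_te
#' @return Tibble `dmu_id`, `theta2`, `cu`, `lp_status`.
#' @export
solve_cu <- function(refset) {
  res <- dea_expand(refset, model = "cu")
  theta <- snap_theta(res$theta)
  vi <- refset$variable_idx
  lam <- (res$z %*% refset$X[, vi, drop = FALSE]) /
    refset$X[, vi, drop = FALSE][seq_along(refset$dmu_ids), , drop = FALSE]
  colnames(lam) <- colnames(refset$X)[vi]
  out <- tibble::tibble(dmu_id = refset$dmu_ids, theta2 = theta,
                        cu = 1 / theta, lp_status = res$status)
  attr(out, "z") <- res$z
  attr(out, "lambda") <- lam
  out
}

#' Score a fleet panel: TE, CU and UCU per vessel-year-strategy
#'
#' Runs the technical-efficiency and capacity programs for every year and
#' strategy group in the panel and derives the three scores per vessel:
#' technical efficiency `te = 1/theta1`, capacity utilisation
#' `cu = 1/theta2`, and unbiased capacity utilisation `ucu = cu/te`, which
#' nets underutilisation of capacity out of technical inefficiency. Scores
#' obey `0 < cu <= te <= 1` and `cu <= ucu <= 1` up to solver tolerance;
#' violations beyond `1e-4` abort (they would indicate a mis-specified
#' program), smaller ones are clipped.
#'
#' @param panel Vessel-year tibble with outputs joined (see [join_ssb()]).
#' @inheritParams build_reference_set
#' @return A `dea_scores` tibble: `vessel_id`, `year`, `strategy`,
#'   `theta1`, `theta2`, `te`, `cu`, `ucu`, `lp_status`. Non-optimal
#'   solves are kept but flagged and carry `NA` scores.
#' @export
#' @examples
#' sim <- simulate_fleet(fleet_config(n_vessels = 8, years = 2000:2002))
#' panel <- join_ssb(sim$panel, sim$ssb)
#' dea_scores(panel)
dea_scores <- function(panel, fixed_input = "length_m",
                       variable_inputs = c("days_fished", "n_sets")) {
  groups <- unique(panel[c("year", "strategy")])
  recs <- purrr::pmap(groups, function(year, strategy) {
    rs <- build_reference_set(panel, year, strategy,
                              fixed_input = fixed_input,
                              variable_inputs = variable_inputs)
    sol_te <- solve_te(rs)
    sol_cu <- solve_cu(rs)
    tibble::tibble(
      vessel_id = rs$dmu_ids, year = year, strategy = strategy,
      theta1 = sol_te$theta1, theta2 = sol_cu$theta2,
      te = sol_te$te, cu = sol_cu$cu,
      lp_status = ifelse(sol_te$lp_status == "optimal" &
                           sol_cu$lp_status == "optimal",
                         "optimal", "failed")
    )
  })
  out <- dplyr::bind_rows(recs)

  ok <- out$lp_status == "optimal"
  viol <- pmax(out$cu[ok] - out$te[ok], out$te[ok] - 1, 1 - out$theta2[ok], 0)
  if (any(viol > 1e-4))
    stop("DEA score invariant violated beyond tolerance (max violation ",
         signif(max(viol), 3), "); the linear programs are inconsistent",
         call. = FALSE)
  out$te[ok] <- pmin(out$te[ok], 1)
  out$cu[ok] <- pmin(out$cu[ok], out$te[ok])
  out$ucu <- out$cu / out$te
  out[!ok, c("te", "cu", "ucu")] <- NA_real_
  class(out) <- c("dea_scores", class(out))
  out
}

#' Annual fleet-mean scores with standard errors
#'
#' Averages the vessel scores by year and strategy and attaches the
#' standard error of the mean, the series plotted as fleet trend lines.
#' A group with a single vessel has an undefined standard error, reported
#' as 0 with `se_defined = FALSE`.
#'
#' @param scores A [dea_scores()] tibble.
#' @return A `dea_annual` tibble in long form: `year`, `strategy`,
#'   `metric` (te/cu/ucu), `mean`, `se`, `n`, `se_defined`.
#' @export
annual_means <- function(scores) {
  long <- tidyr::pivot_longer(
    dplyr::filter(scores, .data$lp_status == "optimal"),
    cols = c("te", "cu", "ucu"), names_to = "metric", values_to = "score"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$year, .data$strategy, .data$metric),
    mean = mean(.data$score),
    se = ifelse(dplyr::n() > 1,
                stats::sd(.data$score) / sqrt(dplyr::n()), 0),
    n = dplyr::n(),
    se_defined = dplyr::n() > 1,
    .groups = "drop"
  )
  class(out) <- c("dea_annual", class(out))
  out
}

#' Management implications of a capacity-utilisation score
#'
#' Translates an unbiased capacity-utilisation score into its two standard
#' management readings: the share of additional catch the fleet could have
#' taken at full capacity utilisation (`1/UCU - 1`) and the share of
#' capacity that is currently in excess (`1 - UCU`). A fleet-mean UCU of
#' 0.80, for example, implies the fleet could have caught 25\% more fish,
#' or the same catch with 20\% fewer vessels.
#'
#' @param ucu Numeric vector of scores in (0, 1].
#' @return Tibble `ucu`, `potential_catch_gain`, `capacity_excess`
#'   (fractions).
#' @export
#' @examples
#' capacity_implications(0.80)
capacity_implications <- function(ucu) {
  stopifnot(all(ucu > 0 & ucu <= 1))
  tibble::tibble(ucu = ucu,
                 potential_catch_gain = 1 / ucu - 1,
                 capacity_excess = 1 - ucu)
}
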