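#' Shephard output distance of observations against another period's frontier
#'
#' Solves the output-expansion program for arbitrary observations `(x, y)`
#' against the frontier defined by `refset`, and returns the Shephard
#' output distance `d = 1/theta`. When the observations come from another
#' period, `theta` may fall below 1 (`d > 1`: the point lies beyond the
#' frontier), and under variable returns to scale the program can be
#' infeasible (the observation's inputs are outside the frontier's convex
#' hull); infeasible solves are flagged, never fabricated.
#'
#' @param refset Frontier reference set from [build_reference_set()].
#' @param x Matrix (or vector) of observation inputs, columns ordered as in
#'   `refset$X`.
#' @param y Matrix (or vector) of observation outputs, columns as in
#'   `refset$Y`.
#' @return Tibble `theta`, `distance`, `feasible`.
#' @export
cross_distance <- function(refset, x, y) {
  x <- matrix(x, ncol = ncol(refset$X))
  y <- matrix(y, ncol = ncol(refset$Y))
  res <- dea_expand(refset, X0 = x, Y0 = y, model = "te")
  tibble::tibble(theta = res$theta,
                 distance = 1 / res$theta,
                 feasible = res$status == "optimal")
}

malmquist_one_pair <- function(panel, t, strategy, fixed_input,
                               variable_inputs) {
  rs_t <- build_reference_set(panel, t, strategy, fixed_input,
                              variable_inputs)
  rs_t1 <- build_reference_set(panel, t + 1, strategy, fixed_input,
                               variable_inputs)
  common <- intersect(rs_t$dmu_ids, rs_t1$dmu_ids)
  if (!length(common)) return(NULL)
  i_t <- match(common, rs_t$dmu_ids)
  i_t1 <- match(common, rs_t1$dmu_ids)

  own_t <- dea_expand(rs_t, rs_t$X[i_t, , drop = FALSE],
                      rs_t$Y[i_t, , drop = FALSE])
  own_t1 <- dea_expand(rs_t1, rs_t1$X[i_t1, , drop = FALSE],
                       rs_t1$Y[i_t1, , drop = FALSE])
  cross_t1_t <- dea_expand(rs_t1, rs_t$X[i_t, , drop = FALSE],
                           rs_t$Y[i_t, , drop = FALSE])
  cross_t_t1 <- dea_expand(rs_t, rs_t1$X[i_t1, , drop = FALSE],
                           rs_t1$Y[i_t1, , drop = FALSE])

  d_t_t <- 1 / snap_theta(own_t$theta)
  d_t1_t1 <- 1 / snap_theta(own_t1$theta)
  d_t1_t <- 1 / cross_t1_t$theta   # period-t bundle vs period-t+1 frontier
  d_t_t1 <- 1 / cross_t_t1$theta   # period-t+1 bundle vs period-t frontier

  feasible <- own_t$status == "optimal" & own_t1$status == "optimal" &
    cross_t1_t$status == "optimal" & cross_t_t1$status == "optimal"

  ec <- d_t1_t1 / d_t_t
  tc <- sqrt((d_t_t / d_t1_t) * (d_t_t1 / d_t1_t1))
  tibble::tibble(
    vessel_id = common, strategy = strategy,
    year_from = t, year_to = t + 1,
    d_t_t = d_t_t, d_t1_t1 = d_t1_t1, d_t1_t = d_t1_t, d_t_t1 = d_t_t1,
    ec = ec, tc = tc, pc = ec * tc,
    feasible = feasible
  )
}

#' Adjacent-period Malmquist productivity change per vessel
#'
#' For every adjacent year pair and strategy, computes the four Shephard
#' output distances (own and cross period) for each vessel present in both
#' years, and decomposes productivity change multiplicatively:
#' `pc = ec * tc`, where efficiency change
#' `ec = d_t1(t+1)/d_t(t)` measures catch-up toward the frontier and
#' technical change `tc = sqrt((d_t(t)/d_t1_t) * (d_t_t1/d_t1(t+1)))`
#' measures the frontier shift itself. Pairing is per adjacent pair: only
#' vessels active in both years of a pair enter that pair's records, which
#' accommodates vessels entering and exiting the fishery. Cross-period
#' programs that are infeasible under variable returns to scale are
#' flagged and later excluded from aggregation.
#'
#' @inheritParams dea_scores
#' @param strategy Optional: restrict to one strategy.
#' @return A `malmquist_records` tibble with one row per vessel and year
#'   pair: the four distances, `ec`, `tc`, `pc` and a `feasible` flag.
#' @export
malmquist <- function(panel, fixed_input = "length_m",
                      variable_inputs = c("days_fished", "n_sets"),
                      strategy = NULL) {
  strategies <- strategy %||% sort(unique(panel$strategy))
  out <- purrr::map(strategies, function(s) {
    yrs <- sort(unique(panel$year[panel$strategy == s]))
    pairs <- yrs[(yrs + 1) %in% yrs]
    purrr::map(pairs, function(t) {
      malmquist_one_pair(panel, t, s, fixed_input, variable_inputs)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (!nrow(out))
    stop("no adjacent-year vessel pairs found; the Malmquist index needs ",
         "vessels present in consecutive years", call. = FALSE)
  class(out) <- c("malmquist_records", class(out))
  out
}

#' Malmquist record for one vessel and year pair
#'
#' Convenience accessor for a single vessel's decomposition between `t`
#' and `t + 1`; errors when the vessel is not active in both years.
#'
#' @inheritParams malmquist
#' @param vessel_id Vessel identifier.
#' @param t First year of the adjacent pair.
#' @export
malmquist_pair <- function(panel, vessel_id, t, strategy,
                           fixed_input = "length_m",
                           variable_inputs = c("days_fished", "n_sets")) {
  rec <- malmquist_one_pair(panel, t, strategy, fixed_input,
                            variable_inputs)
  rec <- rec[!is.null(rec) & rec$vessel_id == vessel_id, , drop = FALSE]
  if (is.null(rec) || !nrow(rec))
    stop("vessel ", vessel_id, " is not active in both ", t, " and ",
         t + 1, " for strategy ", strategy, call. = FALSE)
  rec
}

#' Chain Malmquist records into cumulative fleet indices
#'
#' Aggregates vessel-level records to per-pair geometric means (computed
#' in log space over feasible records only) and chains them into
#' cumulative indices anchored at the base year = 1, the form in which
#' fleet productivity trajectories are read. The cumulative productivity
#' index equals the product of the cumulative efficiency-change and
#' technical-change indices.
#'
#' @param records A [malmquist()] tibble.
#' @return A `malmquist_series` tibble: per strategy and year, cumulative
#'   `cum_ec`, `cum_tc`, `cum_pc` (base year = 1) plus the per-pair
#'   geometric means `ec`, `tc`, `pc`, `n_vessels` and `n_infeasible`.
#'   A pair with no feasible record breaks the chain and errors.
#' @export
cumulate_malmquist <- function(records) {
  pair_means <- dplyr::summarise(
    dplyr::group_by(records, .data$strategy, .data$year_from, .data$year_to),
    ec = exp(mean(log(.data$ec[.data$feasible]))),
    tc = exp(mean(log(.data$tc[.data$feasible]))),
    pc = exp(mean(log(.data$pc[.data$feasible]))),
    n_vessels = sum(.data$feasible),
    n_infeasible = sum(!.data$feasible),
    .groups = "drop"
  )
  broken <- pair_means[pair_means$n_vessels == 0, , drop = FALSE]
  if (nrow(broken))
    stop("cumulative chain broken: no feasible Malmquist record for pair(s) ",
         paste(broken$year_from, broken$year_to, sep = "-", collapse = ", "),
         call. = FALSE)
  out <- pair_means |>
    dplyr::group_by(.data$strategy) |>
    dplyr::arrange(.data$year_from, .by_group = TRUE) |>
    dplyr::mutate(cum_ec = cumprod(.data$ec),
                  cum_tc = cumprod(.data$tc),
                  cum_pc = cumprod(.data$pc)) |>
    dplyr::ungroup()
  # prepend the base-year anchor (all indices = 1)
  base <- out |>
    dplyr::distinct(.data$strategy) |>
    dplyr::mutate(year_from = NA_integer_,
                  year_to = min(records$year_from),
                  ec = NA_real_, tc = NA_real_, pc = NA_real_,
                  n_vessels = NA_integer_, n_infeasible = NA_integer_,
                  cum_ec = 1, cum_tc = 1, cum_pc = 1)
  out <- dplyr::bind_rows(base, out) |>
    dplyr::arrange(.data$strategy, .data$year_to)
  class(out) <- c("malmquist_series", class(out))
  out
}

#' Annualised rate of a cumulative Malmquist index over a sub-period
#'
#' Geometric annualisation of a chained index: the constant per-year
#' factor that would produce the observed cumulative change between two
#' years, minus 1. Applied to the technical-change index this is the
#' effort-creep rate.
#'
#' @param series A [cumulate_malmquist()] tibble.
#' @param index One of `"tc"`, `"ec"`, `"pc"`.
#' @param from,to Year range (defaults: full span of the series).
#' @param strategy Optional strategy filter (required when the series
#'   holds several strategies).
#' @return The annualised rate (e.g. 0.036 for +3.6\% per year).
#' @export
annualised_rate <- function(series, index = c("tc", "ec", "pc"),
                            from = NULL, to = NULL, strategy = NULL) {
  index <- match.arg(index)
  s <- series
  if (!is.null(strategy)) s <- s[s$strategy == strategy, , drop = FALSE]
  if (length(unique(s$strategy)) > 1)
    stop("series holds several strategies; pick one via `strategy`",
         call. = FALSE)
  from <- from %||% min(s$year_to)
  to <- to %||% max(s$year_to)
  col <- paste0("cum_", index)
  v_from <- s[[col]][s$year_to == from]
  v_to <- s[[col]][s$year_to == to]
  if (!length(v_from) || !length(v_to))
    stop("years ", from, "-", to, " not covered by the series",
         call. = FALSE)
  (v_to / v_from)^(1 / (to - from)) - 1
}
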