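#' Read and validate a vessel-year panel
#'
#' Reads the CSV panel schema used throughout the package: one row per
#' vessel, year and fishing strategy, with a fixed capital input (at least
#' one of `length_m`, `kw`, `gt`), the variable effort inputs
#' (`days_fished`, `n_sets`), catches per species in tonnes (`catch_yft_t`,
#' `catch_skj_t`) and any covariate columns (`tac`, `fuel`, `yftpr`,
#' `skjpr`, `events`, `dmi`, `buoys`). Validation is total: every rejected
#' row is reported with its reason, and structural problems (missing
#' columns, duplicate keys, non-numeric cells) abort with a message naming
#' the offenders.
#'
#' @param path CSV file path.
#' @param fixed_input Which capital input must be present and positive for
#'   a row to be usable (default `"length_m"`).
#' @return A tibble of valid rows. Rows rejected for a non-positive or
#'   missing fixed input are dropped and reported in the
#'   `"rejected"` attribute (a tibble with a `reason` column).
#' @export
read_fleet_panel <- function(path, fixed_input = "length_m") {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  panel <- readr::read_csv(path, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("vessel_id", "year", "strategy", "days_fished", "n_sets",
                "catch_yft_t", "catch_skj_t", fixed_input)
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols))
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  num_cols <- setdiff(required, c("vessel_id", "strategy"))
  bad_num <- num_cols[!vapply(panel[num_cols], is.numeric, logical(1))]
  if (length(bad_num))
    stop("non-numeric values in column(s): ",
         paste(bad_num, collapse = ", "), call. = FALSE)

  if (!all(panel$strategy %in% c("FOB", "FSC")))
    stop("strategy must be 'FOB' or 'FSC'; found: ",
         paste(unique(setdiff(panel$strategy, c("FOB", "FSC"))),
               collapse = ", "), call. = FALSE)

  key <- paste(panel$vessel_id, panel$year, panel$strategy, sep = "/")
  dups <- unique(key[duplicated(key)])
  if (length(dups))
    stop("duplicate (vessel_id, year, strategy) key(s): ",
         paste(dups, collapse = ", "), call. = FALSE)

  bad_fixed <- is.na(panel[[fixed_input]]) | panel[[fixed_input]] <= 0
  rejected <- panel[bad_fixed, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- paste0("non-positive or missing ", fixed_input)
  panel <- panel[!bad_fixed, , drop = FALSE]
  attr(panel, "rejected") <- rejected
  panel
}

#' Read a spawning-stock-biomass table
#'
#' @param path CSV with columns `year`, `yft_ssb_t`, `skj_ssb_t` (tonnes).
#' @return A tibble; all biomass values must be positive.
#' @export
read_ssb <- function(path) {
  ssb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("year", "yft_ssb_t", "skj_ssb_t")
  miss <- setdiff(need, names(ssb))
  if (length(miss))
    stop("SSB table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(ssb$yft_ssb_t <= 0) || any(ssb$skj_ssb_t <= 0))
    stop("spawning stock biomass must be positive", call. = FALSE)
  ssb
}

#' Join spawning stock biomass and derive exploitation-rate outputs
#'
#' Adds the two DEA outputs to a panel: `y_yft = catch_yft_t / yft_ssb_t`
#' and `y_skj = catch_skj_t / skj_ssb_t`, each evaluated at the row's year.
#' Catches are preserved, and the operation is idempotent (outputs are
#' always recomputed from catches).
#'
#' @param panel Vessel-year tibble (see [read_fleet_panel()]).
#' @param ssb Year-level biomass tibble (see [read_ssb()]).
#' @return The panel with `y_yft` and `y_skj` columns.
#' @export
join_ssb <- function(panel, ssb) {
  missing_years <- setdiff(unique(panel$year), ssb$year)
  if (length(missing_years))
    stop("SSB table does not cover panel year(s): ",
         paste(sort(missing_years), collapse = ", "), call. = FALSE)
  idx <- match(panel$year, ssb$year)
  panel$y_yft <- panel$catch_yft_t / ssb$yft_ssb_t[idx]
  panel$y_skj <- panel$catch_skj_t / ssb$skj_ssb_t[idx]
  panel
}

write_result_csv <- function(results, path, what) {
  if (is.null(results) || !nrow(results))
    stop("refusing to write empty ", what, " table", call. = FALSE)
  readr::write_csv(results, path, progress = FALSE)
  invisible(path)
}

#' Write result tables to CSV
#'
#' Thin writers for the three result types. Numeric values are serialized
#' at full precision, so a write/read round trip reproduces them exactly.
#' Writing an empty table is an error rather than an empty file.
#'
#' @param results A non-empty tibble of scores, Malmquist records/series,
#'   or a regression report.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_scores <- function(results, path) write_result_csv(results, path, "score")

#' @rdname write_scores
#' @export
write_indices <- function(results, path) write_result_csv(results, path, "index")

#' @rdname write_scores
#' @export
write_regression <- function(results, path) {
  write_result_csv(results, path, "regression")
}
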