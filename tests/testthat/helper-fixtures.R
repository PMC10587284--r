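# Programmatic fixtures: tiny panels and reference sets built in code.

# A reference set straight from matrices, bypassing panel assembly, for
# LP-level tests. First input column is the fixed input.
make_refset <- function(X, Y, year = 2000, strategy = "FOB") {
  J <- nrow(X)
  structure(list(year = year, strategy = strategy,
                 dmu_ids = sprintf("V%02d", seq_len(J)),
                 X = X, Y = Y,
                 fixed_idx = 1L,
                 variable_idx = if (ncol(X) > 1) 2:ncol(X) else integer(0),
                 excluded = tibble::tibble(vessel_id = character(),
                                           reason = character())),
            class = "dea_refset")
}

# A panel tibble from explicit per-row values (outputs already joined).
make_panel <- function(vessel_id, year, length_m, days_fished, n_sets,
                       y_yft, y_skj, strategy = "FOB") {
  tibble::tibble(vessel_id = vessel_id, year = year, strategy = strategy,
                 length_m = length_m, days_fished = days_fished,
                 n_sets = n_sets,
                 catch_yft_t = y_yft * 1e6, catch_skj_t = y_skj * 2e6,
                 y_yft = y_yft, y_skj = y_skj)
}

# Random positive DEA instance (inputs in [0.5, 10], outputs in [0.05, 5]).
random_instance <- function(J, N = 2, M = 2) {
  list(X = matrix(stats::runif(J * N, 0.5, 10), J),
       Y = matrix(stats::runif(J * M, 0.05, 5), J))
}

# Small panel CSV on disk for IO tests; returns the path.
write_panel_csv <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                               .local_envir = parent.frame())) {
  readr::write_csv(rows, path, progress = FALSE)
  path
}

base_panel_rows <- function() {
  tibble::tibble(
    vessel_id = c("v1", "v2", "v3"),
    year = 2000L,
    strategy = "FOB",
    length_m = c(70, 80, 90),
    days_fished = c(150, 180, 200),
    n_sets = c(60, 80, 90),
    catch_yft_t = c(900, 1100, 1500),
    catch_skj_t = c(1800, 2400, 2600)
  )
}

base_ssb_rows <- function(years = 2000L) {
  tibble::tibble(year = years, yft_ssb_t = 1e6, skj_ssb_t = 2e6)
}
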