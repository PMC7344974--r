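#' Load a bundled dataset or configuration fixture
#'
#' The package ships the styrene validation dataset for the
#' fiberglass-reinforced-plastics (FRP) lamination and inspection tasks as
#' plain-text fixtures:
#'
#' * `"factor_table"` - the versioned factor/score configuration
#'   (a [read_factor_table()] object).
#' * `"category_bands"` - the four exposure-category bands.
#' * `"worked_profile"` - the worked FRP-lamination-for-ship-manufacturing
#'   situation profile (a `situation_profile`).
#' * `"measurement_summaries"` - per-company measurement summaries (36 rows:
#'   22 FRP lamination + 14 inspection; columns `situation_id`, `task`,
#'   `company`, `product`, `duration_min`, `n`, `am`, `gm`, `gsd`, `min`,
#'   `max`; GSD absent for n = 1 companies).
#' * `"measurement_totals"` - the printed per-task totals (kept as
#'   transcribed; tests recompute totals from the per-company rows).
#' * `"model_estimates"` - per-company external model estimates (daily
#'   average, 50th and 90th percentile, in ppm) and the new-model log score
#'   with its category (36 rows; `p90_measured` is the measured 90th,
#'   absent for n = 1).
#'
#' @param name One of the fixture names above.
#' @return The typed object described above.
#' @examples
#' ms <- load_fixture("measurement_summaries")
#' sum(ms$n[ms$task == "FRP lamination"])   # 137
#' @export
load_fixture <- function(name = c("factor_table", "category_bands",
                                  "worked_profile", "measurement_summaries",
                                  "measurement_totals", "model_estimates")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "expoband")
  switch(
    name,
    factor_table = read_factor_table(path("factor_table.yaml")),
    category_bands = read_category_bands(path("category_bands.yaml")),
    worked_profile = read_profile(path("worked_profile.yaml")),
    measurement_summaries = read.csv(path("measurement_summaries.csv"),
                                     stringsAsFactors = FALSE),
    measurement_totals = read.csv(path("measurement_totals.csv"),
                                  stringsAsFactors = FALSE),
    model_estimates = read.csv(path("model_estimates.csv"),
                               stringsAsFactors = FALSE)
  )
}
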