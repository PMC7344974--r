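#' Simulate individual lognormal exposure measurements
#'
#' Draws seeded lognormal samples matching per-situation (n, GM, GSD)
#' summaries: `ln(value) ~ Normal(ln gm, (ln gsd)^2)`.  The published
#' validation dataset reports only grouped summaries, so simulated individual
#' values stand in for unpublished raw measurements wherever an
#' individual-level quantity is needed.  In `exact_moments` mode the draws are
#' affinely adjusted on the log scale so that the sample GM and sample (n-1)
#' GSD equal the targets exactly.
#'
#' @param groups Data frame with columns `situation_id`, `n`, `gm`, `gsd`
#'   (gsd may be `NA` for n = 1 groups, treated as no spread).
#' @param seed Integer seed; the same seed yields identical output.  The
#'   caller's RNG state is preserved.
#' @param exact_moments If `TRUE`, rescale each group so its sample log-mean
#'   and log-SD hit `ln gm` and `ln gsd` exactly.
#' @return Long-format data frame with columns `situation_id`, `value_ppm`.
#' @examples
#' sim <- simulate_measurements(
#'   data.frame(situation_id = "A", n = 8, gm = 11.78, gsd = 2.39),
#'   seed = 1, exact_moments = TRUE)
#' summarize_measurements(sim$value_ppm)[, c("gm", "gsd")]
#' @export
simulate_measurements <- function(groups, seed = NULL, exact_moments = FALSE) {
  req <- c("situation_id", "n", "gm", "gsd")
  missing <- setdiff(req, names(groups))
  if (length(missing)) {
    stop_expoband("groups is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(groups$n < 1)) stop_expoband("group sizes must be >= 1")
  if (any(!is.finite(groups$gm) | groups$gm <= 0)) {
    stop_expoband("gm must be positive")
  }
  if (any(!is.na(groups$gsd) & groups$gsd < 1)) {
    stop_expoband("gsd must be >= 1")
  }
  with_seed(seed, {
    out <- lapply(seq_len(nrow(groups)), function(i) {
      n <- groups$n[i]
      gm <- groups$gm[i]
      gsd <- groups$gsd[i]
      sdl <- if (is.na(gsd)) 0 else log(gsd)
      lx <- log(gm) + sdl * rnorm(n)
      if (exact_moments && n >= 2 && sdl > 0) {
        lx <- log(gm) + (lx - mean(lx)) / sd(lx) * sdl
      } else if (exact_moments || sdl == 0) {
        if (n == 1 || sdl == 0) lx <- rep(log(gm), n)
      }
      data.frame(
        situation_id = groups$situation_id[i],
        value_ppm = exp(lx),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}
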