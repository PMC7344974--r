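#' Compute the exposure score of a situation profile
#'
#' The raw score is the product of the eleven multiplier factor scores divided
#' by the room-volume score, and the exposure score is its natural logarithm,
#' subject to the no-exposure convention: a profile with every factor at score
#' 1.0 reports the conventional score 1.00 (category 1), and any non-trivial
#' profile whose log product falls below 1.01 is clamped up to 1.01 so that it
#' lands in category 2; the clamp is flagged in the result.
#'
#' @param profile A `situation_profile`.
#' @param ft A `factor_table`.
#' @param bands A `category_bands` data frame for category assignment.
#' @return An object of class `exposure_score`: a list with `situation_id`,
#'   `task`, `phase`, `raw_product`, `score` (full precision), `score_2dp`
#'   (half-up), `category`, `all_no_exposure`, `clamped`, and `breakdown` (a
#'   data frame with one row per factor: `factor_id`, `role`, `label`,
#'   `applied_score`, `log_contribution`; the divisor's log contribution is
#'   negative and the contributions sum to `log(raw_product)`).
#' @examples
#' prof <- read_profile(system.file("extdata", "worked_profile.yaml",
#'                                  package = "expoband"))
#' res <- compute_exposure_score(prof)
#' res$score_2dp    # 6.32
#' res$category     # 3
#' @export
compute_exposure_score <- function(profile, ft = default_factor_table(),
                                   bands = default_category_bands()) {
  if (!inherits(profile, "situation_profile")) {
    stop_expoband("profile must be a situation_profile")
  }
  applied <- vapply(FACTOR_IDS, function(id) {
    lookup_factor_score(ft, id, profile$selections[[id]],
                        phase = if (ft$factors[[id]]$phase_dependent)
                          profile$phase)
  }, numeric(1))
  roles <- vapply(ft$factors[FACTOR_IDS], `[[`, character(1), "role")
  log_contrib <- ifelse(roles == "divisor", -log(applied), log(applied))
  raw <- exp(sum(log_contrib))
  all_ne <- all(applied == 1)
  ln_raw <- sum(log_contrib)
  if (all_ne) {
    score <- 1.00
    clamped <- FALSE
  } else if (ln_raw < 1.01) {
    score <- 1.01
    clamped <- TRUE
  } else {
    score <- ln_raw
    clamped <- FALSE
  }
  structure(
    list(
      situation_id = profile$situation_id,
      task = profile$task,
      phase = profile$phase,
      raw_product = raw,
      score = score,
      score_2dp = round_half_up(score, 2),
      category = assign_category(score, bands),
      all_no_exposure = all_ne,
      clamped = clamped,
      breakdown = data.frame(
        factor_id = FACTOR_IDS,
        role = unname(roles),
        label = vapply(profile$selections[FACTOR_IDS], identity, character(1)),
        applied_score = unname(applied),
        log_contribution = unname(log_contrib),
        stringsAsFactors = FALSE,
        row.names = NULL
      )
    ),
    class = "exposure_score"
  )
}

#' Per-factor contribution report
#'
#' @param result An `exposure_score`.
#' @return The breakdown data frame, with an attribute `total_log` equal to
#'   the sum of log contributions (`log(raw_product)`).
#' @export
score_breakdown <- function(result) {
  if (!inherits(result, "exposure_score")) {
    stop_expoband("result must be an exposure_score")
  }
  b <- result$breakdown
  attr(b, "total_log") <- sum(b$log_contribution)
  b
}

#' Score a batch of situation profiles
#'
#' Validates every profile before computing anything (fail-fast with an
#' aggregated error report listing each offending situation); on success
#' returns one row per profile.
#'
#' @param profiles A list of `situation_profile` objects.
#' @param ft A `factor_table`.
#' @param bands A `category_bands` data frame.
#' @return A data frame with columns `situation_id`, `task`, `phase`,
#'   `raw_product`, `score` (full precision), `score_2dp`, `category`.
#' @export
score_profiles <- function(profiles, ft = default_factor_table(),
                           bands = default_category_bands()) {
  if (length(profiles) == 0) {
    return(data.frame(
      situation_id = character(), task = character(), phase = character(),
      raw_product = numeric(), score = numeric(), score_2dp = numeric(),
      category = integer(), stringsAsFactors = FALSE
    ))
  }
  results <- vector("list", length(profiles))
  errors <- character()
  for (i in seq_along(profiles)) {
    results[[i]] <- tryCatch(
      compute_exposure_score(profiles[[i]], ft, bands),
      error = function(e) {
        errors <<- c(errors, paste0(
          "[", profiles[[i]]$situation_id %||% i, "] ", conditionMessage(e)))
        NULL
      }
    )
  }
  if (length(errors)) {
    stop_expoband("invalid profile(s):\n", paste(errors, collapse = "\n"))
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      situation_id = r$situation_id, task = r$task, phase = r$phase,
      raw_product = r$raw_product, score = r$score,
      score_2dp = r$score_2dp, category = r$category,
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.exposure_score <- function(x, ...) {
  cat("<exposure_score>", x$situation_id,
      if (nzchar(x$task)) paste0("(", x$task, ")"), "\n")
  cat(sprintf("  raw product : %.6g\n", x$raw_product))
  cat(sprintf("  score       : %.2f (full precision %.6f)%s\n", x$score_2dp,
              x$score,
              if (x$clamped) "  [clamped to 1.01]" else ""))
  cat(sprintf("  category    : %d\n", x$category))
  invisible(x)
}
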