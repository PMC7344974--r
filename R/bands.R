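#' Exposure category bands
#'
#' The four exposure categories are bands of the log-transformed exposure
#' score, printed at 2 decimal places: category 1 is the single point 1.00
#' (no exposure), category 2 covers 1.01-4.76 (low), category 3 covers
#' 4.77-9.38 (medium) and category 4 covers 9.39-14.01 (high).  The upper
#' limits of bands 2 and 3 sit at 34% and 67% of the maximum attainable
#' score.
#'
#' @param path Path to a YAML band definition; `NULL` loads the packaged
#'   bands.
#' @return A data frame of class `category_bands` with columns `category`,
#'   `lower`, `upper`, `description`, `percent_of_max`.
#' @examples
#' default_category_bands()
#' @export
read_category_bands <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "category_bands.yaml", package = "expoband")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_expoband("category bands file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  bands <- do.call(rbind, lapply(raw$bands, function(b) {
    data.frame(
      category = as.integer(b$category),
      lower = as.numeric(b$lower),
      upper = as.numeric(b$upper),
      description = as.character(b$description %||% ""),
      percent_of_max = as.character(b$percent_of_max %||% ""),
      stringsAsFactors = FALSE
    )
  }))
  bands <- bands[order(bands$category), , drop = FALSE]
  if (any(bands$upper < bands$lower)) {
    stop_expoband("category bands: upper < lower")
  }
  if (nrow(bands) > 1) {
    gap <- round_half_up(bands$lower[-1] - bands$upper[-nrow(bands)], 2)
    if (any(gap != 0.01)) {
      stop_expoband("category bands must be contiguous at 2 decimals")
    }
  }
  structure(bands, class = c("category_bands", "data.frame"))
}

#' @rdname read_category_bands
#' @export
default_category_bands <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_category_bands()
    cache
  }
})

#' Assign an exposure category to a score
#'
#' The score is rounded half-up to 2 decimals (the precision at which the
#' bands are defined) and then banded by inclusive ranges.
#'
#' @param score Numeric vector of exposure scores (post-convention, so
#'   >= 1.00).
#' @param bands A `category_bands` data frame.
#' @param tol Slack beyond the top band's upper limit before a score is
#'   rejected as inconsistent with the factor table.
#' @return Integer vector of categories.
#' @examples
#' assign_category(c(1, 6.32, 10.57))
#' @export
assign_category <- function(score, bands = default_category_bands(),
                            tol = 0.005) {
  if (!is.numeric(score)) stop_expoband("score must be numeric")
  r <- round_half_up(score, 2)
  lo <- min(bands$lower)
  hi <- max(bands$upper)
  bad <- !is.na(r) & (r < lo - tol | r > hi + tol)
  if (any(bad)) {
    stop_expoband("score ", format(score[which(bad)[1]]),
                  " outside the band range [", lo, ", ", hi,
                  "]; inconsistent with the factor table")
  }
  out <- rep(NA_integer_, length(r))
  for (i in seq_len(nrow(bands))) {
    inb <- !is.na(r) &
      r >= bands$lower[i] - tol * (i == 1) &
      r <= bands$upper[i] + tol * (i == nrow(bands))
    out[is.na(out) & inb] <- bands$category[i]
  }
  out
}
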