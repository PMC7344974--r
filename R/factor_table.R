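#' The twelve modifying factors of the scoring model
#'
#' Factor identifiers in canonical order.  The first eleven enter the raw
#' score as multipliers; `room_volume` divides.
#'
#' @format Character vector of length 12.
#' @export
FACTOR_IDS <- c(
  "position_factor", "potential_emission", "historical_exposure",
  "process_type", "ventilation_containment", "localized_control",
  "ppe", "health_hazard", "task_duration", "task_frequency",
  "distance", "room_volume"
)

#' Read and validate a factor-score table
#'
#' The factor table is data, not code: a YAML file mapping each of the twelve
#' modifying factors to its defined classifications and numeric scores, so a
#' recalibration only needs a new config file.  Each classification may carry
#' `aliases` (alternative wordings that resolve to the same score) and at most
#' one per factor (one per phase for phase-dependent factors) is flagged
#' `no_exposure: true` with score 1.0.
#'
#' @param path Path to a YAML factor table. `NULL` (default) loads the
#'   packaged table.
#' @return An object of class `factor_table`: a list with `version`, `source`
#'   and `factors`, where `factors` is a named list keyed by factor id, each
#'   element holding `id`, `role` (`"multiplier"` or `"divisor"`),
#'   `phase_dependent`, and a `classifications` data frame with columns
#'   `label`, `score`, `phase`, `no_exposure`.
#' @examples
#' ft <- read_factor_table()
#' ft$factors$room_volume$classifications
#' @export
read_factor_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "factor_table.yaml", package = "expoband")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_expoband("factor table file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  factors <- lapply(raw$factors, function(f) {
    cls <- do.call(rbind, lapply(f$classifications, function(cl) {
      data.frame(
        label = as.character(cl$label),
        score = as.numeric(cl$score),
        phase = as.character(cl$phase %||% NA_character_),
        no_exposure = isTRUE(cl$no_exposure),
        stringsAsFactors = FALSE
      )
    }))
    aliases <- list()
    for (cl in f$classifications) {
      for (a in cl$aliases %||% list()) {
        aliases[[normalize_label(a)]] <- as.character(cl$label)
      }
    }
    list(
      id = as.character(f$id),
      role = as.character(f$role %||% "multiplier"),
      phase_dependent = isTRUE(f$phase_dependent),
      classifications = cls,
      aliases = aliases
    )
  })
  names(factors) <- vapply(factors, `[[`, character(1), "id")
  ft <- structure(
    list(
      version = as.character(raw$version %||% "unversioned"),
      source = as.character(raw$source %||% ""),
      factors = factors
    ),
    class = "factor_table"
  )
  validate_factor_table(ft)
  ft
}

#' @rdname read_factor_table
#' @export
default_factor_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_factor_table()
    cache
  }
})

#' Validate a factor table against the scoring-model invariants
#'
#' Checks: exactly the twelve canonical factor ids; all scores in \[1, 10\];
#' exactly one no-exposure classification (score 1.0) per factor and phase;
#' `room_volume` the only divisor; phase-dependent factors carry parallel
#' liquid/solid classification lists with identical score sets; no duplicate
#' classification labels within a factor/phase.
#'
#' @param ft A `factor_table`.
#' @return `ft`, invisibly, if valid; otherwise an error naming the offending
#'   entry.
#' @export
validate_factor_table <- function(ft) {
  ids <- names(ft$factors)
  missing <- setdiff(FACTOR_IDS, ids)
  extra <- setdiff(ids, FACTOR_IDS)
  if (length(missing)) {
    stop_expoband("factor table is missing factor(s): ",
                  paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stop_expoband("factor table has unknown factor(s): ",
                  paste(extra, collapse = ", "))
  }
  for (f in ft$factors) {
    cls <- f$classifications
    bad <- cls$score < 1 | cls$score > 10 | !is.finite(cls$score)
    if (any(bad)) {
      stop_expoband("factor '", f$id, "': score out of [1, 10] for ",
                    "classification '", cls$label[which(bad)[1]], "'")
    }
    if (!f$role %in% c("multiplier", "divisor")) {
      stop_expoband("factor '", f$id, "': role must be multiplier or divisor")
    }
    if ((f$id == "room_volume") != (f$role == "divisor")) {
      stop_expoband("room_volume must be the only divisor factor (offending: '",
                    f$id, "')")
    }
    phases <- if (f$phase_dependent) c("liquid", "solid") else NA_character_
    for (ph in phases) {
      sub <- if (is.na(ph)) cls else cls[cls$phase %in% ph, , drop = FALSE]
      if (f$phase_dependent && nrow(sub) == 0) {
        stop_expoband("factor '", f$id, "': no classifications for phase ", ph)
      }
      dup <- duplicated(normalize_label(sub$label))
      if (any(dup)) {
        stop_expoband("factor '", f$id, "': duplicate classification label '",
                      sub$label[which(dup)[1]], "'")
      }
      ne <- sub$no_exposure
      if (sum(ne) != 1L || sub$score[ne][1] != 1) {
        stop_expoband("factor '", f$id, "': needs exactly one no-exposure ",
                      "classification with score 1.0",
                      if (!is.na(ph)) paste0(" (phase ", ph, ")"))
      }
    }
    if (f$phase_dependent) {
      sl <- sort(cls$score[cls$phase %in% "liquid"])
      ss <- sort(cls$score[cls$phase %in% "solid"])
      if (!isTRUE(all.equal(sl, ss))) {
        stop_expoband("factor '", f$id, "': liquid and solid score sets differ")
      }
    }
  }
  invisible(ft)
}

#' Look up the score of a factor classification
#'
#' Labels match case-insensitively with collapsed whitespace; configured
#' aliases resolve to their canonical classification.  For phase-dependent
#' factors (`potential_emission`) the `phase` must be given.
#'
#' @param ft A `factor_table`.
#' @param factor_id One of [FACTOR_IDS].
#' @param label Classification label (or alias).
#' @param phase `"liquid"` or `"solid"`; required iff the factor is
#'   phase-dependent.
#' @return The numeric score.
#' @examples
#' lookup_factor_score(default_factor_table(), "health_hazard",
#'                     "Hazard category 2")
#' @export
lookup_factor_score <- function(ft, factor_id, label, phase = NULL) {
  f <- ft$factors[[factor_id]]
  if (is.null(f)) {
    stop_expoband("unknown factor '", factor_id, "'; valid factors: ",
                  paste(FACTOR_IDS, collapse = ", "))
  }
  if (f$phase_dependent && is.null(phase)) {
    stop_expoband("factor '", factor_id, "' is phase-dependent; ",
                  "phase ('liquid' or 'solid') is required")
  }
  cls <- f$classifications
  if (f$phase_dependent) {
    phase <- match.arg(phase, c("liquid", "solid"))
    cls <- cls[cls$phase %in% phase, , drop = FALSE]
  }
  key <- normalize_label(label)
  canon <- f$aliases[[key]]
  if (!is.null(canon)) key <- normalize_label(canon)
  hit <- which(normalize_label(cls$label) == key)
  if (length(hit) != 1L) {
    stop_expoband("factor '", factor_id, "': unknown classification '", label,
                  "'; valid labels:\n  ",
                  paste(cls$label, collapse = "\n  "))
  }
  cls$score[hit]
}

#' Maximum attainable exposure score of a factor table
#'
#' The natural log of the product of each multiplier factor's largest score
#' divided by the divisor's smallest score.  For the packaged table this is
#' the upper limit of exposure category 4.
#'
#' @param ft A `factor_table`.
#' @param phase Phase used for phase-dependent factors (irrelevant for the
#'   packaged table, whose liquid and solid score sets coincide).
#' @return The maximum ln score (unrounded).
#' @examples
#' round(max_attainable_score(default_factor_table()), 2)
#' @export
max_attainable_score <- function(ft, phase = "liquid") {
  lp <- 0
  for (f in ft$factors) {
    cls <- f$classifications
    if (f$phase_dependent) cls <- cls[cls$phase %in% phase, , drop = FALSE]
    lp <- lp + if (f$role == "divisor") -log(min(cls$score)) else
      log(max(cls$score))
  }
  lp
}

#' Enumerate every attainable raw score product
#'
#' Exhaustively enumerates the raw products reachable by any combination of
#' classifications (one per factor), reduced to unique values after each
#' factor.  All configured scores are of the form 2^a 3^b 5^c, so the set of
#' distinct products stays small even though the combination grid is huge;
#' this serves as a brute-force oracle for the score bounds.
#'
#' @inheritParams max_attainable_score
#' @return Sorted numeric vector of distinct attainable raw products.
#' @export
attainable_raw_products <- function(ft, phase = "liquid") {
  prods <- 1
  for (f in ft$factors) {
    cls <- f$classifications
    if (f$phase_dependent) cls <- cls[cls$phase %in% phase, , drop = FALSE]
    s <- unique(cls$score)
    if (f$role == "divisor") s <- 1 / s
    prods <- unique(round(as.vector(outer(prods, s)), 10))
  }
  sort(prods)
}

#' @export
print.factor_table <- function(x, ...) {
  cat("<factor_table> version", x$version, "\n")
  for (f in x$factors) {
    cat(sprintf("  %-24s %-10s %d classifications, scores {%s}\n",
                f$id, f$role, nrow(f$classifications),
                paste(sort(unique(f$classifications$score)), collapse = ", ")))
  }
  invisible(x)
}
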