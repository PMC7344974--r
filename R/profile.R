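#' Build a situation profile
#'
#' A situation profile records, for one job/task exposure situation, the
#' chosen classification of every modifying factor plus the physical phase of
#' the handled product (liquid or solid, which selects the emission-potential
#' classification list).
#'
#' @param selections Named character vector or list mapping every factor id in
#'   [FACTOR_IDS] to a classification label (aliases allowed).
#' @param phase `"liquid"` or `"solid"`.
#' @param situation_id Optional situation identifier.
#' @param task Optional free-text task label.
#' @return An object of class `situation_profile`.
#' @examples
#' prof <- read_profile(system.file("extdata", "worked_profile.yaml",
#'                                  package = "expoband"))
#' prof$selections[["room_volume"]]
#' @export
situation_profile <- function(selections, phase = c("liquid", "solid"),
                              situation_id = "", task = "") {
  phase <- match.arg(phase)
  selections <- as.list(selections)
  missing <- setdiff(FACTOR_IDS, names(selections))
  if (length(missing)) {
    stop_expoband("profile", if (nzchar(situation_id)) paste0(" '", situation_id, "'"),
                  " is missing selection(s) for: ",
                  paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(selections), FACTOR_IDS)
  if (length(extra)) {
    stop_expoband("profile", if (nzchar(situation_id)) paste0(" '", situation_id, "'"),
                  " has unknown factor(s): ", paste(extra, collapse = ", "))
  }
  structure(
    list(
      situation_id = as.character(situation_id),
      task = as.character(task),
      phase = phase,
      selections = lapply(selections[FACTOR_IDS], as.character)
    ),
    class = "situation_profile"
  )
}

#' Read a single situation profile from YAML
#'
#' The file must contain `phase` and a `selections` mapping of factor id to
#' classification label; `situation_id` and `task` are optional.
#'
#' @param path Path to a YAML profile file.
#' @return A `situation_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop_expoband("profile file not found: ", path)
  raw <- yaml::read_yaml(path)
  situation_profile(
    selections = raw$selections,
    phase = raw$phase %||% "liquid",
    situation_id = raw$situation_id %||% "",
    task = raw$task %||% ""
  )
}

#' Read a batch of situation profiles from CSV
#'
#' Expects one row per situation with columns `situation_id`, `phase`
#' (optional, default liquid), optionally `task`, and one column per factor id
#' holding the classification label.
#'
#' @param path Path to a CSV file.
#' @return A list of `situation_profile` objects (empty list for an empty
#'   file).
#' @export
read_profiles_csv <- function(path) {
  if (!file.exists(path)) stop_expoband("profile file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) return(list())
  missing <- setdiff(FACTOR_IDS, names(df))
  if (length(missing)) {
    stop_expoband("profile CSV is missing column(s): ",
                  paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    situation_profile(
      selections = as.list(df[i, FACTOR_IDS, drop = FALSE]),
      phase = if ("phase" %in% names(df)) df$phase[i] else "liquid",
      situation_id = if ("situation_id" %in% names(df)) df$situation_id[i] else
        as.character(i),
      task = if ("task" %in% names(df)) df$task[i] else ""
    )
  })
}

#' The all-no-exposure reference profile
#'
#' Every factor at its flagged no-exposure classification; scoring it yields
#' the conventional score 1.00 and category 1.
#'
#' @param ft A `factor_table`.
#' @param phase Phase for phase-dependent factors.
#' @return A `situation_profile`.
#' @export
no_exposure_profile <- function(ft = default_factor_table(),
                                phase = c("liquid", "solid")) {
  phase <- match.arg(phase)
  sel <- lapply(ft$factors, function(f) {
    cls <- f$classifications
    if (f$phase_dependent) cls <- cls[cls$phase %in% phase, , drop = FALSE]
    cls$label[cls$no_exposure][1]
  })
  situation_profile(sel, phase = phase, situation_id = "no-exposure",
                    task = "office work")
}

#' @export
print.situation_profile <- function(x, ...) {
  cat("<situation_profile>", x$situation_id,
      if (nzchar(x$task)) paste0("(", x$task, ")"), "- phase:", x$phase, "\n")
  for (id in FACTOR_IDS) {
    cat(sprintf("  %-24s %s\n", id, x$selections[[id]]))
  }
  invisible(x)
}
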