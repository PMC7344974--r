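# Shared test helpers: random profile generation and an independent direct
# evaluation of the scoring formula (used as the oracle for the compute path).

ft_default <- default_factor_table()
bands_default <- default_category_bands()

# Draw a uniformly random classification for every factor.
random_profile <- function(ft = ft_default, phase = "liquid", id = "rnd") {
  sel <- lapply(ft$factors, function(f) {
    cls <- f$classifications
    if (f$phase_dependent) cls <- cls[cls$phase %in% phase, , drop = FALSE]
    cls$label[sample.int(nrow(cls), 1)]
  })
  situation_profile(sel, phase = phase, situation_id = id)
}

# Independent direct evaluation of the scoring formula: looks scores up by
# exact label match in the classification tables and multiplies/divides,
# bypassing compute_exposure_score() internals entirely.
direct_ln_score <- function(profile, ft = ft_default) {
  lp <- 0
  for (id in FACTOR_IDS) {
    f <- ft$factors[[id]]
    cls <- f$classifications
    if (f$phase_dependent) cls <- cls[cls$phase %in% profile$phase, , drop = FALSE]
    s <- cls$score[match(profile$selections[[id]], cls$label)]
    stopifnot(length(s) == 1, !is.na(s))
    lp <- lp + if (f$role == "divisor") -log(s) else log(s)
  }
  lp
}

# Grouped fixture split used across tests.
frp_rows <- function(df) df[df$task == "FRP lamination", , drop = FALSE]
ins_rows <- function(df) df[df$task == "Inspection", , drop = FALSE]
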