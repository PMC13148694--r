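# Ground-truth parameters for the synthetic cohort, anchored to published
# calibration values for hip- and wrist-worn GT3X+ and ActTrust devices in
# young adults.

#' Published calibration reference values
#'
#' Published square-root-scale calibration coefficients (intercept `b0`,
#' slope `b1`, with 95% CI bounds) and the counts/min cut-points at the 3, 6
#' and 9 MET intensity boundaries (with 95% CI bounds) for the four
#' device-placement strata, as reported for a treadmill calibration study of
#' healthy young adults. Used as the simulator's default ground truth and as
#' the fixture for [validate_reference()].
#'
#' @return Tibble with one row per stratum, in canonical stratum order.
#' @export
reference_calibration <- function() {
  path <- system.file("extdata", "reference_calibration.csv",
                      package = "actimet", mustWork = TRUE)
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  out$stratum <- factor(out$stratum, levels = stratum_levels())
  out[order(out$stratum), ]
}

#' Ground-truth parameters for the synthetic cohort
#'
#' Collects everything the simulator treats as known truth: the per-stratum
#' square-root-scale calibration coefficients, the residual scatter of
#' sqrt(MET) around the calibration line, the resting oxygen uptake defining
#' 1 MET, the expected steady-state MET at each treadmill speed, the
#' between-participant spread of activity output, breath noise and the rate
#' of errant breaths (coughs, swallows).
#'
#' @param betas Data frame with columns `stratum`, `b0`, `b1`; defaults to
#'   the published values in [reference_calibration()].
#' @param residual_sd_sqrt_met Residual SD of sqrt(MET) about the
#'   calibration line (dimensionless; default 0.15).
#' @param resting_vo2 Oxygen uptake defining 1 MET, ml O2/kg/min
#'   (default 3.5).
#' @param met_by_speed Named numeric vector mapping treadmill speed (km/h,
#'   as character names) to expected steady-state METs.
#' @param between_subject_sdlog SD of the participant-level log-normal
#'   multiplier on activity output (default 0.15): some people move more per
#'   MET than others.
#' @param breath_noise_cv Coefficient of variation of per-breath VO2 about
#'   its instantaneous mean (default 0.08).
#' @param errant_breath_rate Probability a breath is an artefact spike
#'   (default 0.01).
#' @param onkinetics_tau Time constant (s) of the first-order VO2
#'   on-kinetics at a stage transition (default 30 s, so minute 3 onward is
#'   steady).
#' @return List of class `truth_parameters`.
#' @export
truth_parameters <- function(betas = NULL,
                             residual_sd_sqrt_met = 0.15,
                             resting_vo2 = 3.5,
                             met_by_speed = c("0" = 1, "3" = 2.5, "5" = 4,
                                              "7" = 7, "9" = 10),
                             between_subject_sdlog = 0.15,
                             breath_noise_cv = 0.08,
                             errant_breath_rate = 0.01,
                             onkinetics_tau = 30) {
  if (is.null(betas)) {
    ref <- reference_calibration()
    betas <- data.frame(stratum = as.character(ref$stratum),
                        b0 = ref$b0, b1 = ref$b1)
  }
  stopifnot(
    all(c("stratum", "b0", "b1") %in% names(betas)),
    all(betas$b1 > 0),
    residual_sd_sqrt_met >= 0,
    resting_vo2 > 0,
    errant_breath_rate >= 0, errant_breath_rate < 1,
    onkinetics_tau > 0
  )
  structure(
    list(
      betas = betas,
      residual_sd_sqrt_met = residual_sd_sqrt_met,
      resting_vo2 = resting_vo2,
      met_by_speed = met_by_speed,
      between_subject_sdlog = between_subject_sdlog,
      breath_noise_cv = breath_noise_cv,
      errant_breath_rate = errant_breath_rate,
      onkinetics_tau = onkinetics_tau
    ),
    class = "truth_parameters"
  )
}

truth_beta <- function(truth, stratum) {
  i <- match(stratum, truth$betas$stratum)
  if (is.na(i)) stop("no truth coefficients for stratum '", stratum, "'")
  c(b0 = truth$betas$b0[i], b1 = truth$betas$b1[i])
}

# Activity (counts/min) implied by the truth equation at a given MET level,
# clamped at zero where the MET level falls below the equation's intercept
# (at rest the line predicts slightly above 1 MET at zero counts).
truth_activity_at_met <- function(truth, stratum, met) {
  b <- truth_beta(truth, stratum)
  pmax(0, (sqrt(met) - b["b0"]) / b["b1"])^2
}

#' @export
print.truth_parameters <- function(x, ...) {
  cat("Ground-truth simulator parameters\n")
  cat("  residual SD of sqrt(MET):", x$residual_sd_sqrt_met, "\n")
  cat("  resting VO2 (ml/kg/min): ", x$resting_vo2, "\n")
  cat("  METs by speed:", paste(names(x$met_by_speed), "km/h =",
                                x$met_by_speed, collapse = ", "), "\n")
  cat("  errant breath rate:", x$errant_breath_rate, "\n")
  print(tibble::as_tibble(x$betas))
  invisible(x)
}
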