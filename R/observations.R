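# Observation-level simulation: steady-state observations drawn directly
# from the ground-truth calibration model, bypassing signal emulation.
#
# This is the generative model the calibration fit assumes: for each
# participant x condition x stratum row, the activity level is the
# truth-implied counts/min at the stage's MET target scaled by a
# participant-level movement factor, and the observed MET is
# (b0 + b1*sqrt(activity) + e)^2 with e ~ N(0, residual_sd_sqrt_met).
# Because rows are generated exactly from the fitted model family,
# parameter-recovery and confidence-interval coverage studies are exact by
# construction; the signal-level path (simulate_stratum_epochs etc.)
# exercises the same downstream code with device emulation in the loop.

#' Simulate steady-state observations from the ground-truth model
#'
#' Draws one (counts/min, MET) observation per participant, condition and
#' device-placement stratum directly from the ground-truth square-root-scale
#' calibration model (see the package vignette for the generative model).
#'
#' @param cohort Participant tibble from [generate_cohort()].
#' @param truth A [truth_parameters()] object.
#' @param seed Integer seed.
#' @param protocol Protocol tibble (default [treadmill_protocol()]).
#' @return Observation tibble with columns `participant`, `sex`,
#'   `condition`, `speed`, `device`, `placement`, `stratum`, `activity`
#'   (counts/min) and `met`.
#' @export
simulate_observations <- function(cohort, truth = truth_parameters(), seed,
                                  protocol = treadmill_protocol()) {
  set.seed(seed)
  strata <- truth$betas$stratum
  grid <- tidyr::expand_grid(
    participant = cohort$participant,
    condition = protocol$condition,
    stratum = strata
  )
  grid <- dplyr::left_join(grid,
                           cohort[, c("participant", "sex")],
                           by = "participant")
  grid <- dplyr::left_join(grid,
                           protocol[, c("condition", "speed")],
                           by = "condition")
  # participant-level movement factor, shared across strata and speeds
  pf <- setNames(exp(rnorm(nrow(cohort), 0, truth$between_subject_sdlog)),
                 cohort$participant)
  met_target <- truth$met_by_speed[as.character(grid$speed)]
  target <- mapply(function(s, m) truth_activity_at_met(truth, s, m),
                   grid$stratum, met_target)
  grid$activity <- target * pf[grid$participant]
  b0 <- truth$betas$b0[match(grid$stratum, truth$betas$stratum)]
  b1 <- truth$betas$b1[match(grid$stratum, truth$betas$stratum)]
  lin <- b0 + b1 * sqrt(grid$activity) +
    rnorm(nrow(grid), 0, truth$residual_sd_sqrt_met)
  grid$met <- pmax(lin, 0.05)^2
  parts <- strsplit(as.character(grid$stratum), "_", fixed = TRUE)
  grid$device <- vapply(parts, `[`, "", 1)
  grid$placement <- vapply(parts, `[`, "", 2)
  grid[, c("participant", "sex", "condition", "speed", "device",
           "placement", "stratum", "activity", "met")]
}
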