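# Breath-by-breath oxygen-uptake simulation.

#' Simulate a breath-by-breath VO2 series for one condition
#'
#' Breath times are irregular, with breathing rate rising from ~12 to
#' ~40 breaths/min with exercise intensity. Per-kg oxygen uptake rises from
#' the resting value toward the stage's target (MET target x 3.5
#' ml/kg/min) with first-order on-kinetics (time constant
#' `truth$onkinetics_tau`, transient capped at five time constants so the
#' central four minutes of a 10-minute stage are exactly steady).
#' Multiplicative Gaussian noise is applied per breath, and with probability
#' `truth$errant_breath_rate` a breath is replaced by an artefact spike
#' (2.5-4x its clean value), emulating coughs and swallows.
#'
#' @param profile One-row participant tibble with `participant` and
#'   `body_mass`.
#' @param condition One-row protocol tibble with `speed` and `duration`.
#' @param truth A [truth_parameters()] object.
#' @param seed Integer seed.
#' @return Tibble with columns `participant`, `condition`, `time_s`
#'   (strictly increasing), `vo2_ml_min` (absolute VO2) and `body_mass`;
#'   attribute `n_errant` counts injected artefact breaths.
#' @export
simulate_breaths <- function(profile, condition, truth, seed) {
  set.seed(seed)
  speed_key <- as.character(condition$speed)
  if (!speed_key %in% names(truth$met_by_speed))
    stop("no MET target for speed ", condition$speed, " km/h")
  met_target <- truth$met_by_speed[[speed_key]]
  vo2_rest <- truth$resting_vo2
  vo2_target <- met_target * 3.5
  tau <- truth$onkinetics_tau

  vo2_at <- function(t) {
    ramp <- ifelse(t >= 5 * tau, 1, 1 - exp(-t / tau))
    vo2_rest + (vo2_target - vo2_rest) * ramp
  }
  met_at <- function(t) vo2_at(t) / 3.5

  # draw breaths sequentially; rate rises with instantaneous intensity
  times <- numeric(0)
  t <- 0
  repeat {
    rate <- 12 + 2.8 * met_at(t)            # breaths/min
    gap <- 60 / rate * exp(rnorm(1, 0, 0.1))
    t <- t + gap
    if (t > condition$duration) break
    times <- c(times, t)
  }

  vo2_kg <- vo2_at(times)
  if (truth$breath_noise_cv > 0)
    vo2_kg <- vo2_kg * (1 + rnorm(length(times), 0, truth$breath_noise_cv))
  vo2_kg <- pmax(vo2_kg, 0)
  errant <- runif(length(times)) < truth$errant_breath_rate
  if (any(errant))
    vo2_kg[errant] <- vo2_kg[errant] * runif(sum(errant), 2.5, 4)

  out <- tibble::tibble(
    participant = profile$participant,
    condition = condition$condition,
    time_s = times,
    vo2_ml_min = vo2_kg * profile$body_mass,
    body_mass = profile$body_mass
  )
  attr(out, "n_errant") <- sum(errant)
  out
}
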