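# Synthetic cohort of young adults matching the calibration study's
# demographic targets.

# Sex-specific generation targets: mean (SD) of age, height, body mass for
# the young-adult reference cohort (34 men, 22 women, aged 18-35).
cohort_targets <- function() {
  tibble::tibble(
    sex = c("male", "female"),
    age_mean = c(28.3, 26.8), age_sd = c(4.6, 5.0),
    height_mean = c(172, 160), height_sd = c(6.2, 7.3),
    mass_mean = c(78.2, 59.9), mass_sd = c(11.9, 9.4)
  )
}

# Draw from N(mean, sd) truncated to [lo, hi] by rejection; deterministic
# under the caller's RNG state.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Generate a synthetic cohort of participants
#'
#' Draws participant demographics from sex-specific normal distributions
#' matching the reference cohort of healthy young adults: males with age
#' 28.3 (4.6) y, height 172 (6.2) cm, mass 78.2 (11.9) kg; females with age
#' 26.8 (5.0) y, height 160 (7.3) cm, mass 59.9 (9.4) kg. Ages are truncated
#' to the 18-35 y eligibility window, masses to > 35 kg and heights to
#' > 120 cm.
#'
#' @param n_male,n_female Number of male and female participants
#'   (non-negative; at least 2 in total).
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return Tibble with columns `participant`, `sex`, `age` (y), `height`
#'   (cm), `body_mass` (kg), `bmi` (kg/m^2), `dominant_side`.
#' @examples
#' cohort <- generate_cohort(34, 22, seed = 1)
#' table(cohort$sex)
#' @export
generate_cohort <- function(n_male, n_female, seed) {
  if (length(n_male) != 1 || is.na(n_male) || n_male < 0)
    stop("n_male must be a single non-negative count")
  if (length(n_female) != 1 || is.na(n_female) || n_female < 0)
    stop("n_female must be a single non-negative count")
  if (n_male + n_female < 2)
    stop("n_male + n_female must be at least 2")
  set.seed(seed)
  tg <- cohort_targets()
  one_sex <- function(n, sex) {
    p <- tg[tg$sex == sex, ]
    tibble::tibble(
      sex = rep(sex, n),
      age = rnorm_trunc(n, p$age_mean, p$age_sd, 18, 35),
      height = rnorm_trunc(n, p$height_mean, p$height_sd, lo = 120),
      body_mass = rnorm_trunc(n, p$mass_mean, p$mass_sd, lo = 35)
    )
  }
  out <- dplyr::bind_rows(one_sex(n_male, "male"), one_sex(n_female, "female"))
  out$participant <- sprintf("P%03d", seq_len(nrow(out)))
  out$bmi <- out$body_mass / (out$height / 100)^2
  out$dominant_side <- ifelse(runif(nrow(out)) < 0.9, "right", "left")
  out[, c("participant", "sex", "age", "height", "body_mass", "bmi",
          "dominant_side")]
}
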