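# Preprocessing: from breath and epoch streams to the regression's unit of
# analysis, one (mean counts/min, mean MET) row per participant x condition
# x device-placement stratum.

#' Remove errant breaths by the 3-SD four-neighbour rule
#'
#' A breath is errant when it deviates from its local reference by more than
#' three standard deviations, the reference being the mean of the two
#' preceding and two following breaths. The rule is applied in a single pass
#' over the original series: removed breaths still serve as reference values
#' for their neighbours, and the first two and last two breaths (which lack
#' a full reference window) are always retained. When the four reference
#' values are identical (local SD zero), any deviation from them is errant.
#'
#' @param series Breath tibble with column `vo2_ml_min` (any other columns
#'   are carried through).
#' @param sd_multiplier Deviation threshold in local SDs (default 3).
#' @return The series with errant breaths removed; attributes `n_removed`
#'   (count) and `flagged` (TRUE when the series was too short to clean).
#'   Series with fewer than 5 breaths are returned unchanged with a warning.
#' @export
clean_breaths <- function(series, sd_multiplier = 3) {
  stopifnot("vo2_ml_min" %in% names(series))
  v <- series$vo2_ml_min
  n <- length(v)
  if (n < 5) {
    warning("fewer than 5 breaths; series returned unchanged")
    attr(series, "n_removed") <- 0L
    attr(series, "flagged") <- TRUE
    return(series)
  }
  drop <- rep(FALSE, n)
  for (i in 3:(n - 2)) {
    ref <- v[c(i - 2, i - 1, i + 1, i + 2)]
    drop[i] <- abs(v[i] - mean(ref)) > sd_multiplier * sd(ref)
  }
  out <- series[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  attr(out, "flagged") <- FALSE
  out
}

#' Central four-minute steady-state window of a 10-minute stage
#'
#' @param condition_start Stage start time, s.
#' @param duration Stage duration, s; must be 600 (protocol violation
#'   otherwise).
#' @return Numeric `c(start, end)`: the half-open interval
#'   `[start + 180, start + 420)`.
#' @export
central_window <- function(condition_start, duration = 600) {
  if (!isTRUE(all.equal(duration, 600)))
    stop("central_window is defined for 600 s stages, got ", duration)
  c(condition_start + 180, condition_start + 420)
}

#' Convert per-kg oxygen uptake to METs
#'
#' One MET is a resting oxygen uptake of 3.5 ml O2/kg/min.
#'
#' @param vo2_per_kg Oxygen uptake, ml O2/kg/min (non-negative).
#' @return METs.
#' @export
vo2_to_met <- function(vo2_per_kg) {
  if (any(vo2_per_kg < 0)) stop("vo2_per_kg must be non-negative")
  vo2_per_kg / 3.5
}

#' Steady-state MET over a window of a breath series
#'
#' Averages per-breath VO2/kg over the breaths falling inside the window and
#' converts to METs. Breath-by-breath sampling is irregular, so the default
#' is a time-weighted mean, each breath weighted by the interval since the
#' previous breath (clipped to the window start for the first in-window
#' breath); a simple mean is available via `weighting = "simple"`.
#'
#' @param series Breath tibble with `time_s`, `vo2_ml_min`, `body_mass`.
#' @param window Numeric `c(start, end)`, half-open.
#' @param weighting "time" (default) or "simple".
#' @return Mean METs over the window, or `NA` when no breath falls inside
#'   (missing-observation marker).
#' @export
steady_state_met <- function(series, window, weighting = c("time", "simple")) {
  weighting <- match.arg(weighting)
  inside <- series$time_s >= window[1] & series$time_s < window[2]
  if (!any(inside)) return(NA_real_)
  t_in <- series$time_s[inside]
  vo2_kg <- series$vo2_ml_min[inside] / series$body_mass[inside]
  if (weighting == "simple") return(vo2_to_met(mean(vo2_kg)))
  prev <- c(window[1], head(t_in, -1))
  w <- t_in - prev
  if (all(w == 0)) w <- rep(1, length(w))
  vo2_to_met(sum(vo2_kg * w) / sum(w))
}

#' Steady-state counts/min over a window of an epoch series
#'
#' Partitions the four-minute window into four 60-second minutes, sums the
#' sixty 1-second epochs of each minute, and returns the mean of the four
#' per-minute totals. A minute missing at most 5% of its epochs is rescaled
#' to a full minute; more missingness yields `NA` (missing-observation
#' marker).
#'
#' @param series Epoch tibble with `time` (epoch start, s) and `counts`.
#' @param window Numeric `c(start, end)`, half-open, length 240 s.
#' @return Mean counts/min over the window, or `NA`.
#' @export
steady_state_counts <- function(series, window) {
  stopifnot(isTRUE(all.equal(diff(window), 240)))
  inside <- series$time >= window[1] & series$time < window[2]
  sub <- series[inside, ]
  n_expected <- 240
  if (nrow(sub) < n_expected * 0.95) return(NA_real_)
  minute <- floor((sub$time - window[1]) / 60)
  per_min <- tapply(sub$counts, minute, sum)
  n_per_min <- tapply(sub$counts, minute, length)
  if (length(per_min) < 4 || any(n_per_min < 57)) return(NA_real_)
  per_min <- per_min * 60 / n_per_min   # rescale partial minutes
  mean(per_min)
}

#' Assemble the steady-state observation table
#'
#' Reduces cleaned breath series and epoch series to one row per
#' participant, condition and device-placement stratum, holding the mean
#' counts/min and mean MET over the central four minutes of each stage.
#' Rows with either mean missing are dropped and counted in the
#' `exclusions` attribute (no silent data loss: rows in = rows out +
#' exclusions).
#'
#' @param breaths Breath tibble (stacked across participants/conditions)
#'   with `participant`, `condition`, `time_s`, `vo2_ml_min`, `body_mass`;
#'   times are stage-elapsed seconds.
#' @param epochs Epoch tibble (stacked) with `participant`, `condition`,
#'   `device`, `placement`, `time`, `counts`; times are stage-elapsed.
#' @param protocol Protocol tibble (default [treadmill_protocol()]).
#' @param cohort Participant tibble carrying `sex`.
#' @param clean Apply [clean_breaths()] per participant x condition first
#'   (default TRUE).
#' @return Observation tibble (`participant`, `sex`, `condition`, `speed`,
#'   `device`, `placement`, `stratum`, `activity`, `met`) with attributes
#'   `exclusions` (tibble of dropped keys) and `n_breaths_removed`.
#' @export
build_observation_table <- function(breaths, epochs,
                                    protocol = treadmill_protocol(),
                                    cohort, clean = TRUE) {
  win <- central_window(0, 600)  # stage-elapsed times

  n_removed <- 0L
  met_tab <- breaths |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      if (clean && nrow(df) >= 5) {
        df <- clean_breaths(df)
        n_removed <<- n_removed + attr(df, "n_removed")
      }
      tibble::tibble(met = steady_state_met(df, win))
    }) |>
    dplyr::ungroup()

  act_tab <- epochs |>
    dplyr::group_by(.data$participant, .data$condition, .data$device,
                    .data$placement) |>
    dplyr::summarise(
      activity = steady_state_counts(dplyr::pick("time", "counts"), win),
      .groups = "drop"
    )

  if (anyDuplicated(epochs[, c("participant", "condition", "device",
                               "placement", "time")]) > 0)
    stop("duplicate participant x condition x stratum epoch series")

  # complete against the expected design so absent series are logged, not
  # silently dropped
  grid <- tidyr::expand_grid(
    participant = cohort$participant,
    condition = intersect(protocol$condition, unique(epochs$condition)),
    dplyr::distinct(epochs[, c("device", "placement")])
  )
  tab <- grid |>
    dplyr::left_join(act_tab,
                     by = c("participant", "condition", "device",
                            "placement")) |>
    dplyr::left_join(met_tab, by = c("participant", "condition")) |>
    dplyr::left_join(protocol[, c("condition", "speed")], by = "condition") |>
    dplyr::left_join(cohort[, c("participant", "sex")], by = "participant") |>
    dplyr::mutate(stratum = paste(.data$device, .data$placement, sep = "_"))

  missing <- is.na(tab$activity) | is.na(tab$met)
  excl <- tab[missing, c("participant", "condition", "device", "placement")]
  excl$reason <- ifelse(is.na(tab$activity[missing]), "missing_counts",
                        "missing_met")
  out <- tab[!missing, c("participant", "sex", "condition", "speed",
                         "device", "placement", "stratum", "activity",
                         "met")]
  attr(out, "exclusions") <- excl
  attr(out, "n_breaths_removed") <- n_removed
  out
}
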