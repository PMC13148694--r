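# Raw-signal simulation and device count emulation.
#
# The gait model is deliberately simple: a sum of sinusoidal harmonics at a
# step frequency that rises with treadmill speed, with amplitude rising with
# speed and scaled differently at the wrist than at the hip, plus additive
# Gaussian sensor noise, clipped to the device's dynamic range. Only the
# epoch-count statistics matter downstream, not waveform realism.

#' Simulate a raw tri-axial acceleration series
#'
#' Produces a gait-like acceleration signal for one participant, condition
#' and device: harmonics at a speed-dependent step frequency on three axes
#' (vertical axis carries a 1 g gravity offset), Gaussian sensor noise, and
#' clipping to the device's dynamic range.
#'
#' @param profile One-row participant tibble (see [generate_cohort()]).
#' @param condition One-row protocol tibble with `speed` (km/h) and
#'   `duration` (s).
#' @param spec A [device_spec()].
#' @param seed Integer seed.
#' @param amplitude Peak fundamental amplitude in g of the vertical axis.
#'   Default rises linearly with speed (0.05 g per km/h at the hip, 1.6x at
#'   the wrist); [calibrate_amplitude()] chooses it to hit a target count
#'   level instead.
#' @param noise_sd Sensor noise SD in g per axis (default 0.02).
#' @return Object of class `raw_acceleration`: list with `spec`, `time`
#'   (s), `xyz` (n x 3 matrix, g).
#' @export
simulate_raw_acceleration <- function(profile, condition, spec, seed,
                                      amplitude = NULL, noise_sd = 0.02) {
  stopifnot(condition$speed >= 0, condition$duration > 0)
  set.seed(seed)
  fs <- spec$sampling_rate
  n <- round(condition$duration * fs)
  t <- (seq_len(n) - 1) / fs
  speed <- condition$speed
  if (is.null(amplitude)) {
    amplitude <- 0.05 * speed * if (spec$placement == "wrist") 1.6 else 1
  }
  f_step <- if (speed > 0) 1.1 + 0.13 * speed else 0
  axis_weight <- c(1, 0.6, 0.45)      # vertical, antero-posterior, lateral
  gravity <- c(1, 0, 0)
  phase <- runif(9, 0, 2 * pi)
  xyz <- matrix(0, n, 3)
  for (k in 1:3) {
    sig <- 0
    if (amplitude > 0 && f_step > 0) {
      sig <- amplitude * axis_weight[k] *
        (sin(2 * pi * f_step * t + phase[3 * k - 2]) +
           0.35 * sin(4 * pi * f_step * t + phase[3 * k - 1]) +
           0.15 * sin(6 * pi * f_step * t + phase[3 * k]))
    }
    xyz[, k] <- sig + gravity[k] + rnorm(n, 0, noise_sd)
  }
  xyz <- clip_to_range(xyz, spec)
  structure(list(spec = spec, time = t, xyz = xyz),
            class = "raw_acceleration")
}

# Band-pass a tri-axial matrix with the device's 4th-order zero-phase
# Butterworth (order-2 design applied forward and backward). The per-axis
# mean (gravity component) is removed first so the filter sees a zero-mean
# signal and contributes no startup transient.
band_pass_filter <- function(xyz, spec) {
  fs <- spec$sampling_rate
  bf <- signal::butter(2, spec$band_pass / (fs / 2), type = "pass")
  xyz <- sweep(xyz, 2, colMeans(xyz))
  apply(xyz, 2, function(col) signal::filtfilt(bf, col))
}

#' Emulate epoch counts from a raw acceleration series
#'
#' Applies the device's band-pass filter per axis, then integrates into
#' 1-second epochs in the device's count mode. PIM (ActTrust): the rectified
#' filtered norm is integrated over each epoch. VM (GT3X+): each axis is
#' rectified and integrated per epoch, then the Euclidean norm of the three
#' per-axis sums is taken. A fixed per-device scaling constant
#' (`spec$count_scale`, counts per g.s) puts the result on the scale the
#' device family reports.
#'
#' @param raw A `raw_acceleration` object.
#' @return Tibble with columns `time` (epoch start, s) and `counts`
#'   (non-negative), with the device spec attached as attribute `spec`.
#' @export
emulate_counts <- function(raw) {
  stopifnot(inherits(raw, "raw_acceleration"))
  spec <- raw$spec
  fs <- spec$sampling_rate
  n_epochs <- floor(nrow(raw$xyz) / fs)
  if (n_epochs < 1)
    stop("raw series shorter than one full epoch (", fs, " samples)")
  filt <- band_pass_filter(raw$xyz, spec)
  idx <- seq_len(n_epochs * fs)
  g <- rep(seq_len(n_epochs), each = fs)
  if (spec$count_mode == "PIM") {
    nrm <- sqrt(rowSums(filt[idx, , drop = FALSE]^2))
    counts <- as.numeric(tapply(nrm, g, sum)) / fs * spec$count_scale
  } else {
    ax <- vapply(1:3, function(k) {
      as.numeric(tapply(abs(filt[idx, k]), g, sum)) / fs
    }, numeric(n_epochs))
    counts <- sqrt(rowSums(ax^2)) * spec$count_scale
  }
  out <- tibble::tibble(time = seq_len(n_epochs) - 1, counts = counts)
  attr(out, "spec") <- spec
  out
}

# Cache of amplitude calibrations within a session.
.amplitude_cache <- new.env(parent = emptyenv())

#' Amplitude needed to hit a target mean count level
#'
#' Finds, by monotone root search on a noiseless probe signal, the gait
#' amplitude at which [emulate_counts()] produces a given mean counts/min
#' for a device and speed. Used by the dataset writer to place synthetic
#' counts at the activity level the ground-truth calibration implies for
#' each stage.
#'
#' @param spec A [device_spec()].
#' @param speed Treadmill speed, km/h (> 0; at rest the amplitude is 0).
#' @param target_cpm Target mean counts/min.
#' @param probe_duration Probe length in seconds (default 30).
#' @return Amplitude in g.
#' @export
calibrate_amplitude <- function(spec, speed, target_cpm,
                                probe_duration = 30) {
  if (speed <= 0 || target_cpm <= 0) return(0)
  key <- paste(spec$stratum, speed, signif(target_cpm, 6), sep = "|")
  hit <- .amplitude_cache[[key]]
  if (!is.null(hit)) return(hit)
  probe_profile <- tibble::tibble(participant = "probe")
  probe_cond <- tibble::tibble(speed = speed, duration = probe_duration)
  cpm_at <- function(a) {
    raw <- simulate_raw_acceleration(probe_profile, probe_cond, spec,
                                     seed = 1, amplitude = a, noise_sd = 0)
    mean(emulate_counts(raw)$counts) * 60
  }
  f <- function(loga) cpm_at(10^loga) - target_cpm
  sol <- stats::uniroot(f, lower = -4, upper = log10(3), extendInt = "upX",
                        tol = 1e-4)
  a <- 10^sol$root
  .amplitude_cache[[key]] <- a
  a
}

#' Simulate a device epoch series for one participant and condition
#'
#' High-level wrapper around [simulate_raw_acceleration()] and
#' [emulate_counts()]: the gait amplitude is calibrated so the expected
#' counts/min equal the activity level the ground-truth calibration implies
#' at the stage's MET target, scaled by a participant-level movement factor.
#'
#' @param profile One-row participant tibble.
#' @param condition One-row protocol tibble.
#' @param spec A [device_spec()].
#' @param truth A [truth_parameters()] object.
#' @param seed Integer seed.
#' @param participant_factor Multiplier on the participant's movement
#'   amplitude (default 1).
#' @param noise_sd Sensor noise SD in g (default 0.02).
#' @return Epoch tibble with columns `participant`, `condition`, `device`,
#'   `placement`, `mode`, `time`, `counts`.
#' @export
simulate_stratum_epochs <- function(profile, condition, spec, truth, seed,
                                    participant_factor = 1,
                                    noise_sd = 0.02) {
  met <- truth$met_by_speed[[as.character(condition$speed)]]
  target <- truth_activity_at_met(truth, spec$stratum, met)
  amp <- calibrate_amplitude(spec, condition$speed, target) *
    participant_factor
  raw <- simulate_raw_acceleration(profile, condition, spec, seed,
                                   amplitude = amp, noise_sd = noise_sd)
  counts <- emulate_counts(raw)
  tibble::tibble(
    participant = profile$participant,
    condition = condition$condition,
    device = spec$device,
    placement = spec$placement,
    mode = spec$count_mode,
    time = counts$time,
    counts = counts$counts
  )
}
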