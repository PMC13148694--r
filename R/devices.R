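# Device specifications and the treadmill protocol.

#' Device specification for count emulation
#'
#' Returns the acquisition parameters the simulator uses to emulate a
#' device-placement stratum: sampling rate, dynamic range, band-pass corner
#' frequencies, count mode and epoch length. The GT3X+ samples at 30 Hz over
#' +/- 6 g, band-passes at 0.25-2.5 Hz and reports vector-magnitude (VM)
#' counts; the ActTrust samples at 25 Hz over 0.03-4 g, band-passes at
#' 0.5-2.7 Hz and reports proportional-integration-mode (PIM) counts. Both
#' are integrated into 1-second epochs.
#'
#' @param device "GT3X" or "ACTT".
#' @param placement "hip" or "wrist".
#' @return A list of class `device_spec` with fields `device`, `placement`,
#'   `stratum`, `sampling_rate` (Hz), `range_min`/`range_max` (g, per-axis
#'   magnitude bounds), `band_pass` (length-2 Hz), `count_mode` ("VM" or
#'   "PIM"), `epoch` (s) and `count_scale` (counts per g.s, a fixed
#'   emulation constant).
#' @export
device_spec <- function(device = c("GT3X", "ACTT"),
                        placement = c("hip", "wrist")) {
  device <- match.arg(device)
  placement <- match.arg(placement)
  spec <- if (device == "GT3X") {
    list(
      device = "GT3X", sampling_rate = 30, range_min = 0, range_max = 6,
      band_pass = c(0.25, 2.5), count_mode = "VM",
      # counts per g.s; fixed emulation constant placing synthetic counts on
      # the scale the device family reports (hundreds of counts/min walking,
      # thousands running)
      count_scale = 320
    )
  } else {
    list(
      device = "ACTT", sampling_rate = 25, range_min = 0.03, range_max = 4,
      band_pass = c(0.5, 2.7), count_mode = "PIM",
      count_scale = 1500
    )
  }
  spec$placement <- placement
  spec$stratum <- stratum_label(device, placement)
  spec$epoch <- 1
  stopifnot(spec$band_pass[1] < spec$band_pass[2])
  structure(spec, class = "device_spec")
}

#' All four device-placement specifications
#'
#' @return Named list of [device_spec()] objects in canonical stratum order.
#' @export
all_device_specs <- function() {
  out <- lapply(stratum_levels(), function(s) {
    parts <- strsplit(s, "_", fixed = TRUE)[[1]]
    device_spec(parts[1], parts[2])
  })
  setNames(out, stratum_levels())
}

#' Progressive treadmill protocol
#'
#' Five 10-minute conditions at increasing treadmill speed (rest, walking at
#' 3 and 5 km/h, walking-or-running at 7 km/h, running at 9 km/h),
#' interspersed with 5-minute rest periods.
#'
#' @return Tibble with columns `condition`, `speed` (km/h), `duration` (s),
#'   `rest_after` (s) and `start` (s, protocol-elapsed start time of each
#'   condition).
#' @export
treadmill_protocol <- function() {
  cond <- tibble::tibble(
    condition = c("rest", "walk3", "walk5", "run7", "run9"),
    speed = c(0, 3, 5, 7, 9),
    duration = 600,
    rest_after = 300
  )
  cond$start <- cumsum(dplyr::lag(cond$duration + cond$rest_after,
                                  default = 0))
  cond
}

# Clip a tri-axial acceleration matrix to a device's per-axis dynamic range:
# magnitudes above range_max saturate, magnitudes below range_min (the
# device's detection floor) read as zero.
clip_to_range <- function(xyz, spec) {
  s <- sign(xyz)
  mag <- abs(xyz)
  mag[mag > spec$range_max] <- spec$range_max
  mag[mag < spec$range_min] <- 0
  s * mag
}
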