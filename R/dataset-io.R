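# Plain-CSV dataset writing and reading. Every inter-stage file is CSV with
# a header row; the truth-parameter sidecar is YAML.

iso_timestamps <- function(elapsed_s, origin = "2022-06-01 08:00:00") {
  format(as.POSIXct(origin, tz = "UTC") + elapsed_s,
         "%Y-%m-%dT%H:%M:%SZ")
}

#' Write a full synthetic cohort dataset to disk
#'
#' Simulates and writes, per participant and condition: one epoch CSV per
#' device-placement stratum (columns `timestamp` ISO-8601 at 1-s spacing,
#' `counts`, `device`, `placement`, `mode`) and one breath CSV (columns
#' `time_s`, `vo2_ml_min`), plus a participant metadata CSV (`id`, `sex`,
#' `age`, `height_cm`, `mass_kg`), a YAML sidecar of the ground-truth
#' parameters (for parameter-recovery tests), and a manifest CSV listing
#' every file with its MD5 checksum.
#'
#' Counts come from the full signal path ([simulate_stratum_epochs()]);
#' METs driving the breath series are drawn from the ground-truth
#' calibration at each participant's own activity level, so the written
#' dataset carries the truth model end to end.
#'
#' @param cohort Participant tibble from [generate_cohort()].
#' @param truth A [truth_parameters()] object.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param protocol Protocol tibble (default [treadmill_protocol()]).
#' @return Manifest tibble (`file`, `md5`), invisibly; also written as
#'   `manifest.csv`.
#' @export
write_cohort_dataset <- function(cohort, truth, out_dir, seed,
                                 protocol = treadmill_protocol()) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir)
  specs <- all_device_specs()
  files <- character(0)
  set.seed(seed)
  pf <- setNames(exp(rnorm(nrow(cohort), 0, truth$between_subject_sdlog)),
                 cohort$participant)
  seeds <- matrix(sample.int(.Machine$integer.max / 2,
                             nrow(cohort) * nrow(protocol) * 5),
                  nrow = nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    prof <- cohort[i, ]
    for (j in seq_len(nrow(protocol))) {
      cond <- protocol[j, ]
      base <- sprintf("%s_%s", prof$participant, cond$condition)
      # participant-specific MET target: the truth line evaluated at this
      # participant's activity level in the reference stratum
      ref_target <- truth_activity_at_met(
        truth, "GT3X_hip", truth$met_by_speed[[as.character(cond$speed)]])
      b <- truth_beta(truth, "GT3X_hip")
      met_p <- max(0.5, (b["b0"] + b["b1"] *
                           sqrt(ref_target * pf[prof$participant]))^2)
      truth_p <- truth
      truth_p$met_by_speed[[as.character(cond$speed)]] <- met_p
      br <- simulate_breaths(prof, cond, truth_p,
                             seed = seeds[i, (j - 1) * 5 + 1])
      f <- file.path(out_dir, paste0(base, "_breaths.csv"))
      write.csv(br[, c("time_s", "vo2_ml_min")], f, row.names = FALSE)
      files <- c(files, f)
      for (k in seq_along(specs)) {
        ep <- simulate_stratum_epochs(prof, cond, specs[[k]], truth,
                                      seed = seeds[i, (j - 1) * 5 + 1 + k],
                                      participant_factor =
                                        pf[prof$participant])
        out <- tibble::tibble(
          timestamp = iso_timestamps(cond$start + ep$time),
          counts = ep$counts,
          device = ep$device, placement = ep$placement, mode = ep$mode
        )
        f <- file.path(out_dir,
                       paste0(base, "_", names(specs)[k], "_epochs.csv"))
        write.csv(out, f, row.names = FALSE)
        files <- c(files, f)
      }
    }
  }
  meta <- tibble::tibble(
    id = cohort$participant, sex = cohort$sex, age = cohort$age,
    height_cm = cohort$height, mass_kg = cohort$body_mass
  )
  f <- file.path(out_dir, "participants.csv")
  write.csv(meta, f, row.names = FALSE)
  files <- c(files, f)
  truth_list <- unclass(truth)
  truth_list$met_by_speed <- as.list(truth_list$met_by_speed)
  truth_list$betas <- as.list(as.data.frame(truth_list$betas))
  f <- file.path(out_dir, "truth_parameters.yml")
  yaml::write_yaml(truth_list, f)
  files <- c(files, f)
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort dataset written by [write_cohort_dataset()]
#'
#' @param dir Dataset directory.
#' @param protocol Protocol tibble used when writing.
#' @return List with `breaths` (stacked breath tibble, stage-elapsed
#'   times), `epochs` (stacked epoch tibble, stage-elapsed times), `cohort`
#'   (metadata tibble with `participant`, `sex`, `body_mass`), and `truth`
#'   (the sidecar, as [truth_parameters()]).
#' @export
read_cohort_dataset <- function(dir, protocol = treadmill_protocol()) {
  meta <- tibble::as_tibble(read.csv(file.path(dir, "participants.csv"),
                                     stringsAsFactors = FALSE))
  cohort <- tibble::tibble(participant = meta$id, sex = meta$sex,
                           age = meta$age, height = meta$height_cm,
                           body_mass = meta$mass_kg)
  breath_files <- list.files(dir, "_breaths\\.csv$", full.names = TRUE)
  breaths <- dplyr::bind_rows(lapply(breath_files, function(f) {
    key <- sub("_breaths\\.csv$", "", basename(f))
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    d <- tibble::as_tibble(read.csv(f))
    d$participant <- parts[1]
    d$condition <- parts[2]
    d
  }))
  breaths <- dplyr::left_join(
    breaths, cohort[, c("participant", "body_mass")], by = "participant")
  epoch_files <- list.files(dir, "_epochs\\.csv$", full.names = TRUE)
  epochs <- dplyr::bind_rows(lapply(epoch_files, function(f) {
    d <- tibble::as_tibble(read.csv(f, stringsAsFactors = FALSE))
    key <- sub("_epochs\\.csv$", "", basename(f))
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    d$participant <- parts[1]
    d$condition <- parts[2]
    start <- protocol$start[match(parts[2], protocol$condition)]
    t_abs <- as.numeric(as.POSIXct(d$timestamp,
                                   format = "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC"))
    d$time <- t_abs - t_abs[1] + 0  # stage-elapsed seconds
    d[, c("participant", "condition", "device", "placement", "mode",
          "time", "counts")]
  }))
  truth_raw <- yaml::read_yaml(file.path(dir, "truth_parameters.yml"))
  truth <- truth_parameters(
    betas = as.data.frame(truth_raw$betas),
    residual_sd_sqrt_met = truth_raw$residual_sd_sqrt_met,
    resting_vo2 = truth_raw$resting_vo2,
    met_by_speed = unlist(truth_raw$met_by_speed),
    between_subject_sdlog = truth_raw$between_subject_sdlog,
    breath_noise_cv = truth_raw$breath_noise_cv,
    errant_breath_rate = truth_raw$errant_breath_rate,
    onkinetics_tau = truth_raw$onkinetics_tau
  )
  list(breaths = breaths, epochs = epochs, cohort = cohort, truth = truth)
}
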