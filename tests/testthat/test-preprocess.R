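# Breath cleaning, steady-state windows, observation assembly.

test_that("breath cleaning removes an isolated spike and keeps edges", {
  base <- rep(10, 11)
  base[c(2, 4, 7, 9)] <- base[c(2, 4, 7, 9)] + 0.1  # give flanks SD > 0
  spiked <- base
  spiked[6] <- 50
  out <- clean_breaths(breath_fixture(spiked))
  expect_false(50 %in% out$vo2_ml_min)
  expect_equal(attr(out, "n_removed"), 1L)

  constant <- clean_breaths(breath_fixture(rep(7, 10)))
  expect_equal(nrow(constant), 10)

  # zero local SD: any deviation from a perfectly constant neighbourhood is
  # errant
  v <- c(5, 5, 5.1, 5, 5, 5, 5)
  out2 <- clean_breaths(breath_fixture(v))
  expect_false(5.1 %in% out2$vo2_ml_min)
})

test_that("short series are returned unchanged with a warning", {
  four <- breath_fixture(c(1, 2, 3, 4))
  expect_warning(out <- clean_breaths(four), "fewer than 5")
  expect_equal(nrow(out), 4)
  expect_true(attr(out, "flagged"))
})

test_that("cleaning agrees with a brute-force oracle on random series", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    v <- rnorm(n, 10, 1)
    idx <- sample(n, rbinom(1, 3, 0.5))
    v[idx] <- v[idx] * runif(length(idx), 2, 5)
    got <- clean_breaths(breath_fixture(v, times = seq_len(n)))
    expect_identical(got$vo2_ml_min, clean_breaths_oracle(v))
  }
})

test_that("cleaning is idempotent on series without cascading outliers", {
  v <- rep(c(10, 10.1), 25)
  v[25] <- 30
  once <- clean_breaths(breath_fixture(v))
  expect_equal(attr(once, "n_removed"), 1L)
  twice <- clean_breaths(once)
  expect_identical(once$vo2_ml_min, twice$vo2_ml_min)
})

test_that("central window is the middle four minutes of a 600 s stage", {
  expect_equal(central_window(0), c(180, 420))
  expect_equal(central_window(1000), c(1180, 1420))
  expect_error(central_window(0, duration = 300), "600")
})

test_that("VO2 converts to METs by the 3.5 ml/kg/min convention", {
  expect_equal(vo2_to_met(3.5), 1)
  expect_equal(vo2_to_met(0), 0)
  expect_equal(vo2_to_met(35), 10)
  expect_error(vo2_to_met(-1), "non-negative")
})

test_that("steady-state MET averages per-breath VO2 over the window", {
  br <- breath_fixture(rep(7 * 70, 100), times = seq(150, 450, length = 100))
  expect_equal(steady_state_met(br, c(180, 420)), 2)

  two <- breath_fixture(c(3.5, 10.5) * 70, times = c(200, 210))
  expect_equal(steady_state_met(two, c(190, 420)), 2)

  empty <- breath_fixture(c(1, 2), times = c(10, 20))
  expect_true(is.na(steady_state_met(empty, c(180, 420))))
})

test_that("steady-state counts are per-minute sums averaged over minutes", {
  ep <- function(counts) tibble::tibble(time = seq_along(counts) - 1 + 180,
                                        counts = counts)
  expect_equal(steady_state_counts(ep(rep(10, 240)), c(180, 420)), 600)
  expect_equal(steady_state_counts(ep(rep(0, 240)), c(180, 420)), 0)
  expect_equal(steady_state_counts(ep(rep(c(0, 20), 120)), c(180, 420)), 600)
})

test_that("steady-state counts tolerate small gaps and reject large ones", {
  full <- tibble::tibble(time = 180:419, counts = rep(10, 240))
  # drop 4 epochs (1.7%): each minute rescaled, value unchanged
  gap <- full[-c(5, 70, 130, 200), ]
  expect_equal(steady_state_counts(gap, c(180, 420)), 600)
  # drop 20 epochs (8.3%): missing-observation marker
  big_gap <- full[-(1:20), ]
  expect_true(is.na(steady_state_counts(big_gap, c(180, 420))))
})

test_that("steady-state counts are permutation-invariant within minutes and
           scale linearly", {
  set.seed(3)
  counts <- rpois(240, 8)
  base <- tibble::tibble(time = 180:419, counts = counts)
  perm <- base
  for (m in 0:3) {
    i <- which(floor((base$time - 180) / 60) == m)
    perm$counts[i] <- sample(base$counts[i])
  }
  expect_equal(steady_state_counts(perm, c(180, 420)),
               steady_state_counts(base, c(180, 420)))
  scaled <- base
  scaled$counts <- scaled$counts * 3.7
  expect_equal(steady_state_counts(scaled, c(180, 420)),
               3.7 * steady_state_counts(base, c(180, 420)))
})

test_that("observation table covers the design and accounts for all rows", {
  cohort <- generate_cohort(1, 1, seed = 5)
  truth <- truth_parameters()
  dir <- withr::local_tempdir()
  write_cohort_dataset(cohort, truth, dir, seed = 5)
  ds <- read_cohort_dataset(dir)
  tab <- build_observation_table(ds$breaths, ds$epochs, cohort = ds$cohort)
  expect_equal(nrow(tab), 2 * 5 * 4)
  expect_equal(nrow(attr(tab, "exclusions")), 0)
  expect_equal(anyDuplicated(tab[, c("participant", "condition",
                                     "stratum")]), 0)

  # removing one epoch series loses exactly one row, and it is logged
  drop_i <- with(ds$epochs, participant == "P001" & condition == "walk5" &
                   device == "GT3X" & placement == "hip")
  epochs2 <- ds$epochs[!drop_i, ]
  tab2 <- build_observation_table(ds$breaths, epochs2, cohort = ds$cohort)
  expect_equal(nrow(tab2), 39)
  excl <- attr(tab2, "exclusions")
  expect_equal(nrow(excl), 1)
  expect_equal(excl$reason, "missing_counts")

  # duplicated stratum series is a data-integrity error
  dup <- dplyr::bind_rows(ds$epochs, ds$epochs[1:600, ])
  expect_error(build_observation_table(ds$breaths, dup,
                                       cohort = ds$cohort),
               "duplicate")
})

test_that("zero-noise simulator round-trips MET targets exactly", {
  truth <- truth_parameters(breath_noise_cv = 0, errant_breath_rate = 0)
  profile <- tibble::tibble(participant = "P001", body_mass = 60)
  for (speed in c(0, 5, 9)) {
    cond <- tibble::tibble(condition = "c", speed = speed, duration = 600)
    br <- simulate_breaths(profile, cond, truth, seed = 3)
    expect_equal(steady_state_met(br, central_window(0)),
                 truth$met_by_speed[[as.character(speed)]],
                 tolerance = 1e-12)
  }
})
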