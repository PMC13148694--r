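# Shared fixture builders for the test suite.

# A random stratum equation with positive slope, on the scale of published
# calibration coefficients.
random_equation <- function() {
  make_stratum_equation(
    b0 = runif(1, 0.5, 1.5),
    b1 = runif(1, 0.005, 0.03),
    device = sample(c("GT3X", "ACTT"), 1),
    placement = sample(c("hip", "wrist"), 1)
  )
}

# A random observation fixture covering all four strata, suitable for
# fit_calibration (n rows total, >= 12).
random_obs_fixture <- function(n = 40) {
  n <- max(n, 12)
  stratum <- c(rep(stratum_levels(), each = 3),
               sample(stratum_levels(), n - 12, replace = TRUE))
  activity <- runif(n, 0, 5000)
  b0 <- runif(4, 0.8, 1.4)[match(stratum, stratum_levels())]
  b1 <- runif(4, 0.005, 0.03)[match(stratum, stratum_levels())]
  met <- pmax(0.2, b0 + b1 * sqrt(activity) + rnorm(n, 0, 0.1))^2
  tibble::tibble(stratum = stratum, activity = activity, met = met)
}

# Independent least-squares oracle: build the dummy-coded design matrix by
# hand in the package's column order and solve the normal equations.
ols_oracle <- function(obs) {
  present <- intersect(stratum_levels(), unique(as.character(obs$stratum)))
  sa <- sqrt(obs$activity)
  X <- cbind(1, sa)
  for (s in present[-1]) X <- cbind(X, as.numeric(obs$stratum == s))
  for (s in present[-1]) X <- cbind(X, sa * as.numeric(obs$stratum == s))
  y <- sqrt(obs$met)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Brute-force application of the 3-SD four-neighbour errant-breath rule,
# written from the rule's definition with explicit mean/SD arithmetic.
clean_breaths_oracle <- function(v, k = 3) {
  n <- length(v)
  if (n < 5) return(v)
  keep <- vapply(seq_len(n), function(i) {
    if (i <= 2 || i >= n - 1) return(TRUE)
    ref <- v[c(i - 2, i - 1, i + 1, i + 2)]
    m <- sum(ref) / 4
    s <- sqrt(sum((ref - m)^2) / 3)
    abs(v[i] - m) <= k * s
  }, logical(1))
  v[keep]
}

# Tiny deterministic breath tibble.
breath_fixture <- function(values, times = seq_along(values)) {
  tibble::tibble(
    participant = "P001", condition = "rest",
    time_s = times, vo2_ml_min = values, body_mass = 70
  )
}
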