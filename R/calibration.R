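# Calibration: OLS of sqrt(MET) on sqrt(counts/min) with device-placement
# dummies against the hip-worn GT3X+ reference level.
#
# Model: sqrt(MET) = beta0 + beta1*sqrt(activity)
#                    + beta2*ACTT_hip + beta3*ACTT_wrist + beta4*GT3X_wrist
#                    + (beta5*ACTT_hip + beta6*ACTT_wrist
#                       + beta7*GT3X_wrist) * sqrt(activity) + error
# so each stratum collapses to sqrt(MET) = b0 + b1*sqrt(activity) with
# b0 = beta0 + its intercept offset and b1 = beta1 + its slope offset.

#' Fit the square-root-scale calibration model
#'
#' Ordinary least squares of `sqrt(met)` on `sqrt(activity)` crossed with
#' the device-placement stratum, hip-worn GT3X+ as reference level. Strata
#' absent from the data simply get no columns (reduced design, recorded in
#' the fit).
#'
#' @param obs Observation tibble with columns `stratum`, `activity`
#'   (counts/min, non-negative) and `met` (> 0); see
#'   [build_observation_table()] or [simulate_observations()].
#' @param ci_multiplier "z" (default; 1.96-style normal quantiles for CIs
#'   downstream) or "t" (Student t on the residual df).
#' @return Object of class `calibration_fit`: list with `beta` (named
#'   coefficient vector, up to 8 entries), `cov` (coefficient covariance),
#'   `n_obs`, `r_squared`, `sigma2` (residual variance on the sqrt-MET
#'   scale), `residuals`, `fitted_sqrt`, `df_residual`, `strata` (levels
#'   present), `ci_multiplier`, and the underlying `lm` fit as `model`.
#' @export
fit_calibration <- function(obs, ci_multiplier = c("z", "t")) {
  ci_multiplier <- match.arg(ci_multiplier)
  stopifnot(all(c("stratum", "activity", "met") %in% names(obs)))
  if (nrow(obs) < 10) stop("need at least 10 observations")
  if (any(obs$activity < 0)) stop("activity must be non-negative")
  if (any(obs$met <= 0)) stop("met must be positive")

  present <- intersect(stratum_levels(), unique(as.character(obs$stratum)))
  dat <- data.frame(
    sqrt_met = sqrt(obs$met),
    sqrt_act = sqrt(obs$activity),
    stratum = factor(as.character(obs$stratum), levels = present)
  )
  model <- if (length(present) > 1) {
    lm(sqrt_met ~ sqrt_act * stratum, data = dat)
  } else {
    lm(sqrt_met ~ sqrt_act, data = dat)  # single stratum: no dummies
  }
  beta <- coef(model)
  if (anyNA(beta)) {
    stop("rank-deficient design; collinear columns: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  structure(
    list(
      beta = beta,
      cov = vcov(model),
      n_obs = nrow(dat),
      r_squared = summary(model)$r.squared,
      sigma2 = summary(model)$sigma^2,
      residuals = residuals(model),
      fitted_sqrt = model$fitted.values,
      df_residual = model$df.residual,
      strata = present,
      ci_multiplier = ci_multiplier,
      model = model
    ),
    class = "calibration_fit"
  )
}

ci_quantile <- function(fit, level = 0.95) {
  if (fit$ci_multiplier == "t") qt(1 - (1 - level) / 2, fit$df_residual)
  else qnorm(1 - (1 - level) / 2)
}

#' Per-stratum calibration equation
#'
#' Collapses the dummy-coded fit into the stratum's own equation
#' `sqrt(MET) = b0 + b1 * sqrt(activity)`, with 95% confidence intervals
#' and the 2x2 covariance of (b0, b1) obtained from the corresponding
#' linear combinations of the full coefficient covariance.
#'
#' @param fit A `calibration_fit`.
#' @param device "GT3X" or "ACTT".
#' @param placement "hip" or "wrist".
#' @param level Confidence level (default 0.95).
#' @return Object of class `stratum_equation`: list with `device`,
#'   `placement`, `stratum`, `b0`, `b0_ci`, `b1`, `b1_ci`, `cov2`, `level`,
#'   `z` (CI quantile used).
#' @export
stratum_equation <- function(fit, device, placement, level = 0.95) {
  stratum <- stratum_label(device, placement)
  if (!stratum %in% fit$strata)
    stop("stratum '", stratum, "' not present in the fit")
  nm <- names(fit$beta)
  a0 <- as.numeric(nm == "(Intercept)")
  a1 <- as.numeric(nm == "sqrt_act")
  if (stratum != fit$strata[1]) {
    a0 <- a0 + as.numeric(nm == paste0("stratum", stratum))
    a1 <- a1 + as.numeric(nm == paste0("sqrt_act:stratum", stratum))
  }
  A <- rbind(a0, a1)
  est <- as.numeric(A %*% fit$beta)
  cov2 <- A %*% fit$cov %*% t(A)
  z <- ci_quantile(fit, level)
  se <- sqrt(diag(cov2))
  structure(
    list(
      device = device, placement = placement, stratum = stratum,
      b0 = est[1], b0_ci = est[1] + c(-1, 1) * z * se[1],
      b1 = est[2], b1_ci = est[2] + c(-1, 1) * z * se[2],
      cov2 = unname(cov2), level = level, z = z
    ),
    class = "stratum_equation"
  )
}

#' Construct a stratum equation from known coefficients
#'
#' Builds a `stratum_equation` directly from (b0, b1) values — e.g.
#' published coefficients — without a fitted model. The covariance defaults
#' to zero (point equation).
#'
#' @param b0,b1 Square-root-scale intercept and slope.
#' @param device,placement Stratum identifiers.
#' @param cov2 2x2 covariance of (b0, b1); default zero matrix.
#' @param level Confidence level (default 0.95).
#' @return A `stratum_equation`.
#' @export
make_stratum_equation <- function(b0, b1, device = "GT3X",
                                  placement = "hip",
                                  cov2 = matrix(0, 2, 2), level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(cov2))
  structure(
    list(
      device = device, placement = placement,
      stratum = stratum_label(device, placement),
      b0 = b0, b0_ci = b0 + c(-1, 1) * z * se[1],
      b1 = b1, b1_ci = b1 + c(-1, 1) * z * se[2],
      cov2 = cov2, level = level, z = z
    ),
    class = "stratum_equation"
  )
}

#' All stratum equations of a fit
#'
#' @param fit A `calibration_fit`.
#' @return Named list of [stratum_equation()] objects, canonical order.
#' @export
stratum_equations <- function(fit) {
  eqs <- lapply(fit$strata, function(s) {
    parts <- strsplit(s, "_", fixed = TRUE)[[1]]
    stratum_equation(fit, parts[1], parts[2])
  })
  setNames(eqs, fit$strata)
}

#' Predict METs from counts/min with a stratum equation
#'
#' `MET = (b0 + b1 * sqrt(activity))^2`, the back-transformed calibration
#' line. Strictly increasing in activity when `b1 > 0`.
#'
#' @param eq A `stratum_equation`.
#' @param activity Counts/min (non-negative, vectorised).
#' @return Predicted METs.
#' @export
predict_met <- function(eq, activity) {
  if (any(activity < 0)) stop("activity must be non-negative")
  lin <- eq$b0 + eq$b1 * sqrt(activity)
  if (any(lin < 0))
    stop("negative linear predictor: equation out of domain")
  lin^2
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Square-root-scale calibration fit\n")
  cat("  n =", x$n_obs, " R^2 =", round(x$r_squared, 4),
      " sigma =", signif(sqrt(x$sigma2), 4), "\n")
  cat("  strata:", paste(x$strata, collapse = ", "),
      "(reference:", x$strata[1], ")\n\n")
  print(round(x$beta, 5))
  invisible(x)
}

#' @export
print.stratum_equation <- function(x, ...) {
  cat(sprintf("%s (%s): sqrt(MET) = %.4f + %.5f * sqrt(counts/min)\n",
              x$device, x$placement, x$b0, x$b1))
  cat(sprintf("  b0 95%% CI (%.4f, %.4f); b1 95%% CI (%.5f, %.5f)\n",
              x$b0_ci[1], x$b0_ci[2], x$b1_ci[1], x$b1_ci[2]))
  invisible(x)
}

#' Tidy coefficient table of the stratum equations
#'
#' @param fit A `calibration_fit`.
#' @return Tibble with one row per stratum: `stratum`, `device`,
#'   `placement`, `b0`, `b0_lo`, `b0_hi`, `b1`, `b1_lo`, `b1_hi`.
#' @export
equation_table <- function(fit) {
  eqs <- stratum_equations(fit)
  dplyr::bind_rows(lapply(eqs, function(e) {
    tibble::tibble(
      stratum = e$stratum, device = e$device, placement = e$placement,
      b0 = e$b0, b0_lo = e$b0_ci[1], b0_hi = e$b0_ci[2],
      b1 = e$b1, b1_lo = e$b1_ci[1], b1_hi = e$b1_ci[2]
    )
  }))
}
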