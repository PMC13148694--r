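# Cut-point derivation: invert each stratum equation at the 3/6/9 MET
# intensity boundaries and propagate coefficient uncertainty by the delta
# method.

#' Invert a stratum equation at a MET threshold
#'
#' The calibration line `sqrt(MET) = b0 + b1*sqrt(activity)` inverts to
#' `activity = ((sqrt(MET) - b0) / b1)^2` counts/min.
#'
#' @param eq A `stratum_equation` with `b1 > 0`.
#' @param met_threshold MET level (> 0, at or above the equation's
#'   intercept `b0^2`).
#' @return Counts/min cut-point.
#' @export
invert_cutpoint <- function(eq, met_threshold) {
  stopifnot(met_threshold > 0, eq$b1 > 0)
  if (any(sqrt(met_threshold) < eq$b0))
    stop("threshold below model intercept (MET at zero counts is b0^2 = ",
         signif(eq$b0^2, 4), ")")
  ((sqrt(met_threshold) - eq$b0) / eq$b1)^2
}

# Gradient of g(b0, b1) = ((sqrt(M) - b0)/b1)^2 with respect to (b0, b1).
cutpoint_gradient <- function(eq, met_threshold) {
  d <- sqrt(met_threshold) - eq$b0
  c(-2 * d / eq$b1^2, -2 * d^2 / eq$b1^3)
}

#' Delta-method confidence interval for a cut-point
#'
#' First-order propagation of the (b0, b1) covariance through the inversion
#' `g(b0, b1) = ((sqrt(M) - b0)/b1)^2`: the gradient is
#' `(-2(sqrt(M)-b0)/b1^2, -2(sqrt(M)-b0)^2/b1^3)`, the standard error is
#' `sqrt(grad' Sigma grad)`, and the interval is the estimate plus or minus
#' the normal quantile times the SE, truncated below at zero counts/min.
#'
#' @param eq A `stratum_equation` (its `cov2` supplies Sigma).
#' @param met_threshold MET level.
#' @param level Confidence level in (0, 1) (default 0.95).
#' @return List: `cutpoint`, `se`, `lower`, `upper`, `level`.
#' @export
cutpoint_ci <- function(eq, met_threshold, level = 0.95) {
  stopifnot(level > 0, level < 1)
  cp <- invert_cutpoint(eq, met_threshold)
  grad <- cutpoint_gradient(eq, met_threshold)
  se <- sqrt(as.numeric(t(grad) %*% eq$cov2 %*% grad))
  z <- qnorm(1 - (1 - level) / 2)
  list(cutpoint = cp, se = se,
       lower = max(0, cp - z * se), upper = cp + z * se, level = level)
}

#' Parametric-bootstrap standard error of a cut-point
#'
#' Monte-Carlo cross-check of the delta method: draws (b0, b1) from the
#' bivariate normal implied by the equation's covariance and takes the
#' empirical SD of the inverted cut-point.
#'
#' @param eq A `stratum_equation`.
#' @param met_threshold MET level.
#' @param n_draws Number of draws (default 1e5).
#' @param seed Integer seed.
#' @return List: `cutpoint`, `se`, `draws_used`.
#' @export
cutpoint_ci_boot <- function(eq, met_threshold, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, c(eq$b0, eq$b1), eq$cov2)
  ok <- draws[, 2] > 0 & sqrt(met_threshold) >= draws[, 1]
  g <- ((sqrt(met_threshold) - draws[ok, 1]) / draws[ok, 2])^2
  list(cutpoint = invert_cutpoint(eq, met_threshold), se = sd(g),
       draws_used = sum(ok))
}

#' Cut-point table across all strata and thresholds
#'
#' Inverts every fitted stratum equation at the 3, 6 and 9 MET intensity
#' boundaries (moderate, vigorous, very vigorous) with delta-method
#' confidence intervals. Twelve rows for a full four-stratum fit; missing
#' strata yield a partial table with a warning.
#'
#' @param fit A `calibration_fit`, or a named list of stratum equations.
#' @param thresholds MET boundaries (default `c(3, 6, 9)`).
#' @param level Confidence level (default 0.95).
#' @return Tibble: `stratum`, `device`, `placement`, `threshold_met`,
#'   `cutpoint`, `ci_low`, `ci_high`, in canonical stratum order.
#' @export
build_cutpoint_table <- function(fit, thresholds = c(3, 6, 9),
                                 level = 0.95) {
  eqs <- if (inherits(fit, "calibration_fit")) stratum_equations(fit)
         else fit
  missing <- setdiff(stratum_levels(), names(eqs))
  if (length(missing) > 0)
    warning("missing strata, partial table: ",
            paste(missing, collapse = ", "))
  rows <- list()
  for (s in intersect(stratum_levels(), names(eqs))) {
    eq <- eqs[[s]]
    for (m in thresholds) {
      ci <- cutpoint_ci(eq, m, level)
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = s, device = eq$device, placement = eq$placement,
        threshold_met = m, cutpoint = ci$cutpoint,
        ci_low = ci$lower, ci_high = ci$upper
      )
    }
  }
  dplyr::bind_rows(rows)
}
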