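# Model and device diagnostics: speed correlations, ANOVA across
# condition x stratum cells, Bland-Altman agreement, residual checks.

#' Pearson correlations of treadmill speed with METs and counts
#'
#' Correlates speed with measured METs (pooled over strata, one MET record
#' per participant x condition) and with counts/min within each stratum;
#' two-sided p-values from the t transform of r.
#'
#' @param obs Observation tibble.
#' @return Tibble with columns `target`, `r`, `p`, `n`. Zero-variance
#'   targets yield `NA` (undefined correlation).
#' @export
pearson_speed_correlations <- function(obs) {
  cor_row <- function(x, y, label) {
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3 || var(x) == 0 || var(y) == 0)
      return(tibble::tibble(target = label, r = NA_real_, p = NA_real_,
                            n = n))
    r <- cor(x, y)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    tibble::tibble(target = label, r = r,
                   p = 2 * pt(-abs(tstat), n - 2), n = n)
  }
  met_one <- obs |>
    dplyr::distinct(.data$participant, .data$condition, .data$speed,
                    .data$met)
  out <- cor_row(met_one$speed, met_one$met, "met")
  for (s in intersect(stratum_levels(), unique(obs$stratum))) {
    sub <- obs[obs$stratum == s, ]
    out <- dplyr::bind_rows(out,
                            cor_row(sub$speed, sub$activity,
                                    paste0("activity_", s)))
  }
  out
}

#' ANOVA of sqrt counts across condition x stratum cells
#'
#' One-way ANOVA of `sqrt(activity)` across the condition x stratum cells
#' (20 cells in the full five-condition, four-stratum design, so 19 between
#' degrees of freedom), with classical eta-squared (SS_between / SS_total)
#' and Tukey HSD over all cell pairs.
#'
#' @param obs Observation tibble.
#' @return List of class `anova_counts`: `F`, `df_between`, `df_within`,
#'   `p`, `eta_squared`, `tukey` (tibble: `pair`, `diff`, `p_adj`),
#'   `n_cells`.
#' @export
anova_counts <- function(obs) {
  dat <- data.frame(
    y = sqrt(obs$activity),
    cell = interaction(obs$condition, obs$stratum, drop = TRUE)
  )
  sizes <- table(dat$cell)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding cells with < 2 observations: ",
            paste(small, collapse = ", "))
    dat <- droplevels(dat[!dat$cell %in% small, ])
  }
  if (nlevels(dat$cell) < 2) stop("need at least 2 cells")
  fit <- aov(y ~ cell, data = dat)
  at <- anova(fit)
  ss_b <- at["cell", "Sum Sq"]
  ss_tot <- sum(at[, "Sum Sq"])
  tk <- TukeyHSD(fit)$cell
  structure(
    list(
      F = at["cell", "F value"],
      df_between = at["cell", "Df"],
      df_within = at["Residuals", "Df"],
      p = at["cell", "Pr(>F)"],
      eta_squared = ss_b / ss_tot,
      tukey = tibble::tibble(pair = rownames(tk), diff = tk[, "diff"],
                             p_adj = tk[, "p adj"]),
      n_cells = nlevels(dat$cell)
    ),
    class = "anova_counts"
  )
}

#' @export
print.anova_counts <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.1f, p = %.3g, eta^2 = %.3f (%d cells)\n",
              x$df_between, x$df_within, x$F, x$p, x$eta_squared,
              x$n_cells))
  invisible(x)
}

#' Bland-Altman agreement between predicted and measured METs
#'
#' Per stratum: differences predicted minus measured MET, their mean (bias),
#' the 95% limits of agreement (bias +/- 1.96 SD of differences), and the
#' slope of difference on mean as a proportional-bias check.
#'
#' @param equations Named list of stratum equations (see
#'   [stratum_equations()]).
#' @param obs Observation tibble.
#' @return Tibble: `stratum`, `bias`, `loa_low`, `loa_high`,
#'   `prop_bias_slope`, `n`; per-observation differences are attached as
#'   attribute `points` (tibble: `stratum`, `mean_met`, `diff`).
#' @export
bland_altman <- function(equations, obs) {
  rows <- list(); pts <- list()
  for (s in names(equations)) {
    sub <- obs[obs$stratum == s, ]
    if (nrow(sub) == 0) next
    pred <- predict_met(equations[[s]], sub$activity)
    d <- pred - sub$met
    m <- (pred + sub$met) / 2
    slope <- if (var(m) > 0) unname(coef(lm(d ~ m))[2]) else NA_real_
    rows[[s]] <- tibble::tibble(
      stratum = s, bias = mean(d),
      loa_low = mean(d) - 1.96 * sd(d),
      loa_high = mean(d) + 1.96 * sd(d),
      prop_bias_slope = slope, n = length(d)
    )
    pts[[s]] <- tibble::tibble(stratum = s, mean_met = m, diff = d)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "points") <- dplyr::bind_rows(pts)
  out
}

#' Residual diagnostics of a calibration fit
#'
#' Q-Q quantile pairs, residual-versus-fitted pairs, a Shapiro-Wilk
#' normality test (on a subsample of 5000 residuals if needed) and a
#' Breusch-Pagan heteroscedasticity test.
#'
#' @param fit A `calibration_fit`.
#' @return List of class `residual_diagnostics`: `qq` (tibble
#'   `theoretical`, `sample`), `rvf` (tibble `fitted`, `residual`),
#'   `shapiro_w`, `shapiro_p`, `bp_stat`, `bp_p`, `n`.
#' @export
residual_diagnostics <- function(fit) {
  r <- fit$residuals
  qq <- qqnorm(r, plot.it = FALSE)
  ord <- order(qq$x)
  shap <- shapiro.test(if (length(r) > 5000) sample(r, 5000) else r)
  bp <- lmtest::bptest(fit$model)
  structure(
    list(
      qq = tibble::tibble(theoretical = qq$x[ord], sample = qq$y[ord]),
      rvf = tibble::tibble(fitted = fit$fitted_sqrt, residual = r),
      shapiro_w = unname(shap$statistic), shapiro_p = shap$p.value,
      bp_stat = unname(bp$statistic), bp_p = bp$p.value,
      n = length(r)
    ),
    class = "residual_diagnostics"
  )
}

#' Bland-Altman panel plot
#'
#' @param ba Result of [bland_altman()].
#' @return A ggplot object (one facet per stratum, dashed bias line, dotted
#'   limits of agreement).
#' @export
plot_bland_altman <- function(ba) {
  pts <- attr(ba, "points")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean_met, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(data = ba, ggplot2::aes(yintercept = .data$bias),
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_hline(data = ba, ggplot2::aes(yintercept = .data$loa_low),
                        colour = "blue", linetype = "dotted") +
    ggplot2::geom_hline(data = ba, ggplot2::aes(yintercept = .data$loa_high),
                        colour = "blue", linetype = "dotted") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Mean of predicted and measured METs",
                  y = "Predicted - measured METs")
}

#' Residual diagnostic panel plot
#'
#' @param diag Result of [residual_diagnostics()].
#' @return A ggplot object (Q-Q and residual-vs-fitted panels).
#' @export
plot_residual_diagnostics <- function(diag) {
  qq <- dplyr::mutate(diag$qq, panel = "Normal Q-Q",
                      x = .data$theoretical, y = .data$sample)
  rvf <- dplyr::mutate(diag$rvf, panel = "Residuals vs fitted",
                       x = .data$fitted, y = .data$residual)
  both <- dplyr::bind_rows(qq[, c("panel", "x", "y")],
                           rvf[, c("panel", "x", "y")])
  ggplot2::ggplot(both, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}
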