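# Intensity classification and its scoring: confusion matrices,
# sensitivity, specificity, balanced accuracy, one-vs-rest AUC.

#' Map METs to an intensity class
#'
#' Left-closed, right-open bands: light `[0,3)`, moderate `[3,6)`,
#' vigorous `[6,9)`, very vigorous `[9,Inf)`.
#'
#' @param met METs (non-negative, vectorised).
#' @return Factor with levels [intensity_levels()].
#' @export
met_to_class <- function(met) {
  if (any(met < 0)) stop("met must be non-negative")
  cut(met, breaks = c(0, 3, 6, 9, Inf), labels = intensity_levels(),
      right = FALSE, include.lowest = TRUE)
}

#' Map counts/min to an intensity class through a cut-point row set
#'
#' Uses one stratum's three cut-points: light below the 3-MET cut-point,
#' moderate from there to the 6-MET cut-point, vigorous to the 9-MET
#' cut-point, very vigorous above. Boundary ties go to the higher class
#' (left-closed intervals), so this is exactly
#' `met_to_class(predict_met(eq, activity))` for the equation the cut-points
#' came from.
#'
#' @param activity Counts/min (non-negative, vectorised).
#' @param cutpoints Either a numeric vector `c(cp3, cp6, cp9)` or the rows
#'   of [build_cutpoint_table()] for one stratum.
#' @return Factor with levels [intensity_levels()].
#' @export
counts_to_class <- function(activity, cutpoints) {
  if (any(activity < 0)) stop("activity must be non-negative")
  if (is.data.frame(cutpoints)) {
    stopifnot(all(c("threshold_met", "cutpoint") %in% names(cutpoints)))
    cutpoints <- cutpoints$cutpoint[order(cutpoints$threshold_met)]
  }
  if (length(cutpoints) != 3 || any(diff(cutpoints) <= 0))
    stop("cut-points must be three strictly increasing values")
  cut(activity, breaks = c(0, cutpoints, Inf), labels = intensity_levels(),
      right = FALSE, include.lowest = TRUE)
}

#' Score predicted against true intensity classes
#'
#' Builds the 4x4 confusion matrix (true class in rows, predicted in
#' columns) and per-class one-vs-rest sensitivity, specificity and balanced
#' accuracy. Classes absent from the truth get `NA` metrics (undefined, not
#' zero).
#'
#' @param truth,predicted Factors (or MET-class labels) with levels
#'   [intensity_levels()].
#' @param scores Optional continuous prediction score (predicted METs) for
#'   one-vs-rest AUC via [auc_one_vs_rest()].
#' @param group Optional label recorded in the report.
#' @return Object of class `classification_report`: `confusion` (counts),
#'   `confusion_norm` (row-normalised), `metrics` (tibble: `class`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `auc`), `n`,
#'   `group`.
#' @export
score_classification <- function(truth, predicted, scores = NULL,
                                 group = "pooled") {
  lv <- intensity_levels()
  truth <- factor(as.character(truth), levels = lv)
  predicted <- factor(as.character(predicted), levels = lv)
  stopifnot(length(truth) == length(predicted), !anyNA(truth),
            !anyNA(predicted))
  cm <- table(truth = truth, predicted = predicted)
  n <- sum(cm)
  met <- lapply(lv, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    tibble::tibble(class = cl, sensitivity = sens, specificity = spec,
                   balanced_accuracy = (sens + spec) / 2)
  })
  metrics <- dplyr::bind_rows(met)
  metrics$auc <- if (!is.null(scores)) {
    auc_one_vs_rest(scores, truth)$auc[match(metrics$class, lv)]
  } else NA_real_
  rs <- rowSums(cm)
  cm_norm <- sweep(cm, 1, ifelse(rs > 0, rs, 1), "/")
  structure(
    list(confusion = cm, confusion_norm = cm_norm, metrics = metrics,
         n = n, group = group),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Intensity classification report (", x$group, ", n = ", x$n, ")\n",
      sep = "")
  print(x$confusion)
  cat("\n")
  print(as.data.frame(lapply(x$metrics, function(c)
    if (is.numeric(c)) round(c, 4) else c)))
  invisible(x)
}

#' One-vs-rest AUC per intensity class
#'
#' For each class, the AUC of the continuous prediction score (predicted
#' METs) discriminating class membership from non-membership, computed by
#' the rank (Mann-Whitney) formulation with mid-ranks for ties. The raw
#' monotone score is used for every class, including the interior bands
#' `[3,6)` and `[6,9)` whose members are not score-separable from both
#' sides at once; this mirrors standard one-vs-rest reporting and explains
#' why interior-class AUCs sit well below the terminal-class ones. A
#' distance-to-band score (negative distance of the score to the class's
#' MET band) is available via `score_type = "band_distance"`.
#'
#' @param scores Continuous scores (predicted METs).
#' @param truth Class factor with levels [intensity_levels()].
#' @param score_type "raw" (default) or "band_distance".
#' @return Tibble: `class`, `auc`, `n_pos`, `n_neg`; `auc` is `NA` when the
#'   class or its complement is empty.
#' @export
auc_one_vs_rest <- function(scores, truth,
                            score_type = c("raw", "band_distance")) {
  score_type <- match.arg(score_type)
  lv <- intensity_levels()
  truth <- factor(as.character(truth), levels = lv)
  stopifnot(length(scores) == length(truth))
  bands <- list(light = c(0, 3), moderate = c(3, 6), vigorous = c(6, 9),
                very_vigorous = c(9, Inf))
  out <- lapply(lv, function(cl) {
    pos <- truth == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0)
      return(tibble::tibble(class = cl, auc = NA_real_, n_pos = n1,
                            n_neg = n0))
    s <- scores
    if (score_type == "band_distance") {
      b <- bands[[cl]]
      s <- -pmax(0, b[1] - scores, scores - b[2])
    } else if (cl == "light") {
      # lower scores indicate the bottom band; orient so AUC measures
      # discrimination, as one-vs-rest reporting does for terminal classes
      s <- -s
    }
    rk <- rank(s)
    auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    tibble::tibble(class = cl, auc = auc, n_pos = n1, n_neg = n0)
  })
  dplyr::bind_rows(out)
}

#' Classification reports, pooled and stratified
#'
#' Runs the full classify-and-score pipeline per group (sex or
#' device-placement stratum) plus pooled. Each observation is classified
#' from its counts through its own stratum's cut-points; the true class
#' comes from the calorimetry-derived METs.
#'
#' @param obs Observation tibble.
#' @param cutpoint_table Result of [build_cutpoint_table()].
#' @param equations Named list of stratum equations (for the AUC score).
#' @param by "none" (pooled only), "sex" or "stratum".
#' @param min_group Minimum group size (default 5); smaller groups are
#'   skipped with a warning.
#' @return Named list of `classification_report`s (first element `pooled`).
#' @export
stratified_reports <- function(obs, cutpoint_table, equations,
                               by = c("none", "sex", "stratum"),
                               min_group = 5) {
  by <- match.arg(by)
  scored <- classify_observations(obs, cutpoint_table, equations)
  reports <- list(
    pooled = score_classification(scored$true_class, scored$pred_class,
                                  scored$pred_met, group = "pooled")
  )
  if (by != "none") {
    for (g in unique(scored[[by]])) {
      sub <- scored[scored[[by]] == g, ]
      if (length(unique(sub$participant)) < min_group &&
          nrow(sub) < min_group) {
        warning("group '", g, "' below minimum size; skipped")
        next
      }
      reports[[as.character(g)]] <-
        score_classification(sub$true_class, sub$pred_class, sub$pred_met,
                             group = as.character(g))
    }
  }
  reports
}

#' Attach predicted METs and intensity classes to an observation table
#'
#' @param obs Observation tibble.
#' @param cutpoint_table Result of [build_cutpoint_table()].
#' @param equations Named list of stratum equations.
#' @return `obs` with added columns `pred_met`, `pred_class`, `true_class`.
#' @export
classify_observations <- function(obs, cutpoint_table, equations) {
  obs$pred_met <- NA_real_
  obs$pred_class <- factor(NA, levels = intensity_levels())
  for (s in unique(obs$stratum)) {
    i <- obs$stratum == s
    cps <- cutpoint_table[cutpoint_table$stratum == s, ]
    if (nrow(cps) == 0 || is.null(equations[[s]]))
      stop("no cut-points or equation for stratum '", s, "'")
    obs$pred_met[i] <- predict_met(equations[[s]], obs$activity[i])
    obs$pred_class[i] <- counts_to_class(obs$activity[i], cps)
  }
  obs$true_class <- met_to_class(obs$met)
  obs
}
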