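# Intensity classification and agreement metrics.

test_that("MET bands are left-closed and right-open", {
  expect_equal(as.character(met_to_class(c(0, 2.99, 3, 5.99, 6, 8.99, 9))),
               c("light", "light", "moderate", "moderate", "vigorous",
                 "vigorous", "very_vigorous"))
  expect_error(met_to_class(-0.1), "non-negative")
})

test_that("count classification uses left-closed cut-point intervals", {
  cps <- c(1132, 4853, 9468)
  expect_equal(as.character(counts_to_class(c(0, 1131.9, 1132, 4853, 9468),
                                            cps)),
               c("light", "light", "moderate", "vigorous", "very_vigorous"))
  expect_error(counts_to_class(100, c(5, 4, 9)), "strictly increasing")
  expect_error(counts_to_class(-1, cps), "non-negative")
})

test_that("count classification equals MET classification of the
           prediction over a dense grid", {
  eq <- make_stratum_equation(1.062, 0.0199, "GT3X", "hip")
  cps <- sapply(c(3, 6, 9), function(m) invert_cutpoint(eq, m))
  grid <- seq(0, 25000, length.out = 10000)
  expect_equal(as.character(counts_to_class(grid, cps)),
               as.character(met_to_class(predict_met(eq, grid))))
})

test_that("perfect predictions score perfectly", {
  truth <- factor(rep(intensity_levels(), each = 10),
                  levels = intensity_levels())
  rep_perfect <- score_classification(truth, truth)
  expect_equal(unname(diag(rep_perfect$confusion)), rep(10, 4))
  expect_equal(sum(rep_perfect$confusion), 40)
  expect_true(all(rep_perfect$metrics$sensitivity == 1))
  expect_true(all(rep_perfect$metrics$specificity == 1))
  expect_true(all(rep_perfect$metrics$balanced_accuracy == 1))
})

test_that("metrics follow direct count arithmetic on a two-class fixture", {
  # confusion [[8,2],[1,9]] collapsed onto light/moderate
  truth <- c(rep("light", 10), rep("moderate", 10))
  pred <- c(rep("light", 8), rep("moderate", 2),
            rep("light", 1), rep("moderate", 9))
  rep2 <- score_classification(truth, pred)
  m <- rep2$metrics
  expect_equal(m$sensitivity[m$class == "light"], 0.8)
  expect_equal(m$specificity[m$class == "light"], 0.9)
  expect_equal(m$balanced_accuracy[m$class == "light"], 0.85)
  # empty classes give undefined sensitivity, never zero
  expect_true(is.na(m$sensitivity[m$class == "vigorous"]))
  # row-normalised rows sum to one for non-empty rows
  expect_equal(unname(rowSums(rep2$confusion_norm)[1:2]), c(1, 1))
})

test_that("balanced accuracy of label-independent predictions is near 0.5", {
  set.seed(15)
  truth <- sample(intensity_levels(), 4000, replace = TRUE)
  pred <- sample(truth)   # permuted: same marginals, no association
  m <- score_classification(truth, pred)$metrics
  expect_true(all(abs(m$balanced_accuracy - 0.5) < 0.05))
})

test_that("balanced accuracy identity holds per class", {
  set.seed(16)
  truth <- sample(intensity_levels(), 500, replace = TRUE,
                  prob = c(0.4, 0.3, 0.2, 0.1))
  pred <- sample(intensity_levels(), 500, replace = TRUE)
  m <- score_classification(truth, pred)$metrics
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
})

test_that("rank-based AUC matches trapezoidal ROC integration", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- c(rnorm(25, 5), rnorm(25, 7))
  truth <- factor(c(rep("vigorous", 25), rep("very_vigorous", 25)),
                  levels = intensity_levels())
  got <- auc_one_vs_rest(scores, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth == "very_vigorous", predictor = scores,
    direction = "<", quiet = TRUE)))
  expect_equal(got$auc[got$class == "very_vigorous"], ref,
               tolerance = 1e-10)
})

test_that("AUC hits its boundary and null values", {
  truth <- factor(c(rep("light", 20), rep("very_vigorous", 20)),
                  levels = intensity_levels())
  scores <- c(runif(20, 1, 2.5), runif(20, 9, 12))
  got <- auc_one_vs_rest(scores, truth)
  expect_equal(got$auc[got$class == "very_vigorous"], 1)
  expect_equal(got$auc[got$class == "light"], 1)  # orientation-corrected
  expect_true(is.na(got$auc[got$class == "moderate"]))

  set.seed(18)
  truth2 <- sample(c("moderate", "vigorous"), 4000, replace = TRUE)
  rand <- auc_one_vs_rest(runif(4000), truth2)
  expect_true(all(abs(rand$auc[rand$class %in%
                                 c("moderate", "vigorous")] - 0.5) < 0.04))
})

test_that("stratified reports add up to the pooled report", {
  cohort <- generate_cohort(12, 12, seed = 19)
  obs <- simulate_observations(cohort, truth_parameters(), seed = 19)
  fit <- fit_calibration(obs)
  eqs <- stratum_equations(fit)
  cp <- build_cutpoint_table(fit)
  pooled_only <- stratified_reports(obs, cp, eqs, by = "none")
  expect_named(pooled_only, "pooled")
  by_stratum <- stratified_reports(obs, cp, eqs, by = "stratum")
  expect_length(by_stratum, 5)
  by_sex <- stratified_reports(obs, cp, eqs, by = "sex")
  summed <- Reduce(`+`, lapply(by_sex[-1], function(r) r$confusion))
  expect_equal(unclass(summed), unclass(by_sex$pooled$confusion))
})
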