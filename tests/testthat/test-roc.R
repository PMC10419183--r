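test_that("AUC handles separation, interleaving and total ties", {
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(auc_mann_whitney(rep(2, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  expect_error(auc_mann_whitney(1:4, c(1, 1, 1, 1)), "Both classes")
})

test_that("Mann-Whitney AUC equals pairwise enumeration and trapezoid area", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1))) # coarse -> ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(labels) == 0 || sum(!labels) == 0) next
    auc <- auc_mann_whitney(scores, labels)$auc
    expect_equal(auc, brute_auc(scores, labels), tolerance = 1e-12)
    expect_equal(auc, trapezoid_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, plogis(scores))
  ours <- auc_mann_whitney(scores, labels)
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  # DeLong SE against pROC's DeLong variance
  expect_equal(auc_mann_whitney(scores, labels, se_method = "delong")$auc_se,
               sqrt(pROC::var(ref, method = "delong")), tolerance = 1e-8)
})

test_that("complement and monotone-transform invariances hold", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    scores <- round(rnorm(n), 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(labels) == 0 || sum(!labels) == 0) next
    a <- auc_mann_whitney(scores, labels)$auc
    expect_equal(a + auc_mann_whitney(-scores, labels)$auc, 1)
    transformed <- exp(2 * scores) + 5
    expect_equal(auc_mann_whitney(transformed, labels)$auc, a)
    expect_equal(suppressWarnings(youden_cutpoint(transformed, labels))$metrics$youden_j,
                 suppressWarnings(youden_cutpoint(scores, labels))$metrics$youden_j)
  }
})

test_that("Youden search equals exhaustive threshold scan", {
  set.seed(44)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(labels) == 0 || sum(!labels) == 0) next
    fit <- suppressWarnings(youden_cutpoint(scores, labels))
    expect_equal(fit$metrics$youden_j, brute_max_youden(scores, labels),
                 tolerance = 1e-12)
    expect_equal(fit$metrics$youden_j,
                 fit$metrics$sens + fit$metrics$spec - 1, tolerance = 1e-12)
  }
})

test_that("perfect split lands on the midpoint cut-off", {
  # LR+ is undefined at a perfect split (spec = 1), hence the warning
  fit <- suppressWarnings(youden_cutpoint(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(fit$optimal_cutoff, 2.5)
  expect_equal(fit$metrics$youden_j, 1.0)
  expect_equal(fit$metrics$sens, 1.0)
  expect_equal(fit$metrics$spec, 1.0)
})

test_that("J ties break toward sensitivity, then the lower cut-off", {
  # two cut-offs share J = 0.5; the lower one has sens 1.0
  scores <- c(1, 2, 3, 4)
  labels <- c(FALSE, TRUE, FALSE, TRUE)
  fit <- youden_cutpoint(scores, labels)
  expect_equal(fit$metrics$youden_j, 0.5)
  expect_equal(fit$optimal_cutoff, 1.5)
  expect_equal(fit$metrics$sens, 1.0)
})

test_that("diagnostic metrics reproduce 2x2 arithmetic and sentinels", {
  # 2x2 with TP=1109, FN=222, TN=2576, FP=433
  scores <- rep(c(1, 0, 1, 0), c(1109, 222, 433, 2576))
  labels <- rep(c(TRUE, FALSE), c(1331, 3009))
  m <- diagnostic_metrics(scores, labels, cutoff = 0.5)
  expect_equal(m$sens, 1109 / 1331)
  expect_equal(m$spec, 2576 / 3009)
  expect_equal(m$lr_pos, (1109 / 1331) / (1 - 2576 / 3009))
  expect_equal(round(m$lr_pos, 2), 5.79)
  expect_equal(m$ppv, 1109 / (1109 + 433))
  expect_equal(m$npv, 2576 / (2576 + 222))

  lo <- suppressWarnings(diagnostic_metrics(scores, labels, cutoff = -Inf))
  expect_equal(lo$sens, 1)
  expect_equal(lo$spec, 0)
  expect_warning(expect_warning(
    hi <- diagnostic_metrics(scores, labels, cutoff = Inf), "undefined"))
  expect_equal(hi$sens, 0)
  expect_equal(hi$spec, 1)
  expect_true(is.na(hi$ppv)) # empty predicted-positive cell
})

test_that("the ROC curve is a valid staircase from (0,0) to (1,1)", {
  set.seed(45)
  scores <- round(rnorm(60), 1)
  labels <- rbinom(60, 1, plogis(scores)) == 1
  curve <- roc_curve(scores, labels)
  expect_equal(curve$sens[1], 0)
  expect_equal(curve$spec[1], 1)
  expect_equal(curve$sens[nrow(curve)], 1)
  expect_equal(curve$spec[nrow(curve)], 0)
  expect_true(all(diff(curve$sens) >= 0))
  expect_true(all(diff(1 - curve$spec) >= 0))
  expect_true(all(diff(curve$cutoff) < 0))
})

test_that("labels independent of scores give chance-level AUC", {
  set.seed(46)
  scores <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.4)
  auc <- auc_mann_whitney(scores, labels)$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("the ROC battery ranks indices within sex and flags bad strata", {
  cohort <- generate_cohort(n = 800, seed = 47) |>
    compute_index_panel() |>
    mets_components()
  bat <- roc_battery(cohort, indices = c("tyg_wc", "lap", "absi"))
  expect_equal(nrow(bat), 6)
  for (sx in c("male", "female")) {
    sub <- bat[bat$sex == sx, ]
    expect_gt(sub$auc[sub$index == "tyg_wc"], sub$auc[sub$index == "absi"])
    expect_equal(sub$auc_rank[which.max(sub$auc)], 1)
  }
  expect_true(all(bat$youden_j == bat$sens + bat$spec - 1))
  # stratum where an index is all-missing yields an error row, not an abort
  broken <- cohort
  broken$lap[broken$sex == "male"] <- NA_real_
  bat2 <- roc_battery(broken, indices = c("lap", "tyg_wc"))
  expect_true(bat2$error[bat2$sex == "male" & bat2$index == "lap"])
  expect_false(bat2$error[bat2$sex == "female" & bat2$index == "lap"])
})

test_that("accuracy bands follow the conventional AUC interpretation", {
  expect_equal(accuracy_band(c(0.95, 0.85, 0.65, 0.5, 0.3)),
               c("high", "moderate", "low", "chance", "chance"))
})
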