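# The statistical validation layer: effect-size screening, reliability,
# summary-statistic group tests, FDR, and the cross-validated ML harness.

test_that("Cohen's d screening retains medium effects and flags degeneracy", {
  set.seed(1)
  n <- 400
  tab <- data.frame(big = c(rnorm(n), rnorm(n, 1)),       # d = 1
                    null = rnorm(2 * n),                  # d ~ 0
                    flat = rep(1, 2 * n))                 # zero pooled SD
  labels <- rep(c("control", "ALS"), each = n)
  scr <- cohens_d_screen(tab, labels, cutoff = 0.5)
  expect_true("big" %in% scr$retained)
  expect_true("null" %in% scr$discarded)
  expect_equal(scr$flagged, "flat")
  expect_equal(abs(scr$d["big"]), 1, tolerance = 0.15, ignore_attr = TRUE)
  # label swap flips the sign but not the magnitude
  scr2 <- cohens_d_screen(tab, rev(labels), cutoff = 0.5)
  expect_equal(scr2$d["big"], -scr$d["big"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(cohens_d_screen(tab, rep("a", 2 * n)), "two groups")
})

test_that("Cronbach's alpha matches the Spearman-Brown closed form", {
  set.seed(2)
  n <- 5000; rho <- 0.4; k <- 5
  f <- rnorm(n)
  X <- sapply(seq_len(k), function(i) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
  expect_equal(cronbach_alpha(X), k * rho / (1 + (k - 1) * rho),
               tolerance = 0.02)
  # equal-scale perfectly correlated items: alpha = 1
  Xp <- cbind(f, f + 1, f - 2)
  expect_equal(cronbach_alpha(Xp), 1)
  # uncorrelated items: alpha ~ 0
  X0 <- matrix(rnorm(n * 4), n, 4)
  expect_lt(abs(cronbach_alpha(X0)), 0.05)
  expect_error(cronbach_alpha(X[, 1, drop = FALSE]), "single item")
})

test_that("the summary-statistic F test equals a full ANOVA on matching data", {
  # construct raw data with exactly the requested summaries
  mk <- function(m, s, n) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / sd(x)
  }
  set.seed(3)
  g1 <- mk(10, 2, 13); g2 <- mk(12, 3, 10)
  full <- anova(lm(y ~ g, data.frame(y = c(g1, g2),
                                     g = rep(c("a", "b"), c(13, 10)))))
  st <- summary_f_test(10, 2, 13, 12, 3, 10)
  expect_equal(st$F, full$`F value`[1], tolerance = 1e-9)
  expect_equal(st$p, full$`Pr(>F)`[1], tolerance = 1e-9)
  expect_equal(st$df, c(1, 21))
  # equal means: F = 0
  expect_equal(summary_f_test(5, 1, 10, 5, 2, 12)$F, 0)
  expect_error(summary_f_test(1, 0, 5, 1, 0, 5), "zero pooled")
})

test_that("Yates-corrected chi-squared matches the closed form and symmetry", {
  m <- rbind(c(5, 8), c(7, 3))
  got <- chi2_yates(m)
  # direct computation of sum((|O-E|-0.5)^2/E)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(got$chi2, sum((abs(m - E) - 0.5)^2 / E), tolerance = 1e-9)
  expect_equal(got$df, 1)
  # proportional table: near zero
  expect_lt(chi2_yates(rbind(c(20, 40), c(10, 20)))$chi2, 0.1)
  # simultaneous row and column swap leaves the statistic unchanged
  expect_equal(chi2_yates(m[2:1, 2:1])$chi2, got$chi2)
  expect_error(chi2_yates(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("BH adjustment is monotone, capped, and matches the step-up rule", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(4)
  p <- runif(20)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "p")
})

test_that("noiseless linear regression is fit perfectly by the linear learner", {
  set.seed(5)
  X <- matrix(rnorm(150 * 4), 150, 4)
  colnames(X) <- paste0("v", 1:4)
  y <- drop(X %*% c(1, -2, 0.5, 3))
  res <- cv_evaluate(X, y, "regression", "mlr", cv_config(seed = 6,
                                                          repeats = 2))
  expect_gte(res$metrics[["R2"]], 0.999)
  expect_lt(res$metrics[["RMSE"]], 1e-6)
})

test_that("CV metrics are seed-reproducible and honest under the null", {
  set.seed(7)
  X <- matrix(rnorm(160 * 5), 160, 5)
  colnames(X) <- paste0("v", 1:5)
  y <- factor(rep(c("control", "ALS"), each = 80), levels = c("control", "ALS"))
  r1 <- cv_evaluate(X, y, "binary", "rf", cv_config(seed = 8, repeats = 3))
  r2 <- cv_evaluate(X, y, "binary", "rf", cv_config(seed = 8, repeats = 3))
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$importance, r2$importance)
  # permuted labels: AUC near chance
  expect_lt(abs(r1$metrics[["auc"]] - 0.5), 0.1)
  expect_named(r1$importance, colnames(X))
  expect_error(cv_evaluate(X, factor(rep("a", 160)), "binary", "rf"),
               "2 classes")
  expect_error(cv_evaluate(X, y, "binary", "mlr"), "regression learner")
})

test_that("an injected class signal is detected by both classifiers", {
  set.seed(9)
  X <- matrix(rnorm(160 * 5), 160, 5)
  colnames(X) <- paste0("v", 1:5)
  y <- factor(rep(c("control", "ALS"), each = 80), levels = c("control", "ALS"))
  X[y == "ALS", 1:2] <- X[y == "ALS", 1:2] + 1.5
  for (lrn in c("rf", "svm_rbf")) {
    r <- cv_evaluate(X, y, "binary", lrn, cv_config(seed = 10, repeats = 2))
    expect_gt(r$metrics[["auc"]], 0.85)
    expect_gt(r$metrics[["sensitivity"]], 0.6)
    expect_gt(r$metrics[["specificity"]], 0.6)
  }
})

test_that("multiclass evaluation reports pairwise metrics and overall AUC", {
  set.seed(11)
  X <- matrix(rnorm(180 * 4), 180, 4)
  colnames(X) <- paste0("v", 1:4)
  y <- factor(rep(c("control", "ALS-B", "ALS+B"), each = 60),
              levels = c("control", "ALS-B", "ALS+B"))
  X[y == "ALS-B", 1] <- X[y == "ALS-B", 1] + 1.5
  X[y == "ALS+B", 1:2] <- X[y == "ALS+B", 1:2] + 3
  r <- cv_evaluate(X, y, "multiclass", "rf", cv_config(seed = 12, repeats = 2))
  expect_true("multiclass_auc" %in% names(r$metrics))
  expect_gt(r$metrics[["multiclass_auc"]], 0.85)
  expect_length(grep("_vs_", names(r$metrics)), 9)  # 3 pairs x 3 metrics
  # the strongly separated pair classifies best
  expect_gt(r$metrics[["control_vs_ALS+B.accuracy"]],
            r$metrics[["control_vs_ALS-B.accuracy"]] - 0.05)
})
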