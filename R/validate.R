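# Validation layer: effect-size screening, reliability, summary-statistic
# group tests, FDR adjustment, and the repeated cross-validated ML harness.

#' Cohen's d screening of a feature table
#'
#' `d = (mean1 - mean2) / pooled SD` per feature between two groups;
#' features with `|d| > cutoff` (at least a medium effect) are retained.
#' Missing values are ignored pairwise; features with zero pooled SD are
#' flagged and excluded.
#'
#' @param table data.frame/matrix of features (columns)
#' @param labels group labels, exactly two levels
#' @param cutoff retention threshold on `|d|`
#' @return list with `d` (named vector), `retained`, `discarded`,
#'   `flagged` (zero pooled SD)
#' @export
cohens_d_screen <- function(table, labels, cutoff = 0.5) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two groups required")
  g1 <- levels(labels)[1]; g2 <- levels(labels)[2]
  tab <- as.data.frame(table)
  d <- vapply(tab, function(x) {
    x1 <- x[labels == g1]; x2 <- x[labels == g2]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) return(NA_real_)
    sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
      (n1 + n2 - 2)
    if (sp2 <= 0) return(NA_real_)
    (mean(x1) - mean(x2)) / sqrt(sp2)
  }, numeric(1))
  flagged <- names(d)[is.na(d)]
  ok <- !is.na(d)
  list(d = d,
       retained = names(d)[ok & abs(d) > cutoff],
       discarded = names(d)[ok & abs(d) <= cutoff],
       flagged = flagged)
}

#' Cronbach's alpha of an item set
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))` for the
#' `k` items (columns). Not applicable to a single item.
#'
#' @param items matrix/data.frame, observations x items (k >= 2)
#' @return alpha coefficient
#' @export
cronbach_alpha <- function(items) {
  X <- as.matrix(items)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  if (k < 2) stop("Cronbach's alpha is not applicable to a single item")
  if (nrow(X) < 3) stop("need at least 3 observations")
  iv <- apply(X, 2, stats::var)
  tv <- stats::var(rowSums(X))
  k / (k - 1) * (1 - sum(iv) / tv)
}

#' Two-group one-way ANOVA from summary statistics
#'
#' Pooled-variance F test computed from `(mean, SD, n)` per group, as used
#' to compare demographic and functional characteristics between groups:
#' `F = (m1 - m2)^2 / (s_p^2 (1/n1 + 1/n2))` on `(1, n1 + n2 - 2)` degrees
#' of freedom. Equals the full one-way ANOVA on any raw data having exactly
#' these summaries.
#'
#' @param m1,s1,n1 mean, SD, and size of group 1
#' @param m2,s2,n2 mean, SD, and size of group 2
#' @return list with `F`, `df`, `p`
#' @examples
#' summary_f_test(135.02, 41.27, 13, 183.65, 23.02, 10)  # F ~ 11.14
#' @export
summary_f_test <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  Fval <- (m1 - m2)^2 / (sp2 * (1 / n1 + 1 / n2))
  df <- c(1, n1 + n2 - 2)
  list(F = Fval, df = df, p = stats::pf(Fval, df[1], df[2],
                                        lower.tail = FALSE))
}

#' Yates-corrected chi-squared test of a 2x2 table
#'
#' Continuity-corrected Pearson chi-squared,
#' `sum((|O - E| - 0.5)^2 / E)` with 1 degree of freedom.
#'
#' @param counts 2x2 matrix of counts
#' @return list with `chi2`, `df`, `p`
#' @export
chi2_yates <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = TRUE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#' @param p vector of raw p-values in `[0, 1]`
#' @return adjusted p-values
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Cross-validation settings
#'
#' @param folds number of folds
#' @param repeats number of repetitions
#' @param seed integer seed (fold assignment and learners are derived from
#'   it, so all metrics are bit-reproducible)
#' @param stratified stratify folds by class for classification tasks
#' @return list of settings
#' @export
cv_config <- function(folds = 5, repeats = 10, seed = 1L, stratified = TRUE) {
  stopifnot(folds >= 2, repeats >= 1)
  as.list(environment())
}

# fold assignment for one repeat
assign_folds <- function(y, folds, stratified) {
  n <- length(y)
  fold <- integer(n)
  if (stratified && is.factor(y)) {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(folds), n))
  }
  fold
}

fit_predict <- function(Xtr, ytr, Xte, task, learner) {
  if (learner == "rf") {
    fit <- randomForest::randomForest(x = Xtr, y = ytr, ntree = 500)
    if (task == "regression") {
      list(pred = as.numeric(stats::predict(fit, Xte)))
    } else {
      pr <- stats::predict(fit, Xte, type = "prob")
      list(pred = stats::predict(fit, Xte), prob = pr)
    }
  } else if (learner == "svm_rbf") {
    fit <- e1071::svm(x = Xtr, y = ytr, kernel = "radial", cost = 1,
                      gamma = 1 / (ncol(Xtr) * mean(apply(Xtr, 2, stats::var))),
                      probability = (task != "regression"), scale = TRUE)
    if (task == "regression") {
      list(pred = as.numeric(stats::predict(fit, Xte)))
    } else {
      p <- stats::predict(fit, Xte, probability = TRUE)
      list(pred = p, prob = attr(p, "probabilities")[, levels(ytr),
                                                     drop = FALSE])
    }
  } else if (learner == "mlr") {
    df <- data.frame(Xtr); df$.y <- ytr
    fit <- stats::lm(.y ~ ., data = df)
    list(pred = as.numeric(stats::predict(fit, data.frame(Xte))))
  } else stop("unknown learner: ", learner)
}

binary_metrics <- function(truth, pred, prob_pos, positive) {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  roc <- pROC::roc(response = truth == positive, predictor = prob_pos,
                   quiet = TRUE, direction = "<")
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    auc = as.numeric(pROC::auc(roc)))
}

#' Repeated k-fold cross-validated regression / classification
#'
#' Out-of-fold predictions are pooled within each repeat, metrics computed
#' per repeat and averaged over repeats. Regression reports R^2 and RMSE;
#' binary classification reports accuracy, sensitivity, specificity and ROC
#' AUC; multiclass reports pairwise accuracy/sensitivity/specificity for
#' each class pair plus the overall multiclass AUC (mean of the pairwise
#' one-vs-one AUCs). Random-forest runs also return the feature importance
#' (decrease in node impurity, full-data fit).
#'
#' @param X predictor matrix/data.frame
#' @param y numeric response (regression) or factor (classification)
#' @param task `"regression"`, `"binary"`, or `"multiclass"`
#' @param learner `"rf"`, `"svm_rbf"`, or `"mlr"` (regression only)
#' @param cv a [cv_config()]
#' @param positive positive class for binary metrics (default: last level)
#' @return list of averaged `metrics`, per-repeat `per_repeat`, and
#'   `importance` (rf only)
#' @export
cv_evaluate <- function(X, y, task = c("regression", "binary", "multiclass"),
                        learner = c("rf", "svm_rbf", "mlr"),
                        cv = cv_config(), positive = NULL) {
  task <- match.arg(task)
  learner <- match.arg(learner)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (task == "regression") {
    y <- as.numeric(y)
  } else {
    y <- droplevels(as.factor(y))
    if (task == "binary" && nlevels(y) != 2) stop("binary task needs 2 classes")
    if (task == "multiclass" && nlevels(y) < 3)
      stop("multiclass task needs >= 3 classes")
    if (min(table(y)) < cv$folds) stop("degenerate class: fewer samples than folds")
    if (is.null(positive)) positive <- levels(y)[nlevels(y)]
  }
  if (learner == "mlr" && task != "regression")
    stop("mlr is a regression learner")
  per_rep <- list()
  with_seed(cv$seed, {
    for (r in seq_len(cv$repeats)) {
      fold <- assign_folds(y, cv$folds, cv$stratified)
      pred <- if (task == "regression") numeric(length(y))
              else factor(rep(levels(y)[1], length(y)), levels = levels(y))
      prob <- if (task != "regression")
        matrix(NA_real_, length(y), nlevels(y),
               dimnames = list(NULL, levels(y)))
      for (k in seq_len(cv$folds)) {
        te <- fold == k
        fp <- fit_predict(X[!te, , drop = FALSE], if (task == "regression")
          y[!te] else droplevels(y[!te]), X[te, , drop = FALSE], task, learner)
        if (task == "regression") pred[te] <- fp$pred
        else {
          pred[te] <- as.character(fp$pred)
          prob[te, colnames(fp$prob)] <- fp$prob
        }
      }
      if (task == "regression") {
        rmse <- sqrt(mean((y - pred)^2))
        r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
        per_rep[[r]] <- c(R2 = r2, RMSE = rmse)
      } else if (task == "binary") {
        per_rep[[r]] <- binary_metrics(y, pred, prob[, positive], positive)
      } else {
        lv <- levels(y)
        met <- numeric(0)
        aucs <- numeric(0)
        for (i in 1:(nlevels(y) - 1)) for (j in (i + 1):nlevels(y)) {
          sel <- y %in% c(lv[i], lv[j])
          pos <- lv[j]
          pred_pair <- ifelse(prob[sel, lv[j]] >= prob[sel, lv[i]],
                              lv[j], lv[i])
          bm <- binary_metrics(factor(y[sel], levels = c(lv[i], lv[j])),
                               pred_pair, prob[sel, lv[j]], pos)
          tag <- paste0(lv[i], "_vs_", lv[j])
          met[paste0(tag, ".", names(bm)[1:3])] <- bm[1:3]
          aucs <- c(aucs, bm["auc"])
        }
        per_rep[[r]] <- c(met, multiclass_auc = mean(aucs))
      }
    }
  })
  mat <- do.call(rbind, per_rep)
  importance <- NULL
  if (learner == "rf") {
    importance <- with_seed(cv$seed, {
      fit <- randomForest::randomForest(x = X, y = y, ntree = 500,
                                        importance = FALSE)
      imp <- randomForest::importance(fit)
      stats::setNames(imp[, 1], rownames(imp))
    })
  }
  list(metrics = colMeans(mat), per_repeat = mat, importance = importance,
       task = task, learner = learner)
}
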