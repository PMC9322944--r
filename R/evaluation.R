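# Repeated stratified k-fold cross-validation, the five performance
# metrics, pooled confusion matrices, and the statistical comparisons
# between algorithms and feature sets.

#' Stratified fold assignment
#'
#' Splits indices into `k` folds so that per-class counts across folds
#' differ by at most 1 and fold totals are balanced: each class's
#' remainder members are dealt to the currently least-loaded folds.
#' Deterministic given `seed`.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per label.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  if (k < 2) stop_stroopfc("k must be at least 2")
  labels <- as.factor(labels)
  n <- length(labels)
  if (k > n) stop_stroopfc("more folds than subjects")
  fold_of <- integer(n)
  load <- integer(k)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n_c <- length(idx)
      counts <- rep(n_c %/% k, k)
      r <- n_c %% k
      if (r > 0) {
        ord <- order(load, sample.int(k))   # least-loaded first, random ties
        counts[ord[seq_len(r)]] <- counts[ord[seq_len(r)]] + 1L
      }
      fold_of[idx] <- rep.int(seq_len(k), counts)
      load <- load + counts
    }
  })
  fold_of
}

#' Five-metric summary of a multiclass confusion matrix
#'
#' Accuracy is `trace/total`; precision, recall (sensitivity),
#' specificity, and F1 are computed one-vs-rest per class and aggregated
#' as the support-weighted mean (`average = "weighted"`, default) or the
#' unweighted macro mean. Per-class precision is 0 (with a warning) when a
#' class is never predicted. All values in percent.
#'
#' @param confusion Square matrix of counts, rows = truth, cols = predicted.
#' @param average `"weighted"` or `"macro"`.
#' @return Named numeric vector `accuracy, precision, recall, specificity, f1`.
#' @export
multiclass_metrics <- function(confusion, average = c("weighted", "macro")) {
  average <- match.arg(average)
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || nrow(cm) == 0) {
    stop_stroopfc("confusion matrix must be square and non-empty")
  }
  if (any(cm < 0)) stop_stroopfc("confusion counts must be non-negative")
  total <- sum(cm)
  if (total == 0) stop_stroopfc("empty confusion matrix")
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  fp <- predicted - tp
  fn <- support - tp
  tn <- total - tp - fp - fn
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  if (any(predicted == 0 & support > 0)) {
    warning("class never predicted: its precision set to 0")
  }
  recall <- ifelse(support > 0, tp / support, 0)
  specificity <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- if (average == "weighted") support / total else {
    present <- support > 0
    ifelse(present, 1 / sum(present), 0)
  }
  c(accuracy = 100 * sum(tp) / total,
    precision = 100 * sum(w * precision),
    recall = 100 * sum(w * recall),
    specificity = 100 * sum(w * specificity),
    f1 = 100 * sum(w * f1))
}

#' Repeated stratified cross-validation of a classifier
#'
#' Runs `n_runs` repetitions of stratified `k`-fold cross-validation: per
#' run a fresh seeded fold split; per fold, features are standardized on
#' the training rows, the model fitted and the held-out fold predicted;
#' fold predictions are pooled into one run-level confusion matrix from
#' which the five metrics are computed. Metrics are aggregated as
#' mean +/- SD over runs and confusion counts pooled over all runs.
#'
#' @param features Feature data.frame (from [extract_features()] or
#'   [read_features()]) with a `label` column.
#' @param algorithm `"nb"`, `"lda"`, or `"svm"`.
#' @param feature_cols Feature columns to train on (default
#'   `c("ge_cm", "ge_dm", "cq")`).
#' @param n_runs Number of repetitions (default 10).
#' @param k Folds per run (default 10).
#' @param base_seed Run `r` uses seed `base_seed + r`; recorded in the
#'   report for exact reproducibility.
#' @param params [puk_params()] for the SVM.
#' @param standardize Standardize per training fold (default `TRUE`).
#' @param average Metric averaging rule, see [multiclass_metrics()].
#' @return An object of class `evaluation_report`.
#' @export
cross_validate <- function(features, algorithm,
                           feature_cols = c("ge_cm", "ge_dm", "cq"),
                           n_runs = 10, k = 10, base_seed = 1,
                           params = puk_params(), standardize = TRUE,
                           average = "weighted") {
  if (!all(feature_cols %in% names(features))) {
    stop_stroopfc("missing feature columns: ",
                  paste(setdiff(feature_cols, names(features)), collapse = ", "))
  }
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  y <- factor(as.character(features$label), levels = CLASS_LEVELS)
  y <- droplevels(y)
  lv <- levels(y)
  n <- length(y)
  per_run <- matrix(NA_real_, n_runs, 5,
                    dimnames = list(NULL, c("accuracy", "precision", "recall",
                                            "specificity", "f1")))
  pooled <- matrix(0L, length(lv), length(lv),
                   dimnames = list(truth = lv, predicted = lv))
  for (r in seq_len(n_runs)) {
    folds <- stratified_folds(y, k = k, seed = base_seed + r)
    pred <- factor(rep(NA_character_, n), levels = lv)
    for (f in seq_len(k)) {
      test <- which(folds == f)
      train <- which(folds != f)
      ytr <- droplevels(y[train])
      if (nlevels(ytr) < nlevels(y)) {
        warning("fold ", f, " run ", r,
                ": a class is absent from training; model sees remaining classes")
      }
      model <- fit_classifier(x[train, , drop = FALSE], ytr,
                              algorithm = algorithm, params = params,
                              standardize = standardize)
      pred[test] <- as.character(predict(model, x[test, , drop = FALSE]))
    }
    conf <- table(truth = y, predicted = pred)
    per_run[r, ] <- multiclass_metrics(conf, average = average)
    pooled <- pooled + unclass(conf)
  }
  agg <- rbind(mean = colMeans(per_run), sd = apply(per_run, 2, stats::sd))
  row_pct <- 100 * pooled / pmax(rowSums(pooled), 1)
  structure(
    list(algorithm = algorithm, feature_cols = feature_cols,
         n_runs = n_runs, k = k, base_seed = base_seed, average = average,
         per_run_metrics = as.data.frame(per_run), aggregate = agg,
         confusion = pooled, confusion_row_pct = row_pct),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", toupper(x$algorithm), "on",
      paste(x$feature_cols, collapse = "+"),
      sprintf("(%d x %d-fold CV, seed %s)\n", x$n_runs, x$k,
              format(x$base_seed)))
  agg <- x$aggregate
  for (m in colnames(agg)) {
    cat(sprintf("  %-12s %6.2f +/- %.2f %%\n", m, agg["mean", m], agg["sd", m]))
  }
  invisible(x)
}

#' Compare two cross-validation conditions metric by metric
#'
#' Two-tailed t-tests on the per-run metric values (10 per condition):
#' two-sample (Welch by default) for different algorithms, paired for the
#' same algorithm under different feature sets. When both samples are
#' constant with equal means the convention `t = 0, p = 1` is used; when
#' constant with different means, `p = 0`.
#'
#' @param report_a,report_b `evaluation_report`s with per-run metrics.
#' @param test_kind `"two_sample"` or `"paired"`.
#' @param var_equal Use the classic pooled-variance two-sample test instead
#'   of Welch's correction.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per metric: `metric, t_statistic, df,
#'   p_value, significant`.
#' @export
compare_conditions <- function(report_a, report_b,
                               test_kind = c("two_sample", "paired"),
                               var_equal = FALSE, alpha = 0.05) {
  test_kind <- match.arg(test_kind)
  a <- report_a$per_run_metrics
  b <- report_b$per_run_metrics
  metrics <- colnames(a)
  out <- lapply(metrics, function(m) {
    x <- a[[m]]; y <- b[[m]]
    res <- tryCatch({
      tt <- stats::t.test(x, y, paired = test_kind == "paired",
                          var.equal = var_equal)
      c(t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }, error = function(e) {
      # degenerate: (nearly) constant data
      if (isTRUE(all.equal(mean(x), mean(y)))) c(t = 0, df = NA, p = 1)
      else c(t = sign(mean(x) - mean(y)) * Inf, df = NA, p = 0)
    })
    data.frame(metric = m, test_kind = test_kind,
               t_statistic = res["t"], df = res["df"], p_value = res["p"],
               significant = res["p"] < alpha, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Null calibration of the cross-validation comparison test
#'
#' Diagnostic for the run-level t-test: for each replicate the subject
#' labels are permuted (removing any real class signal), and the same
#' permuted data set is cross-validated twice with independent fold seeds.
#' The two resulting reports differ only by fold randomness, so the
#' comparison test's p-value for each metric should be uniform on (0, 1)
#' across replicates if the test is well calibrated at the run level.
#'
#' @param features Feature table.
#' @param n_reps Number of permutation replicates (default 100).
#' @param algorithm Classifier used (default `"nb"`, the cheapest).
#' @param metric Metric whose p-values are collected (default accuracy).
#' @param n_runs,k Reduced-scale CV dimensions (defaults 10 runs, 5 folds).
#' @param seed Base seed for permutations and fold splits.
#' @return Numeric vector of `n_reps` p-values.
#' @export
comparison_null_pvalues <- function(features, n_reps = 100, algorithm = "nb",
                                    metric = "accuracy", n_runs = 10, k = 5,
                                    seed = 1) {
  p <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    perm <- with_seed(derive_seed(seed, i), sample.int(nrow(features)))
    f <- features
    f$label <- features$label[perm]
    ra <- cross_validate(f, algorithm, n_runs = n_runs, k = k,
                         base_seed = derive_seed(seed, n_reps + 2 * i))
    rb <- cross_validate(f, algorithm, n_runs = n_runs, k = k,
                         base_seed = derive_seed(seed, n_reps + 2 * i + 1))
    cmp <- compare_conditions(ra, rb, test_kind = "two_sample")
    p[i] <- cmp$p_value[cmp$metric == metric]
  }
  p
}
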