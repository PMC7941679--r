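#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) definition: the fraction of (case, control)
#' pairs in which the case outranks the control, ties counting one half.
#' Identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores, higher = more case-like.
#' @param labels Logical (or 0/1) labels, `TRUE` = case.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # average ranks give ties weight 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold from high to low and records one
#' (false-positive rate, true-positive rate) point per distinct score. The
#' curve starts at (0, 0), ends at (1, 1), and both coordinates are
#' non-decreasing; tied scores collapse to a single point, so the
#' trapezoidal area equals the rank-statistic AUC exactly.
#'
#' @inheritParams auc
#' @return A `data.frame` with columns `threshold` (`Inf` first), `fpr`,
#'   `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  runs <- rle(s)
  last <- cumsum(runs$lengths)  # last index per distinct score
  tpr <- cumsum(y)[last] / n1
  fpr <- cumsum(!y)[last] / n0
  data.frame(threshold = c(Inf, runs$values),
             fpr = c(0, unname(fpr)), tpr = c(0, unname(tpr)))
}

#' @rdname roc_curve
#' @param roc A curve from `roc_curve()`.
#' @return `auc_trapezoid()` returns the trapezoidal area under the curve.
#' @export
auc_trapezoid <- function(roc) {
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile bootstrap, resampling cases and controls separately
#' (stratified) so every resample has both classes; deterministic given
#' `seed`.
#'
#' @inheritParams auc
#' @param n_boot Number of bootstrap resamples (>= 100; default 2000).
#' @param seed Integer seed.
#' @param alpha Two-sided miscoverage, default 0.05.
#' @return Named vector `c(ci_low, ci_high)`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000, seed = 1, alpha = 0.05) {
  labels <- as.logical(labels)
  stopifnot(n_boot >= 100)
  i1 <- which(labels)
  i0 <- which(!labels)
  if (length(i1) == 0 || length(i0) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  q <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Compare learner families by cross-validated AUC
#'
#' Runs [cross_validated_scores()] for each learner spec on one shared fold
#' assignment (so family differences are not fold noise) and reports each
#' family's out-of-fold AUC, sorted descending.
#'
#' @param cohort Cohort data frame.
#' @param learners List of [learner_spec()]s (>= 2).
#' @param k Number of folds.
#' @param seed Integer seed (folds and learners).
#' @return A `data.frame` with columns `family`, `auc`, sorted by
#'   decreasing AUC; the shared fold assignment is attached as attribute
#'   `"folds"`.
#' @export
compare_learners <- function(cohort, learners, k = 5, seed = 1) {
  stopifnot(length(learners) >= 2)
  folds <- assign_folds(nrow(cohort), k, seed, labels = cohort$is_case)
  res <- do.call(rbind, lapply(learners, function(sp) {
    sc <- cross_validated_scores(cohort, sp, k = k, seed = seed, folds = folds)
    data.frame(family = sp$family, auc = auc(sc$score, sc$is_case),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$auc), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "folds") <- folds
  res
}

#' Per-chromosome feature attributions
#'
#' For gradient-boosting models, computes SHAP-style additive tree
#' contributions: per sample and per chromosome, a signed contribution on
#' the model's margin (log-odds) scale such that baseline + contributions =
#' the sample's margin prediction. For other families the fallback is
#' permutation importance (mean absolute prediction change when one feature
#' is permuted), which supports the mean-|contribution| ranking but not
#' per-sample additivity.
#'
#' @param model A `cslv_model` handle.
#' @param cohort Cohort data frame (or any table with the model's feature
#'   columns).
#' @param seed Seed for the permutation fallback.
#' @return A `cslv_attribution` list: `ranking` (data frame `chromosome`,
#'   `mean_abs_contribution`, descending), `contributions` (samples x
#'   features signed matrix, or `NULL` under the permutation fallback),
#'   `baseline` (margin-scale intercept, or `NA`), `values` (the feature
#'   matrix scored), `method`.
#' @export
feature_attribution <- function(model, cohort, seed = 1) {
  stopifnot(inherits(model, "cslv_model"))
  X <- if (is.matrix(cohort)) cohort else cohort_features(cohort)
  if (!all(model$feature_names %in% colnames(X))) {
    stop("feature columns missing from cohort: ",
         paste(setdiff(model$feature_names, colnames(X)), collapse = ", "),
         call. = FALSE)
  }
  X <- X[, model$feature_names, drop = FALSE]
  if (!is.null(model$impute)) X <- apply_impute(X, model$impute)

  if (model$family == "gradient_boosting") {
    contrib <- stats::predict(model$fit, xgboost::xgb.DMatrix(X),
                              predcontrib = TRUE)
    contrib <- as.matrix(contrib)
    bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
    baseline <- unname(contrib[1, bias_col])
    contrib <- contrib[, setdiff(colnames(contrib), bias_col), drop = FALSE]
    rownames(contrib) <- rownames(X)
    mean_abs <- colMeans(abs(contrib))
    method <- "tree_shap"
  } else {
    base_pred <- predict_scores(model, X)
    mean_abs <- with_seed(seed, {
      vapply(model$feature_names, function(fn) {
        Xp <- X
        Xp[, fn] <- Xp[sample.int(nrow(Xp)), fn]
        mean(abs(predict_scores(model, Xp) - base_pred))
      }, numeric(1))
    })
    contrib <- NULL
    baseline <- NA_real_
    method <- "permutation"
  }
  ranking <- data.frame(chromosome = names(mean_abs),
                        mean_abs_contribution = unname(mean_abs),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean_abs_contribution), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, contributions = contrib,
                 baseline = baseline, values = X, method = method),
            class = "cslv_attribution")
}

#' @export
print.cslv_attribution <- function(x, ...) {
  cat("<cslv_attribution>", x$method, "on", nrow(x$values), "samples\n")
  print(utils::head(x$ranking, 10))
  invisible(x)
}
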