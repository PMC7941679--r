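#' Specify a learner
#'
#' Pluggable learner families behind one interface: gradient boosting
#' (xgboost), random forest and extremely randomized trees (ranger), and a
#' linear-logistic baseline (`stats::glm`). The gradient-boosting defaults —
#' maximum tree depth 5 and sample rate 1 — are the stock GBM configuration
#' this analysis design uses; tree count and learning rate default to 100
#' and 0.1 with no early stopping, so runs are reproducible without hidden
#' tuning.
#'
#' @param family One of `"gradient_boosting"`, `"random_forest"`,
#'   `"extremely_randomized_trees"`, `"linear_logistic"`.
#' @param max_depth Maximum tree depth.
#' @param sample_rate Row subsampling fraction per tree.
#' @param n_trees Number of trees (boosting rounds / forest size).
#' @param learning_rate Boosting shrinkage.
#' @param missing_policy `"native"` uses the learner's own missing-value
#'   handling when it has one (xgboost); otherwise, and under
#'   `"median_impute"`, missing features are imputed with per-column medians
#'   fit on the training split only (no leakage through imputation).
#' @return A `learner_spec` list.
#' @export
learner_spec <- function(family = c("gradient_boosting", "random_forest",
                                    "extremely_randomized_trees",
                                    "linear_logistic"),
                         max_depth = 5, sample_rate = 1.0, n_trees = 100,
                         learning_rate = 0.1,
                         missing_policy = c("native", "median_impute")) {
  family <- match.arg(family)
  missing_policy <- match.arg(missing_policy)
  stopifnot(max_depth >= 1, sample_rate > 0, sample_rate <= 1,
            n_trees >= 1, learning_rate > 0)
  structure(list(family = family, max_depth = as.integer(max_depth),
                 sample_rate = sample_rate, n_trees = as.integer(n_trees),
                 learning_rate = learning_rate,
                 missing_policy = missing_policy),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  cat("<learner_spec>", x$family,
      sprintf("(depth %d, sample_rate %g, %d trees, lr %g, missing: %s)\n",
              x$max_depth, x$sample_rate, x$n_trees, x$learning_rate,
              x$missing_policy))
  invisible(x)
}

# Feature matrix (chr* columns) from a cohort table, rownames = sample_id.
cohort_features <- function(cohort) {
  cols <- grep("^chr", names(cohort), value = TRUE)
  if (length(cols) == 0) stop("cohort has no chr* feature columns", call. = FALSE)
  m <- as.matrix(cohort[, cols, drop = FALSE])
  rownames(m) <- cohort$sample_id
  m
}

# Median imputation values fit on a training matrix; all-missing columns
# fall back to 0 (the diploid CSLV value).
fit_impute <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  med
}

apply_impute <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    X[is.na(X[, j]), j] <- med[[colnames(X)[j]]]
  }
  X
}

#' Fit a learner on a feature matrix
#'
#' Internal-grade but exported for stagewise use: fits `spec` on `X`
#' (samples x chromosome features, `NA` allowed) against logical labels `y`
#' and returns a model handle usable with [predict_scores()] and
#' [feature_attribution()].
#'
#' @param spec A [learner_spec()].
#' @param X Numeric feature matrix.
#' @param y Logical (or 0/1) labels, `TRUE` = case.
#' @param seed Integer seed for the learner's internal randomness.
#' @return A `cslv_model` handle.
#' @export
fit_learner <- function(spec, X, y, seed = 1) {
  stopifnot(inherits(spec, "learner_spec"), nrow(X) == length(y))
  y <- as.logical(y)
  if (length(unique(y)) < 2) {
    stop("training split contains a single class", call. = FALSE)
  }
  impute <- NULL
  native_na <- spec$family == "gradient_boosting"
  if (spec$missing_policy == "median_impute" || !native_na) {
    impute <- fit_impute(X)
    X <- apply_impute(X, impute)
  }
  fit <- switch(spec$family,
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = spec$max_depth,
                      eta = spec$learning_rate,
                      subsample = spec$sample_rate,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = spec$n_trees, verbose = 0
      )
    },
    random_forest = ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(FALSE, TRUE)),
      probability = TRUE, num.trees = spec$n_trees,
      max.depth = spec$max_depth, sample.fraction = spec$sample_rate,
      seed = seed, num.threads = 1
    ),
    extremely_randomized_trees = ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(FALSE, TRUE)),
      probability = TRUE, num.trees = spec$n_trees,
      max.depth = spec$max_depth, sample.fraction = spec$sample_rate,
      splitrule = "extratrees", num.random.splits = 1,
      seed = seed, num.threads = 1
    ),
    linear_logistic = {
      df <- as.data.frame(X)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    }
  )
  structure(list(family = spec$family, spec = spec, fit = fit,
                 feature_names = colnames(X), impute = impute),
            class = "cslv_model")
}

#' Score samples with a fitted model
#'
#' @param model A `cslv_model` from [fit_learner()] or
#'   [train_final_model()].
#' @param X Feature matrix with the model's feature columns.
#' @return Numeric vector of case probabilities in `[0, 1]`.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "cslv_model"))
  if (!all(model$feature_names %in% colnames(X))) {
    stop("feature columns missing from newdata: ",
         paste(setdiff(model$feature_names, colnames(X)), collapse = ", "),
         call. = FALSE)
  }
  X <- X[, model$feature_names, drop = FALSE]
  if (!is.null(model$impute)) X <- apply_impute(X, model$impute)
  switch(model$family,
    gradient_boosting = {
      p <- stats::predict(model$fit, xgboost::xgb.DMatrix(X))
      as.numeric(p)
    },
    random_forest = ,
    extremely_randomized_trees =
      as.numeric(stats::predict(model$fit, data = as.data.frame(X),
                                num.threads = 1)$predictions[, "TRUE"]),
    linear_logistic =
      as.numeric(stats::predict(model$fit, newdata = as.data.frame(X),
                                type = "response"))
  )
}

#' Assign cross-validation folds
#'
#' Randomly partitions `n` samples into `k` folds whose sizes differ by at
#' most one. With `labels` given (the default analysis path), the split is
#' stratified: per-fold case counts also differ by at most one, which at low
#' prevalence prevents degenerate training splits. Deterministic given
#' `seed`.
#'
#' @param n Sample count.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed.
#' @param labels Optional logical labels to stratify by.
#' @return Integer vector of fold ids in `1..k`.
#' @export
assign_folds <- function(n, k, seed = 1, labels = NULL) {
  stopifnot(k >= 2)
  if (n < k) stop("n (", n, ") must be at least k (", k, ")", call. = FALSE)
  if (!is.null(labels)) stopifnot(length(labels) == n)
  with_seed(seed, {
    fold <- integer(n)
    counter <- 0L
    strata <- if (is.null(labels)) list(seq_len(n)) else
      split(seq_len(n), as.logical(labels))
    # one cyclic counter across strata keeps total fold sizes within 1
    for (idx in strata) {
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
      counter <- counter + length(idx)
    }
    fold
  })
}

#' Out-of-fold risk scores by k-fold cross-validation
#'
#' For each fold, trains the learner on the other k-1 folds and scores the
#' held-out fold, so every sample's score comes from a model that never saw
#' it (no leakage; imputation, when used, is also fit on the training folds
#' only). The concatenated scores cover the cohort exactly once.
#'
#' @param cohort Cohort data frame from [assemble_cohort()].
#' @param learner A [learner_spec()].
#' @param k Number of folds.
#' @param seed Integer seed driving the fold assignment and the learners.
#' @param folds Optional pre-computed fold ids (used by
#'   [compare_learners()] to share folds across families).
#' @return A risk-score `data.frame`: `sample_id`, `is_case`, `fold`,
#'   `score`.
#' @export
cross_validated_scores <- function(cohort, learner = learner_spec(), k = 5,
                                   seed = 1, folds = NULL) {
  X <- cohort_features(cohort)
  y <- cohort$is_case
  if (is.null(folds)) folds <- assign_folds(nrow(X), k, seed, labels = y)
  stopifnot(length(folds) == nrow(X))
  score <- rep(NA_real_, nrow(X))
  for (f in sort(unique(folds))) {
    train <- folds != f
    if (length(unique(y[train])) < 2) {
      stop("training split for fold ", f, " contains a single class",
           call. = FALSE)
    }
    model <- fit_learner(learner, X[train, , drop = FALSE], y[train],
                         seed = seed + f)
    score[!train] <- predict_scores(model, X[!train, , drop = FALSE])
  }
  data.frame(sample_id = cohort$sample_id, is_case = y,
             fold = folds, score = score, stringsAsFactors = FALSE)
}

#' Train a single train/test-split model
#'
#' Stratified single split (default 80/20); the model is fit on the training
#' part only and the held-out part is scored, as for a final ROC or
#' attribution analysis.
#'
#' @param cohort Cohort data frame.
#' @param learner A [learner_spec()].
#' @param train_fraction Fraction of samples used for training, in (0, 1).
#' @param seed Integer seed.
#' @return List with `model` (a `cslv_model` reusable by
#'   [feature_attribution()]) and `holdout` (risk-score data frame for the
#'   held-out samples, `fold` = 1).
#' @export
train_final_model <- function(cohort, learner = learner_spec(),
                              train_fraction = 0.8, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  X <- cohort_features(cohort)
  y <- cohort$is_case
  n <- nrow(X)
  # stratified split: same held-out fraction within each class
  test <- logical(n)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_test <- max(1, round(length(idx) * (1 - train_fraction)))
      test[idx[sample.int(length(idx), n_test)]] <- TRUE
    }
  })
  model <- fit_learner(learner, X[!test, , drop = FALSE], y[!test],
                       seed = seed)
  holdout <- data.frame(
    sample_id = cohort$sample_id[test], is_case = y[test],
    fold = 1L, score = predict_scores(model, X[test, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  list(model = model, holdout = holdout)
}

#' Read/write risk-score tables
#'
#' @param scores Risk-score data frame (`sample_id`, `is_case`, `fold`,
#'   `score`).
#' @param path File path.
#' @return `write_scores()` returns `path` invisibly; `read_scores()` the
#'   score data frame.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  out$score <- format_full(out$score)
  out$is_case <- ifelse(scores$is_case, "TRUE", "FALSE")
  write_tsv_plain(out, path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read_tsv_plain(path)
  req <- c("sample_id", "is_case", "fold", "score")
  if (!all(req %in% names(df))) {
    stop("score table lacks required column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$is_case <- as.logical(df$is_case)
  df$fold <- as.integer(df$fold)
  df$score <- as.numeric(df$score)
  df
}
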