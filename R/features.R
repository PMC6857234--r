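FEATURE_SENTINEL <- -1

#' Build the labeled feature matrix for call-set integration
#'
#' One row per individual call across all pipelines. The label is the call's
#' TP status against the truth set under the category's matching rule
#' (reciprocal overlap for deletions, breakpoint window for insertions).
#' The seven caller-reported features are `SVLEN`, `DEPTHPVAL`, `RE`, `MAPQ`,
#' `CIEND`, `CIPOS`, `PRECISE` (encoded 1/0). A feature a caller does not
#' provide is masked: its value is the sentinel -1 and the corresponding
#' `has_*` mask column is 0, so missingness is explicit rather than silently
#' zero-filled.
#'
#' @param callsets list of normalized `sv_callset`s (one per pipeline), all
#'   of one category.
#' @param truth normalized truth `sv_callset` of the same category.
#' @param category `"deletion"` or `"insertion"`.
#' @param min_frac,reciprocal,window matching parameters.
#' @return A data.frame: `source`, `chrom`, `start`, `end`, the seven feature
#'   columns, seven `has_*` mask columns, and logical `label`.
#' @export
extract_features <- function(callsets, truth, category = c("deletion", "insertion"),
                             min_frac = 0.5, reciprocal = TRUE, window = 100) {
  category <- match.arg(category)
  rows <- lapply(callsets, function(cs) {
    m <- match_category(cs, truth, category, min_frac = min_frac,
                        reciprocal = reciprocal, window = window)
    r <- cs$records
    out <- data.frame(source = r$source, chrom = r$chrom,
                      start = r$start, end = r$end,
                      stringsAsFactors = FALSE)
    vals <- list(SVLEN = r$svlen, DEPTHPVAL = r$DEPTHPVAL, RE = r$RE,
                 MAPQ = r$MAPQ, CIEND = r$CIEND, CIPOS = r$CIPOS,
                 PRECISE = as.numeric(r$PRECISE))
    for (k in FEATURE_KEYS) {
      v <- vals[[k]]
      out[[k]] <- ifelse(is.na(v), FEATURE_SENTINEL, v)
      out[[paste0("has_", k)]] <- as.integer(!is.na(v))
    }
    out$label <- m$call_labels$label == "TP"
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random train/test split of feature rows
#'
#' Disjoint, exhaustive random split, reproducible for a fixed seed. With
#' `train_frac = 0.2` on 100 rows the split is exactly 20/80.
#'
#' @param rows feature-row data.frame from [extract_features()].
#' @param train_frac fraction of rows assigned to training (0 < f < 1).
#' @param seed integer seed.
#' @return A list with elements `train` and `test`.
#' @export
split_train_test <- function(rows, train_frac = 0.2, seed = 1L) {
  stopifnot(is.data.frame(rows), train_frac > 0, train_frac < 1)
  n <- nrow(rows)
  if (n < 2) stop("need at least 2 rows to split")
  n_train <- max(1L, min(n - 1L, as.integer(floor(n * train_frac))))
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = rows[idx, , drop = FALSE],
       test = rows[-idx, , drop = FALSE])
}

feature_matrix <- function(rows, feature_order = FEATURE_KEYS) {
  stopifnot(all(feature_order %in% names(rows)))
  as.matrix(rows[, feature_order, drop = FALSE])
}

#' Train the random-forest call-set integrator
#'
#' Fits a random forest (an xgboost ensemble of `n_trees` trees grown in a
#' single boosting round with row and per-node column subsampling) on the
#' seven caller features, predicting whether a call is true. Per-feature
#' contribution percentages are the ensemble's total-Gain importances
#' normalized to sum to 100; features the ensemble never splits on
#' contribute 0.
#'
#' @param train feature rows with both labels present.
#' @param seed integer seed (the fit is single-threaded and reproducible).
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @return An `sv_model`: the fitted handle, feature order, contribution
#'   table and training metadata.
#' @export
train_classifier <- function(train, seed = 1L, n_trees = 500, max_depth = 6) {
  stopifnot(is.data.frame(train), "label" %in% names(train))
  y <- as.numeric(train$label)
  if (length(unique(y)) < 2) stop("training data contains a single class")
  x <- feature_matrix(train)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  params <- list(
    booster = "gbtree",
    objective = "binary:logistic",
    eta = 1,
    max_depth = max_depth,
    subsample = 0.8,
    colsample_bynode = 0.8,
    num_parallel_tree = n_trees,
    nthread = 1,
    seed = as.integer(seed)
  )
  fit <- xgboost::xgb.train(params = params, data = dtrain, nrounds = 1,
                            verbose = 0)
  imp <- xgboost::xgb.importance(model = fit)
  contrib <- setNames(rep(0, length(FEATURE_KEYS)), FEATURE_KEYS)
  if (!is.null(imp) && nrow(imp) > 0) {
    contrib[imp$Feature] <- imp$Gain / sum(imp$Gain) * 100
  }
  structure(list(
    fit = fit,
    feature_order = FEATURE_KEYS,
    contributions = contrib,
    seed = as.integer(seed),
    n_trees = n_trees,
    n_train = nrow(train)
  ), class = "sv_model")
}

#' @export
print.sv_model <- function(x, ...) {
  cat(sprintf("sv_model: %d-tree random forest on %d rows (seed %d)\n",
              x$n_trees, x$n_train, x$seed))
  cat("feature contributions (%):\n")
  print(round(x$contributions, 1))
  invisible(x)
}

#' Predict call labels with a trained integrator
#'
#' @param object an `sv_model`.
#' @param rows feature rows.
#' @param threshold probability cutoff for calling a row true.
#' @param ... unused.
#' @return Logical vector of predicted labels.
#' @export
predict.sv_model <- function(object, rows, threshold = 0.5, ...) {
  x <- feature_matrix(rows, object$feature_order)
  p <- predict(object$fit, xgboost::xgb.DMatrix(x))
  p > threshold
}

#' Evaluate a trained integrator on held-out rows
#'
#' Scores predicted-true rows against the truth labels: TP = predicted true
#' and labeled true, FP = predicted true and labeled false, FN = predicted
#' false and labeled true.
#'
#' @param model an `sv_model`.
#' @param test feature rows disjoint from training.
#' @return A list: `metrics` (an `sv_metrics`) and `contributions` (percent
#'   per feature, summing to 100).
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(model, "sv_model"), is.data.frame(test))
  if (!all(model$feature_order %in% names(test))) {
    stop("test rows lack the model's feature columns")
  }
  pred <- predict(model, test)
  y <- test$label
  metrics <- compute_metrics(list(
    tp = sum(pred & y), fp = sum(pred & !y), fn = sum(!pred & y)
  ))
  list(metrics = metrics, contributions = model$contributions)
}
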