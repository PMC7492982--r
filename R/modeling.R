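#' Cross-validated classifier evaluation
#'
#' The evaluation protocol for both the diagnostic (SSD vs HV) and relapse
#' (illness vs health period) tasks: stratified 5-fold cross-validation of
#' a random forest (`"RF"`), RBF-kernel support vector machine
#' (`"SVM_RBF"`) or gradient boosting (`"GB"`) classifier. Within each
#' fold, behavioral features are standardized on the training rows only,
#' hyperparameters are tuned on an inner held-out validation split of the
#' training rows by AUC, the model is refit on the full training rows and
#' scored on the test rows with continuous scores (class probabilities or
#' decision values) for the AUC. All metrics are computed per fold and
#' then averaged. Deterministic for a fixed seed.
#'
#' @name modeling
NULL

# Small fixed tuning grids; the RBF kernel is fixed for the SVM.
default_grids <- list(
  RF = expand.grid(mtry = c(11L, 41L), min_node = 1L),
  SVM_RBF = expand.grid(cost = c(1, 10), gamma_scale = 1),
  GB = expand.grid(eta = c(0.1, 0.3), max_depth = 3L)
)

fit_model <- function(kind, x, y_pos, params, seed) {
  switch(kind,
    RF = ranger::ranger(
      x = x, y = factor(ifelse(y_pos, "pos", "neg"), c("neg", "pos")),
      probability = TRUE, num.trees = 300,
      mtry = min(params$mtry, ncol(x)), min.node.size = params$min_node,
      seed = seed, num.threads = 1),
    SVM_RBF = e1071::svm(
      x = x, y = factor(ifelse(y_pos, "pos", "neg"), c("neg", "pos")),
      kernel = "radial", cost = params$cost,
      gamma = params$gamma_scale / ncol(x), scale = FALSE),
    GB = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y_pos))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = params$eta,
                      max_depth = params$max_depth, nthread = 1,
                      seed = seed),
        data = dtrain, nrounds = 150, verbose = 0)
    },
    stop("unknown model kind: ", kind))
}

# Continuous score, larger = more positive-class.
predict_scores <- function(kind, model, x) {
  switch(kind,
    RF = unname(predict(model, data = x,
                        num.threads = 1)$predictions[, "pos"]),
    SVM_RBF = {
      pred <- predict(model, x, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      # e1071 orients decision values toward the first level in "A/B"
      if (grepl("^pos/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
    },
    GB = predict(model, xgboost::xgb.DMatrix(x)))
}

predict_positive <- function(kind, scores) {
  if (kind == "SVM_RBF") scores > 0 else scores >= 0.5
}

# Stratified fold assignment (optionally grouped so all of a participant's
# rows share a fold). Returns integer fold ids 1..k per row.
make_folds <- function(y_pos, k, seed, groups = NULL) {
  n <- length(y_pos)
  if (is.null(groups)) {
    folds <- integer(n)
    local_rng(seed, {
      for (cls in unique(y_pos)) {
        idx <- which(y_pos == cls)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    folds
  } else {
    # greedy balance of (positives, rows) over folds, group-atomic
    gt <- unique(groups)
    g_pos <- vapply(gt, function(g) sum(y_pos[groups == g]), numeric(1))
    g_n <- vapply(gt, function(g) sum(groups == g), numeric(1))
    ord <- local_rng(seed, order(g_pos + g_n / (max(g_n) + 1),
                                 runif(length(gt)), decreasing = TRUE))
    fold_pos <- numeric(k); fold_n <- numeric(k)
    g_fold <- integer(length(gt))
    for (i in ord) {
      target <- which.min(fold_pos + fold_n / (sum(g_n) + 1))
      g_fold[i] <- target
      fold_pos[target] <- fold_pos[target] + g_pos[i]
      fold_n[target] <- fold_n[target] + g_n[i]
    }
    g_fold[match(groups, gt)]
  }
}

fold_metrics <- function(y_pos, scores, predicted_pos) {
  tp <- sum(predicted_pos & y_pos); fp <- sum(predicted_pos & !y_pos)
  fn <- sum(!predicted_pos & y_pos); tn <- sum(!predicted_pos & !y_pos)
  prec_pos <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec_pos <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec_neg <- if (tn + fn > 0) tn / (tn + fn) else 0
  rec_neg <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (prec_pos + rec_pos > 0)
    2 * prec_pos * rec_pos / (prec_pos + rec_pos) else 0
  tibble(auc = auc_score(scores, y_pos),
         accuracy = (tp + tn) / length(y_pos), f1_positive = f1,
         precision_pos = prec_pos, precision_neg = prec_neg,
         recall_pos = rec_pos, recall_neg = rec_neg)
}

#' Run stratified 5-fold cross-validation
#'
#' @param features Feature tibble from [build_feature_matrix()] (metadata
#'   columns are used for grouping) or a bare numeric matrix.
#' @param labels Character/factor vector of row labels.
#' @param model_kind One of `"RF"`, `"SVM_RBF"`, `"GB"`.
#' @param seed Integer master seed for fold assignment, tuning split and
#'   model fitting.
#' @param positive Label treated as the positive (clinical) class;
#'   defaults to `"SSD"` or `"illness"` when present.
#' @param group_by_participant For relapse data: keep all of a
#'   participant's windows in one fold (prevents identity leakage).
#' @param k Number of folds (default 5).
#' @param tune Run the inner held-out tuning split; `FALSE` uses the first
#'   grid row.
#' @return A `cv_result`: per-fold metric tibble, aggregate means,
#'   `sd_auc`, fold assignments, fitted per-fold models and
#'   standardization objects (used by [cross_fold_importance()]). Folds
#'   whose test rows contain a single class get `NA` AUC and are excluded
#'   from `mean_auc` with a warning.
#' @export
run_cv <- function(features, labels, model_kind = c("RF", "SVM_RBF", "GB"),
                   seed = 1L, positive = NULL,
                   group_by_participant = FALSE, k = 5L, tune = TRUE) {
  model_kind <- match.arg(model_kind)
  if (is.data.frame(features)) {
    parts <- feature_parts(features)
    x <- parts$x
    groups <- if (group_by_participant) parts$meta$participant_id else NULL
  } else {
    x <- as.matrix(features)
    groups <- NULL
    if (group_by_participant) stop("grouping requires a feature tibble")
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  if (is.null(positive)) {
    positive <- intersect(c("SSD", "illness"), labels)[1]
    if (is.na(positive)) positive <- sort(unique(labels))[1]
  }
  y_pos <- labels == positive
  if (min(sum(y_pos), sum(!y_pos)) < 2L) stop("need >= 2 rows per class")
  folds <- make_folds(y_pos, k, derive_seed(seed, 1L), groups)
  grid <- default_grids[[model_kind]]
  per_fold <- list(); models <- list(); preprocs <- list()
  chosen <- list()
  for (f in sort(unique(folds))) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    prep <- standardize_features(x[train_idx, , drop = FALSE])
    x_train <- prep$x
    x_test <- apply_standardize(prep, x[test_idx, , drop = FALSE])
    y_train <- y_pos[train_idx]
    fseed <- derive_seed(seed, 100L + f)
    best <- grid[1, , drop = FALSE]
    if (tune && nrow(grid) > 1L) {
      # inner held-out validation split (stratified 75/25) scored by AUC
      inner <- make_folds(y_train, 4L, derive_seed(fseed, 2L))
      val <- inner == 1L
      if (length(unique(y_train[val])) == 2L &&
          length(unique(y_train[!val])) == 2L) {
        scores_by_row <- vapply(seq_len(nrow(grid)), function(gi) {
          m <- fit_model(model_kind, x_train[!val, , drop = FALSE],
                         y_train[!val], grid[gi, , drop = FALSE],
                         derive_seed(fseed, 10L + gi))
          auc_score(predict_scores(model_kind, m,
                                   x_train[val, , drop = FALSE]),
                    y_train[val])
        }, numeric(1))
        best <- grid[which.max(scores_by_row), , drop = FALSE]
      }
    }
    model <- fit_model(model_kind, x_train, y_train, best,
                       derive_seed(fseed, 3L))
    scores <- predict_scores(model_kind, model, x_test)
    m <- fold_metrics(y_pos[test_idx], scores,
                      predict_positive(model_kind, scores))
    m$fold <- f
    per_fold[[f]] <- m
    models[[f]] <- model
    preprocs[[f]] <- prep
    chosen[[f]] <- best
  }
  per_fold <- dplyr::bind_rows(per_fold)
  if (anyNA(per_fold$auc)) {
    warning("fold(s) with single-class test set excluded from mean AUC: ",
            paste(per_fold$fold[is.na(per_fold$auc)], collapse = ", "))
  }
  structure(list(
    model_kind = model_kind,
    per_fold = per_fold,
    mean_f1 = mean(per_fold$f1_positive),
    mean_accuracy = mean(per_fold$accuracy),
    mean_auc = mean(per_fold$auc, na.rm = TRUE),
    sd_auc = sd(per_fold$auc, na.rm = TRUE),
    seed = seed, positive = positive,
    fold_assignments = folds,
    models = models, preprocs = preprocs,
    hyperparameters = chosen,
    x = x, y_pos = y_pos), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean AUC %.3f (SD %.3f), accuracy %.3f, F1[%s] %.3f\n",
              x$model_kind, x$mean_auc, x$sd_auc, x$mean_accuracy,
              x$positive, x$mean_f1))
  invisible(x)
}

#' Repeat the control-window draw to check stability
#'
#' Redraws every healthy volunteer's random 4-week control window
#' `n_iter` times (each iteration with its own sub-seed), rebuilds the
#' diagnostic feature matrix and reruns cross-validation, to verify the
#' evaluation is not sensitive to which healthy period was sampled.
#'
#' @param ssd_windows List of diagnostic SSD `observation_window`s (fixed
#'   across iterations).
#' @param hv_archives List of HV [search_archive()] objects.
#' @param lexicon A `liwc_lexicon`.
#' @param n_iter Number of redraw iterations (default 10).
#' @param model_kind,seed,tune Passed to [run_cv()].
#' @return List with `results` (one `cv_result` per iteration) and
#'   `sd_mean_auc`, the across-iteration SD of the mean AUC.
#' @export
repeat_control_sampling <- function(ssd_windows, hv_archives, lexicon,
                                    n_iter = 10L,
                                    model_kind = c("RF", "SVM_RBF", "GB"),
                                    seed = 1L, tune = TRUE) {
  model_kind <- match.arg(model_kind)
  results <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    hv_windows <- list()
    for (j in seq_along(hv_archives)) {
      w <- control_window(hv_archives[[j]],
                          seed = derive_seed(seed, it * 1000L + j))
      if (!is_window_exclusion(w)) hv_windows[[length(hv_windows) + 1L]] <- w
    }
    feats <- build_feature_matrix(c(ssd_windows, hv_windows), lexicon)
    results[[it]] <- run_cv(feats, feats$label, model_kind,
                            seed = derive_seed(seed, it), tune = tune)
  }
  list(results = results,
       sd_mean_auc = sd_pop(vapply(results, `[[`, numeric(1), "mean_auc")))
}

#' Summarize cross-validation results as a report table
#'
#' One row per classifier with the mean F1 score, per-class precision and
#' recall, mean accuracy and "mean (SD) AUC" formatted to 2 decimals.
#' Rows are ordered SVM, RF, GB.
#'
#' @param results A `cv_result` or list of them.
#' @return Tibble report; empty input yields an empty tibble.
#' @export
summarize_cv <- function(results) {
  if (inherits(results, "cv_result")) results <- list(results)
  if (length(results) == 0L) return(tibble())
  rows <- dplyr::bind_rows(lapply(results, function(r) {
    tibble(classifier = r$model_kind,
           mean_f1 = round(r$mean_f1, 2),
           precision_negative = round(mean(r$per_fold$precision_neg), 2),
           precision_positive = round(mean(r$per_fold$precision_pos), 2),
           recall_negative = round(mean(r$per_fold$recall_neg), 2),
           recall_positive = round(mean(r$per_fold$recall_pos), 2),
           mean_accuracy = round(r$mean_accuracy, 2),
           mean_sd_auc = sprintf("%.2f (%.2f)", r$mean_auc, r$sd_auc))
  }))
  ord <- match(rows$classifier, c("SVM_RBF", "RF", "GB"))
  rows[order(ord), ]
}
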