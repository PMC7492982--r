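#' Permutation feature importance on one validation fold
#'
#' Importance of a feature is the drop in the model's score when that
#' feature is randomly shuffled on held-out data, with AUC as the model
#' score: `importance = baseline_auc - mean(AUC over n_repeats shuffles)`.
#' Shuffles are drawn from a single seeded stream, column-major (all
#' repeats of feature 1, then feature 2, ...), so an independent
#' re-implementation sharing the seed reproduces them exactly.
#'
#' @param model A fitted model from [run_cv()]'s fold (ranger, e1071 svm or
#'   xgboost booster).
#' @param model_kind `"RF"`, `"SVM_RBF"` or `"GB"`.
#' @param x_valid Numeric matrix of validation rows (already standardized
#'   as the model saw them).
#' @param y_pos Logical positive-class indicator for the validation rows;
#'   both classes must be present.
#' @param n_repeats Shuffles per feature (default 10).
#' @param seed Integer seed for the shuffle stream.
#' @return Tibble with `feature`, `importance`, `sd_permuted` (SD of the
#'   permuted AUCs) and the fold `baseline` AUC.
#' @export
permutation_importance <- function(model, model_kind, x_valid, y_pos,
                                   n_repeats = 10L, seed = 1L) {
  if (length(unique(y_pos)) < 2L) {
    stop("validation set contains a single class; AUC undefined")
  }
  baseline <- auc_score(predict_scores(model_kind, model, x_valid), y_pos)
  n <- nrow(x_valid)
  p <- ncol(x_valid)
  imp <- numeric(p)
  sd_perm <- numeric(p)
  local_rng(seed, {
    for (j in seq_len(p)) {
      aucs <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        xp <- x_valid
        xp[, j] <- xp[sample.int(n), j]
        aucs[r] <- auc_score(predict_scores(model_kind, model, xp), y_pos)
      }
      imp[j] <- baseline - mean(aucs)
      sd_perm[j] <- sd_pop(aucs)
    }
  })
  tibble(feature = colnames(x_valid), importance = imp,
         sd_permuted = sd_perm, baseline = baseline)
}

#' Cross-fold permutation importance table
#'
#' Computes [permutation_importance()] on the validation (test) rows of
#' each cross-validation fold using that fold's fitted model and
#' standardization, averages the per-feature importances across the 5
#' folds, and returns them sorted by decreasing mean importance (ties
#' broken by feature name for deterministic output). Each feature is
#' annotated with the direction of its raw class-conditional mean
#' difference, mirroring the "Reduced/Increased ... in the positive class"
#' phrasing of published importance tables.
#'
#' @param cv A `cv_result` from [run_cv()] (carries per-fold models,
#'   standardizations, fold assignments and the data).
#' @param n_repeats Shuffles per feature per fold.
#' @param seed Master seed; each fold gets a derived sub-seed.
#' @param top_k Optionally truncate to the top `k` rows after sorting.
#' @return An `importance_table` tibble: `rank`, `feature`,
#'   `mean_importance`, `sd_importance` (across folds), `direction`
#'   (`"higher_in_positive"` / `"lower_in_positive"`). Attributes carry
#'   `model_kind` and `n_repeats`.
#' @export
cross_fold_importance <- function(cv, n_repeats = 10L, seed = 1L,
                                  top_k = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  folds <- sort(unique(cv$fold_assignments))
  per_fold <- lapply(folds, function(f) {
    idx <- which(cv$fold_assignments == f)
    y <- cv$y_pos[idx]
    if (length(unique(y)) < 2L) return(NULL)
    xv <- apply_standardize(cv$preprocs[[f]], cv$x[idx, , drop = FALSE])
    permutation_importance(cv$models[[f]], cv$model_kind, xv, y,
                           n_repeats = n_repeats,
                           seed = derive_seed(seed, 500L + f))
  })
  per_fold <- per_fold[!vapply(per_fold, is.null, logical(1))]
  if (length(per_fold) == 0L) stop("no fold had both classes in validation")
  imp_mat <- vapply(per_fold, `[[`, numeric(ncol(cv$x)), "importance")
  imp_mat <- matrix(imp_mat, nrow = ncol(cv$x))
  mean_imp <- rowMeans(imp_mat)
  sd_imp <- apply(imp_mat, 1, sd_pop)
  # direction from class-conditional means of the raw (unstandardized)
  # feature, not from the model
  mu_pos <- colMeans(cv$x[cv$y_pos, , drop = FALSE])
  mu_neg <- colMeans(cv$x[!cv$y_pos, , drop = FALSE])
  direction <- unname(ifelse(mu_pos >= mu_neg, "higher_in_positive",
                             "lower_in_positive"))
  out <- tibble(feature = colnames(cv$x), mean_importance = mean_imp,
                sd_importance = sd_imp, direction = direction)
  out <- out[order(-out$mean_importance, out$feature), ]
  if (!is.null(top_k)) out <- head(out, top_k)
  out <- dplyr::bind_cols(tibble(rank = seq_len(nrow(out))), out)
  structure(out, model_kind = cv$model_kind, n_repeats = n_repeats,
            class = c("importance_table", class(out)))
}

#' Format an importance table like a published feature-importance report
#'
#' @param imp An `importance_table`.
#' @param positive_label,negative_label Labels used in the direction
#'   phrase.
#' @return Tibble with `rank`, `feature_description` and
#'   `mean_importance` rounded to 4 decimals.
#' @export
format_importance <- function(imp, positive_label = "positive class",
                              negative_label = "comparison class") {
  phrase <- ifelse(imp$direction == "higher_in_positive",
                   sprintf("Increased %s in %s compared to %s", imp$feature,
                           positive_label, negative_label),
                   sprintf("Reduced %s in %s compared to %s", imp$feature,
                           positive_label, negative_label))
  tibble(rank = imp$rank, feature_description = phrase,
         mean_importance = round(imp$mean_importance, 4))
}
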