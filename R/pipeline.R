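#' Configuration-driven pipeline
#'
#' The full analysis — simulate (or load) a cohort, segment windows,
#' extract features, evaluate classifiers, rank features — as a sequence
#' of idempotent steps driven by one YAML run configuration. All
#' randomness flows from the config's single master seed through named
#' substreams, so a rerun with the same config reproduces every output
#' byte-for-byte. Each step writes a `manifest.json` (config echo, seeds,
#' package version) sufficient to replay the run. The steps are plain R
#' functions; `inst/scripts/searchprint-pipeline.R` wraps them for shell
#' use.
#'
#' Config keys (all optional unless a step needs them): `output_dir`,
#' `seed`, `task` (`"diagnostic"` or `"relapse"`), `models`, `month_days`,
#' `n_iter`, `n_repeats`, `group_folds`, `lexicon` (path to a .dic; the
#' bundled fixture when absent), `archives_dir`, `timelines`, and a
#' `cohort` block (`n_ssd`, `n_hv`, ...) forwarded to [cohort_spec()].
#'
#' @param config Path to a YAML file, or a named list.
#' @return Each step returns its main artifact invisibly (paths or
#'   tibbles).
#' @name pipeline
NULL

load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(output_dir = "searchprint_run", seed = 1L,
                   task = "diagnostic", models = c("SVM_RBF", "RF", "GB"),
                   month_days = 28L, n_iter = 10L, n_repeats = 10L,
                   group_folds = TRUE, lexicon = NULL, cohort = list())
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

config_lexicon <- function(cfg) {
  if (is.null(cfg$lexicon)) fixture_lexicon() else load_dic(cfg$lexicon)
}

write_manifest <- function(cfg, step, dir, extra = list()) {
  manifest <- c(list(step = step, seed = cfg$seed,
                     package_version = as.character(
                       utils::packageVersion("searchprint")),
                     config = cfg[setdiff(names(cfg), "cohort")]),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
}

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config) {
  cfg <- load_run_config(config)
  spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  cohort <- generate_cohort(spec)
  dir <- file.path(cfg$output_dir, "cohort")
  write_cohort(cohort, dir)
  write_manifest(cfg, "simulate", dir,
                 list(n_ssd = spec$n_ssd, n_hv = spec$n_hv))
  invisible(dir)
}

# Load archives + timelines either from a prior simulate step or from
# user-supplied paths.
load_inputs <- function(cfg) {
  arch_dir <- cfg$archives_dir %||% file.path(cfg$output_dir, "cohort",
                                              "archives")
  tl_path <- cfg$timelines %||% file.path(cfg$output_dir, "cohort",
                                          "timelines.csv")
  if (!dir.exists(arch_dir) || !file.exists(tl_path)) {
    stop("missing cohort inputs under ", arch_dir,
         "; run pipeline_simulate first or set archives_dir/timelines")
  }
  files <- list.files(arch_dir, pattern = "\\.jsonl$", full.names = TRUE)
  archives <- lapply(files, read_canonical)
  names(archives) <- vapply(archives, `[[`, "", "participant_id")
  list(archives = archives, timelines = read_timeline(tl_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Windows for one task over a whole cohort; exclusions dropped.
segment_cohort <- function(archives, timelines, task, seed,
                           month_days = 28L) {
  windows <- list()
  for (pid in names(timelines)) {
    tl <- timelines[[pid]]
    ar <- archives[[pid]]
    if (is.null(ar)) next
    if (task == "diagnostic") {
      w <- if (tl$group == "SSD") {
        if (nrow(tl$hospitalizations) == 0L) next
        diagnostic_window(ar, tl, month_days)
      } else {
        control_window(ar, seed = derive_seed(seed, 300L + match(pid, names(timelines))),
                       month_days = month_days)
      }
      if (!is_window_exclusion(w)) windows[[length(windows) + 1L]] <- w
    } else {
      if (tl$group != "SSD") next
      ws <- relapse_windows(ar, tl, month_days)
      windows <- c(windows, ws)
    }
  }
  windows
}

#' @rdname pipeline
#' @export
pipeline_featurize <- function(config) {
  cfg <- load_run_config(config)
  inputs <- load_inputs(cfg)
  lexicon <- config_lexicon(cfg)
  windows <- segment_cohort(inputs$archives, inputs$timelines, cfg$task,
                            cfg$seed, cfg$month_days)
  if (length(windows) == 0L) {
    stop(if (cfg$task == "relapse") "no relapse periods in this cohort"
         else "no diagnostic windows in this cohort")
  }
  labels <- vapply(windows, `[[`, "", "label")
  if (cfg$task == "relapse" && !any(labels == "illness")) {
    stop("no relapse periods in this cohort (no illness windows)")
  }
  feats <- build_feature_matrix(windows, lexicon)
  dir <- file.path(cfg$output_dir, cfg$task)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(window_manifest(windows),
            file.path(dir, "window_manifest.csv"), row.names = FALSE)
  write.csv(feats, file.path(dir, "features.csv"), row.names = FALSE)
  write_manifest(cfg, "featurize", dir, list(n_windows = nrow(feats)))
  invisible(feats)
}

read_features <- function(cfg) {
  path <- file.path(cfg$output_dir, cfg$task, "features.csv")
  if (!file.exists(path)) {
    stop("missing feature matrix at ", path, "; run pipeline_featurize first")
  }
  as_tibble(read.csv(path, check.names = FALSE))
}

#' @rdname pipeline
#' @export
pipeline_evaluate <- function(config) {
  cfg <- load_run_config(config)
  feats <- read_features(cfg)
  group <- cfg$task == "relapse" && isTRUE(cfg$group_folds)
  results <- lapply(cfg$models, function(kind) {
    run_cv(feats, feats$label, kind, seed = derive_seed(cfg$seed, 11L),
           group_by_participant = group)
  })
  names(results) <- cfg$models
  report <- summarize_cv(results)
  dir <- file.path(cfg$output_dir, cfg$task)
  write.csv(report, file.path(dir, "classifier_report.csv"),
            row.names = FALSE)
  folds <- lapply(results, `[[`, "fold_assignments")
  jsonlite::write_json(
    list(report = report, fold_assignments = folds,
         mean_auc = lapply(results, `[[`, "mean_auc")),
    file.path(dir, "classifier_report.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  write_manifest(cfg, "evaluate", dir, list(models = cfg$models))
  attr(report, "results") <- results
  invisible(report)
}

#' @rdname pipeline
#' @param model_kind Model to rank features for (default the first of
#'   `config$models`).
#' @export
pipeline_importance <- function(config, model_kind = NULL) {
  cfg <- load_run_config(config)
  feats <- read_features(cfg)
  kind <- model_kind %||% cfg$models[[1]]
  group <- cfg$task == "relapse" && isTRUE(cfg$group_folds)
  cv <- run_cv(feats, feats$label, kind, seed = derive_seed(cfg$seed, 11L),
               group_by_participant = group)
  imp <- cross_fold_importance(cv, n_repeats = cfg$n_repeats,
                               seed = derive_seed(cfg$seed, 13L),
                               top_k = 20L)
  pos <- cv$positive
  neg <- setdiff(unique(feats$label), pos)[1]
  out <- format_importance(imp, positive_label = pos, negative_label = neg)
  dir <- file.path(cfg$output_dir, cfg$task)
  write.csv(out, file.path(dir, sprintf("importance_%s.csv", kind)),
            row.names = FALSE)
  write_manifest(cfg, "importance", dir,
                 list(model = kind, n_repeats = cfg$n_repeats))
  invisible(imp)
}

#' @rdname pipeline
#' @export
pipeline_report <- function(config) {
  cfg <- load_run_config(config)
  dir <- file.path(cfg$output_dir, cfg$task)
  report_path <- file.path(dir, "classifier_report.csv")
  if (!file.exists(report_path)) {
    stop("missing classifier report; run pipeline_evaluate first")
  }
  report <- read.csv(report_path, check.names = FALSE)
  lines <- c(sprintf("searchprint run: task=%s seed=%d", cfg$task, cfg$seed),
             "", "Classifier performance (per-fold means):",
             utils::capture.output(print(report)))
  imp_files <- list.files(dir, pattern = "^importance_.*\\.csv$",
                          full.names = TRUE)
  for (f in imp_files) {
    lines <- c(lines, "", paste0("Top features (", basename(f), "):"),
               utils::capture.output(print(utils::head(
                 read.csv(f, check.names = FALSE), 10))))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(file.path(dir, "summary.txt"))
}
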