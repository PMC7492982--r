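# searchprint

Digital phenotyping from personal search-activity archives: an R package
for testing whether the timing, volume, and content of a person's online
search queries carry signal about their psychiatric state.

## What it does, and for whom

Clinical researchers studying schizophrenia spectrum disorders (SSD) can
obtain, with consent, a participant's own Google Takeout "My Activity"
export — a time-stamped record of every search query. `searchprint`
implements the full analysis pipeline for two questions over such
archives:

* **Diagnostic**: does the 4-week window immediately preceding a first
  psychiatric hospitalization distinguish individuals with SSD from
  healthy volunteers (HV), whose comparison windows are drawn at random
  from their archives?
* **Relapse**: within individuals with SSD, do *periods of relative
  illness* (the 4 weeks before a relapse hospitalization) differ from
  *periods of relative health* (the 4 weeks after a discharge), under
  gap rules that drop windows when hospitalizations crowd together
  (less than 1 month between hospitalizations invalidates the illness
  window; less than 2 months invalidates the intervening health window)?

Each 28-day window is summarized by a fixed 123-dimension feature vector:

| block | dims |
|---|---|
| hourly histograms of query length and frequency (1-h bins, summed over 28 days) | 24 + 24 |
| 4-day-bin histograms of query length and frequency (32-day span) | 8 + 8 |
| SDs of the two 4-day histograms | 2 |
| mean and SD of the first differences of the two 4-day histograms | 4 |
| lexicon word-category proportions (LIWC-style `.dic`, 51 categories) | 51 |
| total queries; mean query length (words) | 2 |

Lexicon features are proportions of total words; behavioral features are
z-scored with statistics fit on training folds only. Three classifiers —
random forest, RBF-kernel SVM, gradient boosting — are evaluated under
stratified 5-fold cross-validation (AUC, accuracy, F1, per-class
precision/recall, averaged over folds), with inner held-out
hyperparameter tuning, participant-grouped folds for the relapse task,
and a 10-iteration redraw of the HV control windows as a stability
check. Features are ranked by permutation importance with AUC as the
model score, averaged across the five validation folds.

Because real participant archives cannot be shared, the package includes
a seeded synthetic-cohort generator whose defaults emulate the group
contrasts reported for this design (SSD query volume ≈ 0.58 × HV;
illness-period volume ≈ 1.74 × health-period; directional word-category
shifts), so the entire pipeline is testable end-to-end.

## Worked example

```r
library(searchprint)

# a seeded synthetic cohort: 25 SSD cases with hospitalization
# calendars, 40 healthy volunteers
cohort <- generate_cohort(cohort_spec(n_ssd = 25, n_hv = 40, seed = 7))
lex <- fixture_lexicon()

# segment: SSD pre-first-admission windows + random HV control windows
windows <- c(
  lapply(grep("^ssd", names(cohort$archives), value = TRUE), function(id)
    diagnostic_window(cohort$archives[[id]], cohort$timelines[[id]])),
  lapply(grep("^hv", names(cohort$archives), value = TRUE), function(id)
    control_window(cohort$archives[[id]], seed = 7)))
windows <- Filter(Negate(is_window_exclusion), windows)

feats <- build_feature_matrix(windows, lex)
cv <- run_cv(feats, feats$label, "RF", seed = 7)
cv
#> <cv_result> RF: mean AUC 1.000 (SD 0.000), accuracy 0.954, F1[SSD] 0.944

summarize_cv(cv)
#> # A tibble: 1 × 8
#>   classifier mean_f1 precision_negative precision_positive recall_negative
#>   <chr>        <dbl>              <dbl>              <dbl>           <dbl>
#> 1 RF            0.94               0.98               0.94            0.95
#> # ℹ 3 more variables: recall_positive <dbl>, mean_accuracy <dbl>,
#> #   mean_sd_auc <chr>

head(cross_fold_importance(cv, n_repeats = 10, seed = 7), 5)
#> # A tibble: 5 × 5
#>    rank feature           mean_importance sd_importance direction
#>   <int> <chr>                       <dbl>         <dbl> <chr>
#> 1     1 mean_query_length        0.00100       0.00200  lower_in_positive
#> 2     2 liwc_posemo              0.000500      0.001000 lower_in_positive
#> 3     3 fourday_freq_b1          0             0        lower_in_positive
#> 4     4 fourday_freq_b2          0             0        lower_in_positive
#> 5     5 fourday_freq_b3          0             0        lower_in_positive
```

The generator's default effects are strong enough that the forest
separates this cohort perfectly (mean AUC 1.000). The top-ranked
features are contrasts the generator truly planted — shorter queries and
reduced positive-affect word usage in the SSD windows — each annotated
with the direction of its raw class difference. The tiny importance
magnitudes are themselves informative: when many redundant features each
suffice to separate the classes, shuffling any single one barely dents a
saturated model, which is exactly how permutation importance behaves on
correlated signals.

The same analysis runs file-to-file from a YAML config through
`pipeline_simulate()` → `pipeline_featurize()` → `pipeline_evaluate()` →
`pipeline_importance()` → `pipeline_report()` (see
`inst/scripts/searchprint-pipeline.R` for shell use), producing a window
manifest, feature matrix CSV, a classifier report shaped like the
published results tables, a ranked importance table, and a run manifest
with every seed needed to replay the run. Real data enter through
`parse_takeout()` (Takeout JSON), `read_timeline()` (hospitalization
CSV) and `load_dic()` (any 51-category LIWC-dialect dictionary).

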