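---
title: "Digital phenotyping from search-activity archives: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital phenotyping from search-activity archives: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchprint)
```

## The problem

Psychiatric assessment relies almost entirely on self-report; there are few
objective collateral signals of a patient's state. Personal search-engine
archives are one candidate: a time-stamped record of what a person asked
and when, stretching back years, obtainable by the patient themselves
through a standard account export. `searchprint` implements a complete
analysis pipeline for two clinical questions over such archives:

* **Diagnostic classification** — can the month of search activity
  immediately preceding a first psychiatric hospitalization distinguish
  individuals with schizophrenia spectrum disorders (SSD) from healthy
  volunteers (HV)?
* **Relapse detection** — within individuals with SSD, can a month of
  search activity distinguish a *period of relative illness* (the 4 weeks
  before a relapse hospitalization) from a *period of relative health*
  (the 4 weeks after a discharge)?

Because participant search archives are sensitive and not publicly
depositable, the package includes a first-class synthetic-cohort generator
with the statistical structure the analysis assumes, so every stage is
testable end-to-end without access to real data.

## Windowing model

The unit of analysis is a half-open, exactly 28-day observation window
`[start, end)` anchored on a clinical event. The admission instant belongs
to the hospitalization, not to the preceding window.

* Diagnostic task: SSD windows are the 28 days before the *first*
  admission; participants with no search data in that period are excluded.
  HV windows are drawn uniformly at random over the archive (window start
  uniform on the days from the first query to the last query minus 28
  days), redrawn until nonempty, and redrawn afresh in the stability check
  (`repeat_control_sampling()`).
* Relapse task, for hospitalizations `h_1..h_n` sorted by admission:
  illness windows precede each admission from the second onward, skipped
  when fewer than `month_days` (default 28) days separate that admission
  from the previous discharge; health windows follow each discharge,
  requiring at least `2 * month_days` days before the next admission, or —
  after the final hospitalization — an archive extending at least 28 days
  past discharge. No relapse window may contain data prior to the first
  admission.

Two points were genuinely open and are decided here as follows. First,
"one month" and "two months" are quantified as exactly 28 and 56 days, so
all gap arithmetic is exact and consistent with the 4-week window
(configurable via `month_days`). Second, the health window after the
*final* hospitalization is included: observed relapse datasets of this
design report more health than illness periods, which is only possible if
post-terminal-discharge periods count. Relatedly, the two-month rule is
interpreted as gating only the health window of a gap; the illness window
has its own one-month rule. Windows containing zero queries are dropped
with a notice rather than zero-filled — a participant who is offline
contributes no linguistic signal, and their temporal features would be
degenerate.

## The 123-feature representation

Each window is summarized by a fixed, ordered, named vector of 123
features in thirteen blocks: hourly histograms of query length and
frequency (24 + 24, local-time hour bins summed over the 28 days), 4-day
histograms of length and frequency (8 + 8), the standard deviations of
the two 4-day histograms (1 + 1), the means and standard deviations of
the first differences ("derivative") of the two 4-day histograms
(1 + 1 + 1 + 1), 51 lexicon word-category proportions, total query count
(1), and mean query length in words (1).

Conventions worth stating explicitly:

* **Query length is in words**, counted by the same tokenizer the lexicon
  features use (letters-and-apostrophes tokens; digits and punctuation
  separate tokens, pure numbers vanish).
* **The 4-day histograms cover a 32-day span** — the 28-day window plus a
  4-day extension *away* from the anchor — so that the eighth bin
  ("31–28 days prior" for a pre-anchor window) exists. The extension
  slice is stored separately on the window object (`extra_queries`), so
  the window invariant (all queries in `[start, end)`) is preserved, and
  the hourly histograms and scalar features use the 28-day window only.
  Bins are indexed by proximity to the anchor event on both sides
  (illness: days before admission; health: days after discharge), which
  keeps bins semantically aligned across the two relapse labels.
  Control windows are treated as pre-anchor with the pseudo-anchor at the
  window end, mirroring the SSD diagnostic windows they are compared to.
* **Derivatives are taken oldest-to-newest**, so activity declining
  toward a hospitalization yields a negative mean difference.
* **Population (divide-by-n) standard deviations** are used throughout,
  and degenerate statistics (0 or 1 observations) are 0 by convention, so
  feature vectors never contain undefined values.
* **Lexicon proportions are on the 0–1 scale** (multiply by 100 to
  compare with LIWC's percentage output). A token may count toward
  several categories; exact dictionary entries take precedence over
  wildcard stems, and among stems the longest match wins.
* **Standardization**: behavioral (non-lexicon) columns are z-scored;
  lexicon columns, already proportion-normalized, pass through. During
  cross-validation the z-score parameters are estimated on the training
  rows of each fold only — fitting them on all rows would leak test-fold
  information. Zero-variance columns map to 0.

The bundled `fixture_lexicon()` is an open, 51-category dictionary in the
LIWC 2007 naming scheme (anger, anx, hear, percept, bio, health, sexual,
sad, posemo, inhib, relativ, incl, quant, preps, insight, ipron, and
standard filler categories), shipped because the real LIWC dictionary is
proprietary. Any user-supplied `.dic` file with 51 categories can replace
it via `load_dic()`.

## Classifiers and evaluation

`run_cv()` evaluates a random forest, an RBF-kernel support vector
machine, and a gradient-boosted tree ensemble under stratified 5-fold
cross-validation, reporting per-fold AUC, accuracy, F1 of the clinical
(positive) class, and per-class precision/recall, averaged across folds
(not pooled). AUC, being insensitive to class imbalance, is the primary
metric; no resampling is applied to the imbalanced classes.

Hyperparameters are tuned per fold on an inner held-out validation split
(a stratified quarter of the training rows) by AUC, over deliberately
small grids (RF: `mtry`; SVM: cost, with the RBF kernel fixed; GB:
learning rate). The grids are artifact choices recorded in the run
manifest. For the relapse task, folds are grouped by participant by
default so that no individual's windows appear in both training and test
sets — ungrouped behavior is available via a flag. Folds whose test rows
contain a single class have undefined AUC; they are flagged, warned
about, and excluded from the mean.

All randomness — fold assignment, inner splits, model seeds, control-window
draws, permutation shuffles — derives from one master seed through a
deterministic substream function, so any result is exactly reproducible
and control windows can be redrawn independently
(`repeat_control_sampling()`, default 10 iterations).

## Permutation feature importance

`cross_fold_importance()` ranks the 123 features by permutation
importance with AUC as the model score: on each fold's validation rows,
the baseline AUC minus the mean AUC over `n_repeats` seeded shuffles of
one feature column, averaged across the five folds, sorted descending
with ties broken by feature name. The number of repeats defaults to 10 —
enough to average out shuffle noise at these validation-fold sizes while
keeping the 123 × 5-fold scan affordable; the permuted-score aggregation
(mean over repeats rather than a single shuffle) is a deliberate choice
recorded here. Each feature is annotated with the direction of its raw
class-conditional mean difference — computed from the data, not the model
— to support "increased/reduced in the positive class" phrasing. Note the
standard caveat: permuting one column ignores feature dependence, and
with nonlinear models the importance of correlated features is shared.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws, per participant: a hospitalization calendar
(SSD only; count distribution, inpatient stay 7–21 days, inter-admission
gaps 20–160 days so both gap-exclusion rules are exercised), daily query
counts from a Poisson process whose rate carries a participant-level
gamma multiplier (mean 1, CV 1 by default — search volume varies wildly
between people, and published query-volume tables for this design show
SDs of the same order as the means, so a homogeneous rate would make
volume features unrealistically clean separators), hour-of-day placement
from a 24-weight circadian profile, query lengths from a shifted
Poisson, and query text sampled word-by-word from the fixture
vocabulary. Effects are
multiplicative — simple, composable, and sign-interpretable:

* `ssd_rate_multiplier` (default 1/3) scales SSD daily rates everywhere;
  `illness_rate_multiplier` (default 1.74) applies within the 28 days
  before each admission. The defaults are calibrated so the
  diagnostic-window contrast is `1/3 × 1.74 ≈ 0.58`, the published
  SSD-to-HV query-volume ratio (192.76/332.93), and the
  illness-to-health window ratio is 1.74 (168.29/96.80). One multiplier
  cannot also match the *absolute* reported health-period volume, which
  differs between the pre-first-hospitalization and between-relapse
  tables; the ratio calibration was chosen.
* Length multipliers (0.8 for SSD, 0.85 during illness) encode the
  reported direction that cases' queries contain fewer words.
* `category_shift` moves word-category usage in the directions of the
  published importance tables (e.g. reduced positive-affect, anxiety,
  inhibition, quantifier, preposition words in SSD; increased sexual,
  hearing, perception, anger and reduced health, sadness words during
  illness periods). Magnitudes (0.5–1.8×) are chosen to be recoverable
  at the study's sample size; the real per-category effect sizes are
  unknown and the generator makes no claim to reproduce the published
  AUCs.

The generator is intentionally unrealistic in ways that do not affect
what the tests establish: query text is a bag of dictionary and filler
words, not language; the process is stationary (no seasonality, which
the control-window randomization in the real design partly addresses);
inpatient periods keep the baseline rate (no relapse window can overlap
them anyway); and all participants share one timezone and one circadian
profile. Passing tests therefore demonstrate that the *pipeline*
recovers planted contrasts of plausible magnitude — not that real
cohorts are classifiable at any particular accuracy.

## Problem sizes and numerical tolerances

The test suite verifies counting features against brute-force oracles
exactly (tolerance 1e-9 on floats), and calibrates the classifier stack
at a cohort of 200 participants (72 SSD / 128 HV, the case fraction of
the study sample): label-permutation nulls must keep every model's mean
AUC within [0.4, 0.6] (20 permutations), and the default-effect cohort
must reach a diagnostic mean AUC of at least 0.85 in at least 9 of 10
generator seeds, with at least one truly shifted lexicon category in the
importance top 5. These sizes are the package's chosen verification
conditions: large enough that the null band and recovery threshold are
comfortably inside their sampling noise, small enough to run routinely.

## Known limitations

* Hospitalization-anchored labels are a coarse proxy for symptom state;
  symptom-scale-based windowing is out of scope.
* The fixture lexicon shares category *names* with LIWC 2007, not its
  proprietary contents; absolute category proportions are not comparable
  to real LIWC output.
* Browser-history (`Visited ...`) records are parsed but excluded from
  features by default; whether such records should contribute is a
  documented open question, and a toggle exists at the archive level.
* Permutation importance inherits its usual blind spots under correlated
  features and nonlinear models.
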