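#' Specify a synthetic cohort
#'
#' Defines the study conditions a generated cohort emulates: two groups
#' (SSD cases with hospitalization calendars, HV controls without), query
#' timestamps from an inhomogeneous Poisson process with a circadian
#' hour-of-day profile, query lengths in words, and query text sampled
#' from the fixture vocabulary with word-category usage shifted by group
#' and by illness period. Default sizes are the study cohort (42 SSD, 74
#' HV) and default effect magnitudes are calibrated so the generated
#' group contrasts track the published query-volume ratios: the SSD
#' pre-hospitalization query rate is 0.58 of the HV rate, and illness
#' periods carry 1.74 times the query rate of health periods.
#'
#' @param n_ssd,n_hv Group sizes.
#' @param archive_span_days Days of history per participant.
#' @param base_query_rate Expected HV queries per day (default 11.9, i.e.
#'   about 333 queries per 4 weeks).
#' @param participant_rate_cv Coefficient of variation of the
#'   participant-level activity multiplier (gamma-distributed, mean 1).
#'   Search volume varies enormously between people — published
#'   query-volume tables for this design report SDs of the same order as
#'   the means (CVs 0.9-1.5) — so the default is 1; set 0 for
#'   homogeneous rates.
#' @param circadian_profile 24 nonnegative hour-of-day weights.
#' @param query_length_mean Mean words per query (>= 1).
#' @param hosp_count_probs Probabilities of 1, 2, ... hospitalizations per
#'   SSD participant.
#' @param gap_range Integer range (days) for the discharge-to-next-admission
#'   gap; the default includes gaps short enough to trigger the window
#'   exclusion rules.
#' @param stay_range Integer range (days) of inpatient stay length.
#' @param effect See [effect_spec()].
#' @param category_weights Optional named per-category sampling weights
#'   (default 1 for every category).
#' @param origin First calendar day of every archive.
#' @param tz Timezone for all generated timestamps.
#' @param seed Master seed; the whole cohort is a pure function of the
#'   spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_ssd = 42L, n_hv = 74L,
                        archive_span_days = 540L,
                        base_query_rate = 11.9,
                        participant_rate_cv = 1,
                        circadian_profile = default_circadian(),
                        query_length_mean = 4,
                        hosp_count_probs = c(0.35, 0.40, 0.25),
                        gap_range = c(20L, 160L),
                        stay_range = c(7L, 21L),
                        effect = effect_spec(),
                        category_weights = NULL,
                        origin = as.Date("2017-01-01"),
                        tz = "UTC",
                        seed = 1L) {
  spec <- list(n_ssd = as.integer(n_ssd), n_hv = as.integer(n_hv),
               archive_span_days = as.integer(archive_span_days),
               base_query_rate = base_query_rate,
               participant_rate_cv = participant_rate_cv,
               circadian_profile = circadian_profile,
               query_length_mean = query_length_mean,
               hosp_count_probs = hosp_count_probs,
               gap_range = as.integer(gap_range),
               stay_range = as.integer(stay_range),
               effect = effect, category_weights = category_weights,
               origin = as.Date(origin), tz = tz, seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_ssd < 0L || spec$n_hv < 0L || spec$n_ssd + spec$n_hv == 0L) {
    stop("cohort sizes must be nonnegative and not both zero")
  }
  if (spec$archive_span_days < 140L) {
    stop("archive_span_days must be >= 140 (room for a hospitalization calendar)")
  }
  if (spec$base_query_rate <= 0) stop("base_query_rate must be positive")
  if (spec$participant_rate_cv < 0 || !is.finite(spec$participant_rate_cv)) {
    stop("participant_rate_cv must be finite and nonnegative")
  }
  if (length(spec$circadian_profile) != 24L ||
      any(spec$circadian_profile < 0) || all(spec$circadian_profile == 0) ||
      any(!is.finite(spec$circadian_profile))) {
    stop("circadian_profile must be 24 finite nonnegative weights, not all zero")
  }
  if (spec$query_length_mean < 1) stop("query_length_mean must be >= 1")
  mult <- unlist(spec$effect[c("ssd_rate_multiplier", "ssd_length_multiplier",
                               "illness_rate_multiplier",
                               "illness_length_multiplier")])
  if (any(mult <= 0) || any(!is.finite(mult))) {
    stop("effect multipliers must be positive and finite")
  }
  invisible(spec)
}

# Evening-peaked hour-of-day weights: sparse overnight activity, a daytime
# plateau and a peak before midnight.
default_circadian <- function() {
  c(3, 2, 1, 0.5, 0.5, 1, 2, 4, 6, 8, 8, 8, 9, 9, 9, 9, 10, 10, 11, 12,
    12, 10, 8, 5)
}

#' Effect sizes for the synthetic cohort
#'
#' Multiplicative effects: `ssd_*` multipliers apply to every SSD query
#' relative to HV; `illness_*` multipliers apply additionally within the
#' 28 days before each hospitalization admission. The defaults make the
#' diagnostic-window rate contrast `ssd_rate_multiplier *
#' illness_rate_multiplier = 0.333 * 1.74 = 0.58` (the published
#' SSD-to-HV query-volume ratio 192.76/332.93) and the illness-to-health
#' rate ratio 1.74 (the published 168.29/96.80). `category_shift` holds
#' two named vectors of per-category word-sampling multipliers:
#' `diagnostic` (SSD vs HV, applied to all SSD queries) and `relapse`
#' (illness vs health, applied during illness periods), with defaults in
#' the directions of the published importance tables (e.g. reduced
#' positive-affect/anxiety/inhibition words in SSD; increased
#' sexual/hear/perception/anger and reduced health/sadness words during
#' illness periods).
#'
#' @param ssd_rate_multiplier,ssd_length_multiplier,illness_rate_multiplier,illness_length_multiplier
#'   Positive multipliers on queries/day and words/query.
#' @param category_shift List with named numeric vectors `diagnostic` and
#'   `relapse`.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(ssd_rate_multiplier = 1 / 3,
                        ssd_length_multiplier = 0.8,
                        illness_rate_multiplier = 1.74,
                        illness_length_multiplier = 0.85,
                        category_shift = default_category_shift()) {
  structure(list(ssd_rate_multiplier = ssd_rate_multiplier,
                 ssd_length_multiplier = ssd_length_multiplier,
                 illness_rate_multiplier = illness_rate_multiplier,
                 illness_length_multiplier = illness_length_multiplier,
                 category_shift = category_shift),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @export
default_category_shift <- function() {
  list(
    diagnostic = c(posemo = 0.5, anx = 0.5, inhib = 0.5, relativ = 0.6,
                   quant = 0.5, preps = 0.7, incl = 0.6, insight = 0.6),
    relapse = c(sexual = 1.8, hear = 1.8, bio = 1.5, percept = 1.5,
                anger = 1.6, incl = 1.3, ipron = 1.3, health = 0.5,
                sad = 0.5))
}

#' @rdname effect_spec
#' @export
neutral_effect_spec <- function() {
  effect_spec(ssd_rate_multiplier = 1, ssd_length_multiplier = 1,
              illness_rate_multiplier = 1, illness_length_multiplier = 1,
              category_shift = list(diagnostic = numeric(),
                                    relapse = numeric()))
}

# Vocabulary table from the fixture lexicon: each exact dictionary word is
# assigned to its most specific category (the highest category index among
# its memberships, since subcategories follow their parents in the fixture
# inventory), plus out-of-dictionary filler words matching no category.
build_vocabulary <- function(lexicon) {
  words <- names(lexicon$exact)
  primary <- vapply(lexicon$exact, max, integer(1))
  fillers <- c("weather", "recipe", "movie", "directions", "news", "store",
               "cheap", "review", "video", "game", "song", "map", "flight",
               "hotel", "restaurant", "phone", "laptop", "shoes", "ticket",
               "quiz")
  tibble(word = c(words, fillers),
         category = c(unname(primary), rep(NA_integer_, length(fillers))))
}

# Per-word sampling weights for one condition. Filler words get weight
# w_filler each, chosen so dictionary words carry about half the mass
# under neutral shifts.
word_weights <- function(vocab, lexicon, cat_weights, shifts) {
  w <- ifelse(is.na(vocab$category), 0,
              cat_weights[ifelse(is.na(vocab$category), 1L, vocab$category)])
  for (nm in names(shifts)) {
    ci <- match(nm, lexicon$categories)
    if (is.na(ci)) stop("category_shift names unknown category: ", nm)
    w[!is.na(vocab$category) & vocab$category == ci] <-
      w[!is.na(vocab$category) & vocab$category == ci] * shifts[[nm]]
  }
  n_dict <- sum(!is.na(vocab$category))
  n_fill <- sum(is.na(vocab$category))
  w[is.na(vocab$category)] <- sum(cat_weights[vocab$category[!is.na(vocab$category)]]) / n_fill
  w
}

# Simulate one participant's query stream over the day grid.
simulate_archive <- function(pid, group, hosp, spec, vocab, lexicon,
                             pseed) {
  span <- spec$archive_span_days
  eff <- spec$effect
  cat_weights <- spec$category_weights
  if (is.null(cat_weights)) {
    cat_weights <- setNames(rep(1, length(lexicon$categories)),
                            lexicon$categories)
  }
  days <- seq_len(span) - 1L
  illness_day <- rep(FALSE, span)
  if (nrow(hosp) > 0L) {
    adm_days <- as.integer(hosp$admission - spec$origin)
    for (a in adm_days) {
      lo <- max(0L, a - 28L)
      if (a >= 1L) illness_day[(lo + 1L):a] <- TRUE  # days [a-28, a)
    }
  }
  rate <- rep(spec$base_query_rate, span)
  len_mean <- rep(spec$query_length_mean, span)
  if (group == "SSD") {
    rate <- rate * eff$ssd_rate_multiplier
    len_mean <- pmax(1, 1 + (len_mean - 1) * eff$ssd_length_multiplier)
    rate[illness_day] <- rate[illness_day] * eff$illness_rate_multiplier
    len_mean[illness_day] <-
      pmax(1, 1 + (len_mean[illness_day] - 1) * eff$illness_length_multiplier)
  }
  shifts_normal <- if (group == "SSD") eff$category_shift$diagnostic
                   else numeric()
  shifts_ill <- if (group == "SSD") {
    merged <- shifts_normal
    rel <- eff$category_shift$relapse
    for (nm in names(rel)) {
      merged[nm] <- if (nm %in% names(merged)) merged[[nm]] * rel[[nm]]
                    else rel[[nm]]
    }
    merged
  } else numeric()
  w_normal <- word_weights(vocab, lexicon, cat_weights, shifts_normal)
  w_ill <- word_weights(vocab, lexicon, cat_weights, shifts_ill)
  local_rng(pseed, {
    # participant-level activity multiplier: gamma with mean 1 and the
    # spec's coefficient of variation (0 -> homogeneous)
    if (spec$participant_rate_cv > 0) {
      shape <- 1 / spec$participant_rate_cv^2
      rate <- rate * stats::rgamma(1, shape = shape, rate = shape)
    }
    n_day <- rpois(span, rate)
    n <- sum(n_day)
    if (n == 0L) {
      return(search_archive(pid, tibble(
        timestamp = as.POSIXct(character(), tz = spec$tz),
        text = character(), source = character())))
    }
    q_day <- rep(days, n_day)
    q_ill <- rep(illness_day, n_day)
    hours <- sample(0:23, n, replace = TRUE, prob = spec$circadian_profile)
    secs <- floor(runif(n, 0, 3600))
    ts <- as.POSIXct(paste(format(spec$origin), "00:00:00"), tz = spec$tz) +
      q_day * 86400 + hours * 3600 + secs
    wc <- 1L + rpois(n, pmax(rep(len_mean, n_day) - 1, 0))
    # sample words per condition in one vectorized draw each
    word_id <- integer(sum(wc))
    q_idx <- rep(seq_len(n), wc)
    ill_tok <- q_ill[q_idx]
    if (any(!ill_tok)) {
      word_id[!ill_tok] <- sample.int(nrow(vocab), sum(!ill_tok),
                                      replace = TRUE, prob = w_normal)
    }
    if (any(ill_tok)) {
      word_id[ill_tok] <- sample.int(nrow(vocab), sum(ill_tok),
                                     replace = TRUE, prob = w_ill)
    }
    text <- vapply(split(vocab$word[word_id], q_idx),
                   paste, character(1), collapse = " ")
    text <- text[order(as.integer(names(text)))]
    search_archive(pid, tibble(timestamp = ts, text = unname(text),
                               source = "search"))
  })
}

# Hospitalization calendar for one SSD participant.
simulate_hospitalizations <- function(spec, pseed) {
  local_rng(pseed, {
    k <- sample.int(length(spec$hosp_count_probs), 1L,
                    prob = spec$hosp_count_probs)
    adm <- integer(); dis <- integer()
    day <- sample(45:90, 1L)
    for (i in seq_len(k)) {
      stay <- sample(spec$stay_range[1]:spec$stay_range[2], 1L)
      if (day + stay + 28L > spec$archive_span_days) break
      adm <- c(adm, day)
      dis <- c(dis, day + stay)
      day <- day + stay + sample(spec$gap_range[1]:spec$gap_range[2], 1L)
    }
    tibble(admission = spec$origin + adm, discharge = spec$origin + dis)
  })
}

#' Generate a synthetic cohort
#'
#' Draws archives and clinical timelines for every participant in the
#' spec, fully deterministically: each participant's calendar and query
#' stream comes from a sub-seed derived from `spec$seed`, so the same
#' spec always yields byte-identical archives.
#'
#' @param spec A [cohort_spec()].
#' @return List with `archives` (named list of [search_archive()]),
#'   `timelines` (named list of [clinical_timeline()]) and `truth`
#'   (effect bookkeeping: the spec's multipliers and the names/directions
#'   of the shifted categories per task).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  lexicon <- fixture_lexicon()
  vocab <- build_vocabulary(lexicon)
  archives <- list(); timelines <- list()
  ids <- c(sprintf("ssd%03d", seq_len(spec$n_ssd)),
           sprintf("hv%03d", seq_len(spec$n_hv)))
  groups <- c(rep("SSD", spec$n_ssd), rep("HV", spec$n_hv))
  for (i in seq_along(ids)) {
    pid <- ids[i]
    group <- groups[i]
    hosp <- if (group == "SSD") {
      simulate_hospitalizations(spec, derive_seed(spec$seed, 5000L + i))
    } else tibble(admission = as.Date(character()),
                  discharge = as.Date(character()))
    timelines[[pid]] <- clinical_timeline(pid, group, hosp)
    archives[[pid]] <- simulate_archive(
      pid, group, timelines[[pid]]$hospitalizations, spec, vocab, lexicon,
      derive_seed(spec$seed, 7000L + i))
  }
  shifts <- spec$effect$category_shift
  truth <- list(
    effect = spec$effect,
    diagnostic_shifted = tibble(
      category = names(shifts$diagnostic),
      multiplier = unname(shifts$diagnostic),
      direction = ifelse(shifts$diagnostic > 1, "higher_in_SSD",
                         "lower_in_SSD")),
    relapse_shifted = tibble(
      category = names(shifts$relapse),
      multiplier = unname(shifts$relapse),
      direction = ifelse(shifts$relapse > 1, "higher_in_illness",
                         "lower_in_illness")))
  list(archives = archives, timelines = timelines, truth = truth)
}

#' Write a generated cohort to disk
#'
#' Emits the canonical JSONL archive per participant, the timeline CSV,
#' the truth bookkeeping as JSON and (optionally) Takeout-style JSON
#' exports to exercise [parse_takeout()] end-to-end.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param takeout Also write `takeout/<id>.json` files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, takeout = FALSE) {
  dir.create(file.path(dir, "archives"), recursive = TRUE,
             showWarnings = FALSE)
  for (pid in names(cohort$archives)) {
    write_canonical(cohort$archives[[pid]],
                    file.path(dir, "archives", paste0(pid, ".jsonl")))
  }
  write_timeline(cohort$timelines, file.path(dir, "timelines.csv"))
  jsonlite::write_json(
    list(diagnostic_shifted = cohort$truth$diagnostic_shifted,
         relapse_shifted = cohort$truth$relapse_shifted),
    file.path(dir, "truth.json"))
  if (takeout) {
    dir.create(file.path(dir, "takeout"), showWarnings = FALSE)
    for (pid in names(cohort$archives)) {
      write_takeout(cohort$archives[[pid]],
                    file.path(dir, "takeout", paste0(pid, ".json")))
    }
  }
  invisible(dir)
}
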