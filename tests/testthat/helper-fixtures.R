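# Shared fixture builders: everything is constructed in code at test time.

# Query tibble from timestamp strings ("YYYY-MM-DD HH:MM:SS").
q_tbl <- function(times, text = NULL, source = "search", tz = "UTC") {
  if (is.null(text)) text <- paste("query", seq_along(times))
  tibble::tibble(timestamp = as.POSIXct(times, tz = tz),
                 text = text, source = rep_len(source, length(times)))
}

arc <- function(id, times, text = NULL, source = "search", tz = "UTC") {
  search_archive(id, q_tbl(times, text, source, tz))
}

# Bare observation window (bypasses the nonempty check so degenerate empty
# windows can be exercised).
bare_window <- function(queries, start, side = "pre", label = "SSD",
                        task = "diagnostic", extra = NULL, tz = "UTC",
                        id = "p1") {
  start <- as.POSIXct(start, tz = tz)
  if (is.null(extra)) {
    extra <- queries[0, ]
  }
  structure(list(participant_id = id, task = task, label = label,
                 anchor = as.Date(start) + if (side == "pre") 28 else 0,
                 start = start, end = start + 28 * 86400, side = side,
                 queries = queries[order(queries$timestamp), ],
                 extra_queries = extra),
            class = "observation_window")
}

empty_window <- function(side = "pre") {
  bare_window(q_tbl(character()), "2020-01-01", side = side)
}

# Toy .dic writer: categories is a named list index -> name, entries a
# character vector of body lines.
write_dic <- function(path, categories, entries) {
  header <- sprintf("%d\t%s", as.integer(names(categories)),
                    unlist(categories))
  writeLines(c("%", header, "%", entries), path)
}

# A 51-category toy lexicon with predictable content for oracle tests.
toy51_dic <- function(path) {
  cats <- as.list(c(sprintf("cat%02d", 1:12), "anger",
                    sprintf("cat%02d", 14:50), "mixed"))
  names(cats) <- 1:51
  write_dic(path, cats,
            c("rage\t13", "mad\t13 51", "happ*\t13 31", "calm\t2",
              "blue\t51"))
  path
}

# Takeout-dialect JSON writer.
write_takeout_json <- function(path, records) {
  writeLines(jsonlite::toJSON(records, auto_unbox = TRUE, pretty = TRUE),
             path, useBytes = TRUE)
}

# Independent brute-force category-count oracle: nested loops, no shared
# code with category_profile beyond tokenize's contract.
oracle_profile <- function(tokens, lexicon) {
  k <- length(lexicon$categories)
  counts <- numeric(k)
  for (tok in tokens) {
    cats <- lexicon$exact[[tok]]
    if (is.null(cats)) {
      best <- ""
      for (si in seq_along(lexicon$stems$stem)) {
        st <- lexicon$stems$stem[si]
        if (substr(tok, 1, nchar(st)) == st && nchar(st) > nchar(best)) {
          best <- st
          cats <- lexicon$stems$cats[[si]]
        }
      }
    }
    if (!is.null(cats)) for (ci in cats) counts[ci] <- counts[ci] + 1
  }
  if (length(tokens) > 0) counts / length(tokens) else counts
}

# Small labeled dataset with one informative feature among noise, shaped
# like a feature matrix (named columns incl. liwc_ block) for model tests.
separable_data <- function(n = 60, p = 123, seed = 1, informative = 1,
                           noise_sd = 0) {
  set.seed(seed)
  labels <- rep(c("SSD", "HV"), length.out = n)
  # with noise_sd = 0 the nuisance columns are constant (standardized to
  # zero), so the engineered signal is the only live dimension and the
  # data are perfectly separable for every model family
  x <- matrix(rnorm(n * p, sd = noise_sd), n, p)
  n_liwc <- if (p > 52) 51L else 0L
  cn <- c(sprintf("behav_%03d", seq_len(p - n_liwc)),
          sprintf("liwc_c%02d", seq_len(n_liwc)))
  colnames(x) <- cn
  for (j in seq_len(informative)) {
    x[, j] <- as.numeric(labels == "SSD") * 2 +
      rnorm(n, sd = max(noise_sd, 1e-9))
  }
  list(x = x, labels = labels)
}

# Tiny real-pipeline cohort shared by several slow-ish tests (cached per
# session).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_spec(n_ssd = 8, n_hv = 10,
                                            archive_span_days = 400,
                                            seed = 11))
    }
    cache
  }
})

# Hand-built calendar cohort covering every segmentation rule: normal
# spacing, <1-month gap, 1-2 month gap, single hospitalization, no
# pre-admission data, and a healthy control. Daily noon queries.
daily_arc <- function(id, from, to) {
  days <- seq(as.Date(from), as.Date(to), by = "day")
  arc(id, paste(days, "12:00:00"))
}

hand_calendar <- function() {
  tl <- function(id, adm, dis) {
    clinical_timeline(id, "SSD", data.frame(admission = as.Date(adm),
                                            discharge = as.Date(dis)))
  }
  list(
    archives = list(
      pA = daily_arc("pA", "2019-01-01", "2019-08-31"),
      pB = daily_arc("pB", "2019-01-01", "2019-05-31"),
      pC = daily_arc("pC", "2019-01-01", "2019-04-30"),
      pD = daily_arc("pD", "2019-03-01", "2019-06-30"),
      pE = daily_arc("pE", "2019-01-01", "2019-06-01"),
      pF = daily_arc("pF", "2019-01-01", "2019-03-31")),
    timelines = list(
      pA = tl("pA", c("2019-03-01", "2019-06-08"),
                    c("2019-03-10", "2019-06-20")),   # gap 90 days
      pB = tl("pB", c("2019-02-01", "2019-03-02"),
                    c("2019-02-10", "2019-03-12")),   # gap 20 days
      pC = tl("pC", "2019-02-15", "2019-02-25"),      # single
      pD = tl("pD", "2019-02-01", "2019-02-08"),      # no pre-adm data
      pE = tl("pE", c("2019-02-01", "2019-03-20"),
                    c("2019-02-08", "2019-03-28")),   # gap 40 days
      pF = clinical_timeline("pF", "HV")),
    # hand-computed enumeration of relapse window labels per participant
    expected_relapse = list(
      pA = c("health", "illness", "health"),
      pB = "health",
      pC = "health",
      pD = "health",
      pE = c("illness", "health"),
      pF = NULL),
    diagnostic_ok = c(pA = TRUE, pB = TRUE, pC = TRUE, pD = FALSE,
                      pE = TRUE))
}
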