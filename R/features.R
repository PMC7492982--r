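#' Feature-vector layout
#'
#' The classifier representation of one observation window is a fixed,
#' named 123-value vector built from thirteen blocks:
#' hourly query-length histogram (24), hourly query-frequency histogram
#' (24), 4-day query-length histogram (8), 4-day query-frequency histogram
#' (8), SD of the 4-day frequency bins (1), SD of the 4-day length bins
#' (1), mean of the derivative of the 4-day frequency bins (1), mean of
#' the derivative of the 4-day length bins (1), SD of the derivative of
#' the 4-day frequency bins (1), SD of the derivative of the 4-day length
#' bins (1), the 51 lexicon category proportions, total query count (1)
#' and mean query length in words (1).
#'
#' @param lexicon A `liwc_lexicon` supplying the 51 category names.
#' @return Named integer vector of block sizes, in feature order.
#' @export
feature_blocks <- function(lexicon = NULL) {
  c(hour_len = 24L, hour_freq = 24L, fourday_len = 8L, fourday_freq = 8L,
    sd_fourday_freq = 1L, sd_fourday_len = 1L,
    mean_deriv_fourday_freq = 1L, mean_deriv_fourday_len = 1L,
    sd_deriv_fourday_freq = 1L, sd_deriv_fourday_len = 1L,
    liwc = 51L, total_queries = 1L, mean_query_length = 1L)
}

#' @rdname feature_blocks
#' @export
feature_names <- function(lexicon) {
  c(sprintf("hour_len_%02d", 0:23), sprintf("hour_freq_%02d", 0:23),
    sprintf("fourday_len_b%d", 1:8), sprintf("fourday_freq_b%d", 1:8),
    "sd_fourday_freq", "sd_fourday_len",
    "mean_deriv_fourday_freq", "mean_deriv_fourday_len",
    "sd_deriv_fourday_freq", "sd_deriv_fourday_len",
    paste0("liwc_", lexicon$categories),
    "total_queries", "mean_query_length")
}

# Words per query, by the same tokenizer the lexicon features use
# (vectorized: one regex pass over all queries).
query_word_counts <- function(text) {
  if (length(text) == 0L) return(integer())
  low <- tolower(text)
  toks <- regmatches(low, gregexpr("[[:alpha:]']+", low))
  u <- unlist(toks, use.names = FALSE)
  if (length(u) == 0L) return(rep(0L, length(text)))
  keep <- !grepl("^'+$", u)  # tokens that are only apostrophes don't count
  tabulate(rep(seq_along(toks), lengths(toks))[keep], nbins = length(text))
}

#' Hourly histograms of query frequency and length
#'
#' 24 bins, one per local-time hour of day, aggregated (summed) over the
#' 28-day window: frequency bins count queries, length bins sum query word
#' counts.
#'
#' @param window An `observation_window`.
#' @return List with `frequency` and `length`, each a named 24-vector
#'   (hours 0-23).
#' @export
hourly_histograms <- function(window) {
  freq <- setNames(numeric(24), sprintf("hour_%02d", 0:23))
  len <- freq
  q <- window$queries
  if (nrow(q) > 0L) {
    hours <- as.integer(format(q$timestamp, "%H"))
    words <- query_word_counts(q$text)
    for (i in seq_along(hours)) {
      h <- hours[i] + 1L
      freq[h] <- freq[h] + 1
      len[h] <- len[h] + words[i]
    }
  }
  list(frequency = freq, length = len)
}

# Anchor-relative 4-day bin index (1..8) for timestamps; bin 1 is nearest
# the anchor event. Pre-anchor windows measure days prior to the window
# end over (end - 32d, end]; post-anchor windows measure days after the
# window start over [start, start + 32d). NA outside the 32-day span.
fourday_bin <- function(ts, window) {
  if (window$side == "pre") {
    offset <- as.numeric(window$end) - as.numeric(ts)
    bin <- ceiling(offset / (4 * 86400))
  } else {
    offset <- as.numeric(ts) - as.numeric(window$start)
    bin <- floor(offset / (4 * 86400)) + 1
  }
  bin[bin < 1 | bin > 8] <- NA
  as.integer(bin)
}

#' 4-day-bin histograms of query frequency and length
#'
#' 8 bins of 4 days each over a 32-day span: the 28-day window plus its
#' 4-day extension away from the anchor (see [observation_window()]). Bins
#' are indexed by proximity to the anchor event, so for a pre-anchor
#' (illness/diagnostic) window bin 1 is "3-0 days prior" to admission and
#' bin 8 is "31-28 days prior", while for a post-anchor (health) window
#' bin 1 is the first 4 days after discharge.
#'
#' @param window An `observation_window`.
#' @return List with `frequency` and `length` (named 8-vectors, bin 1
#'   nearest the anchor) plus `time_order`, the bin indices oldest-first,
#'   used by [derivative_stats()].
#' @export
fourday_histograms <- function(window) {
  freq <- setNames(numeric(8), sprintf("b%d", 1:8))
  len <- freq
  q <- rbind(window$queries, window$extra_queries)
  if (nrow(q) > 0L) {
    bins <- fourday_bin(q$timestamp, window)
    words <- query_word_counts(q$text)
    for (i in seq_along(bins)) {
      b <- bins[i]
      if (is.na(b)) next
      freq[b] <- freq[b] + 1
      len[b] <- len[b] + words[i]
    }
  }
  time_order <- if (window$side == "pre") 8:1 else 1:8
  list(frequency = freq, length = len, time_order = time_order)
}

#' First- and second-order statistics of a histogram derivative
#'
#' Takes the 7 successive differences of the 8 bins in time order
#' (oldest to newest) and returns their mean and population standard
#' deviation; a decline in activity toward the anchor therefore yields a
#' negative mean for pre-anchor windows.
#'
#' @param bins Numeric 8-vector in time order, oldest first.
#' @return Named vector `c(mean_of_diff, sd_of_diff)`.
#' @export
derivative_stats <- function(bins) {
  stopifnot(length(bins) == 8L)
  d <- diff(bins)
  c(mean_of_diff = mean(d), sd_of_diff = sd_pop(d))
}

#' Scalar window features
#'
#' Total query count, mean query length in words (0 for an empty window),
#' and the population standard deviations of the 8 four-day frequency and
#' length bins.
#'
#' @param window An `observation_window`.
#' @param fourday Optionally a precomputed [fourday_histograms()] result
#'   for the same window.
#' @return Named vector `c(total_queries, mean_query_length, sd_freq_bins,
#'   sd_len_bins)`.
#' @export
scalar_features <- function(window, fourday = NULL) {
  q <- window$queries
  total <- nrow(q)
  mean_len <- if (total > 0L) sum(query_word_counts(q$text)) / total else 0
  fh <- if (is.null(fourday)) fourday_histograms(window) else fourday
  c(total_queries = total, mean_query_length = mean_len,
    sd_freq_bins = sd_pop(fh$frequency), sd_len_bins = sd_pop(fh$length))
}

#' Assemble the full 123-dimension feature vector
#'
#' Concatenates all thirteen blocks (see [feature_blocks()]) into one
#' named numeric vector. Deterministic and invariant to the storage order
#' of queries within the window; degenerate statistics on empty windows
#' are 0 by convention.
#'
#' @param window An `observation_window`.
#' @param lexicon A `liwc_lexicon` with 51 categories.
#' @return Named numeric vector of length 123.
#' @export
assemble <- function(window, lexicon) {
  hh <- hourly_histograms(window)
  fh <- fourday_histograms(window)
  dstat_freq <- derivative_stats(fh$frequency[fh$time_order])
  dstat_len <- derivative_stats(fh$length[fh$time_order])
  sc <- scalar_features(window, fourday = fh)
  prof <- category_profile(window, lexicon)
  setNames(
    c(hh$length, hh$frequency, fh$length, fh$frequency,
      sc[["sd_freq_bins"]], sc[["sd_len_bins"]],
      dstat_freq[["mean_of_diff"]], dstat_len[["mean_of_diff"]],
      dstat_freq[["sd_of_diff"]], dstat_len[["sd_of_diff"]],
      prof$values,
      sc[["total_queries"]], sc[["mean_query_length"]]),
    feature_names(lexicon))
}

#' Build a feature matrix from a list of windows
#'
#' @param windows List of `observation_window` objects.
#' @param lexicon A `liwc_lexicon`.
#' @return Tibble with metadata columns `participant_id`, `task`, `label`
#'   followed by the 123 feature columns.
#' @export
build_feature_matrix <- function(windows, lexicon) {
  stopifnot(length(windows) > 0L)
  feats <- t(vapply(windows, assemble, numeric(123), lexicon = lexicon))
  meta <- tibble(
    participant_id = vapply(windows, `[[`, "", "participant_id"),
    task = vapply(windows, `[[`, "", "task"),
    label = vapply(windows, `[[`, "", "label"))
  dplyr::bind_cols(meta, as_tibble(as.data.frame(feats)))
}

#' Split a feature tibble into metadata and numeric matrix
#'
#' @param features Output of [build_feature_matrix()].
#' @return List with `meta` (tibble) and `x` (numeric matrix, 123 cols).
#' @export
feature_parts <- function(features) {
  meta_cols <- intersect(c("participant_id", "task", "label"),
                         names(features))
  x <- as.matrix(features[, setdiff(names(features), meta_cols)])
  list(meta = features[, meta_cols], x = x)
}

#' Standardize behavioral feature columns
#'
#' Z-scores the behavioral (non-lexicon) columns using means and standard
#' deviations estimated on `fit_rows` only — during cross-validation these
#' are the training rows, so no test-fold statistics leak into the
#' transform. Lexicon (`liwc_*`) columns pass through unchanged (they are
#' already proportion-normalized); zero-SD columns map to 0.
#'
#' @param x Numeric matrix, windows in rows, the 123 features in columns.
#' @param fit_rows Integer/logical row subset to estimate the transform on.
#' @return List with `x` (transformed matrix), `center`, `scale` and
#'   `standardized` (logical per column).
#' @export
standardize_features <- function(x, fit_rows = seq_len(nrow(x))) {
  stopifnot(length(fit_rows) > 0L)
  behav <- !startsWith(colnames(x), "liwc_")
  center <- rep(0, ncol(x))
  scale_ <- rep(1, ncol(x))
  fit <- x[fit_rows, , drop = FALSE]
  center[behav] <- colMeans(fit[, behav, drop = FALSE])
  scale_[behav] <- apply(fit[, behav, drop = FALSE], 2, sd_pop)
  out <- x
  for (j in which(behav)) {
    out[, j] <- if (scale_[j] > 0) (x[, j] - center[j]) / scale_[j] else 0
  }
  list(x = out, center = setNames(center, colnames(x)),
       scale = setNames(scale_, colnames(x)), standardized = behav)
}

# Apply a fitted standardization to new rows.
apply_standardize <- function(fitted, x) {
  out <- x
  for (j in which(fitted$standardized)) {
    out[, j] <- if (fitted$scale[j] > 0)
      (x[, j] - fitted$center[j]) / fitted$scale[j] else 0
  }
  out
}
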