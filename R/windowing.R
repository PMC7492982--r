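#' Observation windows
#'
#' An observation window is a labeled, exactly 28-day, half-open
#' `[start, end)` slice of one participant's archive, anchored on a
#' clinical event (hospitalization admission or discharge) or, for healthy
#' controls, on a randomly chosen period. Windows whose anchor event lies
#' at their end (`side = "pre"`: diagnostic and relapse-illness windows,
#' and control windows with pseudo-anchor at the window end) extend their
#' 4-day-histogram lookback 4 days before `start`; `side = "post"` windows
#' (relapse-health) extend it 4 days after `end`. That extension slice is
#' kept in `extra_queries`, separate from `queries`, so every query in
#' `queries` lies in `[start, end)`.
#'
#' @param archive A [search_archive()].
#' @param participant_id,task,label,anchor,start Window metadata; `task` is
#'   `"diagnostic"` or `"relapse"`, `label` one of `"SSD"`, `"HV"`,
#'   `"illness"`, `"health"`.
#' @param side `"pre"` (window ends at the anchor) or `"post"` (window
#'   starts at the anchor).
#' @param month_days Window length in days (default 28).
#' @return An `observation_window`, or a `window_exclusion` notice when the
#'   window contains zero queries.
#' @export
observation_window <- function(archive, participant_id, task, label, anchor,
                               start, side = c("pre", "post"),
                               month_days = 28L) {
  side <- match.arg(side)
  task <- match.arg(task, c("diagnostic", "relapse"))
  label <- match.arg(label, c("SSD", "HV", "illness", "health"))
  end <- start + month_days * 86400
  q <- archive$queries
  q <- q[q$source == "search", , drop = FALSE]
  inside <- q$timestamp >= start & q$timestamp < end
  if (!any(inside)) {
    return(window_exclusion(participant_id, task,
                            sprintf("no queries in window [%s, %s)",
                                    format(start), format(end))))
  }
  extra <- if (side == "pre") {
    q[q$timestamp >= start - 4 * 86400 & q$timestamp < start, , drop = FALSE]
  } else {
    q[q$timestamp >= end & q$timestamp < end + 4 * 86400, , drop = FALSE]
  }
  structure(list(participant_id = participant_id, task = task, label = label,
                 anchor = anchor, start = start, end = end, side = side,
                 queries = q[inside, , drop = FALSE],
                 extra_queries = extra),
            class = "observation_window")
}

window_exclusion <- function(participant_id, task, reason) {
  structure(list(participant_id = participant_id, task = task,
                 reason = reason),
            class = "window_exclusion")
}

#' @export
print.observation_window <- function(x, ...) {
  cat(sprintf("<observation_window> %s/%s %s [%s, %s): %d queries\n",
              x$participant_id, x$task, x$label, format(x$start),
              format(x$end), nrow(x$queries)))
  invisible(x)
}

#' @export
print.window_exclusion <- function(x, ...) {
  cat(sprintf("<window_exclusion> %s/%s: %s\n", x$participant_id, x$task,
              x$reason))
  invisible(x)
}

#' Is this a window-exclusion notice?
#' @param x Object to test.
#' @export
is_window_exclusion <- function(x) inherits(x, "window_exclusion")

# Midnight local time of a Date in the archive's display timezone.
day_start <- function(date, tz) {
  as.POSIXct(paste(format(date), "00:00:00"), tz = tz)
}

archive_tz <- function(archive) {
  tz <- attr(archive$queries$timestamp, "tzone")
  if (is.null(tz) || !nzchar(tz[1])) "UTC" else tz[1]
}

#' Diagnostic window: 4 weeks before the first hospitalization
#'
#' Extracts the 28-day window immediately preceding the participant's first
#' psychiatric hospitalization admission (half-open: the admission instant
#' belongs to the hospitalization, not the window). SSD participants with
#' no search data in that period are excluded with a notice.
#'
#' @param archive A [search_archive()].
#' @param timeline Matching [clinical_timeline()] with group `"SSD"` and at
#'   least one hospitalization.
#' @param month_days Window length in days.
#' @return An `observation_window` labeled `SSD`, or a `window_exclusion`.
#' @export
diagnostic_window <- function(archive, timeline, month_days = 28L) {
  stopifnot(inherits(archive, "search_archive"),
            inherits(timeline, "clinical_timeline"))
  if (timeline$group != "SSD") {
    stop("diagnostic_window requires an SSD timeline; got HV for ",
         timeline$participant_id)
  }
  if (nrow(timeline$hospitalizations) == 0L) {
    stop("SSD timeline without hospitalizations: ", timeline$participant_id)
  }
  anchor <- timeline$hospitalizations$admission[1]
  end <- day_start(anchor, archive_tz(archive))
  observation_window(archive, archive$participant_id, "diagnostic", "SSD",
                     anchor = anchor, start = end - month_days * 86400,
                     side = "pre", month_days = month_days)
}

#' Control window: a random 4-week period from a healthy volunteer
#'
#' Draws a 28-day window whose start date is uniform over the days from the
#' first query date to the last query date minus 28 days, redrawing (up to
#' `max_retries`) until at least one query falls inside; if retries are
#' exhausted the candidate starts are scanned in order so any nonempty
#' window is found deterministically. Fully determined by `seed`.
#'
#' @param archive A [search_archive()] of an HV participant.
#' @param seed Integer seed controlling the draw.
#' @param month_days Window length in days.
#' @param max_retries Random redraws before falling back to a scan.
#' @return An `observation_window` labeled `HV`, or a `window_exclusion`
#'   when the archive spans fewer than `month_days` days or no nonempty
#'   window exists.
#' @export
control_window <- function(archive, seed, month_days = 28L,
                           max_retries = 100L) {
  stopifnot(inherits(archive, "search_archive"))
  q <- archive$queries[archive$queries$source == "search", , drop = FALSE]
  if (nrow(q) == 0L) {
    return(window_exclusion(archive$participant_id, "diagnostic",
                            "empty archive"))
  }
  tz <- archive_tz(archive)
  first_day <- as.Date(min(q$timestamp), tz = tz)
  last_day <- as.Date(max(q$timestamp), tz = tz)
  latest_start <- last_day - month_days
  if (latest_start < first_day) {
    return(window_exclusion(archive$participant_id, "diagnostic",
                            sprintf("archive spans < %d days", month_days)))
  }
  candidates <- seq(first_day, latest_start, by = "day")
  pick <- local_rng(seed, {
    found <- NULL
    for (i in seq_len(max_retries)) {
      s <- candidates[sample.int(length(candidates), 1L)]
      w <- observation_window(archive, archive$participant_id, "diagnostic",
                              "HV", anchor = s + month_days,
                              start = day_start(s, tz), side = "pre",
                              month_days = month_days)
      if (!is_window_exclusion(w)) { found <- w; break }
    }
    found
  })
  if (is.null(pick)) {
    for (s in as.list(candidates)) {
      w <- observation_window(archive, archive$participant_id, "diagnostic",
                              "HV", anchor = s + month_days,
                              start = day_start(s, tz), side = "pre",
                              month_days = month_days)
      if (!is_window_exclusion(w)) return(w)
    }
    return(window_exclusion(archive$participant_id, "diagnostic",
                            "no nonempty 28-day window"))
  }
  pick
}

#' Relapse windows: periods of relative illness and relative health
#'
#' Segments an SSD participant's archive around hospitalizations
#' `h_1..h_n` (sorted by admission):
#' \itemize{
#'   \item Illness windows: the 28 days before `admission_i` for each
#'     relapse hospitalization (`i >= 2`), skipped when fewer than
#'     `month_days` days separate `admission_i` from `discharge_{i-1}`.
#'   \item Health windows: the 28 days after `discharge_i`. Between
#'     consecutive hospitalizations they require at least `2 * month_days`
#'     days before the next admission; after the final hospitalization they
#'     require the archive to extend at least `month_days` days past
#'     discharge.
#' }
#' Search data prior to the first admission never enters any relapse
#' window; windows with zero queries are dropped and reported in the
#' `"notices"` attribute.
#'
#' @inheritParams diagnostic_window
#' @return List of `observation_window` objects with attribute `"notices"`
#'   (a list of `window_exclusion` objects for dropped windows).
#' @export
relapse_windows <- function(archive, timeline, month_days = 28L) {
  stopifnot(inherits(archive, "search_archive"),
            inherits(timeline, "clinical_timeline"))
  if (timeline$group != "SSD") {
    stop("relapse_windows requires an SSD timeline; got HV for ",
         timeline$participant_id)
  }
  hosp <- timeline$hospitalizations
  tz <- archive_tz(archive)
  q <- archive$queries[archive$queries$source == "search", , drop = FALSE]
  archive_end <- if (nrow(q) > 0) max(q$timestamp) else -Inf
  windows <- list()
  notices <- list()
  collect <- function(w) {
    if (is_window_exclusion(w)) notices[[length(notices) + 1L]] <<- w
    else windows[[length(windows) + 1L]] <<- w
  }
  n <- nrow(hosp)
  for (i in seq_len(n)) {
    adm <- hosp$admission[i]
    dis <- hosp$discharge[i]
    # illness window before relapse (not first) admissions, gap permitting
    if (i >= 2L) {
      gap <- as.integer(adm - hosp$discharge[i - 1L])
      if (gap >= month_days) {
        collect(observation_window(
          archive, archive$participant_id, "relapse", "illness",
          anchor = adm, start = day_start(adm, tz) - month_days * 86400,
          side = "pre", month_days = month_days))
      }
    }
    # health window after discharge
    emit_health <- if (i < n) {
      as.integer(hosp$admission[i + 1L] - dis) >= 2L * month_days
    } else {
      is.finite(archive_end) &&
        archive_end >= day_start(dis, tz) + month_days * 86400
    }
    if (emit_health) {
      collect(observation_window(
        archive, archive$participant_id, "relapse", "health",
        anchor = dis, start = day_start(dis, tz), side = "post",
        month_days = month_days))
    }
  }
  structure(windows, notices = notices)
}

#' Window manifest
#'
#' One row per emitted window: the unit of exchange between segmentation
#' and feature extraction.
#'
#' @param windows List of `observation_window` objects.
#' @return Tibble with columns participant_id, task, label, anchor, start,
#'   end, n_queries.
#' @export
window_manifest <- function(windows) {
  dplyr::bind_rows(lapply(windows, function(w) {
    tibble(participant_id = w$participant_id, task = w$task, label = w$label,
           anchor = as.character(w$anchor), start = format_iso8601(w$start),
           end = format_iso8601(w$end), n_queries = nrow(w$queries))
  }))
}
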