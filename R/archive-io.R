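#' @importFrom tibble tibble as_tibble
#' @importFrom stats rpois runif sd setNames aggregate quantile
#' @importFrom utils head tail read.csv write.csv
NULL

#' Construct a search archive
#'
#' A search archive is the in-memory representation of one participant's
#' time-stamped query history: an opaque participant id plus a tibble of
#' queries with columns `timestamp` (POSIXct, timezone-resolved), `text`
#' (non-empty query string) and `source` (`"search"` or `"browse"`).
#' Queries are stored sorted ascending by timestamp; duplicate
#' (timestamp, text) pairs are permitted.
#'
#' @param participant_id Non-empty participant identifier.
#' @param queries Tibble/data frame with columns `timestamp`, `text`,
#'   `source`. Rows are re-sorted by timestamp.
#' @return An object of class `search_archive`.
#' @export
search_archive <- function(participant_id, queries) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            nzchar(participant_id))
  queries <- as_tibble(queries)
  required <- c("timestamp", "text", "source")
  if (!all(required %in% names(queries))) {
    stop("queries must have columns: ", paste(required, collapse = ", "))
  }
  if (!inherits(queries$timestamp, "POSIXct")) {
    stop("queries$timestamp must be POSIXct")
  }
  if (any(!nzchar(trimws(queries$text)))) {
    stop("query text must be non-empty after whitespace trimming")
  }
  if (!all(queries$source %in% c("search", "browse"))) {
    stop("source must be 'search' or 'browse'")
  }
  queries <- queries[order(queries$timestamp), required]
  structure(list(participant_id = participant_id, queries = queries),
            class = "search_archive")
}

#' @export
print.search_archive <- function(x, ...) {
  cat(sprintf("<search_archive> participant %s: %d queries", x$participant_id,
              nrow(x$queries)))
  if (nrow(x$queries) > 0) {
    cat(sprintf(" [%s .. %s]", format(min(x$queries$timestamp)),
                format(max(x$queries$timestamp))))
  }
  cat("\n")
  invisible(x)
}

#' Construct a clinical timeline
#'
#' Holds one participant's group label (`"SSD"` for the schizophrenia
#' spectrum disorder case group, `"HV"` for healthy volunteers) and their
#' ordered, non-overlapping hospitalization intervals. HV timelines must
#' have zero hospitalizations.
#'
#' @param participant_id Non-empty identifier.
#' @param group `"SSD"` or `"HV"`.
#' @param hospitalizations Data frame with `Date` columns `admission`,
#'   `discharge` (zero rows allowed). Sorted by admission on construction.
#' @return An object of class `clinical_timeline`.
#' @export
clinical_timeline <- function(participant_id, group,
                              hospitalizations = NULL) {
  stopifnot(is.character(participant_id), nzchar(participant_id))
  group <- match.arg(group, c("SSD", "HV"))
  if (is.null(hospitalizations) || nrow(hospitalizations) == 0L) {
    hospitalizations <- tibble(admission = as.Date(character()),
                               discharge = as.Date(character()))
  } else {
    hospitalizations <- as_tibble(hospitalizations)[, c("admission", "discharge")]
    hospitalizations$admission <- as.Date(hospitalizations$admission)
    hospitalizations$discharge <- as.Date(hospitalizations$discharge)
    if (any(hospitalizations$discharge < hospitalizations$admission)) {
      bad <- which(hospitalizations$discharge < hospitalizations$admission)[1]
      stop(sprintf("participant %s: discharge before admission in record %d",
                   participant_id, bad))
    }
    hospitalizations <- hospitalizations[order(hospitalizations$admission), ]
    if (nrow(hospitalizations) > 1L) {
      overlaps <- hospitalizations$admission[-1] <=
        hospitalizations$discharge[-nrow(hospitalizations)]
      if (any(overlaps)) {
        stop(sprintf("participant %s: overlapping hospitalizations",
                     participant_id))
      }
    }
  }
  if (group == "HV" && nrow(hospitalizations) > 0L) {
    stop(sprintf("participant %s: HV timeline cannot have hospitalizations",
                 participant_id))
  }
  structure(list(participant_id = participant_id, group = group,
                 hospitalizations = hospitalizations),
            class = "clinical_timeline")
}

# Parse ISO-8601 timestamps ("2018-03-05T14:22:11Z", fractional seconds and
# numeric offsets allowed) into POSIXct displayed in tz.
parse_iso8601 <- function(x, tz = "UTC") {
  x <- sub("\\.[0-9]+", "", x)              # drop fractional seconds
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  # timestamps without any offset are taken as already local to tz
  missing_off <- is.na(out) & !is.na(x)
  if (any(missing_off)) {
    out[missing_off] <- as.POSIXct(x[missing_off],
                                   format = "%Y-%m-%dT%H:%M:%S", tz = tz)
  }
  out
}

format_iso8601 <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S%z")
}

#' Parse a Google Takeout "My Activity" search export
#'
#' Reads the JSON dialect of the Takeout search-history export: an array of
#' records each carrying a `title` such as `"Searched for weather"` (or
#' `"Visited ..."` for browser history) and an ISO-8601 `time` field.
#' Records lacking a parseable time, or whose query text is empty after
#' stripping the title prefix, are dropped and counted in the parse report
#' attached as attribute `"parse_report"`.
#'
#' @param path Path to the Takeout JSON file.
#' @param tz Timezone used to localize timestamps for circadian binning
#'   (the participant's local timezone); default `"UTC"`.
#' @param participant_id Identifier for the archive; defaults to the file
#'   name without extension.
#' @return A [search_archive()] containing both `search` and `browse`
#'   records (downstream feature extraction excludes `browse` by default).
#'   If no usable record remains, an empty archive is returned with a
#'   warning of class `searchprint_empty_archive`.
#' @export
parse_takeout <- function(path, tz = "UTC",
                          participant_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("malformed JSON in %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  n_total <- length(records)
  rows <- lapply(records, function(rec) {
    title <- rec$title
    time <- rec$time
    if (is.null(title) || is.null(time)) return(NULL)
    if (startsWith(title, "Searched for ")) {
      src <- "search"
      text <- substring(title, nchar("Searched for ") + 1L)
    } else if (startsWith(title, "Visited ")) {
      src <- "browse"
      text <- substring(title, nchar("Visited ") + 1L)
    } else {
      return(NULL)
    }
    ts <- parse_iso8601(time, tz = tz)
    if (is.na(ts) || !nzchar(trimws(text))) return(NULL)
    tibble(timestamp = ts, text = text, source = src)
  })
  keep <- !vapply(rows, is.null, logical(1))
  n_dropped <- sum(!keep)
  queries <- if (any(keep)) dplyr::bind_rows(rows[keep]) else
    tibble(timestamp = as.POSIXct(character(), tz = tz),
           text = character(), source = character())
  archive <- search_archive(participant_id, queries)
  attr(archive, "parse_report") <- list(
    n_records = n_total, n_usable = nrow(queries), n_dropped = n_dropped)
  if (nrow(queries) == 0L) {
    warning(structure(
      class = c("searchprint_empty_archive", "warning", "condition"),
      list(message = sprintf("archive %s: no usable records", participant_id),
           call = sys.call(-1))))
  }
  archive
}

#' Read clinical timelines from CSV
#'
#' Expects columns `participant_id`, `group`, `admission`, `discharge`
#' (ISO-8601 dates); HV participants appear as a single row with empty
#' admission/discharge. One row per hospitalization otherwise.
#'
#' @param path CSV file path.
#' @return Named list of [clinical_timeline()] objects, one per participant.
#' @export
read_timeline <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("participant_id", "group", "admission", "discharge")
  if (!all(required %in% names(df))) {
    stop("timeline CSV must have columns: ", paste(required, collapse = ", "))
  }
  out <- lapply(split(df, df$participant_id), function(rows) {
    has_dates <- nzchar(rows$admission) & nzchar(rows$discharge)
    hosp <- if (any(has_dates)) {
      tibble(admission = as.Date(rows$admission[has_dates]),
             discharge = as.Date(rows$discharge[has_dates]))
    } else NULL
    clinical_timeline(rows$participant_id[1], rows$group[1], hosp)
  })
  out[unique(df$participant_id)]
}

#' Write clinical timelines to CSV
#'
#' @param timelines List of [clinical_timeline()] objects.
#' @param path Output CSV path.
#' @export
write_timeline <- function(timelines, path) {
  rows <- lapply(timelines, function(tl) {
    if (nrow(tl$hospitalizations) == 0L) {
      data.frame(participant_id = tl$participant_id, group = tl$group,
                 admission = "", discharge = "")
    } else {
      data.frame(participant_id = tl$participant_id, group = tl$group,
                 admission = as.character(tl$hospitalizations$admission),
                 discharge = as.character(tl$hospitalizations$discharge))
    }
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Canonical JSONL archive store
#'
#' The canonical on-disk form of a search archive is UTF-8 JSONL: one query
#' per line with fields `timestamp` (ISO-8601 with offset), `text`,
#' `source`. The participant id is the file name without extension, so
#' `read_canonical(write_canonical(a, file.path(d, paste0(a$participant_id,
#' ".jsonl"))))` is the identity to second precision.
#'
#' @param archive A [search_archive()].
#' @param path Output path (conventionally `<participant_id>.jsonl`).
#' @return `path`, invisibly.
#' @export
write_canonical <- function(archive, path) {
  stopifnot(inherits(archive, "search_archive"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  q <- archive$queries
  if (nrow(q) > 0L) {
    lines <- vapply(seq_len(nrow(q)), function(i) {
      jsonlite::toJSON(list(timestamp = format_iso8601(q$timestamp[i]),
                            text = q$text[i], source = q$source[i]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_canonical
#' @param tz Timezone for the returned timestamps.
#' @param participant_id Defaults to the file name without extension.
#' @export
read_canonical <- function(path, tz = "UTC",
                           participant_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(search_archive(participant_id,
                          tibble(timestamp = as.POSIXct(character(), tz = tz),
                                 text = character(), source = character())))
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  queries <- tibble(
    timestamp = parse_iso8601(vapply(recs, `[[`, "", "timestamp"), tz = tz),
    text = vapply(recs, `[[`, "", "text"),
    source = vapply(recs, `[[`, "", "source"))
  search_archive(participant_id, queries)
}

#' Write an archive back out in Takeout "My Activity" JSON form
#'
#' Used to exercise [parse_takeout()] end-to-end against generated cohorts.
#'
#' @param archive A [search_archive()].
#' @param path Output JSON path.
#' @export
write_takeout <- function(archive, path) {
  q <- archive$queries
  prefix <- ifelse(q$source == "search", "Searched for ", "Visited ")
  recs <- lapply(seq_len(nrow(q)), function(i) {
    list(header = "Search",
         title = paste0(prefix[i], q$text[i]),
         time = format(q$timestamp[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  })
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE), path,
             useBytes = TRUE)
  invisible(path)
}
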