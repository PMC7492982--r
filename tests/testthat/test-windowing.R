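test_that("diagnostic window is the half-open 28 days before first admission", {
  a <- arc("s1", c("2018-03-05 10:00:00", "2018-03-28 22:00:00",
                   "2018-02-28 09:00:00"))
  tl <- clinical_timeline("s1", "SSD",
                          data.frame(admission = as.Date("2018-03-29"),
                                     discharge = as.Date("2018-04-10")))
  w <- diagnostic_window(a, tl)
  expect_s3_class(w, "observation_window")
  expect_equal(w$start, as.POSIXct("2018-03-01 00:00:00", tz = "UTC"))
  expect_equal(w$end, as.POSIXct("2018-03-29 00:00:00", tz = "UTC"))
  expect_equal(as.numeric(w$end - w$start, units = "days"), 28)
  # 02-28 query precedes the window; the two March queries are inside
  expect_equal(nrow(w$queries), 2L)
  expect_true(all(w$queries$timestamp >= w$start &
                    w$queries$timestamp < w$end))
})

test_that("queries at or after the admission instant are excluded (half-open)", {
  a <- arc("s2", c("2018-03-29 00:00:00", "2018-04-02 10:00:00"))
  tl <- clinical_timeline("s2", "SSD",
                          data.frame(admission = as.Date("2018-03-29"),
                                     discharge = as.Date("2018-04-10")))
  w <- diagnostic_window(a, tl)
  # all data at/after admission -> exclusion notice, not an error
  expect_true(is_window_exclusion(w))
})

test_that("diagnostic and relapse segmentation reject HV timelines", {
  a <- arc("h1", "2018-03-05 10:00:00")
  tl <- clinical_timeline("h1", "HV")
  expect_error(diagnostic_window(a, tl), "HV")
  expect_error(relapse_windows(a, tl), "HV")
})

test_that("control window is deterministic, uniform over the archive span and nonempty", {
  # archive spanning exactly 28 days -> the unique candidate window;
  # the query at the window-end instant is excluded by half-openness
  a28 <- arc("h2", c("2020-01-01 08:00:00", "2020-01-15 12:00:00",
                     "2020-01-29 00:00:00"))
  w <- control_window(a28, seed = 5)
  expect_equal(as.Date(w$start), as.Date("2020-01-01"))
  expect_equal(nrow(w$queries), 2L)

  # same seed twice -> identical window; different seed may differ
  a <- tiny_cohort()$archives[["hv003"]]
  w1 <- control_window(a, seed = 123)
  w2 <- control_window(a, seed = 123)
  expect_identical(w1$start, w2$start)
  expect_identical(w1$queries, w2$queries)

  # archive with a single query in a long span: found within retry bound
  lone <- arc("h3", "2020-06-15 12:00:00")
  lone$queries <- rbind(lone$queries,
                        q_tbl("2021-06-15 12:00:00", text = "z"))
  lone <- search_archive("h3", lone$queries)
  wl <- control_window(lone, seed = 9)
  expect_s3_class(wl, "observation_window")
  expect_gte(nrow(wl$queries), 1L)

  # sub-28-day span and empty archives are excluded
  expect_true(is_window_exclusion(
    control_window(arc("h4", "2020-01-01 10:00:00"), seed = 1)))
  expect_true(is_window_exclusion(
    control_window(search_archive("h5", q_tbl(character())), seed = 1)))
})

test_that("relapse segmentation matches the hand-computed calendar enumeration", {
  hc <- hand_calendar()
  for (id in names(hc$expected_relapse)) {
    if (id == "pF") next
    ws <- relapse_windows(hc$archives[[id]], hc$timelines[[id]])
    expect_equal(vapply(ws, `[[`, "", "label"), hc$expected_relapse[[id]],
                 info = id)
  }
  # diagnostic eligibility matches the hand enumeration
  for (id in names(hc$diagnostic_ok)) {
    w <- diagnostic_window(hc$archives[[id]], hc$timelines[[id]])
    expect_equal(!is_window_exclusion(w), unname(hc$diagnostic_ok[id]),
                 info = id)
  }
})

test_that("relapse windows never overlap inpatient stays or precede first admission", {
  hc <- hand_calendar()
  co <- tiny_cohort()
  cases <- c(
    lapply(setdiff(names(hc$expected_relapse), "pF"), function(id) {
      list(a = hc$archives[[id]], tl = hc$timelines[[id]])
    }),
    lapply(grep("^ssd", names(co$timelines), value = TRUE), function(id) {
      list(a = co$archives[[id]], tl = co$timelines[[id]])
    }))
  for (case in cases) {
    hosp <- case$tl$hospitalizations
    if (nrow(hosp) == 0L) next
    first_adm <- day_start <- as.POSIXct(paste(hosp$admission[1], "00:00:00"),
                                         tz = "UTC")
    for (w in relapse_windows(case$a, case$tl)) {
      expect_equal(as.numeric(w$end - w$start, units = "days"), 28)
      expect_true(all(w$queries$timestamp >= w$start &
                        w$queries$timestamp < w$end))
      expect_true(w$start >= first_adm)
      if (w$label == "illness") {
        for (i in seq_len(nrow(hosp))) {
          s_in <- as.POSIXct(paste(hosp$admission[i], "00:00:00"), tz = "UTC")
          e_in <- as.POSIXct(paste(hosp$discharge[i], "00:00:00"), tz = "UTC") +
            86400
          # half-open window [start, end) vs inpatient [admission, discharge]
          expect_false(w$start < e_in && w$end > s_in)
        }
      }
    }
  }
})

test_that("relapse window counts equal a brute-force calendar enumeration on generated timelines", {
  co <- tiny_cohort()
  # independent enumeration straight from the stated rules
  oracle_labels <- function(tl, a) {
    hosp <- tl$hospitalizations
    n <- nrow(hosp)
    if (n == 0L) return(character())
    have_query <- function(from, to) {
      any(a$queries$timestamp >= from & a$queries$timestamp < to)
    }
    ds <- function(d) as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
    out <- character()
    for (i in seq_len(n)) {
      if (i >= 2 && as.integer(hosp$admission[i] - hosp$discharge[i - 1]) >= 28 &&
          have_query(ds(hosp$admission[i]) - 28 * 86400, ds(hosp$admission[i]))) {
        out <- c(out, "illness")
      }
      ok <- if (i < n) {
        as.integer(hosp$admission[i + 1] - hosp$discharge[i]) >= 56
      } else {
        max(a$queries$timestamp) >= ds(hosp$discharge[i]) + 28 * 86400
      }
      if (ok && have_query(ds(hosp$discharge[i]),
                           ds(hosp$discharge[i]) + 28 * 86400)) {
        out <- c(out, "health")
      }
    }
    out
  }
  for (id in grep("^ssd", names(co$timelines), value = TRUE)) {
    got <- vapply(relapse_windows(co$archives[[id]], co$timelines[[id]]),
                  `[[`, "", "label")
    expect_equal(got, oracle_labels(co$timelines[[id]], co$archives[[id]]),
                 info = id)
  }
})

test_that("window manifest reports one row per window with query counts", {
  hc <- hand_calendar()
  ws <- relapse_windows(hc$archives$pA, hc$timelines$pA)
  m <- window_manifest(ws)
  expect_equal(nrow(m), 3L)
  expect_named(m, c("participant_id", "task", "label", "anchor", "start",
                    "end", "n_queries"))
  expect_true(all(m$n_queries > 0))
})
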