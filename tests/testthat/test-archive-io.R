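test_that("parse_takeout keeps search records, strips prefixes, sorts, and counts drops", {
  path <- withr::local_tempfile(fileext = ".json")
  # deliberately out of time order, with one browse record, one empty-text
  # record and one unparseable time
  write_takeout_json(path, list(
    list(title = "Searched for insomnia help", time = "2018-03-05T22:10:00Z"),
    list(title = "Searched for weather", time = "2018-03-01T08:00:00Z"),
    list(title = "Visited some site", time = "2018-03-02T09:00:00Z"),
    list(title = "Searched for   ", time = "2018-03-03T10:00:00Z"),
    list(title = "Searched for lost record", time = "not-a-time"),
    list(title = "Searched for why can't I sleep", time = "2018-03-04T23:30:00Z")))
  a <- parse_takeout(path, participant_id = "p1")
  searches <- a$queries[a$queries$source == "search", ]
  expect_equal(nrow(searches), 3L)
  expect_equal(searches$text,
               c("weather", "why can't I sleep", "insomnia help"))
  # sorted ascending: equals a brute-force re-sort of the parsed rows
  expect_equal(a$queries$timestamp, sort(a$queries$timestamp))
  rep <- attr(a, "parse_report")
  expect_equal(rep$n_records, 6L)
  expect_equal(rep$n_usable + rep$n_dropped, rep$n_records)
  expect_equal(rep$n_dropped, 2L)  # empty text + bad time
})

test_that("parse_takeout fails on malformed JSON and signals empty archives", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"title": "Searched for x", "time": ', bad)
  expect_error(parse_takeout(bad), "malformed JSON")

  empty <- withr::local_tempfile(fileext = ".json")
  write_takeout_json(empty, list(list(title = "Searched for ",
                                      time = "2018-01-01T00:00:00Z")))
  expect_warning(a <- parse_takeout(empty, participant_id = "p0"),
                 class = "searchprint_empty_archive")
  expect_equal(nrow(a$queries), 0L)
})

test_that("parse_takeout is idempotent through the takeout writer", {
  co <- tiny_cohort()
  a <- co$archives[["hv001"]]
  path <- withr::local_tempfile(fileext = ".json")
  write_takeout(a, path)
  b <- parse_takeout(path, participant_id = a$participant_id)
  expect_equal(b$participant_id, a$participant_id)
  expect_equal(b$queries$text, a$queries$text)
  expect_equal(as.numeric(b$queries$timestamp),
               as.numeric(a$queries$timestamp))
  # parsing a re-serialization of the parse is a fixed point
  path2 <- withr::local_tempfile(fileext = ".json")
  write_takeout(b, path2)
  expect_equal(parse_takeout(path2, participant_id = "x")$queries,
               b$queries, ignore_attr = TRUE)
})

test_that("read_timeline enforces ordering, HV emptiness and date validity", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,group,admission,discharge",
               "s1,SSD,2018-06-01,2018-06-10",
               "s1,SSD,2018-01-05,2018-01-20",
               "h1,HV,,"), path)
  tls <- read_timeline(path)
  expect_named(tls, c("s1", "h1"))
  expect_equal(nrow(tls$h1$hospitalizations), 0L)
  # file order reversed -> sorted by admission
  expect_equal(tls$s1$hospitalizations$admission,
               as.Date(c("2018-01-05", "2018-06-01")))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,group,admission,discharge",
               "s2,SSD,2018-06-01,2018-05-10"), bad)
  expect_error(read_timeline(bad), "s2.*discharge before admission")

  overlap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,group,admission,discharge",
               "s3,SSD,2018-01-01,2018-02-01",
               "s3,SSD,2018-01-20,2018-03-01"), overlap)
  expect_error(read_timeline(overlap), "s3.*overlapping")
})

test_that("canonical JSONL round-trips archives field-for-field", {
  d <- withr::local_tempdir()
  # empty archive
  e <- search_archive("empty", q_tbl(character()))
  p <- file.path(d, "empty.jsonl")
  write_canonical(e, p)
  expect_equal(nrow(read_canonical(p)$queries), 0L)

  # unicode text round-trips byte-identically
  u <- arc("uni", c("2020-05-01 10:00:00", "2020-05-01 11:00:00"),
           text = c("café près de moi \U0001F600", "naïve résumé"))
  pu <- file.path(d, "uni.jsonl")
  write_canonical(u, pu)
  back <- read_canonical(pu)
  expect_identical(back$queries$text, u$queries$text)
  # a second write of the reread archive is byte-identical
  pu2 <- file.path(d, "uni2.jsonl")
  write_canonical(back, pu2)
  expect_identical(readBin(pu, "raw", file.size(pu)),
                   readBin(pu2, "raw", file.size(pu2)))

  # 1,000-query generated archive: timestamps equal to second precision
  co <- tiny_cohort()
  big <- co$archives[["hv002"]]
  big$queries <- utils::head(big$queries, 1000L)
  pb <- file.path(d, paste0(big$participant_id, ".jsonl"))
  write_canonical(big, pb)
  rb <- read_canonical(pb)
  expect_equal(rb$participant_id, big$participant_id)
  expect_equal(as.numeric(rb$queries$timestamp),
               round(as.numeric(big$queries$timestamp)))
  expect_identical(rb$queries$text, big$queries$text)
  expect_identical(rb$queries$source, big$queries$source)
})

test_that("search_archive and clinical_timeline enforce their invariants", {
  expect_error(search_archive("", q_tbl(character())))
  expect_error(search_archive("p", q_tbl("2020-01-01 00:00:00", text = "  ")),
               "non-empty")
  expect_error(clinical_timeline("h", "HV",
                                 data.frame(admission = as.Date("2020-01-01"),
                                            discharge = as.Date("2020-01-05"))),
               "HV")
  tl <- clinical_timeline("s", "SSD",
                          data.frame(admission = as.Date(c("2020-06-01", "2020-01-01")),
                                     discharge = as.Date(c("2020-06-10", "2020-01-09"))))
  expect_equal(tl$hospitalizations$admission,
               as.Date(c("2020-01-01", "2020-06-01")))
})
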