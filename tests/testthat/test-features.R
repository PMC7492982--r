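test_that("hourly histograms bin by local hour and sum word counts", {
  w <- bare_window(q_tbl(c("2020-01-05 08:15:00", "2020-01-06 08:40:00",
                           "2020-01-07 23:59:59"),
                         text = c("two words", "one", "three more words")),
                   "2020-01-01")
  hh <- hourly_histograms(w)
  expect_equal(unname(hh$frequency[9]), 2)   # hour 8
  expect_equal(unname(hh$frequency[24]), 1)  # hour 23
  expect_equal(sum(hh$frequency), 3)
  expect_equal(unname(hh$length[9]), 3)      # 2 + 1 words
  expect_equal(unname(hh$length[24]), 3)

  h0 <- hourly_histograms(empty_window())
  expect_equal(unname(h0$frequency), rep(0, 24))
  expect_equal(unname(h0$length), rep(0, 24))
})

test_that("hourly histograms equal a brute-force per-query loop on a big window", {
  co <- tiny_cohort()
  w <- diagnostic_window(co$archives[["ssd001"]], co$timelines[["ssd001"]])
  hh <- hourly_histograms(w)
  freq <- rep(0, 24); len <- rep(0, 24)
  for (i in seq_len(nrow(w$queries))) {
    h <- as.integer(format(w$queries$timestamp[i], "%H")) + 1
    freq[h] <- freq[h] + 1
    len[h] <- len[h] + length(tokenize(w$queries$text[i]))
  }
  expect_equal(unname(hh$frequency), freq, tolerance = 1e-9)
  expect_equal(unname(hh$length), len, tolerance = 1e-9)
  expect_equal(sum(hh$frequency), nrow(w$queries))
})

test_that("4-day bins are indexed by proximity to the anchor on both sides", {
  # pre-anchor window anchored 2020-02-12 (start 2020-01-15)
  w <- bare_window(q_tbl(c("2020-02-10 10:00:00",   # 2 days prior -> bin 1
                           "2020-01-16 10:00:00"),  # ~27 days prior -> bin 7
                         text = c("a b", "c")),
                   "2020-01-15", side = "pre")
  fh <- fourday_histograms(w)
  expect_equal(unname(fh$frequency), c(1, 0, 0, 0, 0, 0, 1, 0))
  expect_equal(unname(fh$length), c(2, 0, 0, 0, 0, 0, 1, 0))
  expect_equal(fh$time_order, 8:1)

  # a query 30 days before the anchor sits in the extension slice -> bin 8
  w2 <- bare_window(q_tbl("2020-02-10 10:00:00", text = "x"), "2020-01-15",
                    side = "pre",
                    extra = q_tbl("2020-01-13 09:00:00", text = "y z"))
  fh2 <- fourday_histograms(w2)
  expect_equal(unname(fh2$frequency[8]), 1)
  expect_equal(unname(fh2$length[8]), 2)

  # post-anchor window: bin 1 is the first 4 days after the anchor
  w3 <- bare_window(q_tbl(c("2020-01-16 10:00:00", "2020-02-10 10:00:00"),
                          text = c("a", "b")),
                    "2020-01-15", side = "post", label = "health",
                    task = "relapse")
  fh3 <- fourday_histograms(w3)
  expect_equal(unname(fh3$frequency), c(1, 0, 0, 0, 0, 0, 1, 0))
  expect_equal(fh3$time_order, 1:8)
})

test_that("one query per day over 32 days fills every 4-day bin with 4", {
  days <- seq(as.Date("2020-01-11"), by = "day", length.out = 28)
  w <- bare_window(q_tbl(paste(days, "12:00:00")), "2020-01-11",
                   side = "pre",
                   extra = q_tbl(paste(seq(as.Date("2020-01-07"), by = "day",
                                           length.out = 4), "12:00:00")))
  fh <- fourday_histograms(w)
  expect_equal(unname(fh$frequency), rep(4, 8))
  # window queries land in bins 1-7; bin 8 comes from the extension only
  fh_noext <- fourday_histograms(bare_window(q_tbl(paste(days, "12:00:00")),
                                             "2020-01-11", side = "pre"))
  expect_equal(sum(fh_noext$frequency[1:7]), 28)
  expect_equal(unname(fh_noext$frequency[8]), 0)
})

test_that("derivative statistics follow the time-ordered differences", {
  expect_equal(derivative_stats(rep(3, 8)),
               c(mean_of_diff = 0, sd_of_diff = 0))
  expect_equal(derivative_stats(0:7), c(mean_of_diff = 1, sd_of_diff = 0))
  set.seed(77)
  bins <- round(runif(8, 0, 50))
  d <- bins[2:8] - bins[1:7]
  expect_equal(derivative_stats(bins),
               c(mean_of_diff = sum(d) / 7,
                 sd_of_diff = sqrt(sum((d - sum(d) / 7)^2) / 7)),
               tolerance = 1e-9)
})

test_that("scalar features use word counts and population SDs", {
  w <- bare_window(q_tbl(rep("2020-01-05 10:00:00", 3),
                         text = c("a b", "a b c d", "a b c d e f")),
                   "2020-01-01")
  sc <- scalar_features(w)
  expect_equal(unname(sc["total_queries"]), 3)
  expect_equal(unname(sc["mean_query_length"]), 4)
  expect_equal(scalar_features(empty_window()),
               c(total_queries = 0, mean_query_length = 0,
                 sd_freq_bins = 0, sd_len_bins = 0))
  # SDs equal an oracle recomputation from the bin histograms
  co <- tiny_cohort()
  wd <- diagnostic_window(co$archives[["ssd002"]], co$timelines[["ssd002"]])
  fh <- fourday_histograms(wd)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  scd <- scalar_features(wd)
  expect_equal(unname(scd["sd_freq_bins"]), pop_sd(unname(fh$frequency)),
               tolerance = 1e-9)
  expect_equal(unname(scd["sd_len_bins"]), pop_sd(unname(fh$length)),
               tolerance = 1e-9)
})

test_that("assemble yields the 123-feature vector with the documented blocks", {
  lex <- fixture_lexicon()
  co <- tiny_cohort()
  w <- diagnostic_window(co$archives[["ssd001"]], co$timelines[["ssd001"]])
  fv <- assemble(w, lex)
  expect_length(fv, 123L)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_false(anyNA(fv))
  blocks <- feature_blocks()
  expect_equal(unname(blocks),
               c(24L, 24L, 8L, 8L, 1L, 1L, 1L, 1L, 1L, 1L, 51L, 1L, 1L))
  expect_equal(sum(blocks), 123L)
  expect_equal(sum(startsWith(names(fv), "liwc_")), 51L)
  expect_equal(sum(startsWith(names(fv), "hour_len_")), 24L)
  expect_equal(sum(startsWith(names(fv), "hour_freq_")), 24L)
  expect_equal(sum(startsWith(names(fv), "fourday_len_")), 8L)
  expect_equal(sum(startsWith(names(fv), "fourday_freq_")), 8L)
  # internal consistency across blocks
  expect_equal(sum(fv[sprintf("hour_freq_%02d", 0:23)]),
               unname(fv["total_queries"]))

  # empty window -> all zeros
  expect_equal(unname(assemble(empty_window(), lex)), rep(0, 123))

  # determinism and invariance to storage order
  w_shuf <- w
  set.seed(3)
  w_shuf$queries <- w$queries[sample(nrow(w$queries)), ]
  expect_equal(assemble(w_shuf, lex), fv)
})

test_that("standardization fits on the training rows only", {
  lex <- fixture_lexicon()
  co <- tiny_cohort()
  wins <- searchprint:::segment_cohort(co$archives, co$timelines,
                                       "diagnostic", seed = 4)
  feats <- build_feature_matrix(wins, lex)
  x <- feature_parts(feats)$x
  fit_all <- standardize_features(x)
  behav <- !startsWith(colnames(x), "liwc_")
  sds <- apply(x[, behav], 2, function(v) sqrt(mean((v - mean(v))^2)))
  live <- which(behav)[sds > 0]
  expect_equal(unname(colMeans(fit_all$x[, live])), rep(0, length(live)),
               tolerance = 1e-9)
  expect_equal(unname(apply(fit_all$x[, live], 2,
                            function(v) sqrt(mean((v - mean(v))^2)))),
               rep(1, length(live)), tolerance = 1e-9)
  # lexicon columns pass through untouched
  expect_equal(fit_all$x[, !behav], x[, !behav])
  # constant behavioral column maps to 0 without division errors
  xc <- x; xc[, "hour_freq_03"] <- 5
  expect_equal(unname(standardize_features(xc)$x[, "hour_freq_03"]),
               rep(0, nrow(xc)))
  # held-out rows transform with the training mean/sd (oracle)
  train <- 1:10
  fit <- standardize_features(x, fit_rows = train)
  heldout <- setdiff(seq_len(nrow(x)), train)
  j <- which(behav)[1]
  mu <- mean(x[train, j]); sdj <- sqrt(mean((x[train, j] - mu)^2))
  expect_equal(searchprint:::apply_standardize(fit, x[heldout, , drop = FALSE])[, j],
               (x[heldout, j] - mu) / sdj, tolerance = 1e-9)
})
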