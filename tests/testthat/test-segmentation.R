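test_that("visit segmentation follows the 60-minute gap rule", {
  expect_equal(nrow(segment_visits(det_frame("A", character(0)))), 0L)

  one <- segment_visits(det_frame("A", "2004-06-01 10:00:00"))
  expect_equal(one$n_detections, 1L)
  expect_equal(one$duration_h, 0)
  expect_equal(one$start, one$end)

  v <- segment_visits(det_frame("A", c("2004-06-01 00:00:00",
                                       "2004-06-01 00:30:00",
                                       "2004-06-01 02:05:00")))
  expect_equal(v$n_detections, c(2L, 1L))
  expect_equal(v$duration_h, c(0.5, 0))

  # exact 60-min gap splits; 59:59 does not
  split <- segment_visits(det_frame("A", c("2004-06-01 00:00:00",
                                           "2004-06-01 01:00:00")))
  expect_equal(nrow(split), 2L)
  merged <- segment_visits(det_frame("A", c("2004-06-01 00:00:00",
                                            "2004-06-01 00:59:59")))
  expect_equal(nrow(merged), 1L)

  unsorted <- det_frame("A", c("2004-06-01 02:00:00", "2004-06-01 01:00:00"))
  expect_error(segment_visits(unsorted), "sorted")
  expect_error(segment_visits(rbind(det_frame("A", "2004-06-01"),
                                    det_frame("B", "2004-06-02"))),
               "single shark")
})

test_that("presence strings follow the 30-day gap rule with censoring flags", {
  s <- extract_presence_strings(det_frame("A", c("2004-06-01", "2004-06-20",
                                                 "2004-08-01")))
  expect_equal(nrow(s), 2L)
  expect_equal(s$n_detections, c(2L, 1L))
  expect_equal(instant_date(s$departure[1]), as.Date("2004-06-20"))
  # unobserved bounding absences at the stream edges
  expect_true(s$left_censored[1])
  expect_true(s$right_censored[2])
  expect_false(s$right_censored[1])
  expect_false(s$left_censored[2])

  # 29-day gap stays one string
  s29 <- extract_presence_strings(det_frame("A", c("2004-06-01", "2004-06-30")))
  expect_equal(nrow(s29), 1L)
  # exactly 30 d splits
  s30 <- extract_presence_strings(det_frame("A", c("2004-06-01", "2004-07-01")))
  expect_equal(nrow(s30), 2L)

  expect_equal(nrow(extract_presence_strings(det_frame("A", character(0)))), 0L)

  # known monitoring bounds clear the censoring flag when the gap is observed
  sb <- extract_presence_strings(det_frame("A", c("2004-06-01", "2004-06-20")),
                                 stream_start = "2004-04-01",
                                 stream_end = "2004-08-01")
  expect_false(sb$left_censored[1])   # Apr 1 -> Jun 1 arrival: 61 d observed
  expect_false(sb$right_censored[1])  # Jun 20 -> Aug 1 bound: 42 d observed
  sb2 <- extract_presence_strings(det_frame("A", c("2004-06-01", "2004-06-20")),
                                  stream_start = "2004-06-01",
                                  stream_end = "2004-07-01")
  expect_true(sb2$left_censored[1])
})

test_that("segmentations agree with the brute-force oracle on random streams", {
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(1:120, 1)
    times <- random_stream(n)
    det <- det_frame("A", times)
    v <- segment_visits(det)
    grp_v <- naive_segments(times, 3600)
    expect_equal(nrow(v), max(grp_v))
    expect_equal(v$n_detections, as.integer(table(grp_v)[as.character(
      seq_len(max(grp_v)))]), ignore_attr = TRUE)
    expect_equal(as.numeric(v$start),
                 as.numeric(tapply(as.numeric(times), grp_v, min)),
                 ignore_attr = TRUE)
    s <- extract_presence_strings(det)
    grp_s <- naive_segments(times, 30 * 86400)
    expect_equal(nrow(s), max(grp_s))
    # conservation
    expect_equal(sum(v$n_detections), n)
    expect_equal(sum(s$n_detections), n)
  }
})

test_that("raising the gap threshold never increases event counts", {
  set.seed(42)
  for (rep in 1:30) {
    times <- random_stream(sample(2:100, 1))
    det <- det_frame("A", times)
    counts <- vapply(c(15, 30, 60, 120, 480),
                     function(g) nrow(segment_visits(det, g)), 0)
    expect_true(all(diff(counts) <= 0))
    scounts <- vapply(c(5, 15, 30, 60),
                      function(g) nrow(extract_presence_strings(det, g)), 0)
    expect_true(all(diff(scounts) <= 0))
  }
})

test_that("re-segmenting the detections of a single visit returns that visit", {
  set.seed(43)
  times <- random_stream(80)
  det <- det_frame("A", times)
  v <- segment_visits(det)
  for (i in seq_len(min(nrow(v), 10))) {
    sub <- det[det$timestamp >= v$start[i] & det$timestamp <= v$end[i], ]
    v2 <- segment_visits(sub)
    expect_equal(nrow(v2), 1L)
    expect_equal(v2$start, v$start[i])
    expect_equal(v2$end, v$end[i])
    expect_equal(v2$n_detections, v$n_detections[i])
  }
})

test_that("tagging-bias exclusion runs from tagging to the next April 30", {
  strings <- extract_presence_strings(
    det_frame("A", c("2005-09-01", "2006-05-02", "2006-07-01")))
  out <- apply_tagging_exclusion(strings, as.Date("2005-06-15"))
  expect_true(out$excluded_tagging_bias[1])   # Sep 2005: within bias window
  expect_false(out$excluded_tagging_bias[2])  # May 2006: past April 30 cutoff

  # tagged early in the year: cutoff is April 30 of the same year
  s2 <- extract_presence_strings(det_frame("A", c("2005-03-01", "2005-06-20")))
  out2 <- apply_tagging_exclusion(s2, as.Date("2005-02-01"))
  expect_true(out2$excluded_tagging_bias[1])
  expect_false(out2$excluded_tagging_bias[2])

  empty <- extract_presence_strings(det_frame("A", character(0)))
  expect_equal(nrow(apply_tagging_exclusion(empty, as.Date("2005-06-15"))), 0L)
})

test_that("season assignment uses the inclusive June-July window", {
  s <- assign_season(parse_instant(c("2004-06-12 08:00:00",
                                     "2004-08-01 00:00:00",
                                     "2004-07-31 23:59:00",
                                     "2004-06-01 00:00:00",
                                     "2004-05-31 23:59:59")))
  expect_equal(s$season_year, rep(2004L, 5))
  expect_equal(s$in_mating_window, c(TRUE, FALSE, TRUE, TRUE, FALSE))
})
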