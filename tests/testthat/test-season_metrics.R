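reg2 <- toy_registry(c("A", "B"), c("F", "M"), c("2001-06-05", "2001-06-06"))

test_that("season summaries compute visit counts, means and cumulative days", {
  half_hourly <- function(from, to)
    format(seq(parse_instant(from), parse_instant(to), by = 1800),
           "%Y-%m-%d %H:%M:%S")
  det <- rbind(
    det_frame("A", half_hourly("2004-06-10 00:00:00", "2004-06-10 02:00:00")),
    det_frame("A", half_hourly("2004-06-12 00:00:00", "2004-06-12 06:00:00")))
  v <- segment_visits(det)
  s <- extract_presence_strings(det)
  out <- season_summaries(v, s, reg2)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_visits, 2L)
  expect_equal(out$mean_visit_duration_h, 4)
  expect_equal(out$cumulative_days, 8 / 24)
  expect_equal(out$span_days, 2.25)  # Jun 10 00:00 -> Jun 12 06:00

  # tagging-year season omitted when the flag is on
  det_tag <- det_frame("A", c("2001-06-10 00:00:00", "2001-06-10 01:30:00"))
  vt <- segment_visits(det_tag)
  expect_equal(nrow(season_summaries(vt, extract_presence_strings(det_tag),
                                     reg2)), 0L)
  expect_equal(nrow(season_summaries(vt, extract_presence_strings(det_tag),
                                     reg2, exclude_tagging_year = FALSE)), 1L)
})

test_that("multi-season fixture matches hand computation and row order does not matter", {
  half_hourly <- function(from, to)
    format(seq(parse_instant(from), parse_instant(to), by = 1800),
           "%Y-%m-%d %H:%M:%S")
  times <- c(
    half_hourly("2004-06-10 00:00:00", "2004-06-10 01:00:00"),  # 1 h visit
    "2004-07-01 00:00:00",                                      # 0 h visit
    half_hourly("2005-06-20 10:00:00", "2005-06-20 13:00:00"),  # 3 h visit
    half_hourly("2006-07-30 23:00:00", "2006-08-01 01:00:00"))  # crosses end
  det <- det_frame("A", times)
  v <- segment_visits(det)
  s <- extract_presence_strings(det)
  out <- season_summaries(v, s, reg2)
  expect_equal(out$season_year, c(2004L, 2005L, 2006L))
  expect_equal(out$n_visits, c(2L, 1L, 1L))
  expect_equal(out$mean_visit_duration_h, c(0.5, 3, 26))
  # 2006 visit clipped at Aug 1 00:00 for cumulative time (25 of its 26 h)
  expect_equal(out$cumulative_days[3], 25 / 24)

  vv <- v[sample(nrow(v)), ]
  expect_equal(season_summaries(vv, s, reg2), out)
})

test_that("hourly profiles are simplex-valued with closed-form mean and SD", {
  # two seasons concentrated at hours 10 and 14 -> mean .5, SD .5*sqrt(2)
  det <- rbind(
    det_frame("A", sprintf("2004-06-%02d 10:15:00", 10:19)),
    det_frame("A", sprintf("2005-06-%02d 14:45:00", 10:19)))
  hp <- hourly_profile(det, reg2)
  expect_equal(sum(hp$mean_proportion), 1, tolerance = 1e-9)
  expect_equal(hp$mean_proportion[hp$hour_of_day == 10], 0.5)
  expect_equal(hp$mean_proportion[hp$hour_of_day == 14], 0.5)
  expect_equal(hp$sd_proportion[hp$hour_of_day == 10], sqrt(0.5),
               tolerance = 1e-12)

  # all detections in one hour in every season -> mean 1, SD 0
  det1 <- rbind(det_frame("A", sprintf("2004-06-%02d 10:15:00", 10:12)),
                det_frame("A", sprintf("2005-06-%02d 10:45:00", 10:12)))
  hp1 <- hourly_profile(det1, reg2)
  expect_equal(hp1$mean_proportion[hp1$hour_of_day == 10], 1)
  expect_equal(max(hp1$sd_proportion), 0)

  # uniform across hours -> 1/24 each
  detu <- det_frame("A", sprintf("2004-06-10 %02d:30:00", 0:23))
  hpu <- hourly_profile(detu, reg2)
  expect_equal(hpu$mean_proportion, rep(1 / 24, 24))

  # tagging-year detections are excluded
  det_tag <- det_frame("A", "2001-06-10 10:00:00")
  expect_equal(nrow(hourly_profile(det_tag, reg2)), 0L)
})

test_that("monthly event proportions drop singletons, censored bounds and tagging bias", {
  det <- det_frame("A", c(
    "2004-05-20 10:00:00", "2004-05-21 10:00:00",  # May arrival string
    "2004-07-01 10:00:00", "2004-07-02 10:00:00",  # Jun?: gap 40 d -> Jul arr
    "2004-09-15 10:00:00"))                        # singleton
  s <- extract_presence_strings(det)
  s$left_censored <- FALSE; s$right_censored <- FALSE
  mep <- monthly_event_proportions(s, reg2)
  arr <- mep[mep$event == "arrival" & mep$sex == "F", ]
  expect_equal(sum(arr$proportion), 1, tolerance = 1e-9)
  expect_equal(arr$n_events[arr$month == 5], 1L)
  expect_equal(arr$n_events[arr$month == 7], 1L)
  expect_equal(sum(arr$n_events), 2L)  # singleton contributed nothing

  # 3 June + 1 May arrivals -> 0.75 / 0.25
  s2 <- s[rep(1, 4), ]
  s2$arrival <- parse_instant(c("2004-06-01", "2004-06-02", "2005-06-03",
                                "2004-05-04"))
  s2$n_detections <- 2L
  m2 <- monthly_event_proportions(s2, reg2)
  a2 <- m2[m2$event == "arrival", ]
  expect_equal(a2$proportion[a2$month == 6], 0.75)
  expect_equal(a2$proportion[a2$month == 5], 0.25)

  # excluded-by-April-rule strings are not counted
  s3 <- s2
  s3$excluded_tagging_bias <- c(TRUE, FALSE, FALSE, FALSE)
  a3 <- monthly_event_proportions(s3, reg2)
  expect_equal(sum(a3$n_events[a3$event == "arrival"]), 3L)

  # left-censored strings contribute no arrival but still a departure
  s4 <- s2
  s4$left_censored <- c(TRUE, FALSE, FALSE, FALSE)
  m4 <- monthly_event_proportions(s4, reg2)
  expect_equal(sum(m4$n_events[m4$event == "arrival"]), 3L)
  expect_equal(sum(m4$n_events[m4$event == "departure"]), 4L)
})

test_that("daily bins count a shark-day once regardless of detection volume", {
  det <- rbind(
    det_frame("A", sprintf("2004-09-01 %02d:00:00", 0:20)),  # 21 det, 1 day
    det_frame("A", c("2004-09-05 10:00:00", "2004-09-09 10:00:00")),
    det_frame("B", "2004-06-15 10:00:00"))
  db <- daily_detection_bins(det, reg2)
  expect_equal(nrow(db$daily), 4L)
  expect_equal(db$monthly$shark_days[db$monthly$sex == "F" &
                                       db$monthly$month == 9], 3L)
  expect_equal(db$monthly$shark_days[db$monthly$sex == "M" &
                                       db$monthly$month == 6], 1L)
})

test_that("weekly temperature summarizes daily maxima with sample SD", {
  ts <- seq(parse_instant("2004-06-07 00:00:00"),
            parse_instant("2004-06-08 23:00:00"), by = 3600)
  temps <- data.frame(timestamp = ts,
                      temp_c = rep(c(28, 32), each = 24), flagged = FALSE)
  wt <- weekly_max_temperature(temps)
  expect_equal(nrow(wt), 1L)
  expect_equal(wt$mean_daily_max, 30)
  expect_equal(wt$sd_daily_max, stats::sd(c(28, 32)))

  const <- data.frame(timestamp = ts, temp_c = 30, flagged = FALSE)
  wc <- weekly_max_temperature(const)
  expect_equal(wc$mean_daily_max, 30)
  expect_equal(wc$sd_daily_max, 0)

  expect_equal(nrow(weekly_max_temperature(const[0, ])), 0L)
})
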