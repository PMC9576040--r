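test_that("return intervals are consecutive differences of season years", {
  expect_equal(return_intervals(c(2002, 2004, 2007)), c(2L, 3L))
  expect_equal(return_intervals(c(2001, 2002)), 1L)
  expect_equal(return_intervals(2005), integer(0))
  expect_equal(return_intervals(c(2007, 2002, 2004)), c(2L, 3L))  # unsorted in
})

test_that("presence fusion uses the mating window and the method ranking", {
  reg <- toy_registry(c("A", "B"), c("F", "M"), c("2002-06-01", "2002-06-01"))
  sgt <- data.frame(shark_id = "A",
                    date = as.Date(c("2004-06-20", "2002-06-10")),
                    method = c("PIT_scan", "capture"),
                    stringsAsFactors = FALSE)
  det <- det_frame("A", c("2004-07-02 10:00:00",  # same season as PIT scan
                          "2005-08-15 10:00:00")) # outside the window
  out <- build_presence(sgt, det, reg)
  h <- out$histories
  a <- h[h$shark_id == "A", ]
  expect_equal(a$seasons_present[[1]], c(2002L, 2004L))  # Aug 2005 not a season
  expect_true(a$is_returning)
  expect_equal(a$time_at_large_years, 3L)  # 2002 -> 2005 (any-method identification)
  expect_equal(out$season_methods$method[out$season_methods$season_year == 2004],
               "PIT_scan")  # outranks acoustic

  b <- h[h$shark_id == "B", ]
  expect_equal(b$n_seasons, 0L)
  expect_false(b$is_returning)

  bad <- data.frame(shark_id = "A", date = as.Date("2001-06-20"),
                    method = "visual", stringsAsFactors = FALSE)
  expect_error(build_presence(bad, NULL, reg), "predates")
})

test_that("time-at-large bounds the season count", {
  set.seed(7)
  reg <- toy_registry(sprintf("S%02d", 1:20), rep(c("F", "M"), 10),
                      rep("2000-06-10", 20))
  sgt <- do.call(rbind, lapply(reg$shark_id, function(id) {
    yrs <- sort(sample(2000:2015, sample(1:8, 1)))
    data.frame(shark_id = id, date = as.Date(sprintf("%d-06-20", yrs)),
               method = "visual", stringsAsFactors = FALSE)
  }))
  h <- build_presence(sgt, NULL, reg)$histories
  expect_true(all(h$time_at_large_years >= h$n_seasons - 1L))
  # identifications confined to mating windows of distinct years -> equality
  expect_true(all(h$time_at_large_years ==
                    vapply(h$seasons_present, function(s) max(s) - min(s), 0L)))
})

test_that("cycle classification counts intervals, exclusions and switches", {
  c1 <- classify_cycles(c(2, 2, 2))
  expect_equal(c1$n_two_year, 3L)
  expect_equal(c1$n_switches, 0L)
  expect_false(c1$switched_once)

  c2 <- classify_cycles(c(2, 3, 2))
  expect_equal(c2$n_two_year, 2L)
  expect_equal(c2$n_three_year, 1L)
  expect_equal(c2$n_switches, 2L)
  expect_true(c2$switched_multiple)

  c3 <- classify_cycles(c(2, 5, 3))
  expect_equal(c3$n_long, 1L)
  expect_equal(c3$n_switches, 1L)  # retained sequence (2, 3)
  expect_true(c3$switched_once)
  expect_false(c3$switched_multiple)

  # 1-yr intervals tallied but outside the cycle sequence
  c4 <- classify_cycles(c(1, 2, 1, 3))
  expect_equal(c4$n_one_year, 2L)
  expect_equal(c4$n_switches, 1L)

  # invariant: interval counts partition the input
  set.seed(5)
  for (rep in 1:50) {
    iv <- sample(1:6, sample(0:8, 1), replace = TRUE)
    cc <- classify_cycles(iv)
    expect_equal(cc$n_one_year + cc$n_two_year + cc$n_three_year + cc$n_long,
                 length(iv))
    expect_lte(cc$n_switches, max(0, cc$n_two_year + cc$n_three_year - 1))
    # prepending excluded long intervals changes nothing downstream
    cc2 <- classify_cycles(c(7, iv))
    expect_equal(cc2$n_switches, cc$n_switches)
    expect_equal(cc2$n_two_year, cc$n_two_year)
  }
})

test_that("cohort statistics reproduce printed-arithmetic anchors", {
  # 118 tagged, 80 returning, 47 of the returners monitored > 10 years
  n <- 118
  seasons <- c(
    lapply(1:47, function(i) c(2000L, 2000L + 11L + (i %% 3))),  # > 10 y
    lapply(1:33, function(i) c(2000L, 2002L + (i %% 5))),        # short returners
    lapply(1:38, function(i) 2000L))                             # never returned
  h <- histories_from_seasons(sprintf("S%03d", 1:n),
                              rep(c("F", "M"), length.out = n),
                              rep(2000L, n), seasons)
  cs <- cohort_statistics(h, as_of_season = 2021)
  expect_equal(cs$n_tagged, 118L)
  expect_equal(cs$n_returning, 80L)
  expect_equal(cs$pct_returning, 68)        # 67.8 rounds half-up to 68
  expect_equal(cs$n_monitored_gt10y, 47L)
  expect_equal(cs$pct_monitored_gt10y, 59)  # 58.75 rounds half-up to 59

  expect_error(cohort_statistics(h, min_tag_year = 2050, as_of_season = 2060),
               "empty cohort")
})

test_that("pooled female intervals give the triennial share and switch rates", {
  # 83 two-year + 39 three-year intervals pooled across females
  iv_sets <- c(rep(list(rep(2L, 83L %/% 20)), 19), list(rep(2L, 83L %% 20 + 4L)),
               rep(list(rep(3L, 3L)), 13))
  stopifnot(sum(unlist(iv_sets) == 2) == 83, sum(unlist(iv_sets) == 3) == 39)
  seasons <- lapply(iv_sets, function(iv) cumsum(c(2000L, iv)))
  n <- length(iv_sets)
  h <- histories_from_seasons(sprintf("F%03d", 1:n), rep("F", n),
                              rep(2000L, n), seasons)
  cs <- cohort_statistics(h, as_of_season = 2021)
  expect_equal(cs$n_female_two_year, 83L)
  expect_equal(cs$n_female_three_year, 39L)
  expect_equal(cs$triennial_share_pct, 100 * 39 / 122)
  expect_equal(round_half_up(cs$triennial_share_pct), 32)

  # 50 tenured females: 17 switched at least once, 9 of them multiple times
  sw <- c(rep(list(c(2L, 3L, 2L)), 9),            # multiple switches
          rep(list(c(2L, 2L, 3L)), 8),            # exactly one switch
          rep(list(c(2L, 2L, 2L, 2L, 2L)), 33))   # no switch
  seasons <- lapply(sw, function(iv) cumsum(c(2000L, iv)))
  h2 <- histories_from_seasons(sprintf("F%03d", 1:50), rep("F", 50),
                               rep(2000L, 50), seasons)
  cs2 <- cohort_statistics(h2, as_of_season = 2015)
  expect_equal(cs2$n_tenured_females, 50L)
  expect_equal(cs2$pct_switched_once, 34)
  expect_equal(cs2$pct_switched_multiple, 18)
})
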