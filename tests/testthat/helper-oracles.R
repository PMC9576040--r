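# Fixture builders and independent brute-force oracles used across tests.

det_frame <- function(id, times, station = "S1") {
  ts <- if (inherits(times, "POSIXct")) times else parse_instant(times)
  data.frame(shark_id = rep_len(id, length(ts)), timestamp = ts,
             station = rep_len(station, length(ts)),
             stringsAsFactors = FALSE)
}

# random detection stream: mixture of second/minute/day/month-scale gaps so
# both segmentation thresholds are exercised, including exact-boundary gaps
random_stream <- function(n, origin = "2005-06-01 00:00:00") {
  gaps <- sample(c(
    stats::runif(n, 30, 3000),            # within-visit to near-threshold
    c(3600, 3600 - 1, 3600 + 1),          # exact 60-min boundary region
    stats::runif(n, 3600, 86400 * 2),     # between visits
    c(30 * 86400, 30 * 86400 - 1),        # exact 30-day boundary region
    stats::runif(n, 86400 * 25, 86400 * 60)  # between presence strings
  ), n - 1, replace = TRUE)
  parse_instant(origin) + cumsum(c(0, gaps))
}

# O(n) loop oracle: walk the stream and open a new event whenever the gap to
# the previous detection reaches the threshold (seconds)
naive_segments <- function(times, gap_seconds) {
  n <- length(times)
  if (n == 0L) return(integer(0))
  grp <- integer(n)
  grp[1] <- 1L
  for (i in seq_len(n)[-1]) {
    gap <- as.numeric(times[i]) - as.numeric(times[i - 1])
    grp[i] <- if (gap >= gap_seconds) grp[i - 1] + 1L else grp[i - 1]
  }
  grp
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
enumerate_mw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# direct-summation two-sample AD statistic over the pooled distinct values
# (independent of the vectorized implementation)
direct_ad2 <- function(x, y) {
  N <- length(x) + length(y)
  z <- sort(unique(c(x, y)))
  total <- 0
  for (smp in list(x, y)) {
    ni <- length(smp)
    acc <- 0
    for (j in seq_along(z)) {
      lj <- sum(x == z[j]) + sum(y == z[j])
      Baj <- sum(c(x, y) < z[j]) + lj / 2
      Maij <- sum(smp < z[j]) + sum(smp == z[j]) / 2
      den <- Baj * (N - Baj) - N * lj / 4
      if (den > 0) acc <- acc + (lj / N) * (N * Maij - ni * Baj)^2 / den
    }
    total <- total + acc / ni
  }
  (N - 1) / N * total
}

# exhaustive permutation p for the AD statistic at small n
enumerate_ad_p <- function(x, y) {
  pool <- c(x, y)
  idx <- utils::combn(length(pool), length(x))
  obs <- direct_ad2(x, y)
  stats <- apply(idx, 2, function(i) direct_ad2(pool[i], pool[-i]))
  mean(stats >= obs - 1e-12)
}

# small registry fixture
toy_registry <- function(ids, sexes, tag_dates) {
  data.frame(shark_id = ids, sex = sexes,
             tagging_date = as.Date(tag_dates),
             tag_types = "PIT|roto|acoustic", total_length_cm = 250,
             acoustic_tag_end = as.Date(tag_dates) + 3650,
             stringsAsFactors = FALSE)
}

# a return-history frame built directly from seasons-present lists
histories_from_seasons <- function(ids, sexes, tag_seasons, seasons) {
  h <- data.frame(shark_id = ids, sex = sexes, tag_season = tag_seasons,
                  n_seasons = lengths(seasons),
                  time_at_large_years = as.integer(vapply(seasons, function(s)
                    if (length(s)) max(s) - min(s) else 0, 0)),
                  is_returning = mapply(function(s, t) any(s > t),
                                        seasons, tag_seasons),
                  stringsAsFactors = FALSE)
  h$seasons_present <- seasons
  h$intervals <- lapply(seasons, return_intervals)
  h
}
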