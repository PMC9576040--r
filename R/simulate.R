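# Synthetic monitoring-data generator.  Emulates the statistical structure
# the analysis assumes — male annual returns versus female 2/3-year cycles
# with switching, sex-specific arrival/departure phenology, male
# many-short-visit versus female few-long-visit within-season structure,
# gestation-autumn female presence with an August dip above 30 degC, diel
# detection suppression in warm afternoons, a 240-s nominal transmission
# delay and a 3650-d tag life — with full ground truth, so every pipeline
# stage can be validated against known generating values.

#' Simulation configuration
#'
#' Defaults are calibrated to the monitored population: ~89 females and 48
#' males tagged over a 30-year program, a 0.32 per-cycle triennial
#' probability, female arrivals centred on June 24 (SD 5 d) inside the
#' June 12 - July 8 envelope, male arrivals across May 25 - June 28,
#' departures peaking in early July (females gone by the second week, males
#' by the third), per-season visit counts with medians near 34 (males) and
#' 12.5 (females) and visit durations with medians near 1 h (males) and
#' 4.4 h (females, heavy-tailed).  Spread parameters beyond the medians are
#' the generator's own choices (only medians are observed).
#'
#' @param n_females,n_males population sizes.
#' @param start_year first tagging year.
#' @param years monitoring span in years.
#' @param p_triennial per-cycle probability of a 3-year female interval.
#' @param p_male_return per-season probability a male returns.
#' @param female_arrival_mean_doy,female_arrival_sd mean day-of-year (Jun 24)
#'   and SD of female arrivals, truncated to the envelope.
#' @param female_arrival_window,male_arrival_window day-of-year envelopes
#'   (Jun 12 - Jul 8; May 25 - Jun 28).
#' @param female_departure_last_doy,male_departure_last_doy latest departure
#'   (second/third week of July).
#' @param visit_count_median,visit_count_size named (F, M) negative-binomial
#'   medians and size parameters for per-season visit counts.
#' @param visit_duration_median_h,visit_duration_sdlog named (F, M) lognormal
#'   medians (h) and log-SDs for visit durations.
#' @param p_gestation_autumn probability a mating-year female shows an
#'   autumn (Aug-Oct) presence bout.
#' @param august_heat_cutoff_c daily-max temperature above which an August
#'   presence day may be skipped (default 30).
#' @param august_avoidance probability that a hot August presence day is
#'   actually skipped (partial avoidance: the observed dip is relative, not
#'   total).
#' @param diel_heat_cutoff_c hourly temperature above which afternoon
#'   (15:00-17:00) detections are thinned (default 29.6).
#' @param diel_suppression retained fraction of transmissions in suppressed
#'   hours.
#' @param transmission_delay_s nominal delay; actual delays jitter uniformly
#'   on [delay/2, 3*delay/2] (240 s -> U[120, 360]).
#' @param p_detect per-transmission detection probability.
#' @param tag_life_days acoustic tag life (3650 d).
#' @param p_resight per-season identification probabilities by non-acoustic
#'   method during June-July surveys (invented, realism only).
#' @param temp_mean_c,temp_annual_amp_c,temp_diurnal_amp_c,temp_noise_sd
#'   temperature model: annual sinusoid peaking in August, diurnal sinusoid
#'   peaking mid-afternoon, Gaussian noise.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_females = 89, n_males = 48,
                       start_year = 1992, years = 30,
                       p_triennial = 0.32, p_male_return = 0.9,
                       female_arrival_mean_doy = 175, female_arrival_sd = 5,
                       female_arrival_window = c(163, 189),
                       male_arrival_window = c(145, 179),
                       female_departure_last_doy = 195,
                       male_departure_last_doy = 202,
                       visit_count_median = c(F = 12.5, M = 34),
                       visit_count_size = c(F = 4, M = 6),
                       visit_duration_median_h = c(F = 4.4, M = 1),
                       visit_duration_sdlog = c(F = 0.8, M = 0.6),
                       p_gestation_autumn = 0.7,
                       august_heat_cutoff_c = 30,
                       august_avoidance = 0.85,
                       diel_heat_cutoff_c = 29.6,
                       diel_suppression = 0.4,
                       transmission_delay_s = 240,
                       p_detect = 0.5,
                       tag_life_days = 3650,
                       p_resight = c(capture = 0.05, PIT_scan = 0.4,
                                     visual = 0.5),
                       temp_mean_c = 27, temp_annual_amp_c = 4.2,
                       temp_diurnal_amp_c = 1.2, temp_noise_sd = 0.3) {
  cfg <- as.list(environment())
  stopifnot(cfg$p_triennial >= 0, cfg$p_triennial <= 1,
            cfg$p_detect >= 0, cfg$p_detect <= 1,
            all(cfg$p_resight >= 0 & cfg$p_resight <= 1),
            cfg$years >= 1)
  class(cfg) <- "sim_config"
  cfg
}

doy_instant <- function(year, doy, frac_day = 0) {
  as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = MATESITE_TZ) +
    (doy - 1) * 86400 + round(frac_day * 86400)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# negative-binomial mu giving a target median for a fixed size parameter
nb_mu_for_median <- function(median_target, size) {
  f <- function(mu) stats::qnbinom(0.5, size = size, mu = mu) - median_target
  stats::uniroot(f, c(max(median_target / 4, 0.1), median_target * 4))$root
}

#' Simulate the hourly on-site water-temperature series
#'
#' Annual sinusoid peaking in mid-August (so the August monthly mean of
#' daily maxima exceeds 30 degC at the default amplitude), a diurnal
#' sinusoid peaking mid-afternoon, and Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return temperature data.frame (\code{timestamp,temp_c,flagged}).
#' @export
simulate_temperature <- function(config, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", config$start_year),
                   tz = MATESITE_TZ)
  t1 <- as.POSIXct(sprintf("%d-12-31 23:00:00",
                           config$start_year + config$years - 1),
                   tz = MATESITE_TZ)
  ts <- seq(t0, t1, by = 3600)
  doy <- as.POSIXlt(ts, tz = MATESITE_TZ)$yday + 1
  hr <- as.POSIXlt(ts, tz = MATESITE_TZ)$hour
  temp <- config$temp_mean_c +
    config$temp_annual_amp_c * cos(2 * pi * (doy - 224) / 365.25) +
    config$temp_diurnal_amp_c * cos(2 * pi * (hr - 15.5) / 24) +
    stats::rnorm(length(ts), 0, config$temp_noise_sd)
  data.frame(timestamp = ts, temp_c = temp,
             flagged = temp < 10 | temp > 40, stringsAsFactors = FALSE)
}

#' Simulate the tagged population and its true reproductive schedule
#'
#' Tagging years are staggered across the first two-thirds of the program.
#' Each female's first mating year is her tagging year; subsequent
#' inter-mating intervals are drawn independently (3 years with probability
#' \code{p_triennial}, else 2), so cycle switching emerges from the draws
#' rather than being imposed.  Males return each season independently with
#' probability \code{p_male_return} from their tagging year on.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list: \code{registry} data.frame, and ground truth
#'   \code{cycles} (per-female interval vectors) and \code{true_seasons}
#'   (per-shark mating years on site).
#' @export
simulate_population <- function(config, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  y0 <- config$start_year
  y1 <- y0 + config$years - 1
  n <- config$n_females + config$n_males
  ids <- c(sprintf("F%03d", seq_len(config$n_females)),
           sprintf("M%03d", seq_len(config$n_males)))
  sex <- rep(c("F", "M"), c(config$n_females, config$n_males))
  tag_year <- sample(seq(y0, y0 + max(1, floor(config$years * 2 / 3))),
                     n, replace = TRUE)
  tag_date <- as.Date(sprintf("%d-06-%02d", tag_year,
                              sample(10:25, n, replace = TRUE)))
  registry <- data.frame(
    shark_id = ids, sex = sex, tagging_date = tag_date,
    tag_types = "PIT|roto|acoustic",
    total_length_cm = round(ifelse(sex == "F", stats::rnorm(n, 250, 10),
                                   stats::rnorm(n, 242, 10))),
    acoustic_tag_end = tag_date + config$tag_life_days,
    stringsAsFactors = FALSE)
  cycles <- list()
  true_seasons <- list()
  for (i in seq_len(n)) {
    if (sex[i] == "F") {
      yrs <- tag_year[i]
      iv <- integer(0)
      repeat {
        step <- if (stats::runif(1) < config$p_triennial) 3L else 2L
        nxt <- yrs[length(yrs)] + step
        if (nxt > y1) break
        iv <- c(iv, step)
        yrs <- c(yrs, nxt)
      }
      cycles[[ids[i]]] <- iv
      true_seasons[[ids[i]]] <- yrs
    } else {
      span <- tag_year[i]:y1
      on_site <- span == tag_year[i] |
        stats::runif(length(span)) < config$p_male_return
      true_seasons[[ids[i]]] <- span[on_site]
    }
  }
  list(registry = registry, cycles = cycles, true_seasons = true_seasons)
}

# visit placement within one bout: first visit starts at the arrival
# instant, the last ends at the departure instant, and neighbouring visits
# are separated by more than the 60-min segmentation gap.
place_visits <- function(arrival, departure, n_visits, dur_h) {
  span_s <- as.numeric(departure) - as.numeric(arrival)
  dur_s <- pmin(dur_h * 3600, span_s)
  n <- length(dur_s)
  if (n == 1L || span_s < sum(dur_s) + (n - 1) * 3700) {
    # bout too tight for the drawn visits: collapse to one visit
    return(data.frame(start = arrival, end = departure))
  }
  slack <- span_s - sum(dur_s) - (n - 1) * 3700
  gaps <- as.vector(stats::rmultinom(1, size = max(round(slack), 0),
                                     prob = rep(1, n - 1)))
  starts <- as.numeric(arrival) +
    cumsum(c(0, dur_s[-n] + 3700 + gaps))
  ends <- starts + dur_s
  ends[n] <- as.numeric(departure)
  data.frame(start = as.POSIXct(starts, origin = "1970-01-01",
                                tz = MATESITE_TZ),
             end = as.POSIXct(ends, origin = "1970-01-01", tz = MATESITE_TZ))
}

emit_transmissions <- function(start, end, delay) {
  span <- as.numeric(end) - as.numeric(start)
  n_max <- ceiling(span / (delay / 2)) + 1
  offs <- cumsum(c(0, stats::runif(n_max, delay / 2, delay * 1.5)))
  offs <- offs[offs <= span]
  as.numeric(start) + offs
}

#' Simulate detections and sightings for a population
#'
#' For every shark-season truly on site, draws sex-specific arrival and
#' departure instants and within-bout visit structure, emits coded
#' transmissions every ~240 s (uniform jitter) inside visits, thins them by
#' the per-transmission detection probability and by afternoon-heat
#' suppression, stops acoustic emissions at tag expiry, adds
#' gestation-autumn female bouts (August days suppressed when the daily
#' maximum exceeds the heat cutoff), and draws per-season PIT/visual/capture
#' sightings during June-July surveys.
#'
#' @param population output of [simulate_population()].
#' @param temperature output of [simulate_temperature()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list: \code{detections}, \code{sightings}, and ground-truth
#'   \code{true_visits} and \code{true_bouts} data.frames.
#' @export
simulate_detections <- function(population, temperature, config, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  reg <- population$registry
  # hourly temperature series indexed arithmetically (regular 3600-s grid)
  temp_t0 <- as.numeric(temperature$timestamp[1])
  temp_v <- temperature$temp_c
  day_of <- instant_date(temperature$timestamp)
  daily_max <- tapply(temperature$temp_c, day_of, max)
  tz_off <- 5 * 3600  # site local standard time is UTC-5

  nb_mu <- c(F = nb_mu_for_median(config$visit_count_median[["F"]],
                                  config$visit_count_size[["F"]]),
             M = nb_mu_for_median(config$visit_count_median[["M"]],
                                  config$visit_count_size[["M"]]))
  det <- list(); sgt <- list(); tv <- list(); tb <- list()
  for (i in seq_len(nrow(reg))) {
    id <- reg$shark_id[i]; sx <- reg$sex[i]
    tag_start <- reg$tagging_date[i]
    tag_end <- reg$acoustic_tag_end[i]
    for (year in population$true_seasons[[id]]) {
      if (sx == "F") {
        arr_doy <- rtruncnorm1(1, config$female_arrival_mean_doy,
                               config$female_arrival_sd,
                               config$female_arrival_window[1],
                               config$female_arrival_window[2])
        dep_doy <- rtruncnorm1(1, 186, 4, arr_doy + 2,
                               config$female_departure_last_doy)
      } else {
        arr_doy <- rtruncnorm1(1, 163, 8, config$male_arrival_window[1],
                               config$male_arrival_window[2])
        dep_doy <- rtruncnorm1(1, 189, 5, arr_doy + 5,
                               config$male_departure_last_doy)
      }
      arrival <- doy_instant(year, arr_doy, stats::runif(1))
      departure <- doy_instant(year, dep_doy, stats::runif(1))
      n_visits <- max(1L, stats::rnbinom(1, size = config$visit_count_size[[sx]],
                                         mu = nb_mu[[sx]]))
      dur_h <- stats::rlnorm(n_visits,
                             meanlog = log(config$visit_duration_median_h[[sx]]),
                             sdlog = config$visit_duration_sdlog[[sx]])
      visits <- place_visits(arrival, departure, n_visits, dur_h)
      tb[[length(tb) + 1]] <- data.frame(
        shark_id = id, season_year = year, arrival = arrival,
        departure = departure, stringsAsFactors = FALSE)
      # gestation-autumn bout for mating females
      if (sx == "F" && stats::runif(1) < config$p_gestation_autumn) {
        autumn_days <- sort(sample(213:304, stats::rpois(1, 12)))
        for (ad in autumn_days) {
          dkey <- as.character(as.Date(sprintf("%d-01-01", year)) + ad - 1)
          dm <- daily_max[dkey]
          in_august <- ad <= 243
          if (in_august && !is.na(dm) && dm > config$august_heat_cutoff_c &&
              stats::runif(1) < config$august_avoidance)
            next
          vstart <- doy_instant(year, ad, stats::runif(1, 0.2, 0.7))
          vend <- vstart + round(stats::rlnorm(1, log(3 * 3600), 0.5))
          visits <- rbind(visits, data.frame(start = vstart, end = vend))
        }
      }
      visits <- visits[order(visits$start), , drop = FALSE]
      tv[[length(tv) + 1]] <- data.frame(
        shark_id = id, season_year = year, start = visits$start,
        end = visits$end, stringsAsFactors = FALSE)
      # acoustic transmissions inside visits, within tag life
      tag_start_s <- as.numeric(as.POSIXct(format(tag_start),
                                           tz = MATESITE_TZ))
      tag_end_s <- as.numeric(as.POSIXct(format(tag_end + 1),
                                         tz = MATESITE_TZ))
      for (v in seq_len(nrow(visits))) {
        vs <- as.numeric(visits$start[v])
        if (vs >= tag_end_s || vs < tag_start_s) next
        tt <- round(emit_transmissions(visits$start[v], visits$end[v],
                                       config$transmission_delay_s))
        if (!length(tt)) next
        hr <- ((tt - tz_off) %% 86400) %/% 3600
        ht <- temp_v[pmax(1L, pmin(length(temp_v),
                                   ((tt - temp_t0) %/% 3600) + 1L))]
        p <- rep(config$p_detect, length(tt))
        hot <- hr >= 15 & hr <= 17 & ht > config$diel_heat_cutoff_c
        p[hot] <- p[hot] * config$diel_suppression
        keep <- stats::runif(length(tt)) < p
        if (any(keep))
          det[[length(det) + 1]] <- list(id = id, t = tt[keep])
      }
      # June-July survey identifications
      for (mth in names(config$p_resight)) {
        if (stats::runif(1) < config$p_resight[[mth]]) {
          sd_date <- as.Date(sprintf("%d-06-01", year)) +
            sample(0:60, 1)
          if (sd_date >= tag_start)
            sgt[[length(sgt) + 1]] <- data.frame(
              shark_id = id, date = sd_date, method = mth,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  detections <- if (length(det)) {
    data.frame(
      shark_id = rep(vapply(det, `[[`, "", "id"),
                     vapply(det, function(d) length(d$t), 0L)),
      timestamp = as.POSIXct(unlist(lapply(det, `[[`, "t")),
                             origin = "1970-01-01", tz = MATESITE_TZ),
      station = "MG01", stringsAsFactors = FALSE)
  } else {
    data.frame(shark_id = character(0),
               timestamp = parse_instant(character(0)),
               station = character(0), stringsAsFactors = FALSE)
  }
  detections <- detections[order(detections$shark_id, detections$timestamp), ,
                           drop = FALSE]
  rownames(detections) <- NULL
  sightings <- bind(sgt, data.frame(shark_id = character(0),
                                    date = as.Date(character(0)),
                                    method = character(0)))
  sightings <- sightings[order(sightings$shark_id, sightings$date), ,
                         drop = FALSE]
  rownames(sightings) <- NULL
  list(detections = detections, sightings = sightings,
       true_visits = bind(tv, NULL), true_bouts = bind(tb, NULL))
}

#' Sightings under perfect seasonal detection
#'
#' One identification per true shark-season (mid-June), emulating the ideal
#' condition in which every mating-season presence is observed.  Used for
#' end-to-end recovery checks where the detection process itself is not
#' under study.
#'
#' @param population output of [simulate_population()].
#' @param method identification method recorded (default PIT scan).
#' @return sightings data.frame.
#' @export
perfect_season_sightings <- function(population, method = "PIT_scan") {
  reg <- population$registry
  rows <- lapply(names(population$true_seasons), function(id) {
    yrs <- population$true_seasons[[id]]
    if (!length(yrs)) return(NULL)
    d <- as.Date(sprintf("%d-06-15", yrs))
    tagd <- reg$tagging_date[reg$shark_id == id]
    d <- pmax(d, tagd)  # the tag-season identification is the tagging itself
    data.frame(shark_id = id, date = d, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$shark_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_temperature()],
#' [simulate_population()] and [simulate_detections()] off one seed.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (sub-seeds are derived deterministically).
#' @return list with \code{registry,detections,sightings,temperature} and
#'   \code{ground_truth} (cycles, true seasons, bouts, visits).
#' @export
simulate_dataset <- function(config = sim_config(), seed) {
  temperature <- simulate_temperature(config, seed)
  population <- simulate_population(config, seed + 1L)
  obs <- simulate_detections(population, temperature, config, seed + 2L)
  list(registry = population$registry, detections = obs$detections,
       sightings = obs$sightings, temperature = temperature,
       ground_truth = list(cycles = population$cycles,
                           true_seasons = population$true_seasons,
                           true_bouts = obs$true_bouts,
                           true_visits = obs$true_visits))
}

#' Write a simulated dataset to a directory
#'
#' Emits the four input CSVs consumed by the loaders plus a
#' \code{ground_truth.yaml} sidecar.
#'
#' @param dataset output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(dataset$registry, file.path(dir, "registry.csv"))
  write_table(dataset$detections, file.path(dir, "detections.csv"))
  write_table(dataset$sightings, file.path(dir, "sightings.csv"))
  write_table(dataset$temperature[, c("timestamp", "temp_c")],
              file.path(dir, "temperature.csv"))
  gt <- dataset$ground_truth
  yaml::write_yaml(list(
    cycles = lapply(gt$cycles, as.integer),
    true_seasons = lapply(gt$true_seasons, as.integer),
    n_true_visits = nrow(gt$true_visits)
  ), file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
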