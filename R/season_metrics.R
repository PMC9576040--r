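# Within-season residency metrics, diel profiles, monthly arrival/departure
# proportions, daily detection bins, and weekly temperature summaries.

season_window <- function(year) {
  c(as.POSIXct(sprintf("%d-06-01 00:00:00", year), tz = MATESITE_TZ),
    as.POSIXct(sprintf("%d-08-01 00:00:00", year), tz = MATESITE_TZ))
}

#' Per shark-season residency summaries
#'
#' For every shark-season with at least one visit intersecting the June-July
#' mating window this computes: the number of visits, the mean visit duration
#' (each shark-season's own mean, so seasons are equally weighted in
#' downstream comparisons), cumulative time on site (visit durations clipped
#' to the window, summed, in days), and the arrival-to-departure span in days
#' of the presence string overlapping the window (a string is the unit of
#' arrival-to-departure, so spans are never summed; in the rare case of
#' several strings overlapping one season the longest is reported).  Initial
#' tagging-year seasons are omitted by default to avoid sampling bias.
#'
#' @param visits data.frame from [segment_visits()] (any number of sharks).
#' @param strings data.frame from [extract_presence_strings()].
#' @param registry registry data.frame (for tagging year and sex).
#' @param exclude_tagging_year drop each shark's tagging-year season.
#' @return data.frame with one row per retained shark-season:
#'   \code{shark_id,sex,season_year,n_visits,mean_visit_duration_h,
#'   cumulative_days,span_days}.
#' @export
season_summaries <- function(visits, strings, registry,
                             exclude_tagging_year = TRUE) {
  empty <- data.frame(shark_id = character(0), sex = character(0),
                      season_year = integer(0), n_visits = integer(0),
                      mean_visit_duration_h = numeric(0),
                      cumulative_days = numeric(0), span_days = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(visits) == 0L) return(empty)
  tag_year <- as.integer(format(registry$tagging_date, "%Y"))
  names(tag_year) <- registry$shark_id
  sex_of <- stats::setNames(registry$sex, registry$shark_id)

  vy <- instant_year(visits$start)
  vsplit <- split(visits, list(visits$shark_id, vy), drop = TRUE, sep = "\r")
  ssplit <- split(strings, strings$shark_id)
  rows <- list()
  for (key in names(vsplit)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    id <- parts[1]; year <- as.integer(parts[2])
    if (exclude_tagging_year && !is.na(tag_year[id]) && year == tag_year[id])
      next
    win <- season_window(year)
    vg <- vsplit[[key]]
    v <- vg[vg$start < win[2] & vg$end >= win[1], , drop = FALSE]
    if (nrow(v) == 0L) next
    # clip to the window for cumulative time on site
    cs <- pmax(as.numeric(v$start), as.numeric(win[1]))
    ce <- pmin(as.numeric(v$end), as.numeric(win[2]))
    cum_days <- sum(ce - cs) / 86400
    sg <- ssplit[[id]]
    spans <- if (is.null(sg)) numeric(0) else {
      keep <- as.numeric(sg$arrival) < as.numeric(win[2]) &
        as.numeric(sg$departure) >= as.numeric(win[1])
      as.numeric(sg$departure[keep] - sg$arrival[keep], units = "days")
    }
    rows[[key]] <- data.frame(
      shark_id = id, sex = unname(sex_of[id]), season_year = year,
      n_visits = nrow(v),
      mean_visit_duration_h = mean(v$duration_h),
      cumulative_days = cum_days,
      span_days = if (length(spans)) max(spans) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$shark_id, out$season_year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean and SD of hourly detection proportions across mating seasons
#'
#' For each sex and mating season (calendar year), the proportion of that
#' season's detections falling in each hour of day (local standard time,
#' \code{floor(hour)} binning) is computed; the mean and sample SD of these
#' 24-vectors across seasons is returned per sex.  Detections from each
#' shark's initial tagging year are excluded, as are detections outside the
#' June-July window.
#'
#' @param detections detections data.frame (all sharks).
#' @param registry registry data.frame.
#' @return data.frame \code{sex,hour_of_day,mean_proportion,sd_proportion}.
#' @export
hourly_profile <- function(detections, registry) {
  tag_year <- as.integer(format(registry$tagging_date, "%Y"))
  names(tag_year) <- registry$shark_id
  sex_of <- stats::setNames(registry$sex, registry$shark_id)
  s <- assign_season(detections$timestamp)
  keep <- s$in_mating_window &
    s$season_year != tag_year[detections$shark_id]
  det <- detections[keep, , drop = FALSE]
  yr <- s$season_year[keep]
  empty <- data.frame(sex = character(0), hour_of_day = integer(0),
                      mean_proportion = numeric(0),
                      sd_proportion = numeric(0), stringsAsFactors = FALSE)
  if (nrow(det) == 0L) return(empty)
  out <- list()
  for (sx in sort(unique(unname(sex_of[det$shark_id])))) {
    dsx <- det[sex_of[det$shark_id] == sx, , drop = FALSE]
    ysx <- yr[sex_of[det$shark_id] == sx]
    vecs <- lapply(unique(ysx), function(y) {
      h <- instant_hour(dsx$timestamp[ysx == y])
      tabulate(h + 1L, nbins = 24L) / length(h)
    })
    m <- Reduce(`+`, vecs) / length(vecs)
    sdv <- if (length(vecs) > 1L) {
      apply(do.call(rbind, vecs), 2, stats::sd)
    } else rep(0, 24)
    out[[sx]] <- data.frame(sex = sx, hour_of_day = 0:23,
                            mean_proportion = m, sd_proportion = sdv,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monthly proportions of arrival and departure events
#'
#' Uses presence strings with at least two detections (a singleton cannot
#' define distinct arrival and departure events), not flagged for tagging
#' bias, and with the relevant bound uncensored: left-censored strings
#' contribute no arrival, right-censored strings no departure.  Proportions
#' are per (sex, event) and sum to one.
#'
#' @param strings presence strings (all sharks) with flags applied.
#' @param registry registry data.frame.
#' @return data.frame \code{sex,month,event,n_events,proportion}.
#' @export
monthly_event_proportions <- function(strings, registry) {
  sex_of <- stats::setNames(registry$sex, registry$shark_id)
  s <- strings[strings$n_detections >= 2L & !strings$excluded_tagging_bias, ,
               drop = FALSE]
  rows <- list()
  for (ev in c("arrival", "departure")) {
    ss <- if (ev == "arrival") s[!s$left_censored, , drop = FALSE]
          else s[!s$right_censored, , drop = FALSE]
    mo <- instant_month(if (ev == "arrival") ss$arrival else ss$departure)
    sx <- unname(sex_of[ss$shark_id])
    for (sex in sort(unique(sx))) {
      counts <- tabulate(mo[sx == sex], nbins = 12L)
      total <- sum(counts)
      if (total == 0L) next
      rows[[paste(ev, sex)]] <- data.frame(
        sex = sex, month = 1:12, event = ev, n_events = counts,
        proportion = counts / total, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sex = character(0), month = integer(0),
                      event = character(0), n_events = integer(0),
                      proportion = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Daily presence bins and per-sex monthly shark-day totals
#'
#' A shark-day is counted once regardless of how many detections the shark
#' produced that day.
#'
#' @param detections detections data.frame.
#' @param registry registry data.frame.
#' @return list with \code{daily} (\code{shark_id,date}, unique) and
#'   \code{monthly} (\code{sex,month,shark_days} summed over years).
#' @export
daily_detection_bins <- function(detections, registry) {
  sex_of <- stats::setNames(registry$sex, registry$shark_id)
  daily <- unique(data.frame(shark_id = detections$shark_id,
                             date = instant_date(detections$timestamp),
                             stringsAsFactors = FALSE))
  daily <- daily[order(daily$shark_id, daily$date), , drop = FALSE]
  rownames(daily) <- NULL
  if (nrow(daily) == 0L) {
    monthly <- data.frame(sex = character(0), month = integer(0),
                          shark_days = integer(0), stringsAsFactors = FALSE)
    return(list(daily = daily, monthly = monthly))
  }
  mo <- as.integer(format(daily$date, "%m"))
  sx <- unname(sex_of[daily$shark_id])
  monthly <- as.data.frame(table(sex = sx, month = factor(mo, levels = 1:12)),
                           stringsAsFactors = FALSE)
  names(monthly)[3] <- "shark_days"
  monthly$month <- as.integer(monthly$month)
  monthly <- monthly[order(monthly$sex, monthly$month), , drop = FALSE]
  rownames(monthly) <- NULL
  list(daily = daily, monthly = monthly)
}

#' Weekly mean and SD of daily maximum water temperature
#'
#' Daily maxima are computed first, then pooled by ISO week number across
#' years; weeks with no data are omitted.
#'
#' @param temps temperature data.frame from [load_temperature()] or the
#'   simulator.
#' @return data.frame \code{week,mean_daily_max,sd_daily_max,n_days}.
#' @export
weekly_max_temperature <- function(temps) {
  if (nrow(temps) == 0L)
    return(data.frame(week = integer(0), mean_daily_max = numeric(0),
                      sd_daily_max = numeric(0), n_days = integer(0)))
  day <- instant_date(temps$timestamp)
  dmax <- tapply(temps$temp_c, day, max)
  days <- as.Date(names(dmax))
  wk <- as.integer(strftime(days, format = "%V"))
  agg <- tapply(as.numeric(dmax), wk, function(v)
    c(mean(v), if (length(v) > 1L) stats::sd(v) else 0, length(v)))
  out <- data.frame(week = as.integer(names(agg)),
                    mean_daily_max = vapply(agg, `[`, 0, 1),
                    sd_daily_max = vapply(agg, `[`, 0, 2),
                    n_days = as.integer(vapply(agg, `[`, 0, 3)))
  out <- out[order(out$week), , drop = FALSE]
  rownames(out) <- NULL
  out
}
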