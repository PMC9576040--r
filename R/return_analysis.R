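# Multi-year return analysis: fuse every identification method into
# mating-season presence histories, extract return intervals, classify
# biennial/triennial cycles and cycle switching, and summarize the cohort.

DEFAULT_METHOD_RANK <- c("capture", "PIT_scan", "visual", "acoustic")

#' Build per-shark mating-season presence histories
#'
#' A shark is "present" in a season when any identification method (capture,
#' PIT scan, visual resight, acoustic detection) records it inside the
#' June 1 - July 31 window of that year.  Each shark-season also records the
#' most-verifiable method seen, per a configurable ranking.  Time-at-large is
#' the elapsed whole years between a shark's first and most recent
#' identification by any method on any date.
#'
#' @param sightings sightings data.frame (may include rows of every method).
#' @param detections acoustic detections data.frame (or NULL).
#' @param registry registry data.frame.
#' @param method_rank character vector ordering methods from most to least
#'   verifiable.
#' @return list with \code{histories} — one row per shark
#'   (\code{shark_id,sex,tag_season,n_seasons,time_at_large_years,
#'   is_returning} plus list-columns \code{seasons_present} and
#'   \code{intervals}) — and \code{season_methods}
#'   (\code{shark_id,season_year,method}: the top-ranked method per
#'   shark-season).
#' @export
build_presence <- function(sightings, detections = NULL, registry,
                           method_rank = DEFAULT_METHOD_RANK) {
  ev <- data.frame(shark_id = sightings$shark_id, date = sightings$date,
                   method = sightings$method, stringsAsFactors = FALSE)
  if (!is.null(detections) && nrow(detections) > 0L) {
    ev <- rbind(ev, data.frame(shark_id = detections$shark_id,
                               date = instant_date(detections$timestamp),
                               method = "acoustic", stringsAsFactors = FALSE))
  }
  ev <- ev[ev$shark_id %in% registry$shark_id, , drop = FALSE]
  tagd <- registry$tagging_date[match(ev$shark_id, registry$shark_id)]
  if (any(ev$date < tagd))
    stop("identification predates tagging date for shark ",
         ev$shark_id[which(ev$date < tagd)[1]], call. = FALSE)

  yr <- as.integer(format(ev$date, "%Y"))
  mo <- as.integer(format(ev$date, "%m"))
  in_window <- mo %in% c(6L, 7L)
  rank_of <- stats::setNames(seq_along(method_rank), method_rank)

  histories <- vector("list", nrow(registry))
  season_methods <- list()
  for (i in seq_len(nrow(registry))) {
    id <- registry$shark_id[i]
    sel <- ev$shark_id == id
    seasons <- sort(unique(yr[sel & in_window]))
    tag_season <- as.integer(format(registry$tagging_date[i], "%Y"))
    ident_years <- yr[sel]
    tal <- if (length(ident_years)) max(ident_years) - min(ident_years) else 0L
    for (sy in seasons) {
      m <- ev$method[sel & in_window & yr == sy]
      season_methods[[paste(id, sy)]] <- data.frame(
        shark_id = id, season_year = sy,
        method = m[which.min(rank_of[m])], stringsAsFactors = FALSE)
    }
    histories[[i]] <- data.frame(
      shark_id = id, sex = registry$sex[i], tag_season = tag_season,
      n_seasons = length(seasons), time_at_large_years = as.integer(tal),
      is_returning = any(seasons > tag_season),
      stringsAsFactors = FALSE)
    histories[[i]]$seasons_present <- list(seasons)
    histories[[i]]$intervals <- list(return_intervals(seasons))
  }
  hist_df <- do.call(rbind, histories)
  rownames(hist_df) <- NULL
  sm <- if (length(season_methods)) do.call(rbind, season_methods) else
    data.frame(shark_id = character(0), season_year = integer(0),
               method = character(0), stringsAsFactors = FALSE)
  rownames(sm) <- NULL
  list(histories = hist_df, season_methods = sm)
}

#' Whole-year intervals between consecutive mating-season returns
#'
#' @param seasons_present integer vector of mating-season years.
#' @return integer vector of consecutive differences (empty for a singleton).
#' @export
return_intervals <- function(seasons_present) {
  s <- sort(unique(as.integer(seasons_present)))
  if (length(s) < 2L) return(integer(0))
  diff(s)
}

#' Classify a return-interval sequence into reproductive cycles
#'
#' Intervals of four years or longer may span a missed mating season and are
#' excluded from the cycle sequence; 1-year intervals are tallied and (by
#' default) also excluded, since females are nearly always absent in the
#' season following a mating year — a 1-year "return" is identification
#' noise rather than a reproductive cycle.  A switch is a change between
#' 2-year and 3-year intervals at adjacent positions of the retained
#' chronological sequence.
#'
#' @param intervals integer vector from [return_intervals()], chronological.
#' @param exclude_one_year drop 1-year intervals from the cycle sequence
#'   (default TRUE, appropriate for females; set FALSE to keep the raw
#'   tally's interpretation for annual returners).
#' @return one-row data.frame: \code{n_one_year,n_two_year,n_three_year,
#'   n_long,n_switches,switched_once,switched_multiple}.
#' @export
classify_cycles <- function(intervals, exclude_one_year = TRUE) {
  intervals <- as.integer(intervals)
  n_one <- sum(intervals == 1L)
  n_two <- sum(intervals == 2L)
  n_three <- sum(intervals == 3L)
  n_long <- sum(intervals >= 4L)
  retained <- intervals[intervals %in% c(2L, 3L)]
  n_sw <- if (length(retained) > 1L) sum(diff(retained) != 0L) else 0L
  data.frame(n_one_year = n_one, n_two_year = n_two, n_three_year = n_three,
             n_long = n_long, n_switches = n_sw,
             switched_once = n_sw >= 1L, switched_multiple = n_sw >= 2L)
}

#' Cohort-level return and cycle statistics
#'
#' Restricts to sharks tagged within \code{[min_tag_year, max_tag_year]} and
#' reports the return rate, monitoring-duration shares, per-sex medians, the
#' pooled female triennial share, and switching rates among long-tenured
#' females.  "Monitored over 10 (20) years" means a time-at-large strictly
#' greater than 10 (20) whole years; "tag tenure" of a female is
#' \code{as_of_season - tag_season}.  Percentages are rounded half-up to
#' integers except the triennial share, which is reported unrounded.
#'
#' @param histories data.frame from [build_presence()]\code{$histories}.
#' @param min_tag_year,max_tag_year inclusive tagging-year bounds.
#' @param as_of_season season used to measure tag tenure.
#' @param tenure_years minimum female tag tenure (years) for the switching
#'   rates (default 10).
#' @return named list; see Details in the vignette.
#' @export
cohort_statistics <- function(histories, min_tag_year = -Inf,
                              max_tag_year = Inf, as_of_season,
                              tenure_years = 10) {
  h <- histories[histories$tag_season >= min_tag_year &
                   histories$tag_season <= max_tag_year, , drop = FALSE]
  if (nrow(h) == 0L) stop("empty cohort", call. = FALSE)
  ret <- h[h$is_returning, , drop = FALSE]
  n_tagged <- nrow(h)
  n_returning <- nrow(ret)

  fem <- h[h$sex == "F", , drop = FALSE]
  fem_cls <- do.call(rbind, lapply(fem$intervals, classify_cycles))
  n_two <- sum(fem_cls$n_two_year)
  n_three <- sum(fem_cls$n_three_year)

  tenured <- fem[fem$is_returning &
                   (as_of_season - fem$tag_season) >= tenure_years, ,
                 drop = FALSE]
  ten_cls <- do.call(rbind, lapply(tenured$intervals, classify_cycles))

  med_by_sex <- function(col) {
    vapply(split(ret[[col]], ret$sex), stats::median, 0)
  }
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den)
  }
  list(
    n_tagged = n_tagged,
    n_returning = n_returning,
    pct_returning = pct(n_returning, n_tagged),
    n_monitored_gt10y = sum(ret$time_at_large_years > 10),
    pct_monitored_gt10y = pct(sum(ret$time_at_large_years > 10), n_returning),
    n_monitored_gt20y = sum(ret$time_at_large_years > 20),
    pct_monitored_gt20y = pct(sum(ret$time_at_large_years > 20), n_returning),
    median_n_seasons = med_by_sex("n_seasons"),
    median_time_at_large = med_by_sex("time_at_large_years"),
    n_female_two_year = n_two,
    n_female_three_year = n_three,
    triennial_share_pct = if (n_two + n_three > 0)
      100 * n_three / (n_two + n_three) else NA_real_,
    n_tenured_females = nrow(tenured),
    n_switched_once = if (nrow(tenured)) sum(ten_cls$switched_once) else 0L,
    pct_switched_once = pct(if (nrow(tenured)) sum(ten_cls$switched_once)
                            else 0L, nrow(tenured)),
    n_switched_multiple = if (nrow(tenured)) sum(ten_cls$switched_multiple)
                          else 0L,
    pct_switched_multiple = pct(if (nrow(tenured))
      sum(ten_cls$switched_multiple) else 0L, nrow(tenured))
  )
}
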