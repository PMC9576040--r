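# Event segmentation: detections -> visits (60-min gap rule) and
# arrival/departure presence strings (30-day gap rule).  Gap comparison is
# ">= threshold splits" in both cases, so an exact-boundary gap starts a new
# event.

check_single_sorted <- function(detections) {
  if (nrow(detections) == 0L) return(invisible(TRUE))
  if (length(unique(detections$shark_id)) > 1L)
    stop("detections must belong to a single shark", call. = FALSE)
  if (is.unsorted(as.numeric(detections$timestamp)))
    stop("detections must be sorted ascending by timestamp", call. = FALSE)
  invisible(TRUE)
}

run_boundaries <- function(ts, gap_seconds) {
  # indices starting a new run under the ">= gap splits" rule
  if (length(ts) == 0L) return(integer(0))
  gaps <- diff(as.numeric(ts))
  c(1L, which(gaps >= gap_seconds) + 1L)
}

#' Segment one shark's detections into visits
#'
#' A visit is a single detection or a maximal run of detections in which no
#' two consecutive detections are separated by \code{gap_minutes} or more.
#' A single-detection visit has zero duration.
#'
#' @param detections data.frame of one shark's detections, sorted ascending.
#' @param gap_minutes splitting threshold in minutes (default 60).
#' @return data.frame with columns \code{shark_id,start,end,n_detections,
#'   duration_h}, one row per visit in chronological order.
#' @export
segment_visits <- function(detections, gap_minutes = 60) {
  check_single_sorted(detections)
  n <- nrow(detections)
  empty <- data.frame(shark_id = character(0),
                      start = parse_instant(character(0)),
                      end = parse_instant(character(0)),
                      n_detections = integer(0), duration_h = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  starts <- run_boundaries(detections$timestamp, gap_minutes * 60)
  ends <- c(starts[-1] - 1L, n)
  data.frame(
    shark_id = detections$shark_id[starts],
    start = detections$timestamp[starts],
    end = detections$timestamp[ends],
    n_detections = ends - starts + 1L,
    duration_h = as.numeric(detections$timestamp[ends] -
                              detections$timestamp[starts], units = "hours"),
    stringsAsFactors = FALSE
  )
}

#' Extract arrival/departure presence strings
#'
#' A presence string is a maximal run of detections bounded on both sides by
#' absences of \code{gap_days} or more; its first detection is an arrival
#' event and its last a departure event.  Strings bounded by the edge of the
#' observation stream have an unobserved bounding absence and are flagged
#' censored: a left-censored string contributes no arrival, a right-censored
#' one no departure.  Single-detection strings are kept and identifiable via
#' \code{n_detections == 1}; phenology consumers drop them (strings need two
#' or more observations to define distinct arrival and departure events).
#'
#' @param detections data.frame of one shark's detections, sorted ascending.
#' @param gap_days splitting threshold in days (default 30).
#' @param stream_start,stream_end optional known monitoring bounds (Date or
#'   POSIXct).  When supplied and the gap between the bound and the first
#'   (last) string is itself \code{>= gap_days}, the bounding absence was
#'   observed and the censoring flag is cleared.
#' @return data.frame with columns \code{shark_id,arrival,departure,
#'   n_detections,left_censored,right_censored,excluded_tagging_bias}.
#' @export
extract_presence_strings <- function(detections, gap_days = 30,
                                     stream_start = NULL, stream_end = NULL) {
  check_single_sorted(detections)
  n <- nrow(detections)
  empty <- data.frame(shark_id = character(0),
                      arrival = parse_instant(character(0)),
                      departure = parse_instant(character(0)),
                      n_detections = integer(0),
                      left_censored = logical(0), right_censored = logical(0),
                      excluded_tagging_bias = logical(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  gap_s <- gap_days * 86400
  starts <- run_boundaries(detections$timestamp, gap_s)
  ends <- c(starts[-1] - 1L, n)
  out <- data.frame(
    shark_id = detections$shark_id[starts],
    arrival = detections$timestamp[starts],
    departure = detections$timestamp[ends],
    n_detections = ends - starts + 1L,
    left_censored = FALSE, right_censored = FALSE,
    excluded_tagging_bias = FALSE,
    stringsAsFactors = FALSE
  )
  left_ok <- !is.null(stream_start) &&
    as.numeric(out$arrival[1]) - as.numeric(as.POSIXct(stream_start,
      tz = MATESITE_TZ)) >= gap_s
  right_ok <- !is.null(stream_end) &&
    as.numeric(as.POSIXct(stream_end, tz = MATESITE_TZ)) -
      as.numeric(out$departure[nrow(out)]) >= gap_s
  out$left_censored[1] <- !left_ok
  out$right_censored[nrow(out)] <- !right_ok
  out
}

#' Flag presence strings biased by the tagging event
#'
#' Strings whose arrival falls between the tagging date and April 30 of the
#' first April strictly after tagging are flagged
#' \code{excluded_tagging_bias = TRUE} (the animal was placed on site by the
#' tagging encounter, so its first observed bout does not reflect voluntary
#' arrival).  The April cutoff is used because mating-season arrivals begin
#' in May.  Flagged strings are retained in the output; phenology consumers
#' omit them.
#'
#' @param strings data.frame from [extract_presence_strings()] for one shark.
#' @param tagging_date that shark's tagging date (Date).
#' @return \code{strings} with the flag applied.
#' @export
apply_tagging_exclusion <- function(strings, tagging_date) {
  if (nrow(strings) == 0L) return(strings)
  tagging_date <- as.Date(tagging_date)
  yr <- as.integer(format(tagging_date, "%Y"))
  april30 <- as.Date(sprintf("%d-04-30", yr))
  cutoff <- if (tagging_date < april30) april30 else
    as.Date(sprintf("%d-04-30", yr + 1L))
  arr <- instant_date(strings$arrival)
  strings$excluded_tagging_bias <- arr >= tagging_date & arr <= cutoff
  strings
}

#' Map an instant to its mating season
#'
#' The mating season is the June 1 - July 31 window (inclusive) of each
#' calendar year.
#'
#' @param x POSIXct or Date vector.
#' @return data.frame with \code{season_year} (calendar year) and
#'   \code{in_mating_window} (logical).
#' @export
assign_season <- function(x) {
  if (inherits(x, "Date")) x <- as.POSIXct(format(x), tz = MATESITE_TZ)
  data.frame(season_year = instant_year(x),
             in_mating_window = instant_month(x) %in% c(6L, 7L))
}
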