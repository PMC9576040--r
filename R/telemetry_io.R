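# Readers and writers for the four input tables and all pipeline outputs.
# Everything is comma-delimited text with a header; timestamps are ISO-8601 in
# site-local standard time (UTC-5, no DST).  Column names are fixed:
#   detections:  shark_id, timestamp, station
#   registry:    shark_id, sex, tagging_date, tag_types, total_length_cm
#   sightings:   shark_id, date, method
#   temperature: timestamp, temp_c

SIGHTING_METHODS <- c("capture", "PIT_scan", "visual", "acoustic")
STUDY_WINDOW <- as.Date(c("1990-01-01", "2030-12-31"))

read_csv_checked <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Load the tag registry
#'
#' One row per tagged shark.  \code{tag_types} is a \code{|}-separated subset
#' of \code{PIT}, \code{roto}, \code{acoustic}.  When a shark carries an
#' acoustic tag and no explicit \code{acoustic_tag_end} column is present, the
#' tag end is derived as \code{tagging_date + tag_life_days}.
#'
#' @param path CSV with columns \code{shark_id,sex,tagging_date,tag_types}
#'   and optionally \code{total_length_cm,acoustic_tag_end}.
#' @param tag_life_days acoustic tag battery life used to derive
#'   \code{acoustic_tag_end} (default 3650 d, the transmitters' maximum life).
#' @return data.frame with one validated record per shark.
#' @export
load_registry <- function(path, tag_life_days = 3650) {
  df <- read_csv_checked(path, c("shark_id", "sex", "tagging_date", "tag_types"))
  n <- nrow(df)
  out <- data.frame(
    shark_id = df$shark_id,
    sex = df$sex,
    tagging_date = rep(as.Date(NA), n),
    tag_types = df$tag_types,
    total_length_cm = rep(NA_real_, n),
    acoustic_tag_end = rep(as.Date(NA), n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    if (!nzchar(df$shark_id[i])) stop_row(i, "empty shark_id")
    if (!df$sex[i] %in% c("F", "M"))
      stop_row(i, sprintf("sex must be F or M, got '%s'", df$sex[i]))
    d <- suppressWarnings(as.Date(df$tagging_date[i]))
    if (is.na(d)) stop_row(i, "missing or unparseable tagging_date")
    out$tagging_date[i] <- d
    types <- strsplit(df$tag_types[i], "|", fixed = TRUE)[[1]]
    bad <- setdiff(types, c("PIT", "roto", "acoustic"))
    if (length(bad))
      stop_row(i, sprintf("unknown tag type(s): %s", paste(bad, collapse = ",")))
  }
  if (anyDuplicated(out$shark_id)) {
    dup <- out$shark_id[duplicated(out$shark_id)][1]
    stop(sprintf("duplicate shark_id in registry: %s", dup), call. = FALSE)
  }
  if ("total_length_cm" %in% names(df)) {
    tl <- suppressWarnings(as.numeric(df$total_length_cm))
    bad <- which(!is.na(tl) & tl <= 0)
    if (length(bad)) stop_row(bad[1], "total_length_cm must be positive")
    out$total_length_cm <- tl
  }
  has_ac <- grepl("acoustic", out$tag_types, fixed = TRUE)
  if ("acoustic_tag_end" %in% names(df)) {
    explicit <- suppressWarnings(as.Date(df$acoustic_tag_end))
    out$acoustic_tag_end <- explicit
    derive <- has_ac & is.na(explicit)
  } else {
    derive <- has_ac
  }
  out$acoustic_tag_end[derive] <- out$tagging_date[derive] + tag_life_days
  out
}

#' Load acoustic detections
#'
#' Returns records sorted by (shark_id, timestamp).  Detections whose
#' \code{shark_id} is not in the registry are returned separately as orphans,
#' never silently dropped; exact duplicate rows are de-duplicated with a
#' count.  All on-site receivers are treated as one logical station, so the
#' station label is carried through but never used analytically.
#'
#' @param path CSV with columns \code{shark_id,timestamp,station}.
#' @param registry data.frame from [load_registry()]; pass \code{NULL} to skip
#'   the registry check (all records returned, no orphans).
#' @return list with elements \code{detections} (data.frame sorted ascending),
#'   \code{orphans} (same columns, unregistered IDs) and \code{n_duplicates}
#'   (count of exact duplicate input rows removed).
#' @export
load_detections <- function(path, registry = NULL) {
  df <- read_csv_checked(path, c("shark_id", "timestamp", "station"))
  n <- nrow(df)
  ts <- parse_instant(df$timestamp)
  if (n > 0L) {
    bad <- which(is.na(ts) | !nzchar(df$shark_id))
    if (length(bad))
      stop_row(bad[1], sprintf("unparseable timestamp or empty shark_id: '%s'",
                               df$timestamp[bad[1]]))
    d <- instant_date(ts)
    oow <- which(d < STUDY_WINDOW[1] | d > STUDY_WINDOW[2])
    if (length(oow))
      stop_row(oow[1], sprintf("timestamp outside study window: %s",
                               df$timestamp[oow[1]]))
  }
  det <- data.frame(shark_id = df$shark_id, timestamp = ts,
                    station = df$station, stringsAsFactors = FALSE)
  dup <- duplicated(det)
  n_dup <- sum(dup)
  det <- det[!dup, , drop = FALSE]
  det <- det[order(det$shark_id, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  if (is.null(registry)) {
    orphans <- det[0, , drop = FALSE]
  } else {
    is_orphan <- !(det$shark_id %in% registry$shark_id)
    orphans <- det[is_orphan, , drop = FALSE]
    det <- det[!is_orphan, , drop = FALSE]
    rownames(det) <- rownames(orphans) <- NULL
  }
  list(detections = det, orphans = orphans, n_duplicates = n_dup)
}

#' Load the multi-method sighting table
#'
#' @param path CSV with columns \code{shark_id,date,method}; method one of
#'   \code{capture}, \code{PIT_scan}, \code{visual}, \code{acoustic}.
#' @param registry optional registry for the tagging-date check: a sighting
#'   dated before its shark's tagging date is an error.
#' @return data.frame sorted by (shark_id, date).
#' @export
load_sightings <- function(path, registry = NULL) {
  df <- read_csv_checked(path, c("shark_id", "date", "method"))
  n <- nrow(df)
  dates <- suppressWarnings(as.Date(df$date))
  if (n > 0L) {
    bad <- which(is.na(dates))
    if (length(bad)) stop_row(bad[1], "unparseable date")
    bad <- which(!df$method %in% SIGHTING_METHODS)
    if (length(bad))
      stop_row(bad[1], sprintf("unknown method '%s'", df$method[bad[1]]))
    if (!is.null(registry)) {
      tagd <- registry$tagging_date[match(df$shark_id, registry$shark_id)]
      bad <- which(!is.na(tagd) & dates < tagd)
      if (length(bad))
        stop_row(bad[1], "sighting predates the shark's tagging date")
    }
  }
  out <- data.frame(shark_id = df$shark_id, date = dates, method = df$method,
                    stringsAsFactors = FALSE)
  out <- out[order(out$shark_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load the on-site water temperature series
#'
#' Temperatures outside the physically plausible 10-40 degC band are kept but
#' flagged (with a warning); non-numeric temperatures are a hard error.
#'
#' @param path CSV with columns \code{timestamp,temp_c}.
#' @return data.frame sorted by timestamp with a logical \code{flagged} column.
#' @export
load_temperature <- function(path) {
  df <- read_csv_checked(path, c("timestamp", "temp_c"))
  n <- nrow(df)
  ts <- parse_instant(df$timestamp)
  tc <- suppressWarnings(as.numeric(df$temp_c))
  if (n > 0L) {
    bad <- which(is.na(ts))
    if (length(bad)) stop_row(bad[1], "unparseable timestamp")
    bad <- which(is.na(tc))
    if (length(bad))
      stop_row(bad[1], sprintf("non-numeric temperature '%s'", df$temp_c[bad[1]]))
  }
  flagged <- tc < 10 | tc > 40
  if (any(flagged))
    warning(sprintf("%d temperature record(s) outside [10, 40] degC flagged",
                    sum(flagged)), call. = FALSE)
  out <- data.frame(timestamp = ts, temp_c = tc, flagged = flagged,
                    stringsAsFactors = FALSE)
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write any pipeline table as CSV
#'
#' Timestamps (POSIXct) are serialized as ISO-8601 local standard time and
#' Dates as \code{YYYY-MM-DD}, so that the matching loader round-trips the
#' table exactly.
#'
#' @param records data.frame of one record type.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) out[[nm]] <- format_instant(out[[nm]])
    else if (inherits(out[[nm]], "Date")) out[[nm]] <- format(out[[nm]], "%Y-%m-%d")
  }
  tryCatch(
    suppressWarnings(utils::write.csv(out, path, row.names = FALSE,
                                      quote = FALSE, na = "")),
    error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  invisible(path)
}
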