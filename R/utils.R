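#' @keywords internal
"_PACKAGE"

# Local standard time for the study site: UTC-5 with no daylight saving.
# Diel summaries are only meaningful in local time, so every timestamp in the
# pipeline is parsed into and written from this zone.
MATESITE_TZ <- "Etc/GMT+5"

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; report percentages use
#' conventional half-up rounding (58.75 -> 59).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Parse timestamps in site-local standard time
#'
#' @param x character vector of ISO-8601 timestamps (\code{YYYY-MM-DD HH:MM:SS}
#'   or with a \code{T} separator; bare dates are taken as midnight).
#' @return POSIXct vector in the site time zone (UTC-5, no DST).
#' @export
parse_instant <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = MATESITE_TZ)
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = MATESITE_TZ))
  }
  out
}

#' Format timestamps for output tables
#' @param x POSIXct vector.
#' @return ISO-8601 character vector (seconds resolution, local standard time).
#' @export
format_instant <- function(x) {
  format(x, format = "%Y-%m-%dT%H:%M:%S", tz = MATESITE_TZ)
}

instant_year <- function(x) as.integer(format(x, "%Y", tz = MATESITE_TZ))
instant_month <- function(x) as.integer(format(x, "%m", tz = MATESITE_TZ))
instant_hour <- function(x) as.integer(format(x, "%H", tz = MATESITE_TZ))
instant_date <- function(x) as.Date(format(x, "%Y-%m-%d", tz = MATESITE_TZ))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_row <- function(row, msg) {
  stop(sprintf("row %d: %s", row, msg), call. = FALSE)
}
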