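#' Clock-time helpers on the minutes-since-noon axis
#'
#' Sleep-centred analysis days run from 12:00 to 11:59 the next calendar day,
#' so all clock arithmetic in this package is done in *minutes since noon*
#' (msn): slot 0 is 12:00, slot 720 is midnight, slot 1439 is 11:59 the next
#' morning. On this axis every ordinary night is a monotone interval and
#' means, SDs, and midpoints need no circular statistics.
#'
#' `clock_to_msn()` converts `"HH:MM"` strings (or `"HH:MM:SS"`) to minutes
#' since noon; times at or after 12:00 map to 0..719, times before 12:00 map
#' to 720..1439 (interpreted as the following morning). `msn_to_clock()`
#' inverts the mapping; fractional minutes are rendered as seconds so that a
#' midpoint falling on a half minute prints as, e.g., `"02:49:30"`.
#'
#' @param x character vector of `"HH:MM"` clock times.
#' @param m numeric vector of minutes since noon (may be fractional).
#' @return `clock_to_msn()`: numeric minutes since noon. `msn_to_clock()`:
#'   character clock times.
#' @examples
#' clock_to_msn("22:44")   # 644
#' clock_to_msn("06:46")   # 1126
#' msn_to_clock(856.5)     # "02:16:30"
#' @export
clock_to_msn <- function(x) {
  parts <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?$", x))
  bad <- vapply(parts, length, 1L) == 0L
  if (any(bad)) {
    stop("unparseable clock time(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  h <- vapply(parts, function(p) as.numeric(p[2]), 1)
  mi <- vapply(parts, function(p) as.numeric(p[3]), 1)
  s <- vapply(parts, function(p) if (is.na(p[4]) || p[4] == "") 0 else as.numeric(p[4]), 1)
  if (any(h > 23) || any(mi > 59)) {
    stop("clock time out of range: ", paste(x[h > 23 | mi > 59], collapse = ", "),
         call. = FALSE)
  }
  m <- h * 60 + mi + s / 60
  ifelse(m >= 720, m - 720, m + 720)
}

#' @rdname clock_to_msn
#' @export
msn_to_clock <- function(m) {
  mm <- (m + 720) %% 1440
  whole <- floor(mm + 1e-9)
  sec <- round((mm - whole) * 60)
  out <- ifelse(sec > 0,
                sprintf("%02d:%02d:%02d", whole %/% 60, whole %% 60, sec),
                sprintf("%02d:%02d", whole %/% 60, whole %% 60))
  out[is.na(m)] <- NA_character_
  out
}

# minutes since noon for POSIXct timestamps (wall clock, minute resolution)
timestamp_msn <- function(ts) {
  h <- as.integer(format(ts, "%H"))
  mi <- as.integer(format(ts, "%M"))
  m <- h * 60L + mi
  ifelse(m >= 720L, m - 720L, m + 720L)
}

# anchor date of the noon-to-noon day containing a timestamp
timestamp_anchor <- function(ts) {
  as.Date(format(ts - 12 * 3600, "%Y-%m-%d"))
}
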