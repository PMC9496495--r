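#' Scoring configuration
#'
#' Tunable parameters of the nightly sleep-window search. Defaults follow the
#' published algorithm: the potential nighttime sleep window runs 19:00 to
#' 11:59 the following day; an evening wake bout of at least 10 minutes
#' before midnight pushes the candidate sleep onset forward; and the window
#' ends at the last sleep minute that is followed by at least 90 consecutive
#' minutes of upright (not lying) time.
#'
#' @param night_start clock time opening the nightly search window.
#' @param night_end clock time closing the window (the following morning).
#' @param wake_reset_minutes minimum length, in minutes, of an evening wake
#'   bout (before midnight) that resets the candidate onset.
#' @param upright_terminate_minutes minimum consecutive upright minutes after
#'   a sleep bout for the bout to be final.
#' @param min_wear_minutes worn minutes required for a valid day.
#' @param min_weekdays,min_weekend_days valid-day counts required for a valid
#'   week.
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(night_start = "19:00", night_end = "11:59",
                           wake_reset_minutes = 10,
                           upright_terminate_minutes = 90,
                           min_wear_minutes = 1361,
                           min_weekdays = 2, min_weekend_days = 1) {
  ns <- clock_to_msn(night_start)
  ne <- clock_to_msn(night_end)
  if (ns >= 720) stop("night_start must precede midnight", call. = FALSE)
  if (ne <= 720) stop("night_end must follow midnight", call. = FALSE)
  stopifnot(wake_reset_minutes >= 1, upright_terminate_minutes >= 1,
            min_wear_minutes >= 0, min_wear_minutes <= 1440)
  structure(list(night_start = night_start, night_end = night_end,
                 night_start_msn = as.integer(ns),
                 night_end_msn = as.integer(ne),
                 wake_reset_minutes = as.integer(wake_reset_minutes),
                 upright_terminate_minutes = as.integer(upright_terminate_minutes),
                 min_wear_minutes = as.integer(min_wear_minutes),
                 min_weekdays = as.integer(min_weekdays),
                 min_weekend_days = as.integer(min_weekend_days)),
            class = "scoring_config")
}

#' Locate the nightly sleep window
#'
#' Implements the sleep-window search on one noon-to-noon day. All positions
#' are minutes since noon (msn): slot 0 = 12:00, slot 720 = midnight. The
#' window is half-open `[onset, offset)`.
#'
#' Steps: (1) the candidate onset is the first minute inside the night window
#' classified as both lying down and asleep; (2) scanning forward, any wake
#' bout of at least `wake_reset_minutes` that starts before midnight moves
#' the candidate onset to the next lying-and-asleep minute; (3) if the
#' subject is awake at midnight the onset becomes the first lying-and-asleep
#' minute after midnight;
#' (4) the window extends over lying-and-asleep bouts and ends one past the
#' last such minute that is followed — before any further lying-and-asleep
#' minute — by at least `upright_terminate_minutes` consecutive not-lying
#' minutes, or at the end of the night window. Sleep registered while not
#' lying down never anchors the window (upright spurious sleep epochs cannot
#' drag the offset into the morning), but any sleep minute between onset and
#' offset counts toward total sleep time.
#'
#' @param day a `device_day`.
#' @param config a [scoring_config()].
#' @return a list `(onset, offset, flags)` of class `sleep_window`, or `NULL`
#'   when the night contains no lying-and-asleep minute.
#' @export
detect_sleep_window <- function(day, config = scoring_config()) {
  ns <- config$night_start_msn
  ne <- config$night_end_msn
  mid <- 720L
  slp <- day$sleeping
  ly <- day$lying
  flags <- character()

  cand <- which(ly == 1L & slp == 1L) - 1L
  cand <- cand[cand >= ns & cand <= ne]
  if (!length(cand)) return(NULL)
  onset <- cand[1]

  # evening resets: wake bouts >= wake_reset_minutes starting before midnight
  scan <- onset
  while (scan < mid) {
    w <- scan
    while (w < mid && slp[w + 1L] == 1L) w <- w + 1L
    if (w >= mid) break
    e <- w
    while (e <= ne && slp[e + 1L] == 0L) e <- e + 1L
    if (e - w >= config$wake_reset_minutes) {
      nxt <- if (e <= ne) {
        which(slp[(e + 1L):(ne + 1L)] == 1L & ly[(e + 1L):(ne + 1L)] == 1L)
      } else {
        integer(0)
      }
      if (!length(nxt)) return(NULL)
      onset <- e + nxt[1] - 1L
      flags <- c(flags, "onset_reset")
      scan <- onset
    } else {
      scan <- e
    }
  }

  # awake at midnight: onset becomes first lying-asleep minute after midnight
  if (onset < mid && slp[mid + 1L] == 0L) {
    nxt <- which(slp[(mid + 1L):(ne + 1L)] == 1L & ly[(mid + 1L):(ne + 1L)] == 1L)
    if (!length(nxt)) return(NULL)
    onset <- mid + nxt[1] - 1L
    flags <- c(flags, "awake_at_midnight")
  }

  # offset: last lying-and-asleep minute followed by >= 90 consecutive
  # upright (not lying) minutes before any further lying-and-asleep minute
  sl <- which(slp == 1L & ly == 1L) - 1L
  sl <- sl[sl >= onset & sl <= ne]
  if (!length(sl)) return(NULL)
  brk <- which(diff(sl) > 1L)
  run_starts <- c(sl[1], sl[brk + 1L])
  run_ends <- c(sl[brk], sl[length(sl)])
  offset <- run_ends[length(run_ends)] + 1L
  for (i in seq_along(run_ends)) {
    if (i == length(run_ends)) break
    gap <- ly[(run_ends[i] + 2L):(run_starts[i + 1L])] == 0L
    r <- rle(gap)
    if (any(r$lengths[r$values] >= config$upright_terminate_minutes)) {
      offset <- run_ends[i] + 1L
      flags <- c(flags, "upright_termination")
      break
    }
  }
  if (offset == ne + 1L) flags <- c(flags, "truncated_at_night_end")

  structure(list(onset = onset, offset = offset, flags = unique(flags)),
            class = "sleep_window")
}

#' Locate the bed window around a sleep window
#'
#' Bedtime is the start of the contiguous lying run scanned backward from
#' sleep onset (bedtime equals onset when the minute before onset is not
#' lying); waketime is one past the end of the contiguous lying run scanned
#' forward from sleep offset. Half-open `[bedtime, waketime)`.
#'
#' @param day a `device_day`.
#' @param window a `sleep_window` from [detect_sleep_window()].
#' @return a list `(bedtime, waketime)` of class `bed_window`.
#' @export
detect_bed_window <- function(day, window) {
  ly <- day$lying
  b <- window$onset
  while (b > 0L && ly[b] == 1L) b <- b - 1L
  w <- window$offset
  while (w <= 1439L && ly[w + 1L] == 1L) w <- w + 1L
  structure(list(bedtime = b, waketime = w), class = "bed_window")
}

#' Wake after sleep onset and sleep fragmentations
#'
#' WASO is the number of minutes classified as awake inside the half-open
#' sleep window; SF is the number of maximal wake runs (every wake bout of at
#' least one minute counts as one fragmentation).
#'
#' @param day a `device_day`.
#' @param window a `sleep_window`.
#' @return a list `(waso, sf)`.
#' @export
count_waso_sf <- function(day, window) {
  idx <- (window$onset + 1L):(window$offset)
  wake <- day$sleeping[idx] == 0L
  r <- rle(wake)
  list(waso = sum(wake), sf = sum(r$values))
}

#' Score one night
#'
#' Composes the window searches into the eleven per-night sleep indices. All
#' clock quantities are reported both as minutes since noon (`*_min`) and as
#' `HH:MM` strings; the midpoint is reported to half-minute precision.
#'
#' @param day a `device_day`.
#' @param config a [scoring_config()].
#' @return a one-row data.frame, or `NULL` when the day is invalid or no
#'   sleep window exists.
#' @export
score_day <- function(day, config = scoring_config()) {
  if (!isTRUE(day$is_valid)) return(NULL)
  win <- detect_sleep_window(day, config)
  if (is.null(win)) return(NULL)
  bed <- detect_bed_window(day, win)
  ws <- count_waso_sf(day, win)
  span <- win$offset - win$onset
  tst <- span - ws$waso
  midpoint <- win$onset + span / 2
  nonwear_tib <- sum(day$wearing[(bed$bedtime + 1L):(bed$waketime)] == 0L)
  flags <- win$flags
  if (nonwear_tib > 0L) flags <- c(flags, "nonwear_in_tib")
  data.frame(subject_id = day$subject_id,
             device_id = day$device_id,
             anchor_date = day$anchor_date,
             is_weekend = day$is_weekend,
             bedtime_min = bed$bedtime,
             sleep_onset_min = win$onset,
             sleep_offset_min = win$offset,
             waketime_min = bed$waketime,
             midpoint_min = midpoint,
             bedtime = msn_to_clock(bed$bedtime),
             sleep_onset = msn_to_clock(win$onset),
             sleep_offset = msn_to_clock(win$offset),
             waketime = msn_to_clock(bed$waketime),
             midpoint = msn_to_clock(midpoint),
             tib_min = bed$waketime - bed$bedtime,
             tst_min = tst,
             se_pct = 100 * tst / span,
             sol_min = win$onset - bed$bedtime,
             waso_min = ws$waso,
             sf_n = ws$sf,
             nonwear_tib_min = nonwear_tib,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Score a list of device days
#'
#' @param days a list of `device_day` objects (see [assign_noon_days()]).
#' @param config a [scoring_config()].
#' @return a nightly data.frame, one row per scored night (invalid days and
#'   nights without a sleep window are dropped).
#' @export
score_days <- function(days, config = scoring_config()) {
  rows <- lapply(days, score_day, config = config)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_nightly())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score an epoch series end to end
#'
#' Slices the series into noon-to-noon days, applies the wear-time validity
#' rule, and scores every valid day.
#'
#' @param series an `epoch_series`.
#' @param config a [scoring_config()].
#' @return a nightly data.frame (see [score_day()]).
#' @export
score_epochs <- function(series, config = scoring_config()) {
  days <- assign_noon_days(series, min_wear = config$min_wear_minutes)
  score_days(days, config)
}

empty_nightly <- function() {
  data.frame(subject_id = character(), device_id = character(),
             anchor_date = as.Date(character()), is_weekend = logical(),
             bedtime_min = numeric(), sleep_onset_min = numeric(),
             sleep_offset_min = numeric(), waketime_min = numeric(),
             midpoint_min = numeric(),
             bedtime = character(), sleep_onset = character(),
             sleep_offset = character(), waketime = character(),
             midpoint = character(),
             tib_min = numeric(), tst_min = numeric(), se_pct = numeric(),
             sol_min = numeric(), waso_min = numeric(), sf_n = numeric(),
             nonwear_tib_min = numeric(), flags = character(),
             stringsAsFactors = FALSE)
}
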