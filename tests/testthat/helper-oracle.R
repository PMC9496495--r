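# Independent brute-force reference scorer: a plain minute-by-minute forward
# scan applying the night-window rules literally. Deliberately written
# without run-length encoding or vectorised shortcuts so it shares no code
# path with the production scorer.

oracle_score_night <- function(day, config = scoring_config()) {
  ns <- config$night_start_msn
  ne <- config$night_end_msn
  slp <- ifelse(day$wearing == 1L, day$sleeping, 0L)
  ly <- ifelse(day$wearing == 1L, day$lying, 0L)

  # candidate onset: first lying & sleeping minute in the night window
  onset <- NA_integer_
  for (t in ns:ne) {
    if (ly[t + 1L] == 1L && slp[t + 1L] == 1L) { onset <- t; break }
  }
  if (is.na(onset)) return(NULL)

  # evening resets: any wake bout >= wake_reset_minutes starting before
  # midnight pushes the onset to the next sleep minute
  t <- onset
  while (t < 720L) {
    if (slp[t + 1L] == 0L) {
      u <- t
      while (u <= ne && slp[u + 1L] == 0L) u <- u + 1L
      if (u - t >= config$wake_reset_minutes) {
        # next lying-and-asleep minute becomes the candidate onset
        while (u <= ne && !(slp[u + 1L] == 1L && ly[u + 1L] == 1L)) u <- u + 1L
        if (u > ne) return(NULL)
        onset <- u
      }
      t <- u
    } else {
      t <- t + 1L
    }
  }

  # awake at midnight: onset becomes the first lying-and-asleep minute
  # after midnight
  if (onset < 720L && slp[721L] == 0L) {
    v <- 720L
    while (v <= ne && !(slp[v + 1L] == 1L && ly[v + 1L] == 1L)) v <- v + 1L
    if (v > ne) return(NULL)
    onset <- v
  }

  # offset: walk forward remembering the last lying-and-asleep minute; once
  # >= 90 consecutive not-lying minutes are seen before any further
  # lying-and-asleep minute, the window is over. Sleep registered while not
  # lying counts as upright time here, not as a window anchor.
  last_anchor <- NA_integer_
  upright_run <- 0L
  terminated <- FALSE
  t <- onset
  while (t <= ne) {
    if (ly[t + 1L] == 1L && slp[t + 1L] == 1L) {
      if (terminated) break
      last_anchor <- t
      upright_run <- 0L
    } else if (ly[t + 1L] == 0L) {
      upright_run <- upright_run + 1L
      if (upright_run >= config$upright_terminate_minutes) terminated <- TRUE
    } else {
      upright_run <- 0L
    }
    t <- t + 1L
  }
  if (is.na(last_anchor)) return(NULL)
  offset <- last_anchor + 1L

  # bedtime: walk backward through contiguous lying minutes before onset
  bedtime <- onset
  while (bedtime > 0L && ly[bedtime] == 1L) bedtime <- bedtime - 1L
  # waketime: walk forward through contiguous lying minutes from offset
  waketime <- offset
  while (waketime <= 1439L && ly[waketime + 1L] == 1L) waketime <- waketime + 1L

  waso <- 0L
  sf <- 0L
  prev_wake <- FALSE
  for (t in onset:(offset - 1L)) {
    if (slp[t + 1L] == 0L) {
      waso <- waso + 1L
      if (!prev_wake) sf <- sf + 1L
      prev_wake <- TRUE
    } else {
      prev_wake <- FALSE
    }
  }
  span <- offset - onset
  list(bedtime_min = bedtime, sleep_onset_min = onset,
       sleep_offset_min = offset, waketime_min = waketime,
       midpoint_min = onset + span / 2,
       tib_min = waketime - bedtime, tst_min = span - waso,
       se_pct = 100 * (span - waso) / span,
       sol_min = onset - bedtime, waso_min = waso, sf_n = sf)
}

# compare production scorer with the oracle on one day; returns TRUE or a
# string describing the first disagreement
agree_with_oracle <- function(day, config = scoring_config()) {
  got <- score_day(day, config)
  want <- oracle_score_night(day, config)
  if (is.null(got) && is.null(want)) return(TRUE)
  if (is.null(got) != is.null(want)) {
    return(sprintf("one side scored no window (production=%s, oracle=%s)",
                   !is.null(got), !is.null(want)))
  }
  for (cc in names(want)) {
    if (abs(got[[cc]] - want[[cc]]) > 1e-9) {
      return(sprintf("%s: production=%s oracle=%s", cc, got[[cc]], want[[cc]]))
    }
  }
  TRUE
}
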