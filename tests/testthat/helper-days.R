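# Builders for device days used across tests. Slots are minutes since noon
# (msn): slot 0 = 12:00, 720 = midnight, 1439 = 11:59 next day.

# build a device_day from msn ranges (inclusive) or full-length vectors
make_day <- function(sleep_ranges = list(), lying_ranges = list(),
                     lying = NULL, sleeping = NULL, wearing = NULL,
                     anchor = as.Date("2023-01-03"), subject = "t",
                     device = "d", valid = TRUE) {
  if (is.null(lying)) {
    lying <- integer(1440)
    for (r in lying_ranges) lying[(r[1]:r[2]) + 1L] <- 1L
  }
  if (is.null(sleeping)) {
    sleeping <- integer(1440)
    for (r in sleep_ranges) sleeping[(r[1]:r[2]) + 1L] <- 1L
  }
  if (is.null(wearing)) wearing <- rep(1L, 1440)
  lying[wearing == 0L] <- 0L
  sleeping[wearing == 0L] <- 0L
  structure(list(subject_id = subject, device_id = device,
                 anchor_date = anchor,
                 lying = as.integer(lying), sleeping = as.integer(sleeping),
                 wearing = as.integer(wearing),
                 n_records = sum(wearing),
                 wear_minutes = sum(wearing),
                 is_valid = valid,
                 is_weekend = format(anchor, "%u") %in% c("6", "7")),
            class = "device_day")
}

# alternating-run binary sequence with geometric bout lengths
random_binary <- function(n, mean_on, mean_off, start = stats::rbinom(1, 1, 0.5)) {
  x <- integer(n)
  state <- as.integer(start)
  i <- 1L
  while (i <= n) {
    len <- 1L + stats::rgeom(1, 1 / (if (state == 1L) mean_on else mean_off))
    len <- min(len, n - i + 1L)
    if (state == 1L) x[i:(i + len - 1L)] <- 1L
    state <- 1L - state
    i <- i + len
  }
  x
}

# random synthetic night mixing realistic and adversarial structures
random_night <- function() {
  style <- sample(3, 1)
  lying <- integer(1440)
  sleeping <- integer(1440)
  if (style == 1) {
    # one lying block containing sleep bouts of mixed lengths
    bt <- sample(430:900, 1)
    wt <- sample((bt + 60):min(bt + 700, 1439), 1)
    lying[(bt:wt) + 1L] <- 1L
    sleeping[(bt:wt) + 1L] <- random_binary(wt - bt + 1L,
                                            mean_on = sample(c(5, 30, 120), 1),
                                            mean_off = sample(c(2, 8, 15), 1))
  } else if (style == 2) {
    # independent random chains over the whole day
    lying <- random_binary(1440, sample(c(10, 60, 300), 1),
                           sample(c(10, 60, 300), 1))
    sleeping <- random_binary(1440, sample(c(3, 20, 90), 1),
                              sample(c(3, 20, 90), 1))
  } else {
    # sparse short bouts, often near the window edges and midnight
    k <- sample(0:6, 1)
    for (b in seq_len(k)) {
      st <- sample(c(420:440, 700:740, 1400:1439, sample(420:1439, 5)), 1)
      en <- min(1439L, st + sample(1:60, 1) - 1L)
      sleeping[(st:en) + 1L] <- 1L
      if (stats::runif(1) < 0.8) {
        lo <- max(0L, st - sample(0:30, 1))
        hi <- min(1439L, en + sample(0:30, 1))
        lying[(lo:hi) + 1L] <- 1L
      }
    }
  }
  wearing <- rep(1L, 1440)
  if (stats::runif(1) < 0.2) {
    st <- sample(0:1380, 1)
    en <- min(1439L, st + sample(1:120, 1))
    wearing[(st:en) + 1L] <- 0L
  }
  make_day(lying = lying, sleeping = sleeping, wearing = wearing)
}

# write an epoch series for one subject-day as a temporary CSV
write_temp_epochs <- function(times, lying, sleeping, wearing = NULL,
                              extra_cols = NULL, path = tempfile(fileext = ".csv")) {
  df <- data.frame(timestamp = times, lying = lying, sleeping = sleeping)
  if (!is.null(wearing)) df$wearing <- wearing
  if (!is.null(extra_cols)) df <- cbind(df, extra_cols)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# minute-resolution timestamp sequence helper
minute_seq <- function(from, n) {
  as.POSIXct(from, tz = "UTC") + 60 * (seq_len(n) - 1)
}

nightly_index_cols <- c("bedtime_min", "sleep_onset_min", "sleep_offset_min",
                        "waketime_min", "midpoint_min", "tib_min", "tst_min",
                        "se_pct", "sol_min", "waso_min", "sf_n")
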