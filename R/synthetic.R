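#' Ground-truth simulation parameters
#'
#' Defaults describe a free-living adult cohort of the size and sleep timing
#' reported in wearable-validation studies: 30 subjects wearing devices for
#' 7 consecutive nights, bedtimes centred on 22:44 (SD 60 min) and waketimes
#' on 06:46 (SD 62 min), a mean sleep onset latency of 14 minutes, about 10
#' wake bouts per night with a mean length of 5 minutes (so roughly 50 min of
#' WASO), and a short daytime nonwear block (showering) of 20 minutes.
#'
#' Wake bouts are only placed after midnight and never touch the first or
#' last minute of the sleep window, so the generated truth bookkeeping and
#' the scorer's window rules describe the same night exactly; see the
#' methods vignette for why this keeps noiseless truth recovery exact.
#'
#' @param n_subjects,n_days cohort size and nights per subject.
#' @param bedtime_mean,bedtime_sd bedtime distribution (clock time, minutes).
#' @param waketime_mean,waketime_sd waketime distribution.
#' @param sol_mean mean sleep onset latency, minutes (geometric).
#' @param wake_latency_mean mean lying-awake time after sleep offset, minutes.
#' @param n_awakenings_mean expected wake bouts per night (Poisson).
#' @param awakening_len_mean mean wake-bout length, minutes (>= 1, shifted
#'   geometric).
#' @param nonwear_minutes daytime nonwear per day, minutes.
#' @param start_date anchor date of the first noon-to-noon day (default a
#'   Monday so a 7-day week holds 5 weekdays and 2 weekend days).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return a `truth_params` list.
#' @export
truth_params <- function(n_subjects = 30, n_days = 7,
                         bedtime_mean = "22:44", bedtime_sd = 60,
                         waketime_mean = "06:46", waketime_sd = 62,
                         sol_mean = 14, wake_latency_mean = 5,
                         n_awakenings_mean = 10, awakening_len_mean = 5,
                         nonwear_minutes = 20,
                         start_date = as.Date("2023-01-02"), seed = NULL) {
  stopifnot(n_subjects >= 1, n_days >= 1, bedtime_sd >= 0, waketime_sd >= 0,
            sol_mean >= 0, wake_latency_mean >= 0, n_awakenings_mean >= 0,
            awakening_len_mean >= 1, nonwear_minutes >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_days = as.integer(n_days),
                 bedtime_mean = bedtime_mean, bedtime_sd = bedtime_sd,
                 waketime_mean = waketime_mean, waketime_sd = waketime_sd,
                 sol_mean = sol_mean, wake_latency_mean = wake_latency_mean,
                 n_awakenings_mean = n_awakenings_mean,
                 awakening_len_mean = awakening_len_mean,
                 nonwear_minutes = nonwear_minutes,
                 start_date = as.Date(start_date),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "truth_params")
}

#' Device observation-error model
#'
#' Independent-Bernoulli epoch misclassification: a true-sleep minute is
#' recorded as sleep with probability `sleep_detect_prob` (the device's
#' target sensitivity) and a true-wake minute as wake with probability
#' `wake_detect_prob` (target specificity). Lying-run boundaries are shifted
#' by an integer jitter drawn uniformly on `-lying_jitter_minutes ..
#' +lying_jitter_minutes` at each run edge.
#'
#' @param sleep_detect_prob,wake_detect_prob detection probabilities in
#'   `[0, 1]`.
#' @param lying_jitter_minutes maximum absolute shift of lying-run edges.
#' @param device_id label stamped on the observed series.
#' @return a `device_model` list.
#' @export
device_model <- function(sleep_detect_prob = 0.94, wake_detect_prob = 0.88,
                         lying_jitter_minutes = 5, device_id = "device") {
  stopifnot(sleep_detect_prob >= 0, sleep_detect_prob <= 1,
            wake_detect_prob >= 0, wake_detect_prob <= 1,
            lying_jitter_minutes >= 0)
  structure(list(sleep_detect_prob = sleep_detect_prob,
                 wake_detect_prob = wake_detect_prob,
                 lying_jitter_minutes = as.integer(lying_jitter_minutes),
                 device_id = as.character(device_id)),
            class = "device_model")
}

#' Simulate ground-truth sleep/wake/lying epoch streams
#'
#' For every subject-night: bedtime and waketime are drawn from truncated
#' normals on the minutes-since-noon axis; lying is 1 on
#' `[bedtime, waketime)`; sleep onset is bedtime plus a geometric sleep onset
#' latency; sleep offset is waketime minus a geometric lying-awake tail; wake
#' bouts (Poisson count, shifted-geometric lengths) are placed uniformly
#' inside the sleep window after midnight. The truth table records the exact
#' indices implied by the generated epochs (WASO and SF are counted from the
#' realised minute vector, so merged overlapping bouts are counted as one).
#'
#' @param params a [truth_params()].
#' @return a list with `epochs` (named list of per-subject `epoch_series`,
#'   device id `"truth"`) and `truth` (a nightly indices data.frame in the
#'   same layout as [score_day()] output).
#' @export
simulate_truth <- function(params = truth_params()) {
  stopifnot(inherits(params, "truth_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  bt_mu <- clock_to_msn(params$bedtime_mean)
  wt_mu <- clock_to_msn(params$waketime_mean)
  nd <- params$n_days
  n_slots <- nd * 1440L
  subjects <- sprintf("S%02d", seq_len(params$n_subjects))
  epochs <- vector("list", length(subjects))
  names(epochs) <- subjects
  truth_rows <- list()

  for (s in seq_along(subjects)) {
    lying <- integer(n_slots)
    sleeping <- integer(n_slots)
    wearing <- rep(1L, n_slots)
    for (j in seq_len(nd)) {
      night <- draw_night(bt_mu, params$bedtime_sd, wt_mu, params$waketime_sd,
                          params$sol_mean, params$wake_latency_mean)
      base <- (j - 1L) * 1440L
      lying[base + (night$bedtime:(night$waketime - 1L)) + 1L] <- 1L
      slp <- integer(1440)
      slp[(night$onset:(night$offset - 1L)) + 1L] <- 1L
      nb <- stats::rpois(1, params$n_awakenings_mean)
      lo <- max(night$onset + 1L, 721L)
      hi <- night$offset - 2L
      if (nb > 0 && hi >= lo) {
        for (b in seq_len(nb)) {
          st <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          len <- 1L + stats::rgeom(1, 1 / params$awakening_len_mean)
          en <- min(st + len - 1L, night$offset - 2L)
          slp[(st:en) + 1L] <- 0L
        }
      }
      sleeping[base + seq_len(1440L)] <- slp
      # daytime nonwear block, placed before any plausible bedtime
      if (params$nonwear_minutes > 0) {
        dur <- min(params$nonwear_minutes, 300L)
        st <- 30L + sample.int(400L - dur - 30L + 1L, 1L) - 1L
        wearing[base + (st:(st + dur - 1L)) + 1L] <- 0L
      }
      wk <- slp[(night$onset:(night$offset - 1L)) + 1L] == 0L
      waso <- sum(wk)
      sf <- sum(rle(wk)$values)
      span <- night$offset - night$onset
      anchor <- params$start_date + (j - 1L)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subject_id = subjects[s], device_id = "truth", anchor_date = anchor,
        is_weekend = format(anchor, "%u") %in% c("6", "7"),
        bedtime_min = night$bedtime, sleep_onset_min = night$onset,
        sleep_offset_min = night$offset, waketime_min = night$waketime,
        midpoint_min = night$onset + span / 2,
        bedtime = msn_to_clock(night$bedtime),
        sleep_onset = msn_to_clock(night$onset),
        sleep_offset = msn_to_clock(night$offset),
        waketime = msn_to_clock(night$waketime),
        midpoint = msn_to_clock(night$onset + span / 2),
        tib_min = night$waketime - night$bedtime,
        tst_min = span - waso, se_pct = 100 * (span - waso) / span,
        sol_min = night$onset - night$bedtime,
        waso_min = waso, sf_n = sf,
        nonwear_tib_min = 0, flags = "", stringsAsFactors = FALSE)
    }
    ts <- as.POSIXct(paste(params$start_date, "12:00:00"), tz = "UTC") +
      60 * (seq_len(n_slots) - 1L)
    epochs[[s]] <- new_epoch_series(subjects[s], "truth", ts,
                                    lying, sleeping, wearing)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(epochs = epochs, truth = truth)
}

# one night's timing draws; errors after 100 infeasible resamples
draw_night <- function(bt_mu, bt_sd, wt_mu, wt_sd, sol_mean, wul_mean) {
  for (try in seq_len(100L)) {
    bt <- round(stats::rnorm(1, bt_mu, bt_sd))
    sol <- stats::rgeom(1, 1 / (1 + sol_mean))
    wul <- stats::rgeom(1, 1 / (1 + wul_mean))
    wt <- round(stats::rnorm(1, wt_mu, wt_sd))
    if (bt < 421 || bt > 719) next
    if (wt < max(bt + sol + wul + 30, 781) || wt > 1349) next
    return(list(bedtime = as.integer(bt), onset = as.integer(bt + sol),
                offset = as.integer(wt - wul), waketime = as.integer(wt)))
  }
  stop("could not draw a feasible night (waketime <= bedtime) in 100 ",
       "attempts; check bedtime/waketime parameter settings", call. = FALSE)
}

#' Overlay device observation error on a truth stream
#'
#' Each true-sleep minute is kept as sleep with probability
#' `sleep_detect_prob`, each true-wake minute kept as wake with probability
#' `wake_detect_prob` (independent Bernoulli draws); lying-run boundaries are
#' jittered by up to `lying_jitter_minutes`. Wearing is carried over from the
#' truth stream and nonworn minutes are masked to 0.
#'
#' @param truth an `epoch_series` from [simulate_truth()].
#' @param model a [device_model()].
#' @return an observed `epoch_series` with the model's `device_id`.
#' @export
apply_device_model <- function(truth, model) {
  stopifnot(inherits(truth, "epoch_series"), inherits(model, "device_model"))
  n <- nrow(truth)
  u <- stats::runif(n)
  sleeping <- ifelse(truth$sleeping == 1L,
                     as.integer(u < model$sleep_detect_prob),
                     as.integer(u < 1 - model$wake_detect_prob))
  lying <- truth$lying
  j <- model$lying_jitter_minutes
  if (j > 0) {
    r <- rle(truth$lying == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lying <- integer(n)
    for (i in which(r$values)) {
      st <- max(1L, starts[i] + sample.int(2L * j + 1L, 1L) - j - 1L)
      en <- min(n, ends[i] + sample.int(2L * j + 1L, 1L) - j - 1L)
      if (st <= en) lying[st:en] <- 1L
    }
  }
  wearing <- truth$wearing
  sleeping[wearing == 0L] <- 0L
  lying[wearing == 0L] <- 0L
  new_epoch_series(truth$subject_id[1], model$device_id, truth$timestamp,
                   lying, sleeping, wearing)
}

#' Simulate a complete two-device validation study
#'
#' Generates the ground-truth cohort and passes every subject's truth stream
#' through two device-error models, yielding everything needed for the full
#' score / summarise / compare pipeline.
#'
#' @param params a [truth_params()] (its `seed` fixes the whole study).
#' @param model_a,model_b [device_model()]s. Device A defaults to a
#'   criterion-grade wrist-actigraphy-like observer, device B to an
#'   armband-like observer.
#' @return a `sim_study` list: `truth` (nightly truth indices),
#'   `epochs_truth`, `epochs_a`, `epochs_b` (named lists of per-subject
#'   `epoch_series`), and `params` (full provenance).
#' @export
simulate_study <- function(params = truth_params(),
                           model_a = device_model(0.97, 0.95, 2, "A"),
                           model_b = device_model(0.94, 0.88, 5, "B")) {
  sim <- simulate_truth(params)
  obs_a <- lapply(sim$epochs, apply_device_model, model = model_a)
  obs_b <- lapply(sim$epochs, apply_device_model, model = model_b)
  structure(list(truth = sim$truth, epochs_truth = sim$epochs,
                 epochs_a = obs_a, epochs_b = obs_b,
                 params = list(truth = unclass(params),
                               model_a = unclass(model_a),
                               model_b = unclass(model_b))),
            class = "sim_study")
}

#' Write a simulated study bundle to disk
#'
#' Writes `deviceA.csv` and `deviceB.csv` in the canonical epoch format,
#' `truth_indices.csv`, and `params.json` with full provenance (including
#' the seed).
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_series_list <- function(lst, path) {
    combined <- do.call(rbind, lapply(lst, function(s) {
      data.frame(subject_id = s$subject_id, device_id = s$device_id,
                 timestamp = format(s$timestamp, "%Y-%m-%dT%H:%M"),
                 lying = s$lying, sleeping = s$sleeping, wearing = s$wearing)
    }))
    utils::write.csv(combined, path, row.names = FALSE, quote = FALSE)
  }
  write_series_list(study$epochs_a, file.path(dir, "deviceA.csv"))
  write_series_list(study$epochs_b, file.path(dir, "deviceB.csv"))
  utils::write.csv(study$truth, file.path(dir, "truth_indices.csv"),
                   row.names = FALSE)
  p <- study$params
  p$truth$start_date <- format(p$truth$start_date)
  jsonlite::write_json(p, file.path(dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Score every subject of a simulated device
#'
#' Convenience wrapper running [score_epochs()] over a named list of
#' per-subject epoch series and binding the nightly rows.
#'
#' @param series_list named list of `epoch_series`.
#' @param config a [scoring_config()].
#' @return a combined nightly data.frame.
#' @export
score_series_list <- function(series_list, config = scoring_config()) {
  out <- do.call(rbind, lapply(series_list, score_epochs, config = config))
  rownames(out) <- NULL
  if (is.null(out)) empty_nightly() else out
}
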