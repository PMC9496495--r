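#' Sleep regularity: standard deviation of waketime
#'
#' Sample standard deviation (n - 1 denominator) of a subject's waketimes,
#' expressed in minutes on the minutes-since-noon axis so that overnight
#' times are monotone and no circular statistics are needed.
#'
#' @param waketimes numeric minutes since noon, or `"HH:MM"` clock strings.
#' @return SD of waketime in minutes.
#' @export
sleep_regularity <- function(waketimes) {
  if (is.character(waketimes)) waketimes <- clock_to_msn(waketimes)
  if (length(waketimes) < 2) {
    stop("sleep regularity needs at least 2 waketimes", call. = FALSE)
  }
  stats::sd(waketimes)
}

# variables summarised weekly: msn clock variables first, then durations/counts
clock_vars <- c("bedtime", "sleep_onset", "sleep_offset", "waketime", "midpoint")
duration_vars <- c("tib", "tst", "se", "sol", "waso", "sf")

#' Per-subject weekly summaries of nightly sleep indices
#'
#' Aggregates a nightly table (one device) into one row per subject: the
#' arithmetic mean and sample SD (n - 1) of every index across that
#' subject's valid nights, plus sleep regularity (SD of waketime). Clock
#' variables are averaged in minutes since noon and reported back as clock
#' times. Subjects failing the week rule (at least `min_weekdays` valid
#' weekday nights and `min_weekend_days` valid weekend nights) are dropped.
#'
#' @param nightly a nightly data.frame from [score_days()] or
#'   [score_epochs()]; may contain several subjects.
#' @param min_weekdays,min_weekend_days week-validity rule.
#' @return a data.frame with one row per qualifying subject: `subject_id`,
#'   `device_id`, `n_valid_days`, `<var>_mean` / `<var>_sd` for each index
#'   (clock variables in minutes since noon, with `<var>_mean_clock`
#'   companions), and `regularity_min`.
#' @export
weekly_summary <- function(nightly, min_weekdays = 2, min_weekend_days = 1) {
  if (nrow(nightly) == 0) return(empty_weekly())
  pieces <- lapply(split(nightly, nightly$subject_id), function(d) {
    if (sum(!d$is_weekend) < min_weekdays || sum(d$is_weekend) < min_weekend_days) {
      return(NULL)
    }
    row <- data.frame(subject_id = d$subject_id[1], device_id = d$device_id[1],
                      n_valid_days = nrow(d), stringsAsFactors = FALSE)
    for (v in clock_vars) {
      x <- d[[paste0(v, "_min")]]
      row[[paste0(v, "_mean")]] <- mean(x)
      row[[paste0(v, "_sd")]] <- stats::sd(x)
      row[[paste0(v, "_mean_clock")]] <- msn_to_clock(mean(x))
    }
    for (v in duration_vars) {
      x <- d[[weekly_source_col(v)]]
      row[[paste0(v, "_mean")]] <- mean(x)
      row[[paste0(v, "_sd")]] <- stats::sd(x)
    }
    row$regularity_min <- sleep_regularity(d$waketime_min)
    row
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) return(empty_weekly())
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

weekly_source_col <- function(v) {
  switch(v, se = "se_pct", sf = "sf_n", paste0(v, "_min"))
}

empty_weekly <- function() {
  out <- data.frame(subject_id = character(), device_id = character(),
                    n_valid_days = integer(), stringsAsFactors = FALSE)
  for (v in clock_vars) {
    out[[paste0(v, "_mean")]] <- numeric()
    out[[paste0(v, "_sd")]] <- numeric()
    out[[paste0(v, "_mean_clock")]] <- character()
  }
  for (v in duration_vars) {
    out[[paste0(v, "_mean")]] <- numeric()
    out[[paste0(v, "_sd")]] <- numeric()
  }
  out$regularity_min <- numeric()
  out
}
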