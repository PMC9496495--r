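#' Read a multi-subject epoch CSV into per-stream series
#'
#' The canonical epoch CSV may hold many subjects (and devices); streams are
#' split by `(subject_id, device_id)` and each is validated as in
#' [read_epoch_csv()].
#'
#' @inheritParams read_epoch_csv
#' @return a named list of `epoch_series` (names `subject/device`).
#' @export
read_epoch_streams <- function(path, column_map = NULL, epoch_seconds = 60,
                               sep = ",") {
  if (!file.exists(path)) stop("epoch file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  cmap <- c(timestamp = "timestamp", lying = "lying", sleeping = "sleeping",
            wearing = "wearing")
  if (!is.null(column_map)) cmap[names(column_map)] <- unname(column_map)
  sid <- if ("subject_id" %in% names(raw)) as.character(raw$subject_id) else "unknown"
  did <- if ("device_id" %in% names(raw)) as.character(raw$device_id) else "unknown"
  key <- paste(sid, did, sep = "/")
  ts <- parse_minute_timestamps(raw[[cmap[["timestamp"]]]], path)
  lying <- check_binary(raw[[cmap[["lying"]]]], cmap[["lying"]], path)
  sleeping <- check_binary(raw[[cmap[["sleeping"]]]], cmap[["sleeping"]], path)
  wearing <- if (cmap[["wearing"]] %in% names(raw)) {
    check_binary(raw[[cmap[["wearing"]]]], cmap[["wearing"]], path)
  } else {
    rep(1L, nrow(raw))
  }
  idx_by_key <- split(seq_len(nrow(raw)), key)
  out <- lapply(idx_by_key, function(idx) {
    new_epoch_series(sid[idx[1]], did[idx[1]], ts[idx],
                     lying[idx], sleeping[idx], wearing[idx],
                     epoch_seconds = epoch_seconds)
  })
  out
}

default_run_config <- function() {
  list(night_start = "19:00", night_end = "11:59",
       wake_reset_minutes = 10, upright_terminate_minutes = 90,
       min_wear_minutes = 1361, min_weekdays = 2, min_weekend_days = 1,
       reference = "a", alpha = 0.05,
       margins = as.list(default_margins()),
       simulate = list(n_subjects = 30, n_days = 7,
                       bedtime_mean = "22:44", bedtime_sd = 60,
                       waketime_mean = "06:46", waketime_sd = 62,
                       sol_mean = 14, wake_latency_mean = 5,
                       n_awakenings_mean = 10, awakening_len_mean = 5,
                       nonwear_minutes = 20, start_date = "2023-01-02",
                       seed = NULL,
                       device_a = list(sleep_detect_prob = 0.97,
                                       wake_detect_prob = 0.95,
                                       lying_jitter_minutes = 2),
                       device_b = list(sleep_detect_prob = 0.94,
                                       wake_detect_prob = 0.88,
                                       lying_jitter_minutes = 5)))
}

#' Load a run configuration
#'
#' Merges, in order of increasing precedence: built-in defaults, an optional
#' YAML or JSON config file, and programmatic overrides (CLI flags). Unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path optional path to a YAML (`.yml`/`.yaml`) or JSON config file.
#' @param overrides named list of overrides (may contain nested `margins` /
#'   `simulate` lists).
#' @return a `run_config` list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yml", "yaml")) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cfg <- merge_config(cfg, user, where = path)
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides, where = "overrides")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, user, where = "config") {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], where = paste0(where, "$", k))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

config_scoring <- function(cfg) {
  scoring_config(night_start = cfg$night_start, night_end = cfg$night_end,
                 wake_reset_minutes = cfg$wake_reset_minutes,
                 upright_terminate_minutes = cfg$upright_terminate_minutes,
                 min_wear_minutes = cfg$min_wear_minutes,
                 min_weekdays = cfg$min_weekdays,
                 min_weekend_days = cfg$min_weekend_days)
}

write_effective_config <- function(cfg, dir) {
  echo <- unclass(cfg)
  echo$package_version <- as.character(utils::packageVersion("actisleep"))
  jsonlite::write_json(echo, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Score an epoch CSV into nightly and weekly tables
#'
#' Reads a (possibly multi-subject) canonical epoch CSV, scores every valid
#' noon-to-noon day, aggregates weekly per-subject summaries, and writes
#' `nightly.csv`, `weekly.csv`, and the effective configuration to
#' `out_dir`.
#'
#' @param epochs_csv input epoch CSV.
#' @param out_dir output directory (created if needed).
#' @param config_file optional YAML/JSON run config.
#' @param overrides named list of config overrides (highest precedence).
#' @return invisibly, a list with `nightly` and `weekly` data.frames.
#' @export
cmd_score <- function(epochs_csv, out_dir, config_file = NULL,
                      overrides = list()) {
  cfg <- load_run_config(config_file, overrides)
  sc <- config_scoring(cfg)
  streams <- read_epoch_streams(epochs_csv)
  nightly <- do.call(rbind, lapply(streams, score_epochs, config = sc))
  if (is.null(nightly)) nightly <- empty_nightly()
  rownames(nightly) <- NULL
  if (nrow(nightly) == 0) {
    warning("no valid scored nights in ", epochs_csv,
            " (wear-time rule: >= ", cfg$min_wear_minutes, " min/day)",
            call. = FALSE)
  }
  weekly <- weekly_summary(nightly, cfg$min_weekdays, cfg$min_weekend_days)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(nightly, file.path(out_dir, "nightly.csv"), row.names = FALSE)
  utils::write.csv(weekly, file.path(out_dir, "weekly.csv"), row.names = FALSE)
  write_effective_config(cfg, out_dir)
  message(sprintf("scored %d night(s) for %d subject(s); %d valid week(s)",
                  nrow(nightly), length(unique(nightly$subject_id)),
                  nrow(weekly)))
  invisible(list(nightly = nightly, weekly = weekly, config = cfg))
}

#' Compare two scored devices
#'
#' Runs the full agreement battery (equivalence TOSTs on weekly summaries,
#' ICCs and repeated-measures Bland-Altman on person-days, and, when both
#' epoch CSVs are given, epoch-level confusion metrics) and writes
#' `equivalence.csv`, `icc.csv`, `ba_summary.csv`, `ba_points.csv`,
#' `confusion_per_subject.csv`, `confusion.json`, and the effective config.
#'
#' @param nightly_a_csv,nightly_b_csv nightly tables written by
#'   [cmd_score()] for devices A and B.
#' @param out_dir output directory.
#' @param epochs_a_csv,epochs_b_csv optional canonical epoch CSVs for the
#'   epoch-level comparison.
#' @param config_file,overrides as in [cmd_score()].
#' @return invisibly, the `agreement_report`.
#' @export
cmd_compare <- function(nightly_a_csv, nightly_b_csv, out_dir,
                        epochs_a_csv = NULL, epochs_b_csv = NULL,
                        config_file = NULL, overrides = list()) {
  cfg <- load_run_config(config_file, overrides)
  sc <- config_scoring(cfg)
  nightly_a <- read_nightly_csv(nightly_a_csv)
  nightly_b <- read_nightly_csv(nightly_b_csv)
  shared <- intersect(nightly_a$subject_id, nightly_b$subject_id)
  if (!length(shared)) {
    stop("no overlapping subjects between the two nightly tables; ",
         "device A has {", paste(unique(nightly_a$subject_id), collapse = ", "),
         "}, device B has {", paste(unique(nightly_b$subject_id), collapse = ", "),
         "}", call. = FALSE)
  }
  paired <- NULL
  if (!is.null(epochs_a_csv) && !is.null(epochs_b_csv)) {
    sa <- read_epoch_streams(epochs_a_csv)
    sb <- read_epoch_streams(epochs_b_csv)
    by_subj <- function(lst) {
      nm <- vapply(lst, function(s) s$subject_id[1], "")
      stats::setNames(lst, nm)
    }
    sa <- by_subj(sa); sb <- by_subj(sb)
    common <- intersect(names(sa), names(sb))
    paired <- do.call(rbind, lapply(common, function(s) {
      align_two_devices(sa[[s]], sb[[s]], min_wear = cfg$min_wear_minutes)
    }))
    class(paired) <- c("paired_epochs", "data.frame")
  }
  margins <- unlist(cfg$margins)
  report <- compare_devices(nightly_a, nightly_b, paired = paired,
                            margins = margins, reference = cfg$reference,
                            alpha = cfg$alpha, config = sc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$equivalence, file.path(out_dir, "equivalence.csv"),
                   row.names = FALSE)
  utils::write.csv(report$icc, file.path(out_dir, "icc.csv"), row.names = FALSE)
  ba_summary <- do.call(rbind, lapply(names(report$bland_altman), function(v) {
    r <- report$bland_altman[[v]]
    data.frame(variable = v, bias = r$bias, sd_total = r$sd_total,
               loa_low = r$loa_low, loa_high = r$loa_high,
               slope = r$slope, slope_ci_low = r$slope_ci[1],
               slope_ci_high = r$slope_ci[2], slope_p = r$slope_p,
               n_subjects = r$n_subjects, n_pairs = r$n_pairs,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(ba_summary, file.path(out_dir, "ba_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ba_points, file.path(out_dir, "ba_points.csv"),
                   row.names = FALSE)
  if (!is.null(report$confusion)) {
    cm <- report$confusion
    utils::write.csv(cm$per_subject,
                     file.path(out_dir, "confusion_per_subject.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(reference = cm$reference,
           pooled = cm[c("tp", "fn", "tn", "fp", "sensitivity", "specificity",
                         "accuracy", "lr_pos", "lr_neg")],
           subject_mean = lapply(cm$subject_mean, as.list)),
      file.path(out_dir, "confusion.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  write_effective_config(cfg, out_dir)
  message(sprintf("agreement report over %d subject(s) written to %s",
                  length(report$subjects), out_dir))
  invisible(report)
}

read_nightly_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "anchor_date", "is_weekend", "waketime_min")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("nightly table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d$anchor_date <- as.Date(d$anchor_date)
  d
}

#' Simulate a two-device study bundle to disk
#'
#' Draws a seed if none is configured (and records it in `params.json`),
#' simulates the study, and writes the bundle via [write_study()].
#'
#' @param out_dir output directory.
#' @param config_file,overrides as in [cmd_score()] (simulator settings live
#'   under the `simulate` key).
#' @return invisibly, the `sim_study`.
#' @export
cmd_simulate <- function(out_dir, config_file = NULL, overrides = list()) {
  cfg <- load_run_config(config_file, overrides)
  s <- cfg$simulate
  if (is.null(s$seed)) {
    s$seed <- sample.int(.Machine$integer.max, 1)
    message("no seed configured; drew seed ", s$seed)
  }
  params <- truth_params(n_subjects = s$n_subjects, n_days = s$n_days,
                         bedtime_mean = s$bedtime_mean,
                         bedtime_sd = s$bedtime_sd,
                         waketime_mean = s$waketime_mean,
                         waketime_sd = s$waketime_sd,
                         sol_mean = s$sol_mean,
                         wake_latency_mean = s$wake_latency_mean,
                         n_awakenings_mean = s$n_awakenings_mean,
                         awakening_len_mean = s$awakening_len_mean,
                         nonwear_minutes = s$nonwear_minutes,
                         start_date = as.Date(s$start_date), seed = s$seed)
  ma <- device_model(s$device_a$sleep_detect_prob, s$device_a$wake_detect_prob,
                     s$device_a$lying_jitter_minutes, "A")
  mb <- device_model(s$device_b$sleep_detect_prob, s$device_b$wake_detect_prob,
                     s$device_b$lying_jitter_minutes, "B")
  study <- simulate_study(params, ma, mb)
  write_study(study, out_dir)
  cfg$simulate$seed <- s$seed
  write_effective_config(cfg, out_dir)
  message(sprintf("simulated %d subject(s) x %d day(s) into %s",
                  params$n_subjects, params$n_days, out_dir))
  invisible(study)
}
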