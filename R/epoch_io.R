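#' Read a minute-level epoch CSV into an epoch series
#'
#' An epoch series is the canonical per-subject-per-device container: one row
#' per worn minute with a binary lying-down indicator and a binary sleep
#' indicator, plus an optional wear indicator. Gaps between timestamps are
#' *not* filled in: a missing minute is treated as nonwear when the series is
#' sliced into noon-to-noon days.
#'
#' @param path path to a delimited text file with a header row.
#' @param subject_id,device_id labels attached to every record; when `NULL`,
#'   taken from `subject_id` / `device_id` columns if present, otherwise
#'   `"unknown"`.
#' @param column_map named character vector remapping the required logical
#'   columns to the file's column names. Names used: `timestamp`, `lying`,
#'   `sleeping`, and optionally `wearing`. Defaults to identity.
#' @param epoch_seconds epoch length in seconds; only 60-second epochs have
#'   been exercised but any length that divides the scoring thresholds evenly
#'   is accepted.
#' @param sep field separator passed to [utils::read.csv()].
#' @return a `data.frame` of class `epoch_series` with columns `subject_id`,
#'   `device_id`, `timestamp` (POSIXct, wall clock stored as UTC), `lying`,
#'   `sleeping`, `wearing` (all integer 0/1), sorted by time, and an
#'   `epoch_seconds` attribute.
#' @details Records with `sleeping = 1` while `wearing = 0` are not
#'   interpretable (the device was not on the body) and raise a warning;
#'   downstream scoring masks both indicators to 0 on nonworn minutes.
#'   Duplicate timestamps are an error naming the offending minute.
#' @export
read_epoch_csv <- function(path, subject_id = NULL, device_id = NULL,
                           column_map = NULL, epoch_seconds = 60, sep = ",") {
  if (!file.exists(path)) stop("epoch file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  cmap <- c(timestamp = "timestamp", lying = "lying", sleeping = "sleeping",
            wearing = "wearing")
  if (!is.null(column_map)) cmap[names(column_map)] <- unname(column_map)
  for (key in c("timestamp", "lying", "sleeping")) {
    if (!cmap[[key]] %in% names(raw)) {
      stop("column '", cmap[[key]], "' (", key, ") not found in ", path,
           call. = FALSE)
    }
  }
  ts <- parse_minute_timestamps(raw[[cmap[["timestamp"]]]], path)
  lying <- check_binary(raw[[cmap[["lying"]]]], cmap[["lying"]], path)
  sleeping <- check_binary(raw[[cmap[["sleeping"]]]], cmap[["sleeping"]], path)
  wearing <- if (cmap[["wearing"]] %in% names(raw)) {
    check_binary(raw[[cmap[["wearing"]]]], cmap[["wearing"]], path)
  } else {
    rep(1L, nrow(raw))
  }
  sid <- subject_id %||%
    (if ("subject_id" %in% names(raw)) as.character(raw$subject_id[1]) else "unknown")
  did <- device_id %||%
    (if ("device_id" %in% names(raw)) as.character(raw$device_id[1]) else "unknown")
  new_epoch_series(sid, did, ts, lying, sleeping, wearing,
                   epoch_seconds = epoch_seconds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_minute_timestamps <- function(x, path) {
  x <- as.character(x)
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
               "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%m/%d/%Y %H:%M")
  ts <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in formats) {
    todo <- which(is.na(ts))
    if (!length(todo)) break
    ts[todo] <- as.POSIXct(x[todo], tz = "UTC", format = f)
  }
  bad <- which(is.na(ts) & !is.na(x))
  if (length(bad)) {
    stop("unparseable timestamp in ", path, " at row ", bad[1], ": '",
         x[bad[1]], "'", call. = FALSE)
  }
  trunc(ts, units = "mins")
}

check_binary <- function(x, col, path) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) | !(v %in% c(0L, 1L)))
  if (length(bad)) {
    stop("non-binary value in column '", col, "' of ", path, " at row ",
         bad[1], ": '", x[bad[1]], "'", call. = FALSE)
  }
  v
}

#' Construct an epoch series from vectors
#'
#' Low-level constructor used by [read_epoch_csv()] and the study simulator.
#' Sorts by timestamp, rejects duplicates, and flags sleep recorded on
#' nonworn minutes.
#'
#' @param subject_id,device_id scalar labels.
#' @param timestamp POSIXct vector at minute resolution.
#' @param lying,sleeping,wearing integer 0/1 vectors.
#' @param epoch_seconds epoch length in seconds.
#' @return an `epoch_series` data.frame.
#' @export
new_epoch_series <- function(subject_id, device_id, timestamp, lying, sleeping,
                             wearing = rep(1L, length(timestamp)),
                             epoch_seconds = 60) {
  stopifnot(length(lying) == length(timestamp),
            length(sleeping) == length(timestamp),
            length(wearing) == length(timestamp))
  ord <- order(timestamp)
  df <- data.frame(subject_id = as.character(subject_id),
                   device_id = as.character(device_id),
                   timestamp = timestamp[ord],
                   lying = as.integer(lying)[ord],
                   sleeping = as.integer(sleeping)[ord],
                   wearing = as.integer(wearing)[ord],
                   stringsAsFactors = FALSE)
  dup <- duplicated(df$timestamp)
  if (any(dup)) {
    stop("duplicate timestamp in stream ", df$subject_id[1], "/",
         df$device_id[1], ": ", format(df$timestamp[dup][1], "%Y-%m-%d %H:%M"),
         call. = FALSE)
  }
  ghost <- df$sleeping == 1L & df$wearing == 0L
  if (any(ghost)) {
    warning(sum(ghost), " record(s) with sleeping=1 while wearing=0 in ",
            df$subject_id[1], "/", df$device_id[1],
            "; treated as nonwear downstream", call. = FALSE)
  }
  attr(df, "epoch_seconds") <- as.integer(epoch_seconds)
  class(df) <- c("epoch_series", "data.frame")
  df
}

#' Write an epoch series to the canonical epoch CSV
#'
#' Columns: `subject_id`, `device_id`, `timestamp` (ISO-8601 at minute
#' precision), `lying`, `sleeping`, `wearing`. Re-reading the file with
#' [read_epoch_csv()] reproduces the series exactly.
#'
#' @param series an `epoch_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  out <- data.frame(subject_id = series$subject_id,
                    device_id = series$device_id,
                    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M"),
                    lying = series$lying,
                    sleeping = series$sleeping,
                    wearing = series$wearing)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Slice an epoch series into noon-to-noon device days
#'
#' Analysis days run 12:00 to 11:59 the next calendar day so that a night's
#' sleep is never split across days. Slot `k` of a day is `k` minutes after
#' the anchor noon (slot 0 = 12:00, slot 1439 = 11:59). Minutes absent from
#' the series, and minutes with `wearing = 0`, count as nonwear; nonworn
#' slots have lying and sleeping masked to 0.
#'
#' A day is weekend iff its anchor date (the noon start) is a Saturday or a
#' Sunday: the night the day mostly covers begins on the anchor date.
#'
#' @param series an `epoch_series` (60-second epochs).
#' @param min_wear minimum worn minutes for a valid day (default 1361,
#'   i.e. 95% of 1440).
#' @return a list of `device_day` objects, each a list with fields
#'   `subject_id`, `device_id`, `anchor_date`, `lying`, `sleeping`, `wearing`
#'   (integer vectors of length 1440), `wear_minutes`, `is_valid`,
#'   `is_weekend`.
#' @export
assign_noon_days <- function(series, min_wear = 1361) {
  stopifnot(inherits(series, "epoch_series"))
  if (nrow(series) == 0L) stop("empty epoch series", call. = FALSE)
  es <- attr(series, "epoch_seconds") %||% 60L
  if (es != 60L) {
    if ((60L %% es) != 0L && (es %% 60L) != 0L) {
      stop("epoch length ", es, "s does not divide the 1-minute day grid",
           call. = FALSE)
    }
  }
  anchor <- timestamp_anchor(series$timestamp)
  slot <- timestamp_msn(series$timestamp)
  days <- lapply(split(seq_len(nrow(series)), anchor), function(idx) {
    a <- anchor[idx[1]]
    lying <- integer(1440)
    sleeping <- integer(1440)
    wearing <- integer(1440)
    k <- slot[idx] + 1L
    lying[k] <- series$lying[idx]
    sleeping[k] <- series$sleeping[idx]
    wearing[k] <- series$wearing[idx]
    lying[wearing == 0L] <- 0L
    sleeping[wearing == 0L] <- 0L
    wm <- sum(wearing)
    structure(list(subject_id = series$subject_id[idx[1]],
                   device_id = series$device_id[idx[1]],
                   anchor_date = a,
                   lying = lying, sleeping = sleeping, wearing = wearing,
                   n_records = length(idx),
                   wear_minutes = wm,
                   is_valid = wm >= min_wear,
                   is_weekend = format(a, "%u") %in% c("6", "7")),
              class = "device_day")
  })
  names(days) <- NULL
  days
}

#' @export
print.device_day <- function(x, ...) {
  cat(sprintf("<device_day> %s/%s %s (%s): %d worn min, %s%s\n",
              x$subject_id, x$device_id, format(x$anchor_date),
              if (x$is_weekend) "weekend" else "weekday",
              x$wear_minutes,
              if (x$is_valid) "valid" else "invalid",
              if (sum(x$sleeping) > 0) sprintf(", %d sleep min", sum(x$sleeping)) else ""))
  invisible(x)
}

#' Day- and week-level validity rules
#'
#' A day is valid when it has at least `min_wear` worn minutes (default 1361,
#' the 95% wear-time rule for a 1440-minute day). A subject's week is valid
#' when it contains at least `min_weekdays` valid weekday days and at least
#' `min_weekend` valid weekend days.
#'
#' @param day a `device_day`.
#' @param days a list of `device_day` objects from one subject.
#' @param min_wear minimum worn minutes per valid day.
#' @param min_weekdays,min_weekend minimum counts of valid weekday / weekend
#'   days for a valid week.
#' @return `validate_day()` and `validate_week()` return a logical scalar;
#'   `validate_days()` returns the day list with `is_valid` recomputed.
#' @export
validate_day <- function(day, min_wear = 1361) {
  stopifnot(inherits(day, "device_day"))
  day$wear_minutes >= min_wear
}

#' @rdname validate_day
#' @export
validate_days <- function(days, min_wear = 1361) {
  lapply(days, function(d) {
    d$is_valid <- validate_day(d, min_wear)
    d
  })
}

#' @rdname validate_day
#' @export
validate_week <- function(days, min_weekdays = 2, min_weekend = 1) {
  subj <- unique(vapply(days, function(d) d$subject_id, ""))
  if (length(subj) > 1) {
    stop("validate_week() expects days from a single subject, got: ",
         paste(subj, collapse = ", "), call. = FALSE)
  }
  valid <- vapply(days, function(d) isTRUE(d$is_valid), TRUE)
  weekend <- vapply(days, function(d) isTRUE(d$is_weekend), TRUE)
  sum(valid & !weekend) >= min_weekdays && sum(valid & weekend) >= min_weekend
}

#' Align two devices' epoch streams on shared valid days
#'
#' Restricts both streams to minutes that are present and worn in *both*
#' devices, and further to noon-to-noon days that pass the wear-time validity
#' rule on both devices, so that epoch-level comparisons only ever see days
#' both devices measured adequately.
#'
#' @param a,b `epoch_series` for the same subject (devices A and B).
#' @param min_wear per-day validity threshold in worn minutes.
#' @return a `paired_epochs` data.frame with columns `subject_id`,
#'   `timestamp`, `lying_a`, `lying_b`, `sleeping_a`, `sleeping_b`.
#' @export
align_two_devices <- function(a, b, min_wear = 1361) {
  stopifnot(inherits(a, "epoch_series"), inherits(b, "epoch_series"))
  esa <- attr(a, "epoch_seconds") %||% 60L
  esb <- attr(b, "epoch_seconds") %||% 60L
  if (esa != esb) {
    stop("devices use different epoch lengths (", esa, "s vs ", esb,
         "s); resample before aligning", call. = FALSE)
  }
  valid_anchors <- function(s) {
    d <- assign_noon_days(s, min_wear = min_wear)
    va <- vapply(d, function(x) x$is_valid, TRUE)
    as.character(vapply(d, function(x) format(x$anchor_date), "")[va])
  }
  shared_days <- intersect(valid_anchors(a), valid_anchors(b))
  ka <- format(a$timestamp, "%Y-%m-%dT%H:%M")
  kb <- format(b$timestamp, "%Y-%m-%dT%H:%M")
  ia <- match(intersect(ka, kb), ka)
  ib <- match(ka[ia], kb)
  keep <- a$wearing[ia] == 1L & b$wearing[ib] == 1L &
    format(timestamp_anchor(a$timestamp[ia])) %in% shared_days
  out <- data.frame(subject_id = a$subject_id[ia][keep],
                    timestamp = a$timestamp[ia][keep],
                    lying_a = a$lying[ia][keep],
                    lying_b = b$lying[ib][keep],
                    sleeping_a = a$sleeping[ia][keep],
                    sleeping_b = b$sleeping[ib][keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("paired_epochs", "data.frame")
  out
}
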