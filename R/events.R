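#' Construct or read an event log
#'
#' Events are falls (any person coming to rest on the ground) and
#' transfers to intensive care; `subtype` carries the faller type
#' (`patient`/`family`/`staff`) or the transfer cause.
#'
#' @param kind character, each `"fall"` or `"icu_transfer"`.
#' @param time `POSIXct` event times (UTC).
#' @param subtype character annotations (optional).
#' @return data.frame of class `event_log`, sorted by time.
#' @export
event_log <- function(kind, time, subtype = NA_character_) {
  kind <- as.character(kind)
  bad <- !kind %in% c("fall", "icu_transfer")
  if (any(bad)) stop("unknown event kind(s): ",
                     paste(unique(kind[bad]), collapse = ", "))
  if (!inherits(time, "POSIXct")) stop("'time' must be POSIXct")
  attr(time, "tzone") <- "UTC"
  df <- data.frame(kind = kind, time = time,
                   subtype = rep_len(as.character(subtype), length(kind)),
                   stringsAsFactors = FALSE)
  df <- df[order(as.numeric(df$time)), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("event_log", "data.frame"))
}

#' @rdname event_log
#' @param path CSV with header `kind,timestamp,subtype`.
#' @param tz input time zone.
#' @export
read_events <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, colClasses = "character")
  event_log(df$kind, parse_iso_time(df$timestamp, tz = tz),
            subtype = if ("subtype" %in% names(df)) df$subtype else NA)
}

#' @rdname event_log
#' @param events an `event_log`.
#' @export
write_events <- function(events, path) {
  out <- data.frame(kind = events$kind,
                    timestamp = format_iso_time(events$time),
                    subtype = events$subtype)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Shift schedule with patient-to-nurse ratios
#'
#' Staffing is a per-minute covariate: each calendar minute belongs to the
#' shift in force, whose patient-to-nurse ratio (patients per nurse) is
#' attached to the minute table. The default mirrors a common acute-care
#' pattern: day 07:00-15:00 at 7:1, evening 15:00-23:00 at 9:1, night
#' 23:00-07:00 at 10:1.
#'
#' @param shifts data.frame with columns `name`, `start`, `end` (clock
#'   times `"HH:MM"`) and `ratio` (> 0). Shifts must partition the 24 h
#'   day; a shift may wrap past midnight.
#' @return data.frame of class `shift_schedule`.
#' @export
shift_schedule <- function(shifts) {
  stopifnot(all(c("name", "start", "end", "ratio") %in% names(shifts)))
  hm <- function(s) {
    p <- strsplit(s, ":", fixed = TRUE)
    vapply(p, function(q) as.numeric(q[1]) * 60 + as.numeric(q[2]), 0)
  }
  sh <- data.frame(name = as.character(shifts$name),
                   start_min = hm(shifts$start), end_min = hm(shifts$end),
                   ratio = as.numeric(shifts$ratio))
  if (any(sh$ratio <= 0)) stop("patient-to-nurse ratios must be > 0")
  len <- ifelse(sh$end_min > sh$start_min, sh$end_min - sh$start_min,
                1440 - sh$start_min + sh$end_min)
  if (sum(len) != 1440)
    stop("shifts must partition the 24 h day (got ", sum(len), " minutes)")
  structure(sh, class = c("shift_schedule", "data.frame"))
}

#' @rdname shift_schedule
#' @export
default_shift_schedule <- function() {
  shift_schedule(data.frame(
    name = c("day", "evening", "night"),
    start = c("07:00", "15:00", "23:00"),
    end = c("15:00", "23:00", "07:00"),
    ratio = c(7, 9, 10)))
}

#' @rdname shift_schedule
#' @param path CSV with columns `name,start,end,ratio`.
#' @export
read_shift_schedule <- function(path) {
  shift_schedule(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Patient-to-nurse ratio in force at given times
#'
#' @param time `POSIXct` vector.
#' @param schedule a [shift_schedule()].
#' @return numeric vector of ratios.
#' @export
ratio_at <- function(time, schedule = default_shift_schedule()) {
  mins <- as.POSIXlt(time, tz = "UTC")
  mod <- mins$hour * 60 + mins$min
  out <- rep(NA_real_, length(mod))
  for (k in seq_len(nrow(schedule))) {
    s <- schedule$start_min[k]; e <- schedule$end_min[k]
    hit <- if (e > s) mod >= s & mod < e else mod >= s | mod < e
    out[hit] <- schedule$ratio[k]
  }
  out
}
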