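#' Remove isolated positional jumps from a stream
#'
#' RTLS streams occasionally contain spurious displacements: a single
#' emission that lands far from the trajectory and immediately returns. A
#' record is flagged as noise iff its planar distance to *both* its
#' preceding and its following emission (within the same tag) exceeds
#' `jump_threshold` — the "isolated outlier" reading. A point far from only
#' one neighbour is a legitimate move; two consecutive displaced points are
#' a sustained excursion and are never flagged. The first and last record of
#' a tag have only one neighbour and are never flagged.
#'
#' @param stream a [position_stream], sorted per tag (the constructor
#'   guarantees this).
#' @param jump_threshold isolation distance in meters (default 2.5).
#' @return A list with `stream` (the filtered [position_stream]),
#'   `flagged` (integer row indices of `stream` input that were removed) and
#'   `report`, a list with `total_points`, `noise_points`, `noise_rate` and
#'   `odds_denominator` as produced by [compute_noise_rate()].
#' @seealso [compute_noise_rate()]
#' @export
filter_noise <- function(stream, jump_threshold = 2.5) {
  stopifnot(inherits(stream, "position_stream"), jump_threshold > 0)
  n <- nrow(stream)
  flag <- logical(n)
  if (n) {
    tag <- stream$tag_id
    x <- stream$x
    y <- stream$y
    same_prev <- c(FALSE, tag[-1] == tag[-n])
    same_next <- c(tag[-n] == tag[-1], FALSE)
    d_prev <- c(NA_real_, sqrt(diff(x)^2 + diff(y)^2))
    d_next <- c(d_prev[-1], NA_real_)
    flag <- same_prev & same_next &
      !is.na(d_prev) & d_prev > jump_threshold &
      !is.na(d_next) & d_next > jump_threshold
    short <- names(which(table(tag) < 3L))
    if (length(short))
      warning("tag(s) with < 3 records, no noise flagging possible: ",
              paste(short, collapse = ", "))
  }
  kept <- stream[!flag, , drop = FALSE]
  class(kept) <- class(stream)
  attr(kept, "n_duplicates") <- 0L
  rownames(kept) <- NULL
  rate <- compute_noise_rate(n, sum(flag))
  list(stream = kept, flagged = which(flag),
       report = c(list(total_points = n, noise_points = sum(flag)), rate))
}

#' Noise rate and its "1 in k" denominator
#'
#' @param total_points number of recorded location points.
#' @param noise_points number of points classified as noise.
#' @return list with `noise_rate` (fraction), `percent` and
#'   `odds_denominator` (rounded `total/noise`; `NA` when no noise).
#' @examples
#' compute_noise_rate(47230357, 106564)  # ~0.226%, 1 in 443
#' @export
compute_noise_rate <- function(total_points, noise_points) {
  stopifnot(total_points > 0, noise_points >= 0,
            noise_points <= total_points)
  rate <- noise_points / total_points
  list(noise_rate = rate,
       percent = 100 * rate,
       odds_denominator = if (noise_points > 0)
         round(total_points / noise_points) else NA_integer_)
}

#' Hourly missing-data rate of an emission stream
#'
#' Tags emit at 1 Hz while moving and once per minute while stationary, so
#' the expected number of emissions depends on the motion regime. Each
#' inter-emission gap is classified as stationary when its duration lies in
#' `stationary_gap` seconds (the once-per-minute beacon cadence, with
#' tolerance) or the positional displacement across it is below
#' `stationary_disp` meters; expected emissions over a gap of `g` seconds
#' are then `g/60` (stationary) or `g` (motion, 1 Hz). Gaps are attributed
#' to the clock hour of their ending emission; the per-hour missing rate is
#' `1 - observed/expected`, clipped to `[0, 1]`. This excludes the
#' stationary beacon-rate reduction from the 1 Hz expectation, so a
#' complete once-per-minute stream scores 0.
#'
#' @param stream a [position_stream] spanning at least one hour.
#' @param stationary_gap two-sided gap-duration window (seconds) treated as
#'   the stationary beacon cadence.
#' @param stationary_disp displacement (meters) below which a gap is
#'   treated as stationary regardless of duration.
#' @return list with `hourly` (data.frame: `tag_id`, `hour` start time,
#'   `expected`, `observed`, `rate`), `mean`, `ci95` (normal approximation)
#'   and `n_hours`.
#' @export
missing_rate_per_hour <- function(stream, stationary_gap = c(45, 75),
                                  stationary_disp = 0.5) {
  stopifnot(inherits(stream, "position_stream"))
  tsec <- as.numeric(stream$time)
  if (nrow(stream) < 2 || diff(range(tsec)) < 3600)
    stop("stream must span at least one hour")
  per_tag <- split(seq_len(nrow(stream)), stream$tag_id)
  rows <- lapply(per_tag, function(idx) {
    if (length(idx) < 2) return(NULL)
    t <- tsec[idx]
    g <- diff(t)
    disp <- sqrt(diff(stream$x[idx])^2 + diff(stream$y[idx])^2)
    stationary <- (g >= stationary_gap[1] & g <= stationary_gap[2]) |
      disp < stationary_disp
    expected <- ifelse(stationary, g / 60, g)
    hour <- floor(t[-1] / 3600)
    data.frame(tag_id = stream$tag_id[idx[1]], hour = hour,
               expected = expected, observed = 1)
  })
  gaps <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(expected, observed) ~ tag_id + hour,
                          data = gaps, FUN = sum)
  agg$rate <- pmin(1, pmax(0, 1 - agg$observed / agg$expected))
  agg <- agg[agg$expected > 0, , drop = FALSE]
  agg$hour <- as.POSIXct(agg$hour * 3600, origin = "1970-01-01", tz = "UTC")
  m <- mean(agg$rate)
  se <- stats::sd(agg$rate) / sqrt(nrow(agg))
  list(hourly = agg, mean = m,
       ci95 = m + c(-1, 1) * stats::qnorm(0.975) * ifelse(is.na(se), 0, se),
       n_hours = nrow(agg))
}

#' Assemble and serialize a stream quality report
#'
#' Combines the noise-filter report and the hourly missing-rate fragment
#' into one structure; [write_quality_report()] serializes it as JSON.
#'
#' @param noise `report` element of [filter_noise()].
#' @param missing result of [missing_rate_per_hour()] (optional).
#' @return list of class `quality_report`.
#' @export
quality_report <- function(noise, missing = NULL) {
  out <- list(total_points = noise$total_points,
              noise_points = noise$noise_points,
              noise_rate = noise$noise_rate,
              odds_denominator = noise$odds_denominator)
  if (!is.null(missing)) {
    out$missing_rate_mean <- missing$mean
    out$missing_rate_ci95 <- missing$ci95
    out$missing_rate_hours <- missing$n_hours
  }
  structure(out, class = "quality_report")
}

#' @rdname quality_report
#' @param report a `quality_report`.
#' @param path output JSON path.
#' @export
write_quality_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  points: %d, noise: %d (%.3f%%%s)\n", x$total_points,
              x$noise_points, 100 * x$noise_rate,
              if (!is.na(x$odds_denominator))
                sprintf(", 1 in %d", x$odds_denominator) else ""))
  if (!is.null(x$missing_rate_mean))
    cat(sprintf("  missing rate/h: %.3f (95%% CI %.3f to %.3f, %d tag-hours)\n",
                x$missing_rate_mean, x$missing_rate_ci95[1],
                x$missing_rate_ci95[2], x$missing_rate_hours))
  invisible(x)
}
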