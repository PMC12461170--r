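#' Configuration of the synthetic ward simulator
#'
#' Describes a rectangular acute-care unit with beds along two walls and a
#' fleet of mobile workstations moving bed-to-bed as a semi-Markov process:
#' each workstation dwells at a bed (stationary, beaconing once per
#' minute), then transits in a straight line at a sampled speed to another
#' bed (emitting at 1 Hz while in motion). Corruption (isolated positional
#' jumps, missing emissions) and minute-level event processes (falls, ICU
#' transfers) with known log-odds coefficients on the shadow percentage are
#' layered on top, so every pipeline stage can be scored against recorded
#' truth.
#'
#' Defaults mirror a 400 m² 40-bed unit observed for 210 days with 4
#' workstations moving at 0.5--1 m/s, a 0.226% isolated-jump rate with
#' jumps of 4--8 m, 37.6% missingness in the 1 Hz motion regime, about 8
#' falls and 89 ICU transfers per 210 days, a fall log-odds slope of
#' `ln(1.02)` per percentage point of shadow and an ICU slope of
#' `ln(0.99)`. Dwell times are lognormal with median 20 minutes — carts
#' are parked most of the time and make occasional rounds.
#'
#' @param seed integer seed; all outputs are bit-reproducible given the
#'   seed, and each phase (trajectories, corruption, events, clustering)
#'   uses its own derived substream so toggling one does not shift the
#'   others.
#' @param width,height unit dimensions in meters.
#' @param n_beds number of beds (laid out along the two long walls unless
#'   `beds` is given).
#' @param beds optional two-column matrix of bed coordinates.
#' @param n_workstations number of mobile workstations.
#' @param speed_range transit speed range in m/s.
#' @param dwell_meanlog,dwell_sdlog lognormal dwell-time parameters
#'   (seconds).
#' @param days simulated days.
#' @param start simulation start (`POSIXct` or ISO string, UTC).
#' @param noise_prob per-emission probability of an isolated jump.
#' @param noise_jump jump-magnitude range in meters (must clear the 2.5 m
#'   isolation rule after accounting for 1 s steps of up to 1 m).
#' @param missing_prob deletion probability for motion-regime (1 Hz)
#'   emissions.
#' @param d_cells,T_minutes shadow parameters used for the internal truth
#'   series.
#' @param beta_shadow_fall,beta_shadow_icu true per-percentage-point
#'   log-odds slopes of the event processes.
#' @param target_falls,target_icu expected event counts over the simulated
#'   span (defaults scale 8 falls and 89 transfers per 210 days); the
#'   baseline intercepts are calibrated so the expected counts match.
#' @param icu_clustering logical: inject pre-transfer bedside presence (a
#'   response cart at the event bed) so ICU transfers are preceded by
#'   lowered shadow, the mechanism behind an inverse ICU association.
#' @param clustering_minutes length of the injected bedside window.
#' @param max_staleness per-minute carry-forward limit (minutes).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, width = 20, height = 20, n_beds = 40,
                       beds = NULL, n_workstations = 4,
                       speed_range = c(0.5, 1.0),
                       dwell_meanlog = log(20 * 60), dwell_sdlog = 0.6,
                       days = 210, start = "2024-08-04 00:00:00",
                       noise_prob = 0.00226, noise_jump = c(4, 8),
                       missing_prob = 0.376,
                       d_cells = 2, T_minutes = 60,
                       beta_shadow_fall = log(1.02),
                       beta_shadow_icu = log(0.99),
                       target_falls = NULL, target_icu = NULL,
                       icu_clustering = TRUE, clustering_minutes = 60,
                       max_staleness = 2) {
  if (is.null(beds)) beds <- default_bed_layout(width, height, n_beds)
  beds <- as.matrix(beds)
  dimnames(beds) <- NULL
  if (any(beds[, 1] < 0 | beds[, 1] > width |
          beds[, 2] < 0 | beds[, 2] > height))
    stop("bed coordinates outside the unit")
  stopifnot(all(speed_range > 0), days > 0,
            noise_prob >= 0, noise_prob <= 1,
            missing_prob >= 0, missing_prob <= 1)
  if (is.null(target_falls)) target_falls <- 8 * days / 210
  if (is.null(target_icu)) target_icu <- 89 * days / 210
  structure(list(seed = as.integer(seed), width = width, height = height,
                 beds = beds, n_workstations = n_workstations,
                 speed_range = speed_range, dwell_meanlog = dwell_meanlog,
                 dwell_sdlog = dwell_sdlog, days = days,
                 start = as.POSIXct(start, tz = "UTC"),
                 noise_prob = noise_prob, noise_jump = noise_jump,
                 missing_prob = missing_prob, d_cells = d_cells,
                 T_minutes = T_minutes,
                 beta_shadow_fall = beta_shadow_fall,
                 beta_shadow_icu = beta_shadow_icu,
                 target_falls = target_falls, target_icu = target_icu,
                 icu_clustering = icu_clustering,
                 clustering_minutes = clustering_minutes,
                 max_staleness = max_staleness),
            class = "sim_config")
}

default_bed_layout <- function(width, height, n_beds) {
  per_wall <- ceiling(n_beds / 2)
  xs <- seq(width * 0.05, width * 0.95, length.out = per_wall)
  beds <- rbind(cbind(xs, height * 0.075),
                cbind(xs, height * 0.925))
  beds[seq_len(n_beds), , drop = FALSE]
}

sub_seed <- function(config, k) {
  as.integer((as.numeric(config$seed) + 1000003 * k) %% 2147483629)
}

#' Simulate clean workstation trajectories
#'
#' Each workstation alternates bedside dwells (1 beacon per minute) and
#' straight-line transits to another bed (1 Hz emissions), confined to the
#' unit. The returned stream carries a `regime` column
#' (`"dwell"`/`"transit"`) as generation truth.
#'
#' @param config a [sim_config()].
#' @return a [position_stream] with an extra `regime` column.
#' @export
simulate_trajectories <- function(config) {
  set.seed(sub_seed(config, 1))
  total <- config$days * 86400
  beds <- config$beds
  n_beds <- nrow(beds)
  parts <- vector("list", config$n_workstations)
  for (w in seq_len(config$n_workstations)) {
    mean_cycle <- exp(config$dwell_meanlog + config$dwell_sdlog^2 / 2) + 30
    nd <- max(2L, ceiling(total / mean_cycle * 1.5) + 10L)
    b <- integer(nd + 1L)
    b[1] <- sample.int(n_beds, 1)
    if (n_beds > 1) {
      r <- sample.int(n_beds - 1L, nd, replace = TRUE)
      for (k in seq_len(nd)) b[k + 1L] <- r[k] + (r[k] >= b[k])
    } else b[] <- 1L
    dw <- pmax(60, round(stats::rlnorm(nd, config$dwell_meanlog,
                                       config$dwell_sdlog)))
    sp <- stats::runif(nd, config$speed_range[1], config$speed_range[2])
    seg_from <- beds[b[seq_len(nd)], , drop = FALSE]
    seg_to <- beds[b[seq_len(nd) + 1L], , drop = FALSE]
    dist <- sqrt(rowSums((seg_to - seg_from)^2))
    tt <- pmax(1, dist / sp)
    dur <- as.vector(rbind(dw, tt))
    st <- cumsum(c(0, dur))[seq_len(2 * nd)]
    keep_seg <- st < total
    # dwell beacons: offsets 0, 60, 120, ... within each dwell
    dws <- st[seq(1, 2 * nd, by = 2)]
    kd <- pmin(floor(dw / 60) + 1L, 1e6)
    dwell_t <- rep(dws, kd) + 60 * (sequence(kd) - 1)
    dwell_x <- rep(seg_from[, 1], kd)
    dwell_y <- rep(seg_from[, 2], kd)
    # transit emissions: 1 Hz plus the exact arrival point
    trs <- st[seq(2, 2 * nd, by = 2)]
    kt <- ceiling(tt)
    off <- sequence(kt)
    tt_rep <- rep(tt, kt)
    frac <- pmin(off, tt_rep) / tt_rep
    tr_t <- rep(trs, kt) + pmin(off, tt_rep)
    tr_x <- rep(seg_from[, 1], kt) + frac * rep(seg_to[, 1] - seg_from[, 1], kt)
    tr_y <- rep(seg_from[, 2], kt) + frac * rep(seg_to[, 2] - seg_from[, 2], kt)
    tms <- c(dwell_t, tr_t)
    df <- data.frame(time = tms,
                     x = c(dwell_x, tr_x), y = c(dwell_y, tr_y),
                     regime = rep(c("dwell", "transit"),
                                  c(length(dwell_t), length(tr_t))))
    df <- df[df$time < total, , drop = FALSE]
    df <- df[order(df$time), , drop = FALSE]
    df <- df[!duplicated(round(df$time, 6)), , drop = FALSE]
    df$tag_id <- sprintf("W%d", w)
    parts[[w]] <- df
  }
  df <- do.call(rbind, parts)
  finalize_sim_stream(df, config)
}

# assemble a sorted, classed position stream from simulator rows
finalize_sim_stream <- function(df, config) {
  if (is.null(df) || !nrow(df)) {
    out <- data.frame(tag_id = character(), time = config$start[integer()],
                      x = numeric(), y = numeric(), regime = character())
  } else {
    ord <- order(df$tag_id, df$time)
    df <- df[ord, , drop = FALSE]
    abs_time <- if (inherits(df$time, "POSIXct")) df$time
                else config$start + df$time
    out <- data.frame(tag_id = df$tag_id,
                      time = abs_time,
                      x = df$x, y = df$y, regime = df$regime,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, n_duplicates = 0L,
            class = c("position_stream", "data.frame"))
}

#' Corrupt a clean stream with positioning artifacts
#'
#' Deletes motion-regime emissions with probability `missing_prob`
#' (emulating 1 Hz data loss), then displaces isolated points with
#' probability `noise_prob` by a jump drawn from `noise_jump` meters in a
#' uniform direction. Jump candidates adjacent to another candidate, or at
#' a tag's first/last record, are skipped so every injected artifact truly
#' is an isolated outlier. Truth indices are returned for scoring.
#'
#' @param stream a clean simulated [position_stream] (with `regime`).
#' @param config a [sim_config()].
#' @return list with `stream` (corrupted), `noise_idx` (rows of the
#'   returned stream that were displaced), `missing_idx` (rows of the input
#'   stream that were deleted).
#' @export
corrupt <- function(stream, config) {
  set.seed(sub_seed(config, 2))
  n <- nrow(stream)
  regime <- if ("regime" %in% names(stream)) stream$regime
            else rep("transit", n)
  drop <- regime == "transit" & stats::runif(n) < config$missing_prob
  missing_idx <- which(drop)
  s <- stream[!drop, , drop = FALSE]
  rownames(s) <- NULL
  m <- nrow(s)
  cand <- which(stats::runif(m) < config$noise_prob)
  if (length(cand)) {
    tag <- s$tag_id
    interior <- cand > 1 & cand < m &
      tag[pmax(cand - 1L, 1L)] == tag[cand] &
      tag[pmin(cand + 1L, m)] == tag[cand]
    cand <- cand[interior]
    if (length(cand) > 1) {
      adj <- c(FALSE, diff(cand) == 1L)
      cand <- cand[!adj]
    }
  }
  if (length(cand)) {
    r <- stats::runif(length(cand), config$noise_jump[1],
                      config$noise_jump[2])
    th <- stats::runif(length(cand), 0, 2 * pi)
    s$x[cand] <- s$x[cand] + r * cos(th)
    s$y[cand] <- s$y[cand] + r * sin(th)
  }
  class(s) <- c("position_stream", "data.frame")
  list(stream = s, noise_idx = cand, missing_idx = missing_idx)
}

# intercept such that the expected number of Bernoulli events over the
# series matches `target`; solved by root finding on the expected count
calibrate_intercept <- function(percent, beta, target) {
  f <- function(b0) sum(stats::plogis(b0 + beta * percent)) - target
  stats::uniroot(f, c(-60, 20), tol = 1e-10)$root
}

#' Simulate minute-level events from a shadow series
#'
#' Draws independent per-minute Bernoulli events with
#' `logit p = b0 + beta * percent_shadow`, where `b0` is calibrated by root
#' finding so the expected event count over the series equals `target`.
#'
#' @param series a [shadow_series()] (or any data.frame with `percent` and
#'   `time`).
#' @param beta true log-odds slope per percentage point.
#' @param target expected number of events.
#' @param kind `"fall"` or `"icu_transfer"`.
#' @param subtype_probs named probabilities used to draw fall subtypes.
#' @return list with `events` (an [event_log()]), `minutes` (event minute
#'   indices) and `b0` (calibrated intercept).
#' @export
simulate_events <- function(series, beta, target, kind = "fall",
                            subtype_probs = c(patient = 0.6, family = 0.2,
                                              staff = 0.2)) {
  pct <- series$percent
  ok <- !is.na(pct)
  if (target < 1)
    warning("expected event count ", signif(target, 3),
            " < 1 over the simulated span; association analyses will be",
            " underpowered")
  b0 <- calibrate_intercept(pct[ok], beta, target)
  p <- stats::plogis(b0 + beta * pct)
  p[!ok] <- 0
  hit <- stats::rbinom(length(p), 1, p) == 1
  mins <- which(hit)
  subtype <- if (kind == "fall" && length(mins))
    sample(names(subtype_probs), length(mins), replace = TRUE,
           prob = subtype_probs) else rep("deterioration", length(mins))
  ev <- event_log(rep(kind, length(mins)), series$time[mins],
                  subtype = subtype)
  list(events = ev, minutes = mins, b0 = b0)
}

#' Simulate a complete synthetic observational study
#'
#' Orchestrates the full generative process: clean trajectories; the
#' internal (truth) shadow series; ICU transfers drawn with the negative
#' shadow slope; optional pre-transfer bedside clustering injected back
#' into the stream (a response cart "W0" beaconing at the event bed during
#' the window before each transfer), after which the shadow series is
#' recomputed; falls drawn with the positive slope from the final series;
#' and stream corruption. Everything needed to score recovery is kept in
#' `$truth`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study` with `config`, `grid`,
#'   `clean_stream`, `stream` (corrupted), `events`, `frames` (clean,
#'   post-injection), and `truth` (list: `series` (final), `series_pre`
#'   (pre-injection), `b0_fall`, `b0_icu`, `fall_minutes`, `icu_minutes`,
#'   `noise_idx`, `missing_idx`).
#' @export
simulate_study <- function(config) {
  grid <- build_grid(c(config$width, config$height))
  params <- shadow_params(config$d_cells, config$T_minutes)
  span_end <- config$start + config$days * 86400
  clean <- simulate_trajectories(config)
  frames <- resample_per_minute(clean, grid, config$max_staleness,
                                start = config$start, end = span_end)
  series_pre <- shadow_series(frames, params)

  icu <- list(events = event_log(character(), config$start[integer()]),
              minutes = integer(), b0 = NA_real_)
  if (config$target_icu >= 0.5) {
    set.seed(sub_seed(config, 4))
    icu <- simulate_events(series_pre, config$beta_shadow_icu,
                           config$target_icu, kind = "icu_transfer")
  }

  combined <- clean
  series <- series_pre
  if (config$icu_clustering && length(icu$minutes)) {
    set.seed(sub_seed(config, 5))
    beds <- config$beds[sample.int(nrow(config$beds),
                                   length(icu$minutes), replace = TRUE),
                        , drop = FALSE]
    inj <- lapply(seq_along(icu$minutes), function(k) {
      t_ev <- as.numeric(icu$events$time[k]) - as.numeric(config$start)
      tms <- seq(max(0, t_ev - config$clustering_minutes * 60), t_ev, by = 60)
      data.frame(time = config$start + tms, x = beds[k, 1], y = beds[k, 2],
                 regime = "dwell", tag_id = "W0")
    })
    combined <- finalize_sim_stream(
      rbind(as.data.frame(clean), do.call(rbind, inj)), config)
    frames <- resample_per_minute(combined, grid, config$max_staleness,
                                  start = config$start, end = span_end)
    series <- shadow_series(frames, params)
  }

  fall <- list(events = event_log(character(), config$start[integer()]),
               minutes = integer(), b0 = NA_real_)
  if (config$target_falls >= 1e-9) {
    set.seed(sub_seed(config, 6))
    fall <- simulate_events(series, config$beta_shadow_fall,
                            config$target_falls, kind = "fall")
  }

  crp <- corrupt(combined, config)
  events <- event_log(c(fall$events$kind, icu$events$kind),
                      c(fall$events$time, icu$events$time),
                      subtype = c(fall$events$subtype, icu$events$subtype))
  structure(list(config = config, grid = grid, clean_stream = combined,
                 stream = crp$stream, events = events, frames = frames,
                 truth = list(series = series, series_pre = series_pre,
                              b0_fall = fall$b0, b0_icu = icu$b0,
                              beta_shadow_fall = config$beta_shadow_fall,
                              beta_shadow_icu = config$beta_shadow_icu,
                              fall_minutes = fall$minutes,
                              icu_minutes = icu$minutes,
                              noise_idx = crp$noise_idx,
                              missing_idx = crp$missing_idx)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %g day(s), %d workstation(s), %d bed(s)\n",
              x$config$days, x$config$n_workstations, nrow(x$config$beds)))
  cat(sprintf("  %d emissions (%d after corruption), %d fall(s), %d ICU transfer(s)\n",
              nrow(x$clean_stream), nrow(x$stream),
              sum(x$events$kind == "fall"),
              sum(x$events$kind == "icu_transfer")))
  invisible(x)
}

#' Run the analysis pipeline on a (corrupted) stream
#'
#' The standard end-to-end path a user would run on real exported data:
#' noise filtering, per-minute resampling, shadow series, minute labeling
#' and the two adjusted logistic models. Used to close the loop on
#' synthetic studies.
#'
#' @param stream a raw [position_stream].
#' @param events an [event_log()].
#' @param grid a [build_grid()] result.
#' @param params a [shadow_params()].
#' @param schedule a [shift_schedule()].
#' @param start,end optional span overrides passed to
#'   [resample_per_minute()].
#' @param max_staleness carry-forward limit in minutes.
#' @return list with `qc` (the [filter_noise()] result), `frames`,
#'   `series`, `table`, `fall_fit`, `icu_fit` (model objects or `NULL`
#'   when an outcome has no events).
#' @export
run_pipeline <- function(stream, events, grid, params = shadow_params(),
                         schedule = default_shift_schedule(),
                         start = NULL, end = NULL, max_staleness = 2) {
  qc <- filter_noise(stream)
  frames <- resample_per_minute(qc$stream, grid, max_staleness,
                                start = start, end = end)
  series <- shadow_series(frames, params)
  table <- label_minutes(series, events, schedule)
  fit_or_null <- function(outcome) {
    if (!any(table[[outcome]]) || all(table[[outcome]])) return(NULL)
    fit_event_model(table, outcome)
  }
  list(qc = qc, frames = frames, series = series, table = table,
       fall_fit = fit_or_null("fall"), icu_fit = fit_or_null("icu"))
}
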