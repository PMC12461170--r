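#' Build the minute-level analysis table
#'
#' The unit of analysis is the calendar minute. A minute is event-flagged
#' iff it lies in the exposure window of `window_minutes` minutes ending at
#' (and including) the event's minute; windows of nearby events merge, and
#' windows are truncated at the series start. Day of week and the
#' patient-to-nurse ratio of the shift in force are attached as covariates.
#'
#' @param series a [shadow_series()].
#' @param events an [event_log()].
#' @param schedule a [shift_schedule()].
#' @param window_minutes exposure-window length; defaults to the series'
#'   persistence threshold `T_minutes`.
#' @param subtype_filter optional character vector: keep only fall events
#'   whose `subtype` is in it (e.g. `"patient"` for the patients-only
#'   analysis); ICU transfers are unaffected.
#' @return A `minute_table`: data.frame with `minute`, `time`, `percent`,
#'   `fall`, `icu` (logicals), `dow` (factor, Monday reference) and
#'   `ratio`. Warm-up-masked minutes (`NA` percent) are dropped.
#' @export
label_minutes <- function(series, events,
                          schedule = default_shift_schedule(),
                          window_minutes = NULL, subtype_filter = NULL) {
  stopifnot(inherits(series, "shadow_series"),
            inherits(events, "event_log"))
  p <- attr(series, "params")
  if (is.null(window_minutes)) window_minutes <- p$T_minutes
  stopifnot(window_minutes >= 1)
  n <- nrow(series)
  start <- as.numeric(series$time[1]) - 60
  flag_for <- function(ev) {
    flags <- logical(n)
    if (!nrow(ev)) return(flags)
    mins <- ceiling((as.numeric(ev$time) - start) / 60 - 1e-9)
    outside <- mins < 1 | mins > n
    if (any(outside))
      warning(sum(outside), " event(s) outside the series span, skipped")
    for (e in mins[!outside])
      flags[max(1L, e - window_minutes + 1L):e] <- TRUE
    flags
  }
  falls <- events[events$kind == "fall", , drop = FALSE]
  if (!is.null(subtype_filter))
    falls <- falls[falls$subtype %in% subtype_filter, , drop = FALSE]
  icu <- events[events$kind == "icu_transfer", , drop = FALSE]
  lt <- as.POSIXlt(series$time, tz = "UTC")
  dow_levels <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  dow <- factor(dow_levels[(lt$wday + 6L) %% 7L + 1L], levels = dow_levels)
  tab <- data.frame(minute = series$minute, time = series$time,
                    percent = series$percent,
                    fall = flag_for(falls), icu = flag_for(icu),
                    dow = dow, ratio = ratio_at(series$time, schedule))
  tab <- tab[!is.na(tab$percent), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, window_minutes = window_minutes, params = p,
            class = c("minute_table", "data.frame"))
}

#' Compare shadow exposure between event and non-event minutes
#'
#' Welch (unequal-variance) two-sample t test, 2-tailed, of the per-minute
#' shadow percentage between flagged and unflagged minutes. Welch's form is
#' used because the two groups differ enormously in size and need not share
#' a variance.
#'
#' @param table a [label_minutes()] result.
#' @param outcome `"fall"` or `"icu"`.
#' @return A `shadow_comparison`: list with group `n`, `means`, `sds`,
#'   `difference` (event minus non-event), `ci95`, `p_value` and the
#'   underlying `htest`.
#' @export
compare_groups <- function(table, outcome = c("fall", "icu")) {
  outcome <- match.arg(outcome)
  flag <- table[[outcome]]
  a <- table$percent[flag]
  b <- table$percent[!flag]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 minutes (", outcome, ": ", length(a),
         " flagged, ", length(b), " unflagged)")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(outcome = outcome,
                 n = c(event = length(a), non_event = length(b)),
                 means = c(event = mean(a), non_event = mean(b)),
                 sds = c(event = stats::sd(a), non_event = stats::sd(b)),
                 difference = mean(a) - mean(b),
                 ci95 = as.vector(ht$conf.int),
                 p_value = ht$p.value, htest = ht),
            class = "shadow_comparison")
}

#' @export
print.shadow_comparison <- function(x, ...) {
  cat(sprintf("<shadow_comparison> %s minutes\n", x$outcome))
  cat(sprintf("  event:     mean %.1f (SD %.1f), n = %d\n",
              x$means[1], x$sds[1], x$n[1]))
  cat(sprintf("  non-event: mean %.1f (SD %.1f), n = %d\n",
              x$means[2], x$sds[2], x$n[2]))
  cat(sprintf("  difference %.2f pp (95%% CI %.2f to %.2f), p = %.3g\n",
              x$difference, x$ci95[1], x$ci95[2], x$p_value))
  invisible(x)
}

#' Adjusted logistic regression of event minutes on shadow exposure
#'
#' Fits a multivariable logistic regression of the per-minute event flag on
#' the shadow percentage, adjusted for the patient-to-nurse ratio and day
#' of the week (six dummies, Monday reference). Odds ratios are per unit:
#' one percentage point of shadow, one patient per nurse. Wald 95% CIs.
#' Constant covariates (e.g. a sub-day table with one weekday) are dropped
#' with a message; quasi-complete separation raises an explicit error.
#'
#' @param table a [label_minutes()] result.
#' @param outcome `"fall"` or `"icu"`.
#' @param adjust include the staffing and day-of-week covariates (default
#'   `TRUE`); `FALSE` fits the unadjusted exposure-only model, e.g. for
#'   parameter-recovery experiments against a generator without covariate
#'   effects.
#' @return A `shadow_glm` (subclassing `glm`): all `glm` methods work
#'   (`coef`, `predict`, `residuals`, ...); `print`/`summary` report the
#'   odds-ratio table, also stored in attribute `or_table`.
#' @export
fit_event_model <- function(table, outcome = c("fall", "icu"),
                            adjust = TRUE) {
  outcome <- match.arg(outcome)
  flag <- table[[outcome]]
  if (!any(flag) || all(flag))
    stop("outcome '", outcome, "' does not have both classes")
  dat <- data.frame(y = flag, percent = table$percent,
                    ratio = table$ratio, dow = table$dow)
  terms <- "percent"
  if (adjust) {
    if (length(unique(dat$ratio)) > 1) terms <- c(terms, "ratio")
    else message("patient-to-nurse ratio constant; dropped from the model")
    if (length(unique(as.character(dat$dow))) > 1) terms <- c(terms, "dow")
    else message("day of week constant; dropped from the model")
  }
  if (stats::sd(dat$percent) == 0) stop("shadow percentage is constant")
  f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(f, data = dat, family = stats::binomial()),
    warning = function(cond) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(cond)))
        invokeRestart("muffleWarning")
    })
  # perfect separation: the outcome is predicted exactly, or a continuous
  # predictor's coefficient diverges. Sparse factor cells (e.g. a weekday
  # with no event minutes) only lose their own dummy, not the exposure OR.
  est <- stats::coef(fit)
  cont <- intersect(c("percent", "ratio"), names(est))
  fitted_p <- stats::fitted(fit)
  perfect <- max(fitted_p[!dat$y]) < 1e-8 && min(fitted_p[dat$y]) > 1 - 1e-8
  if (!fit$converged || perfect || any(abs(est[cont]) > 10))
    stop("perfect separation detected in the '", outcome,
         "' model; odds ratios are not identifiable")
  sparse <- names(est)[abs(est) > 10 & !names(est) %in%
                         c(cont, "(Intercept)")]
  if (length(sparse))
    message("quasi-separated covariate level(s) (no events observed): ",
            paste(sparse, collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))
  z <- est / se
  or_table <- data.frame(
    term = names(est),
    odds_ratio = exp(est),
    ci_lo = exp(est - stats::qnorm(0.975) * se),
    ci_hi = exp(est + stats::qnorm(0.975) * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    row.names = NULL)
  attr(fit, "or_table") <- or_table
  attr(fit, "outcome") <- outcome
  attr(fit, "n") <- nrow(dat)
  class(fit) <- c("shadow_glm", class(fit))
  fit
}

#' @rdname fit_event_model
#' @export
fit_fall_model <- function(table) fit_event_model(table, "fall")

#' @rdname fit_event_model
#' @export
fit_icu_model <- function(table) fit_event_model(table, "icu")

#' @rdname fit_event_model
#' @param x,object a `shadow_glm`.
#' @param ... unused.
#' @export
print.shadow_glm <- function(x, ...) {
  cat(sprintf("<shadow_glm> logistic model of %s minutes (n = %d)\n",
              attr(x, "outcome"), attr(x, "n")))
  tab <- attr(x, "or_table")
  tab$odds_ratio <- sprintf("%.3f", tab$odds_ratio)
  tab$ci <- sprintf("(%.3f to %.3f)", tab$ci_lo, tab$ci_hi)
  tab$p <- format.pval(tab$p_value, digits = 2)
  print(tab[tab$term != "(Intercept)", c("term", "odds_ratio", "ci", "p")],
        row.names = FALSE)
  invisible(x)
}

#' @rdname fit_event_model
#' @export
summary.shadow_glm <- function(object, ...) {
  print.shadow_glm(object)
  cat("\nUnderlying glm summary:\n")
  cl <- class(object)
  class(object) <- cl[cl != "shadow_glm"]
  summary(object, ...)
}

#' Odds-ratio table of a fitted event model
#'
#' @param fit a [fit_event_model()] result.
#' @return data.frame `term`, `odds_ratio`, `ci_lo`, `ci_hi`, `p_value`.
#' @export
odds_ratios <- function(fit) attr(fit, "or_table")

#' Sensitivity grid over dilation and persistence parameters
#'
#' For each (d, T) pair the shadow series is rebuilt, minutes are relabeled
#' with an exposure window equal to T, and the event/non-event mean
#' difference with its Welch 95% CI is computed. A cell whose groups are
#' degenerate is reported as `NA`.
#'
#' @param frames a [resample_per_minute()] result.
#' @param events an [event_log()].
#' @param schedule a [shift_schedule()].
#' @param d_list,T_list parameter ranges, defaults 1:4 cells and
#'   15--90 min.
#' @param outcome `"fall"` or `"icu"`.
#' @return data.frame `d_cells`, `T_minutes`, `difference`, `ci_lo`,
#'   `ci_hi`, `p_value`, `significant` (CI excluding 0).
#' @export
sensitivity_table <- function(frames, events,
                              schedule = default_shift_schedule(),
                              d_list = 1:4,
                              T_list = c(15, 30, 45, 60, 75, 90),
                              outcome = "fall") {
  surf <- sensitivity_surface(frames, d_list, T_list)
  grid_pairs <- expand.grid(T_minutes = T_list, d_cells = d_list)
  rows <- lapply(seq_len(nrow(grid_pairs)), function(k) {
    d <- grid_pairs$d_cells[k]; Tm <- grid_pairs$T_minutes[k]
    res <- tryCatch({
      s <- surface_slice(surf, d, Tm)
      tab <- label_minutes(s, events, schedule, window_minutes = Tm)
      cg <- compare_groups(tab, outcome)
      data.frame(d_cells = d, T_minutes = Tm, difference = cg$difference,
                 ci_lo = cg$ci95[1], ci_hi = cg$ci95[2],
                 p_value = cg$p_value)
    }, error = function(e) {
      warning("cell (d=", d, ", T=", Tm, "): ", conditionMessage(e))
      data.frame(d_cells = d, T_minutes = Tm, difference = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, p_value = NA_real_)
    })
    res
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$ci_lo) & (out$ci_lo > 0 | out$ci_hi < 0)
  out
}

#' Temporal split-half analysis
#'
#' Splits the minute table at the midpoint week boundary and reruns the
#' event/non-event comparison in each half, probing the stability of the
#' association over the study period.
#'
#' @param table a [label_minutes()] result spanning at least 2 weeks.
#' @param outcome `"fall"` or `"icu"`.
#' @return list with `first` and `second` [compare_groups()] results (`NA`
#'   with a warning when a half lacks events).
#' @export
split_half <- function(table, outcome = "fall") {
  span_weeks <- nrow(table) / (7 * 1440)
  if (span_weeks < 2) stop("split-half analysis needs >= 2 weeks of minutes")
  cut_week <- floor(ceiling(span_weeks) / 2)
  first <- table[table$minute <= cut_week * 10080, , drop = FALSE]
  second <- table[table$minute > cut_week * 10080, , drop = FALSE]
  run <- function(tb, label) {
    tryCatch(compare_groups(tb, outcome), error = function(e) {
      warning(label, " half: ", conditionMessage(e))
      NA
    })
  }
  list(first = run(first, "first"), second = run(second, "second"),
       cut_week = cut_week)
}

#' Fall rate per 1000 patient-days
#'
#' @param n_falls number of falls.
#' @param n_beds bed capacity of the unit.
#' @param n_days observation days.
#' @return rate per 1000 patient-days, reported to 1 decimal.
#' @examples
#' fall_rate(8, 40, 210)  # 1.0
#' @export
fall_rate <- function(n_falls, n_beds, n_days) {
  stopifnot(n_falls >= 0, n_beds >= 0, n_days >= 0)
  if (n_beds * n_days <= 0) stop("n_beds * n_days must be positive")
  round(1000 * n_falls / (n_beds * n_days), 1)
}
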