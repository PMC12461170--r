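# minimal handmade series/table builders for labeling and model tests
fake_series <- function(percent,
                        origin = as.POSIXct("2024-08-05 00:00:00",
                                            tz = "UTC"),
                        params = shadow_params()) {
  n <- length(percent)
  structure(data.frame(minute = seq_len(n), time = origin + 60 * seq_len(n),
                       percent = percent, warmup = seq_len(n) <= params$T_minutes),
            params = params, n_inside = 400,
            class = c("shadow_series", "data.frame"))
}

fake_table <- function(percent, fall, icu = FALSE,
                       ratio = NULL, origin = as.POSIXct("2024-08-05",
                                                         tz = "UTC")) {
  n <- length(percent)
  time <- origin + 60 * seq_len(n)
  lt <- as.POSIXlt(time, tz = "UTC")
  lv <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  if (is.null(ratio)) ratio <- ratio_at(time)
  structure(data.frame(minute = seq_len(n), time = time, percent = percent,
                       fall = rep_len(fall, n), icu = rep_len(icu, n),
                       dow = factor(lv[(lt$wday + 6L) %% 7L + 1L],
                                    levels = lv),
                       ratio = ratio),
            window_minutes = 60, class = c("minute_table", "data.frame"))
}

test_that("event windows flag the T minutes ending at the event", {
  ser <- fake_series(runif(300, 40, 80))
  origin <- ser$time[1] - 60
  ev <- event_log("fall", origin + 60 * 100)
  tab <- label_minutes(ser, ev, window_minutes = 60)
  expect_equal(which(tab$fall), 41:100)

  # overlapping windows merge
  ev2 <- event_log(c("fall", "fall"), origin + 60 * c(100, 130))
  tab2 <- label_minutes(ser, ev2, window_minutes = 60)
  expect_equal(which(tab2$fall), 41:130)
  expect_equal(sum(tab2$fall), 90)

  # left truncation at the series start
  ev3 <- event_log("fall", origin + 60 * 10)
  tab3 <- label_minutes(ser, ev3, window_minutes = 60)
  expect_equal(which(tab3$fall), 1:10)

  # events outside the span are skipped with a warning
  ev4 <- event_log("fall", origin + 60 * 500)
  expect_warning(tab4 <- label_minutes(ser, ev4, window_minutes = 60),
                 "outside")
  expect_equal(sum(tab4$fall), 0)

  # flagged count never exceeds n_events * window
  set.seed(3)
  for (rep in 1:5) {
    mins <- sample(300, 4)
    evr <- event_log(rep("fall", 4), origin + 60 * mins)
    tabr <- label_minutes(ser, evr, window_minutes = 30)
    expect_lte(sum(tabr$fall), 4 * 30)
  }

  # faller-subtype filter restricts which falls flag minutes
  ev5 <- event_log(c("fall", "fall"), origin + 60 * c(100, 200),
                   subtype = c("patient", "staff"))
  tab5 <- label_minutes(ser, ev5, window_minutes = 60,
                        subtype_filter = "patient")
  expect_equal(which(tab5$fall), 41:100)

  # ICU flags are independent of fall flags
  ev6 <- event_log(c("fall", "icu_transfer"), origin + 60 * c(60, 250))
  tab6 <- label_minutes(ser, ev6, window_minutes = 60)
  expect_equal(sum(tab6$icu), 60)
  expect_equal(which(tab6$icu), 191:250)
})

test_that("group comparison is a two-tailed Welch t test", {
  # identical groups: zero difference, p = 1
  pct <- rep(c(50, 60, 70), 40)
  tab <- fake_table(pct, fall = rep(c(TRUE, FALSE), each = 3))
  cg <- compare_groups(tab, "fall")
  expect_equal(cg$difference, 0)
  expect_equal(cg$p_value, 1)
  expect_true(cg$ci95[1] <= 0 && 0 <= cg$ci95[2])

  # group summary statistics at the scale reported in unit studies:
  # ~470 event minutes at mean 77.8 (SD 10.9) vs ~250k at 76.8 (SD 10.3)
  set.seed(14)
  a <- rnorm(470, 77.8, 10.9)
  b <- rnorm(249893, 76.8, 10.3)
  tab2 <- fake_table(c(a, b), fall = rep(c(TRUE, FALSE), c(470, 249893)))
  cg2 <- compare_groups(tab2, "fall")
  se <- 10.9 / sqrt(470)
  expect_lt(abs(cg2$difference - 1.0), 3 * se)
  expect_match(cg2$htest$method, "Welch")

  # degenerate group errors
  expect_error(compare_groups(fake_table(pct, fall = FALSE), "fall"),
               ">= 2")
})

test_that("the Welch CI covers a known mean shift at nominal rate", {
  set.seed(99)
  delta <- 1.5
  cover <- vapply(1:200, function(r) {
    a <- rnorm(150, 60 + delta, 8)
    b <- rnorm(400, 60, 8)
    ci <- stats::t.test(a, b)$conf.int
    ci[1] <= delta && delta <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("logistic models recover generating coefficients", {
  set.seed(205)
  n <- 2 * 10080
  pct <- pmin(100, pmax(0, rnorm(n, 60, 8)))
  tab0 <- fake_table(pct, fall = FALSE)

  # shadow slope ln(1.02) and staffing slope ln(0.84), null day effects
  b0 <- -3.9
  p <- plogis(b0 + log(1.02) * tab0$percent + log(0.84) * tab0$ratio)
  tab <- tab0
  tab$fall <- rbinom(n, 1, p) == 1
  fit <- fit_event_model(tab, "fall")
  or <- odds_ratios(fit)
  shadow_row <- or[or$term == "percent", ]
  ratio_row <- or[or$term == "ratio", ]
  expect_gt(shadow_row$ci_hi, 1.02); expect_lt(shadow_row$ci_lo, 1.02)
  expect_gt(ratio_row$ci_hi, 0.84); expect_lt(ratio_row$ci_lo, 0.84)

  # null generator: OR ~ 1, CI covers 1
  tabn <- tab0
  tabn$fall <- rbinom(n, 1, 0.01) == 1
  orn <- odds_ratios(fit_event_model(tabn, "fall"))
  nrow_ <- orn[orn$term == "percent", ]
  expect_gt(nrow_$ci_hi, 1); expect_lt(nrow_$ci_lo, 1)
  expect_lt(abs(log(nrow_$odds_ratio)), 0.03)

  # ICU slope ln(0.99) recovered through the icu outcome
  tabi <- tab0
  pi_ <- plogis(-2.9 + log(0.99) * tab0$percent)
  tabi$icu <- rbinom(n, 1, pi_) == 1
  ori <- odds_ratios(fit_icu_model(tabi))
  irow <- ori[ori$term == "percent", ]
  expect_gt(irow$ci_hi, 0.99); expect_lt(irow$ci_lo, 0.99)

  # row order does not matter
  perm <- sample(n)
  fit_p <- fit_event_model(tab[perm, ], "fall")
  expect_equal(coef(fit_p), coef(fit))

  # outcome with a single class errors
  expect_error(fit_event_model(tab0, "fall"), "both classes")
})

test_that("perfect separation raises a diagnostic error", {
  set.seed(33)
  pct <- c(runif(800, 10, 50), runif(15, 60, 80))
  tab <- fake_table(pct, fall = rep(c(FALSE, TRUE), c(800, 15)))
  expect_error(fit_event_model(tab, "fall", adjust = FALSE),
               "separation")
})

test_that("pipeline model recovers the generating fall slope end to end", {
  wk <- shared_week_study()
  tab <- label_minutes(wk$pl$series, wk$sim$events, window_minutes = 1)
  fit <- fit_event_model(tab, "fall", adjust = FALSE)
  or <- odds_ratios(fit)
  row <- or[or$term == "percent", ]
  expect_gt(row$ci_hi, 1.02)
  expect_lt(row$ci_lo, 1.02)
})

test_that("the sensitivity grid matches standalone recomputation at (2,60)", {
  wk <- shared_week_study()
  st <- sensitivity_table(wk$pl$frames, wk$sim$events,
                          d_list = c(1, 2), T_list = c(30, 60))
  cell <- st[st$d_cells == 2 & st$T_minutes == 60, ]
  standalone <- compare_groups(
    label_minutes(wk$pl$series, wk$sim$events, window_minutes = 60),
    "fall")
  expect_equal(cell$difference, standalone$difference)
  expect_equal(c(cell$ci_lo, cell$ci_hi), standalone$ci95)
  expect_equal(cell$significant,
               standalone$ci95[1] > 0 || standalone$ci95[2] < 0)
  expect_equal(nrow(st), 4)
})

test_that("split-half reruns the comparison per half and flags sparse halves", {
  set.seed(55)
  n <- 4 * 7 * 1440
  pct <- pmin(100, pmax(0, rnorm(n, 60, 8)))
  half2 <- seq_len(n) > n / 2
  # effect only in the second half; sparse uncorrelated falls in the first
  fall <- logical(n)
  fall[half2] <- rbinom(sum(half2), 1, plogis(-9 + 0.08 * pct[half2])) == 1
  fall[sample(which(!half2), 30)] <- TRUE
  tab <- fake_table(pct, fall = fall)
  sh <- split_half(tab, "fall")
  expect_equal(sh$cut_week, 2)
  expect_gt(sh$second$difference, 0)
  expect_true(sh$second$p_value < 0.05)
  expect_gt(sh$second$difference, abs(sh$first$difference))
  expect_false(sh$first$p_value < 0.05)

  # pooled analysis is just the comparison on the full table
  pooled <- compare_groups(tab, "fall")
  expect_equal(pooled$n[["event"]], sum(fall))

  # halves lacking events yield NA with a warning
  fall2 <- logical(n)
  fall2[which(half2)[1:200]] <- TRUE
  expect_warning(sh2 <- split_half(fake_table(pct, fall = fall2), "fall"),
                 "first half")
  expect_true(is.na(sh2$first[[1]]))
  expect_s3_class(sh2$second, "shadow_comparison")

  expect_error(split_half(fake_table(pct[1:2000], fall = FALSE)), "2 weeks")
})

test_that("fall rates are per 1000 patient-days to one decimal", {
  expect_equal(fall_rate(8, 40, 210), 1.0)
  expect_equal(fall_rate(0, 40, 210), 0.0)
  expect_equal(fall_rate(1, 1, 1000), 1.0)
  expect_error(fall_rate(1, 0, 10), "positive")
})
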