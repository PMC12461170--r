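test_that("a cell enters shadow exactly at the persistence threshold", {
  Tm <- 10
  n_min <- 40
  # three cells: always covered / never covered / covered once mid-run
  cov <- matrix(FALSE, n_min, 3)
  cov[, 1] <- TRUE
  cov[Tm, 3] <- TRUE  # breaks the run at minute T
  pct <- shadow_percent_matrix(cov, Tm)
  shadow_share_never <- 100 / 3
  expect_equal(pct[seq_len(Tm - 1)], rep(0, Tm - 1))
  expect_equal(pct[Tm], shadow_share_never)          # cell 2 enters at T
  expect_true(all(pct[Tm:n_min] >= shadow_share_never))
  # cell 3: uncovered T-1, covered once, uncovered again T-1 -> shadow only
  # once a full T-run accumulates after the break
  expect_equal(pct[2 * Tm - 1], shadow_share_never)
  expect_equal(pct[2 * Tm], 2 * shadow_share_never)
})

test_that("stepwise state updates match the spec'd counter semantics", {
  g <- build_grid(c(5, 5))
  p <- shadow_params(d_cells = 0, T_minutes = 3)
  state <- NULL
  cov_none <- matrix(FALSE, 5, 5)
  for (i in 1:3) state <- update_shadow(state, cov_none, p, g)
  expect_true(all(state$shadow_mask))
  cov_one <- cov_none; cov_one[2, 2] <- TRUE
  state <- update_shadow(state, cov_one, p, g)
  expect_false(state$shadow_mask[2, 2])
  expect_equal(state$uncovered_minutes[2, 2], 0L)
  expect_equal(sum(state$shadow_mask), 24)
  expect_error(update_shadow(state, matrix(FALSE, 4, 4), p, g), "grid")
})

test_that("incremental tracker equals the sliding-window oracle bitwise", {
  set.seed(42)
  for (rep in 1:25) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    n_min <- sample(50:200, 1)
    Tm <- sample(c(5, 10, 25), 1)
    cov <- matrix(runif(n_min * nr * nc) < runif(1, 0.02, 0.3),
                  n_min, nr * nc)
    inside <- runif(nr * nc) < 0.9
    inside[1] <- TRUE
    cov[, !inside] <- FALSE
    expect_identical(shadow_percent_matrix(cov, Tm, inside),
                     oracle_shadow_percent(cov, Tm, inside))
  }
})

test_that("a lone stationary workstation leaves 93.75% of the unit dark", {
  g <- build_grid(c(20, 20))
  origin <- as.POSIXct("2024-08-04 00:00:00", tz = "UTC")
  ts <- seq(0, 120 * 60, by = 60)
  s <- position_stream(rep("A", length(ts)), origin + ts,
                       rep(10.5, length(ts)), rep(10.5, length(ts)))
  fr <- resample_per_minute(s, g, start = origin, end = origin + 120 * 60)
  ser <- shadow_series(fr, shadow_params(d_cells = 2, T_minutes = 60))
  expect_true(all(ser$percent[1:59] == 0))
  expect_true(all(ser$percent[60:120] == (400 - 25) / 400 * 100))
  # warm-up masking flags exactly the first T minutes
  ser_m <- shadow_series(fr, shadow_params(2, 60, warmup = "mask_first_T"))
  expect_true(all(is.na(ser_m$percent[1:60])))
  expect_false(anyNA(ser_m$percent[61:120]))
})

test_that("full coverage every minute keeps shadow at zero", {
  g <- build_grid(c(4, 4))
  origin <- as.POSIXct("2024-08-04 00:00:00", tz = "UTC")
  ts <- rep(seq(0, 60 * 60, by = 60), each = 4)
  tags <- rep(c("A", "B", "C", "D"), times = length(ts) / 4)
  xs <- rep(c(1, 3, 1, 3), times = length(ts) / 4)
  ys <- rep(c(1, 1, 3, 3), times = length(ts) / 4)
  s <- position_stream(tags, origin + ts, xs, ys)
  fr <- resample_per_minute(s, g, start = origin, end = origin + 3600)
  ser <- shadow_series(fr, shadow_params(d_cells = 2, T_minutes = 10))
  expect_true(all(ser$percent == 0))
})

test_that("random trajectories agree with the windowed-scan oracle", {
  set.seed(77)
  g <- build_grid(c(8, 8))
  origin <- as.POSIXct("2024-08-04 00:00:00", tz = "UTC")
  n_min <- 150
  ts <- rep(60 * seq_len(n_min) - 30, each = 2)
  tags <- rep(c("A", "B"), n_min)
  xs <- runif(2 * n_min, 0, 8)
  ys <- runif(2 * n_min, 0, 8)
  s <- position_stream(tags, origin + ts, xs, ys)
  fr <- resample_per_minute(s, g, max_staleness = 0.9, start = origin,
                            end = origin + n_min * 60)
  for (Tm in c(5, 20)) {
    ser <- shadow_series(fr, shadow_params(d_cells = 1, T_minutes = Tm))
    cov <- t(vapply(seq_len(n_min), function(m)
      as.vector(coverage_at_minute(fr, m, 1)), logical(64)))
    expect_equal(ser$percent,
                 oracle_shadow_percent(cov, Tm, as.vector(g$inside)))
  }
})

test_that("sensitivity surface is consistent with independent recomputation", {
  day <- shared_day_frames()
  fr <- day$frames
  surf <- sensitivity_surface(fr, d_list = c(1, 2), T_list = c(15, 60))
  for (d in c(1, 2)) for (Tm in c(15, 60)) {
    ser <- shadow_series(fr, shadow_params(d, Tm))
    expect_equal(surface_slice(surf, d, Tm)$percent, ser$percent)
  }
  expect_error(surface_slice(surf, 3, 60), "not in the surface")
})

test_that("shadow percentage is antitone in both dilation and persistence", {
  day <- shared_day_frames()
  surf <- sensitivity_surface(day$frames, d_list = 1:3,
                              T_list = c(15, 45, 90))
  wide <- reshape(surf[, c("minute", "d_cells", "T_minutes", "percent")],
                  direction = "wide",
                  idvar = c("minute", "T_minutes"), timevar = "d_cells")
  expect_true(all(wide$percent.1 >= wide$percent.2 - 1e-12))
  expect_true(all(wide$percent.2 >= wide$percent.3 - 1e-12))
  wideT <- reshape(surf[, c("minute", "d_cells", "T_minutes", "percent")],
                   direction = "wide",
                   idvar = c("minute", "d_cells"), timevar = "T_minutes")
  expect_true(all(wideT$percent.15 >= wideT$percent.45 - 1e-12))
  expect_true(all(wideT$percent.45 >= wideT$percent.90 - 1e-12))
})
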