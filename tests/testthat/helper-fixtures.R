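# Shared simulated fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

# one-week synthetic study with inflated event rates, used by the
# association tests
shared_week_study <- function() {
  if (is.null(.fixture_cache$week)) {
    cfg <- sim_config(seed = 424242, days = 7, target_falls = 60,
                      target_icu = 40, icu_clustering = TRUE)
    sim <- simulate_study(cfg)
    pl <- run_pipeline(sim$stream, sim$events, sim$grid, shadow_params(),
                       start = cfg$start, end = cfg$start + 7 * 86400)
    .fixture_cache$week <- list(cfg = cfg, sim = sim, pl = pl)
  }
  .fixture_cache$week
}

# full-scale synthetic study at the default configuration (210 days)
full_scale_study <- function() {
  if (is.null(.fixture_cache$full)) {
    cfg <- sim_config(seed = 7, days = 210)
    sim <- simulate_study(cfg)
    pl <- run_pipeline(sim$stream, sim$events, sim$grid, shadow_params(),
                       start = cfg$start, end = cfg$start + 210 * 86400)
    .fixture_cache$full <- list(cfg = cfg, sim = sim, pl = pl)
  }
  .fixture_cache$full
}

# one simulated day, clean trajectories only
shared_day_frames <- function() {
  if (is.null(.fixture_cache$day)) {
    cfg <- sim_config(seed = 99, days = 1, target_falls = 0,
                      target_icu = 0, noise_prob = 0, missing_prob = 0)
    stream <- simulate_trajectories(cfg)
    grid <- build_grid(c(cfg$width, cfg$height))
    frames <- resample_per_minute(stream, grid, start = cfg$start,
                                  end = cfg$start + 86400)
    .fixture_cache$day <- list(cfg = cfg, stream = stream, grid = grid,
                               frames = frames)
  }
  .fixture_cache$day
}
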