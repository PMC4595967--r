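# positions data.frame for a scripted arc-length series on the default path
positions_from_s <- function(s, dt = 1 / 33, path = default_c_track()) {
  pp <- path_point(path, s)
  data.frame(t_s = (seq_along(s) - 1) * dt, x_cm = pp$x, y_cm = pp$y,
             hd_deg = pp$heading)
}

test_that("a single end-to-end traverse is one lap on traj1 only", {
  s <- seq(2, 298, by = 1)  # monotone run, well to well
  lin <- linearize_and_segment(positions_from_s(s), default_c_track())
  expect_equal(nrow(lin$laps), 1L)
  expect_equal(lin$laps$trajectory_id, "traj1")
  # lap starts at the last sample inside the departure zone (s < 10)
  i_start <- max(which(s < 10))
  i_end <- min(which(s > 290))
  expect_equal(lin$laps$t_start, (i_start - 1) / 33)
  expect_equal(lin$laps$t_end, (i_end - 1) / 33)
})

test_that("a mid-track turn-around that never reaches the far well is no lap", {
  s <- c(seq(2, 150, by = 1), seq(149, 2, by = -1))
  lin <- linearize_and_segment(positions_from_s(s), default_c_track())
  expect_equal(nrow(lin$laps), 0L)
  s2 <- c(seq(2, 150, by = 1), seq(149, 3, by = -1), seq(4, 298, by = 1))
  lin2 <- linearize_and_segment(positions_from_s(s2), default_c_track())
  expect_equal(nrow(lin2$laps), 1L)  # only the completed traversal counts
})

test_that("degenerate inputs error", {
  expect_error(linearize_and_segment(positions_from_s(2), default_c_track()),
               "at least 2")
  expect_error(track_path(rbind(c(0, 0), c(0, 0))), "degenerate")
  p <- positions_from_s(c(2, 50, 40))
  p$t_s <- c(0, 1, 1)
  expect_error(linearize_and_segment(p, default_c_track()), "increasing")
})

test_that("simulator laps are recovered within one sample period", {
  sim <- default_sim()
  prep <- prep_session(sim)
  truth <- sim$truth$laps
  expect_equal(nrow(prep$laps), nrow(truth))
  for (tr in c("traj1", "traj2")) {
    got <- prep$laps[prep$laps$trajectory_id == tr, ]
    want <- truth[truth$trajectory_id == tr, ]
    expect_equal(got$lap_index, want$lap_index)
    expect_true(all(abs(got$t_start - want$t_start) <= 1 / 33 + 1e-9))
    expect_true(all(abs(got$t_end - want$t_end) <= 1 / 33 + 1e-9))
  }
})

test_that("speed is the forward-differenced distance, last sample copied", {
  s <- seq(2, 298, by = 30 / 33)  # 30 cm/s at 33 Hz
  lin <- linearize_and_segment(positions_from_s(s), default_c_track())
  m <- compute_speed_and_mask(lin$samples)
  expect_equal(m$speed, rep(30, nrow(m)), tolerance = 1e-6)
  pbad <- positions_from_s(s)
  pbad$t_s[3] <- pbad$t_s[2]
  expect_error(linearize_and_segment(pbad, default_c_track()), "increasing")
})

test_that("sub-threshold speed dips shorter than 0.5 s are not masked", {
  dt <- 1 / 33
  # forward run with a 0.4-s slow patch (4 cm/s) mid-track
  slow_n <- round(0.4 / dt)
  steps <- c(rep(35 * dt, 200), rep(4 * dt, slow_n), rep(35 * dt, 200))
  s <- 2 + cumsum(steps)
  stopifnot(max(s) > 290)
  lin <- linearize_and_segment(positions_from_s(s), default_c_track())
  m <- compute_speed_and_mask(lin$samples)
  slow_idx <- 201:(200 + slow_n)
  in_lap <- !is.na(m$trajectory_id)
  expect_true(all(m$running[slow_idx][in_lap[slow_idx]]))
  # the same dip stretched to 1 s is masked
  slow_n2 <- round(1 / dt)
  steps2 <- c(rep(35 * dt, 200), rep(4 * dt, slow_n2), rep(35 * dt, 200))
  s2 <- 2 + cumsum(steps2)
  lin2 <- linearize_and_segment(positions_from_s(s2), default_c_track())
  m2 <- compute_speed_and_mask(lin2$samples)
  expect_false(any(m2$running[201:(200 + slow_n2 - 1)]))
})

test_that("scripted mid-track pauses are masked for their scripted duration", {
  cells <- synth_cells(1, baseline_hz = 1)
  cfg <- synthetic_config(cells, n_laps = 3,
                          pause_schedule = data.frame(lap = c(1, 3),
                                                      pos_cm = 150,
                                                      duration_s = 2))
  sim <- simulate_session(cfg, seed = 11)
  prep <- prep_session(c(sim, list(config = cfg)))
  m <- prep$samples
  mid <- m$pos > 30 & m$pos < 270 & !is.na(m$trajectory_id)
  masked_t <- sum(!m$running[mid]) / 33
  expect_equal(masked_t, 4, tolerance = 2 / 33 * 2 + 0.1)
})

test_that("well zones are excluded by position regardless of speed", {
  s <- seq(2, 298, by = 1)
  lin <- linearize_and_segment(positions_from_s(s), default_c_track())
  m <- compute_speed_and_mask(lin$samples)
  expect_false(any(m$running[m$s < 10 | m$s > 290]))
  expect_true(all(m$running[!is.na(m$trajectory_id) & m$s > 11 & m$s < 289]))
})

test_that("masking is idempotent", {
  sim <- default_sim()
  prep <- prep_session(sim)
  again <- compute_speed_and_mask(prep$samples, 300)
  expect_identical(prep$samples$running, again$running)
  expect_equal(prep$samples$speed, again$speed)
})

test_that("lap intervals per trajectory are disjoint and inside the session", {
  sim <- default_sim()
  prep <- prep_session(sim)
  for (tr in c("traj1", "traj2")) {
    lp <- prep$laps[prep$laps$trajectory_id == tr, ]
    lp <- lp[order(lp$t_start), ]
    expect_true(all(lp$t_start < lp$t_end))
    if (nrow(lp) > 1)
      expect_true(all(lp$t_start[-1] >= lp$t_end[-nrow(lp)]))
  }
  expect_true(min(prep$laps$t_start) >= min(prep$samples$t))
  expect_true(max(prep$laps$t_end) <= max(prep$samples$t))
})

test_that("behavior metrics: laps per minute and mean running speed", {
  toy <- toy_traj(n_laps = 10, L = 300, dt = 1 / 33, speed = 35, gap_s = 0)
  # stretch session to exactly 5 minutes by appending a stationary tail
  tail_t <- seq(max(toy$samples$t) + 1 / 33, 300, by = 1 / 33)
  tail_df <- data.frame(t = tail_t, s = 2, pos = 2, hd = 0,
                        trajectory_id = NA, lap_index = NA, speed = 0,
                        running = FALSE)
  samples <- rbind(toy$samples, tail_df)
  samples$t[1] <- 0
  bm <- behavior_metrics(toy$laps, samples)
  expect_equal(bm$laps_per_min, 10 / 5, tolerance = 0.01)
  expect_equal(bm$mean_speed_cms, 35)
  expect_warning(behavior_metrics(toy$laps[0, ], samples), "no laps")
})

test_that("simulated running speed matches the configured mean", {
  sim <- default_sim()
  prep <- prep_session(sim)
  run <- prep$samples$running
  v <- prep$samples$speed[run]
  se <- sd(v) / sqrt(length(v) / 33)  # ~1 effective sample per second
  expect_lt(abs(mean(v) - 35), 3 * max(se, 0.5))
})
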