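# Hand-constructed linearized samples for unit tests: n_laps traversals of a
# track of length L at constant speed, all samples flagged running, evenly
# spaced in time with period dt. Laps are separated by `gap_s` of untracked
# trajectory (lap metadata set directly, bypassing geometry).
toy_traj <- function(n_laps = 2, L = 6, dt = 0.1, speed = 2,
                     trajectory = "traj1", gap_s = 1) {
  lap_dur <- L / speed
  n_per <- round(lap_dur / dt)
  samples <- list(); laps <- list()
  t0 <- 0
  for (l in seq_len(n_laps)) {
    tt <- t0 + (0:(n_per - 1)) * dt
    pos <- (0:(n_per - 1)) * speed * dt
    samples[[l]] <- data.frame(
      t = tt, s = if (trajectory == "traj1") pos else L - pos, pos = pos,
      hd = 0, trajectory_id = trajectory, lap_index = l, speed = speed,
      running = TRUE)
    laps[[l]] <- data.frame(trajectory_id = trajectory, lap_index = l,
                            t_start = tt[1], t_end = tt[n_per] + dt)
    t0 <- tt[n_per] + gap_s
  }
  list(samples = do.call(rbind, samples), laps = do.call(rbind, laps))
}

# rate_curve object built directly from a smoothed curve (for detector and
# correlogram tests on constructed curves)
toy_curve <- function(smoothed, bin_cm = 2, trajectory = "traj1") {
  n <- length(smoothed)
  structure(list(trajectory_id = trajectory, bin_cm = bin_cm,
                 bin_edges = seq(0, n * bin_cm, by = bin_cm), n_bins = n,
                 occupancy = rep(1, n), occ_prob = rep(1 / n, n),
                 rate = smoothed, smoothed_rate = smoothed,
                 per_lap_rates = matrix(smoothed, 1), mean_rate = mean(smoothed),
                 overall_rate = mean(smoothed), n_spikes = NA, n_laps = 1),
            class = "rate_curve")
}

gauss_bump <- function(n_bins, center_bin, sigma_bins, height) {
  height * exp(-((seq_len(n_bins) - center_bin)^2) / (2 * sigma_bins^2))
}

# default-condition simulator session cached across tests in one run
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cells <- rbind(
        synth_cells(3, region = "V1", baseline_hz = 2, prefix = "v"),
        synth_cells(3, region = "CA1", baseline_hz = 0.2, prefix = "c"))
      fields <- data.frame(
        cell_id = c("v_1", "v_2", "c_1", "c_2"),
        trajectory_id = "traj1",
        center_cm = c(100, 200, 104, 230), width_cm = 8,
        peak_hz = c(18, 15, 16, 14))
      pairs <- data.frame(cell_a = "v_1", cell_b = "c_1",
                          rho_gain = 0.8, rho_com = 0.5)
      cfg <- synthetic_config(cells, fields, pairs, n_laps = 14,
                              refine = 2L, master_seed = 42)
      cache <<- c(simulate_session(cfg, seed = 42), list(config = cfg))
    }
    cache
  }
})

# linearize+mask a simulated session with default parameters
prep_session <- function(sim) {
  lin <- linearize_and_segment(sim$session$positions, sim$config$path)
  samples <- compute_speed_and_mask(lin$samples,
                                    sim$config$track_length_cm)
  list(samples = samples, laps = lin$laps)
}
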