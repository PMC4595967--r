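#' Configuration for a synthetic session
#'
#' Describes a simulated back-and-forth running session with known ground
#' truth: trajectory kinematics, per-cell location-modulated Poisson firing
#' (multi-field Gaussian rate bumps over a non-zero baseline, with speed and
#' head-direction rate modulation), and lap-wise latent structure — a shared
#' multiplicative gain and a firing-location (COM) jitter whose between-cell
#' correlations are set per designated pair.
#'
#' @param cells data.frame with `cell_id`, `region`, `layer`, `day`,
#'   `baseline_hz` and optional `c_speed`, `c_hdir` modulation coefficients
#'   (order-1; head-direction deviation is scaled by 30 degrees).
#' @param fields optional data.frame with `cell_id`, `trajectory_id`,
#'   `center_cm`, `width_cm` (Gaussian sigma), `peak_hz`.
#' @param pairs optional data.frame with `cell_a`, `cell_b`, `rho_gain`,
#'   `rho_com` — latent correlations in `[-1, 1]` between the two cells'
#'   lap-wise gain and COM-jitter draws.
#' @param track_length_cm,n_laps,sampling_hz track length (cm), laps per
#'   trajectory, tracking rate (Hz).
#' @param mean_speed_cms,speed_sd_cms,lap_speed_sd_cms,speed_tau_s running
#'   speed model: within-lap Ornstein-Uhlenbeck noise (sd, time constant)
#'   around a per-lap target speed drawn around the session mean.
#' @param well_pause_s pause duration at each food well (s).
#' @param well_margin_cm food-well zone depth defining true lap boundaries
#'   (cm).
#' @param pause_schedule optional data.frame `lap`, `pos_cm`, `duration_s`
#'   of scripted mid-track stops (lap counted over all laps in order).
#' @param hd_noise_deg sd of head-direction deviation from the movement
#'   heading (degrees).
#' @param gain_sd sd of the lap-wise multiplicative field gain (gain is
#'   `max(0, 1 + gain_sd * z)`).
#' @param jitter_sd_cm sd of the lap-wise field-center jitter (cm).
#' @param refine integer time-grid refinement factor for spike generation
#'   (1 = the 33-Hz tracking grid; ~30 gives 1-ms resolution for
#'   cross-correlogram work).
#' @param path a [track_path()]; its length must equal `track_length_cm`.
#' @param master_seed default RNG seed for [simulate_session()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(cells, fields = NULL, pairs = NULL,
                             track_length_cm = 300, n_laps = 20,
                             sampling_hz = 33, mean_speed_cms = 35,
                             speed_sd_cms = 5, lap_speed_sd_cms = 3,
                             speed_tau_s = 1, well_pause_s = 2,
                             well_margin_cm = 10,
                             pause_schedule = NULL, hd_noise_deg = 3,
                             gain_sd = 0.7, jitter_sd_cm = 3, refine = 1L,
                             path = default_c_track(), master_seed = 1L) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "region", "baseline_hz") %in% names(cells)))
  if (mean_speed_cms <= 0) stop("mean speed must be positive")
  if (n_laps < 1) stop("need at least one lap per trajectory")
  if (abs(path$length - track_length_cm) > 1e-6)
    stop("path length does not match track_length_cm")
  if (!"layer" %in% names(cells)) cells$layer <- "unassigned"
  if (!"day" %in% names(cells)) cells$day <- 1L
  if (!"c_speed" %in% names(cells)) cells$c_speed <- 0
  if (!"c_hdir" %in% names(cells)) cells$c_hdir <- 0
  if (is.null(fields))
    fields <- data.frame(cell_id = character(), trajectory_id = character(),
                         center_cm = numeric(), width_cm = numeric(),
                         peak_hz = numeric())
  if (is.null(pairs))
    pairs <- data.frame(cell_a = character(), cell_b = character(),
                        rho_gain = numeric(), rho_com = numeric())
  if (nrow(pairs)) {
    stopifnot(all(abs(pairs$rho_gain) <= 1), all(abs(pairs$rho_com) <= 1))
    ids <- c(pairs$cell_a, pairs$cell_b)
    if (anyDuplicated(ids))
      stop("a cell may appear in at most one latent-correlation pair")
  }
  structure(list(cells = cells, fields = fields, pairs = pairs,
                 track_length_cm = track_length_cm, n_laps = n_laps,
                 sampling_hz = sampling_hz, mean_speed_cms = mean_speed_cms,
                 speed_sd_cms = speed_sd_cms,
                 lap_speed_sd_cms = lap_speed_sd_cms,
                 speed_tau_s = speed_tau_s, well_pause_s = well_pause_s,
                 well_margin_cm = well_margin_cm,
                 pause_schedule = pause_schedule,
                 hd_noise_deg = hd_noise_deg, gain_sd = gain_sd,
                 jitter_sd_cm = jitter_sd_cm, refine = as.integer(refine),
                 path = path, master_seed = master_seed),
            class = "synthetic_config")
}

#' Generate the position tracking of a synthetic session
#'
#' Simulates alternating end-to-end runs at the tracking rate: a pause at
#' each food well, then a traversal at Ornstein-Uhlenbeck-perturbed speed
#' around a per-lap target, with optional scripted mid-track stops. Head
#' direction follows the movement heading plus angular noise.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @return list with `positions` (tracking data.frame `t_s`, `x_cm`,
#'   `y_cm`, `hd_deg`), `laps` (true lap boundaries), and `state` (per
#'   sample: `t`, `s` arc length, `pos` running coordinate, `v` true speed,
#'   `trajectory_id`, `lap_index`, `hd_dev` head-direction deviation).
#' @export
generate_trajectory <- function(config, seed = config$master_seed) {
  with_seed(seed, generate_trajectory_impl(config))
}

generate_trajectory_impl <- function(config) {
  dt <- 1 / config$sampling_hz
  L <- config$track_length_cm
  margin <- 2  # resting position inside the well zone, cm from the end
  n_total <- 2L * config$n_laps
  t_list <- list()
  # accumulators
  S <- numeric(0); V <- numeric(0); TR <- character(0); LI <- integer(0)
  run_start_idx <- integer(n_total); run_end_idx <- integer(n_total)
  sched <- config$pause_schedule
  sched_used <- if (is.null(sched)) logical(0) else logical(nrow(sched))
  s_cur <- margin
  lapc <- c(traj1 = 0L, traj2 = 0L)
  for (k in seq_len(n_total)) {
    dir <- if (k %% 2L == 1L) 1 else -1
    tr <- if (dir > 0) "traj1" else "traj2"
    lapc[tr] <- lapc[tr] + 1L
    n_p <- max(1L, round(config$well_pause_s / dt))
    S <- c(S, rep(s_cur, n_p)); V <- c(V, rep(0, n_p))
    TR <- c(TR, rep(NA_character_, n_p)); LI <- c(LI, rep(NA_integer_, n_p))
    run_start_idx[k] <- length(S)  # last pause sample: lap departure
    v_target <- max(5, stats::rnorm(1, config$mean_speed_cms,
                                    config$lap_speed_sd_cms))
    v <- v_target
    target_s <- if (dir > 0) L - margin else margin
    sr <- numeric(0); vr <- numeric(0)
    while ((dir > 0 && s_cur < target_s) || (dir < 0 && s_cur > target_s)) {
      v <- v + (dt / config$speed_tau_s) * (v_target - v) +
        config$speed_sd_cms * sqrt(2 * dt / config$speed_tau_s) *
        stats::rnorm(1)
      v <- max(2, v)
      s_cur <- s_cur + dir * v * dt
      s_cur <- min(max(s_cur, margin / 2), L - margin / 2)
      sr <- c(sr, s_cur); vr <- c(vr, v)
      if (!is.null(sched)) {
        pos_now <- if (dir > 0) s_cur else L - s_cur
        hit <- which(!sched_used & sched$lap == k & sched$pos_cm <= pos_now)
        for (h in hit) {
          sched_used[h] <- TRUE
          n_stop <- round(sched$duration_s[h] / dt)
          sr <- c(sr, rep(s_cur, n_stop)); vr <- c(vr, rep(0, n_stop))
        }
      }
    }
    S <- c(S, sr); V <- c(V, vr)
    TR <- c(TR, rep(tr, length(sr))); LI <- c(LI, rep(lapc[[tr]], length(sr)))
    run_end_idx[k] <- length(S)
  }
  n <- length(S)
  t <- (seq_len(n) - 1L) * dt
  # true lap boundaries: last sample inside the departure well zone to the
  # first sample inside the arrival zone (s is monotone within each run)
  wm <- config$well_margin_cm
  t_start <- t_end <- numeric(n_total)
  for (k in seq_len(n_total)) {
    seg <- run_start_idx[k]:run_end_idx[k]
    dirp <- k %% 2L == 1L
    in_dep <- if (dirp) S[seg] < wm else S[seg] > L - wm
    in_arr <- if (dirp) S[seg] > L - wm else S[seg] < wm
    t_start[k] <- t[max(seg[in_dep])]
    t_end[k] <- t[min(seg[in_arr])]
  }
  laps <- data.frame(
    trajectory_id = rep(c("traj1", "traj2"), config$n_laps),
    t_start = t_start, t_end = t_end)
  laps$lap_index <- stats::ave(seq_len(n_total), laps$trajectory_id,
                               FUN = seq_along)
  laps <- laps[, c("trajectory_id", "lap_index", "t_start", "t_end")]
  pp <- path_point(config$path, S)
  dir_vec <- ifelse(!is.na(TR) & TR == "traj2", -1, 1)
  heading <- (pp$heading + ifelse(dir_vec < 0, 180, 0)) %% 360
  hd_dev <- stats::rnorm(n, 0, config$hd_noise_deg)
  hd <- (heading + hd_dev) %% 360
  pos <- ifelse(!is.na(TR) & TR == "traj2", L - S, S)
  list(positions = data.frame(t_s = t, x_cm = pp$x, y_cm = pp$y,
                              hd_deg = hd),
       laps = laps,
       state = data.frame(t = t, s = S, pos = pos, v = V,
                          trajectory_id = TR, lap_index = LI,
                          hd_dev = hd_dev))
}

#' Generate spike trains for a synthetic session
#'
#' Each cell fires as an inhomogeneous Poisson process realized by Bernoulli
#' thinning on the (optionally refined) time grid. The instantaneous rate is
#' `clip0( [baseline + gain_l * sum_f peak_f * N(pos; center_f + jitter_l,
#' width_f)] * (1 + c_speed*(v - vbar)/vbar + c_hdir*hd_dev/30) )`, with the
#' lap-wise gain and jitter drawn from latent Gaussians correlated within
#' designated pairs.
#'
#' @param config a [synthetic_config()].
#' @param traj result of [generate_trajectory()].
#' @param seed RNG seed.
#' @return list with `spikes` (named list of spike-time vectors) and
#'   `truth` (lap gains and jitters matrices, fields, pairs, seed).
#' @export
generate_spikes <- function(config, traj, seed = config$master_seed + 1L) {
  with_seed(seed, generate_spikes_impl(config, traj))
}

generate_spikes_impl <- function(config, traj) {
  st <- traj$state
  dt0 <- 1 / config$sampling_hz
  if (config$refine > 1L) {
    n <- nrow(st)
    k <- config$refine
    base <- rep(seq_len(n), each = k)
    frac <- rep((seq_len(k) - 1) / k, times = n)
    nxt <- pmin(base + 1L, n)
    same <- !is.na(st$lap_index[base]) & !is.na(st$lap_index[nxt]) &
      st$lap_index[base] == st$lap_index[nxt] &
      st$trajectory_id[base] == st$trajectory_id[nxt]
    pos <- ifelse(same, st$pos[base] + frac * (st$pos[nxt] - st$pos[base]),
                  st$pos[base])
    st <- data.frame(t = st$t[base] + frac * dt0, pos = pos,
                     v = st$v[base], trajectory_id = st$trajectory_id[base],
                     lap_index = st$lap_index[base],
                     hd_dev = st$hd_dev[base])
    dt <- dt0 / k
  } else dt <- dt0
  cells <- config$cells
  n_cells <- nrow(cells)
  ids <- as.character(cells$cell_id)
  # global lap counter aligned with traj$laps rows
  lp <- traj$laps
  glap <- rep(NA_integer_, nrow(st))
  for (g in seq_len(nrow(lp))) {
    m <- !is.na(st$trajectory_id) & st$trajectory_id == lp$trajectory_id[g] &
      st$lap_index == lp$lap_index[g]
    glap[m] <- g
  }
  n_glaps <- nrow(lp)
  correlated_latents <- function(rho_col) {
    Z <- matrix(stats::rnorm(n_cells * n_glaps), n_cells, n_glaps,
                dimnames = list(ids, NULL))
    if (nrow(config$pairs)) for (p in seq_len(nrow(config$pairs))) {
      a <- as.character(config$pairs$cell_a[p])
      b <- as.character(config$pairs$cell_b[p])
      rho <- config$pairs[[rho_col]][p]
      Z[b, ] <- rho * Z[a, ] + sqrt(1 - rho^2) * Z[b, ]
    }
    Z
  }
  gains <- pmax(1 + config$gain_sd * correlated_latents("rho_gain"), 0)
  jitters <- config$jitter_sd_cm * correlated_latents("rho_com")
  vbar <- config$mean_speed_cms
  in_lap <- !is.na(glap)
  gl <- ifelse(in_lap, glap, 1L)
  spikes <- vector("list", n_cells)
  names(spikes) <- ids
  n_capped <- 0L
  for (c_i in seq_len(n_cells)) {
    id <- ids[c_i]
    lam <- rep(cells$baseline_hz[c_i], nrow(st))
    ff <- config$fields[as.character(config$fields$cell_id) == id, ,
                        drop = FALSE]
    if (nrow(ff)) {
      bump <- numeric(nrow(st))
      for (f in seq_len(nrow(ff))) {
        m <- in_lap & st$trajectory_id == ff$trajectory_id[f]
        if (!any(m)) next
        jit <- jitters[id, gl]
        bump[m] <- bump[m] + ff$peak_hz[f] *
          exp(-(st$pos[m] - ff$center_cm[f] - jit[m])^2 /
                (2 * ff$width_cm[f]^2))
      }
      lam <- lam + ifelse(in_lap, gains[id, gl], 1) * bump
    }
    mod <- 1 + cells$c_speed[c_i] * (st$v - vbar) / vbar +
      cells$c_hdir[c_i] * st$hd_dev / 30
    lam <- pmax(ifelse(in_lap, lam * mod, cells$baseline_hz[c_i]), 0)
    p <- lam * dt
    over <- p > 0.95
    if (any(over)) {
      n_capped <- n_capped + sum(over)
      p[over] <- 0.95
    }
    fire <- stats::runif(length(p)) < p
    spikes[[c_i]] <- st$t[fire] + stats::runif(sum(fire)) * dt
  }
  if (n_capped > 0.2 * sum(in_lap))
    stop("spike probability capped on >20% of in-lap samples; ",
         "use a finer time grid (refine)")
  if (n_capped > 0)
    warning(n_capped, " samples had spike probability capped at 0.95")
  list(spikes = spikes,
       truth = list(gains = gains, jitters = jitters, lap_table = lp,
                    fields = config$fields, pairs = config$pairs,
                    cells = cells))
}

#' Simulate a full session with ground truth
#'
#' Runs [generate_trajectory()] and [generate_spikes()] from one master seed
#' and assembles a [track_session()]. Identical seeds give identical
#' sessions.
#'
#' @param config a [synthetic_config()].
#' @param seed master RNG seed.
#' @return list with `session` (a [track_session()]), `truth` (simulator
#'   ground truth: lap boundaries, gains, jitters, fields, pairs, seed) and
#'   `state` (the per-sample kinematic truth).
#' @export
simulate_session <- function(config, seed = config$master_seed) {
  traj <- generate_trajectory(config, seed)
  spk <- generate_spikes(config, traj, seed + 1000003L)
  cells <- config$cells[, c("cell_id", "region", "layer", "day")]
  sess <- track_session(traj$positions, spk$spikes, cells,
                        track_length_cm = config$track_length_cm)
  truth <- c(spk$truth, list(laps = traj$laps, seed = seed))
  list(session = sess, truth = truth, state = traj$state)
}

#' Quick cell-table builder
#'
#' Convenience constructor for simulator cell metadata.
#'
#' @param n number of cells.
#' @param region,layer,day,baseline_hz,c_speed,c_hdir recycled columns.
#' @param prefix cell-id prefix.
#' @return data.frame suitable for [synthetic_config()]'s `cells`.
#' @export
synth_cells <- function(n, region = "V1", layer = "L2/3", day = 1,
                        baseline_hz = 0.5, c_speed = 0, c_hdir = 0,
                        prefix = region) {
  data.frame(cell_id = paste0(prefix, "_", seq_len(n)), region = region,
             layer = layer, day = day, baseline_hz = baseline_hz,
             c_speed = c_speed, c_hdir = c_hdir)
}
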