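#' Linearize positions and segment laps
#'
#' Projects room-frame tracking onto the track path, expresses each sample as
#' cm along the running direction, and segments complete end-to-end laps.
#' The two trajectories are the two directed traversals of the same path:
#' `traj1` runs from arc length 0 to L, `traj2` from L to 0, and positions on
#' `traj2` are reported as `L - s` so that `pos` always increases in the
#' running direction.
#'
#' A lap starts at the last sample inside the departure food-well zone
#' (within `well_margin_cm` of a track end) and ends at the first sample
#' inside the opposite zone; turn-arounds that never reach the far well are
#' not laps.
#'
#' @param positions data.frame with `t_s`, `x_cm`, `y_cm`, `hd_deg` columns.
#' @param path a [track_path()].
#' @param well_margin_cm food-well zone depth at each track end (cm).
#' @return A list with `samples` (data.frame: `t`, `s` arc length, `pos`
#'   running-direction cm, `hd`, `trajectory_id`, `lap_index`) and `laps`
#'   (data.frame: `trajectory_id`, `lap_index`, `t_start`, `t_end`).
#' @export
linearize_and_segment <- function(positions, path, well_margin_cm = 10) {
  if (!inherits(path, "track_path")) stop("path must be a track_path")
  if (is.null(positions) || nrow(positions) < 2L) stop("need at least 2 position samples")
  if (any(diff(positions$t_s) <= 0)) stop("timestamps must be strictly increasing")
  L <- path$length
  s <- project_to_path(path, positions$x_cm, positions$y_cm)
  zone <- ifelse(s < well_margin_cm, "A", ifelse(s > L - well_margin_cm, "B", "M"))
  n <- length(s)

  traj <- rep(NA_character_, n)
  lapi <- rep(NA_integer_, n)
  laps <- list()
  cur_zone <- NA_character_
  idx_last <- NA_integer_
  counts <- c(traj1 = 0L, traj2 = 0L)
  for (i in seq_len(n)) {
    z <- zone[i]
    if (z == "M") next
    if (is.na(cur_zone) || z == cur_zone) {
      cur_zone <- z
      idx_last <- i
      next
    }
    # arrived at the opposite well: a complete lap
    tr <- if (cur_zone == "A") "traj1" else "traj2"
    counts[tr] <- counts[tr] + 1L
    laps[[length(laps) + 1L]] <- data.frame(
      trajectory_id = tr, lap_index = counts[[tr]],
      t_start = positions$t_s[idx_last], t_end = positions$t_s[i])
    traj[idx_last:i] <- tr
    lapi[idx_last:i] <- counts[[tr]]
    cur_zone <- z
    idx_last <- i
  }
  laps <- if (length(laps)) do.call(rbind, laps) else
    data.frame(trajectory_id = character(), lap_index = integer(),
               t_start = numeric(), t_end = numeric())
  pos <- ifelse(!is.na(traj) & traj == "traj2", L - s, s)
  samples <- data.frame(t = positions$t_s, s = s, pos = pos,
                        hd = positions$hd_deg,
                        trajectory_id = traj, lap_index = lapi)
  list(samples = samples, laps = laps)
}

#' Compute running speed and the active-running mask
#'
#' Speed is the forward-differenced arc-length distance between consecutive
#' samples (the last sample copies its predecessor). A sample is flagged
#' `running` only if it lies inside a lap, outside the food-well zones
#' (final `well_margin_cm` at each end), and outside any stopping interval,
#' defined as a maximal run of samples with speed below `speed_floor_cms`
#' spanning at least `stop_min_s` seconds. All downstream rate estimates use
#' only `running = TRUE` samples.
#'
#' @param samples `samples` data.frame from [linearize_and_segment()].
#' @param track_length_cm trajectory length L in cm.
#' @param well_margin_cm food-well exclusion depth (cm).
#' @param speed_floor_cms stopping-speed threshold (cm/s).
#' @param stop_min_s minimum stop duration to exclude (s).
#' @return `samples` with `speed` (cm/s) and `running` (logical) columns.
#' @export
compute_speed_and_mask <- function(samples, track_length_cm = 300,
                                   well_margin_cm = 10, speed_floor_cms = 6,
                                   stop_min_s = 0.5) {
  t <- samples$t
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  n <- nrow(samples)
  speed <- c(abs(diff(samples$s)) / diff(t), NA_real_)
  speed[n] <- speed[n - 1L]
  slow <- speed < speed_floor_cms
  stopped <- logical(n)
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    if (t[ends[k]] - t[starts[k]] >= stop_min_s)
      stopped[starts[k]:ends[k]] <- TRUE
  }
  in_well <- samples$s < well_margin_cm | samples$s > track_length_cm - well_margin_cm
  samples$speed <- speed
  samples$running <- !is.na(samples$trajectory_id) & !in_well & !stopped
  samples
}

#' Per-trajectory behavioral metrics
#'
#' Laps per minute (lap count over the session duration) and mean running
#' speed (over `running = TRUE` samples), per trajectory.
#'
#' @param laps laps data.frame from [linearize_and_segment()].
#' @param samples masked samples from [compute_speed_and_mask()].
#' @return data.frame with `trajectory_id`, `n_laps`, `laps_per_min`,
#'   `mean_speed_cms`.
#' @export
behavior_metrics <- function(laps, samples) {
  if (nrow(laps) == 0L) {
    warning("no laps; returning empty behavior table")
    return(data.frame(trajectory_id = character(), n_laps = integer(),
                      laps_per_min = numeric(), mean_speed_cms = numeric()))
  }
  session_min <- diff(range(samples$t)) / 60
  out <- lapply(split(laps, laps$trajectory_id), function(lp) {
    tr <- lp$trajectory_id[1]
    run <- samples$running & !is.na(samples$trajectory_id) &
      samples$trajectory_id == tr
    data.frame(trajectory_id = tr, n_laps = nrow(lp),
               laps_per_min = nrow(lp) / session_min,
               mean_speed_cms = mean(samples$speed[run]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
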