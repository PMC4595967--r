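# run expr with a local RNG state seeded by `seed`; the caller's RNG stream
# is left untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-(cell, trajectory) sub-seed below 2^31, FNV-1a style over
# the id string so results do not depend on cell ordering
cell_seed <- function(master_seed, cell_id, trajectory = "") {
  s <- paste0(cell_id, "|", trajectory)
  h <- 10570841  # arbitrary odd basis; modulus keeps products exact doubles
  for (ch in utf8ToInt(s)) h <- ((bitwXor(as.integer(h), ch)) * 16777619) %% 67108859
  as.integer((h + as.numeric(master_seed)) %% 2147483629)
}

#' Circularly shift spikes within one lap
#'
#' Each spike at time P maps to `T1 + ((P + R - T1) mod (T2 - T1))`, where
#' `[T1, T2]` are the lap boundaries. This preserves the lap's spike count
#' and (up to the single wrap point) its inter-spike intervals, while
#' decoupling spikes from position.
#'
#' @param times spike times within `[t_start, t_end]`.
#' @param t_start,t_end lap boundaries (s).
#' @param shift circular shift R in `[0, t_end - t_start)` seconds.
#' @return Sorted shifted spike times in `[t_start, t_end)`.
#' @export
circular_shuffle <- function(times, t_start, t_end, shift) {
  dur <- t_end - t_start
  if (shift < 0 || shift >= dur) stop("shift must lie in [0, lap duration)")
  sort(t_start + ((times + shift - t_start) %% dur))
}

#' Spatial modulation index from a circular-shuffle null
#'
#' Shuffles a cell's spike train `n_shuffles` times by circularly shifting
#' spikes within each lap by an independent uniform random interval,
#' recomputes the spatial information content (or rate) of each shuffled
#' train, and z-scores the actual value against the shuffle distribution:
#' `SMI = (a - m) / s`. Cells with `SMI > threshold` (default 2.325, the
#' 99th percentile of the chance level) are classified location-responsive.
#'
#' @param times spike times (s) of one cell.
#' @param laps laps data.frame from [linearize_and_segment()].
#' @param samples masked samples from [compute_speed_and_mask()].
#' @param trajectory `"traj1"` or `"traj2"`.
#' @param n_shuffles number of shuffles.
#' @param seed RNG seed for this cell's shuffle stream.
#' @param basis `"sic"` (default) or `"sir"`.
#' @param threshold location-responsiveness cutoff on the z-score.
#' @param track_length_cm,bin_cm,smooth_sigma_bins rate-curve parameters.
#' @return list with `smi`, `actual`, `null_mean`, `null_sd`, `null_values`,
#'   `location_responsive`. `smi` is `NA` (not responsive) when the null
#'   standard deviation is zero or the actual value undefined.
#' @export
compute_smi <- function(times, laps, samples, trajectory, n_shuffles = 100,
                        seed = 1L, basis = c("sic", "sir"), threshold = 2.325,
                        track_length_cm = 300, bin_cm = 2,
                        smooth_sigma_bins = 2) {
  basis <- match.arg(basis)
  ctx <- traj_ctx(samples, laps, trajectory, track_length_cm, bin_cm,
                  smooth_sigma_bins)
  compute_smi_ctx(ctx, times, n_shuffles, seed, basis, threshold)
}

compute_smi_ctx <- function(ctx, times, n_shuffles = 100, seed = 1L,
                            basis = "sic", threshold = 2.325) {
  stopifnot(n_shuffles >= 2)
  p <- ifelse(ctx$occupancy > 0, ctx$occupancy / sum(ctx$occupancy), 0)
  value_of <- function(tt) {
    sb <- bin_spikes_ctx(ctx, tt)
    counts <- tabulate(sb$bin, nbins = ctx$n_bins)
    x <- curve_from_counts(ctx, counts)
    v <- sic_from_curve(x, p)
    if (basis == "sir" && !is.na(v)) v <- v * sum(p * x)
    v
  }
  lp <- ctx$laps
  # restrict to spikes inside this trajectory's laps, remembering the lap
  k <- nrow(lp)
  lap_of <- rep(NA_integer_, length(times))
  for (l in seq_len(k)) {
    inl <- times >= lp$t_start[l] & times <= lp$t_end[l]
    lap_of[inl] <- l
  }
  keep <- !is.na(lap_of)
  tt0 <- times[keep]
  lap0 <- lap_of[keep]
  actual <- value_of(tt0)
  dur <- lp$t_end - lp$t_start
  null_values <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      R <- stats::runif(k, 0, dur)
      shifted <- lp$t_start[lap0] +
        ((tt0 + R[lap0] - lp$t_start[lap0]) %% dur[lap0])
      value_of(shifted)
    }, numeric(1))
  })
  m <- mean(null_values)
  s <- stats::sd(null_values)
  smi <- if (is.na(actual) || is.na(s) || s == 0) NA_real_ else (actual - m) / s
  list(smi = smi, actual = actual, null_mean = m, null_sd = s,
       null_values = null_values,
       location_responsive = !is.na(smi) && smi > threshold)
}
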