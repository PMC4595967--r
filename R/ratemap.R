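# Truncated-renormalized Gaussian smoothing matrix: rows sum to 1, kernel cut
# at +/- 4 sigma with no reflection or wrap (track ends are physical walls).
gauss_kernel_matrix <- function(n_bins, sigma_bins) {
  if (sigma_bins <= 0) return(diag(n_bins))
  h <- ceiling(4 * sigma_bins)
  K <- matrix(0, n_bins, n_bins)
  offs <- -h:h
  w <- stats::dnorm(offs / sigma_bins)
  for (i in seq_len(n_bins)) {
    j <- i + offs
    ok <- j >= 1 & j <= n_bins
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

# Precomputed per-trajectory binning context shared by the rate curve and the
# shuffle null (occupancy never changes under circular shuffling, only spike
# positions do).
traj_ctx <- function(samples, laps, trajectory, track_length_cm = 300,
                     bin_cm = 2, smooth_sigma_bins = 2) {
  lp <- laps[laps$trajectory_id == trajectory, , drop = FALSE]
  if (nrow(lp) < 1L) stop("no laps on ", trajectory)
  lp <- lp[order(lp$lap_index), , drop = FALSE]
  sel <- which(!is.na(samples$trajectory_id) &
                 samples$trajectory_id == trajectory)
  if (!length(sel)) stop("no samples on ", trajectory)
  t_sub <- samples$t[sel]
  pos_sub <- samples$pos[sel]
  lap_sub <- samples$lap_index[sel]
  run_sub <- samples$running[sel]
  n <- length(sel)
  dt <- c(diff(t_sub), NA_real_)
  same_lap <- c(lap_sub[-1] == lap_sub[-n], FALSE)
  dt[!same_lap] <- stats::median(dt[same_lap], na.rm = TRUE)

  n_bins <- ceiling(track_length_cm / bin_cm)
  bin <- pmin(pmax(floor(pos_sub / bin_cm) + 1L, 1L), n_bins)

  occ <- numeric(n_bins)
  rmask <- run_sub
  occ_tab <- tapply(dt[rmask], bin[rmask], sum)
  occ[as.integer(names(occ_tab))] <- occ_tab

  n_laps <- nrow(lp)
  lap_occ <- matrix(0, n_laps, n_bins)
  for (l in seq_len(n_laps)) {
    m <- rmask & lap_sub == lp$lap_index[l]
    if (any(m)) {
      ot <- tapply(dt[m], bin[m], sum)
      lap_occ[l, as.integer(names(ot))] <- ot
    }
  }
  list(trajectory_id = trajectory, laps = lp, track_length_cm = track_length_cm,
       bin_cm = bin_cm, n_bins = n_bins, smooth_sigma_bins = smooth_sigma_bins,
       K = gauss_kernel_matrix(n_bins, smooth_sigma_bins),
       t = t_sub, pos = pos_sub, lap = lap_sub, running = run_sub,
       hd = samples$hd[sel], speed = samples$speed[sel],
       same_lap = same_lap, occupancy = occ, lap_occ = lap_occ,
       total_time = sum(occ))
}

# Assign spike times to spatial bins: position interpolated linearly between
# the two tracking samples enclosing each spike (33-Hz tracking is coarser
# than spike timing); only spikes on running samples count.
bin_spikes_ctx <- function(ctx, times) {
  if (!length(times))
    return(data.frame(bin = integer(), lap = integer(), pos = numeric()))
  j <- findInterval(times, ctx$t)
  ok <- j >= 1L & j < length(ctx$t) & ctx$same_lap[pmax(j, 1L)] &
    ctx$running[pmax(j, 1L)]
  j <- j[ok]
  tt <- times[ok]
  frac <- (tt - ctx$t[j]) / (ctx$t[j + 1L] - ctx$t[j])
  pos <- ctx$pos[j] + frac * (ctx$pos[j + 1L] - ctx$pos[j])
  bin <- pmin(pmax(floor(pos / ctx$bin_cm) + 1L, 1L), ctx$n_bins)
  data.frame(bin = bin, lap = ctx$lap[j], pos = pos)
}

curve_from_counts <- function(ctx, counts) {
  raw <- ifelse(ctx$occupancy > 0, counts / ifelse(ctx$occupancy > 0,
                                                   ctx$occupancy, 1), 0)
  as.numeric(ctx$K %*% raw)
}

#' Occupancy-normalized firing rate curve
#'
#' Bins running-epoch occupancy and spikes into uniform spatial bins along
#' one trajectory, divides to obtain the raw rate curve, and smooths with a
#' truncated-renormalized Gaussian kernel. Per-lap curves are computed
#' identically within each lap.
#'
#' @param times spike times (s) of one cell.
#' @param laps laps data.frame from [linearize_and_segment()].
#' @param samples masked samples from [compute_speed_and_mask()].
#' @param trajectory `"traj1"` or `"traj2"`.
#' @param track_length_cm trajectory length (cm).
#' @param bin_cm spatial bin width (cm).
#' @param smooth_sigma_bins Gaussian kernel sigma, in bins.
#' @return An object of class `rate_curve`: bin edges, occupancy (s/bin),
#'   occupancy probability over occupied bins, raw and smoothed rates (Hz),
#'   per-lap smoothed rate matrix, smoothed-curve mean rate, overall rate and
#'   spike count.
#' @export
compute_rate_curve <- function(times, laps, samples, trajectory,
                               track_length_cm = 300, bin_cm = 2,
                               smooth_sigma_bins = 2) {
  ctx <- traj_ctx(samples, laps, trajectory, track_length_cm, bin_cm,
                  smooth_sigma_bins)
  rate_curve_from_ctx(ctx, times)
}

rate_curve_from_ctx <- function(ctx, times) {
  if (ctx$total_time <= 0) stop("zero total occupancy on trajectory")
  sb <- bin_spikes_ctx(ctx, times)
  counts <- tabulate(sb$bin, nbins = ctx$n_bins)
  smoothed <- curve_from_counts(ctx, counts)
  occupied <- ctx$occupancy > 0
  p <- ifelse(occupied, ctx$occupancy / sum(ctx$occupancy), 0)
  n_laps <- nrow(ctx$laps)
  per_lap <- matrix(0, n_laps, ctx$n_bins)
  for (l in seq_len(n_laps)) {
    li <- ctx$laps$lap_index[l]
    cl <- tabulate(sb$bin[sb$lap == li], nbins = ctx$n_bins)
    occ_l <- ctx$lap_occ[l, ]
    raw_l <- ifelse(occ_l > 0, cl / ifelse(occ_l > 0, occ_l, 1), 0)
    per_lap[l, ] <- as.numeric(ctx$K %*% raw_l)
  }
  raw <- ifelse(occupied, counts / ifelse(occupied, ctx$occupancy, 1), 0)
  structure(list(
    trajectory_id = ctx$trajectory_id, bin_cm = ctx$bin_cm,
    bin_edges = seq(0, ctx$n_bins * ctx$bin_cm, by = ctx$bin_cm),
    n_bins = ctx$n_bins, occupancy = ctx$occupancy, occ_prob = p,
    rate = raw, smoothed_rate = smoothed, per_lap_rates = per_lap,
    mean_rate = sum(p * smoothed),
    overall_rate = nrow(sb) / ctx$total_time,
    n_spikes = nrow(sb), n_laps = n_laps), class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat("<rate_curve>", x$trajectory_id, ":", x$n_bins, "bins x", x$bin_cm,
      "cm,", x$n_laps, "laps,", x$n_spikes, "spikes, overall",
      sprintf("%.2f Hz, peak %.2f Hz\n", x$overall_rate,
              max(x$smoothed_rate)))
  invisible(x)
}

#' Skaggs spatial information content and rate
#'
#' Spatial information content `SIc = sum_i p_i (x_i / r) log2(x_i / r)`
#' (bits/spike), where `p_i` is the occupancy probability of bin i, `x_i` the
#' firing rate there and `r = sum_i p_i x_i` the mean rate; bins with zero
#' rate contribute 0 (the `x log x -> 0` limit). Spatial information rate is
#' `SIr = SIc * r` (bits/s).
#'
#' @param curve a [compute_rate_curve()] result.
#' @param use `"smoothed"` (default) or `"raw"` curve.
#' @return list with `sic` (bits/spike), `sir` (bits/s) and `mean_rate` (Hz);
#'   `NA` values when the mean rate is zero.
#' @export
spatial_information <- function(curve, use = c("smoothed", "raw")) {
  use <- match.arg(use)
  x <- if (use == "smoothed") curve$smoothed_rate else curve$rate
  p <- curve$occ_prob
  occ <- p > 0
  r <- sum(p[occ] * x[occ])
  if (r <= 0) return(list(sic = NA_real_, sir = NA_real_, mean_rate = 0))
  xi <- x[occ]
  pi <- p[occ]
  pos <- xi > 0
  sic <- sum(pi[pos] * (xi[pos] / r) * log2(xi[pos] / r))
  list(sic = sic, sir = sic * r, mean_rate = r)
}

# internal fast path used by the shuffle null: SIc from a smoothed curve
sic_from_curve <- function(x, p) {
  occ <- p > 0
  r <- sum(p[occ] * x[occ])
  if (r <= 0) return(NA_real_)
  xi <- x[occ]
  pi <- p[occ]
  pos <- xi > 0
  sum(pi[pos] * (xi[pos] / r) * log2(xi[pos] / r))
}

#' Lap-pair spatial stability
#'
#' Pearson correlation between the smoothed per-lap rate curves of every
#' unordered lap pair, over occupied bins; stability is the mean across
#' pairs. Pairs where either lap's curve has zero variance are skipped.
#'
#' @param curve a [compute_rate_curve()] result.
#' @return list with `stability` (mean lap-pair correlation; `NA` when fewer
#'   than 2 usable laps), `n_pairs_used`, `n_pairs_skipped`.
#' @export
spatial_stability <- function(curve) {
  occ <- curve$occ_prob > 0
  M <- curve$per_lap_rates[, occ, drop = FALSE]
  n_laps <- nrow(M)
  if (n_laps < 2L)
    return(list(stability = NA_real_, n_pairs_used = 0L, n_pairs_skipped = 0L))
  sds <- apply(M, 1, stats::sd)
  used <- 0L
  skipped <- 0L
  acc <- 0
  for (i in seq_len(n_laps - 1L)) for (j in (i + 1L):n_laps) {
    if (sds[i] == 0 || sds[j] == 0) { skipped <- skipped + 1L; next }
    acc <- acc + stats::cor(M[i, ], M[j, ])
    used <- used + 1L
  }
  list(stability = if (used > 0) acc / used else NA_real_,
       n_pairs_used = used, n_pairs_skipped = skipped)
}

#' Activity and putative-interneuron classification
#'
#' A cell is active on a trajectory if its overall running-epoch rate exceeds
#' `active_hz`. CA1 cells above `interneuron_hz` are flagged as putative
#' interneurons and excluded downstream; high-rate V1 cells are retained.
#'
#' @param overall_rate mean firing rate (Hz) over running epochs.
#' @param region `"V1"` or `"CA1"`.
#' @param active_hz activity threshold (Hz).
#' @param interneuron_hz CA1 putative-interneuron threshold (Hz).
#' @return list with logicals `active` and `putative_interneuron`.
#' @export
classify_active <- function(overall_rate, region, active_hz = 0.5,
                            interneuron_hz = 5) {
  list(active = overall_rate > active_hz,
       putative_interneuron = region == "CA1" & overall_rate > interneuron_hz)
}
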