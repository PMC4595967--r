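#' Detect firing fields on a rate curve
#'
#' The baseline rate is the `baseline_pct`-th percentile of the smoothed
#' curve; it is subtracted (negatives clipped to 0). Local maxima of the
#' remaining curve whose height exceeds both `peak_min_hz` and
#' `peak_baseline_frac` of the baseline become candidate fields. Field
#' boundaries extend outward from the peak to the first bin where the
#' subtracted rate drops to `boundary_frac` of the subtracted peak (10% of
#' the peak rate). Fields separated by a gap smaller than `merge_gap_cm` are
#' merged (interval union, the larger peak kept), repeatedly until stable.
#'
#' Intended for trajectory-active CA1 cells and location-responsive V1 cells.
#'
#' @param curve a [compute_rate_curve()] result.
#' @param baseline_pct percentile (0-100) defining the baseline rate.
#' @param peak_min_hz absolute floor for a field peak (Hz, baseline
#'   subtracted).
#' @param peak_baseline_frac peak must also exceed this fraction of the
#'   baseline rate.
#' @param boundary_frac boundary threshold as a fraction of the subtracted
#'   peak.
#' @param merge_gap_cm fields closer than this are merged (cm).
#' @return data.frame with `start_cm`, `end_cm` (half-open), `peak_pos_cm`,
#'   `peak_rate_hz` (baseline-subtracted), `length_cm`, `dominant`.
#' @export
detect_fields <- function(curve, baseline_pct = 30, peak_min_hz = 1,
                          peak_baseline_frac = 0.2, boundary_frac = 0.1,
                          merge_gap_cm = 4) {
  x <- curve$smoothed_rate
  bw <- curve$bin_cm
  n <- length(x)
  empty <- data.frame(start_cm = numeric(), end_cm = numeric(),
                      peak_pos_cm = numeric(), peak_rate_hz = numeric(),
                      length_cm = numeric(), dominant = logical())
  if (all(x <= 0)) return(empty)
  baseline <- as.numeric(stats::quantile(x, baseline_pct / 100))
  y <- pmax(x - baseline, 0)
  is_peak <- vapply(seq_len(n), function(i) {
    y[i] > 0 &&
      (i == 1L || y[i] >= y[i - 1L]) && (i == n || y[i] >= y[i + 1L])
  }, logical(1))
  cand <- which(is_peak & y > pmax(peak_min_hz, peak_baseline_frac * baseline))
  if (!length(cand)) return(empty)

  fields <- lapply(cand, function(pk) {
    thr <- boundary_frac * y[pk]
    lb <- pk
    while (lb > 1L && y[lb - 1L] > thr) lb <- lb - 1L
    rb <- pk
    while (rb < n && y[rb + 1L] > thr) rb <- rb + 1L
    data.frame(start_cm = (lb - 1L) * bw, end_cm = rb * bw,
               peak_pos_cm = (pk - 0.5) * bw, peak_rate_hz = y[pk])
  })
  fields <- do.call(rbind, fields)
  # two candidate maxima inside the same interval are one field
  key <- paste(fields$start_cm, fields$end_cm)
  fields <- do.call(rbind, lapply(split(fields, key), function(f)
    f[which.max(f$peak_rate_hz), , drop = FALSE]))
  fields <- fields[order(fields$start_cm), , drop = FALSE]

  repeat {
    if (nrow(fields) < 2L) break
    gaps <- fields$start_cm[-1] - fields$end_cm[-nrow(fields)]
    k <- which(gaps < merge_gap_cm)
    if (!length(k)) break
    i <- k[1]
    a <- fields[i, ]
    b <- fields[i + 1, ]
    keep_peak <- if (a$peak_rate_hz >= b$peak_rate_hz) a else b
    merged <- data.frame(start_cm = min(a$start_cm, b$start_cm),
                         end_cm = max(a$end_cm, b$end_cm),
                         peak_pos_cm = keep_peak$peak_pos_cm,
                         peak_rate_hz = keep_peak$peak_rate_hz)
    fields <- rbind(if (i > 1) fields[seq_len(i - 1), ], merged,
                    if (i + 1 < nrow(fields))
                      fields[seq(i + 2, nrow(fields)), ])
  }
  fields$length_cm <- fields$end_cm - fields$start_cm
  fields$dominant <- seq_len(nrow(fields)) ==
    which.max(fields$peak_rate_hz)
  rownames(fields) <- NULL
  fields
}

#' Spatial distribution of field peaks
#'
#' Counts field peaks per spatial bin along a trajectory, smooths the
#' histogram with a Gaussian window, and normalizes by the total field count.
#'
#' @param peak_pos_cm field peak positions (cm, running coordinate).
#' @param track_length_cm trajectory length (cm).
#' @param bin_cm bin width (cm).
#' @param smooth_sigma_bins Gaussian sigma in bins.
#' @return list with `bin_centers_cm`, `counts`, `smoothed`, `normalized`
#'   (smoothed curve divided by total field count).
#' @export
field_distribution <- function(peak_pos_cm, track_length_cm = 300,
                               bin_cm = 2, smooth_sigma_bins = 2) {
  n_bins <- ceiling(track_length_cm / bin_cm)
  bin <- pmin(pmax(floor(peak_pos_cm / bin_cm) + 1L, 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  K <- gauss_kernel_matrix(n_bins, smooth_sigma_bins)
  smoothed <- as.numeric(K %*% counts)
  list(bin_centers_cm = (seq_len(n_bins) - 0.5) * bin_cm, counts = counts,
       smoothed = smoothed,
       normalized = if (sum(counts) > 0) smoothed / sum(counts) else smoothed)
}

#' Sliding-lag Pearson cross-correlogram
#'
#' Pearson correlation between `x[i]` and `y[i + k]` over the overlapping
#' support at every integer-bin lag `k`. Positive lags mean features of `y`
#' sit at larger coordinates than matching features of `x`.
#'
#' @param x,y numeric vectors on identical binning.
#' @param max_lag_bins largest |lag| in bins.
#' @param min_overlap minimum overlapping length for a lag to be computed.
#' @return data.frame with `lag_bins`, `r`, `n` (overlap length).
#' @export
sliding_pearson <- function(x, y, max_lag_bins, min_overlap = 3L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  lags <- -max_lag_bins:max_lag_bins
  out <- data.frame(lag_bins = lags, r = NA_real_, n = 0L)
  for (i in seq_along(lags)) {
    k <- lags[i]
    ix <- if (k >= 0) seq_len(n - k) else seq(1 - k, n)
    iy <- ix + k
    if (length(ix) < min_overlap) next
    xs <- x[ix]
    ys <- y[iy]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    out$r[i] <- stats::cor(xs, ys)
    out$n[i] <- length(ix)
  }
  out
}

#' Cross-correlogram between two field-distribution curves
#'
#' Pearson correlation between two smoothed field-distribution (or rate)
#' curves at each integer-bin position lag, with the peak lag and its
#' Pearson p-value.
#'
#' @param curve_a,curve_b smoothed curves on identical binning.
#' @param max_lag_cm largest |lag| in cm.
#' @param bin_cm bin width (cm).
#' @return list with `lag_cm`, `r`, `peak_lag_cm`, `peak_r`, `peak_p`.
#' @export
field_distribution_xcorr <- function(curve_a, curve_b, max_lag_cm = 50,
                                     bin_cm = 2) {
  if (stats::sd(curve_a) == 0 || stats::sd(curve_b) == 0)
    stop("zero-variance curve")
  cc <- sliding_pearson(curve_a, curve_b, round(max_lag_cm / bin_cm))
  ok <- !is.na(cc$r)
  pk <- which(ok)[which.max(cc$r[ok])]
  peak_p <- pearson_p(cc$r[pk], cc$n[pk])
  list(lag_cm = cc$lag_bins * bin_cm, r = cc$r,
       peak_lag_cm = cc$lag_bins[pk] * bin_cm, peak_r = cc$r[pk],
       peak_p = peak_p)
}

# two-sided Pearson p from r and n (t distribution), as cor.test computes it
pearson_p <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  r <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Bidirectional (prospective/retrospective) firing classification
#'
#' A cell responsive on both running directions is bidirectional if the
#' cross-correlogram between its two directions' rate curves — with the
#' opposite direction's curve flipped into the first direction's physical
#' coordinate — has its peak within `window_cm` at a Pearson p below `alpha`
#' (0.05 Bonferroni-adjusted for the 51 lags tested). A positive peak lag
#' means the cell fires before reaching the shared landmark on both
#' directions (prospective); a negative lag means after (retrospective).
#'
#' @param curve_traj1,curve_traj2 [compute_rate_curve()] results for the two
#'   opposite trajectories.
#' @param responsive_both is the cell location-responsive on both
#'   trajectories?
#' @param window_cm half-width of the admissible peak-lag window (cm).
#' @param alpha per-lag significance level.
#' @return list with `class` (`"prospective"`, `"retrospective"` or
#'   `"none"`), `peak_lag_cm`, `peak_r`, `peak_p`, `reason`.
#' @export
classify_bidirectional <- function(curve_traj1, curve_traj2,
                                   responsive_both = TRUE, window_cm = 50,
                                   alpha = 0.00098) {
  if (!responsive_both)
    return(list(class = "none", peak_lag_cm = NA_real_, peak_r = NA_real_,
                peak_p = NA_real_, reason = "not responsive on both trajectories"))
  x <- curve_traj1$smoothed_rate
  # trajectory 2 runs the path backwards; flipping re-expresses its curve in
  # trajectory 1's physical coordinate
  y <- rev(curve_traj2$smoothed_rate)
  bw <- curve_traj1$bin_cm
  # search the full lag range so an out-of-window global peak is rejected
  # rather than shadowed by a secondary in-window one
  cc <- sliding_pearson(x, y, length(x) - 10L, min_overlap = 10L)
  ok <- !is.na(cc$r)
  if (!any(ok))
    return(list(class = "none", peak_lag_cm = NA_real_, peak_r = NA_real_,
                peak_p = NA_real_, reason = "degenerate curves"))
  pk <- which(ok)[which.max(cc$r[ok])]
  lag_cm <- cc$lag_bins[pk] * bw
  p <- pearson_p(cc$r[pk], cc$n[pk])
  if (abs(lag_cm) > window_cm)
    cls <- "none"
  else if (is.na(p) || p >= alpha)
    cls <- "none"
  else cls <- if (lag_cm > 0) "prospective" else "retrospective"
  reason <- if (cls == "none") {
    if (abs(lag_cm) > window_cm) "peak outside window" else "peak not significant"
  } else ""
  list(class = cls, peak_lag_cm = lag_cm, peak_r = cc$r[pk], peak_p = p,
       reason = reason)
}
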