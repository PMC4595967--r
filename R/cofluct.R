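# circular helpers (degrees)
wrap180 <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

circ_mean_deg <- function(deg) {
  deg <- deg[!is.na(deg)]
  if (!length(deg)) return(NA_real_)
  r <- deg * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

#' Fractional overlap of two firing fields
#'
#' Overlap length divided by the shorter field's length (the strictest
#' symmetric reading of "overlapped by at least 50%").
#'
#' @param a,b length-2 numeric `c(start_cm, end_cm)` intervals.
#' @param denom `"shorter"` (default) or `"longer"` field as denominator.
#' @return overlap fraction in `[0, 1]`.
#' @export
field_overlap_frac <- function(a, b, denom = c("shorter", "longer")) {
  denom <- match.arg(denom)
  ov <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  lens <- c(a[2] - a[1], b[2] - b[1])
  d <- if (denom == "shorter") min(lens) else max(lens)
  if (d <= 0) return(0)
  ov / d
}

dominant_field <- function(fields) {
  if (!nrow(fields)) return(NULL)
  f <- if ("dominant" %in% names(fields) && any(fields$dominant))
    fields[which(fields$dominant)[1], ] else
      fields[which.max(fields$peak_rate_hz), ]
  c(f$start_cm, f$end_cm)
}

#' Classify a cell pair and choose its probed spatial intervals
#'
#' Overlapping: both cells location-responsive, at least one field pair
#' overlapping by `overlap_min_frac`, and the pair's spike cross-correlogram
#' has a peak of at least `xcorr_min_peak` within `xcorr_window_s`; the
#' probed fields are the overlapped pair with the maximum sum of peak rates.
#' Non-overlapping: both responsive but no field pair overlaps by the
#' criterion; each cell is probed in its dominant field. Non-responsive: one
#' cell responsive (probed in its dominant field), the other not; the
#' non-responsive cell is probed in a copy of that field shifted by a random
#' distance yielding an overlap uniform in `[overlap_min_frac, 1]`.
#' Responsive pairs whose fields overlap but whose cross-correlogram fails
#' the peak criterion fit neither definition and come back `unclassified`.
#'
#' @param fields_a,fields_b [detect_fields()] data.frames.
#' @param responsive_a,responsive_b location-responsiveness flags.
#' @param xcorr optional [normalized_xcorr()] result for the pair.
#' @param overlap_min_frac minimum field overlap fraction.
#' @param xcorr_min_peak,xcorr_window_s cross-correlogram peak criterion.
#' @param track_length_cm trajectory length (cm).
#' @param seed RNG seed for the non-responsive probe shift.
#' @param denom overlap denominator rule, see [field_overlap_frac()].
#' @return list with `class` (`overlapping`, `non_overlapping`,
#'   `non_responsive`, `unclassified`, `none`), `interval_a`, `interval_b`
#'   (`c(start, end)` cm), `overlap_frac`.
#' @export
classify_pair <- function(fields_a, fields_b, responsive_a, responsive_b,
                          xcorr = NULL, overlap_min_frac = 0.5,
                          xcorr_min_peak = 8, xcorr_window_s = 0.2,
                          track_length_cm = 300, seed = NULL,
                          denom = "shorter") {
  has_a <- responsive_a && nrow(fields_a) > 0
  has_b <- responsive_b && nrow(fields_b) > 0
  none <- list(class = "none", interval_a = NULL, interval_b = NULL,
               overlap_frac = NA_real_)
  if (has_a && has_b) {
    best <- NULL
    best_sum <- -Inf
    max_frac <- 0
    for (i in seq_len(nrow(fields_a))) for (j in seq_len(nrow(fields_b))) {
      fa <- c(fields_a$start_cm[i], fields_a$end_cm[i])
      fb <- c(fields_b$start_cm[j], fields_b$end_cm[j])
      fr <- field_overlap_frac(fa, fb, denom)
      max_frac <- max(max_frac, fr)
      if (fr >= overlap_min_frac) {
        s <- fields_a$peak_rate_hz[i] + fields_b$peak_rate_hz[j]
        if (s > best_sum) {
          best_sum <- s
          best <- list(interval_a = fa, interval_b = fb, overlap_frac = fr)
        }
      }
    }
    if (is.null(best))
      return(list(class = "non_overlapping",
                  interval_a = dominant_field(fields_a),
                  interval_b = dominant_field(fields_b),
                  overlap_frac = max_frac))
    xc_ok <- !is.null(xcorr) && !is.na(xcorr$peak_value) &&
      xcorr$peak_value >= xcorr_min_peak &&
      abs(xcorr$peak_time_s) <= xcorr_window_s + 1e-12
    if (!xc_ok) return(c(list(class = "unclassified"), best))
    return(c(list(class = "overlapping"), best))
  }
  if (has_a == has_b) return(none)  # neither usable
  f <- if (has_a) dominant_field(fields_a) else dominant_field(fields_b)
  len <- f[2] - f[1]
  draw <- function() {
    u <- stats::runif(1, overlap_min_frac, 1)
    sgn <- sample(c(-1, 1), 1)
    shift <- sgn * (1 - u) * len
    if (f[1] + shift < 0 || f[2] + shift > track_length_cm) shift <- -shift
    list(interval = f + shift, frac = u)
  }
  sh <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (has_a)
    list(class = "non_responsive", interval_a = f, interval_b = sh$interval,
         overlap_frac = sh$frac)
  else
    list(class = "non_responsive", interval_a = sh$interval, interval_b = f,
         overlap_frac = sh$frac)
}

#' Lap-by-lap within-interval firing rate, COM and behavioral covariates
#'
#' For each lap of a trajectory: the firing rate of spikes inside the probed
#' spatial interval (spike count over in-interval running time), the center
#' of mass (mean linearized position) of those spikes, the mean running
#' speed through the interval, and the lap's mean head direction. Laps with
#' no in-interval running time get `NA` rate; laps with no spikes get `NA`
#' COM.
#'
#' @param times spike times (s) of one cell.
#' @param laps laps data.frame from [linearize_and_segment()].
#' @param samples masked samples from [compute_speed_and_mask()].
#' @param trajectory `"traj1"` or `"traj2"`.
#' @param interval `c(start_cm, end_cm)` probed spatial interval.
#' @param ctx optional precomputed binning context (internal reuse).
#' @return data.frame with `lap`, `n_spikes`, `time_in_s`, `rate_hz`,
#'   `com_cm`, `speed_cms`, `hdir_deg` and attribute `dhdir_deg` column
#'   (head direction minus the circular mean across laps, wrapped to
#'   `(-180, 180]`).
#' @export
lap_fluctuations <- function(times, laps, samples, trajectory, interval,
                             ctx = NULL, track_length_cm = 300) {
  if (is.null(ctx))
    ctx <- traj_ctx(samples, laps, trajectory, track_length_cm)
  sb <- bin_spikes_ctx(ctx, times)
  sb <- sb[sb$pos >= interval[1] & sb$pos < interval[2], , drop = FALSE]
  lp <- ctx$laps
  in_int <- ctx$running & ctx$pos >= interval[1] & ctx$pos < interval[2]
  dt <- c(diff(ctx$t), 0)
  dt[!ctx$same_lap] <- stats::median(dt[ctx$same_lap])
  out <- lapply(seq_len(nrow(lp)), function(l) {
    li <- lp$lap_index[l]
    m <- in_int & ctx$lap == li
    time_in <- sum(dt[m])
    spk <- sb[sb$lap == li, , drop = FALSE]
    data.frame(lap = li, n_spikes = nrow(spk), time_in_s = time_in,
               rate_hz = if (time_in > 0) nrow(spk) / time_in else NA_real_,
               com_cm = if (nrow(spk)) mean(spk$pos) else NA_real_,
               speed_cms = if (any(m)) mean(ctx$speed[m]) else NA_real_,
               hdir_deg = circ_mean_deg(ctx$hd[m]))
  })
  out <- do.call(rbind, out)
  mu <- circ_mean_deg(out$hdir_deg)
  out$dhdir_deg <- wrap180(out$hdir_deg - mu)
  out
}

#' Lap-wise deviations from the across-lap mean
#'
#' @param x per-lap values (`NA` allowed).
#' @return `x - mean(x, na.rm = TRUE)`; the included laps sum to 0.
#' @export
delta_series <- function(x) x - mean(x, na.rm = TRUE)

#' Pearson correlation between two lap-wise fluctuation series
#'
#' Laps where either series is `NA` are dropped pairwise. Correlations are
#' flagged missing below `min_laps` usable laps or for constant series.
#'
#' @param da,db lap-wise fluctuation series.
#' @param min_laps minimum number of paired laps.
#' @return list with `r`, `p`, `n`.
#' @export
pair_correlation <- function(da, db, min_laps = 10) {
  ok <- stats::complete.cases(da, db)
  n <- sum(ok)
  if (n < min_laps || stats::sd(da[ok]) == 0 || stats::sd(db[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(da[ok], db[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Regress behavioral covariates out of a fluctuation series
#'
#' Ordinary least squares of the lap-wise fluctuation on lap speed and head
#' direction deviation (with intercept); the residual is the modified
#' fluctuation series, uncorrelated with either covariate by construction.
#'
#' @param x lap-wise fluctuation series (`NA` allowed).
#' @param V lap speeds (cm/s).
#' @param D lap head-direction deviations (degrees).
#' @return residual series aligned with `x` (`NA` where `x` is `NA`).
#' @export
regress_out_behavior <- function(x, V, D) {
  fit <- stats::lm(x ~ V + D, na.action = stats::na.exclude)
  if (anyNA(stats::coef(fit)[-1]))
    warning("collinear covariates; aliased term dropped")
  as.numeric(stats::residuals(fit))
}

#' Full co-fluctuation record for one probed pair
#'
#' Builds both cells' lap tables in their probed intervals, forms the
#' lap-wise fluctuation series in within-field rate and COM, correlates them
#' across laps, and repeats after regressing lap speed and head-direction
#' deviation out of each cell's series.
#'
#' @param times_a,times_b spike times of the two cells.
#' @param interval_a,interval_b probed `c(start, end)` intervals (cm).
#' @param laps,samples,trajectory as in [lap_fluctuations()].
#' @param min_laps minimum paired laps for any correlation.
#' @param ctx optional precomputed binning context.
#' @return list with the two lap tables (`lap_a`, `lap_b`) and a one-row
#'   data.frame `stats` holding `n_laps`, `r_drate`, `p_drate`, `r_dcom`,
#'   `p_dcom` and their modified (`*_mod`) counterparts.
#' @export
pair_cofluctuation <- function(times_a, times_b, interval_a, interval_b,
                               laps, samples, trajectory, min_laps = 10,
                               ctx = NULL, track_length_cm = 300) {
  if (is.null(ctx))
    ctx <- traj_ctx(samples, laps, trajectory, track_length_cm)
  la <- lap_fluctuations(times_a, laps, samples, trajectory, interval_a, ctx)
  lb <- lap_fluctuations(times_b, laps, samples, trajectory, interval_b, ctx)
  da_r <- delta_series(la$rate_hz)
  db_r <- delta_series(lb$rate_hz)
  da_c <- delta_series(la$com_cm)
  db_c <- delta_series(lb$com_cm)
  cr <- pair_correlation(da_r, db_r, min_laps)
  cc <- pair_correlation(da_c, db_c, min_laps)
  mod <- function(d, lt) {
    if (all(is.na(d))) return(d)
    regress_out_behavior(d, lt$speed_cms, lt$dhdir_deg)
  }
  crm <- pair_correlation(mod(da_r, la), mod(db_r, lb), min_laps)
  ccm <- pair_correlation(mod(da_c, la), mod(db_c, lb), min_laps)
  list(lap_a = la, lap_b = lb,
       stats = data.frame(n_laps = cr$n,
                          r_drate = cr$r, p_drate = cr$p,
                          r_dcom = cc$r, p_dcom = cc$p,
                          r_drate_mod = crm$r, p_drate_mod = crm$p,
                          r_dcom_mod = ccm$r, p_dcom_mod = ccm$p))
}

#' Population COM shift relative to its stabilized value
#'
#' For cells with enough laps, the per-lap COM change is taken relative to
#' the cell's stabilized COM (the mean over `stab_laps`, laps 21-25 by
#' default); the population mean change per lap and the least-squares slope
#' over the early laps (`fit_laps`) quantify systematic backward shift.
#'
#' @param com_matrix cells x laps matrix of per-lap COM (cm; `NA` allowed).
#' @param stab_laps lap indices defining the stabilized COM.
#' @param fit_laps lap indices for the regression of COM change on lap.
#' @return list with `per_lap` (data.frame: `lap`, `mean_change_cm`, `se`,
#'   `n_cells`), `slope_cm_per_lap`, `slope_p`, `n_cells`. Empty output with
#'   a warning when no cell qualifies.
#' @export
com_shift_curve <- function(com_matrix, stab_laps = 21:25, fit_laps = 1:10) {
  need <- max(stab_laps)
  if (is.null(dim(com_matrix))) com_matrix <- matrix(com_matrix, nrow = 1)
  ok <- ncol(com_matrix) >= need &
    apply(com_matrix, 1, function(r) any(!is.na(r[stab_laps])))
  if (ncol(com_matrix) < need) ok <- rep(FALSE, nrow(com_matrix))
  M <- com_matrix[ok, , drop = FALSE]
  if (!nrow(M)) {
    warning("no cells with enough laps for COM-shift analysis")
    return(list(per_lap = data.frame(lap = integer(),
                                     mean_change_cm = numeric(),
                                     se = numeric(), n_cells = integer()),
                slope_cm_per_lap = NA_real_, slope_p = NA_real_,
                n_cells = 0L))
  }
  stab <- rowMeans(M[, stab_laps, drop = FALSE], na.rm = TRUE)
  chg <- M - stab
  per_lap <- data.frame(
    lap = seq_len(ncol(M)),
    mean_change_cm = colMeans(chg, na.rm = TRUE),
    se = apply(chg, 2, function(x) stats::sd(x, na.rm = TRUE) /
                 sqrt(sum(!is.na(x)))),
    n_cells = colSums(!is.na(chg)))
  y <- per_lap$mean_change_cm[fit_laps]
  fit <- stats::lm(y ~ fit_laps)
  sm <- summary(fit)$coefficients
  list(per_lap = per_lap,
       slope_cm_per_lap = unname(stats::coef(fit)[2]),
       slope_p = if (nrow(sm) > 1) sm[2, 4] else NA_real_,
       n_cells = nrow(M))
}
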