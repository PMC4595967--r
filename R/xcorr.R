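#' Poisson-normalized spike-count cross-correlogram
#'
#' For each time lag, counts spikes of train Q falling within a window of
#' width `bin_ms` centered at each P spike plus the lag:
#' `C(dT) = sum_i #{Q in [P_i + dT - B/2, P_i + dT + B/2]}`. The count is
#' normalized by the count expected were both trains homogeneous Poisson,
#' `m = M * N * B / T` (M, N spike counts; T the total included time), as
#' `(C - m) / sqrt(m)`, which makes the measure insensitive to firing rate.
#' A pair is highly significant when the peak within
#' `[-peak_window_ms, peak_window_ms]` exceeds `sig_threshold`.
#'
#' @param p,q spike-time vectors (s), restricted to running epochs.
#' @param total_time_s total included (running) time T in seconds.
#' @param bin_ms count-window width B (ms).
#' @param max_lag_ms largest displayed |lag| (ms).
#' @param peak_window_ms peak search half-window (ms).
#' @param sig_threshold normalized-count threshold for significance.
#' @param normalizer `"poisson"` for `m = M*N*B/T`; `"printed"` for the
#'   literal `m = M*N/B` with B in seconds (dimensionally inconsistent,
#'   exposed for comparison only).
#' @return An object of class `spike_xcorr`: `lag_ms`, `normalized` values,
#'   `peak_value`, `peak_time_s`, `highly_significant`, `m`.
#' @export
normalized_xcorr <- function(p, q, total_time_s, bin_ms = 10,
                             max_lag_ms = 500, peak_window_ms = 200,
                             sig_threshold = 8,
                             normalizer = c("poisson", "printed")) {
  normalizer <- match.arg(normalizer)
  M <- length(p)
  N <- length(q)
  if (M == 0L || N == 0L)
    return(structure(list(lag_ms = numeric(), normalized = numeric(),
                          peak_value = NA_real_, peak_time_s = NA_real_,
                          highly_significant = FALSE, m = NA_real_),
                     class = "spike_xcorr"))
  if (total_time_s <= 0) stop("total_time_s must be positive")
  B <- bin_ms / 1000
  q <- sort(q)
  lags <- seq(-max_lag_ms, max_lag_ms, by = bin_ms) / 1000
  counts <- vapply(lags, function(dT) {
    hi <- p + dT + B / 2
    lo <- p + dT - B / 2
    sum(findInterval(hi, q) - findInterval(lo, q, left.open = TRUE))
  }, numeric(1))
  m <- if (normalizer == "poisson") M * N * B / total_time_s else M * N / B
  z <- (counts - m) / sqrt(m)
  inwin <- abs(lags) <= peak_window_ms / 1000 + 1e-12
  pk <- which(inwin)[which.max(z[inwin])]
  structure(list(lag_ms = lags * 1000, normalized = z,
                 peak_value = z[pk], peak_time_s = lags[pk],
                 highly_significant = z[pk] > sig_threshold &&
                   abs(lags[pk]) <= peak_window_ms / 1000 + 1e-12,
                 m = m),
            class = "spike_xcorr")
}

#' @export
print.spike_xcorr <- function(x, ...) {
  cat("<spike_xcorr> peak", sprintf("%.2f at %+.0f ms", x$peak_value,
                                    x$peak_time_s * 1000),
      if (isTRUE(x$highly_significant)) "(highly significant)" else "", "\n")
  invisible(x)
}

#' Sign bias of cross-correlogram peak times
#'
#' Exact two-sided binomial test of the fraction of positive peak times
#' against 0.5. Zero peak times are excluded.
#'
#' @param peak_times_s signed peak times (s) of highly significant pairs.
#' @return list with `n`, `n_positive`, `fraction_positive`, `p_value`.
#' @export
peak_time_bias <- function(peak_times_s) {
  pt <- peak_times_s[peak_times_s != 0]
  if (!length(pt)) stop("no nonzero peak times")
  npos <- sum(pt > 0)
  bt <- stats::binom.test(npos, length(pt), p = 0.5,
                          alternative = "two.sided")
  list(n = length(pt), n_positive = npos,
       fraction_positive = npos / length(pt), p_value = bt$p.value)
}

#' Spike times on running samples
#'
#' Restricts a spike train to spikes whose enclosing tracking sample is
#' flagged running, and reports the total running time — the inputs the
#' normalized cross-correlogram expects.
#'
#' @param times spike times (s).
#' @param samples masked samples from [compute_speed_and_mask()].
#' @param trajectory optional trajectory restriction.
#' @return list with `times` (filtered) and `total_time_s`.
#' @export
running_spikes <- function(times, samples, trajectory = NULL) {
  run <- samples$running
  if (!is.null(trajectory))
    run <- run & !is.na(samples$trajectory_id) &
      samples$trajectory_id == trajectory
  j <- findInterval(times, samples$t)
  ok <- j >= 1L & j <= nrow(samples) & run[pmax(j, 1L)]
  dt <- c(diff(samples$t), stats::median(diff(samples$t)))
  list(times = times[ok], total_time_s = sum(dt[run]))
}
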