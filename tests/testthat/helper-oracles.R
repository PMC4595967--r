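# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

oracle_sic <- function(occupancy, rates) {
  tot <- sum(occupancy)
  r <- 0
  for (i in seq_along(rates)) if (occupancy[i] > 0)
    r <- r + (occupancy[i] / tot) * rates[i]
  if (r <= 0) return(NA_real_)
  s <- 0
  for (i in seq_along(rates)) {
    if (occupancy[i] <= 0 || rates[i] <= 0) next
    p <- occupancy[i] / tot
    s <- s + p * (rates[i] / r) * log(rates[i] / r, base = 2)
  }
  s
}

oracle_sliding_pearson <- function(x, y, max_lag) {
  n <- length(x)
  out <- data.frame(lag = -max_lag:max_lag, r = NA_real_)
  for (row in seq_len(nrow(out))) {
    k <- out$lag[row]
    xs <- c(); ys <- c()
    for (i in seq_len(n)) {
      j <- i + k
      if (j >= 1 && j <= n) { xs <- c(xs, x[i]); ys <- c(ys, y[j]) }
    }
    if (length(xs) >= 3 && sd(xs) > 0 && sd(ys) > 0)
      out$r[row] <- sum((xs - mean(xs)) * (ys - mean(ys))) /
        ((length(xs) - 1) * sd(xs) * sd(ys))
  }
  out
}

# two-sided exact binomial p by tail summation (the small-p-mass definition)
oracle_binom_p <- function(k, n, p0 = 0.5) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# raw spike-count cross-correlation at one lag, by nested loops
oracle_xcorr_count <- function(p, q, dT, B) {
  cnt <- 0
  for (pi in p) for (qi in q)
    if (qi >= pi + dT - B / 2 && qi <= pi + dT + B / 2) cnt <- cnt + 1
  cnt
}

# independent circular-shuffle SMI implementation (plain loops throughout);
# mirrors the published procedure but shares no code with compute_smi()
oracle_smi <- function(times, laps, samples, trajectory, n_shuffles, seed,
                       L = 300, bin_cm = 2, sigma = 2) {
  lp <- laps[laps$trajectory_id == trajectory, ]
  lp <- lp[order(lp$lap_index), ]
  sel <- which(!is.na(samples$trajectory_id) &
                 samples$trajectory_id == trajectory)
  ts <- samples$t[sel]; ps <- samples$pos[sel]
  lapv <- samples$lap_index[sel]; run <- samples$running[sel]
  n <- length(sel)
  nb <- ceiling(L / bin_cm)
  dts <- rep(NA_real_, n)
  for (i in seq_len(n - 1)) if (lapv[i + 1] == lapv[i]) dts[i] <- ts[i + 1] - ts[i]
  dts[is.na(dts)] <- median(dts, na.rm = TRUE)
  occ <- rep(0, nb)
  for (i in seq_len(n)) if (run[i]) {
    b <- min(max(floor(ps[i] / bin_cm) + 1, 1), nb)
    occ[b] <- occ[b] + dts[i]
  }
  h <- ceiling(4 * sigma)
  smooth1 <- function(x) {
    out <- numeric(nb)
    for (i in seq_len(nb)) {
      ws <- 0; acc <- 0
      for (o in -h:h) {
        j <- i + o
        if (j < 1 || j > nb) next
        w <- dnorm(o / sigma)
        ws <- ws + w; acc <- acc + w * x[j]
      }
      out[i] <- acc / ws
    }
    out
  }
  sic_of <- function(spk) {
    counts <- rep(0, nb)
    for (s in spk) {
      j <- NA
      for (i in seq_len(n - 1)) if (ts[i] <= s && s < ts[i + 1]) { j <- i; break }
      if (is.na(j) || lapv[j] != lapv[j + 1] || !run[j]) next
      pos <- ps[j] + (ps[j + 1] - ps[j]) * (s - ts[j]) / (ts[j + 1] - ts[j])
      b <- min(max(floor(pos / bin_cm) + 1, 1), nb)
      counts[b] <- counts[b] + 1
    }
    raw <- ifelse(occ > 0, counts / pmax(occ, 1e-300), 0)
    oracle_sic(occ, smooth1(raw))
  }
  inlap <- rep(NA_integer_, length(times))
  for (l in seq_len(nrow(lp)))
    inlap[times >= lp$t_start[l] & times <= lp$t_end[l]] <- l
  tt <- times[!is.na(inlap)]
  lap0 <- inlap[!is.na(inlap)]
  actual <- sic_of(tt)
  dur <- lp$t_end - lp$t_start
  set.seed(seed)
  null_vals <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    R <- runif(nrow(lp), 0, dur)
    shifted <- numeric(length(tt))
    for (i in seq_along(tt)) {
      l <- lap0[i]
      shifted[i] <- lp$t_start[l] + ((tt[i] + R[l] - lp$t_start[l]) %% dur[l])
    }
    null_vals[s] <- sic_of(shifted)
  }
  (actual - mean(null_vals)) / sd(null_vals)
}
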