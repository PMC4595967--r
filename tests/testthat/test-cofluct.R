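mk_fields <- function(...) {
  ivs <- list(...)
  do.call(rbind, lapply(ivs, function(iv)
    data.frame(start_cm = iv[1], end_cm = iv[2],
               peak_pos_cm = mean(iv[1:2]), peak_rate_hz = iv[3],
               length_cm = iv[2] - iv[1], dominant = FALSE)))
}

fake_xc <- function(peak, t_peak) {
  structure(list(peak_value = peak, peak_time_s = t_peak,
                 highly_significant = peak > 8 && abs(t_peak) <= 0.2),
            class = "spike_xcorr")
}

test_that("overlap fraction uses the shorter field as denominator", {
  expect_equal(field_overlap_frac(c(100, 140), c(110, 150)), 30 / 40)
  expect_equal(field_overlap_frac(c(100, 140), c(110, 170)), 30 / 40)
  expect_equal(field_overlap_frac(c(0, 10), c(20, 30)), 0)
  expect_equal(field_overlap_frac(c(100, 140), c(110, 170), denom = "longer"),
               30 / 60)
})

test_that("75%-overlapping fields with a strong xcorr classify as overlapping", {
  fa <- mk_fields(c(100, 140, 10))
  fb <- mk_fields(c(110, 150, 8))
  pc <- classify_pair(fa, fb, TRUE, TRUE, fake_xc(9, 0.04))
  expect_equal(pc$class, "overlapping")
  expect_equal(pc$overlap_frac, 0.75)
  expect_equal(pc$interval_a, c(100, 140))
  expect_equal(pc$interval_b, c(110, 150))
})

test_that("disjoint fields are non-overlapping regardless of the xcorr", {
  fa <- mk_fields(c(20, 60, 10))
  fb <- mk_fields(c(150, 200, 8))
  pc <- classify_pair(fa, fb, TRUE, TRUE, fake_xc(20, 0))
  expect_equal(pc$class, "non_overlapping")
  expect_equal(pc$interval_a, c(20, 60))
  expect_equal(pc$interval_b, c(150, 200))
})

test_that("overlapped fields failing the xcorr criterion are unclassified", {
  fa <- mk_fields(c(100, 140, 10))
  fb <- mk_fields(c(110, 150, 8))
  expect_equal(classify_pair(fa, fb, TRUE, TRUE, fake_xc(4, 0))$class,
               "unclassified")
  expect_equal(classify_pair(fa, fb, TRUE, TRUE, fake_xc(12, 0.35))$class,
               "unclassified")
  expect_equal(classify_pair(fa, fb, TRUE, TRUE, NULL)$class, "unclassified")
})

test_that("the most dominant overlapped field pair is probed", {
  fa <- mk_fields(c(20, 60, 3), c(100, 140, 10))
  fb <- mk_fields(c(25, 65, 2), c(110, 150, 8))
  pc <- classify_pair(fa, fb, TRUE, TRUE, fake_xc(9, 0))
  expect_equal(pc$interval_a, c(100, 140))  # sum 18 beats sum 5
})

test_that("responsive + unresponsive gives a shifted probe with 50-100% overlap", {
  fa <- mk_fields(c(100, 140, 10))
  for (sd in 1:25) {
    pc <- classify_pair(fa, empty_flds(), TRUE, FALSE, NULL, seed = sd)
    expect_equal(pc$class, "non_responsive")
    expect_equal(pc$interval_a, c(100, 140))
    got <- field_overlap_frac(pc$interval_a, pc$interval_b)
    expect_equal(got, pc$overlap_frac, tolerance = 1e-9)
    expect_gte(pc$overlap_frac, 0.5)
    expect_lte(pc$overlap_frac, 1)
    expect_equal(diff(pc$interval_b), 40)
  }
  # symmetric order
  pc2 <- classify_pair(empty_flds(), fa, FALSE, TRUE, NULL, seed = 3)
  expect_equal(pc2$class, "non_responsive")
  expect_equal(pc2$interval_b, c(100, 140))
  # neither responsive: skipped
  expect_equal(classify_pair(empty_flds(), empty_flds(), FALSE, FALSE)$class,
               "none")
})

test_that("lap fluctuation tables: rates, COM and zero-mean deltas", {
  toy <- toy_traj(n_laps = 2, L = 300, dt = 0.05, speed = 30)
  # lap 1: spikes at pos 102, 104, 109 cm (t = pos/30); lap 2: at 100 and 110
  t2 <- toy$samples$t[toy$samples$lap_index == 2][1]
  spk <- c(c(102, 104, 109) / 30, t2 + c(100, 110) / 30)
  lt <- lap_fluctuations(spk, toy$laps, toy$samples, "traj1", c(95, 115))
  expect_equal(lt$n_spikes, c(3, 2))
  expect_equal(lt$com_cm, c(105, 105), tolerance = 0.15)
  expect_equal(lt$rate_hz, lt$n_spikes / lt$time_in_s)
  expect_equal(lt$time_in_s, c(20, 20) / 30, tolerance = 0.06)
  d <- delta_series(lt$rate_hz)
  expect_equal(mean(d), 0, tolerance = 1e-12)
  expect_equal(delta_series(c(4, 6)), c(-1, 1))
})

test_that("pair correlation handles perfect, inverse and degenerate series", {
  x <- rnorm(12)
  expect_equal(pair_correlation(x, x)$r, 1)
  expect_equal(pair_correlation(x, -x)$r, -1)
  expect_true(is.na(pair_correlation(x, rep(1, 12))$r))
  expect_true(is.na(pair_correlation(x[1:5], x[1:5])$r))  # < 10 laps
  short <- pair_correlation(c(x[1:9], NA, NA, NA), x)
  expect_true(is.na(short$r))
})

test_that("behavior regression residuals are orthogonal to the covariates", {
  set.seed(31)
  V <- rnorm(30, 35, 3)
  D <- rnorm(30, 0, 10)
  x1 <- 0.5 * V
  r1 <- regress_out_behavior(x1, V, D)
  expect_equal(max(abs(r1)), 0, tolerance = 1e-10)
  x2 <- 0.3 * V - 0.2 * D + rnorm(30, 0, 0.5)
  r2 <- regress_out_behavior(x2, V, D)
  expect_lt(abs(cor(r2, V)), 1e-10)
  expect_lt(abs(cor(r2, D)), 1e-10)
  fit <- lm(x2 ~ V + D)
  se <- summary(fit)$coefficients[, 2]
  expect_lt(abs(coef(fit)["V"] - 0.3), 3 * se["V"])
  expect_lt(abs(coef(fit)["D"] + 0.2), 3 * se["D"])
  # pure noise: residual is essentially the centered series
  x3 <- rnorm(30)
  r3 <- regress_out_behavior(x3, V, D)
  expect_gt(cor(r3, x3 - mean(x3)), 0.9)
  expect_warning(regress_out_behavior(x2, V, 2 * V), "collinear")
})

test_that("OLS recovery of injected speed/head-direction coefficients", {
  set.seed(32)
  ok <- replicate(50, {
    V <- rnorm(40, 35, 4)
    D <- rnorm(40, 0, 12)
    x <- 0.3 * V - 0.2 * D + rnorm(40, 0, 1)
    fit <- summary(lm(x ~ V + D))$coefficients
    abs(fit["V", 1] - 0.3) < 3 * fit["V", 2] &
      abs(fit["D", 1] + 0.2) < 3 * fit["D", 2]
  })
  expect_gt(mean(ok), 0.9)
})

test_that("COM shift curve recovers injected linear drift", {
  set.seed(33)
  n_cells <- 100
  n_laps <- 25
  drift <- -0.5
  M <- t(replicate(n_cells, {
    base <- runif(1, 80, 220)
    base + drift * pmin(seq_len(n_laps), 15) + rnorm(n_laps, 0, 1.5)
  }))
  cs <- com_shift_curve(M)
  expect_equal(cs$n_cells, n_cells)
  expect_equal(cs$slope_cm_per_lap, drift, tolerance = 0.1)
  # stationary fields: flat near-zero curve
  M0 <- t(replicate(50, 150 + rnorm(n_laps, 0, 1)))
  cs0 <- com_shift_curve(M0)
  expect_lt(abs(cs0$slope_cm_per_lap), 0.1)
  # cells with fewer than 25 laps are excluded
  expect_warning(out <- com_shift_curve(M[, 1:20]), "no cells")
  expect_equal(out$n_cells, 0L)
})

test_that("circular helpers wrap and average directions correctly", {
  expect_equal(wrap180(350), -10)
  expect_equal(wrap180(190), -170)
  expect_equal(wrap180(180), 180)
  expect_equal(sin(circ_mean_deg(c(350, 10)) * pi / 180), 0, tolerance = 1e-9)
  d <- wrap180(c(350, 10) - circ_mean_deg(c(350, 10)))
  expect_equal(sort(d), c(-10, 10), tolerance = 1e-9)
})

empty_flds <- function() cofluct:::empty_fields()
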