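test_that("a constant curve has no firing fields", {
  expect_equal(nrow(detect_fields(toy_curve(rep(5, 150)))), 0L)
  expect_equal(nrow(detect_fields(toy_curve(rep(0, 150)))), 0L)
})

test_that("a single Gaussian bump yields one field with 10%-of-peak bounds", {
  y <- gauss_bump(150, 75, 5, 10)
  f <- detect_fields(toy_curve(y))
  expect_equal(nrow(f), 1L)
  expect_equal(f$peak_pos_cm, (75 - 0.5) * 2)
  # baseline is ~0 here, so boundaries sit where the curve first drops to
  # <= 1 Hz (10% of the 10-Hz subtracted peak)
  bl <- as.numeric(quantile(y, 0.3))
  ysub <- pmax(y - bl, 0)
  above <- which(ysub > 0.1 * max(ysub))
  expect_equal(f$start_cm, (min(above) - 1) * 2)
  expect_equal(f$end_cm, max(above) * 2)
  expect_true(f$dominant)
  expect_equal(f$length_cm, f$end_cm - f$start_cm)
})

test_that("two bumps merge when their boundary gap is under 4 cm", {
  # sigma-3-bin bumps; 10% boundaries reach ~+/-6.4 bins from each peak
  near <- gauss_bump(150, 60, 3, 10) + gauss_bump(150, 74, 3, 10)
  f_near <- detect_fields(toy_curve(near))
  expect_equal(nrow(f_near), 1L)  # gap < 4 cm -> merged
  far <- gauss_bump(150, 60, 3, 10) + gauss_bump(150, 78, 3, 10)
  f_far <- detect_fields(toy_curve(far))
  expect_equal(nrow(f_far), 2L)   # gap >= 4 cm -> kept separate
  gap <- f_far$start_cm[2] - f_far$end_cm[1]
  expect_gte(gap, 4)
})

test_that("merged fields keep the larger peak and union interval", {
  y <- gauss_bump(150, 60, 3, 10) + gauss_bump(150, 73, 3, 6)
  f1 <- detect_fields(toy_curve(gauss_bump(150, 60, 3, 10)))
  f <- detect_fields(toy_curve(y))
  if (nrow(f) == 1L) {
    expect_equal(f$peak_pos_cm, (60 - 0.5) * 2, tolerance = 2)
    expect_gt(f$end_cm, f1$end_cm)
  }
  expect_true(all(f$start_cm < f$end_cm))
})

test_that("peaks must exceed 1 Hz and 20% of baseline after subtraction", {
  weak <- gauss_bump(150, 75, 5, 0.8)   # subtracted peak < 1 Hz
  expect_equal(nrow(detect_fields(toy_curve(weak))), 0L)
  # high baseline: peak of 2 Hz over baseline 15 fails 20%-of-baseline
  y <- rep(15, 150) + gauss_bump(150, 75, 5, 2)
  expect_equal(nrow(detect_fields(toy_curve(y))), 0L)
  y2 <- rep(15, 150) + gauss_bump(150, 75, 5, 4)
  expect_equal(nrow(detect_fields(toy_curve(y2))), 1L)
})

test_that("post-merge fields are disjoint with gaps of at least 4 cm", {
  set.seed(14)
  for (rep in 1:20) {
    y <- rep(0, 150)
    for (k in 1:sample(2:5, 1))
      y <- y + gauss_bump(150, sample(10:140, 1), runif(1, 2, 6),
                          runif(1, 2, 15))
    f <- detect_fields(toy_curve(y))
    if (nrow(f) > 1) {
      f <- f[order(f$start_cm), ]
      expect_true(all(f$start_cm[-1] - f$end_cm[-nrow(f)] >= 4))
    }
    expect_equal(sum(f$dominant), if (nrow(f)) 1L else 0L)
  }
})

test_that("field distribution counts, smooths and normalizes peak positions", {
  fd <- field_distribution(c(10, 11, 50, 250), track_length_cm = 300)
  expect_equal(sum(fd$counts), 4)
  expect_equal(fd$counts[6], 2)  # 10 and 11 cm share bin [10,12)
  expect_equal(sum(fd$normalized), sum(fd$smoothed) / 4)
})

test_that("distribution cross-correlogram: identity peaks at 0, shift at +2 cm", {
  set.seed(3)
  y <- as.numeric(cofluct:::gauss_kernel_matrix(150, 2) %*% runif(150))
  self <- field_distribution_xcorr(y, y, max_lag_cm = 20)
  expect_equal(self$peak_lag_cm, 0)
  expect_equal(self$peak_r, 1, tolerance = 1e-12)
  shifted <- c(y[-1], y[1])  # y moved one bin toward 0; features of y2 at +1 bin
  sh <- field_distribution_xcorr(shifted, y, max_lag_cm = 20)
  expect_equal(sh$peak_lag_cm, 2)
  expect_error(field_distribution_xcorr(rep(1, 10), runif(10)), "variance")
})

test_that("sliding Pearson matches the brute-force oracle at every lag", {
  set.seed(4)
  x <- runif(150)
  y <- runif(150)
  got <- sliding_pearson(x, y, 25)
  want <- oracle_sliding_pearson(x, y, 25)
  expect_equal(got$r, want$r, tolerance = 1e-12)
})

test_that("bidirectional firing is classified from the flipped cross-correlogram", {
  landmark <- 150
  d <- 18  # fires 18 cm before the landmark on both directions
  n <- 150
  # traj1 coordinate: bump at landmark - d; traj2 runs the opposite way, so
  # in traj2's own running coordinate the same behavior puts the bump at
  # (L - landmark) - d
  c1 <- toy_curve(gauss_bump(n, (landmark - d) / 2, 4, 10))
  c2 <- toy_curve(gauss_bump(n, (300 - landmark - d) / 2, 4, 10),
                  trajectory = "traj2")
  bc <- classify_bidirectional(c1, c2)
  expect_equal(bc$class, "prospective")
  expect_equal(bc$peak_lag_cm, 2 * d, tolerance = 2)
  # retrospective: fires d cm after the landmark on both directions
  c1r <- toy_curve(gauss_bump(n, (landmark + d) / 2, 4, 10))
  c2r <- toy_curve(gauss_bump(n, (300 - landmark + d) / 2, 4, 10),
                   trajectory = "traj2")
  bcr <- classify_bidirectional(c1r, c2r)
  expect_equal(bcr$class, "retrospective")
  expect_equal(bcr$peak_lag_cm, -2 * d, tolerance = 2)
})

test_that("peaks outside the +/-50 cm window or non-responsive cells are rejected", {
  c1 <- toy_curve(gauss_bump(150, 60, 4, 10))
  # flipped trajectory-2 bump sits 62 cm beyond the trajectory-1 bump
  c2 <- toy_curve(gauss_bump(150, 150 - 91 + 1, 4, 10), trajectory = "traj2")
  bc <- classify_bidirectional(c1, c2)
  expect_equal(bc$peak_lag_cm, 62)
  expect_equal(bc$class, "none")
  expect_match(bc$reason, "window")
  nr <- classify_bidirectional(c1, c2, responsive_both = FALSE)
  expect_equal(nr$class, "none")
  expect_match(nr$reason, "responsive")
})
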