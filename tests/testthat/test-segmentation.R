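test_that("segmentation finds well-separated blobs and handles empty maps", {
  expect_equal(nrow(segment_couplons(matrix(0, 64, 64),
                                     pixel_size = PX)), 0L)
  expect_error(segment_couplons(matrix(-1, 16, 16), pixel_size = PX),
               "non-negative")
  expect_error(segment_couplons(matrix(1, 16, 16),
                                matrix(FALSE, 16, 16), PX), "empty")

  # two equal blobs 3 um apart
  m <- gauss_blob(64, 64, 32, 18, 2, 50) + gauss_blob(64, 64, 32, 32, 2, 50)
  s <- segment_couplons(m, pixel_size = PX)
  expect_equal(nrow(s), 2L)
  expect_lt(max(abs(sort(s$x_um) - sort(c(18, 32) * PX))), 0.25)
  expect_lt(max(abs(s$y_um - 32 * PX)), 0.25)
})

test_that("satellites below 5% of the local maximum are rejected, above kept", {
  main <- gauss_blob(64, 64, 32, 26, 1.5, 100)
  sat4 <- gauss_blob(64, 64, 32, 32, 0.8, 4)  # 1.3 um away, 4% of peak
  sat6 <- gauss_blob(64, 64, 32, 32, 0.8, 6)  # same spot, 6%
  s4 <- segment_couplons(main + sat4, pixel_size = PX,
                         presmooth_sigma = 0, ws_tolerance = 1)
  s6 <- segment_couplons(main + sat6, pixel_size = PX,
                         presmooth_sigma = 0, ws_tolerance = 1)
  expect_equal(nrow(s4), 1L)
  expect_equal(nrow(s6), 2L)
})

test_that("site count is non-increasing in the rejection floor", {
  set.seed(21)
  m <- matrix(0, 64, 64)
  for (i in 1:6)
    m <- m + gauss_blob(64, 64, sample(10:54, 1), sample(10:54, 1), 1.5,
                        runif(1, 10, 100))
  n <- sapply(c(0.01, 0.05, 0.2, 0.5), function(fl)
    nrow(segment_couplons(m, pixel_size = PX, rel_floor = fl)))
  expect_true(all(diff(n) <= 0))
})

test_that("site FWHM fitting returns 2s and flags degenerate sites", {
  # sampled Gaussian with s = 0.5 um -> FWHM 1.0 um (2s convention)
  m <- gauss_blob(64, 64, 32, 32, 0.5 / PX, 100)
  m[m < 1] <- 0
  s <- segment_couplons(m, pixel_size = PX)
  expect_equal(nrow(s), 1L)
  expect_true(s$fit_ok)
  expect_equal(s$fwhm_um, 1.0, tolerance = 0.02)

  # single-pixel site: fit failure flag
  m1 <- matrix(0, 32, 32)
  m1[16, 16] <- 10
  s1 <- segment_couplons(m1, pixel_size = PX, presmooth_sigma = 0)
  expect_equal(nrow(s1), 1L)
  expect_false(s1$fit_ok)
  expect_true(is.na(s1$fwhm_um))
})

test_that("2D couplon density follows the mask area arithmetic", {
  mask <- matrix(TRUE, 100, 100)     # 462.25 um^2 at 0.215 um/px
  sites <- data.frame(x_um = runif(50, 1, 20), y_um = runif(50, 1, 20))
  expect_equal(couplon_density_2d(sites, mask, PX),
               50 / (100 * 100 * PX^2) * 1000, tolerance = 1e-12)
  expect_equal(couplon_density_2d(sites[0, ], mask, PX), 0)
  expect_error(couplon_density_2d(sites, matrix(FALSE, 4, 4), PX), "empty")
})

test_that("re-fire rate matches worked example and boundary cases", {
  set.seed(2)
  base <- data.frame(x_um = runif(342, 0, 50), y_um = runif(342, 0, 50))
  # second transient: 215 shared sites + 137 new far-away ones
  t2 <- rbind(base[1:215, ],
              data.frame(x_um = runif(137, 60, 100),
                         y_um = runif(137, 60, 100)))
  r <- refire_rate(base, t2)
  expect_gte(r, 62.8)
  expect_lte(r, 62.9)

  expect_equal(refire_rate(base, base), 100)
  far <- data.frame(x_um = base$x_um + 500, y_um = base$y_um)
  expect_equal(refire_rate(base, far), 0)
  expect_error(refire_rate(base[0, ], base), "empty")
})

test_that("firing probability reports exact per-site fractions", {
  a <- data.frame(x_um = c(1, 5, 9), y_um = c(1, 5, 9))
  same4 <- firing_probability(list(a, a, a, a))
  expect_equal(same4$fraction, rep(1, 3))

  b <- data.frame(x_um = c(1, 5), y_um = c(1, 5))
  cc <- data.frame(x_um = 1, y_um = 1)
  fp <- firing_probability(list(a, b, cc, cc))
  fp <- fp[order(fp$x_um), ]
  expect_equal(fp$fraction, c(1, 0.5, 0.25))
  expect_error(firing_probability(list(a)), ">= 2")
})

test_that("temporal and spatial CV use population SD and are scale-invariant", {
  m <- rbind(c(1, 1, 1, 1, 1, 3), c(2, 2, 2, 2, 2, 6))
  direct <- sqrt(mean((m[1, ] - mean(m[1, ]))^2)) / mean(m[1, ])
  expect_equal(temporal_cv(m), direct)       # both rows have identical CV
  expect_equal(temporal_cv(m * 7), temporal_cv(m))
  expect_equal(temporal_cv(rbind(c(2, 2, 2), c(5, 5, 5))), 0)
  expect_error(temporal_cv(matrix(0, 2, 3)), "all-zero")

  expect_equal(spatial_cv(c(1, 3)), 0.5)
  expect_equal(spatial_cv(c(4, 4, 4)), 0)
  expect_equal(spatial_cv(c(1, 3) * 100), 0.5)
  expect_error(spatial_cv(5), ">= 2")
})

test_that("map correlation and structure-only SSIM behave at the extremes", {
  set.seed(31)
  a <- matrix(rnorm(64 * 64), 64)
  expect_equal(map_correlation(a, a), 1)
  expect_equal(map_correlation(a, -a), -1)
  # checkerboard against its own shift, verified by direct covariance
  cb <- outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  cbs <- rbind(cb[-1, ], cb[1, ])
  expect_equal(map_correlation(cb, cbs),
               cov(as.vector(cb), as.vector(cbs)) / (sd(cb) * sd(cbs)))
  expect_error(map_correlation(a, matrix(1, 64, 64)), "constant")

  expect_equal(structural_similarity(a, a), 1, tolerance = 1e-9)
  b <- matrix(rnorm(64 * 64), 64)
  s <- structural_similarity(a, b)
  expect_lt(abs(s), 0.1)
  expect_equal(s, structural_similarity(b, a))
  expect_gte(s, -1); expect_lte(s, 1)
})

test_that("FFT periodicity recovers grating periods within one frequency bin", {
  h <- w <- 128
  binw <- 1 / (w * PX)
  for (period in c(1.2, 1.8, 2.5)) {
    stripes <- matrix(rep((sin(2 * pi * (1:w) * PX / period) > 0.5) * 1,
                          each = h), h, w)
    r <- fft_periodicity(stripes, PX, longitudinal_axis = 0)
    expect_lt(abs(r$spatial_frequency - 1 / period), binw + 1e-9)
    expect_gt(r$peak_power, 5)
  }
  # white noise: no strong enrichment over the annulus baseline
  set.seed(5)
  wn <- matrix(abs(rnorm(h * w)), h)
  expect_lt(fft_periodicity(wn, PX, 0)$peak_power, 3)
  expect_error(fft_periodicity(wn, PX, 270), "angle")
  expect_error(fft_periodicity(matrix(1, 16, 16), PX, 0), "32 px")
})

test_that("mask axis estimation recovers the principal orientation", {
  mask <- matrix(FALSE, 64, 64)
  mask[28:36, 5:60] <- TRUE          # horizontal rod -> 0 degrees
  expect_lt(abs(estimate_axis(mask)), 2)
  expect_lt(abs(estimate_axis(t(mask)) - 90), 2)
})

test_that("3D stacking merges aligned sites and computes volumetric density", {
  plane <- matrix(0, 48, 48)
  plane[15, 15] <- 5
  plane[30, 35] <- 2
  maps <- replicate(5, plane, simplify = FALSE)
  r <- build_3d_map(maps, pixel_size = PX)
  expect_equal(r$n_sites, 2L)
  expect_equal(r$volume_um3, 48 * 48 * PX^2 * 5 * 0.417)
  expect_equal(r$density_per_um3, 2 / r$volume_um3)
  expect_error(build_3d_map(maps[1], pixel_size = PX), "planes")

  # diagonal touch counts as connected (26-connectivity)
  p2 <- matrix(0, 16, 16); p2[8, 8] <- 1
  p3 <- matrix(0, 16, 16); p3[9, 9] <- 1
  expect_equal(build_3d_map(list(p2, p3), pixel_size = PX)$n_sites, 1L)
})
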