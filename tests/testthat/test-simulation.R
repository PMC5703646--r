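test_that("central-pixel transient matches an independent Gaussian*exponential convolution", {
  m <- transient_model(A = 1, B = 0, sigma = 3, tau = 40, mu = 10)
  # oracle: A * tau * (density of N(mu, sigma^2) + Exp(rate 1/tau)),
  # evaluated by numerical convolution on a fine grid
  dt <- 0.01
  tg <- seq(-200, 400, by = dt)
  g <- dnorm(tg, 10, 3)
  ex <- ifelse(tg >= 0, exp(-tg / 40) / 40, 0)
  conv <- convolve(g, rev(ex), type = "open") * dt
  tc <- seq(2 * tg[1], by = dt, length.out = length(conv))
  oracle <- approxfun(tc, conv * 40)
  ts <- c(-5, 0, 5, 10, 15, 25, 50, 100, 200)
  expect_equal(central_pixel_transient(m, ts), oracle(ts), tolerance = 1e-3)

  # limits and degenerate amplitude
  expect_equal(central_pixel_transient(m, -1e4), 0)
  expect_equal(central_pixel_transient(transient_model(A = 0, B = 7), 1:5),
               rep(7, 5))
  expect_true(all(is.finite(central_pixel_transient(m, seq(-1e3, 1e3, 50)))))
})

test_that("peak of the default spark time course is stable (regression fixture)", {
  m <- transient_model(A = 1, B = 0, sigma = 3, tau = 40, mu = 10)
  tg <- seq(0, 100, by = 0.01)
  v <- central_pixel_transient(m, tg)
  # frozen from dense evaluation of the closed form on a 0.01 ms grid
  expect_equal(tg[which.max(v)], 15.76, tolerance = 1e-3)
  expect_equal(max(v), 0.84009, tolerance = 1e-4)
})

test_that("spatial width follows the clipped saturating growth law", {
  m <- transient_model(sigma_m = 1.5, tau_s = 10, mu = 5)
  expect_equal(spatial_width(m, c(-10, 0, 5)), c(0, 0, 0))
  expect_equal(spatial_width(m, 5 + 10), 1.5 * (1 - exp(-1)))
  expect_equal(spatial_width(m, 1e6), 1.5)
})

test_that("rendered events are radially symmetric with the maximum at the center", {
  m <- spark_model(); m$mu <- 5; m$B <- 10
  grid <- list(H = 63, W = 63, pixel_size = PX)
  ctr <- c(32 * PX, 32 * PX)
  st <- render_local_transient(m, grid, ctr, times = seq(0, 40, by = 5))
  for (t in seq_len(n_frames(st))) {
    f <- get_frame(st, t) - 10
    if (max(f) < 1e-6) next
    expect_equal(which(f == max(f), arr.ind = TRUE)[1, ],
                 c(row = 32, col = 32))
    expect_lt(max(abs(f - f[nrow(f):1, ])), 1e-6)
    expect_lt(max(abs(f - t(f))), 1e-6)
  }
  expect_error(render_local_transient(m, grid, c(100, 100), 0:3), "outside")
})

test_that("axial reslicing attenuates monotonically and is exact at z = 0", {
  m <- spark_model(); m$mu <- 5; m$B <- 0
  grid <- list(H = 63, W = 63, pixel_size = PX)
  ctr <- c(32 * PX, 32 * PX)
  times <- seq(0, 40, by = 5)
  z0 <- reslice_at_z(m, 0, grid, ctr, times)
  expect_equal(z0$frames, render_local_transient(m, grid, ctr, times)$frames)
  peaks <- sapply(seq(0, 2, by = 0.5), function(z)
    max(reslice_at_z(m, z, grid, ctr, times)$frames))
  expect_true(all(diff(peaks) < 0))
  expect_error(reslice_at_z(m, -1, grid, ctr, times), "z_offset")
})

test_that("recording noise reproduces the Poisson-Gaussian moments", {
  st <- fl_stack(array(54, dim = c(320, 320, 1)), DT, PX)  # ~1e5 pixels
  nm <- noise_model(gain = 2.7, offset = 0, white_sigma = 5.93)
  noisy <- add_recording_noise(st, nm, seed = 77)
  n <- length(noisy$frames)
  mu_th <- 54
  var_th <- 2.7^2 * 20 + 5.93^2
  sem <- sqrt(var_th / n)
  expect_lt(abs(mean(noisy$frames) - mu_th), 3 * sem)
  expect_lt(abs(var(as.vector(noisy$frames)) - var_th),
            3 * var_th * sqrt(2 / n))
  # white_sigma = 0, gain = 1, zero input -> offset only
  z <- fl_stack(array(0, c(8, 8, 1)), DT, PX)
  out <- add_recording_noise(z, noise_model(gain = 1, offset = 3,
                                            white_sigma = 0), seed = 1)
  expect_equal(unique(as.vector(out$frames)), 3)
  neg <- fl_stack(array(-1, c(8, 8, 1)) + 0.5, DT, PX)
  expect_error(add_recording_noise(neg, nm), "negative")
})

test_that("background SNR is mean over SD with the noiseless case flagged", {
  set.seed(6)
  st <- fl_stack(array(rnorm(64 * 64 * 2, 40, 10), c(64, 64, 2)), DT, PX)
  expect_equal(background_snr(st, 2), 4, tolerance = 0.1)
  expect_equal(background_snr(const_stack(5)), Inf)
})

test_that("simulators are reproducible and honor their ground truth contracts", {
  mask <- make_cell_mask(64, 64, PX)
  a <- simulate_random_transient(mask, n_events = 5, seed = 3)
  b <- simulate_random_transient(mask, n_events = 5, seed = 3)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
  cc <- simulate_random_transient(mask, n_events = 5, seed = 4)
  expect_false(identical(a$stack$frames, cc$stack$frames))

  z <- simulate_random_transient(mask, n_events = 0, noise = NULL, seed = 1)
  expect_equal(nrow(z$truth), 0L)
  expect_true(all(apply(z$stack$frames, 3, identical, z$stack$frames[, , 1])))

  # truth centers stay inside the mask bounding box
  r <- simulate_random_transient(mask, n_events = 50, seed = 9)
  expect_true(all(r$truth$x_um >= 0 & r$truth$x_um <= 64 * PX))
  expect_true(all(r$truth$y_um >= 0 & r$truth$y_um <= 64 * PX))
})

test_that("gridded simulation places nodes at the stated spacings and fills them evenly", {
  mask <- matrix(TRUE, 100, 60)
  sim <- simulate_gridded_transient(mask, n_events = 2000, seed = 2,
                                    noise = NULL)
  gx <- sort(unique(sim$truth$x_um))
  gy <- sort(unique(sim$truth$y_um))
  expect_equal(unique(round(diff(gx), 6)), 1.075)
  expect_equal(unique(round(diff(gy), 6)), 1.935)
  # 5 px and 9 px at 0.215 um/px
  expect_equal(1.075 / PX, 5)
  expect_equal(1.935 / PX, 9)
  # events near-uniform across nodes (chi-square sanity at fixed seed)
  counts <- tabulate(sim$events$node, nbins = nrow(sim$truth))
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, qchisq(0.999, df = nrow(sim$truth) - 1))
  expect_error(simulate_gridded_transient(mask, spacing_x = 0.1), "spacing")
})

test_that("n_events = 0 gridded run returns a basal-only stack", {
  mask <- matrix(TRUE, 32, 32)
  sim <- simulate_gridded_transient(mask, n_events = 0, noise = NULL,
                                    seed = 1)
  expect_true(all(apply(sim$stack$frames, 3, identical,
                        sim$stack$frames[, , 1])))
})
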