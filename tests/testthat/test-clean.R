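test_that("ACO peaks at the requested amplitude and is narrower than the D kernel", {
  aco <- build_aco(30, DT, PX, amplitude = 0.25)
  expect_equal(max(aco$weights), 0.25)
  # second moment of the K = 30 ACO is half that of the D = 60 kernel
  m2 <- function(w) {
    c0 <- (nrow(w) + 1) / 2
    idx <- seq_len(nrow(w)) - c0
    sum(w * outer(idx^2, idx^2, "+")) / sum(w)
  }
  kd <- build_diffusion_kernel(60, DT, PX)
  expect_lt(m2(aco$weights), m2(kd$weights))
  expect_error(build_aco(30, DT, PX, amplitude = 0), "amplitude")
})

test_that("CLEAN loop terminates at the threshold with exact flux accounting", {
  aco <- build_aco(30, DT, PX, amplitude = 0.05)
  blob <- gauss_blob(64, 64, 40, 25, sigma_px = 0.8 / PX, peak = 100)
  cf <- clean_frame(blob, aco, threshold = 10)
  expect_true(cf$converged)
  expect_lte(max(cf$residual), 10)
  expect_equal(which(cf$counts == max(cf$counts), arr.ind = TRUE)[1, ],
               c(row = 40, col = 25))
  removed <- sum(blob) - sum(cf$residual)
  expect_lt(abs(removed - sum(cf$counts) * sum(aco$weights)) / removed, 0.01)

  # below-threshold input: untouched
  low <- matrix(5, 32, 32)
  cf0 <- clean_frame(low, aco, threshold = 10)
  expect_equal(sum(cf0$counts), 0)
  expect_identical(cf0$residual, low)
  expect_equal(cf0$iterations, 0)

  expect_error(clean_frame(matrix(NaN, 8, 8), aco, 10), "finite")
})

test_that("iteration cap flags non-convergence instead of erroring", {
  aco <- build_aco(30, DT, PX, amplitude = 0.01)
  blob <- gauss_blob(48, 48, 24, 24, sigma_px = 4, peak = 100)
  cf <- clean_frame(blob, aco, threshold = 10, max_iterations = 5)
  expect_false(cf$converged)
  expect_equal(cf$iterations, 5)
  expect_gt(max(cf$residual), 10)
})

test_that("raising the threshold never increases subtraction counts", {
  set.seed(11)
  rel <- gauss_blob(48, 48, 20, 30, 3, 80) + matrix(rnorm(48^2, 0, 4), 48)
  aco <- build_aco(30, DT, PX, amplitude = 0.08)
  total <- sapply(c(5, 10, 20, 40), function(th)
    sum(clean_frame(rel, aco, th)$counts))
  expect_true(all(diff(total) <= 0))
})

test_that("mirroring the release frame mirrors the count map", {
  set.seed(12)
  rel <- gauss_blob(40, 56, 18, 30, 3, 90) + matrix(rnorm(40 * 56, 0, 3), 40)
  aco <- build_aco(30, DT, PX, amplitude = 0.1)
  a <- clean_frame(rel, aco, 10)$counts
  b <- clean_frame(rel[, ncol(rel):1], aco, 10)$counts
  expect_identical(a, b[, ncol(b):1])
})

test_that("counts scale linearly with the inverse ACO fraction", {
  st <- events_stack(rbind(c(8, 8), c(14, 12)))
  prepped <- subtract_reference(st, compute_baseline_reference(st, 2L))
  r1 <- caclean_transient(prepped, clean_config(threshold = 12,
                                                aco_fraction = 1e-3))
  r2 <- caclean_transient(prepped, clean_config(threshold = 12,
                                                aco_fraction = 5e-4))
  n1 <- sum(sapply(r1$per_frame, function(f) sum(f$counts$count)))
  n2 <- sum(sapply(r2$per_frame, function(f) sum(f$counts$count)))
  expect_equal(n2 / n1, 2, tolerance = 0.05)
  # map flux (counts x amplitude) is fraction-invariant
  expect_equal(sum(r1$map), sum(r2$map), tolerance = 0.02)
})

test_that("an all-noise stack below threshold yields an empty map", {
  set.seed(9)
  st <- fl_stack(array(rnorm(32 * 32 * 4, 0, 1), c(32, 32, 4)), DT, PX)
  res <- caclean_transient(st, clean_config(threshold = 12,
                                            aco_fraction = 1e-3))
  expect_equal(max(res$map), 0)
})

test_that("well-separated noiseless blobs are recovered at their true centers", {
  centers <- rbind(c(5, 5), c(14, 6), c(9, 15))  # um
  st <- events_stack(centers)
  prepped <- subtract_reference(st, compute_baseline_reference(st, 2L))
  res <- caclean_transient(prepped, clean_config(threshold = 12,
                                                 aco_fraction = 1e-3))
  # the 3 highest count-map pixels coincide with the 3 true centers
  sm <- smooth_map_for_display(res$map, 0.3)
  found <- matrix(0, 3, 2)
  tmp <- sm
  for (i in 1:3) {
    k <- which(tmp == max(tmp), arr.ind = TRUE)[1, ]
    found[i, ] <- k
    tmp[pmax(1, k[1] - 6):pmin(nrow(tmp), k[1] + 6),
        pmax(1, k[2] - 6):pmin(ncol(tmp), k[2] + 6)] <- 0
  }
  d <- sqrt(outer(found[, 1] * PX, centers[, 2], "-")^2 +
              outer(found[, 2] * PX, centers[, 1], "-")^2)
  expect_equal(nrow(caclean:::match_sites(found[, 2] * PX, found[, 1] * PX,
                                          centers[, 1], centers[, 2], 0.5)),
               3L)
  # residuals end below threshold in every frame
  for (r in res$residuals) expect_lte(max(r), 12)
})

test_that("display smoothing preserves total intensity and s = 0 is identity", {
  m <- gauss_blob(32, 32, 16, 16, 2, 50)
  expect_identical(smooth_map_for_display(m, 0), m)
  s <- smooth_map_for_display(m, 0.3)
  expect_equal(sum(s), sum(m), tolerance = 1e-3)
})

test_that("rebuild reverses the CLEAN process faithfully", {
  # removal factor: 0.00219/ms x 6.8 ms is ~1.5% per frame
  expect_equal(0.00219 * DT, 0.0149, tolerance = 0.01)

  st <- events_stack(rbind(c(5, 5), c(15, 8), c(9, 15), c(5, 14), c(15, 15)))
  prepped <- subtract_reference(st, compute_baseline_reference(st, 2L))
  res <- caclean_transient(prepped, clean_config(threshold = 12,
                                                 aco_fraction = 1e-3))
  # zero counts + zero removal -> pure diffusion forecast
  res0 <- res
  for (i in seq_along(res0$per_frame))
    res0$per_frame[[i]]$counts <- res0$per_frame[[i]]$counts[0, ]
  init <- get_frame(prepped, 1)
  rb0 <- rebuild_transient(res0, init, removal_rate = 0)
  fc <- init
  for (t in 2:n_frames(rb0)) {
    fc <- predict_diffusion(fc, res$kernel)
    expect_equal(get_frame(rb0, t), fc, tolerance = 1e-9)
  }
  # full rebuild correlates >= 0.9 with the input on signal-bearing frames
  rb <- rebuild_transient(res, init)
  for (t in 2:n_frames(rb)) {
    input <- get_frame(prepped, t)
    if (max(input) > 5 * res$config$threshold)
      expect_gte(cor(as.vector(get_frame(rb, t)), as.vector(input)), 0.9)
  }
})
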