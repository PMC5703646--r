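#' Calibrate the CLEAN stop threshold on noise-only series
#'
#' Duplicates a noise-free basal cell frame into a short image series,
#' applies Poisson-Gaussian recording noise at each detector gain,
#' runs the full detection pipeline, and counts the detected couplon
#' sites -- all of which are false positives, since the input contains
#' no release events. The smallest integer threshold with zero
#' detections across all seeds, at the gain whose background SNR is
#' closest to 4 (the regime of raw recordings), is reported as the
#' calibrated threshold.
#'
#' @param noise_free_frame Basal cell frame in a.u. (no release
#'   events); `NULL` builds the default synthetic cell.
#' @param gains Detector gains to simulate.
#' @param white_sigma White-noise SD in a.u. (default 5.95).
#' @param thresholds Integer thresholds scanned.
#' @param n_frames Series length (default 7, ~48 ms).
#' @param n_seeds Noise realisations per gain.
#' @param seed Base seed.
#' @param mask Cell mask for segmentation (`NULL` = default cell).
#' @param pixel_size,dt Calibration of the simulated series.
#' @param denoise_method,denoise_sigma Denoising hook settings.
#' @param aco_fraction ACO fraction for the CLEAN stage (default 1e-2:
#'   false-positive *sites* only require one subtraction per
#'   supra-threshold pixel, and counts scale linearly with
#'   1/fraction).
#' @return data.frame with columns `gain`, `bgr_snr`, `seed`,
#'   `threshold`, `false_positives`; attributes `min_zero_fp`
#'   (calibrated threshold at bgrSNR ~ 4) and `snr_table`.
#' @export
calibrate_threshold <- function(noise_free_frame = NULL,
                                gains = 2.7, white_sigma = 5.95,
                                thresholds = 1:40, n_frames = 7L,
                                n_seeds = 10L, seed = 1L, mask = NULL,
                                pixel_size = 0.215, dt = 6.8,
                                denoise_method = "gaussian3d",
                                denoise_sigma = 1.5,
                                aco_fraction = 1e-2) {
  if (is.null(mask)) mask <- make_cell_mask(256L, 256L, pixel_size)
  if (is.null(noise_free_frame))
    noise_free_frame <- make_cell_frame(mask)
  base <- fl_stack(array(noise_free_frame,
                         dim = c(dim(noise_free_frame), n_frames)),
                   dt, pixel_size)
  rows <- list()
  snr_tab <- data.frame(gain = gains, bgr_snr = NA_real_)
  for (gi in seq_along(gains)) {
    g <- gains[gi]
    nm <- noise_model(gain = g, offset = 0, white_sigma = white_sigma)
    snrs <- numeric(n_seeds)
    for (si in seq_len(n_seeds)) {
      noisy <- add_recording_noise(base, nm,
                                   seed = seed + 1000L * gi + si)
      snrs[si] <- background_snr(noisy, n_frames, mask = mask)
      s <- denoise(noisy, denoise_method, denoise_sigma)
      s <- subtract_reference(s, compute_baseline_reference(s, 2L))
      rel <- isolate_release_series(s)
      for (th in thresholds) {
        cfg <- clean_config(threshold = th, aco_fraction = aco_fraction)
        map <- matrix(0, nrow(mask), ncol(mask))
        aco1 <- build_aco(cfg$K, dt, pixel_size, amplitude = 1,
                          form = cfg$form)
        for (r in rel) {
          amp <- max(cfg$aco_fraction * max(r), th * cfg$aco_fraction)
          aco <- aco1; aco$weights <- aco1$weights * amp
          cf <- clean_frame(r, aco, th, cfg$max_iterations)
          map <- map + cf$counts * amp
        }
        fp <- if (max(map) <= 0) 0L else
          nrow(segment_couplons(map, mask, pixel_size, fit_fwhm = FALSE))
        rows[[length(rows) + 1L]] <-
          data.frame(gain = g, bgr_snr = snrs[si],
                     seed = seed + 1000L * gi + si,
                     threshold = th, false_positives = fp)
      }
    }
    snr_tab$bgr_snr[gi] <- mean(snrs)
  }
  tab <- do.call(rbind, rows)
  target_gain <- gains[which.min(abs(snr_tab$bgr_snr - 4))]
  sub <- tab[tab$gain == target_gain, ]
  per_th <- tapply(sub$false_positives, sub$threshold, max)
  zero <- as.integer(names(per_th))[per_th == 0]
  attr(tab, "min_zero_fp") <- if (length(zero)) min(zero) else NA_integer_
  attr(tab, "snr_table") <- snr_tab
  tab
}

# Render two events separated along x, run the pipeline, return sites.
two_event_run <- function(separation, model, noise, pixel_size, dt,
                          grid_px, config, flux_photons, seed,
                          onset_mean = 10) {
  set.seed(seed)
  h <- grid_px; w <- grid_px
  cx <- w * pixel_size / 2; cy <- h * pixel_size / 2
  centers <- rbind(c(cx - separation / 2, cy), c(cx + separation / 2, cy))
  times <- seq(-4L, 7L) * dt
  gain <- if (is.null(noise)) 2.7 else noise$gain
  basal <- gain * flux_photons
  frames <- array(basal, dim = c(h, w, length(times)))
  for (e in 1:2) {
    m <- model; m$mu <- onset_mean; m$B <- 0
    frames <- splat_event(frames, m, centers[e, ], times, pixel_size)
  }
  stack <- fl_stack(frames, dt, pixel_size)
  if (!is.null(noise)) stack <- add_recording_noise(stack, noise)
  out <- caclean_pipeline(stack, mask = interior_mask(h, w), config = config)
  list(sites = out$sites, centers = centers)
}

# Interior mask excluding a border margin, where replicate-padding and
# baseline-reference edge effects would otherwise seed artifacts (a real
# analysis always applies a cell mask).
interior_mask <- function(h, w, margin = 10L) {
  m <- matrix(FALSE, h, w)
  m[(margin + 1L):(h - margin), (margin + 1L):(w - margin)] <- TRUE
  m
}

#' Lateral (xy) resolution experiment
#'
#' For each centre-to-centre separation, simulates two simultaneous
#' elementary events, adds recording noise, runs the full pipeline,
#' and calls the separation "resolved" when exactly two sites are
#' found, each within `match_radius` of a distinct true centre, in at
#' least `min_hits` of `n_seeds` seeded repeats.
#'
#' @param separations Separations in um, ascending.
#' @param model Event model (default [spark_model()]).
#' @param noise A [noise_model()].
#' @param n_seeds,min_hits Repeats and required successes (8/10).
#' @param match_radius Matching radius in um.
#' @param pixel_size,dt,grid_px,flux_photons Simulation grid settings.
#' @param config CLEAN configuration (ACO fraction 1e-3 keeps runtimes
#'   short; detected positions are fraction-independent).
#' @param seed Base seed.
#' @return List with `smallest_resolved` (um, `NA` if none),
#'   `table` (per separation: hits, n).
#' @export
resolution_experiment_xy <- function(separations = c(0.5, 0.75, 1, 1.25, 1.5),
                                     model = spark_model(),
                                     noise = noise_model(),
                                     n_seeds = 10L, min_hits = 8L,
                                     match_radius = 0.5,
                                     pixel_size = 0.215, dt = 6.8,
                                     grid_px = 96L, flux_photons = 20,
                                     config = clean_config(threshold = 12, aco_fraction = 1e-3),
                                     seed = 1L) {
  stopifnot(!is.unsorted(separations))
  hits <- integer(length(separations))
  for (k in seq_along(separations)) {
    for (si in seq_len(n_seeds)) {
      run <- two_event_run(separations[k], model, noise, pixel_size, dt,
                           grid_px, config, flux_photons,
                           seed + 100L * k + si)
      s <- run$sites
      ok <- FALSE
      if (nrow(s) == 2L) {
        m <- match_sites(s$x_um, s$y_um, run$centers[, 1], run$centers[, 2],
                         match_radius)
        ok <- nrow(m) == 2L
      }
      hits[k] <- hits[k] + ok
    }
  }
  resolved <- separations[hits >= min_hits]
  list(smallest_resolved = if (length(resolved)) min(resolved) else NA_real_,
       table = data.frame(separation_um = separations, hits = hits,
                          n = n_seeds))
}

#' Axial (z) response experiment
#'
#' Reslices the rotationally symmetric 3D event at increasing axial
#' offsets, adds recording noise, runs the pipeline per offset and
#' records the peak couplon-map value. The apparent axial resolution
#' is the full width at half maximum of the (symmetric) peak-versus-z
#' curve, i.e. twice the linearly interpolated offset at which the
#' seed-averaged peak halves.
#'
#' @param z_offsets Axial offsets in um, must include 0.
#' @param model,noise,n_seeds,pixel_size,dt,grid_px,flux_photons,config,seed
#'   As in [resolution_experiment_xy()].
#' @return List with `fwhm_um`, `curve` (data.frame `z_um`,
#'   `mean_peak`).
#' @export
resolution_experiment_z <- function(z_offsets = seq(0, 2, by = 0.25),
                                    model = spark_model(),
                                    noise = noise_model(),
                                    n_seeds = 10L,
                                    pixel_size = 0.215, dt = 6.8,
                                    grid_px = 96L, flux_photons = 20,
                                    config = clean_config(threshold = 12, aco_fraction = 1e-3),
                                    seed = 1L) {
  if (!any(z_offsets == 0)) stop("z_offsets: must include 0")
  times <- seq(-4L, 7L) * dt
  grid <- list(H = grid_px, W = grid_px, pixel_size = pixel_size)
  ctr <- c(grid_px * pixel_size / 2, grid_px * pixel_size / 2)
  gain <- if (is.null(noise)) 2.7 else noise$gain
  basal <- gain * flux_photons
  peaks <- matrix(0, length(z_offsets), n_seeds)
  for (k in seq_along(z_offsets)) {
    m <- model; m$mu <- 10; m$B <- basal
    pure <- reslice_at_z(m, z_offsets[k], grid, ctr, times)
    for (si in seq_len(n_seeds)) {
      stack <- if (is.null(noise)) pure else
        add_recording_noise(pure, noise, seed = seed + 100L * k + si)
      out <- caclean_pipeline(stack, mask = NULL, config = config)
      im <- interior_mask(grid_px, grid_px)
      peaks[k, si] <- max(out$map[im])
    }
  }
  curve <- data.frame(z_um = z_offsets, mean_peak = rowMeans(peaks))
  ord <- order(curve$z_um)
  z <- curve$z_um[ord]; p <- curve$mean_peak[ord]
  half <- p[z == 0] / 2
  fwhm <- NA_real_
  for (i in seq_len(length(z) - 1L)) {
    if (p[i] >= half && p[i + 1L] < half) {
      zh <- z[i] + (p[i] - half) / (p[i] - p[i + 1L]) * (z[i + 1L] - z[i])
      fwhm <- 2 * zh
      break
    }
  }
  list(fwhm_um = fwhm, curve = curve)
}

#' Noise tolerance of the detection pipeline
#'
#' Applies a grid of noise conditions (varying gain at fixed white
#' noise, then varying white noise at fixed gain) to a noiseless
#' transient, runs the pipeline, and tabulates detected site counts
#' against the background SNR. Counts drop only at very low SNR
#' (below ~4).
#'
#' @param clean_stack Noiseless [fl_stack] of a transient.
#' @param mask Cell mask.
#' @param gains Gains tested at `white_sigma_fixed`.
#' @param sigmas White-noise SDs tested at `gain_fixed`.
#' @param gain_fixed,white_sigma_fixed The fixed counterparts.
#' @param config CLEAN configuration.
#' @param baseline_frames Baseline frames of the stack.
#' @param seed Base seed.
#' @return data.frame with `varied`, `gain`, `white_sigma`, `bgr_snr`,
#'   `n_sites`.
#' @export
noise_tolerance_experiment <- function(clean_stack, mask = NULL,
                                       gains = c(2.7, 5, 10, 15, 20),
                                       sigmas = c(0, 10, 20, 30, 40),
                                       gain_fixed = 2.7,
                                       white_sigma_fixed = 5.93,
                                       config = clean_config(threshold = 12, aco_fraction = 1e-3),
                                       baseline_frames = 2L, seed = 1L) {
  conds <- rbind(
    data.frame(varied = "gain", gain = gains, white_sigma = white_sigma_fixed),
    data.frame(varied = "white_sigma", gain = gain_fixed, white_sigma = sigmas))
  out <- conds
  out$bgr_snr <- NA_real_; out$n_sites <- NA_integer_
  for (i in seq_len(nrow(conds))) {
    nm <- noise_model(gain = conds$gain[i],
                      white_sigma = conds$white_sigma[i])
    noisy <- add_recording_noise(clean_stack, nm, seed = seed + i)
    out$bgr_snr[i] <- background_snr(noisy, baseline_frames, mask = mask)
    run <- caclean_pipeline(noisy, mask = mask, config = config,
                            baseline_frames = baseline_frames)
    out$n_sites[i] <- nrow(run$sites)
  }
  out
}

#' Sweep the diffusion and ACO constants
#'
#' Reruns the deconvolution over a transient varying one constant while
#' the other is held at its default (D fixed at 60 um^2/s when
#' sweeping the ACO constant; ACO fixed at 30 um^2/s when sweeping D)
#' and reports the mean fitted site FWHM per value -- the calibration
#' used to choose the defaults.
#'
#' @param stack Pre-processed (baseline-subtracted) upstroke stack.
#' @param aco_values ACO constants (um^2/s) to sweep.
#' @param D_values Diffusion constants (um^2/s) to sweep.
#' @param mask Cell mask.
#' @param config Base configuration.
#' @return data.frame with `swept`, `value`, `mean_fwhm_um`, `n_sites`,
#'   `is_default`.
#' @export
sweep_constants <- function(stack, aco_values = c(10, 30, 60),
                            D_values = c(30, 60, 120), mask = NULL,
                            config = clean_config(aco_fraction = 1e-3)) {
  one <- function(swept, value) {
    cfg <- config
    if (swept == "ACO") { cfg$K <- value; cfg$D <- 60 }
    else { cfg$D <- value; cfg$K <- 30 }
    res <- caclean_transient(stack, cfg)
    sites <- segment_couplons(res$map, mask, stack$pixel_size)
    data.frame(swept = swept, value = value,
               mean_fwhm_um = mean(sites$fwhm_um[sites$fit_ok],
                                   na.rm = TRUE),
               n_sites = nrow(sites),
               is_default = (swept == "ACO" && value == 30) ||
                 (swept == "D" && value == 60))
  }
  rows <- c(lapply(aco_values, function(v) one("ACO", v)),
            lapply(D_values, function(v) one("D", v)))
  do.call(rbind, rows)
}
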