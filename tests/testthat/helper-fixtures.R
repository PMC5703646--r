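# Shared fixture builders for the test suite. Everything is generated
# in code under fixed seeds; no stored data.

PX <- 0.215   # um per pixel, as in the recordings
DT <- 6.8     # ms per frame

# A constant-background stack with optional per-frame values.
const_stack <- function(value = 7, h = 16, w = 16, T = 3,
                        dt = DT, px = PX) {
  fl_stack(array(value, dim = c(h, w, T)), dt, px)
}

# Noiseless stack of well-separated elementary events with a common
# onset, on a flat basal background.
events_stack <- function(centers_um, onset = 10, A = 200, basal = 54,
                         h = 96, w = 96, n_pre = 2, n_up = 9,
                         model = spark_model(A = A)) {
  times <- seq(-n_pre, n_up - 1) * DT
  frames <- array(basal, dim = c(h, w, length(times)))
  for (e in seq_len(nrow(centers_um))) {
    m <- model
    m$mu <- onset
    m$B <- 0
    frames <- caclean:::splat_event(frames, m, centers_um[e, ], times, PX)
  }
  fl_stack(frames, DT, PX)
}

# Greedy matched pairs between a site table and truth coordinates.
matched_count <- function(sites, truth_x, truth_y, radius = 0.5) {
  nrow(caclean:::match_sites(sites$x_um, sites$y_um, truth_x, truth_y,
                             radius))
}

# Isotropic Gaussian blob image (analytic, for CLEAN oracles).
gauss_blob <- function(h, w, cy, cx, sigma_px, peak = 100) {
  peak * exp(-(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")) /
               (2 * sigma_px^2))
}
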