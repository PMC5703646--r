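#' Fluorescence image stack
#'
#' Container for a single-channel time-lapse fluorescence recording.
#' Frames are stored as a numeric array of dimension `c(H, W, T)` (rows,
#' columns, frames) in acquisition order, together with the frame
#' interval in milliseconds and the pixel size in micrometres.
#'
#' @param frames Numeric array `H x W x T` (a matrix is accepted as a
#'   single frame). All values must be finite.
#' @param frame_interval Frame interval in ms, strictly positive.
#' @param pixel_size Pixel edge length in um, strictly positive.
#' @param meta Named list of free-form provenance metadata.
#' @return An object of class `fl_stack` with elements `frames`,
#'   `frame_interval`, `pixel_size`, `meta`.
#' @export
fl_stack <- function(frames, frame_interval, pixel_size, meta = list()) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames: expected an H x W x T array")
  storage.mode(frames) <- "double"
  d <- dim(frames)
  if (d[1] < 8L || d[2] < 8L)
    stop("frames: image must be at least 8 x 8 pixels")
  if (!all(is.finite(frames)))
    stop("frames: all pixel values must be finite")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval: must be a single positive number (ms)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size: must be a single positive number (um)")
  structure(
    list(frames = frames, frame_interval = as.numeric(frame_interval),
         pixel_size = as.numeric(pixel_size), meta = meta),
    class = "fl_stack")
}

#' @export
print.fl_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("fl_stack: %d frame(s), %d x %d px, dt = %g ms, px = %g um\n",
              d[3], d[1], d[2], x$frame_interval, x$pixel_size))
  cat(sprintf("  intensity range [%.3g, %.3g] a.u.\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An `fl_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Extract one frame as a matrix
#' @param stack An `fl_stack`.
#' @param t Frame index (1-based).
#' @return `H x W` numeric matrix.
#' @export
get_frame <- function(stack, t) {
  stopifnot(t >= 1L, t <= n_frames(stack))
  stack$frames[, , t]
}

#' Read a multi-page TIFF recording
#'
#' Reads a single-channel multi-page TIFF into an [fl_stack]. Integer
#' TIFFs are read at their native scale (no 0--1 rescaling); float
#' TIFFs are read as stored.
#'
#' @param path Path to the TIFF file.
#' @param frame_interval Frame interval in ms.
#' @param pixel_size Pixel size in um.
#' @return An [fl_stack].
#' @export
read_stack <- function(path, frame_interval, pixel_size) {
  if (!file.exists(path)) stop("path: file not found: ", path)
  raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  plain <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(raw)) { raw <- list(raw); plain <- list(plain) }
  for (p in raw) {
    if (length(dim(p)) > 2L && dim(p)[3] > 1L)
      stop("path: multi-channel TIFF not supported (single channel required)")
  }
  drop_ch <- function(p) if (length(dim(p)) == 3L) p[, , 1L] else p
  raw <- lapply(raw, drop_ch); plain <- lapply(plain, drop_ch)
  # integer TIFFs: as.is returns the stored counts and plain the counts
  # rescaled to [0,1] by 2^bits - 1; float TIFFs: plain holds the stored
  # values while as.is reinterprets the raw bits as integers.
  is_int <- any(vapply(c(8, 16, 32), function(b)
    isTRUE(all.equal(raw[[1]], plain[[1]] * (2^b - 1),
                     tolerance = 1e-6, scale = 1)), logical(1)))
  pages <- if (is_int) raw else plain
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(h, w, length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  fl_stack(frames, frame_interval, pixel_size,
           meta = list(source = path, n_pages = length(pages),
                       storage = if (is_int) "integer" else "float"))
}

#' Write a stack to a multi-page TIFF
#'
#' Integer mode (`bits = 16`, default) stores values as 16-bit counts,
#' exactly, as cameras do -- values must be integers in 0..65535.
#' Float mode (`bits = 32`) stores IEEE floats but the TIFF writer only
#' supports the \[0, 1\] range; values must lie within it (couplon maps
#' can be written normalised, see [run_pipeline()]).
#'
#' @param stack An [fl_stack].
#' @param path Output path.
#' @param bits 16 (integer, exact) or 32 (float in \[0, 1\]).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  pages <- lapply(seq_len(n_frames(stack)), function(t) get_frame(stack, t))
  if (bits == 16L) {
    rng <- range(stack$frames)
    if (rng[1] < 0 || rng[2] > 65535 ||
        max(abs(stack$frames - round(stack$frames))) > 1e-6)
      stop("bits=16: values must be integers in 0..65535 ",
           "(use bits=32 for [0,1] float data)")
    pages <- lapply(pages, function(p) round(p) / 65535)
  } else if (bits == 32L) {
    rng <- range(stack$frames)
    if (rng[1] < 0 || rng[2] > 1)
      stop("bits=32: float TIFF storage supports only the [0,1] range")
  } else stop("bits: must be 16 or 32")
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' Baseline reference image
#'
#' Pixel-wise mean of the first `n_frames` frames, recorded prior to
#' electrical stimulation. The reference carries the camera offset plus
#' basal fluorescence and is subtracted from all subsequent frames
#' before deconvolution; two or three frames (14--21 ms at 6.8 ms/frame)
#' are the usual choice.
#'
#' @param stack An [fl_stack].
#' @param n_frames Number of leading frames to average (1..T).
#' @return An object of class `ca_reference`: list with `image`
#'   (`H x W` matrix) and `n_frames_averaged`.
#' @export
compute_baseline_reference <- function(stack, n_frames = 2L) {
  T <- dim(stack$frames)[3]
  if (n_frames < 1L || n_frames > T)
    stop("n_frames: must be in 1..", T)
  img <- if (n_frames == 1L) stack$frames[, , 1L]
         else rowMeans(stack$frames[, , seq_len(n_frames), drop = FALSE],
                       dims = 2L)
  structure(list(image = img, n_frames_averaged = as.integer(n_frames)),
            class = "ca_reference")
}

#' Subtract a reference image from every frame
#'
#' Returns the dF stack (`stack - reference`, per frame). Negative
#' values are preserved: clamping would bias the downstream release
#' estimates.
#'
#' @param stack An [fl_stack].
#' @param reference A `ca_reference` or an `H x W` matrix.
#' @return An [fl_stack] of the same shape.
#' @export
subtract_reference <- function(stack, reference) {
  ref <- if (inherits(reference, "ca_reference")) reference$image else reference
  d <- dim(stack$frames)
  if (!identical(dim(ref), d[1:2]))
    stop("reference: shape mismatch with stack frames")
  out <- stack
  out$frames <- stack$frames - as.vector(ref)  # recycles per frame (column-major)
  out$meta$baseline_subtracted <- TRUE
  out
}

#' Extract the baseline + upstroke window
#'
#' Returns the sub-stack of `n_pre` frames preceding the stimulus and
#' `n_up` frames from the stimulus on; this ~25 ms baseline + ~50 ms
#' upstroke window is the only part of the transient the deconvolution
#' analyses. `stim_index` is the 1-based index of the first
#' post-stimulus frame; the window is frames
#' `(stim_index - n_pre) .. (stim_index + n_up - 1)`.
#'
#' @param stack An [fl_stack].
#' @param stim_index 1-based frame index of the stimulus.
#' @param n_pre Frames before the stimulus (default 4, ~25 ms at 6.8 ms).
#' @param n_up Frames from the stimulus on (default 7, ~50 ms).
#' @return An [fl_stack] with `n_pre + n_up` frames; the window is
#'   recorded in `meta$upstroke_window`.
#' @export
extract_upstroke <- function(stack, stim_index, n_pre = 4L, n_up = 7L) {
  T <- n_frames(stack)
  lo <- stim_index - n_pre
  hi <- stim_index + n_up - 1L
  if (lo < 1L || hi > T)
    stop(sprintf("window [%d, %d] exceeds stack bounds 1..%d", lo, hi, T))
  out <- stack
  out$frames <- stack$frames[, , lo:hi, drop = FALSE]
  out$meta$upstroke_window <- c(first = lo, last = hi,
                                stim_index = stim_index)
  out
}

#' Denoising hook
#'
#' Optional pre-processing before deconvolution. `"none"` returns the
#' input unchanged; `"gaussian"` applies mass-preserving per-frame
#' isotropic Gaussian smoothing; `"gaussian3d"` (the default)
#' additionally smooths along time with a short Gaussian, exploiting
#' the temporal redundancy of the recording the way the heavier 3D
#' patch-based denoisers this hook stands in for do, at much lower
#' spatial cost. This is the documented extension point where such a
#' denoiser can be plugged in.
#'
#' @param stack An [fl_stack].
#' @param method `"gaussian3d"`, `"gaussian"` or `"none"`.
#' @param sigma_px Spatial Gaussian sigma in pixels (>= 0).
#' @param sigma_t Temporal Gaussian sigma in frames (`gaussian3d` only).
#' @return An [fl_stack].
#' @export
denoise <- function(stack, method = c("gaussian3d", "gaussian", "none"),
                    sigma_px = 1.5, sigma_t = 0.75) {
  method <- match.arg(method)
  if (method == "none") return(stack)
  if (sigma_px < 0) stop("sigma_px: must be >= 0")
  out <- stack
  if (method == "gaussian3d" && sigma_t > 0 && n_frames(stack) > 1L) {
    T <- n_frames(stack)
    r <- max(1L, ceiling(2 * sigma_t))
    wk <- exp(-((-r:r)^2) / (2 * sigma_t^2))
    sm <- array(0, dim = dim(stack$frames))
    for (t in seq_len(T)) {
      ks <- max(1L, t - r):min(T, t + r)
      w <- wk[ks - t + r + 1L]
      w <- w / sum(w)
      acc <- matrix(0, dim(sm)[1], dim(sm)[2])
      for (i in seq_along(ks))
        acc <- acc + w[i] * out$frames[, , ks[i]]
      sm[, , t] <- acc
    }
    out$frames <- sm
  }
  if (sigma_px > 0)
    for (t in seq_len(n_frames(stack)))
      out$frames[, , t] <- gaussian_blur(out$frames[, , t], sigma_px)
  out$meta$denoise <- list(method = method, sigma_px = sigma_px,
                           sigma_t = if (method == "gaussian3d") sigma_t)
  out
}

# Mass-preserving Gaussian blur with replicate boundary handling.
gaussian_blur <- function(img, sigma_px) {
  r <- max(2L, ceiling(3 * sigma_px))
  g <- outer(-r:r, -r:r, function(i, j) exp(-(i^2 + j^2) / (2 * sigma_px^2)))
  g <- g / sum(g)
  conv2_replicate(img, g)
}

# 2D convolution with replicate (edge-extend) padding.
conv2_replicate <- function(img, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  if (h <= 2 * kr || w <= 2 * kc) {
    # pad manually, filter2's replicate needs image larger than kernel
    ri <- c(rep(1L, kr), seq_len(h), rep(h, kr))
    ci <- c(rep(1L, kc), seq_len(w), rep(w, kc))
    pad <- img[ri, ci]
    out <- EBImage::filter2(pad, kern, boundary = "replicate")
    return(out[kr + seq_len(h), kc + seq_len(w)])
  }
  EBImage::filter2(img, kern, boundary = "replicate")
}
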