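## Rendering pipeline: head points and tail polylines -> grayscale frame.
##
## Stage names follow the cell-image pipeline: I1/I2 are rasterized head and
## tail point images, I3 the scaled head-centre response, I4 its complement,
## I5 the head centre on the uniform background, I6 the membrane halo, I8 the
## flagellum ridge, and I9 = clip(I5 + I6 + I8) the finished 8-bit frame.

#' Appearance parameters of a rendered cell
#'
#' Collects the PSF widths, peak gray levels and background level used by the
#' rendering pipeline.  Defaults are the calibrated values for 200x
#' magnification bright-field semen images: head axes (1.86, 2.86) px,
#' membrane axes (2.79, 4.29) px, flagellum width 1.5 px, head peak 255,
#' membrane peak 51 (20% of 255), flagellum peak 13 (~5% of 255), and a
#' uniform background of 204 (80% of 255).
#'
#' @param sigma_head Length-2 sd (x, y) of the head Gaussian, px.
#' @param sigma_membrane Length-2 sd (x, y) of the membrane halo kernel, px.
#' @param sigma_flagellum Sd of the flagellum ridge kernel, px.
#' @param kernel_half_width Half-width of all kernel supports, px.
#' @param head_peak,membrane_peak,flagellum_peak Peak gray levels in
#'   \[0, 255\] of the three components for an isolated cell.
#' @param background Uniform background gray level `B_L` in \[0, 255\].
#' @return A list of class `appearance_params`.
#' @export
appearance_params <- function(sigma_head = c(1.86, 2.86),
                              sigma_membrane = c(2.79, 4.29),
                              sigma_flagellum = 1.5,
                              kernel_half_width = 12,
                              head_peak = 255,
                              membrane_peak = 51,
                              flagellum_peak = 13,
                              background = 204) {
  sigma_head <- check_sigmas(sigma_head)
  sigma_membrane <- check_sigmas(sigma_membrane)
  sigma_flagellum <- check_sigmas(sigma_flagellum, 1L)
  for (v in list(head_peak, membrane_peak, flagellum_peak, background)) {
    stop_if_not_number(v, "gray level", nonneg = TRUE)
    if (v > 255) abort("Gray levels must lie in [0, 255].")
  }
  structure(
    list(sigma_head = sigma_head, sigma_membrane = sigma_membrane,
         sigma_flagellum = sigma_flagellum,
         kernel_half_width = as.integer(kernel_half_width),
         head_peak = head_peak, membrane_peak = membrane_peak,
         flagellum_peak = flagellum_peak, background = background),
    class = "appearance_params"
  )
}

#' Rasterize continuous points onto a frame
#'
#' Marks the nearest-integer pixel of every in-frame point with gray level
#' 255; all other pixels are 0.  Continuous positions are rounded half-up,
#' coincident points merge, and out-of-frame points are silently dropped.
#' This produces the binary point images from which head and tail responses
#' are synthesized by PSF convolution.
#'
#' @param points Continuous positions: n x 2 matrix, data frame with `x`/`y`,
#'   or a length-2 vector.  0-based pixel coordinates, origin at the top-left
#'   pixel, y downward.
#' @param frame_size Frame side length N in pixels (frames are N x N).
#' @return An N x N numeric matrix (rows = y, columns = x) with values in
#'   \{0, 255\}.
#' @examples
#' b <- rasterize_points(c(10.4, 20.6), 64)
#' which(b == 255, arr.ind = TRUE)  # row 22 (y = 21), col 11 (x = 10)
#' @export
rasterize_points <- function(points, frame_size) {
  stop_if_not_number(frame_size, "frame_size", positive = TRUE)
  n <- as.integer(frame_size)
  pts <- as_points_matrix(points)
  if (nrow(pts) > 0L && any(!is.finite(pts))) {
    abort("Point coordinates must be finite.")
  }
  buf <- matrix(0, n, n)
  if (nrow(pts) == 0L) return(buf)
  px <- round_half_up(pts[, 1])
  py <- round_half_up(pts[, 2])
  keep <- px >= 0 & px < n & py >= 0 & py < n
  if (any(keep)) buf[cbind(py[keep] + 1L, px[keep] + 1L)] <- 255
  buf
}

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("Image buffers must share dimensions.")
}

#' Render the dark head centre (stage I5)
#'
#' Convolves the rasterized head points with the Gaussian head PSF, scales the
#' response so an isolated head peaks at `head_peak` (stage I3), complements
#' it (I4 = 255 - I3), and places it on the uniform background:
#' `I5 = max(0, I4 - (255 - background))`.  Pixels far from any head equal
#' the background level exactly; an isolated default head's darkest pixel is 0.
#'
#' @param head_points Output of [rasterize_points()] for the head positions.
#' @param psf Gaussian head kernel from [make_gaussian_psf()].
#' @param params [appearance_params()].
#' @return Real-valued buffer I5 (same size as `head_points`).
#' @export
render_head_center <- function(head_points, psf = make_gaussian_psf(),
                               params = appearance_params()) {
  stopifnot(inherits(psf, "psf_kernel"))
  gain <- calibrate_gain(psf, params$head_peak)
  i3 <- pmax(convolve2d(head_points / 255, psf$weights) * gain, 0)
  i4 <- 255 - i3
  pmax(i4 - (255 - params$background), 0)
}

#' Render the membrane halo (stage I6)
#'
#' Convolves the rasterized head points with the clipped-Laplacian halo PSF
#' and applies the fixed membrane calibration gain, so an isolated head's
#' halo peaks at `membrane_peak`.  The buffer is additive (all values >= 0)
#' and is added on top of I5 when composing the cell.
#'
#' @inheritParams render_head_center
#' @param psf Halo kernel from [make_halo_psf()].
#' @return Real-valued non-negative buffer I6.
#' @export
render_membrane <- function(head_points, psf = make_halo_psf(),
                            params = appearance_params()) {
  stopifnot(inherits(psf, "psf_kernel"))
  gain <- calibrate_gain(psf, params$membrane_peak)
  # FFT convolution of non-negative inputs can leave ~1e-15 ringing
  pmax(convolve2d(head_points / 255, psf$weights) * gain, 0)
}

#' Render the flagellum ridge (stage I8)
#'
#' Convolves the rasterized tail polyline with the clipped
#' Laplacian-of-Gaussian ridge PSF and scales the result so the rendered
#' tail's ridge peaks at exactly `flagellum_peak`.  Because a dense polyline
#' superposes many single-point responses, the flagellum gain is calibrated
#' against the rendered line response itself (the single-point gain of
#' [calibrate_gain()] would overshoot); an empty tail image yields an
#' all-zero buffer.
#'
#' @param tail_points Output of [rasterize_points()] for the tail polylines.
#' @param psf Ridge kernel from [make_ridge_psf()].
#' @inheritParams render_head_center
#' @return Real-valued non-negative buffer I8.
#' @export
render_flagellum <- function(tail_points, psf = make_ridge_psf(),
                             params = appearance_params()) {
  stopifnot(inherits(psf, "psf_kernel"))
  resp <- pmax(convolve2d(tail_points / 255, psf$weights), 0)
  m <- max(resp)
  if (m <= 0) return(resp * 0)
  resp * (params$flagellum_peak / m)
}

#' Compose the final 8-bit cell image (stage I9)
#'
#' Adds the head-centre, membrane and flagellum buffers, clips to
#' \[0, 255\] and quantizes to integer gray levels:
#' `I9 = round(clip(I5 + I6 + I8, 0, 255))`.
#'
#' @param i5,i6,i8 Buffers from [render_head_center()], [render_membrane()],
#'   [render_flagellum()] (equal dimensions).
#' @return Integer-valued matrix with entries in 0..255.
#' @export
compose_sperm_image <- function(i5, i6, i8) {
  check_same_dim(i5, i6)
  check_same_dim(i5, i8)
  quantize_gray(i5 + i6 + i8)
}

quantize_gray <- function(x) round_half_up(clip_gray(x))

## ---- fast per-cell scene rendering -------------------------------------
## The scene simulator renders per cell (so per-cell intensity factors can
## attenuate each cell's deviation from background) without per-cell frame
## convolutions: a head is a single point, so its I3/I6 responses are just
## the calibrated kernels stamped at the rounded head pixel; tails are
## accumulated into one weighted raster (each cell's fixed flagellum gain and
## intensity factor applied to its own points) and convolved once per frame.

# add `stamp * weight` into `acc` centred at 0-based pixel (px, py), clipped
# at the borders (equivalent to zero-padded convolution)
stamp_kernel <- function(acc, stamp, px, py, weight = 1) {
  n_r <- nrow(acc); n_c <- ncol(acc)
  hw <- (nrow(stamp) - 1L) %/% 2L
  r0 <- py + 1L - hw; r1 <- py + 1L + hw
  c0 <- px + 1L - hw; c1 <- px + 1L + hw
  if (r1 < 1L || c1 < 1L || r0 > n_r || c0 > n_c) return(acc)
  rr <- max(r0, 1L):min(r1, n_r)
  cc <- max(c0, 1L):min(c1, n_c)
  acc[rr, cc] <- acc[rr, cc] + weight * stamp[rr - r0 + 1L, cc - c0 + 1L]
  acc
}

# peak response of the ridge PSF to one rasterized tail, computed on a local
# patch around the points; returns 0 for an empty/out-of-frame tail
tail_peak_response <- function(points, frame_size, psf) {
  pts <- as_points_matrix(points)
  if (nrow(pts) == 0L) return(0)
  hw <- psf$half_width
  px <- round_half_up(pts[, 1]); py <- round_half_up(pts[, 2])
  keep <- px >= 0 & px < frame_size & py >= 0 & py < frame_size
  if (!any(keep)) return(0)
  px <- px[keep]; py <- py[keep]
  x0 <- min(px) - hw; x1 <- max(px) + hw
  y0 <- min(py) - hw; y1 <- max(py) + hw
  patch <- matrix(0, y1 - y0 + 1L, x1 - x0 + 1L)
  patch[cbind(py - y0 + 1L, px - x0 + 1L)] <- 1
  max(convolve2d(patch, psf$weights))
}

# scene-level frame renderer: `cells` is a list of lists with elements
# head (length-2), tail (n x 2), intensity (scalar in (0, 1]), tail_gain
# (response peak -> flagellum_peak scale, already including nothing else).
# Returns the quantized 8-bit frame.  Head/halo kernels are stamped in
# place (a single accumulator, no per-cell convolution); all tails are
# accumulated into one weighted raster and convolved once.
render_scene_frame <- function(cells, frame_size, params, kernels) {
  n <- as.integer(frame_size)
  head_stamp <- pmin(kernels$f1$weights *
                       calibrate_gain(kernels$f1, params$head_peak),
                     params$background)
  halo_stamp <- kernels$f2$weights * calibrate_gain(kernels$f2, params$membrane_peak)
  hw <- kernels$f1$half_width
  deficit <- matrix(0, n, n)   # per-cell head darkening below background
  halo <- matrix(0, n, n)
  tail_raster <- matrix(0, n, n)
  any_tail <- FALSE
  for (cell in cells) {
    w <- cell$intensity
    hx <- round_half_up(cell$head[1]); hy <- round_half_up(cell$head[2])
    r0 <- hy + 1L - hw; r1 <- hy + 1L + hw
    c0 <- hx + 1L - hw; c1 <- hx + 1L + hw
    if (r1 >= 1L && c1 >= 1L && r0 <= n && c0 <= n) {
      rr <- max(r0, 1L):min(r1, n)
      cc <- max(c0, 1L):min(c1, n)
      sr <- rr - r0 + 1L
      sc <- cc - c0 + 1L
      # deviation-from-background form of Process A: the dark centre removes
      # min(background, I3) gray levels, scaled by the cell's intensity factor
      deficit[rr, cc] <- deficit[rr, cc] + w * head_stamp[sr, sc]
      halo[rr, cc] <- halo[rr, cc] + w * halo_stamp[sr, sc]
    }
    tl <- cell$tail
    if (!is.null(tl) && nrow(tl) > 0L && !is.null(cell$tail_gain) &&
        is.finite(cell$tail_gain) && cell$tail_gain > 0) {
      px <- round_half_up(tl[, 1]); py <- round_half_up(tl[, 2])
      keep <- px >= 0 & px < n & py >= 0 & py < n
      if (any(keep)) {
        idx <- cbind(py[keep] + 1L, px[keep] + 1L)
        idx <- idx[!duplicated(idx), , drop = FALSE]
        tail_raster[idx] <- tail_raster[idx] + w * cell$tail_gain
        any_tail <- TRUE
      }
    }
  }
  img <- params$background - deficit + halo
  if (any_tail) img <- img + convolve2d(tail_raster, kernels$f3$weights)
  quantize_gray(img)
}
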