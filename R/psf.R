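## Point-spread functions used to render sperm cells.
##
## Three kernels build a cell: an anisotropic Gaussian for the dark head
## centre, a positive-clipped Laplacian-of-Gaussian producing the bright
## "horseshoe" membrane halo, and an isotropic clipped Laplacian-of-Gaussian
## whose line response draws the flagellum as a single bright ridge.

new_psf_kernel <- function(weights, half_width, sigmas, kind) {
  structure(
    list(weights = weights, half_width = as.integer(half_width),
         sigmas = sigmas, kind = kind),
    class = "psf_kernel"
  )
}

psf_grid <- function(half_width) {
  stop_if_not_number(half_width, "half_width", positive = TRUE)
  half_width <- as.integer(half_width)
  g <- seq(-half_width, half_width)
  list(x = matrix(g, nrow = length(g), ncol = length(g), byrow = TRUE),
       y = matrix(g, nrow = length(g), ncol = length(g)),
       half_width = half_width)
}

check_sigmas <- function(sigmas, n = 2L) {
  sigmas <- as.numeric(sigmas)
  if (length(sigmas) == 1L && n == 2L) sigmas <- rep(sigmas, 2L)
  if (length(sigmas) != n || any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    abort("PSF standard deviations must be positive finite numbers.")
  }
  sigmas
}

#' Gaussian head point-spread function
#'
#' Builds the anisotropic 2-D Gaussian kernel used as the point-spread
#' function of the sperm head centre,
#' \deqn{f_1(x,y) = \frac{1}{2\pi\sigma_x\sigma_y}
#'   \exp\!\left(-\frac{(x/\sigma_x)^2 + (y/\sigma_y)^2}{2}\right),}
#' evaluated on the integer grid \eqn{x, y \in [-h, h]}.  The two standard
#' deviations control the minor and major axis of the rendered head oval.
#'
#' @param sigmas Length-2 numeric, standard deviations \eqn{(\sigma_x,
#'   \sigma_y)} in pixels.  Defaults to the calibrated head axes
#'   (1.86, 2.86) px.
#' @param half_width Integer half-width \eqn{h} of the square support in
#'   pixels; the kernel is \eqn{(2h+1)\times(2h+1)} (default 12, i.e. 25 x 25).
#' @return A `psf_kernel`: list with `weights` (matrix, rows index y),
#'   `half_width`, `sigmas`, `kind`.
#' @examples
#' f1 <- make_gaussian_psf()
#' f1$weights[13, 13] * 2 * pi * 1.86 * 2.86  # central weight, = 1
#' @seealso [make_halo_psf()], [make_ridge_psf()], [calibrate_gain()]
#' @export
make_gaussian_psf <- function(sigmas = c(1.86, 2.86), half_width = 12) {
  sigmas <- check_sigmas(sigmas)
  g <- psf_grid(half_width)
  w <- exp(-((g$x / sigmas[1])^2 + (g$y / sigmas[2])^2) / 2) /
    (2 * pi * sigmas[1] * sigmas[2])
  new_psf_kernel(w, g$half_width, sigmas, "gaussian")
}

# analytic Laplacian of the anisotropic Gaussian above
laplacian_gaussian <- function(x, y, sx, sy) {
  g <- exp(-((x / sx)^2 + (y / sy)^2) / 2) / (2 * pi * sx * sy)
  g * (x^2 / sx^4 + y^2 / sy^4 - 1 / sx^2 - 1 / sy^2)
}

#' Membrane halo point-spread function
#'
#' Positive-clipped Laplacian of an anisotropic Gaussian,
#' \eqn{f_2 = \max(0, \nabla^2 G_{\sigma_x,\sigma_y})}, whose response to a
#' single point is the bright halo ("horseshoe") surrounding the sperm head.
#' The Laplacian is evaluated analytically on the grid; clipping keeps only
#' the positive outer ring so the halo adds light on top of the background.
#'
#' @param sigmas Length-2 numeric \eqn{(\sigma_x, \sigma_y)} px (default
#'   (2.79, 4.29), the calibrated membrane axes).
#' @inheritParams make_gaussian_psf
#' @return A `psf_kernel`.
#' @examples
#' f2 <- make_halo_psf()
#' f2$weights[13, 13]  # central weight is clipped to 0
#' @export
make_halo_psf <- function(sigmas = c(2.79, 4.29), half_width = 12) {
  sigmas <- check_sigmas(sigmas)
  g <- psf_grid(half_width)
  w <- pmax(laplacian_gaussian(g$x, g$y, sigmas[1], sigmas[2]), 0)
  new_psf_kernel(w, g$half_width, sigmas, "halo")
}

#' Flagellum ridge point-spread function
#'
#' Isotropic Laplacian-of-Gaussian kernel with standard deviation `sigma`,
#' clipped to non-negative values (the same clipping as the membrane kernel).
#' Convolved with the rasterized tail polyline it renders the flagellum as a
#' single bright ridge of roughly uniform calibre; without clipping the LoG
#' line response would be a double ridge with a dark core.
#'
#' @param sigma Ridge width in pixels (default 1.5).
#' @inheritParams make_gaussian_psf
#' @return A `psf_kernel`.
#' @export
make_ridge_psf <- function(sigma = 1.5, half_width = 12) {
  sigma <- check_sigmas(sigma, n = 1L)
  g <- psf_grid(half_width)
  w <- pmax(laplacian_gaussian(g$x, g$y, sigma, sigma), 0)
  new_psf_kernel(w, g$half_width, c(sigma, sigma), "ridge")
}

#' Calibration gain for a point-spread function
#'
#' Returns the constant gain such that the response of `psf` to a single
#' isolated unit point, multiplied by the gain, peaks at exactly
#' `target_peak` gray levels.  These are the fixed calibration constants
#' (C1, C2, C3 in the rendering pipeline) computed once from a single-point
#' response — not per-frame normalizers — so overlapping cells superpose
#' additively.
#'
#' @param psf A [psf_kernel][make_gaussian_psf].
#' @param target_peak Target peak gray level in \[0, 255\].
#' @return A single numeric gain.
#' @examples
#' calibrate_gain(make_gaussian_psf(), 255)  # = 255 * 2 * pi * 1.86 * 2.86
#' @export
calibrate_gain <- function(psf, target_peak) {
  stopifnot(inherits(psf, "psf_kernel"))
  stop_if_not_number(target_peak, "target_peak", nonneg = TRUE)
  m <- max(psf$weights)
  if (!is.finite(m) || m <= 0) {
    abort("Cannot calibrate an all-zero kernel.")
  }
  target_peak / m
}

#' @export
print.psf_kernel <- function(x, ...) {
  cat(sprintf("<psf_kernel: %s, %dx%d, sigmas = (%.3g, %.3g)>\n",
              x$kind, nrow(x$weights), ncol(x$weights),
              x$sigmas[1], x$sigmas[2]))
  invisible(x)
}

#' @export
as.matrix.psf_kernel <- function(x, ...) x$weights

#' Dump a kernel as a plain-text matrix
#'
#' Writes the kernel weights as whitespace-separated text for external
#' inspection; [read_psf()] restores the numeric matrix.
#'
#' @param psf A `psf_kernel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psf <- function(psf, path) {
  stopifnot(inherits(psf, "psf_kernel"))
  utils::write.table(format(psf$weights, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_psf
#' @export
read_psf <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}
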