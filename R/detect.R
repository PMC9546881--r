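## Segmentation + localization detectors.
##
## Cells are dark heads with bright halos on a light background, so every
## static method thresholds the complemented frame (foreground = head).
## Masks are cleaned morphologically (closing, dilation, erosion with a
## small disc), components below the minimum area are dropped, and blob
## centroids are reported in the package's 0-based pixel coordinates.

#' Detector parameters
#'
#' @param sensitivity Adaptive (Bradley) threshold sensitivity in (0, 1\];
#'   higher values threshold more pixels as foreground (default 0.8).
#' @param window Adaptive local-mean window in px; `NULL` picks
#'   `2 * floor(N / 16) + 1` from the frame size.
#' @param training_frames Frames used to train the background mixture before
#'   the GMM detector reports detections (default 20).
#' @param gmm_modes Number of Gaussians per pixel (default 3).
#' @param learning_rate Mixture learning rate (default 0.005).
#' @param background_ratio Minimum cumulative weight of background modes
#'   (default 0.7).
#' @param morph_radius Disc radius (px) of the structuring element used for
#'   closing, dilation and erosion (default 2).
#' @param min_area Minimum blob area in px^2 (default 20: comfortably below the ~30 px^2 rendered head blob, above morphology-merged noise specks).
#' @param spot_sigmas Length-2 sd of the spot-enhancement matched filter;
#'   defaults to the rendered head axes (1.86, 2.86) px.
#' @param watershed Split touching blobs with a distance-map watershed
#'   before centroiding (default `TRUE`).
#' @param centroid_weighting Weight blob centroids by (squared) complement
#'   intensity (default `TRUE`); `FALSE` uses the plain binary centroid,
#'   whose quantization error is the classical localization noise of
#'   threshold-based CASA detectors.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(sensitivity = 0.8, window = NULL,
                            training_frames = 20, gmm_modes = 3,
                            learning_rate = 0.005, background_ratio = 0.7,
                            morph_radius = 2, min_area = 20,
                            spot_sigmas = c(1.86, 2.86),
                            watershed = TRUE, centroid_weighting = TRUE) {
  if (sensitivity <= 0 || sensitivity > 1) {
    abort("`sensitivity` must lie in (0, 1].")
  }
  structure(
    list(sensitivity = sensitivity, window = window,
         training_frames = as.integer(training_frames),
         gmm_modes = as.integer(gmm_modes), learning_rate = learning_rate,
         background_ratio = background_ratio,
         morph_radius = as.integer(morph_radius), min_area = min_area,
         spot_sigmas = spot_sigmas, watershed = watershed,
         centroid_weighting = centroid_weighting),
    class = "detector_params"
  )
}

DETECTOR_METHODS <- c("otsu", "adaptive", "spot", "edge", "gmm")

# closing, dilation, erosion with a disc; drop small components; centroids
# (intensity-weighted by `weights` when given, e.g. the complemented frame,
# which localizes the dark head centre better than the binary blob mean)
mask_to_centroids <- function(mask, params, weights = NULL) {
  brush <- EBImage::makeBrush(2L * params$morph_radius + 1L, shape = "disc")
  m <- EBImage::closing(mask, brush)
  m <- EBImage::dilate(m, brush)
  m <- EBImage::erode(m, brush)
  # distance-map watershed separates touching cells that a plain connected
  # component labeling would merge
  lab <- if (isTRUE(params$watershed)) {
    EBImage::watershed(EBImage::distmap(m), tolerance = 1)
  } else {
    EBImage::bwlabel(m)
  }
  nlab <- max(lab)
  if (nlab == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), area = numeric(0)))
  }
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(labs, nlab)
  if (is.null(weights) || !isTRUE(params$centroid_weighting)) {
    w <- rep(1, length(idx))
  } else {
    # quadratic intensity weighting concentrates the centroid on the dark
    # head core, so localization is insensitive to blob-boundary asymmetry
    w <- pmax(weights[idx] - stats::median(weights), 0)^2 + 1e-9
  }
  # centroid in 0-based x (columns) / y (rows)
  wsum <- tapply(w, labs, sum)
  cx <- tapply(w * (cols - 1L), labs, sum) / wsum
  cy <- tapply(w * (rows - 1L), labs, sum) / wsum
  keep <- area >= params$min_area
  tibble::tibble(x = as.numeric(cx[keep]), y = as.numeric(cy[keep]),
                 area = as.numeric(area[keep]))
}

# local mean via summed-area table, window w (odd), zero-gradient borders
local_mean <- function(img, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr + 2L * h) - h, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * h) - h, 1L), nc)
  pad <- img[ri, ci]
  sat <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- rbind(0, cbind(0, sat))                  # (nc+2h+1) x (nr+2h+1)
  r1 <- seq_len(nr); r2 <- r1 + 2L * h
  c1 <- seq_len(nc); c2 <- c1 + 2L * h
  s <- t(sat[c2 + 1L, r2 + 1L] - sat[c1, r2 + 1L] -
           sat[c2 + 1L, r1] + sat[c1, r1])
  s / (w * w)
}

otsu_threshold <- function(img01) EBImage::otsu(EBImage::Image(img01))

# frame (0-255 integer matrix) -> binary mask, per static method
static_mask <- function(frame, method, params) {
  comp <- (255 - frame) / 255   # cells bright on dark
  if (stats::var(as.numeric(frame)) < 1e-9) {
    return(matrix(0L, nrow(frame), ncol(frame)))  # degenerate-threshold guard
  }
  if (method == "otsu") {
    (comp > otsu_threshold(comp)) * 1L
  } else if (method == "adaptive") {
    w <- params$window %||% (2L * (min(dim(frame)) %/% 16L) + 1L)
    mu <- local_mean(comp, as.integer(w))
    # Bradley threshold: foreground where the (box-smoothed) pixel exceeds
    # the local window mean by the sensitivity factor (s = 1 keeps the mean
    # itself); the 5x5 pre-smoother stabilizes the comparison under frame
    # noise without blurring the ~6 px head
    (local_mean(comp, 5L) > mu * (2 - params$sensitivity)) * 1L
  } else if (method == "spot") {
    # blob-enhancing matched filter at the head scale: negated (zero-mean)
    # Laplacian of Gaussian, so a bright head blob yields a positive peak
    # and the uniform background maps to ~0
    g <- psf_grid(12L)
    w <- -laplacian_gaussian(g$x, g$y, params$spot_sigmas[1],
                             params$spot_sigmas[2])
    w <- w - mean(w)
    resp <- EBImage::filter2(comp, w, boundary = "replicate")
    rng <- range(resp)
    if (diff(rng) < 1e-12) return(matrix(0L, nrow(frame), ncol(frame)))
    resp01 <- (resp - rng[1]) / diff(rng)
    (resp01 > otsu_threshold(resp01)) * 1L
  } else if (method == "edge") {
    med <- EBImage::medianFilter(EBImage::Image(comp), 1L)
    sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
    gx <- EBImage::filter2(med, sx, boundary = "replicate")
    gy <- EBImage::filter2(med, t(sx), boundary = "replicate")
    g <- sqrt(gx^2 + gy^2)
    rng <- range(g)
    if (diff(rng) < 1e-12) return(matrix(0L, nrow(frame), ncol(frame)))
    g01 <- (g - rng[1]) / diff(rng)
    edges <- (g01 > otsu_threshold(g01)) * 1L
    brush <- EBImage::makeBrush(2L * params$morph_radius + 1L, shape = "disc")
    edges <- EBImage::dilate(EBImage::Image(edges), brush)
    as.numeric(EBImage::fillHull(edges)) |>
      matrix(nrow(frame), ncol(frame))
  } else {
    abort(sprintf("Unknown detection method '%s'.", method))
  }
}

#' Detect cells in a single frame
#'
#' Applies one of the four static segmentation + localization methods to an
#' 8-bit grayscale frame: global Otsu thresholding, Bradley adaptive
#' thresholding, spot enhancement (a clipped-LoG matched filter at the head
#' scale followed by Otsu), or Sobel edge detection of the median-filtered
#' frame with hole filling.  All methods threshold the complemented frame
#' (heads are dark on a light background), clean the mask morphologically
#' and return blob centroids; a frame with (near-)zero gray-level variance
#' returns no detections rather than an arbitrary threshold.
#'
#' @param frame Integer gray-level matrix (0-255).
#' @param method One of `"otsu"`, `"adaptive"`, `"spot"`, `"edge"`.
#' @param params [detector_params()].
#' @return Tibble with columns `x`, `y`, `area`.
#' @export
detect_frame <- function(frame, method = c("otsu", "adaptive", "spot", "edge"),
                         params = detector_params()) {
  method <- match.arg(method)
  mask_to_centroids(static_mask(frame, method, params), params,
                    weights = 255 - frame)
}

#' Detect cells across a video
#'
#' Runs a detection algorithm over every frame of a video and returns the
#' per-frame centroid table.  The four static methods (see [detect_frame()])
#' are applied frame by frame; `"gmm"` runs the Gaussian-mixture background
#' subtraction motion detector (see [detect_gmm()]), which reports nothing
#' during its training window.
#'
#' @param video A `casa_scene` or list of integer gray-level matrices.
#' @param method One of `"otsu"`, `"adaptive"`, `"spot"`, `"edge"`,
#'   `"gmm"`.
#' @param params [detector_params()].
#' @return Tibble with columns `frame` (0-based), `x`, `y`, `area`.
#' @examples
#' sc <- simulate_semen(simulation_config(frame_size = 96, n_cells = 2,
#'                                        n_immotile = 0, duration = 0.2),
#'                      seed = 1)
#' detect_cells(sc, "adaptive")
#' @export
detect_cells <- function(video, method = DETECTOR_METHODS,
                         params = detector_params()) {
  method <- match.arg(method, DETECTOR_METHODS)
  frames <- if (inherits(video, "casa_scene")) video$frames else video
  if (method == "gmm") return(detect_gmm(frames, params))
  purrr::map2_dfr(frames, seq_along(frames) - 1L, function(f, j) {
    d <- detect_frame(f, method, params)
    if (nrow(d) > 0) dplyr::bind_cols(tibble::tibble(frame = j), d)
    else tibble::tibble(frame = integer(0), x = numeric(0),
                        y = numeric(0), area = numeric(0))
  })
}
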