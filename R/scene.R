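## Scene simulator: multi-cell videos with exact per-frame ground truth.

#' Simulation configuration
#'
#' Collects every parameter of a simulated semen video: geometry (square
#' frame of side `frame_size`, `fps`, `duration`), the cell census
#' (`n_cells` total, of which `n_immotile` are placed as non-moving cells;
#' the rest draw a swim mode from `mode_probs`), appearance, per-mode
#' kinematic parameter blocks, frame noise variance (gray-level^2 on the
#' 0-255 scale), positional jitter, the per-cell intensity-factor range, and
#' an optional swim-mode transition model.
#'
#' @param frame_size Frame side length N, px.
#' @param fps Frame rate, frames/s (default 15).
#' @param duration Video length, s.
#' @param n_cells Total number of cells.
#' @param n_immotile Number of non-moving (immotile) cells, `<= n_cells`.
#' @param mode_probs Named probabilities over `c("circular", "linear",
#'   "hyperactive", "immotile")` used for the cells not covered by
#'   `n_immotile`; missing names count as 0.
#' @param appearance [appearance_params()].
#' @param circular,linear,hyperactive Per-mode kinematic parameter blocks
#'   ([circular_params()], [linear_params()], [hyperactive_params()]); each
#'   cell of that mode gets the block with randomized position, heading and
#'   beat phase.
#' @param noise_variance Zero-mean Gaussian frame-noise variance in
#'   gray-levels^2 on the 0-255 scale (the benchmark sweep spans 0-1225,
#'   i.e. up to sd 35).
#' @param jitter_sigma Positional jitter sd, px; the jittered position is
#'   rendered and recorded as ground truth.
#' @param intensity_range Length-2 range (0, 1\] from which each cell's
#'   intensity factor is drawn uniformly (default `c(1, 1)`).
#' @param transitions Optional [transition_model()].
#' @param seed Optional default seed for [simulate_semen()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(frame_size = 250, fps = 15, duration = 2,
                              n_cells = 10, n_immotile = 3,
                              mode_probs = c(circular = 0.5, linear = 0.5),
                              appearance = appearance_params(),
                              circular = circular_params(),
                              linear = linear_params(),
                              hyperactive = hyperactive_params(),
                              noise_variance = 0, jitter_sigma = 0,
                              intensity_range = c(1, 1),
                              transitions = NULL, seed = NULL) {
  stop_if_not_number(frame_size, "frame_size", positive = TRUE)
  stop_if_not_number(fps, "fps", positive = TRUE)
  stop_if_not_number(duration, "duration", positive = TRUE)
  stop_if_not_number(noise_variance, "noise_variance", nonneg = TRUE)
  stop_if_not_number(jitter_sigma, "jitter_sigma", nonneg = TRUE)
  if (n_cells < 0 || n_immotile < 0 || n_immotile > n_cells) {
    abort("Cell counts must satisfy 0 <= n_immotile <= n_cells.")
  }
  mp <- setNames(numeric(4), SWIM_MODES)
  mp[names(mode_probs)] <- mode_probs
  if (sum(mp) <= 0 && n_cells > n_immotile) {
    abort("`mode_probs` must have positive mass for the moving cells.")
  }
  if (n_cells > n_immotile) mp <- mp / sum(mp)
  structure(
    list(frame_size = as.integer(frame_size), fps = fps, duration = duration,
         n_cells = as.integer(n_cells), n_immotile = as.integer(n_immotile),
         mode_probs = mp, appearance = appearance, circular = circular,
         linear = linear, hyperactive = hyperactive,
         noise_variance = noise_variance, jitter_sigma = jitter_sigma,
         intensity_range = as.numeric(intensity_range),
         transitions = transitions, seed = seed),
    class = "simulation_config"
  )
}

#' Packaged benchmark configurations
#'
#' `sample1_config()` loads the packaged fixture with the parameters
#' estimated from real sample 1 (250 x 250 frames, 10 cells of which 3
#' non-moving, head axes 1.86/2.86 px, normalized noise variance 8.22e-6 —
#' converted to the 0-255 gray scale by multiplying by 255^2): the
#' configuration of the detection benchmark.  `tracking_config()` builds the
#' tracking-benchmark scenario: 500 x 500 px, 15 FPS, 10 s, equal
#' probabilities over the four swim modes, and the printed kinematic
#' parameters (r_c 80 px, f_c 50 deg/s, f_s 4 Hz, a 3 px, f_l 3 Hz, r_h 12
#' px, r_v 8 px, A_har 0.1, V 50 px/s, sigma_b 10 px).
#'
#' @param duration Video length, s (detection fixture default 2 s:
#'   20 background-training frames plus an evaluation window).
#' @param ... Overrides passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
sample1_config <- function(duration = 2, ...) {
  path <- system.file("extdata", "sample1.yaml", package = "casasim")
  fx <- yaml::read_yaml(path)
  simulation_config(
    frame_size = fx$frame_size, duration = duration,
    n_cells = fx$n_cells, n_immotile = fx$n_immotile,
    mode_probs = unlist(fx$mode_probs),
    appearance = appearance_params(
      sigma_head = c(fx$head_radius_minor, fx$head_radius_major),
      background = fx$background
    ),
    noise_variance = fx$noise_variance_normalized * 255^2,
    ...
  )
}

#' @rdname sample1_config
#' @param n_cells Number of cells in the tracking scenario (the benchmark
#'   uses 20, 40, 100 and 200).
#' @export
tracking_config <- function(n_cells = 20, duration = 10, ...) {
  simulation_config(
    frame_size = 500, fps = 15, duration = duration,
    n_cells = n_cells, n_immotile = 0,
    mode_probs = c(circular = 0.25, linear = 0.25,
                   hyperactive = 0.25, immotile = 0.25),
    circular = circular_params(r_c = 80, omega_deg = 50, f_s = 4, a = 3),
    linear = linear_params(V = 50, f_l = 3, r_h = 12, r_v = 8, A_har = 0.1),
    hyperactive = hyperactive_params(sigma_b = 10),
    ...
  )
}

#' Simulate a semen video with ground truth
#'
#' Renders `round(duration * fps)` grayscale frames of swimming cells and
#' the exact per-frame ground-truth table.  Cells are placed uniformly at
#' random with uniform headings and beat phases; each frame advances every
#' cell's kinematic state, applies positional jitter (rendered positions are
#' recorded as truth), renders the cells through the PSF pipeline onto the
#' uniform background, and adds frame noise.  Cells whose head leaves the
#' frame drop out of the truth table for those frames and reappear on
#' re-entry; the whole simulation is reproducible bit-for-bit for a fixed
#' seed.
#'
#' @param config [simulation_config()].
#' @param seed Integer seed (falls back to `config$seed`; if both are
#'   `NULL` the current RNG state is used).
#' @return A `casa_scene`: list with `frames` (list of integer matrices,
#'   gray 0-255), `truth` (tibble: `frame` 0-based, `cell_id`, `x`, `y`,
#'   `mode`), `config`, `seed`.
#' @examples
#' sc <- simulate_semen(simulation_config(frame_size = 96, n_cells = 2,
#'                                        n_immotile = 0, duration = 0.4),
#'                      seed = 1)
#' dplyr::count(sc$truth, frame)
#' @export
simulate_semen <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$frame_size
  T <- 1 / config$fps
  n_frames <- max(1L, round(config$duration * config$fps))
  kernels <- scene_kernels(config$appearance)

  cells <- init_scene_cells(config)
  tm <- config$transitions
  check_every <- if (!is.null(tm)) max(1L, round(config$fps * tm$period)) else NA_integer_

  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (j in seq_len(n_frames) - 1L) {
    t <- j * T
    if (!is.null(tm) && j > 0L && j %% check_every == 0L) {
      cells <- lapply(cells, step_mode, tm = tm, config = config, t = t)
    }
    if (j > 0L) cells <- lapply(cells, advance_cell, t = t, T = T)

    rendered <- lapply(cells, function(cell) {
      off <- if (config$jitter_sigma > 0) rnorm(2, sd = config$jitter_sigma) else c(0, 0)
      list(id = cell$id, mode = cell$mode,
           head = cell$head + off,
           tail = sweep(cell$tail, 2, -off),
           intensity = cell$intensity,
           tail_gain = cell$tail_gain)
    })
    # calibrate missing flagellum gains from this frame's tail response
    for (i in seq_along(rendered)) {
      if (!is.finite(rendered[[i]]$tail_gain)) {
        m <- tail_peak_response(rendered[[i]]$tail, n, kernels$f3)
        if (m > 0) {
          g <- config$appearance$flagellum_peak / m
          rendered[[i]]$tail_gain <- g
          cells[[i]]$tail_gain <- g
        }
      }
    }
    frame <- render_scene_frame(rendered, n, config$appearance, kernels)
    if (config$noise_variance > 0) {
      frame <- add_frame_noise(frame, config$noise_variance)
    }
    frames[[j + 1L]] <- frame

    in_frame <- vapply(rendered, function(r) {
      px <- round_half_up(r$head[1]); py <- round_half_up(r$head[2])
      px >= 0 && px < n && py >= 0 && py < n
    }, logical(1))
    truth[[j + 1L]] <- tibble::tibble(
      frame = j,
      cell_id = vapply(rendered[in_frame], `[[`, integer(1), "id"),
      x = vapply(rendered[in_frame], function(r) r$head[1], numeric(1)),
      y = vapply(rendered[in_frame], function(r) r$head[2], numeric(1)),
      mode = vapply(rendered[in_frame], `[[`, character(1), "mode")
    )
  }

  structure(
    list(frames = frames, truth = dplyr::bind_rows(truth),
         config = config, seed = seed),
    class = "casa_scene"
  )
}

scene_kernels <- function(appearance) {
  hw <- appearance$kernel_half_width
  list(f1 = make_gaussian_psf(appearance$sigma_head, hw),
       f2 = make_halo_psf(appearance$sigma_membrane, hw),
       f3 = make_ridge_psf(appearance$sigma_flagellum, hw))
}

init_scene_cells <- function(config) {
  n <- config$frame_size
  modes <- character(config$n_cells)
  if (config$n_immotile > 0) modes[seq_len(config$n_immotile)] <- "immotile"
  rest <- which(modes == "")
  if (length(rest) > 0) {
    modes[rest] <- sample(SWIM_MODES, length(rest), replace = TRUE,
                          prob = config$mode_probs)
  }
  lapply(seq_len(config$n_cells), function(i) {
    start <- runif(2, 0, n - 1)
    heading <- runif(1, 0, 2 * pi)
    intensity <- runif(1, config$intensity_range[1], config$intensity_range[2])
    init_mode_state(i, modes[i], start, heading, 0, config, intensity)
  })
}

#' Add zero-mean Gaussian frame noise
#'
#' Adds independent zero-mean Gaussian noise of the given variance
#' (gray-levels^2 on the 0-255 scale) to every pixel, then clips to
#' \[0, 255\] and re-quantizes.  The benchmark sweep uses variances from 0
#' to 1225 (sd 35).
#'
#' @param frame Integer gray-level matrix (0-255).
#' @param variance Noise variance, gray^2 (>= 0).
#' @return Integer matrix of the same size.
#' @export
add_frame_noise <- function(frame, variance) {
  stop_if_not_number(variance, "variance", nonneg = TRUE)
  if (variance == 0) return(frame)
  quantize_gray(frame + matrix(rnorm(length(frame), sd = sqrt(variance)),
                               nrow(frame), ncol(frame)))
}

#' @export
print.casa_scene <- function(x, ...) {
  cat(sprintf(
    "<casa_scene: %d frames of %dx%d px, %d cells, %d truth rows>\n",
    length(x$frames), x$config$frame_size, x$config$frame_size,
    x$config$n_cells, nrow(x$truth)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
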