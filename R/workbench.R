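## Scripted benchmarks: the detection noise sweep and the tracking study.

#' Detection benchmark: noise sweep
#'
#' For each replicate, simulates a clean video from `config`, then for every
#' noise level adds zero-mean Gaussian frame noise and runs every detection
#' algorithm.  Detections are scored per frame against ground truth (OSPA
#' with cutoff `c` and order `p`; pooled precision and recall under the same
#' cutoff) on the frames after the background-training window, so all
#' algorithms — including the motion detector, which reports nothing while
#' training — are compared on the same frames.  Scoring crops a border band
#' of one kernel half-width: a cell whose head has left the frame is
#' absent from ground truth while its partially visible body still renders
#' at the border, so border blobs cannot fairly count for or against a
#' detector.
#'
#' @param config [simulation_config()]; defaults to the packaged sample-1
#'   fixture ([sample1_config()]) with immotile non-moving cells.
#' @param noise_levels Noise variances (gray^2, 0-255 scale) to sweep.
#' @param algorithms Detector names (subset of `r toString(DETECTOR_METHODS)`).
#' @param replicates Independent simulated videos per condition (default
#'   20).
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param params [detector_params()].
#' @param ospa_c,ospa_p OSPA cutoff and order (defaults 20 px, 2).
#' @return A tibble of class `casa_sweep`: one row per (algorithm, noise
#'   variance, replicate) with `ospa`, `precision`, `recall`, `n_eval_frames`.
#' @seealso [summarize_sweep()], [autoplot.casa_sweep()]
#' @export
detection_noise_sweep <- function(config = sample1_config(),
                                  noise_levels = c(0, 300, 600, 1225),
                                  algorithms = DETECTOR_METHODS,
                                  replicates = 20, seed = 1,
                                  params = detector_params(),
                                  ospa_c = 20, ospa_p = 2) {
  algorithms <- match.arg(algorithms, DETECTOR_METHODS, several.ok = TRUE)
  cfg <- config
  cfg$noise_variance <- 0
  rows <- list()
  for (r in seq_len(replicates)) {
    scene <- simulate_semen(cfg, seed = seed + r - 1)
    eval_from <- params$training_frames
    truth_eval <- dplyr::filter(scene$truth, .data$frame >= eval_from)
    for (nv in noise_levels) {
      noisy <- if (nv > 0) {
        lapply(scene$frames, add_frame_noise, variance = nv)
      } else scene$frames
      for (algo in algorithms) {
        det <- detect_cells(noisy, algo, params)
        det_eval <- dplyr::filter(det, .data$frame >= eval_from)
        sc <- score_detections(truth_eval, det_eval,
                               frames = eval_from:(length(noisy) - 1L),
                               cutoff = ospa_c, ospa_c = ospa_c,
                               ospa_p = ospa_p,
                               margin = cfg$appearance$kernel_half_width,
                               frame_size = cfg$frame_size)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          algorithm = algo, noise_var = nv, replicate = r,
          ospa = sc$ospa, precision = sc$precision, recall = sc$recall,
          n_eval_frames = sc$n_frames)
      }
    }
  }
  structure(dplyr::bind_rows(rows), class = c("casa_sweep", "tbl_df", "tbl",
                                              "data.frame"))
}

# frame-averaged OSPA and pooled precision/recall of detections vs truth.
# `margin` defines a border ignore band handled match-first: ground truth
# inside the band is dropped together with its matched detection, and
# unmatched detections inside the band are dropped (a cell whose head has
# left the frame is absent from truth while its partially visible body
# still renders near the border, so unmatched border blobs cannot fairly
# count against a detector).
score_detections <- function(truth, detections, frames, cutoff = 20,
                             ospa_c = 20, ospa_p = 2, margin = 0,
                             frame_size = Inf) {
  in_band <- function(x, y) {
    x < margin | y < margin |
      x > frame_size - 1 - margin | y > frame_size - 1 - margin
  }
  ospa_vals <- numeric(length(frames))
  tp <- 0L; nd <- 0L; ng <- 0L
  for (i in seq_along(frames)) {
    f <- frames[i]
    G <- dplyr::filter(truth, .data$frame == f)
    D <- dplyr::filter(detections, .data$frame == f)
    keep_g <- rep(TRUE, nrow(G))
    keep_d <- rep(TRUE, nrow(D))
    if (margin > 0 && (nrow(G) > 0 || nrow(D) > 0)) {
      pr0 <- match_and_pr(G[c("x", "y")], D[c("x", "y")], cutoff)
      g_band <- in_band(G$x, G$y)
      keep_g[g_band] <- FALSE
      if (nrow(pr0$matching) > 0) {
        keep_d[pr0$matching$detection[g_band[pr0$matching$truth]]] <- FALSE
      }
      d_matched <- rep(FALSE, nrow(D))
      d_matched[pr0$matching$detection] <- TRUE
      keep_d[!d_matched & in_band(D$x, D$y)] <- FALSE
    }
    G <- G[keep_g, ]
    D <- D[keep_d, ]
    ospa_vals[i] <- ospa(G[c("x", "y")], D[c("x", "y")],
                         c = ospa_c, p = ospa_p)$total
    pr <- match_and_pr(G[c("x", "y")], D[c("x", "y")], cutoff)
    tp <- tp + pr$tp; nd <- nd + nrow(D); ng <- ng + nrow(G)
  }
  list(ospa = mean(ospa_vals),
       precision = if (nd > 0) tp / nd else as.numeric(ng == 0),
       recall = if (ng > 0) tp / ng else 1,
       n_frames = length(frames))
}

#' Summarize a benchmark over replicates
#'
#' Means and standard deviations of every metric column by condition.
#'
#' @param report A `casa_sweep` or `casa_benchmark` tibble.
#' @return A tibble with one row per condition.
#' @export
summarize_sweep <- function(report) {
  keys <- intersect(c("algorithm", "tracker", "noise_var", "n_cells"),
                    names(report))
  metrics <- setdiff(names(report),
                     c(keys, "replicate", "n_eval_frames"))
  report |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metrics),
                                   list(mean = ~mean(.x), sd = ~sd(.x))),
                     .groups = "drop")
}

#' Tracking benchmark across cell counts
#'
#' Reproduces the tracking study: for each replicate and cell count, a 10 s
#' 500 x 500 px scene with equal swim-mode probabilities is simulated
#' ([tracking_config()]), cells are detected per frame (adaptive
#' thresholding with plain binary blob centroids on the noiseless frames,
#' so the ~1 px localization error is attributable to centroid
#' quantization), each tracking algorithm is run on the same detections,
#' and the measurement-updated track positions are scored with CLEAR-MOT
#' against the simulation ground truth.  The default Kalman process noise
#' is matched to the swim models' maneuvering scale (see
#' [kalman_config()]), unlike the deliberately generic package default.
#'
#' @param cell_counts Cell counts to test (the study uses 20, 40, 100, 200).
#' @param replicates Scenes per cell count (default 20).
#' @param trackers Tracker names (subset of nn, gnn, pdaf, jpdaf).
#' @param seed Base seed; scene (count i, replicate r) derives its own seed.
#' @param cfg [kalman_config()].
#' @param detector Static detector used to produce measurements.
#' @param duration Scene length in seconds (default 10).
#' @param c_T CLEAR-MOT cutoff, px (default 5).
#' @return A tibble of class `casa_benchmark`: one row per (tracker,
#'   n_cells, replicate) with `motp`, `fp`, `miss`, `mme`, `mota`.
#' @export
tracking_benchmark <- function(cell_counts = c(20, 40, 100, 200),
                               replicates = 20,
                               trackers = TRACKER_ALGOS, seed = 1,
                               cfg = kalman_config(process_intensity = 2000),
                               detector = "adaptive", duration = 10,
                               c_T = 5) {
  trackers <- match.arg(trackers, TRACKER_ALGOS, several.ok = TRUE)
  rows <- list()
  for (ci in seq_along(cell_counts)) {
    nc <- cell_counts[ci]
    for (r in seq_len(replicates)) {
      scene_seed <- seed + 1000L * (ci - 1L) + (r - 1L)
      scene <- simulate_semen(tracking_config(nc, duration = duration),
                              seed = scene_seed)
      det <- detect_cells(scene, detector,
                          detector_params(watershed = FALSE,
                                          centroid_weighting = FALSE))
      for (algo in trackers) {
        trk <- track_cells(det, algo, cfg, n_frames = length(scene$frames))
        trk <- dplyr::filter(trk, !.data$coasted)
        rep_mot <- clear_mot(scene$truth, trk, c_T = c_T)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          tracker = algo, n_cells = nc, replicate = r,
          motp = rep_mot$motp, fp = rep_mot$fp_rate,
          miss = rep_mot$miss_rate, mme = rep_mot$mismatch_rate,
          mota = rep_mot$mota)
      }
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("casa_benchmark", "tbl_df", "tbl", "data.frame"))
}
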