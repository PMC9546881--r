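## Evaluation metrics: OSPA distance, assignment-based precision/recall,
## and CLEAR-MOT (MOTP/MOTA) scoring of tracks against ground truth.

#' Optimal subpattern assignment (OSPA) distance
#'
#' Schuhmacher's OSPA metric between two planar point sets with cutoff `c`
#' and order `p`: with \eqn{m = |X| \le n = |Y|} (sets swapped otherwise),
#' \deqn{d = \left(\frac{1}{n}\left[\min_\pi \sum_i d_c(x_i,
#'   y_{\pi(i)})^p + c^p (n - m)\right]\right)^{1/p},}
#' where \eqn{d_c = \min(d, c)} and the minimum runs over one-to-one
#' assignments (solved exactly).  It combines a localization component (the
#' matched-distance term) and a cardinality component (the \eqn{c^p(n-m)}
#' term); two empty sets are at distance 0.
#'
#' @param x,y Point sets: n x 2 matrices, data frames with `x`/`y`, or
#'   length-2 vectors; either may be empty.
#' @param c Cutoff distance, px (> 0); the distance is bounded by `c`.
#' @param p Order exponent (>= 1).
#' @return An `ospa_result`: list with `total`, `localization`,
#'   `cardinality`, `c`, `p`, `n_x`, `n_y`.
#' @examples
#' ospa(c(0, 0), c(3, 4))$total  # 5
#' ospa(c(0, 0), NULL)$total     # 20: pure cardinality error
#' @export
ospa <- function(x, y, c = 20, p = 2) {
  stop_if_not_number(c, "c", positive = TRUE)
  if (p < 1) abort("`p` must be >= 1.")
  X <- as_points_matrix(x)
  Y <- as_points_matrix(y)
  if (nrow(X) > nrow(Y)) { tmp <- X; X <- Y; Y <- tmp }
  m <- nrow(X); n <- nrow(Y)
  if (n == 0L) {
    return(new_ospa(0, 0, 0, c, p, m, n))
  }
  if (m == 0L) {
    return(new_ospa(c, 0, c, c, p, m, n))
  }
  dmat <- pmin(cross_dist(X, Y), c)
  assign <- solve_assignment(dmat^p)
  loc_sum <- sum(dmat[cbind(seq_len(m), assign)]^p)
  total <- ((loc_sum + c^p * (n - m)) / n)^(1 / p)
  new_ospa(total,
           localization = (loc_sum / n)^(1 / p),
           cardinality = (c^p * (n - m) / n)^(1 / p),
           c, p, m, n)
}

new_ospa <- function(total, localization, cardinality, c, p, n_x, n_y) {
  structure(
    list(total = total, localization = localization,
         cardinality = cardinality, c = c, p = p, n_x = n_x, n_y = n_y),
    class = "ospa_result"
  )
}

#' @export
print.ospa_result <- function(x, ...) {
  cat(sprintf(
    "OSPA(c = %g, p = %g) = %.4f  [localization %.4f, cardinality %.4f; |X| = %d, |Y| = %d]\n",
    x$c, x$p, x$total, x$localization, x$cardinality, x$n_x, x$n_y))
  invisible(x)
}

#' Assignment-based precision and recall
#'
#' Matches detections to ground-truth points one-to-one by a minimum-cost
#' assignment in which only pairs closer than `cutoff` may pair; matched
#' pairs are true positives.  Precision = TP / #detections, recall =
#' TP / #truth.  Conventions at degenerate inputs: with no detections,
#' precision is 1 if there is also no truth and 0 otherwise; with no truth,
#' recall is 1 (vacuous).
#'
#' @param truth,detections Point sets (n x 2 matrix, data frame with
#'   `x`/`y`, or length-2 vector); either may be empty.
#' @param cutoff Maximum pairing distance, px (default 20, the OSPA cutoff,
#'   so detection metrics share one distance scale).
#' @return List with `precision`, `recall`, `tp`, and `matching` (tibble of
#'   matched index pairs and distances).
#' @export
match_and_pr <- function(truth, detections, cutoff = 20) {
  stop_if_not_number(cutoff, "cutoff", positive = TRUE)
  G <- as_points_matrix(truth)
  D <- as_points_matrix(detections)
  ng <- nrow(G); nd <- nrow(D)
  if (ng == 0L || nd == 0L) {
    return(list(
      precision = if (nd == 0L) as.numeric(ng == 0L) else 0,
      recall = if (ng == 0L) 1 else 0,
      tp = 0L,
      matching = tibble::tibble(truth = integer(0), detection = integer(0),
                                distance = numeric(0))
    ))
  }
  dmat <- cross_dist(G, D)
  # all over-cutoff pairs share one large cost, so the assignment first
  # maximizes the number of valid pairs, then minimizes their distance
  big <- cutoff * (max(ng, nd) + 1)
  assign <- solve_assignment(ifelse(dmat <= cutoff, dmat, big))
  ti <- which(!is.na(assign))
  di <- assign[ti]
  ok <- dmat[cbind(ti, di)] <= cutoff
  matching <- tibble::tibble(truth = ti[ok], detection = di[ok],
                             distance = dmat[cbind(ti[ok], di[ok])])
  tp <- nrow(matching)
  list(precision = tp / nd, recall = tp / ng, tp = tp, matching = matching)
}

#' Multi-object tracking accuracy from its component rates
#'
#' The CLEAR-MOT accuracy identity: `MOTA = 1 - (FP + M + MME)`, where the
#' three arguments are the false-positive, miss, and mismatch rates
#' normalized by the total number of ground-truth objects over all frames.
#'
#' @param fp_rate,miss_rate,mismatch_rate Normalized error rates.
#' @return MOTA (1 is perfect; can be negative).
#' @examples
#' mot_accuracy(0.2101, 0.0941, 0.0003)  # 0.6955
#' @export
mot_accuracy <- function(fp_rate, miss_rate, mismatch_rate) {
  1 - (fp_rate + miss_rate + mismatch_rate)
}

#' CLEAR-MOT evaluation of tracks against ground truth
#'
#' Bernardin-Stiefelhagen scoring: per frame, correspondences from the
#' previous frame persist while both sides exist and remain within the
#' cutoff `c_T`; remaining objects and hypotheses are matched by a
#' minimum-distance one-to-one assignment under `c_T`.  A ground-truth
#' object whose matched track identity changes counts as a mismatch.  MOTP
#' is the mean distance over all matches (the raw sum is also reported);
#' the false-positive, miss and mismatch rates are normalized by the total
#' ground-truth object count over all frames, and
#' `MOTA = 1 - (FP + M + MME)`.
#'
#' @param truth Ground-truth tibble (`frame`, `cell_id`, `x`, `y`) or a
#'   `casa_scene`.
#' @param tracks Track tibble (`track_id`, `frame`, `x`, `y`).
#' @param c_T Match cutoff distance, px (default 5).
#' @return A `mot_report`: list with `motp`, `motp_sum`, `fp_rate`,
#'   `miss_rate`, `mismatch_rate`, `mota`, raw counts, and the per-frame
#'   count tibble.
#' @export
clear_mot <- function(truth, tracks, c_T = 5) {
  if (inherits(truth, "casa_scene")) truth <- truth$truth
  stop_if_not_number(c_T, "c_T", positive = TRUE)
  frames <- sort(union(unique(truth$frame),
                       if (nrow(tracks) > 0) unique(tracks$frame) else integer(0)))
  truth_by <- split(truth, truth$frame)
  tracks_by <- if (nrow(tracks) > 0) split(tracks, tracks$frame) else list()

  map_prev <- list()   # cell_id (chr) -> track_id of last correspondence
  n_match <- 0L; n_fp <- 0L; n_miss <- 0L; n_mme <- 0L; n_truth <- 0L
  dist_sum <- 0
  per_frame <- vector("list", length(frames))

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    gt <- truth_by[[as.character(f)]]
    hy <- tracks_by[[as.character(f)]]
    ng <- if (is.null(gt)) 0L else nrow(gt)
    nh <- if (is.null(hy)) 0L else nrow(hy)
    n_truth <- n_truth + ng
    matches <- integer(0)        # index into hy per matched gt row
    gt_open <- seq_len(ng)
    hy_open <- seq_len(nh)
    pair_gt <- integer(0); pair_hy <- integer(0)

    if (ng > 0L && nh > 0L) {
      dmat <- cross_dist(cbind(gt$x, gt$y), cbind(hy$x, hy$y))
      # persist previous correspondences still within the cutoff
      for (i in seq_len(ng)) {
        key <- as.character(gt$cell_id[i])
        tid <- map_prev[[key]]
        if (!is.null(tid)) {
          k <- which(hy$track_id == tid)
          if (length(k) == 1L && dmat[i, k] <= c_T && k %in% hy_open) {
            pair_gt <- c(pair_gt, i); pair_hy <- c(pair_hy, k)
            gt_open <- setdiff(gt_open, i)
            hy_open <- setdiff(hy_open, k)
          }
        }
      }
      if (length(gt_open) > 0L && length(hy_open) > 0L) {
        sub <- dmat[gt_open, hy_open, drop = FALSE]
        big <- c_T * (max(ng, nh) + 1)
        assign <- solve_assignment(ifelse(sub <= c_T, sub, big))
        for (a in seq_along(assign)) {
          if (!is.na(assign[a]) && sub[a, assign[a]] <= c_T) {
            pair_gt <- c(pair_gt, gt_open[a])
            pair_hy <- c(pair_hy, hy_open[assign[a]])
          }
        }
      }
    }

    nm <- length(pair_gt)
    if (nm > 0L) {
      d <- sqrt((gt$x[pair_gt] - hy$x[pair_hy])^2 +
                  (gt$y[pair_gt] - hy$y[pair_hy])^2)
      dist_sum <- dist_sum + sum(d)
      for (a in seq_len(nm)) {
        key <- as.character(gt$cell_id[pair_gt[a]])
        tid <- hy$track_id[pair_hy[a]]
        old <- map_prev[[key]]
        if (!is.null(old) && old != tid) n_mme <- n_mme + 1L
        map_prev[[key]] <- tid
      }
    }
    n_match <- n_match + nm
    n_miss <- n_miss + (ng - nm)
    n_fp <- n_fp + (nh - nm)
    per_frame[[fi]] <- tibble::tibble(frame = f, n_truth = ng,
                                      n_tracks = nh, matches = nm)
  }

  if (n_truth == 0L) abort("Ground truth has no objects.")
  fp_rate <- n_fp / n_truth
  miss_rate <- n_miss / n_truth
  mme_rate <- n_mme / n_truth
  structure(
    list(motp = if (n_match > 0) dist_sum / n_match else NA_real_,
         motp_sum = dist_sum,
         fp_rate = fp_rate, miss_rate = miss_rate, mismatch_rate = mme_rate,
         mota = mot_accuracy(fp_rate, miss_rate, mme_rate),
         n_matches = n_match, n_fp = n_fp, n_miss = n_miss, n_mme = n_mme,
         n_truth = n_truth, c_T = c_T,
         per_frame = dplyr::bind_rows(per_frame)),
    class = "mot_report"
  )
}

#' @export
print.mot_report <- function(x, ...) {
  cat(sprintf(
    "CLEAR-MOT (c_T = %g px): MOTP = %.3f px, MOTA = %.4f\n  FP = %.4f, miss = %.4f, mismatch = %.4f  (%d truth objects over %d frames)\n",
    x$c_T, x$motp, x$mota, x$fp_rate, x$miss_rate, x$mismatch_rate,
    x$n_truth, nrow(x$per_frame)))
  invisible(x)
}
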