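## Gaussian-mixture background-subtraction motion detector.
##
## Per-pixel adaptive mixture of K Gaussians (Stauffer-Grimson style):
## modes are matched within 2.5 sd, matched modes are blended with the
## learning rate, unmatched pixels replace the weakest mode, and the modes
## with the largest weight/sd ratio form the background up to the cumulative
## background ratio.  Foreground = pixels not explained by background modes.

#' Detect moving cells by background subtraction
#'
#' Trains a per-pixel Gaussian mixture over the first `training_frames`
#' frames (those frames yield empty detection lists) and afterwards reports
#' the centroids of morphologically cleaned foreground blobs.  Static cells
#' are absorbed into the background model, so this motion detector finds
#' only moving cells.
#'
#' @param frames List of integer gray-level matrices (0-255) or a
#'   `casa_scene`.
#' @param params [detector_params()] (`training_frames`, `gmm_modes`,
#'   `learning_rate`, `background_ratio`, morphology settings).
#' @return Tibble with columns `frame` (0-based), `x`, `y`, `area`.
#' @export
detect_gmm <- function(frames, params = detector_params()) {
  if (inherits(frames, "casa_scene")) frames <- frames$frames
  nf <- length(frames)
  if (nf < params$training_frames) {
    abort(sprintf("GMM needs at least %d frames (%d given).",
                  params$training_frames, nf))
  }
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  npx <- nr * nc
  K <- params$gmm_modes
  alpha <- params$learning_rate
  var_init <- 40^2  # wide enough that fresh modes absorb heavy frame noise
  var_min <- 15^2   # floor keeps the faint flagellum (contrast ~13) sub-threshold

  W <- matrix(0, npx, K); W[, 1] <- 1
  MU <- matrix(0, npx, K); MU[, 1] <- as.numeric(frames[[1]])
  V <- matrix(var_init, npx, K)

  out <- vector("list", nf)
  for (j in seq_len(nf)) {
    # adaptive 1/t rate during training so transient cells in the first
    # frames are averaged out of the background model
    alpha <- max(params$learning_rate, 1 / j)
    x <- as.numeric(frames[[j]])
    d2 <- (MU - x)^2
    matched <- d2 < 6.25 * V             # within 2.5 sd
    rank <- W / sqrt(V)
    score <- ifelse(matched, rank, -Inf)
    best <- max.col(score, ties.method = "first")
    has_match <- matched[cbind(seq_len(npx), best)]

    sel <- cbind(which(has_match), best[has_match])
    W <- (1 - alpha) * W
    W[sel] <- W[sel] + alpha
    MU[sel] <- MU[sel] + alpha * (x[sel[, 1]] - MU[sel])
    V[sel] <- pmax(var_min,
                   V[sel] + alpha * ((x[sel[, 1]] - MU[sel])^2 - V[sel]))

    if (any(!has_match)) {
      weakest <- max.col(-W, ties.method = "first")
      repl <- cbind(which(!has_match), weakest[!has_match])
      W[repl] <- 0.05
      MU[repl] <- x[repl[, 1]]
      V[repl] <- var_init
    }
    W <- W / rowSums(W)

    if (j > params$training_frames) {
      # background = top modes (by weight/sd) holding background_ratio mass;
      # ranking vectorized by repeated max.col (K is small)
      rnk <- W / sqrt(V)
      ii <- seq_len(npx)
      ord <- matrix(0L, npx, K)
      csum <- matrix(0, npx, K)
      acc <- numeric(npx)
      tmp <- rnk
      for (b in seq_len(K)) {
        ord[, b] <- max.col(tmp, ties.method = "first")
        acc <- acc + W[cbind(ii, ord[, b])]
        csum[, b] <- acc
        tmp[cbind(ii, ord[, b])] <- -Inf
      }
      n_bg <- 1L + rowSums(csum[, -K, drop = FALSE] <
                             params$background_ratio)
      best_pos <- integer(npx)
      for (b in seq_len(K)) best_pos[ord[, b] == best] <- b
      # foreground decision at 4 sd (stricter than the 2.5 sd model match,
      # which also truncates the learned variance) so Gaussian noise tails
      # do not seed spurious blobs
      bg_ok <- matrix(FALSE, npx, K)
      for (b in seq_len(K)) {
        bg_ok[, b] <- d2[cbind(seq_len(npx), ord[, b])] < 16 *
          V[cbind(seq_len(npx), ord[, b])] & b <= n_bg
      }
      fg <- rowSums(bg_ok) == 0
      mask <- matrix(as.integer(fg), nr, nc)
      det <- mask_to_centroids(mask, params, weights = 255 - frames[[j]])
      out[[j]] <- if (nrow(det) > 0) {
        dplyr::bind_cols(tibble::tibble(frame = j - 1L), det)
      } else NULL
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(frame = integer(0), x = numeric(0),
                          y = numeric(0), area = numeric(0))
  }
  res
}
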