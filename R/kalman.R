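## Constant-velocity Kalman core shared by the four trackers.
##
## State (x, y, vx, vy); position-only measurements; white-acceleration
## process noise of configurable intensity.  Velocity starts at 0 with a
## large prior so the first few updates pull it toward the data.

#' Tracker configuration
#'
#' @param T Frame period, s.
#' @param process_intensity White-acceleration process-noise intensity q,
#'   px^2/s^3 (default 50).
#' @param measurement_sd Measurement noise sd, px (default 1).
#' @param gate Euclidean association gate radius around the predicted
#'   position, px (default 20).
#' @param p_detect Detection probability P_D used by the probabilistic
#'   associators (default 0.95).
#' @param clutter_density Spatial clutter density, detections per px^2
#'   (default 1e-4).
#' @param confirm_hits Consecutive associations needed to confirm a new
#'   track (default 2).
#' @param max_misses Consecutive misses after which a track is closed
#'   (default 3).
#' @param spawn_claim Association-probability mass above which a gated
#'   detection is considered consumed by the probabilistic associators and
#'   cannot initiate a new track (default 0.3).
#' @param v0_sd Prior sd of each velocity component, px/s (default 100).
#' @return A list of class `kalman_config`.
#' @export
kalman_config <- function(T = 1 / 15, process_intensity = 50,
                          measurement_sd = 1, gate = 20, p_detect = 0.95,
                          clutter_density = 1e-4, confirm_hits = 2,
                          max_misses = 3, spawn_claim = 0.3, v0_sd = 100) {
  stop_if_not_number(T, "T", positive = TRUE)
  stop_if_not_number(gate, "gate", positive = TRUE)
  if (p_detect <= 0 || p_detect > 1) abort("`p_detect` must be in (0, 1].")
  structure(
    list(T = T, q = process_intensity, r = measurement_sd, gate = gate,
         p_detect = p_detect, clutter_density = clutter_density,
         confirm_hits = as.integer(confirm_hits),
         max_misses = as.integer(max_misses), spawn_claim = spawn_claim,
         v0_sd = v0_sd),
    class = "kalman_config"
  )
}

kalman_matrices <- function(cfg) {
  T <- cfg$T
  F <- diag(4)
  F[1, 3] <- T; F[2, 4] <- T
  q <- cfg$q
  Q <- q * matrix(c(T^3 / 3, 0, T^2 / 2, 0,
                    0, T^3 / 3, 0, T^2 / 2,
                    T^2 / 2, 0, T, 0,
                    0, T^2 / 2, 0, T), 4, 4)
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  R <- diag(cfg$r^2, 2)
  list(F = F, Q = Q, H = H, R = R)
}

new_kalman_state <- function(z, cfg) {
  list(x = c(z[1], z[2], 0, 0),
       P = diag(c(cfg$r^2, cfg$r^2, cfg$v0_sd^2, cfg$v0_sd^2)))
}

kalman_predict <- function(st, mats) {
  x <- mats$F %*% st$x
  P <- mats$F %*% st$P %*% t(mats$F) + mats$Q
  list(x = as.numeric(x), P = (P + t(P)) / 2)
}

# standard single-measurement update; z = NULL coasts on the prediction
kalman_update <- function(st, z, mats) {
  if (is.null(z)) return(st)
  S <- mats$H %*% st$P %*% t(mats$H) + mats$R
  K <- st$P %*% t(mats$H) %*% solve(S)
  nu <- z - as.numeric(mats$H %*% st$x)
  x <- st$x + as.numeric(K %*% nu)
  IKH <- diag(4) - K %*% mats$H
  # Joseph form keeps P symmetric positive definite
  P <- IKH %*% st$P %*% t(IKH) + K %*% mats$R %*% t(K)
  list(x = x, P = (P + t(P)) / 2)
}

# probabilistic data association update: measurements zs (k x 2) with
# association probabilities beta (length k) and miss probability beta0
kalman_update_pda <- function(st, zs, beta, beta0, mats) {
  S <- mats$H %*% st$P %*% t(mats$H) + mats$R
  K <- st$P %*% t(mats$H) %*% solve(S)
  zhat <- as.numeric(mats$H %*% st$x)
  nus <- sweep(zs, 2, zhat)                    # k x 2 innovations
  nu_bar <- colSums(nus * beta)
  x <- st$x + as.numeric(K %*% nu_bar)
  Pc <- st$P - K %*% S %*% t(K)                # covariance if one z certain
  spread <- t(nus * beta) %*% nus - outer(nu_bar, nu_bar)
  P <- beta0 * st$P + (1 - beta0) * Pc + K %*% spread %*% t(K)
  list(x = x, P = (P + t(P)) / 2)
}

#' One constant-velocity Kalman step
#'
#' Predicts a track state one frame ahead and updates it with a detection
#' (or coasts when `detection` is `NULL` or outside the gate).  Exposed
#' mainly for testing and for building custom trackers; [track_cells()]
#' drives the same core.
#'
#' @param state List with `x` (state: x, y, vx, vy) and `P` (4 x 4
#'   covariance); `NULL` initializes a fresh state at the detection.
#' @param detection Length-2 measured position, or `NULL` for a miss.
#' @param cfg [kalman_config()].
#' @return Updated state list.
#' @export
kalman_cv_step <- function(state, detection = NULL, cfg = kalman_config()) {
  mats <- kalman_matrices(cfg)
  if (is.null(state)) {
    if (is.null(detection)) abort("Need a detection to initialize a state.")
    return(new_kalman_state(detection, cfg))
  }
  pred <- kalman_predict(state, mats)
  if (!is.null(detection)) {
    d <- sqrt(sum((detection - pred$x[1:2])^2))
    if (d > cfg$gate) detection <- NULL     # outside gate: treated as a miss
  }
  kalman_update(pred, detection, mats)
}

# Gaussian measurement likelihood N(nu; 0, S) for rows of nus
gauss_lik <- function(nus, S) {
  Si <- solve(S)
  dets <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  q <- nus[, 1]^2 * Si[1, 1] + 2 * nus[, 1] * nus[, 2] * Si[1, 2] +
    nus[, 2]^2 * Si[2, 2]
  exp(-q / 2) / (2 * pi * sqrt(dets))
}
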