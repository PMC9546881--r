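## Head trajectories and tail polylines for the four swim modes.
##
## All kinematics are evaluated at frame times t = j / fps.  Tail polylines
## always have exactly M points; the tail index grid is k = seq(0, M,
## length.out = M) so the profile functions b(.) are evaluated at both
## printed endpoints (k = 0 at the head, k = M at the tip, where the
## un-rotated tail lies exactly lambda px from the head).

rotate_xy <- function(x, y, theta) {
  ct <- cos(theta); st <- sin(theta)
  cbind(x = ct * x - st * y, y = st * x + ct * y)
}

#' Circular swim: head position
#'
#' Head of a circular swimming cell at time `t`:
#' \deqn{x(t) = (r_c + a\sin 2\pi f_s t)\cos\theta_c(t) + C_x,\quad
#'       y(t) = (r_c + a\sin 2\pi f_s t)\sin\theta_c(t) + C_y,}
#' with circle phase \eqn{\theta_c(t) = \omega t + \phi_0} (\eqn{\omega}
#' configured in degrees/s).
#'
#' @param t Time(s) in seconds (vectorized).
#' @param p [circular_params()].
#' @return Tibble with columns `t`, `x`, `y` (px).
#' @examples
#' circular_head(0, circular_params(r_c = 10, a = 0))  # (10, 0)
#' @export
circular_head <- function(t, p = circular_params()) {
  stopifnot(inherits(p, "circular_params"))
  if (any(t < 0)) abort("`t` must be >= 0.")
  rho <- p$r_c + p$a * sin(2 * pi * p$f_s * (t + p$t_beat0))
  th <- p$omega * t + p$phase0
  tibble::tibble(t = t, x = rho * cos(th) + p$offset[1],
                 y = rho * sin(th) + p$offset[2])
}

# instantaneous direction of motion of the circular head (rad); falls back
# to the circle tangent when the analytic velocity degenerates to zero
circular_heading <- function(t, p) {
  tb <- t + p$t_beat0
  rho <- p$r_c + p$a * sin(2 * pi * p$f_s * tb)
  drho <- 2 * pi * p$f_s * p$a * cos(2 * pi * p$f_s * tb)
  th <- p$omega * t + p$phase0
  vx <- drho * cos(th) - rho * p$omega * sin(th)
  vy <- drho * sin(th) + rho * p$omega * cos(th)
  ifelse(abs(vx) + abs(vy) < 1e-12, th + pi / 2, atan2(vy, vx))
}

tail_index_grid <- function(M) seq(0, M, length.out = M)

#' Circular swim: tail polyline
#'
#' Tail of a circular swimming cell (Dresdner's travelling-wave flagellum):
#' in the local frame `x(k, t) = b(k) sin(2 pi (k / M - f_s t))`,
#' `y(k) = -lambda k / M`, with the linear amplitude profile
#' `b(k) = a (alpha lambda k / M + beta)`.  The local curve is rotated to
#' trail behind the instantaneous direction of motion and translated to the
#' head.
#'
#' @param t Time in seconds (scalar).
#' @param head Length-2 head position (px); defaults to
#'   `circular_head(t, p)`.
#' @param p [circular_params()].
#' @return Tibble with columns `k`, `x`, `y` (`M` rows).
#' @export
circular_tail <- function(t, head = NULL, p = circular_params()) {
  xy <- circular_tail_xy(t, head, p)
  tibble::tibble(k = tail_index_grid(p$M), x = xy[, 1], y = xy[, 2])
}

# matrix version used in the per-frame simulation loop
circular_tail_xy <- function(t, head = NULL, p) {
  stopifnot(inherits(p, "circular_params"), length(t) == 1L)
  if (is.null(head)) {
    h <- circular_head(t, p)
    head <- c(h$x, h$y)
  }
  s <- tail_index_grid(p$M) / p$M
  b <- p$a * (p$alpha * p$lambda * s + p$beta)
  xl <- b * sin(2 * pi * (s - p$f_s * (t + p$t_beat0)))
  yl <- -p$lambda * s
  rot <- circular_heading(t, p) - pi / 2   # local -y axis trails the motion
  xy <- rotate_xy(xl, yl, rot)
  xy[, 1] <- xy[, 1] + head[1]
  xy[, 2] <- xy[, 2] + head[2]
  xy
}

#' Ribbon amplitude correction constant
#'
#' `A_c = 1 / max_theta (sin(theta) + A_har * sin(3 theta))`: the constant
#' that rescales the two-harmonic across-track oscillation of the linear
#' mean swim so its amplitude is exactly `r_h / 2`.
#'
#' @param A_har Third-harmonic ratio, >= 0.
#' @return A single numeric in (0, 1\].
#' @examples
#' ribbon_constant(0)  # 1
#' @export
ribbon_constant <- function(A_har) {
  stop_if_not_number(A_har, "A_har", nonneg = TRUE)
  f <- function(th) sin(th) + A_har * sin(3 * th)
  grid <- seq(0, 2 * pi, length.out = 4001L)
  i <- which.max(f(grid))
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)
  1 / max(opt$objective, f(grid[i]))
}

linear_ribbon <- function(t, p) {
  tb <- t + p$t_beat0
  px <- p$r_v / 2 * sin(4 * pi * p$f_l * tb)
  py <- p$r_h * p$A_c / 2 *
    (sin(2 * pi * p$f_l * tb) + p$A_har * sin(6 * pi * p$f_l * tb))
  cbind(px, py)
}

#' Linear mean swim: head position
#'
#' Straight-line progression plus rotated ribbon offset: the centre moves as
#' `(V cos(theta_r) t + C_x, V sin(theta_r) t + C_y)` and the head adds the
#' ribbon oscillation `R(theta_r) P(t)` with
#' `P(t) = (r_v/2 sin(4 pi f_l t), r_h A_c / 2 (sin(2 pi f_l t) + A_har
#' sin(6 pi f_l t)))`.
#'
#' @param t Time(s) in seconds (vectorized).
#' @param p [linear_params()].
#' @return Tibble with columns `t`, `x`, `y` (px).
#' @export
linear_head <- function(t, p = linear_params()) {
  stopifnot(inherits(p, "linear_params"))
  if (any(t < 0)) abort("`t` must be >= 0.")
  cx <- p$V * cos(p$theta_r) * t + p$offset[1]
  cy <- p$V * sin(p$theta_r) * t + p$offset[2]
  rib <- linear_ribbon(t, p)
  xy <- rotate_xy(rib[, 1], rib[, 2], p$theta_r)
  tibble::tibble(t = t, x = cx + xy[, 1], y = cy + xy[, 2])
}

#' Linear mean swim: tail polyline
#'
#' Tail of a linear mean swimming cell: horizontal/vertical oscillations
#' `x_T = r_v/2 sin(4 pi (k/M + f_l t))`, `y_T = r_h/2 sin(2 pi (k/M + f_l
#' t))` are shaped by the amplitude profiles `b1` (transformed sigmoid) and
#' `b2` (decaying exponential), laid along the travel axis via `-lambda k /
#' M`, vertically corrected by `b3` for the harmonic content the tail does
#' not carry, then rotated by `theta_r` and translated to the head.
#'
#' @inheritParams circular_tail
#' @param p [linear_params()].
#' @return Tibble with columns `k`, `x`, `y` (`M` rows).
#' @export
linear_tail <- function(t, head = NULL, p = linear_params()) {
  xy <- linear_tail_xy(t, head, p)
  tibble::tibble(k = tail_index_grid(p$M), x = xy[, 1], y = xy[, 2])
}

# matrix version used in the per-frame simulation loop
linear_tail_xy <- function(t, head = NULL, p) {
  stopifnot(inherits(p, "linear_params"), length(t) == 1L)
  if (is.null(head)) {
    h <- linear_head(t, p)
    head <- c(h$x, h$y)
  }
  s <- tail_index_grid(p$M) / p$M
  tb <- t + p$t_beat0
  xT <- p$r_v / 2 * sin(4 * pi * (s + p$f_l * tb))
  yT <- p$r_h / 2 * sin(2 * pi * (s + p$f_l * tb))
  b1 <- 1 / (1 + exp(p$alpha * s + p$beta))
  b2 <- exp(-p$gamma1 * s)
  b3 <- 1 - exp(-p$gamma2 * s)
  xo <- b1 * xT
  yo <- b2 * yT
  xlm <- xo - p$lambda * s
  py <- linear_ribbon(t, p)[, 2]
  yT0 <- p$r_h / 2 * sin(2 * pi * p$f_l * tb)
  ylm2 <- yo - (py - yT0) * b3
  xy <- rotate_xy(xlm, ylm2, p$theta_r)
  xy[, 1] <- xy[, 1] + head[1]
  xy[, 2] <- xy[, 2] + head[2]
  xy
}

#' Hyperactive swim: one Brownian step
#'
#' Advances a hyperactive head by one frame of period `T`:
#' `pos + mu * T + sigma_b * W(T)` per axis with independent `W(T) ~ N(0,
#' T)`.
#'
#' @param pos Length-2 current position, px.
#' @param p [hyperactive_params()].
#' @param T Frame period, s.
#' @return Length-2 numeric position.
#' @export
hyperactive_step <- function(pos, p = hyperactive_params(), T = 1 / 15) {
  stopifnot(inherits(p, "hyperactive_params"))
  stop_if_not_number(T, "T", positive = TRUE)
  pos + p$mu * T + p$sigma_b * sqrt(T) * rnorm(2)
}

#' Trailing tail through recent head positions
#'
#' The tail of hyperactive (and frozen immotile) cells is the piecewise
#' linear curve through the last `n + 1` head positions, resampled by arc
#' length to exactly `M` points with the newest end at the head.  A
#' single-point (or zero-length) history collapses to `M` coincident points.
#'
#' @param history Matrix/data frame of head positions in chronological order
#'   (oldest first, newest last = the current head).
#' @param n Number of past positions to use (the curve spans up to `n + 1`
#'   points).
#' @param M Number of output tail points.
#' @return Tibble with columns `x`, `y` (`M` rows; row 1 is the head).
#' @export
trailing_tail <- function(history, n, M = 200) {
  xy <- trailing_tail_xy(history, n, M)
  tibble::tibble(x = xy[, 1], y = xy[, 2])
}

# matrix version used in the per-frame simulation loop
trailing_tail_xy <- function(history, n, M = 200) {
  pts <- as_points_matrix(history, allow_empty = FALSE)
  m <- min(nrow(pts), n + 1L)
  pts <- pts[nrow(pts) - (seq_len(m) - 1L), , drop = FALSE]  # newest first
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  len <- c(0, cumsum(seg))
  total <- len[length(len)]
  if (nrow(pts) == 1L || total <= 0) {
    return(cbind(x = rep(pts[1, 1], M), y = rep(pts[1, 2], M)))
  }
  at <- seq(0, total, length.out = M)
  cbind(x = stats::approx(len, pts[, 1], xout = at, ties = "ordered")$y,
        y = stats::approx(len, pts[, 2], xout = at, ties = "ordered")$y)
}

#' Positional jitter
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `sigma_j`
#' to each coordinate.  In the scene simulator the jittered position is what
#' gets rendered and recorded as ground truth; the underlying kinematic
#' state is left untouched.
#'
#' @param pos Length-2 position or n x 2 matrix of positions, px.
#' @param sigma_j Jitter standard deviation, px (>= 0).
#' @return Same shape as `pos`.
#' @export
jitter_position <- function(pos, sigma_j) {
  stop_if_not_number(sigma_j, "sigma_j", nonneg = TRUE)
  if (sigma_j == 0) return(pos)
  pos + rnorm(length(pos), sd = sigma_j)
}

#' Flagellar amplitude profiles
#'
#' `beat_amplitude()` evaluates the circular-swim local beat amplitude
#' `b(k) = a (alpha * lambda * k / M + beta)`; `linear_amplitude_profiles()`
#' evaluates the linear-swim shaping functions `b1(k) = 1 / (1 +
#' exp(alpha k / M + beta))` (transformed sigmoid), `b2(k) = exp(-gamma1 k /
#' M)` (decaying exponential) and the placement-correction profile `b3(k) =
#' 1 - exp(-gamma2 k / M)`.
#'
#' @param k Tail index or indices in `[0, M]`.
#' @param p [circular_params()] / [linear_params()].
#' @return `beat_amplitude()`: numeric vector; `linear_amplitude_profiles()`:
#'   tibble with columns `k`, `b1`, `b2`, `b3`.
#' @examples
#' beat_amplitude(200, circular_params(a = 4, lambda = 40))  # 6.4
#' @export
beat_amplitude <- function(k, p = circular_params()) {
  stopifnot(inherits(p, "circular_params"))
  p$a * (p$alpha * p$lambda * k / p$M + p$beta)
}

#' @rdname beat_amplitude
#' @export
linear_amplitude_profiles <- function(k, p = linear_params()) {
  stopifnot(inherits(p, "linear_params"))
  s <- k / p$M
  tibble::tibble(k = k,
                 b1 = 1 / (1 + exp(p$alpha * s + p$beta)),
                 b2 = exp(-p$gamma1 * s),
                 b3 = 1 - exp(-p$gamma2 * s))
}
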