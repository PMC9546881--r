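## Parameter blocks for the four swim modes and the mode-transition model.

SWIM_MODES <- c("circular", "linear", "hyperactive", "immotile")

#' Circular swim parameters
#'
#' A circular swimming cell follows a sinusoid-modulated circular path: the
#' head orbits a centre at radius `r_c` while the flagellar beat modulates
#' the radius with amplitude `a` at frequency `f_s`.  The tail is a
#' travelling sine wave of wavelength `lambda` whose local beat amplitude
#' grows linearly along the flagellum, `b(k) = a (alpha * lambda * k / M +
#' beta)`.
#'
#' @param r_c Radius of the circular path, px.
#' @param omega_deg Angular rate of the circular cycle, degrees/s (50 deg/s
#'   corresponds to a cycle frequency of 50/360 cycles/s).
#' @param f_s Beat frequency of the sinusoid modulated on the path, Hz.
#' @param a Amplitude of the modulated sinusoid, px.
#' @param offset Length-2 centre offset `(C_x, C_y)`, px.
#' @param phase0 Initial angle on the circle, rad.
#' @param t_beat0 Beat-phase time offset, s (decouples beat phases of
#'   different cells in a scene).
#' @param lambda Flagellum wavelength (head-to-tip distance), px.
#' @param M Number of tail points (default 200).
#' @param alpha,beta Coefficients of the amplitude profile `b(k)`.
#' @return A list of class `circular_params`.
#' @export
circular_params <- function(r_c = 80, omega_deg = 50, f_s = 4, a = 3,
                            offset = c(0, 0), phase0 = 0, t_beat0 = 0,
                            lambda = 40, M = 200,
                            alpha = 0.02, beta = 0.8) {
  stop_if_not_number(r_c, "r_c", positive = TRUE)
  stop_if_not_number(lambda, "lambda", positive = TRUE)
  if (M < 2) abort("`M` must be at least 2.")
  structure(
    list(r_c = r_c, omega = omega_deg * pi / 180, omega_deg = omega_deg,
         f_s = f_s, a = a, offset = as.numeric(offset), phase0 = phase0,
         t_beat0 = t_beat0, lambda = lambda, M = as.integer(M),
         alpha = alpha, beta = beta),
    class = "circular_params"
  )
}

#' Linear mean swim parameters
#'
#' A linear mean swimming cell progresses along a straight line at speed `V`
#' in direction `theta_r` while rolling side to side, tracing a ribbon of
#' width `r_h` (across track) and height `r_v` (along the ribbon figure)
#' around the line.  The across-track oscillation is a fundamental plus a
#' third harmonic with ratio `A_har`; the correction constant `A_c`
#' (see [ribbon_constant()]) keeps the ribbon amplitude at `r_h / 2`.
#'
#' @param V Straight-line speed, px/s.
#' @param theta_r Direction of forward movement, rad.
#' @param f_l Rate of change of the ribbon angle, Hz.
#' @param r_h,r_v Ribbon width and height, px.
#' @param A_har Third-harmonic ratio (default 0.1).
#' @param offset Start position `(C_x, C_y)`, px.
#' @param t_beat0 Beat-phase time offset, s.
#' @param lambda,M Tail wavelength (px) and point count.
#' @param alpha,beta Sigmoid coefficients of the horizontal amplitude profile
#'   `b1`.
#' @param gamma1,gamma2 Decay rates of the vertical amplitude profile `b2`
#'   and of the placement-correction profile `b3`.
#' @return A list of class `linear_params`.
#' @export
linear_params <- function(V = 50, theta_r = 0, f_l = 3, r_h = 12, r_v = 8,
                          A_har = 0.1, offset = c(0, 0), t_beat0 = 0,
                          lambda = 40, M = 200,
                          alpha = 22, beta = -2, gamma1 = 5, gamma2 = 1.5) {
  stop_if_not_number(V, "V", nonneg = TRUE)
  stop_if_not_number(A_har, "A_har", nonneg = TRUE)
  if (M < 2) abort("`M` must be at least 2.")
  structure(
    list(V = V, theta_r = theta_r, f_l = f_l, r_h = r_h, r_v = r_v,
         A_har = A_har, A_c = ribbon_constant(A_har),
         offset = as.numeric(offset), t_beat0 = t_beat0,
         lambda = lambda, M = as.integer(M),
         alpha = alpha, beta = beta, gamma1 = gamma1, gamma2 = gamma2),
    class = "linear_params"
  )
}

#' Hyperactive swim parameters
#'
#' Hyperactivated ("whiplash") motility is modeled as 2-D Brownian motion:
#' per frame of period `T`, each coordinate gains an independent
#' `N(mu * T, sigma_b^2 * T)` increment.  The tail is the trailing polyline
#' through the last `n = ceil(0.2 / T)` head positions (0.2 s of history).
#'
#' @param sigma_b Diffusion coefficient, px/sqrt(s).
#' @param mu Length-2 drift, px/s (default no drift).
#' @param M Number of tail points.
#' @return A list of class `hyperactive_params`.
#' @export
hyperactive_params <- function(sigma_b = 10, mu = c(0, 0), M = 200) {
  stop_if_not_number(sigma_b, "sigma_b", nonneg = TRUE)
  structure(
    list(sigma_b = sigma_b, mu = as.numeric(mu), M = as.integer(M)),
    class = "hyperactive_params"
  )
}

history_length <- function(T) max(1L, as.integer(ceiling(0.2 / T)))

#' Swim-mode transition model
#'
#' Row-stochastic 4 x 4 matrix of per-second transition probabilities between
#' the swim modes (rows and columns ordered circular, linear, hyperactive,
#' immotile).  Once per evaluation period the simulator resamples each cell's
#' mode from the row of its current mode; on a transition the new mode is
#' re-initialized at the cell's current position with its heading preserved.
#'
#' @param prob 4 x 4 numeric matrix; rows must sum to 1 (tolerance 1e-9) and
#'   entries must be non-negative.  Defaults to the identity (no
#'   transitions).
#' @param period Evaluation period in seconds (default 1).
#' @return A list of class `transition_model`.
#' @export
transition_model <- function(prob = diag(4), period = 1) {
  prob <- as.matrix(prob)
  if (!identical(dim(prob), c(4L, 4L))) {
    abort("`prob` must be a 4 x 4 matrix over the four swim modes.")
  }
  if (any(prob < 0) || any(abs(rowSums(prob) - 1) > 1e-9)) {
    abort("Transition rows must be non-negative and sum to 1.")
  }
  dimnames(prob) <- list(SWIM_MODES, SWIM_MODES)
  structure(list(prob = prob, period = period), class = "transition_model")
}
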