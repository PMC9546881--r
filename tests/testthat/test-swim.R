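test_that("circular head follows the modulated circle closed form", {
  p0 <- circular_params(r_c = 10, a = 0)
  h <- circular_head(0, p0)
  expect_equal(c(h$x, h$y), c(10, 0))
  # quarter cycle of a pure circle (one cycle per second), offsets (5, 5)
  p1 <- circular_params(r_c = 10, a = 0, omega_deg = 360, offset = c(5, 5))
  h1 <- circular_head(0.25, p1)
  expect_equal(c(h1$x, h1$y), c(5, 15))
  # benchmark parameters: radius term r_c + a sin(2 pi f_s t) = 83 at the
  # beat quarter-period
  p2 <- circular_params(r_c = 80, a = 3, f_s = 4, omega_deg = 50)
  h2 <- circular_head(0.0625, p2)
  expect_equal(sqrt(h2$x^2 + h2$y^2), 83)
  expect_error(circular_head(-1, p0), ">= 0")
})

test_that("circular tail obeys the beat-amplitude profile and wavelength", {
  expect_equal(beat_amplitude(200, circular_params(a = 4, lambda = 40, M = 200)),
               4 * (0.02 * 40 + 0.8))  # 6.4 px at the tip
  expect_equal(beat_amplitude(0, circular_params(a = 4)), 0.8 * 4)

  p <- circular_params(a = 4, lambda = 40, f_s = 4)
  head <- c(100, 100)
  for (t in c(0, 0.03, 0.11)) {
    tl <- circular_tail(t, head, p)
    expect_equal(nrow(tl), p$M)
    # rotation+translation preserve distances: root offset = |b(0) sin(...)|
    root_d <- sqrt((tl$x[1] - head[1])^2 + (tl$y[1] - head[2])^2)
    expect_equal(root_d, abs(0.8 * 4 * sin(2 * pi * 4 * t)), tolerance = 1e-9)
    # tip: local (b(M) sin(-2 pi f_s t), -lambda)
    tip_d <- sqrt((tl$x[p$M] - head[1])^2 + (tl$y[p$M] - head[2])^2)
    expect_equal(tip_d, sqrt((6.4 * sin(2 * pi * 4 * t))^2 + 40^2),
                 tolerance = 1e-9)
  }
  # at beat phase zero the root coincides with the head exactly
  tl0 <- circular_tail(0, head, p)
  expect_equal(c(tl0$x[1], tl0$y[1]), head)
})

test_that("ribbon correction constant normalizes the two-harmonic sum", {
  expect_equal(ribbon_constant(0), 1)
  # dense grid-search oracle at 1e-5 rad resolution
  th <- seq(0, 2 * pi, by = 1e-5)
  oracle <- 1 / max(sin(th) + 0.1 * sin(3 * th))
  expect_equal(ribbon_constant(0.1), oracle, tolerance = 1e-8)
  # resulting across-track amplitude is exactly r_h / 2
  p <- linear_params(r_h = 12, A_har = 0.1, f_l = 3)
  tt <- seq(0, 1 / 3, length.out = 20001)
  py <- p$r_h * p$A_c / 2 *
    (sin(2 * pi * 3 * tt) + 0.1 * sin(6 * pi * 3 * tt))
  expect_equal(max(py), 6, tolerance = 1e-6)
})

test_that("linear head is the line plus rotated ribbon", {
  p <- linear_params(offset = c(3, 4))
  h0 <- linear_head(0, p)
  expect_equal(c(h0$x, h0$y), c(3, 4))
  # ribbon amplitudes zero: exactly the straight line
  pz <- linear_params(V = 50, theta_r = 0, r_h = 0, r_v = 0, offset = c(3, 4))
  h1 <- linear_head(1, pz)
  expect_equal(c(h1$x, h1$y), c(53, 4))
  # independent evaluation of the full form at t = 1 / (4 f_l)
  pb <- linear_params(V = 50, theta_r = 0.7, f_l = 3, r_h = 12, r_v = 8,
                      A_har = 0.1, offset = c(10, 20))
  t <- 1 / 12
  Ac <- 1 / max(sin(seq(0, 2 * pi, by = 1e-5)) +
                  0.1 * sin(3 * seq(0, 2 * pi, by = 1e-5)))
  Px <- 8 / 2 * sin(4 * pi * 3 * t)
  Py <- 12 * Ac / 2 * (sin(2 * pi * 3 * t) + 0.1 * sin(6 * pi * 3 * t))
  ex <- 50 * cos(0.7) * t + 10 + cos(0.7) * Px - sin(0.7) * Py
  ey <- 50 * sin(0.7) * t + 20 + sin(0.7) * Px + cos(0.7) * Py
  hb <- linear_head(t, pb)
  expect_equal(c(hb$x, hb$y), c(ex, ey), tolerance = 1e-7)
})

test_that("linear amplitude profiles match their printed substitutions", {
  pr <- linear_amplitude_profiles(c(0, 200), linear_params(M = 200))
  expect_equal(pr$b1[1], 1 / (1 + exp(-2)))
  expect_equal(pr$b2[2], exp(-5))
  expect_equal(pr$b3[1], 0)
})

test_that("linear tail matches an independent evaluation of its equations", {
  p <- linear_params(V = 40, theta_r = -0.4, f_l = 3, r_h = 12, r_v = 8,
                     A_har = 0.1, offset = c(30, 60), lambda = 40, M = 50)
  for (t in c(0, 0.17)) {
    h <- linear_head(t, p)
    got <- linear_tail(t, c(h$x, h$y), p)
    # oracle: direct transcription of the oscillation/shaping/rotation chain
    s <- seq(0, 1, length.out = 50)
    xT <- 8 / 2 * sin(4 * pi * (s + 3 * t))
    yT <- 12 / 2 * sin(2 * pi * (s + 3 * t))
    b1 <- 1 / (1 + exp(22 * s - 2))
    b2 <- exp(-5 * s)
    b3 <- 1 - exp(-1.5 * s)
    Py <- 12 * p$A_c / 2 * (sin(2 * pi * 3 * t) + 0.1 * sin(6 * pi * 3 * t))
    xlm <- b1 * xT - 40 * s
    ylm2 <- b2 * yT - (Py - 12 / 2 * sin(2 * pi * 3 * t)) * b3
    ex <- cos(-0.4) * xlm - sin(-0.4) * ylm2 + h$x
    ey <- sin(-0.4) * xlm + cos(-0.4) * ylm2 + h$y
    expect_equal(got$x, ex, tolerance = 1e-9)
    expect_equal(got$y, ey, tolerance = 1e-9)
  }
  # root coincides with the head at beat phase zero
  tl0 <- linear_tail(0, c(30, 60), p)
  expect_equal(c(tl0$x[1], tl0$y[1]), c(30, 60))
})

test_that("hyperactive steps are Brownian increments", {
  p <- hyperactive_params(sigma_b = 0)
  expect_equal(hyperactive_step(c(5, 7), p, T = 1 / 15), c(5, 7))
  set.seed(11)
  p10 <- hyperactive_params(sigma_b = 10)
  steps <- t(replicate(3000, hyperactive_step(c(0, 0), p10, T = 1 / 15)))
  expect_equal(stats::var(steps[, 1]), 100 / 15, tolerance = 0.08)
  expect_lt(abs(stats::cor(steps[, 1], steps[, 2])), 0.05)
  expect_error(hyperactive_params(sigma_b = -1), ">= 0")
})

test_that("trailing tails resample the head history by arc length", {
  # single point history collapses to coincident points
  t1 <- trailing_tail(matrix(c(4, 9), 1, 2), n = 3, M = 20)
  expect_true(all(t1$x == 4) && all(t1$y == 9))
  # collinear equally-spaced history stays equally spaced
  hist <- cbind(x = c(0, 1, 2, 3), y = c(0, 2, 4, 6))
  t2 <- trailing_tail(hist, n = 3, M = 7)
  expect_equal(t2$x, seq(3, 0, length.out = 7))
  expect_equal(t2$y, seq(6, 0, length.out = 7))
  expect_equal(c(t2$x[1], t2$y[1]), c(3, 6))  # newest end at the head
  # arbitrary 4-point history vs a dense-polyline resampling oracle
  set.seed(2)
  hist2 <- matrix(runif(8, 0, 50), 4, 2)
  got <- trailing_tail(hist2, n = 3, M = 33)
  pts <- hist2[4:1, ]
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- pmin(pmax(sum((p - a) * ab) / sum(ab^2), 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  for (i in seq_len(33)) {
    d <- min(vapply(1:3, function(k) {
      seg_dist(c(got$x[i], got$y[i]), pts[k, ], pts[k + 1, ])
    }, numeric(1)))
    expect_lt(d, 1e-6)
  }
})

test_that("positional jitter is unbiased with the requested spread", {
  expect_equal(jitter_position(c(1, 2), 0), c(1, 2))
  set.seed(5)
  draws <- t(replicate(5000, jitter_position(c(0, 0), 1.5)))
  expect_equal(sd(draws[, 1]), 1.5, tolerance = 0.05)
  expect_equal(mean(draws), 0, tolerance = 0.1)
})

test_that("mode transitions follow the transition matrix", {
  expect_error(transition_model(matrix(1, 4, 4)), "sum to 1")
  expect_error(transition_model(diag(3)), "4 x 4")
  cfg <- simulation_config()
  tm_id <- transition_model(diag(4))
  cell <- casasim:::init_mode_state(1, "linear", c(50, 50), 0, 0, cfg)
  set.seed(3)
  for (i in 1:50) cell <- step_mode(cell, tm_id, cfg)
  expect_equal(cell$mode, "linear")

  # linear-row transition frequencies vs the printed 85/10/5 example
  prob <- diag(4)
  prob[2, ] <- c(0.10, 0.85, 0.05, 0)   # circular, linear, hyperactive, immotile
  tm <- transition_model(prob)
  set.seed(7)
  n <- 4000
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- step_mode(cell, tm, cfg)$mode
  }
  freq <- table(factor(out, levels = casasim:::SWIM_MODES)) / n
  for (m in c("circular", "linear", "hyperactive")) {
    pexp <- prob[2, casasim:::SWIM_MODES == m]
    expect_lt(abs(freq[[m]] - pexp), 3 * sqrt(pexp * (1 - pexp) / n))
  }
  expect_equal(freq[["immotile"]], 0)
})
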