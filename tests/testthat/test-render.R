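test_that("rasterization rounds half-up, merges collisions, drops out-of-frame", {
  expect_equal(rasterize_points(NULL, 250), matrix(0, 250, 250))
  b <- rasterize_points(c(10.4, 20.6), 250)
  expect_equal(sum(b == 255), 1L)
  expect_equal(b[22, 11], 255)  # y = 21, x = 10 (0-based, half-up)
  expect_equal(rasterize_points(c(10.5, 20.5), 4)[1, 1], 0)  # off-frame

  # a dense simulated tail: nonzero pixels == distinct rounded points oracle
  tl <- circular_tail(0.2, head = c(120, 130), p = circular_params())
  b2 <- rasterize_points(tl, 250)
  rounded <- unique(cbind(floor(tl$x + 0.5), floor(tl$y + 0.5)))
  expect_equal(sum(b2 == 255), nrow(rounded))
  expect_lte(sum(b2 == 255), 200)

  expect_error(rasterize_points(c(NaN, 1), 100), "finite")
})

test_that("head-centre stage produces the calibrated dark oval on background", {
  hb <- rasterize_points(c(80, 80), 160)
  i5 <- render_head_center(hb)
  expect_equal(i5[81, 81], 0)          # darkest pixel of a default head
  expect_equal(i5[1, 1], 204)          # far field = B_L exactly
  expect_equal(render_head_center(rasterize_points(NULL, 64)),
               matrix(204, 64, 64))

  # two heads 50 px apart: two disjoint dark ovals, each centre at 0
  hb2 <- rasterize_points(rbind(c(50, 80), c(100, 80)), 160)
  i52 <- render_head_center(hb2)
  expect_equal(i52[81, 51], 0)
  expect_equal(i52[81, 101], 0)
  expect_equal(i52[81, 76], 204)       # midpoint untouched
})

test_that("membrane stage peaks at 51 on a ring around the head", {
  hb <- rasterize_points(c(80, 80), 160)
  i6 <- render_membrane(hb)
  expect_equal(max(i6), 51)
  expect_true(all(i6 >= 0))
  amax <- which(i6 == max(i6), arr.ind = TRUE)[1, ]
  expect_gt(sqrt(sum((amax - 81)^2)), 2)  # off-centre
  expect_equal(render_membrane(rasterize_points(NULL, 64)), matrix(0, 64, 64))
})

test_that("flagellum stage peaks at 13 with support near the tail", {
  tl <- circular_tail(0.1, head = c(80, 80), p = circular_params())
  tb <- rasterize_points(tl, 160)
  i8 <- render_flagellum(tb)
  expect_equal(max(i8), 13)
  expect_true(all(i8 >= 0))
  expect_equal(render_flagellum(rasterize_points(NULL, 64)), matrix(0, 64, 64))
  # dilation oracle: every rasterized tail pixel is covered by ridge support
  # within the kernel half width
  on <- which(tb == 255, arr.ind = TRUE)
  lit <- which(i8 > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(on))) {
    d <- sqrt((lit[, 1] - on[i, 1])^2 + (lit[, 2] - on[i, 2])^2)
    expect_lte(min(d), 12)
  }
})

test_that("composition is additive, clipped and 8-bit", {
  n <- 96
  i5 <- matrix(204, n, n)
  z <- matrix(0, n, n)
  expect_equal(compose_sperm_image(i5, z, z), i5)
  hb <- rasterize_points(c(48, 48), n)
  i9 <- build_frame(c(48, 48), n = n)
  expect_true(all(i9 >= 0 & i9 <= 255))
  expect_equal(i9[1, 1], 204)
  # membrane over background saturates at white, never beyond
  expect_lte(max(i9), 255)
  expect_error(compose_sperm_image(i5, matrix(0, 2, 2), z), "dimensions")
})

test_that("rendering is translation-equivariant and local", {
  f1 <- build_frame(c(60, 70), n = 160)
  f2 <- build_frame(c(60 + 17, 70 - 9), n = 160)
  expect_equal(f2[(71 - 9 - 20):(71 - 9 + 20), (61 + 17 - 20):(61 + 17 + 20)],
               f1[(71 - 20):(71 + 20), (61 - 20):(61 + 20)])
  # adding a distant cell leaves the first cell's neighbourhood untouched
  f3 <- build_frame(rbind(c(60, 70), c(140, 140)), n = 160)
  expect_equal(f3[46:96, 36:86], f1[46:96, 36:86])
})

test_that("isolated-cell peaks are position-independent away from borders", {
  for (pos in list(c(40, 40), c(80.3, 52.7), c(110, 95))) {
    hb <- rasterize_points(pos, 160)
    expect_lt(abs(min(render_head_center(hb)) - 0), 1)
    expect_lt(abs(max(render_membrane(hb)) - 51), 1)
  }
})

test_that("the scene fast path matches the exported pipeline for one cell", {
  p <- circular_params(offset = c(80, 80))
  tail <- circular_tail(0, head = c(80, 80), p = p)
  ref <- build_frame(c(80, 80), tails = tail, n = 160)
  kernels <- casasim:::scene_kernels(appearance_params())
  gain <- 13 / casasim:::tail_peak_response(as.matrix(tail[, c("x", "y")]),
                                            160, kernels$f3)
  fast <- casasim:::render_scene_frame(
    list(list(head = c(80, 80), tail = as.matrix(tail[, c("x", "y")]),
              intensity = 1, tail_gain = gain)),
    160, appearance_params(), kernels)
  expect_equal(fast, ref, tolerance = 1e-12)
})
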