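test_that("OSPA reproduces closed-form cases and the brute-force oracle", {
  X <- rbind(c(3, 4), c(10, 2))
  expect_equal(ospa(X, X)$total, 0)
  expect_equal(ospa(c(0, 0), NULL)$total, 20)
  expect_equal(ospa(NULL, NULL)$total, 0)
  r <- ospa(c(0, 0), c(3, 4))
  expect_equal(r$total, 5)
  expect_equal(r$cardinality, 0)

  set.seed(42)
  for (i in 1:40) {
    m <- sample(0:4, 1); n <- sample(0:4, 1)
    A <- matrix(runif(2 * m, 0, 40), ncol = 2)
    B <- matrix(runif(2 * n, 0, 40), ncol = 2)
    if (m == 0 && n == 0) next
    expect_equal(ospa(A, B)$total, ospa_brute(A, B), tolerance = 1e-10)
  }
})

test_that("OSPA behaves as a metric bounded by c", {
  set.seed(9)
  for (i in 1:60) {
    A <- matrix(runif(8, 0, 50), ncol = 2)
    B <- matrix(runif(runif(1, 2, 10) %/% 2 * 2, 0, 50), ncol = 2)
    C <- matrix(runif(6, 0, 50), ncol = 2)
    dab <- ospa(A, B)$total; dba <- ospa(B, A)$total
    dac <- ospa(A, C)$total; dcb <- ospa(C, B)$total
    expect_identical(dab, dba)
    expect_lte(dab, 20)
    expect_lte(dab, dac + dcb + 1e-12)
  }
  # equal cardinality, all distances < c: pure localization
  A <- rbind(c(0, 0), c(10, 10)); B <- A + 1
  r <- ospa(A, B)
  expect_equal(r$cardinality, 0)
  expect_equal(r$total, r$localization)
})

test_that("precision/recall matching counts true positives optimally", {
  G <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  r <- match_and_pr(G, G, 5)
  expect_equal(c(r$precision, r$recall), c(1, 1))
  r2 <- match_and_pr(G, G[1:8, ], 5)
  expect_equal(c(r2$precision, r2$recall), c(1, 0.8))
  # crowded random instances vs exhaustive maximum matching
  set.seed(31)
  for (i in 1:25) {
    ng <- sample(1:6, 1); nd <- sample(1:6, 1)
    Gx <- matrix(runif(2 * ng, 0, 12), ncol = 2)
    Dx <- matrix(runif(2 * nd, 0, 12), ncol = 2)
    got <- match_and_pr(Gx, Dx, 4)
    expect_equal(got$tp, max_matching_brute(Gx, Dx, 4))
  }
  # degenerate conventions
  e <- match_and_pr(NULL, NULL)
  expect_equal(c(e$precision, e$recall), c(1, 1))
  e2 <- match_and_pr(c(1, 1), NULL)
  expect_equal(c(e2$precision, e2$recall), c(0, 0))
})

test_that("CLEAR-MOT scores perfect, empty and swapping tracks correctly", {
  truth <- tibble::tibble(frame = rep(0:9, each = 2),
                          cell_id = rep(1:2, 10),
                          x = rep(0:9, each = 2) * 3 + rep(c(0, 30), 10),
                          y = 5)
  perfect <- tibble::tibble(track_id = rep(1:2, 10),
                            frame = rep(0:9, each = 2),
                            x = truth$x, y = truth$y)
  m <- clear_mot(truth, perfect)
  expect_equal(m$motp, 0)
  expect_equal(m$mota, 1)
  expect_equal(m$mota, mot_accuracy(m$fp_rate, m$miss_rate, m$mismatch_rate))

  # no tracks at all: everything missed
  m0 <- clear_mot(truth[truth$cell_id == 1, ],
                  tibble::tibble(track_id = integer(0), frame = integer(0),
                                 x = numeric(0), y = numeric(0)))
  expect_equal(m0$miss_rate, 1)
  expect_equal(m0$mota, 0)

  # identity swap at frame 5: two mismatch events
  swapped <- perfect
  late <- swapped$frame >= 5
  swapped$track_id[late] <- 3L - swapped$track_id[late]
  ms <- clear_mot(truth, swapped)
  expect_equal(ms$n_mme, 2L)
  expect_equal(ms$mota, 1 - 2 / 20)

  # label permutation invariance
  relab <- perfect
  relab$track_id <- relab$track_id + 100L
  mr <- clear_mot(truth, relab)
  expect_equal(mr$mota, 1)
})

test_that("MOT identity holds to numerical precision on noisy reports", {
  set.seed(77)
  truth <- tibble::tibble(frame = rep(0:19, each = 3),
                          cell_id = rep(1:3, 20),
                          x = runif(60, 0, 100), y = runif(60, 0, 100))
  tracks <- tibble::tibble(track_id = rep(1:3, 20),
                           frame = rep(0:19, each = 3),
                           x = truth$x + rnorm(60, sd = 3),
                           y = truth$y + rnorm(60, sd = 3))
  m <- clear_mot(truth, tracks)
  expect_equal(m$mota,
               1 - (m$fp_rate + m$miss_rate + m$mismatch_rate),
               tolerance = 1e-12)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5L)
  expect_equal(glance(m)$mota, m$mota)
})
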