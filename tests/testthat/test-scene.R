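test_that("an empty scene renders the uniform background everywhere", {
  cfg <- simulation_config(frame_size = 64, n_cells = 0, n_immotile = 0,
                           duration = 0.2)
  sc <- simulate_semen(cfg, seed = 1)
  expect_equal(length(sc$frames), 3L)
  for (f in sc$frames) expect_equal(f, matrix(204, 64, 64))
  expect_equal(nrow(sc$truth), 0L)
})

test_that("the sample-1 fixture reproduces its census and stays in frame", {
  cfg <- sample1_config(duration = 2)
  expect_equal(cfg$frame_size, 250L)
  expect_equal(cfg$n_cells, 10L)
  expect_equal(cfg$n_immotile, 3L)
  expect_equal(cfg$appearance$sigma_head, c(1.86, 2.86))
  expect_equal(cfg$noise_variance, 8.22e-6 * 255^2)
  sc <- simulate_semen(cfg, seed = 7)
  first <- dplyr::filter(sc$truth, frame == 0)
  expect_equal(nrow(first), 10L)
  expect_setequal(unique(sc$truth$mode),
                  c("immotile", "linear", "circular"))
  # rounded truth positions always index a real pixel
  expect_true(all(floor(sc$truth$x + 0.5) >= 0 & floor(sc$truth$x + 0.5) < 250))
  # some cells swim out of the frame during the clip and drop out of truth
  per_frame <- dplyr::count(sc$truth, frame)
  expect_lt(min(per_frame$n), 10L)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  cfg <- simulation_config(frame_size = 96, n_cells = 4, n_immotile = 1,
                           duration = 0.4, jitter_sigma = 0.5,
                           mode_probs = c(circular = 0.4, linear = 0.4,
                                          hyperactive = 0.2))
  a <- simulate_semen(cfg, seed = 123)
  b <- simulate_semen(cfg, seed = 123)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  c <- simulate_semen(cfg, seed = 124)
  expect_false(identical(a$frames, c$frames))
})

test_that("configuration guards reject impossible censuses", {
  expect_error(simulation_config(n_cells = 2, n_immotile = 3), "n_immotile")
  expect_error(simulation_config(fps = 0), "> 0")
})

test_that("frame noise has the requested spread and respects the range", {
  mid <- matrix(128, 400, 250)
  expect_identical(add_frame_noise(mid, 0), mid)
  set.seed(99)
  noisy <- add_frame_noise(mid, 1225)
  expect_true(all(noisy >= 0 & noisy <= 255))
  # mid-gray never clips, so the sample sd reflects the injected noise
  # (plus 1/12 quantization variance)
  expect_equal(sd(noisy - mid), sqrt(1225 + 1 / 12), tolerance = 0.03)
  expect_error(add_frame_noise(mid, -5), ">= 0")
})

test_that("noise is applied to frames but never to ground truth", {
  cfg <- simulation_config(frame_size = 96, n_cells = 2, n_immotile = 0,
                           duration = 0.2)
  cfg_noisy <- cfg
  cfg_noisy$noise_variance <- 400
  a <- simulate_semen(cfg, seed = 5)
  b <- simulate_semen(cfg_noisy, seed = 5)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$frames, b$frames))
})

test_that("per-cell intensity factors attenuate the deviation from background", {
  cfg_full <- simulation_config(frame_size = 96, n_cells = 1, n_immotile = 1,
                                duration = 0.1)
  cfg_half <- cfg_full
  cfg_half$intensity_range <- c(0.5, 0.5)
  f_full <- simulate_semen(cfg_full, seed = 8)$frames[[1]]
  f_half <- simulate_semen(cfg_half, seed = 8)$frames[[1]]
  # the darkest pixel sits half as far below the background
  expect_equal(204 - min(f_half), 0.5 * (204 - min(f_full)), tolerance = 0.03)
  expect_lt(max(f_half) - 204, max(f_full) - 204)  # halo attenuated too
})

test_that("mode transitions re-initialize cells on schedule", {
  to_immotile <- matrix(0, 4, 4)
  to_immotile[, 4] <- 1
  cfg <- simulation_config(frame_size = 128, n_cells = 3, n_immotile = 0,
                           duration = 2, fps = 5,
                           mode_probs = c(circular = 0.5, linear = 0.5),
                           transitions = transition_model(to_immotile))
  sc <- simulate_semen(cfg, seed = 4)
  modes <- dplyr::summarise(dplyr::group_by(sc$truth, frame),
                            all_immotile = all(mode == "immotile"))
  expect_false(any(modes$all_immotile[modes$frame < 5]))
  expect_true(all(modes$all_immotile[modes$frame >= 5]))
  # immotile cells are frozen: identical positions across later frames
  late <- dplyr::filter(sc$truth, frame >= 5)
  drift <- dplyr::summarise(dplyr::group_by(late, cell_id),
                            dx = max(x) - min(x), dy = max(y) - min(y))
  expect_true(all(drift$dx == 0 & drift$dy == 0))
})

test_that("video and table artifacts round-trip losslessly", {
  cfg <- simulation_config(frame_size = 64, n_cells = 2, n_immotile = 0,
                           duration = 0.2)
  sc <- simulate_semen(cfg, seed = 3)
  tdir <- withr::local_tempdir()
  vp <- file.path(tdir, "v.tif")
  write_video(sc, vp)
  expect_identical(read_video(vp), sc$frames)

  tp <- file.path(tdir, "t.csv")
  write_truth(sc, tp)
  back <- read_truth(tp)
  expect_equal(back$x, sc$truth$x, tolerance = 1e-6)
  expect_equal(back$cell_id, sc$truth$cell_id)
  expect_equal(back$mode, sc$truth$mode)

  det <- tibble::tibble(frame = 0:1, x = c(1.25, 2.5), y = c(3, 4), area = c(9, 12))
  dp <- file.path(tdir, "d.csv")
  write_detections(det, dp)
  expect_equal(read_detections(dp), det, tolerance = 1e-6)

  trk <- tibble::tibble(track_id = c(1L, 1L), frame = 0:1, x = c(1, 2), y = c(3, 4))
  kp <- file.path(tdir, "k.csv")
  write_tracks(trk, kp)
  expect_equal(read_tracks(kp), trk, tolerance = 1e-6)

  # malformed table: missing column names the file and the columns
  bad <- file.path(tdir, "bad.csv")
  writeLines(c("frame,x,y", "0,1,2"), bad)
  expect_error(read_detections(bad), "missing column")
  expect_error(write_video(list(), file.path(tdir, "e.tif")), "non-empty")
})
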