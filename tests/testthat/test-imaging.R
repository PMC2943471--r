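geom2d <- function(n = 48) movie_geometry(nx = n, ny = n, nz = 1,
                                          pixel_size_um = 0.1,
                                          frame_interval_s = 1)

test_that("rendering places intensity at the spot and conserves mass", {
  g <- geom2d()
  tr <- trajectory("s", 0:6, cbind(rep(2.0, 7), rep(1.5, 7)))
  st <- render_movie(list(tr), g, psf_sigma = 0.15, amplitude = 500,
                     background = 10)
  fr <- matrix(st[1, , ], dim(st)[2], dim(st)[3])
  # argmax at the nearest pixel: x = 2.0 um -> col 21 (0-based 20),
  # y = 1.5 um -> row 16
  ij <- which(fr == max(fr), arr.ind = TRUE)
  expect_equal(unname(ij[1, ]), c(16, 21))
  # total mass above background ~ amplitude * 2*pi*sigma_px^2
  sig_px <- 0.15 / 0.1
  expect_lt(abs(sum(fr - 10) - 500 * 2 * pi * sig_px^2) /
              (500 * 2 * pi * sig_px^2), 0.01)
  # zero trajectories -> uniform background
  st0 <- render_movie(list(), g, background = 7)
  expect_true(all(st0 == 7))
})

test_that("mass conservation holds for several spots in 3D", {
  g <- movie_geometry(nx = 40, ny = 40, nz = 20, pixel_size_um = 0.1,
                      z_step_um = 0.2)
  trs <- list(trajectory("a", 0:2, cbind(1.0, 1.0, 1.0)[rep(1, 3), ]),
              trajectory("b", 0:2, cbind(3.0, 2.5, 2.4)[rep(1, 3), ]))
  st <- render_movie(trs, g, psf_sigma = 0.2, amplitude = 300,
                     background = 5)
  fr <- array(st[1, , , ], dim(st)[-1])
  mass <- 300 * (2 * pi)^1.5 * (0.2 / 0.1)^2 * (0.2 / 0.2)
  expect_lt(abs(sum(fr - 5) - 2 * mass) / (2 * mass), 0.01)
})

test_that("out-of-field spots are rejected with the track id", {
  g <- geom2d(16)
  tr <- trajectory("runaway", 0:6, cbind(seq(1, 2.5, 0.25), 0.5))
  expect_error(render_movie(list(tr), g), "runaway")
})

test_that("detection recovers subpixel positions on clean frames", {
  g <- geom2d(64)
  true_xy <- c(2.03, 1.57)
  tr <- trajectory("s", 0:6, matrix(true_xy, 7, 2, byrow = TRUE))
  st <- render_movie(list(tr), g, psf_sigma = 0.15, amplitude = 500,
                     background = 10)
  det <- detect_spots(matrix(st[1, , ], dim(st)[2], dim(st)[3]),
                      linking_config(), g)
  expect_equal(nrow(det), 1)
  err_px <- sqrt((det$x_um - true_xy[1])^2 + (det$y_um - true_xy[2])^2) /
    g$pixel_size_um
  expect_lt(err_px, 0.1)
  # two spots 10 diameters apart -> exactly two detections
  tr2 <- trajectory("s2", 0:6, matrix(true_xy + 3.0, 7, 2, byrow = TRUE))
  st2 <- render_movie(list(tr, tr2), g, psf_sigma = 0.15, amplitude = 500,
                      background = 10)
  det2 <- detect_spots(matrix(st2[1, , ], dim(st2)[2], dim(st2)[3]),
                       linking_config(), g)
  expect_equal(nrow(det2), 2)
  # constant frame -> no detections, warning
  expect_warning(d0 <- detect_spots(matrix(5, 48, 48), linking_config(), g),
                 "constant")
  expect_equal(nrow(d0), 0)
})

test_that("linking follows spots, bridges gaps and respects max_distance", {
  g <- geom2d()
  dets <- lapply(0:19, function(fr)
    data.frame(x_um = c(1.0 + 0.1 * fr, 4.0 - 0.1 * fr),
               y_um = c(1.0, 4.0)))
  trks <- link_detections(dets, linking_config(), frame_interval_s = 1)
  expect_length(trks, 2)
  expect_equal(vapply(trks, function(tr) length(tr$times), integer(1)),
               c(20L, 20L))

  # one detection missing mid-track: bridged, position omitted
  dets_gap <- dets
  dets_gap[[10]] <- dets_gap[[10]][2, , drop = FALSE]
  trks <- link_detections(dets_gap, linking_config(), frame_interval_s = 1)
  expect_length(trks, 2)
  lens <- sort(vapply(trks, function(tr) length(tr$times), integer(1)))
  expect_equal(lens, c(19L, 20L))
  short <- trks[[which.min(vapply(trks, function(tr) length(tr$times),
                                  integer(1)))]]
  expect_false(9 %in% short$times)   # frame 10 (t = 9 s) omitted

  # a 0.8 um jump exceeds max_distance 0.5: the link must break
  jump <- lapply(0:19, function(fr)
    data.frame(x_um = 1.0 + 0.02 * fr + if (fr >= 10) 0.8 else 0,
               y_um = 2.0))
  trks <- link_detections(jump, linking_config(), frame_interval_s = 1)
  for (tr in trks) {
    gaps <- diff(tr$times)
    steps <- sqrt(rowSums(diff(tr$positions)^2))
    expect_true(all(steps <= 0.5 * gaps + 1e-9))
  }
  expect_equal(sort(vapply(trks, function(tr) length(tr$times),
                           integer(1))), c(10L, 10L))

  # fragments below min_steps are dropped
  trks6 <- link_detections(jump[1:8], linking_config(),
                           frame_interval_s = 1)
  expect_length(trks6, 1)   # 8 frames -> 7 steps, kept
  trks5 <- link_detections(jump[1:6], linking_config(),
                           frame_interval_s = 1)
  expect_length(trks5, 0)   # 5 steps, dropped
})

test_that("simulate -> render -> detect -> link round trip is faithful", {
  g <- geom2d(64)
  set.seed(3)
  starts <- expand.grid(x = c(1.2, 2.8, 4.4), y = c(1.2, 2.8, 4.4))
  trs <- lapply(seq_len(nrow(starts)), function(i) {
    p <- sim_params("random", dim = 2, D = 0.002, sigma_loc = 0,
                    n_steps = 12, dt = 1, seed = 300 + i,
                    origin = c(starts$x[i], starts$y[i]))
    simulate_trajectory(p, track_id = paste0("gt", i))
  })
  st <- render_movie(trs, g, psf_sigma = 0.15, amplitude = 800,
                     background = 10)
  found <- link_detections(detect_movie(st), linking_config(),
                           frame_interval_s = 1)
  expect_length(found, length(trs))
  # match each ground-truth track by start position; RMSE < 0.5 px
  for (tr in trs) {
    d0 <- vapply(found, function(f)
      sqrt(sum((f$positions[1, ] - tr$positions[1, ])^2)), numeric(1))
    f <- found[[which.min(d0)]]
    expect_equal(length(f$times), length(tr$times))
    rmse_px <- sqrt(mean(rowSums((f$positions - tr$positions)^2))) /
      g$pixel_size_um
    expect_lt(rmse_px, 0.5)
  }
})
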