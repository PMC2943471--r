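test_that("compute_msd matches the brute-force double-loop oracle", {
  set.seed(71)
  for (i in 1:40) {
    dim <- sample(2:3, 1)
    n <- sample(10:60, 1)
    pos <- apply(matrix(rnorm((n + 1) * dim, sd = 0.3), n + 1, dim), 2,
                 cumsum)
    times <- (0:n) * 0.5
    if (i %% 3 == 0 && n > 15) {   # punch gaps: pair-exclusion path
      drop <- sample(2:n, 3)
      times <- times[-drop]
      pos <- pos[-drop, , drop = FALSE]
    }
    tr <- trajectory(paste0("p", i), times, pos)
    cu <- compute_msd(tr, max_lag_fraction = 1)
    or <- brute_msd(times, pos, max_lag_fraction = 1)
    expect_equal(cu$lag_times, or$lag_times)
    expect_equal(cu$n_pairs, or$n_pairs)
    expect_lt(max(abs(cu$msd - or$msd) / pmax(or$msd, 1e-300)), 1e-12)
  }
})

test_that("pure drift and stationary tracks give the textbook MSD", {
  drift <- trajectory("d", 0:6, cbind(0:6, 0, 0))
  expect_equal(compute_msd(drift, 1)$msd, (1:6)^2)
  still <- trajectory("s", 0:9, matrix(1.5, 10, 2))
  expect_equal(compute_msd(still, 1)$msd, rep(0, 9))
})

test_that("periodic unit-square loop reproduces the brute-force values", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  pos <- rbind(sq, sq, sq, c(0, 0))   # 3 loops, 12 steps
  tr <- trajectory("loop", 0:12, pos)
  cu <- compute_msd(tr, max_lag_fraction = 0.5)
  # frozen from brute_msd: displacement pattern period 4 (1, 2, 1, 0, ...)
  expect_equal(cu$msd, c(1, 2, 1, 0, 1, 2))
  expect_equal(cu$msd, brute_msd(tr$times, pos, 0.5)$msd)
})

test_that("compute_msd enforces its contracts", {
  short <- trajectory("sh", 0:4, cbind(0:4, 0))
  expect_error(compute_msd(short), "fewer than 6 steps")
  irregular <- trajectory("ir", c(0, 1, 2.5, 3, 4, 5, 6.2, 7),
                          cbind(0:7, 0))
  expect_error(compute_msd(irregular), "non-uniform")
  six <- trajectory("six", 0:6, cbind(0:6, 0))
  expect_error(compute_msd(six, max_lag_fraction = 0.5),
               "too short for fitting")
})

test_that("noise-free model curves are recovered exactly", {
  t <- 1:20
  fr <- fit_msd_models(make_curve(0.06 * t, dim = 3))
  expect_equal(fr$random$D, 0.01, tolerance = 1e-9)
  expect_equal(fr$random$k, 0, tolerance = 1e-9)
  expect_equal(fr$random$r_squared, 1, tolerance = 1e-12)

  fd <- fit_msd_models(make_curve((0.1 * t)^2, dim = 3))
  expect_equal(fd$directed$v, 0.1, tolerance = 1e-9)
  expect_equal(fd$directed$D, 0, tolerance = 1e-9)
  expect_equal(fd$directed$r_squared, 1, tolerance = 1e-12)

  caged_true <- 0.25 * (1 - 0.99 * exp(-6 * 0.85 * 0.05 * t / 0.25)) + 0.01
  fc <- fit_msd_models(make_curve(caged_true, dim = 3))
  expect_equal(fc$caged$R, 0.5, tolerance = 1e-8)
  expect_equal(fc$caged$D, 0.05, tolerance = 1e-8)
  expect_equal(fc$caged$k, 0.01, tolerance = 1e-6)
  expect_equal(fc$caged$r_squared, 1, tolerance = 1e-12)
})

test_that("2D curves use the 4*D*t prefactor", {
  t <- 1:15
  f <- fit_msd_models(make_curve(4 * 0.02 * t + 0.005, dim = 2))
  expect_equal(f$random$D, 0.02, tolerance = 1e-9)
  expect_equal(f$random$k, 0.005, tolerance = 1e-9)
})

test_that("fit parameters respect their bounds on adversarial curves", {
  t <- 1:12
  # decreasing curve: unconstrained slope would be negative
  f <- fit_msd_models(make_curve(1 - 0.05 * t, dim = 3))
  expect_gte(f$random$D, 0)
  expect_gte(f$random$k, 0)
  expect_gte(f$directed$v, 0)
  expect_true(all(vapply(f, function(x) x$r_squared <= 1, logical(1))))
})

test_that("noise makes the fitted intercept absorb 2*dim*sigma_loc^2", {
  # noise-dominated regime: the D >= 0, k >= 0 constraints leave the paired
  # intercept shift unbiased here, unlike the absolute single-track intercept
  sig <- 0.08
  shift <- vapply(1:150, function(i) {
    base <- sim_params("random", dim = 3, D = 0.0005, sigma_loc = 0,
                       n_steps = 100, dt = 1, seed = 5000 + i)
    noisy <- sim_params("random", dim = 3, D = 0.0005, sigma_loc = sig,
                        n_steps = 100, dt = 1, seed = 5000 + i)
    k0 <- fit_msd_models(compute_msd(simulate_trajectory(base)))$random$k
    k1 <- fit_msd_models(compute_msd(simulate_trajectory(noisy)))$random$k
    k1 - k0
  }, numeric(1))
  expected <- 2 * 3 * sig^2
  expect_lt(abs(median(shift) - expected) / expected, 0.2)
})

test_that("caged fit plateaus at R^2 + k and relaxes to a line for huge R", {
  t <- 1:30
  curve <- make_curve(0.36 * (1 - 0.99 * exp(-6 * 0.85 * 0.02 * t / 0.36)) +
                        0.02, dim = 3)
  f <- fit_msd_models(curve)$caged
  expect_equal(f$R^2 + f$k,
               max(curve$msd) + 0.99 * 0.36 *
                 exp(-6 * 0.85 * 0.02 * 30 / 0.36),
               tolerance = 0.01)
  # nearly linear data: caged fit approaches the (perfect) random fit; the
  # k >= 0 bound and the 1 - a1 intercept floor keep it from exact equality
  lin <- make_curve(0.06 * t + 0.01, dim = 3)
  fl <- fit_msd_models(lin)
  expect_equal(fl$random$r_squared, 1, tolerance = 1e-12)
  expect_gt(fl$caged$r_squared, 0.98)
})

test_that("average_msd pools per class with the 80% presence rule", {
  c1 <- make_curve(c(1, 2, 3, 4, 5), track_id = "a")
  c2 <- make_curve(c(1, 2, 3, 4, 5), track_id = "b")
  av <- average_msd(list(c1, c2), c("x", "x"))
  expect_equal(av$msd_um2, c1$msd)
  # zero curve + quadratic curve -> halved quadratic
  cz <- make_curve(rep(0, 5), track_id = "z")
  cq <- make_curve((1:5)^2, track_id = "q")
  av2 <- average_msd(list(cz, cq), c("y", "y"))
  expect_equal(av2$msd_um2, (1:5)^2 / 2)
  # lags present in under 80% of tracks are dropped
  clong <- make_curve(1:10, track_id = "l")
  av3 <- average_msd(list(c1, c2, clong, cz, cq),
                     rep("m", 5))
  expect_equal(max(av3$lag_s), 5)
  expect_warning(average_msd(list(), character(0)), NA)
})

test_that("averaged directed cohorts curve upward", {
  trs <- lapply(1:100, function(i)
    simulate_trajectory(sim_params("directed", dim = 3, D = 0.005,
                                   v = c(0.15, 0, 0), sigma_loc = 0.02,
                                   n_steps = 50, seed = 7000 + i)))
  curves <- lapply(trs, compute_msd)
  av <- average_msd(curves, rep("directed", length(curves)))
  d2 <- diff(diff(av$msd_um2[1:10]))
  expect_true(all(d2 > 0))
})
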