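test_that("immobility threshold defaults and calibration behave", {
  expect_equal(calibrate_immobile_threshold(NULL), 0.2)
  expect_error(calibrate_immobile_threshold(list()), "empty")
  expect_error(calibrate_immobile_threshold(
    simulate_fixed_cell_population(0.05, 5, seed = 1)), ">= 20")
  # all-zero tracks -> threshold 0
  quiet <- simulate_fixed_cell_population(0, 30, n_steps = 20, seed = 3)
  expect_equal(calibrate_immobile_threshold(quiet), 0)
  # Monte-Carlo oracle: an independent re-simulation with a different seed
  # reproduces the percentile within 15%
  t1 <- calibrate_immobile_threshold(
    simulate_fixed_cell_population(0.05, 1000, n_steps = 50, seed = 11))
  t2 <- calibrate_immobile_threshold(
    simulate_fixed_cell_population(0.05, 1000, n_steps = 50, seed = 222))
  expect_lt(abs(t1 - t2) / t2, 0.15)
})

test_that("the decision rules fire in the documented order", {
  cfg <- classification_config()
  low_curve <- make_curve(rep(0.15, 20))        # max MSD 0.15 um^2
  mobile_curve <- make_curve(seq(0.1, 2, length.out = 20))

  # rule 1: immobile regardless of (excellent) fits
  mc <- classify_track(low_curve, make_fits(0.99, 0.999, 0.99), cfg)
  expect_equal(mc$label, "immobile")
  expect_equal(mc$rule_fired, "max_msd")
  expect_null(mc$fit)

  # rule 2: all r2 below 0.33 -> complex
  mc <- classify_track(mobile_curve, make_fits(0.20, 0.30, 0.10), cfg)
  expect_equal(mc$label, "complex")
  expect_equal(mc$rule_fired, "all_r2_low")

  # rule 3: nearly equal r2 -> random even though directed fits best
  mc <- classify_track(mobile_curve, make_fits(0.950, 0.956, 0.952), cfg)
  expect_equal(mc$label, "random")
  expect_equal(mc$rule_fired, "r2_std")

  # rule 4: best fit wins
  mc <- classify_track(mobile_curve, make_fits(0.50, 0.90, 0.60), cfg)
  expect_equal(mc$label, "directed")
  expect_equal(mc$rule_fired, "best_r2")
  mc <- classify_track(mobile_curve, make_fits(0.50, 0.60, 0.90), cfg)
  expect_equal(mc$label, "caged")

  # exact ties resolve by parsimony
  mc <- classify_track(mobile_curve, make_fits(0.9, 0.9, 0.9), cfg)
  expect_equal(mc$label, "random")
  mc <- classify_track(mobile_curve, make_fits(0.5, 0.9, 0.9), cfg)
  expect_equal(mc$label, "caged")
})

test_that("sentinel fits participate as -Inf", {
  cfg <- classification_config()
  mobile_curve <- make_curve(seq(0.1, 2, length.out = 20))
  mc <- classify_track(mobile_curve, make_fits(-Inf, 0.9, -Inf), cfg)
  expect_equal(mc$label, "directed")
  expect_warning(
    mc <- classify_track(mobile_curve, make_fits(-Inf, -Inf, -Inf), cfg),
    "all three fits failed")
  expect_equal(mc$label, "complex")
})

test_that("immobility test only uses lags inside the observation window", {
  cfg <- classification_config(observation_window = 10)
  # quiet for 10 s, escapes afterwards
  vals <- c(rep(0.1, 10), seq(0.3, 2, length.out = 20))
  mc <- classify_track(make_curve(vals), make_fits(0.9, 0.5, 0.5), cfg)
  expect_equal(mc$label, "immobile")
})

test_that("a tight immobile cohort is labelled immobile nearly always", {
  trs <- simulate_fixed_cell_population(0.01, 100, n_steps = 50, seed = 17)
  cl <- classify_cohort(trs)
  frac <- mean(cl$table$label == "immobile")
  expect_gte(frac, 0.95)
})

test_that("cohort fractions normalize and empty cohorts are flagged", {
  cl <- classify_cohort(list())
  expect_equal(nrow(cl$table), 0)
  expect_equal(nrow(cl$fractions), 0)
  sp <- data.frame(model = c("immobile", "directed"), count = c(10, 10),
                   sigma_loc = 0.02, v = c(0, 0.2), D = c(0, 0.005))
  coh <- simulate_cohort(sp, seed = 31)
  cl <- classify_cohort(coh$trajectories)
  classes <- c("immobile", "random", "directed", "caged", "complex")
  sums <- rowSums(cl$fractions[, classes])
  expect_equal(sums, rep(1, nrow(cl$fractions)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(cl$fractions$n), 20)
})

test_that("raising the immobility bound never shrinks the immobile set", {
  sp <- data.frame(model = c("immobile", "random"), count = c(20, 20),
                   sigma_loc = 0.05, D = c(0, 0.002))
  coh <- simulate_cohort(sp, seed = 13)
  fr <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), function(th) {
    cl <- classify_cohort(coh$trajectories,
                          classification_config(immobile_msd_max = th))
    mean(cl$table$label == "immobile")
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("classification is invariant to rigid motions", {
  sp <- data.frame(model = c("random", "directed", "caged"), count = 5,
                   sigma_loc = 0.02, D = c(0.02, 0.005, 0.05),
                   v = c(0, 0.15, 0), R = c(NA, NA, 0.4))
  coh <- simulate_cohort(sp, seed = 47)
  cl0 <- classify_cohort(coh$trajectories)
  moved <- lapply(coh$trajectories, rigid_transform)
  cl1 <- classify_cohort(moved)
  expect_identical(cl0$table$label, cl1$table$label)
})
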