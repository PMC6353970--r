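two_by_two <- function(T_bins = 30) {
  task_design("sym", parameter_levels = c("a", "b"),
              window = c(0, T_bins * 40))
}

test_that("distance curves follow the euclidean definition", {
  expect_equal(distance_curve(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(distance_curve(c(5, 5), c(3, 3)), c(2, 2))
  # 2-component case: per-bin differences (3, 4) give distance 5
  a <- rbind(c(3, 0), c(4, 0))
  b <- rbind(c(0, 0), c(0, 0))
  expect_equal(distance_curve(a, b), c(5, 0))
  expect_error(distance_curve(1:3, 1:4), "identical dimensions")
})

test_that("averaged projections are the mean over the other factor's levels", {
  spec <- noiseless_spec(seed = 31)
  rec <- simulate_population(two_by_two(), 15, spec)
  fit <- dpca(rec, q = 2)
  ap <- averaged_projections(fit, "parameter", c("a", "b"))
  comp <- fit$components$component[
    fit$components$marginalization == "parameter"][1]
  manual_a <- (fit$projections[comp, 1, 1, ] +
                 fit$projections[comp, 1, 2, ]) / 2
  expect_equal(as.numeric(ap$a), manual_a, tolerance = 1e-10)
  expect_error(averaged_projections(fit, "parameter", c("a", "zz")),
               "not in the design")
})

test_that("distance curves survive a global component sign flip", {
  spec <- noiseless_spec(seed = 32)
  rec <- simulate_population(two_by_two(), 15, spec)
  fit <- dpca(rec, q = 2)
  ap <- averaged_projections(fit, "parameter")
  d0 <- distance_curve(ap[[1]], ap[[2]])
  flipped <- fit
  comp <- fit$components$component[
    fit$components$marginalization == "parameter"][1]
  flipped$projections[comp, , , ] <- -flipped$projections[comp, , , ]
  ap2 <- averaged_projections(flipped, "parameter")
  expect_equal(distance_curve(ap2[[1]], ap2[[2]]), d0, tolerance = 1e-12)
})

test_that("bootstrap bands are reproducible and contain the point curves", {
  spec <- effect_spec(seed = 33, noise = "gaussian", sigma_hz = 1,
                      trials = c(4, 5))
  rec <- simulate_population(two_by_two(), 25, spec)
  b1 <- bootstrap_bands(rec, n_bootstrap = 25, seed = 5,
                        min_consecutive = 10)
  b2 <- bootstrap_bands(rec, n_bootstrap = 25, seed = 5,
                        min_consecutive = 10)
  expect_identical(b1$ci_lower, b2$ci_lower)
  cover_p <- mean(b1$parameter_curve >= b1$ci_lower["parameter", ] &
                    b1$parameter_curve <= b1$ci_upper["parameter", ])
  cover_v <- mean(b1$visual_curve >= b1$ci_lower["visual", ] &
                    b1$visual_curve <= b1$ci_upper["visual", ])
  expect_gte(cover_p, 0.9)
  expect_gte(cover_v, 0.9)
  expect_warning(bootstrap_bands(rec, n_bootstrap = 5, seed = 5),
                 "unstable")
})

test_that("equal planted factor strengths produce no separation intervals", {
  d <- two_by_two()
  prof <- boxcar_profile(d, 8, 22)
  spec <- effect_spec(
    target_fractions = c(condition_independent = 0.5, parameter = 0.25,
                         visual = 0.25, interaction = 0),
    profiles = list(parameter = list(prof), visual = list(prof)),
    noise = "gaussian", sigma_hz = 1, baseline_hz = 20, seed = 34,
    trials = c(4, 5))
  rec <- simulate_population(d, 30, spec)
  bands <- bootstrap_bands(rec, n_bootstrap = 30, seed = 6,
                           min_consecutive = 10)
  expect_equal(nrow(bands$separation_intervals), 0)
})

test_that("a dominant factor separates exactly over its planted window", {
  # visual variance is zero, so outside the parameter window both curves sit
  # at the trial-noise floor and their bands overlap
  d <- two_by_two(40)
  spec <- effect_spec(
    target_fractions = c(condition_independent = 0.4, parameter = 0.6,
                         visual = 0, interaction = 0),
    profiles = list(parameter = list(boxcar_profile(d, 15, 30))),
    noise = "gaussian", sigma_hz = 1, baseline_hz = 20,
    signal_sd_hz = 5, seed = 35, trials = c(4, 5))
  rec <- simulate_population(d, 40, spec)
  bands <- bootstrap_bands(rec, n_bootstrap = 30, seed = 7,
                           min_consecutive = 10)
  expect_equal(nrow(bands$separation_intervals), 1)
  expect_lte(abs(bands$separation_intervals[1, 1] - 15), 3)
  expect_lte(abs(bands$separation_intervals[1, 2] - 30), 3)
})

test_that("the randomization null is calibrated on structureless data", {
  # under a pure condition-independent population the factor labels are
  # exchangeable, so per-bin p-values are uniform
  spec <- effect_spec(target_fractions = c(condition_independent = 1,
                                           parameter = 0, visual = 0,
                                           interaction = 0),
                      noise = "gaussian", sigma_hz = 2,
                      seed = 36, trials = c(4, 5))
  rec <- simulate_population(two_by_two(25), 20, spec)
  rc <- randomization_compare(rec, n_iter = 40, seed = 8,
                              min_consecutive = 10)
  expect_equal(nrow(rc$intervals), 0)
  expect_gte(min(rc$p_values), 1 / 41)
  expect_lte(mean(rc$p_values < 0.05), 0.2)
  expect_gt(mean(rc$p_values), 0.25)
})

test_that("randomization flags the window where one factor dominates", {
  d <- two_by_two(40)
  spec <- effect_spec(
    target_fractions = c(condition_independent = 0.4, parameter = 0.6,
                         visual = 0, interaction = 0),
    profiles = list(parameter = list(boxcar_profile(d, 15, 30))),
    noise = "gaussian", sigma_hz = 1, baseline_hz = 20,
    signal_sd_hz = 5, seed = 37, trials = c(4, 5))
  rec <- simulate_population(d, 40, spec)
  rc <- randomization_compare(rec, n_iter = 40, seed = 9,
                              min_consecutive = 10)
  expect_equal(nrow(rc$intervals), 1)
  expect_lte(abs(rc$intervals[1, 1] - 15), 3)
  expect_lte(abs(rc$intervals[1, 2] - 30), 3)
})
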