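# decoding tests run on reduced problem sizes (small windows, few CV
# iterations) so the whole suite stays fast; acceptance-scale runs live in
# test-acceptance.R

chance_recording <- function(n = 25, T_bins = 30, seed = 21) {
  # labels carry no information: all signal variance is condition-independent
  spec <- effect_spec(target_fractions = c(condition_independent = 1,
                                           parameter = 0, visual = 0,
                                           interaction = 0),
                      noise = "gaussian", sigma_hz = 2,
                      seed = seed, trials = c(4, 6))
  simulate_population(small_reach(T_bins), n, spec)
}

tuned_recording <- function(n = 30, T_bins = 40, from = 15, to = 30,
                            seed = 22, param_frac = 0.5) {
  d <- small_reach(T_bins)
  prof <- list(parameter = list(boxcar_profile(d, from, to)))
  spec <- effect_spec(
    target_fractions = c(condition_independent = 1 - param_frac,
                         parameter = param_frac, visual = 0,
                         interaction = 0),
    profiles = prof, baseline_hz = 20, signal_sd_hz = 5,
    seed = seed, trials = c(4, 6))
  # boxcar profiles concentrate signal variance in few bins; the mild rate
  # clipping this causes is irrelevant to the decoding checks
  suppressWarnings(simulate_population(d, n, spec))
}

test_that("decoding chance-structure data stays at chance level", {
  rec <- chance_recording()
  res <- decode_timecourse(rec, n_iterations = 20, seed = 1)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  se <- stats::sd(rowMeans(res$accuracy_iterations)) /
    sqrt(res$n_iterations)
  expect_lt(abs(mean(res$accuracy) - 1 / 3), 3 * se + 0.02)
})

test_that("a strongly tuned noiseless population decodes perfectly in its window", {
  d <- small_reach(40)
  prof <- list(parameter = list(boxcar_profile(d, 15, 30)))
  spec <- effect_spec(
    target_fractions = c(condition_independent = 0.5, parameter = 0.5,
                         visual = 0, interaction = 0),
    profiles = prof, noise = "gaussian", sigma_hz = 0,
    baseline_hz = 100, seed = 23, trials = c(3, 4))
  rec <- simulate_population(d, 20, spec)
  res <- decode_timecourse(rec, n_iterations = 5, seed = 2)
  expect_true(all(res$accuracy[15:30] == 1))
})

test_that("decoding is reproducible bit-for-bit under a fixed seed", {
  rec <- tuned_recording(n = 15, T_bins = 20, from = 8, to = 16)
  a <- decode_timecourse(rec, n_iterations = 5, seed = 9)
  b <- decode_timecourse(rec, n_iterations = 5, seed = 9)
  expect_identical(a$accuracy, b$accuracy)
})

test_that("single-trial conditions are rejected with the neuron named", {
  rec <- hand_recording()
  nt <- rec$n_trials; nt[1, 2, 1] <- 1L
  rec1 <- population_recording(rec$design, rec$rates, nt, rec$neuron_ids)
  expect_error(decode_timecourse(rec1), "u1.*>= 2")
})

test_that("shuffle significance brackets the planted tuning window", {
  rec <- tuned_recording(n = 30, T_bins = 40, from = 15, to = 30)
  res <- decode_timecourse(rec, n_iterations = 15, seed = 3)
  sig <- significance_intervals(res, n_shuffles = 15, min_consecutive = 10,
                                seed = 4)
  expect_equal(nrow(sig$intervals), 1)
  expect_lte(abs(sig$intervals[1, 1] - 15), 3)
  expect_lte(abs(sig$intervals[1, 2] - 30), 3)
})

test_that("chance data yields no intervals under the 10-bin run rule", {
  rec <- chance_recording(n = 20, T_bins = 30)
  res <- decode_timecourse(rec, n_iterations = 10, seed = 5)
  sig <- significance_intervals(res, n_shuffles = 20, min_consecutive = 10,
                                seed = 6)
  expect_equal(nrow(sig$intervals), 0)
  # with min_consecutive = 1, roughly an alpha fraction of bins is flagged
  sig1 <- significance_intervals(res, n_shuffles = 20, min_consecutive = 1,
                                 seed = 6)
  frac <- mean(sig1$significant)
  expect_lte(frac, 0.25)  # binomial band around 0.05 over 30 bins
})

test_that("label-shuffled accuracies are indistinguishable from the null", {
  rec <- chance_recording(n = 20, T_bins = 25)
  shuffled <- popdemix:::shuffle_condition_labels(rec, seed = 30)
  obs <- decode_timecourse(shuffled, n_iterations = 10, seed = 7)
  sig <- significance_intervals(obs, n_shuffles = 15, min_consecutive = 10,
                                seed = 8)
  ks <- suppressWarnings(
    stats::ks.test(obs$accuracy, as.vector(sig$null_accuracies)))
  expect_gt(ks$p.value, 0.01)
})

test_that("stronger planted tuning never hurts accuracy in tuned bins", {
  weak <- tuned_recording(seed = 24, param_frac = 0.25)
  strong <- tuned_recording(seed = 24, param_frac = 0.5)
  acc_w <- decode_timecourse(weak, n_iterations = 15, seed = 10)$accuracy
  acc_s <- decode_timecourse(strong, n_iterations = 15, seed = 10)$accuracy
  expect_gte(mean(acc_s[15:30]) - mean(acc_w[15:30]), -0.02)
})

test_that("the minimum-population analysis includes the full population", {
  rec <- tuned_recording(n = 24, T_bins = 30, from = 10, to = 25)
  out <- min_population_analysis(rec, sizes = 12, seed = 11,
                                 n_iterations = 8, n_shuffles = 10,
                                 min_consecutive = 8)
  expect_named(out, c("12", "24"))
  # size = N reuses the recording itself: identical to direct decoding
  direct <- decode_timecourse(rec, n_iterations = 8, seed = 11)
  expect_identical(out[["24"]]$decoding$accuracy, direct$accuracy)
  # significant duration does not shrink with more neurons (up to noise)
  dur <- vapply(out, function(x) {
    iv <- x$significance$intervals
    if (nrow(iv) == 0) 0L else sum(iv[, 2] - iv[, 1] + 1L)
  }, integer(1))
  expect_gte(dur[["24"]], dur[["12"]] - 10L)
})
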