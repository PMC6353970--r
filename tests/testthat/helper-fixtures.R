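# shared fixtures: small designs and generator settings that keep unit tests
# fast; acceptance-scale runs live in test-acceptance.R

small_reach <- function(T_bins = 30) {
  reach_design(window = c(0, T_bins * 40))
}

# noiseless spec at a baseline high enough that rate clipping never occurs
noiseless_spec <- function(fractions = c(condition_independent = 0.58,
                                         parameter = 0.24,
                                         visual = 0.11,
                                         interaction = 0.07),
                           seed = 1, trials = c(3, 4), ...) {
  effect_spec(target_fractions = fractions, noise = "gaussian",
              sigma_hz = 0, baseline_hz = 200, seed = seed,
              trials = trials, ...)
}

# boxcar temporal profile over a bin range (1-based, inclusive)
boxcar_profile <- function(design, from_bin, to_bin) {
  t_on <- design$bin_starts_ms[from_bin]
  t_off <- design$bin_starts_ms[to_bin]
  function(t_ms) as.numeric(t_ms >= t_on & t_ms <= t_off)
}

# a hand-built two-neuron recording with known trial rates (2 x 2 design,
# 3 bins) for exact PSTH checks
hand_recording <- function() {
  d <- task_design("toy", parameter_levels = c("a", "b"),
                   window = c(0, 120), bin_width = 40)
  rates <- array(NA_real_, dim = c(2, 2, 2, 3, 2))
  nt <- array(0L, dim = c(2, 2, 2))
  # neuron 1: condition-dependent rates, 2 trials everywhere
  for (s in 1:2) for (v in 1:2) {
    base <- 10 * s + 2 * v
    rates[1, s, v, , 1] <- base + c(0, 1, 2)
    rates[1, s, v, , 2] <- base + c(2, 3, 4)
    nt[1, s, v] <- 2L
  }
  # neuron 2: constant 10 Hz in every trial and bin
  for (s in 1:2) for (v in 1:2) {
    rates[2, s, v, , 1] <- 10
    rates[2, s, v, , 2] <- 10
    nt[2, s, v] <- 2L
  }
  population_recording(d, rates, nt, c("u1", "u2"))
}

# wrap an [N, S, V, T] centered array as a rate_tensor (for solver-level
# tests that construct tensors directly)
as_rate_tensor <- function(X, design) {
  structure(list(X = X, neuron_means = rowMeans(matrix(X, nrow = dim(X)[1])),
                 centered = TRUE, design = design, recording = NULL),
            class = "rate_tensor")
}

random_centered_tensor <- function(N, S, V, T_, seed = 1) {
  set.seed(seed)
  X <- array(rnorm(N * S * V * T_), dim = c(N, S, V, T_))
  X - array(rowMeans(matrix(X, nrow = N)), dim = dim(X))
}
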