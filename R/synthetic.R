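#' Specify planted variance structure for a synthetic population
#'
#' An effect spec declares how a synthetic pseudo-population distributes its
#' signal variance across the four marginalizations (condition-independent,
#' task parameter, visual condition, interaction), what the latent temporal
#' profiles look like, the baseline firing rate, the trial-count range, and
#' the trial noise model. The generator rescales each marginalization's
#' noiseless part so the population signal-variance split equals
#' `target_fractions` exactly, giving every downstream stage an analytic
#' recovery oracle.
#'
#' @param target_fractions named numeric vector over
#'   `c("condition_independent", "parameter", "visual", "interaction")`,
#'   non-negative, summing to 1. Default mirrors a reach-task-like split.
#' @param n_latents latent components per marginalization (default 2).
#' @param baseline_hz mean firing rate in spikes/s (default 10).
#' @param signal_sd_hz RMS amplitude of the noiseless centered signal per
#'   tensor entry, in spikes/s (default 3; small enough that rate clipping
#'   at 0 under the default baseline is negligible).
#' @param noise `"poisson"` (spike counts in each bin drawn from the
#'   clipped rate), or `"gaussian"` (additive, sd `sigma_hz`).
#' @param sigma_hz sd of Gaussian trial noise (spikes/s); 0 gives noiseless
#'   trials.
#' @param trials integer pair, range of trials per condition per neuron
#'   (default `c(7, 15)`).
#' @param profiles optional list of temporal-profile functions per
#'   marginalization, e.g. `list(parameter = list(function(t_ms) ...))`;
#'   each function maps bin-start times in ms to a profile. Defaults to
#'   smooth random Gaussian bumps drawn from the seed.
#' @param grip_clusters logical; when `TRUE` and the design has 5 parameter
#'   levels, the parameter contrasts form two level clusters (3 + 2 levels
#'   sharing profiles), emulating grouped prehension types. Default `FALSE`.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return An object of class `"effect_spec"`.
#' @export
effect_spec <- function(target_fractions = c(condition_independent = 0.58,
                                             parameter = 0.24,
                                             visual = 0.11,
                                             interaction = 0.07),
                        n_latents = 2L,
                        baseline_hz = 10,
                        signal_sd_hz = 3,
                        noise = c("poisson", "gaussian"),
                        sigma_hz = 1,
                        trials = c(7L, 15L),
                        profiles = NULL,
                        grip_clusters = FALSE,
                        seed = 1L) {
  noise <- match.arg(noise)
  abort_if(is.null(names(target_fractions)) ||
             !setequal(names(target_fractions), MARGINALIZATIONS),
           "target_fractions must be named over the four marginalizations")
  target_fractions <- target_fractions[MARGINALIZATIONS]
  abort_if(any(target_fractions < 0), "variance fractions must be >= 0")
  abort_if(abs(sum(target_fractions) - 1) > 1e-9,
           "variance fractions must sum to 1 (got %.6f)",
           sum(target_fractions))
  abort_if(baseline_hz < 0, "baseline rate must be >= 0")
  abort_if(noise == "poisson" && baseline_hz <= 0,
           "Poisson noise needs a positive baseline rate")
  abort_if(length(trials) != 2L || trials[1] < 1L || trials[2] < trials[1],
           "trials must be an increasing pair of positive counts")
  structure(list(
    target_fractions = target_fractions,
    n_latents = as.integer(n_latents),
    baseline_hz = baseline_hz,
    signal_sd_hz = signal_sd_hz,
    noise = noise,
    sigma_hz = sigma_hz,
    trials = as.integer(trials),
    profiles = profiles,
    grip_clusters = isTRUE(grip_clusters),
    seed = as.integer(seed)
  ), class = "effect_spec")
}

#' The analytic variance split planted by an effect spec
#'
#' Returns the noiseless population signal-variance fractions the generator
#' enforces — by construction these equal the spec's `target_fractions`
#' (a fraction whose marginalization cannot be realized under the design is
#' impossible only for `S < 2`, which the design constructor forbids).
#' Serves as ground truth in recovery tests.
#'
#' @param spec an [effect_spec()].
#' @param design a [task_design()] (kept for interface symmetry with the
#'   generator; the planted split does not depend on it).
#' @return Named numeric vector over the four marginalizations, summing to 1.
#' @export
planted_fractions <- function(spec, design = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  spec$target_fractions
}

# smooth random temporal profile: sum of 1-3 Gaussian bumps over the window
random_profile <- function(t_ms) {
  n_bump <- sample(1:3, 1)
  width <- diff(range(t_ms))
  y <- rep(0, length(t_ms))
  for (i in seq_len(n_bump)) {
    mu <- stats::runif(1, min(t_ms), max(t_ms))
    sd <- stats::runif(1, width / 20, width / 5)
    y <- y + stats::rnorm(1) * exp(-(t_ms - mu)^2 / (2 * sd^2))
  }
  y
}

# build the S x V x T condition profile of one latent of marginalization phi
latent_condition_profile <- function(phi, p_t, S, V, spec) {
  T_ <- length(p_t)
  G <- array(0, dim = c(S, V, T_))
  if (phi == "condition_independent") {
    p0 <- p_t - mean(p_t)   # zero-mean in time: the only grand mean is baseline
    G[] <- rep(p0, each = S * V)
  } else if (phi == "parameter") {
    if (spec$grip_clusters && S == 5L) {
      cs <- c(1, 1, 1, -1.5, -1.5)      # two prehension clusters
    } else {
      cs <- stats::rnorm(S)
    }
    cs <- cs - mean(cs)
    G <- outer(cs, rep(1, V)) %o% p_t
  } else if (phi == "visual") {
    cv <- stats::rnorm(2)
    cv <- cv - mean(cv)
    G <- outer(rep(1, S), cv) %o% p_t
  } else {  # interaction: outer product of zero-mean level contrasts
    cs <- stats::rnorm(S); cs <- cs - mean(cs)
    cv <- stats::rnorm(V); cv <- cv - mean(cv)
    G <- outer(cs, cv) %o% p_t
  }
  G
}

#' Generate a synthetic pseudo-population with planted variance structure
#'
#' Each neuron's noiseless rate is
#' `baseline + sum_phi sum_k w[n, phi, k] * g[phi, k](s, v, t)`, where the
#' condition profiles `g` satisfy the marginalization constraints exactly
#' (the condition-independent profile depends on `t` only; the parameter
#' profile has zero mean over `s`; the visual profile zero mean over `v`;
#' the interaction profile zero mean over both at every `t`). Loadings `w`
#' are i.i.d. standard normal, then each marginalization's part is globally
#' rescaled so the population signal-variance split equals the spec's
#' `target_fractions` exactly in the noiseless limit. Trials then add noise
#' per the spec's noise model; for Poisson noise rates are clipped at 0
#' (with a warning if clipping touches more than 0.1% of entries).
#'
#' @param design a [task_design()].
#' @param n_neurons number of neurons (>= 2).
#' @param spec an [effect_spec()].
#' @param keep_truth logical; attach the noiseless centered signal tensor as
#'   attribute `"noiseless"` (used by recovery oracles). Default `FALSE`.
#' @return A [population_recording()]; its attribute `"planted"` records the
#'   planted fractions and the spec.
#' @examples
#' rec <- simulate_population(reach_design(), 20, effect_spec(seed = 7))
#' rec$trial_range
#' @export
simulate_population <- function(design, n_neurons, spec, keep_truth = FALSE) {
  stopifnot(inherits(design, "task_design"), inherits(spec, "effect_spec"))
  abort_if(n_neurons < 2L, "need at least 2 neurons")
  S <- length(design$parameter_levels)
  V <- length(design$visual_levels)
  T_ <- design$n_bins
  N <- as.integer(n_neurons)
  t_ms <- design$bin_starts_ms
  with_seed(spec$seed, {
    signal <- array(0, dim = c(N, S, V, T_))
    for (phi in MARGINALIZATIONS) {
      f <- spec$target_fractions[[phi]]
      user_profiles <- spec$profiles[[phi]]
      K <- if (!is.null(user_profiles)) length(user_profiles) else spec$n_latents
      part <- array(0, dim = c(N, S, V, T_))
      for (k in seq_len(K)) {
        p_t <- if (!is.null(user_profiles)) user_profiles[[k]](t_ms)
               else random_profile(t_ms)
        G <- latent_condition_profile(phi, p_t, S, V, spec)
        w <- stats::rnorm(N)
        part <- part + outer(w, G)
      }
      if (f == 0) next
      nrm2 <- sum(part^2)
      abort_if(nrm2 == 0,
               "marginalization '%s' has target fraction %g but zero realized profile",
               phi, f)
      total_signal_var <- N * S * V * T_ * spec$signal_sd_hz^2
      signal <- signal + part * sqrt(f * total_signal_var / nrm2)
    }
    rates0 <- spec$baseline_hz + signal
    if (spec$noise == "poisson") {
      n_clip <- sum(rates0 < 0)
      if (n_clip > 0.001 * length(rates0))
        warning(sprintf(
          "Poisson rate clipping affects %.2f%% of tensor entries; planted fractions are perturbed",
          100 * n_clip / length(rates0)))
      rates0 <- pmax(rates0, 0)
    }
    Kmax <- spec$trials[2]
    counts <- seq(spec$trials[1], spec$trials[2])
    nt <- array(if (length(counts) == 1L) rep(counts, N * S * V)
                else sample(counts, N * S * V, replace = TRUE),
                dim = c(N, S, V))
    trials <- array(NA_real_, dim = c(N, S, V, T_, Kmax))
    dt_s <- design$bin_width / 1000
    for (k in seq_len(Kmax)) {
      live <- array(nt >= k, dim = c(N, S, V, T_))
      noisy <- switch(spec$noise,
        poisson = stats::rpois(length(rates0), rates0 * dt_s) / dt_s,
        gaussian = pmax(rates0 + stats::rnorm(length(rates0),
                                              sd = spec$sigma_hz), 0))
      slab <- array(NA_real_, dim = c(N, S, V, T_))
      slab[live] <- array(noisy, dim = c(N, S, V, T_))[live]
      trials[, , , , k] <- slab
    }
    rec <- population_recording(design, trials, nt)
    attr(rec, "planted") <- list(fractions = spec$target_fractions,
                                 spec = spec)
    if (keep_truth) {
      truth <- signal - array(rowMeans(unfold_tensor(signal)),
                              dim = dim(signal))
      attr(rec, "noiseless") <- truth
    }
    rec
  })
}
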