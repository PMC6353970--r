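# Euclidean-distance discrimination time-courses: how separable are the two
# levels of each factor in the population read-out, bin by bin.

# leading components (global order) of a marginalization
leading_components <- function(fit, marginalization, k = 1L) {
  rows <- fit$components[fit$components$marginalization == marginalization, ]
  rows <- rows[order(rows$variance, decreasing = TRUE), ]
  abort_if(nrow(rows) < k, "fit has fewer than %d '%s' components",
           k, marginalization)
  rows$component[seq_len(k)]
}

#' Level-averaged component projections of one factor
#'
#' For each of two levels of the chosen factor, averages the projections of
#' the factor's leading demixed component(s) over the levels of the other
#' factor. For the reach task, the "left" curve is the mean of the
#' left-in-light and left-in-dark projections.
#'
#' @param fit a [dpca()] fit.
#' @param factor `"parameter"` or `"visual"`.
#' @param levels pair of level labels of that factor (defaults to the
#'   factor's first two levels).
#' @param n_components how many leading components of the factor's
#'   marginalization to use (default 1).
#' @return List of two `n_components x T` matrices, named by level.
#' @export
averaged_projections <- function(fit, factor = c("parameter", "visual"),
                                 levels = NULL, n_components = 1L) {
  stopifnot(inherits(fit, "dpca"))
  factor <- match.arg(factor)
  design <- fit$design
  all_levels <- if (factor == "parameter") design$parameter_levels
                else design$visual_levels
  if (is.null(levels)) levels <- all_levels[1:2]
  abort_if(length(levels) != 2L, "exactly two levels are compared")
  idx <- match(levels, all_levels)
  abort_if(anyNA(idx), "level(s) not in the design: %s",
           paste(levels[is.na(idx)], collapse = ", "))
  comps <- leading_components(fit, factor, n_components)
  T_ <- dim(fit$projections)[4]
  out <- lapply(idx, function(l) {
    m <- matrix(0, n_components, T_)
    for (j in seq_along(comps)) {
      p <- fit$projections[comps[j], , , , drop = FALSE]
      dim(p) <- dim(fit$projections)[-1]          # [S, V, T]
      m[j, ] <- if (factor == "parameter") colMeans(p[l, , , drop = FALSE][1, , ])
                else colMeans(p[, l, , drop = FALSE][, 1, ])
    }
    m
  })
  names(out) <- levels
  out
}

#' Per-bin euclidean distance between two component curves
#'
#' With a single component this is the absolute per-bin difference; with
#' `k` components it is the `k`-dimensional euclidean norm of the per-bin
#' difference vector.
#'
#' @param curve_a,curve_b numeric vectors (one component) or `k x T`
#'   matrices of equal size.
#' @return Numeric vector of per-bin distances (>= 0).
#' @examples
#' distance_curve(c(1, 2, 3), c(1, 2, 3))   # all zero
#' distance_curve(rbind(3, 0), rbind(0, 4)) # NULL-safe 2-component case
#' @export
distance_curve <- function(curve_a, curve_b) {
  if (is.null(dim(curve_a))) curve_a <- matrix(curve_a, nrow = 1)
  if (is.null(dim(curve_b))) curve_b <- matrix(curve_b, nrow = 1)
  abort_if(!all(dim(curve_a) == dim(curve_b)),
           "curves must have identical dimensions")
  sqrt(colSums((curve_a - curve_b)^2))
}

# both discrimination curves (task parameter and visual condition) of a
# recording restricted to two parameter levels; refits dPCA from scratch
discrimination_curves <- function(recording, parameter_levels = NULL,
                                  n_components = 1L, q = 5L, lambda = NULL) {
  tensor <- build_rate_tensor(recording)
  if (!is.null(parameter_levels) &&
      !identical(sort(parameter_levels),
                 sort(recording$design$parameter_levels)))
    tensor <- subset_conditions(tensor, parameter_levels)
  fit <- dpca(tensor, q = q, lambda = lambda)
  pl <- tensor$design$parameter_levels[1:2]
  vl <- tensor$design$visual_levels
  pp <- averaged_projections(fit, "parameter", pl, n_components)
  vp <- averaged_projections(fit, "visual", vl, n_components)
  list(parameter = distance_curve(pp[[1]], pp[[2]]),
       visual = distance_curve(vp[[1]], vp[[2]]),
       fit = fit, tensor = tensor)
}

#' Discrimination time-courses with bootstrap confidence bands
#'
#' Computes the per-bin euclidean distance between the level-averaged
#' projections of the task-parameter component and of the visual-condition
#' component (two discrimination curves), then resamples neurons with
#' replacement, refitting the demixed PCA on every resample, to obtain 95%
#' percentile confidence bands. Bins where the two curves' bands do not
#' overlap, in runs of at least `min_consecutive` bins, are reported as
#' separation intervals.
#'
#' @param recording a [population_recording()].
#' @param parameter_levels pair of task-parameter levels entering the
#'   symmetric 2 x 2 comparison (default: the design's first two levels;
#'   designs with more levels are subset and re-centered).
#' @param n_bootstrap bootstrap resamples (default 100; fewer than 20 gives
#'   a warning — bands are unstable).
#' @param n_components leading components per marginalization used in the
#'   distance (default 1).
#' @param q components per marginalization in each dPCA refit (default 5).
#' @param lambda ridge strength (`NULL` = stabilizer default).
#' @param min_consecutive minimum separation run length in bins (default 10).
#' @param seed RNG seed.
#' @return An object of class `"distance_curves"`: `parameter_curve`,
#'   `visual_curve`, `ci_lower`/`ci_upper` (2 x T matrices, rows parameter /
#'   visual), `separation_intervals`, `n_bootstrap`, `design`.
#' @export
bootstrap_bands <- function(recording, parameter_levels = NULL,
                            n_bootstrap = 100L, n_components = 1L,
                            q = 5L, lambda = NULL, min_consecutive = 10L,
                            seed = 1L) {
  stopifnot(inherits(recording, "population_recording"))
  if (n_bootstrap < 20L)
    warning("fewer than 20 bootstrap resamples: confidence bands are unstable")
  point <- discrimination_curves(recording, parameter_levels,
                                 n_components, q, lambda)
  T_ <- length(point$parameter)
  boot_p <- matrix(NA_real_, n_bootstrap, T_)
  boot_v <- matrix(NA_real_, n_bootstrap, T_)
  N <- recording$n_neurons
  boot_idx <- with_seed(seed, matrix(sample.int(N, N * n_bootstrap,
                                                replace = TRUE),
                                     nrow = n_bootstrap))
  for (b in seq_len(n_bootstrap)) {
    idx <- boot_idx[b, ]
    rec_b <- population_recording(
      recording$design,
      recording$rates[idx, , , , , drop = FALSE],
      recording$n_trials[idx, , , drop = FALSE],
      sprintf("b%04d", seq_len(N)))
    cb <- discrimination_curves(rec_b, parameter_levels, n_components, q,
                                lambda)
    boot_p[b, ] <- cb$parameter
    boot_v[b, ] <- cb$visual
  }
  ci <- function(m) apply(m, 2, stats::quantile, probs = c(0.025, 0.975),
                          names = FALSE)
  ci_p <- ci(boot_p); ci_v <- ci(boot_v)
  separated <- ci_p[1, ] > ci_v[2, ] | ci_v[1, ] > ci_p[2, ]
  design_used <- point$tensor$design
  intervals <- significant_runs(separated, min_len = min_consecutive,
                                epoch_boundary = design_used$epoch_boundary)
  structure(list(
    parameter_curve = point$parameter,
    visual_curve = point$visual,
    ci_lower = rbind(parameter = ci_p[1, ], visual = ci_v[1, ]),
    ci_upper = rbind(parameter = ci_p[2, ], visual = ci_v[2, ]),
    bootstrap_parameter = boot_p,
    bootstrap_visual = boot_v,
    separation_intervals = intervals,
    n_bootstrap = n_bootstrap,
    min_consecutive = min_consecutive,
    design = design_used
  ), class = "distance_curves")
}

#' @export
print.distance_curves <- function(x, ...) {
  cat(sprintf(
    "Discrimination curves (%d bins, %d bootstrap resamples)\n",
    length(x$parameter_curve), x$n_bootstrap))
  cat(sprintf("  parameter curve: mean %.3f; visual curve: mean %.3f\n",
              mean(x$parameter_curve), mean(x$visual_curve)))
  n <- nrow(x$separation_intervals)
  cat(sprintf("  %d separation interval(s) of >= %d bins\n",
              n, x$min_consecutive))
  invisible(x)
}

#' Plot discrimination curves with confidence bands
#'
#' @param x a `distance_curves` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.distance_curves <- function(x, ...) {
  t_ms <- x$design$bin_starts_ms
  y <- cbind(x$parameter_curve, x$visual_curve,
             t(x$ci_lower), t(x$ci_upper))
  graphics::matplot(t_ms, y, type = "l",
                    lty = c(1, 1, 3, 3, 3, 3),
                    col = c("black", "red", "black", "red", "black", "red"),
                    xlab = "time (ms)", ylab = "euclidean distance (a.u.)",
                    ...)
  if (!is.null(x$design$epoch_boundary))
    graphics::abline(v = t_ms[x$design$epoch_boundary], lty = 2)
  if (nrow(x$separation_intervals) > 0)
    for (i in seq_len(nrow(x$separation_intervals)))
      graphics::segments(t_ms[x$separation_intervals[i, 1]],
                         max(y) * 1.02,
                         t_ms[x$separation_intervals[i, 2]],
                         max(y) * 1.02, lwd = 3)
  invisible(x)
}

#' Randomization comparison of the two discrimination curves
#'
#' Tests, bin by bin, whether the task-parameter and visual-condition
#' discrimination curves differ more than expected under exchangeability of
#' the two factors. The null permutes condition labels across trials within
#' each neuron and recomputes the difference of the two distance curves;
#' the per-bin p-value is the permutation fraction of null absolute
#' differences at least as large as the observed one (Phipson-Smyth
#' `(count + 1) / (n_iter + 1)`, so the attainable resolution at 100
#' iterations is about 0.01). Reported intervals are runs of at least
#' `min_consecutive` bins with `p < alpha`.
#'
#' @inheritParams bootstrap_bands
#' @param n_iter randomization iterations (default 100).
#' @param alpha per-bin significance level (default 0.05).
#' @return An object of class `"distance_randomization"`: `p_values`
#'   (per bin), `observed_difference`, `null_differences`
#'   (`n_iter x T`), `intervals`, plus parameters.
#' @export
randomization_compare <- function(recording, parameter_levels = NULL,
                                  n_iter = 100L, alpha = 0.05,
                                  n_components = 1L, q = 5L, lambda = NULL,
                                  min_consecutive = 10L, seed = 1L) {
  stopifnot(inherits(recording, "population_recording"))
  point <- discrimination_curves(recording, parameter_levels,
                                 n_components, q, lambda)
  obs <- point$parameter - point$visual
  T_ <- length(obs)
  null_diff <- matrix(NA_real_, n_iter, T_)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_iter))
  for (i in seq_len(n_iter)) {
    shuffled <- shuffle_condition_labels(recording, seed = seeds[i])
    ci <- discrimination_curves(shuffled, parameter_levels, n_components,
                                q, lambda)
    null_diff[i, ] <- ci$parameter - ci$visual
  }
  exceed <- colSums(abs(null_diff) >= matrix(abs(obs), n_iter, T_,
                                             byrow = TRUE))
  p <- (exceed + 1) / (n_iter + 1)
  design_used <- point$tensor$design
  intervals <- significant_runs(p < alpha, min_len = min_consecutive,
                                epoch_boundary = design_used$epoch_boundary)
  structure(list(
    p_values = p,
    observed_difference = obs,
    null_differences = null_diff,
    intervals = intervals,
    alpha = alpha,
    n_iter = n_iter,
    min_consecutive = min_consecutive,
    design = design_used
  ), class = "distance_randomization")
}

#' @export
print.distance_randomization <- function(x, ...) {
  cat(sprintf(
    "Randomization comparison (%d iterations, alpha = %g): %d interval(s)\n",
    x$n_iter, x$alpha, nrow(x$intervals)))
  invisible(x)
}
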