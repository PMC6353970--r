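#' Build the trial-averaged rate tensor of a population
#'
#' Averages each neuron's trials within every (parameter, visual) condition
#' cell to form the PSTH tensor `X[n, s, v, t]` (spikes/s), the substrate of
#' the demixed PCA. Centering removes, per neuron, the grand mean over all
#' `(s, v, t)` entries with equal condition weighting — trial counts do not
#' weight the mean, so unbalanced designs do not bias it.
#'
#' @param recording a [population_recording()].
#' @param center logical; return the centered tensor (default `TRUE`). The
#'   removed per-neuron means are kept in `neuron_means` either way, so
#'   centering can be undone exactly.
#' @return An object of class `"rate_tensor"`: list with `X`
#'   (`[N, S, V, T]`), `neuron_means` (length N), `centered`, `design`, and a
#'   reference to the trial-resolved `recording` (used for cross-validation
#'   and noise estimation downstream).
#' @examples
#' spec <- effect_spec(seed = 1)
#' rec <- simulate_population(reach_design(), n_neurons = 12, spec)
#' tx <- build_rate_tensor(rec)
#' max(abs(apply(tx$X, 1, mean)))  # per-neuron means are 0 after centering
#' @export
build_rate_tensor <- function(recording, center = TRUE) {
  stopifnot(inherits(recording, "population_recording"))
  d <- dim(recording$rates)
  N <- d[1]; S <- d[2]; V <- d[3]; T_ <- d[4]
  X <- colMeans(aperm(recording$rates, c(5, 1, 2, 3, 4)), na.rm = TRUE)
  X <- array(X, dim = c(N, S, V, T_))
  neuron_means <- rowMeans(unfold_tensor(X))
  if (center) X <- X - array(neuron_means, dim = dim(X))
  structure(list(
    X = X,
    neuron_means = neuron_means,
    centered = center,
    design = recording$design,
    recording = recording
  ), class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("Rate tensor: %d neurons x %d x %d conditions x %d bins (%s)\n",
              d[1], d[2], d[3], d[4],
              if (x$centered) "centered" else "raw"))
  invisible(x)
}

# undo per-neuron centering
uncenter_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "rate_tensor"))
  if (!tensor$centered) return(tensor)
  tensor$X <- tensor$X + array(tensor$neuron_means, dim = dim(tensor$X))
  tensor$centered <- FALSE
  tensor
}

#' Restrict a rate tensor to a subset of parameter levels
#'
#' Keeps the requested task-parameter levels (for example the symmetric
#' 2 x 2 re-analysis that retains two reach targets or two grip types) and
#' re-centers each neuron over the restricted condition set.
#'
#' @param tensor a `rate_tensor`.
#' @param keep_parameters character vector of >= 2 parameter levels to keep.
#' @return A re-centered `rate_tensor` over the restricted design; the
#'   attached recording is subset accordingly.
#' @export
subset_conditions <- function(tensor, keep_parameters) {
  stopifnot(inherits(tensor, "rate_tensor"))
  design <- tensor$design
  keep_parameters <- as.character(keep_parameters)
  missing <- setdiff(keep_parameters, design$parameter_levels)
  abort_if(length(missing) > 0L,
           "parameter level(s) not in the design: %s",
           paste(missing, collapse = ", "))
  abort_if(length(keep_parameters) < 2L,
           "at least 2 parameter levels must be kept")
  idx <- match(keep_parameters, design$parameter_levels)
  new_design <- task_design(
    name = design$name,
    parameter_levels = keep_parameters,
    visual_levels = design$visual_levels,
    bin_width = design$bin_width,
    window = design$window,
    alignment_events = design$alignment_events,
    epoch_boundary = design$epoch_boundary)
  raw <- uncenter_tensor(tensor)
  Xsub <- raw$X[, idx, , , drop = FALSE]
  means <- rowMeans(unfold_tensor(Xsub))
  Xc <- Xsub - array(means, dim = dim(Xsub))
  rec <- tensor$recording
  if (!is.null(rec)) {
    rec <- population_recording(
      new_design,
      rec$rates[, idx, , , , drop = FALSE],
      rec$n_trials[, idx, , drop = FALSE],
      rec$neuron_ids)
  }
  structure(list(
    X = if (tensor$centered) Xc else Xsub,
    neuron_means = means,
    centered = tensor$centered,
    design = new_design,
    recording = rec
  ), class = "rate_tensor")
}
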