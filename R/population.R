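#' Trial-resolved population recordings
#'
#' A `population_recording` holds the binned firing rates of every trial of
#' every neuron under a factorial [task_design()]. Neurons are typically
#' recorded in separate sessions, so trials are aligned only through their
#' condition labels (a pseudo-population). Internally trials live in a dense
#' `[N, S, V, T, K_max]` array with `NA` slots beyond each condition's trial
#' count; missing trials are represented by that mask and never imputed.
#'
#' @param design a [task_design()].
#' @param rates numeric array `[N, S, V, T, K_max]` of firing rates in
#'   spikes/s; entries beyond a condition's trial count must be `NA`.
#' @param n_trials integer array `[N, S, V]` of trial counts per neuron and
#'   condition (all >= 1).
#' @param neuron_ids optional character vector of neuron identifiers.
#' @return An object of class `"population_recording"` with fields `design`,
#'   `rates`, `n_trials`, `neuron_ids`, `n_neurons`, and `trial_range`.
#' @export
population_recording <- function(design, rates, n_trials, neuron_ids = NULL) {
  stopifnot(inherits(design, "task_design"))
  S <- length(design$parameter_levels)
  V <- length(design$visual_levels)
  T_ <- design$n_bins
  d <- dim(rates)
  abort_if(length(d) != 5L || d[2] != S || d[3] != V || d[4] != T_,
           "rates must be an [N x %d x %d x %d x K] array", S, V, T_)
  N <- d[1]; Kmax <- d[5]
  n_trials <- array(as.integer(n_trials), dim = c(N, S, V))
  bad <- which(n_trials < 1L, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "neuron %s has no trials for condition (%s, %s)",
      bad[1, 1], design$parameter_levels[bad[1, 2]],
      design$visual_levels[bad[1, 3]]), call. = FALSE)
  abort_if(max(n_trials) > Kmax, "n_trials exceeds the trial axis of rates")
  # mask consistency and non-negativity
  for (k in seq_len(Kmax)) {
    slab <- rates[, , , , k, drop = FALSE]
    valid <- array(rep(n_trials >= k, each = 1L), dim = c(N, S, V))
    valid_full <- aperm(array(valid, dim = c(N, S, V, T_)), c(1, 2, 3, 4))
    abort_if(anyNA(slab[valid_full]),
             "NA rate inside the valid trial mask (trial %d)", k)
    if (any(!is.na(slab) & slab < 0))
      stop("negative firing rates are not allowed", call. = FALSE)
  }
  if (is.null(neuron_ids)) neuron_ids <- sprintf("n%03d", seq_len(N))
  abort_if(length(neuron_ids) != N, "neuron_ids length must match N")
  structure(list(
    design = design,
    rates = rates,
    n_trials = n_trials,
    neuron_ids = as.character(neuron_ids),
    n_neurons = N,
    trial_range = range(n_trials)
  ), class = "population_recording")
}

#' @export
print.population_recording <- function(x, ...) {
  d <- x$design
  cat(sprintf("Population recording: %d neurons, %s task\n",
              x$n_neurons, d$name))
  cat(sprintf("  %d x %d conditions, %d bins, %d-%d trials/condition\n",
              length(d$parameter_levels), length(d$visual_levels),
              d$n_bins, x$trial_range[1], x$trial_range[2]))
  invisible(x)
}

#' Randomly subsample neurons from a recording
#'
#' Draws `n` neurons uniformly without replacement; deterministic for a
#' fixed seed. Used by the minimum-population-size analysis.
#'
#' @param recording a [population_recording()].
#' @param n number of neurons to keep (`n <= N`).
#' @param seed integer RNG seed.
#' @return A `population_recording` restricted to the sampled neurons.
#' @export
subsample_neurons <- function(recording, n, seed = 1L) {
  stopifnot(inherits(recording, "population_recording"))
  N <- recording$n_neurons
  abort_if(n > N, "cannot sample %d neurons from a population of %d", n, N)
  idx <- with_seed(seed, sample.int(N, n))
  population_recording(
    recording$design,
    recording$rates[idx, , , , , drop = FALSE],
    recording$n_trials[idx, , , drop = FALSE],
    recording$neuron_ids[idx])
}

# Permute condition labels across trials within each neuron, preserving the
# per-condition trial counts. This is the shuffle null used by the decoding
# significance test and the randomization comparison of distance curves.
shuffle_condition_labels <- function(recording, seed = NULL) {
  stopifnot(inherits(recording, "population_recording"))
  with_seed(seed, {
    d <- dim(recording$rates)
    N <- d[1]; S <- d[2]; V <- d[3]; T_ <- d[4]
    rates <- recording$rates
    nt <- recording$n_trials
    for (n in seq_len(N)) {
      # gather all valid trials of this neuron as T-length rows
      pool <- list()
      slots <- list()
      for (s in seq_len(S)) for (v in seq_len(V)) {
        for (k in seq_len(nt[n, s, v])) {
          pool[[length(pool) + 1L]] <- rates[n, s, v, , k]
          slots[[length(slots) + 1L]] <- c(s, v, k)
        }
      }
      perm <- sample.int(length(pool))
      for (i in seq_along(slots)) {
        sl <- slots[[i]]
        rates[n, sl[1], sl[2], , sl[3]] <- pool[[perm[i]]]
      }
    }
    population_recording(recording$design, rates, nt, recording$neuron_ids)
  })
}

#' Read and write population recordings as long CSV
#'
#' The canonical text format is a long table with header
#' `neuron_id,trial_id,parameter_level,visual_level,bin_index,rate_hz`,
#' one row per neuron x trial x bin; `bin_index` is 0-based. Rates are
#' written with 17 significant digits, so a write/read cycle reproduces the
#' recording bit-exactly.
#'
#' @param recording a [population_recording()].
#' @param path CSV file path.
#' @export
write_population_csv <- function(recording, path) {
  stopifnot(inherits(recording, "population_recording"))
  d <- recording$design
  nt <- recording$n_trials
  N <- recording$n_neurons
  S <- length(d$parameter_levels); V <- length(d$visual_levels)
  T_ <- d$n_bins
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("neuron_id,trial_id,parameter_level,visual_level,bin_index,rate_hz",
             con)
  bins <- seq_len(T_) - 1L
  for (n in seq_len(N)) for (s in seq_len(S)) for (v in seq_len(V)) {
    for (k in seq_len(nt[n, s, v])) {
      rows <- sprintf("%s,%d,%s,%s,%d,%.17g",
                      recording$neuron_ids[n], k,
                      d$parameter_levels[s], d$visual_levels[v],
                      bins, recording$rates[n, s, v, , k])
      writeLines(rows, con)
    }
  }
  invisible(path)
}

#' @rdname write_population_csv
#' @param design the [task_design()] of the recording (levels in the file
#'   must match it).
#' @export
read_population_csv <- function(path, design) {
  stopifnot(inherits(design, "task_design"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(neuron_id = "character",
                                       trial_id = "integer",
                                       parameter_level = "character",
                                       visual_level = "character",
                                       bin_index = "integer",
                                       rate_hz = "numeric"))
  ids <- unique(df$neuron_id)
  N <- length(ids)
  S <- length(design$parameter_levels); V <- length(design$visual_levels)
  T_ <- design$n_bins
  abort_if(!all(df$parameter_level %in% design$parameter_levels),
           "unknown parameter level in CSV")
  abort_if(!all(df$visual_level %in% design$visual_levels),
           "unknown visual level in CSV")
  ni <- match(df$neuron_id, ids)
  si <- match(df$parameter_level, design$parameter_levels)
  vi <- match(df$visual_level, design$visual_levels)
  Kmax <- max(df$trial_id)
  rates <- array(NA_real_, dim = c(N, S, V, T_, Kmax))
  rates[cbind(ni, si, vi, df$bin_index + 1L, df$trial_id)] <- df$rate_hz
  nt <- array(0L, dim = c(N, S, V))
  agg <- unique(df[, c("neuron_id", "parameter_level", "visual_level",
                       "trial_id")])
  cnt <- stats::aggregate(trial_id ~ neuron_id + parameter_level + visual_level,
                          data = agg, FUN = max)
  nt[cbind(match(cnt$neuron_id, ids),
           match(cnt$parameter_level, design$parameter_levels),
           match(cnt$visual_level, design$visual_levels))] <- cnt$trial_id
  population_recording(design, rates, nt, ids)
}
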