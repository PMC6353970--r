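# Time-resolved population decoding from dPCA decoding axes.
#
# The cross-validation is the stratified Monte-Carlo leave-group-out scheme:
# on each iteration one random trial per neuron per condition is held out and
# assembled into test pseudo-trials, the remaining trials are averaged into a
# training set, the decoding axis of the target marginalization is fit on the
# training set, and test pseudo-trials are classified at every bin by the
# nearest class mean of the training projections.

# ridge reduced-rank decoding axes for one marginalization (q x N)
target_decoder_axes <- function(X_train_c, target, q_axes, lambda) {
  d <- dim(X_train_c)
  N <- d[1]; M <- prod(d[-1])
  Xm <- unfold_tensor(X_train_c)
  if (is.null(lambda)) lambda <- 1e-6 * sum(Xm^2) / length(Xm)
  marg <- marginalize(X_train_c)
  Xphi <- unfold_tensor(marg$parts[[target]])
  C <- tcrossprod(Xm) + diag(lambda, N)
  A <- (Xphi %*% t(Xm)) %*% solve(C)
  sv <- svd(A %*% Xm, nu = q_axes, nv = 0)
  t(sv$u) %*% A
}

#' Time-resolved cross-validated decoding of a task factor
#'
#' Decodes the task parameter (or the visual condition) from pseudo-trial
#' population vectors at every time bin, using the leading decoding axes of
#' the target marginalization as a linear classifier (nearest class mean in
#' the projection space). Cross-validation is stratified Monte-Carlo
#' leave-group-out: each iteration holds out one random trial per neuron per
#' condition as test pseudo-trials and trains on the average of the rest.
#'
#' @param recording a [population_recording()]; every neuron needs >= 2
#'   trials per condition.
#' @param target `"parameter"` or `"visual"` — which factor to decode (the
#'   classes are that factor's levels, collapsed over the other factor).
#' @param n_iterations cross-validation iterations (default 100).
#' @param q_axes number of decoding axes used by the classifier (default 1,
#'   the leading axis).
#' @param lambda ridge strength per training fit (`NULL` = stabilizer
#'   default).
#' @param seed RNG seed; the whole procedure is deterministic given it.
#' @return An object of class `"decoding_result"`: `accuracy` (per-bin mean
#'   over iterations), `chance` (1 / number of classes), `target`,
#'   `n_iterations`, `q_axes`, `population_size`, `seed`, `design`, and the
#'   `recording` (retained for the shuffle null).
#' @examples
#' spec <- effect_spec(seed = 5, trials = c(3, 4))
#' d <- reach_design(window = c(-400, 400))
#' rec <- simulate_population(d, 15, spec)
#' res <- decode_timecourse(rec, n_iterations = 3, seed = 1)
#' range(res$accuracy)
#' @export
decode_timecourse <- function(recording, target = c("parameter", "visual"),
                              n_iterations = 100L, q_axes = 1L,
                              lambda = NULL, seed = 1L) {
  stopifnot(inherits(recording, "population_recording"))
  target <- match.arg(target)
  nt <- recording$n_trials
  if (any(nt < 2L)) {
    bad <- which(nt < 2L, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "neuron %s has a single trial in condition (%s, %s); decoding needs >= 2",
      recording$neuron_ids[bad[1]],
      recording$design$parameter_levels[bad[2]],
      recording$design$visual_levels[bad[3]]), call. = FALSE)
  }
  d <- dim(recording$rates)
  N <- d[1]; S <- d[2]; V <- d[3]; T_ <- d[4]
  n_classes <- if (target == "parameter") S else V
  r <- recording$rates
  sum_all <- colSums(aperm(r, c(5, 1, 2, 3, 4)), na.rm = TRUE)  # [N,S,V,T]
  Kfull <- array(nt, dim = c(N, S, V, T_))
  grid <- as.matrix(expand.grid(n = seq_len(N), s = seq_len(S),
                                v = seq_len(V), t = seq_len(T_)))
  acc <- matrix(0, n_iterations, T_)
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      held <- ceiling(stats::runif(N * S * V) * as.vector(nt))
      idx <- cbind(grid, k = as.vector(array(held, dim = c(N, S, V, T_))))
      X_test <- array(r[idx], dim = c(N, S, V, T_))
      X_train <- (sum_all - X_test) / (Kfull - 1)
      mu <- rowMeans(unfold_tensor(X_train))
      X_train <- X_train - array(mu, dim = dim(X_train))
      X_test <- X_test - array(mu, dim = dim(X_test))
      D <- target_decoder_axes(X_train, target, q_axes, lambda)
      q <- nrow(D)
      Ztr <- array(D %*% unfold_tensor(X_train), dim = c(q, S, V, T_))
      Zte <- array(D %*% unfold_tensor(X_test), dim = c(q, S, V, T_))
      if (target == "parameter") {
        # class means over the visual factor: [q, S(classes), T]
        cm <- colMeans(aperm(Ztr, c(3, 1, 2, 4)))
        truth_dim <- 2L
      } else {
        cm <- colMeans(aperm(Ztr, c(2, 1, 3, 4)))         # [q, V, T]
        truth_dim <- 3L
      }
      # squared distance of every test point to every class mean
      dist2 <- array(0, dim = c(n_classes, S, V, T_))
      for (j in seq_len(q)) {
        zj <- Zte[j, , , , drop = TRUE]                   # [S, V, T]
        zj <- array(zj, dim = c(S, V, T_))
        for (cl in seq_len(n_classes)) {
          cmat <- aperm(array(cm[j, cl, ], dim = c(T_, S, V)), c(2, 3, 1))
          dist2[cl, , , ] <- dist2[cl, , , ] + (zj - cmat)^2
        }
      }
      pred <- apply(dist2, c(2, 3, 4), which.min)          # [S, V, T]
      truth <- if (target == "parameter") slice.index(pred, 1L)
               else slice.index(pred, 2L)
      acc[it, ] <- colMeans(matrix(pred == truth, nrow = S * V))
    }
  })
  structure(list(
    accuracy = colMeans(acc),
    accuracy_iterations = acc,
    chance = 1 / n_classes,
    target = target,
    n_iterations = n_iterations,
    q_axes = q_axes,
    lambda = lambda,
    population_size = N,
    seed = seed,
    design = recording$design,
    recording = recording
  ), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "Decoding of %s: %d neurons, %d CV iterations, chance = %.2f\n",
    x$target, x$population_size, x$n_iterations, x$chance))
  cat(sprintf("  accuracy: mean %.3f, max %.3f over %d bins\n",
              mean(x$accuracy), max(x$accuracy), length(x$accuracy)))
  invisible(x)
}

#' Shuffle-null significance intervals of a decoding time course
#'
#' Builds a null distribution of per-bin accuracies by permuting condition
#' labels across trials within each neuron (preserving per-condition trial
#' counts) and rerunning the full cross-validated decoder. A bin is
#' significant when the observed accuracy exceeds the `(1 - alpha)` quantile
#' of its shuffle null; reported intervals are maximal runs of at least
#' `min_consecutive` significant bins (runs never span the epoch boundary of
#' dual-aligned designs).
#'
#' @param result a [decode_timecourse()] result.
#' @param n_shuffles number of label shuffles (default 100; with 100
#'   shuffles and `alpha = 0.05` the threshold is the 95th order statistic).
#' @param alpha significance level (default 0.05).
#' @param min_consecutive minimum run length in bins (default 10).
#' @param n_iterations CV iterations per shuffle (default: same as the
#'   observed decoding).
#' @param seed RNG seed for the shuffles.
#' @return An object of class `"decoding_significance"`: `intervals`
#'   (matrix of start/end bin indices, 1-based), `significant` (per-bin
#'   logical), `null_quantile` (per-bin threshold), `null_accuracies`
#'   (`n_shuffles x T`), plus the parameters.
#' @export
significance_intervals <- function(result, n_shuffles = 100L, alpha = 0.05,
                                   min_consecutive = 10L,
                                   n_iterations = NULL, seed = 1L) {
  stopifnot(inherits(result, "decoding_result"))
  if (is.null(n_iterations)) n_iterations <- result$n_iterations
  T_ <- length(result$accuracy)
  null_acc <- matrix(NA_real_, n_shuffles, T_)
  shuffle_seeds <- with_seed(seed,
                             sample.int(.Machine$integer.max, 2 * n_shuffles))
  for (b in seq_len(n_shuffles)) {
    shuffled <- shuffle_condition_labels(result$recording,
                                         seed = shuffle_seeds[2 * b - 1])
    res_b <- decode_timecourse(shuffled, target = result$target,
                               n_iterations = n_iterations,
                               q_axes = result$q_axes,
                               lambda = result$lambda,
                               seed = shuffle_seeds[2 * b])
    null_acc[b, ] <- res_b$accuracy
  }
  k <- ceiling((1 - alpha) * n_shuffles)
  thr <- apply(null_acc, 2, function(v) sort(v)[k])
  signif_bins <- result$accuracy > thr
  intervals <- significant_runs(signif_bins, min_len = min_consecutive,
                                epoch_boundary = result$design$epoch_boundary)
  structure(list(
    intervals = intervals,
    significant = signif_bins,
    null_quantile = thr,
    null_accuracies = null_acc,
    alpha = alpha,
    min_consecutive = min_consecutive,
    n_shuffles = n_shuffles,
    design = result$design
  ), class = "decoding_significance")
}

#' @export
print.decoding_significance <- function(x, ...) {
  cat(sprintf("Decoding significance (%d shuffles, alpha = %g, >= %d bins):\n",
              x$n_shuffles, x$alpha, x$min_consecutive))
  if (nrow(x$intervals) == 0L) cat("  no significant intervals\n")
  else {
    t_ms <- x$design$bin_starts_ms
    for (i in seq_len(nrow(x$intervals)))
      cat(sprintf("  bins %d-%d (%g..%g ms)\n",
                  x$intervals[i, 1], x$intervals[i, 2],
                  t_ms[x$intervals[i, 1]], t_ms[x$intervals[i, 2]]))
  }
  invisible(x)
}

#' Minimum-population-size decoding analysis
#'
#' Repeats the decoding and its significance analysis on random neuron
#' subsets of the requested sizes (the full population is always included),
#' to locate the smallest population that still supports reliable demixed
#' decoding.
#'
#' @param recording a [population_recording()].
#' @param sizes integer vector of subpopulation sizes (each <= N).
#' @param seed RNG seed governing subsampling, decoding and shuffles.
#' @param ... passed to [decode_timecourse()] and [significance_intervals()]
#'   (`target`, `n_iterations`, `n_shuffles`, `alpha`, `min_consecutive`,
#'   `q_axes`).
#' @return Named list (one entry per size, plus the full population) of
#'   lists with `decoding` and `significance`.
#' @export
min_population_analysis <- function(recording, sizes, seed = 1L, ...) {
  stopifnot(inherits(recording, "population_recording"))
  N <- recording$n_neurons
  abort_if(any(sizes > N), "subpopulation sizes must not exceed N = %d", N)
  sizes <- sort(unique(c(as.integer(sizes), N)))
  dots <- list(...)
  dec_args <- dots[names(dots) %in% c("target", "n_iterations", "q_axes",
                                      "lambda")]
  sig_args <- dots[names(dots) %in% c("n_shuffles", "alpha",
                                      "min_consecutive")]
  out <- list()
  for (sz in sizes) {
    sub <- if (sz == N) recording
           else subsample_neurons(recording, sz, seed = seed + sz)
    res <- do.call(decode_timecourse,
                   c(list(recording = sub, seed = seed), dec_args))
    sig <- do.call(significance_intervals,
                   c(list(result = res, seed = seed), sig_args))
    out[[as.character(sz)]] <- list(decoding = res, significance = sig)
  }
  out
}
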