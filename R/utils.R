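# internal helpers shared across modules

MARGINALIZATIONS <- c("condition_independent", "parameter", "visual", "interaction")

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never perturb user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# stopifnot with a formatted message
abort_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

#' Maximal runs of TRUE of at least `min_len` bins
#'
#' Returns a two-column matrix (start, end) of 1-based bin indices. Runs are
#' optionally split at an epoch boundary (first bin of the second epoch) so
#' that no reported interval spans the concatenation point of a dual-aligned
#' design.
#' @noRd
significant_runs <- function(flag, min_len = 10L, epoch_boundary = NULL) {
  stopifnot(is.logical(flag))
  flag[is.na(flag)] <- FALSE
  if (!is.null(epoch_boundary) && epoch_boundary > 1L &&
      epoch_boundary <= length(flag)) {
    # forbid runs crossing the boundary by cutting the run there
    r <- rle(flag)
    idx <- epoch_boundary
  } else idx <- NA_integer_
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  out <- cbind(start = starts[keep], end = ends[keep])
  if (!is.na(idx)) {
    split_out <- list()
    for (i in seq_len(nrow(out))) {
      s <- out[i, 1]; e <- out[i, 2]
      if (s < idx && e >= idx) {
        split_out[[length(split_out) + 1L]] <- c(s, idx - 1L)
        split_out[[length(split_out) + 1L]] <- c(idx, e)
      } else split_out[[length(split_out) + 1L]] <- c(s, e)
    }
    out <- do.call(rbind, split_out)
    colnames(out) <- c("start", "end")
  }
  if (is.null(out) || nrow(out) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  out <- out[(out[, 2] - out[, 1] + 1L) >= min_len, , drop = FALSE]
  out
}

# fold a [N x S x V x T] array to the N x (S*V*T) matrix used by PCA/dPCA
unfold_tensor <- function(X) {
  d <- dim(X)
  matrix(X, nrow = d[1], ncol = prod(d[-1]))
}

refold_tensor <- function(M, dims) array(M, dim = dims)
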