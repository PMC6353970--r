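#' ANOVA-style marginalization of a centered rate tensor
#'
#' Splits the per-neuron-centered PSTH tensor `X[n, s, v, t]` into four
#' additive parts, one per task-variable combination:
#' \describe{
#'   \item{condition_independent}{`ci[n, t]` = mean over `(s, v)` — varies
#'     with trial time only.}
#'   \item{parameter}{`mean over v - ci` — task-parameter effect, zero mean
#'     over `s` at every `(n, t)`.}
#'   \item{visual}{`mean over s - ci` — visual-condition effect, zero mean
#'     over `v`.}
#'   \item{interaction}{the remainder, zero mean over `s` and over `v` at
#'     every `(n, t)`.}
#' }
#' The four parts reconstruct the input exactly; each part is returned as a
#' full `[N, S, V, T]` tensor (lower-dimensional parts broadcast over the
#' factors they do not depend on).
#'
#' @param x a centered `rate_tensor` or a centered `[N, S, V, T]` array.
#' @return An object of class `"marginalized_data"`: a list `parts` of four
#'   tensors keyed by marginalization, plus `dims`.
#' @examples
#' spec <- effect_spec(seed = 2)
#' tx <- build_rate_tensor(simulate_population(reach_design(), 10, spec))
#' m <- marginalize(tx)
#' max(abs(Reduce(`+`, m$parts) - tx$X))  # exact reconstruction
#' @export
marginalize <- function(x) {
  X <- if (inherits(x, "rate_tensor")) {
    abort_if(!x$centered, "marginalize() needs a centered tensor")
    x$X
  } else x
  d <- dim(X)
  abort_if(length(d) != 4L, "expected an [N x S x V x T] array")
  nm <- rowMeans(unfold_tensor(X))
  abort_if(max(abs(nm)) > 1e-6,
           "input is not centered per neuron (max |mean| = %.3g)", max(abs(nm)))
  N <- d[1]; S <- d[2]; V <- d[3]; T_ <- d[4]
  # means over factors (colMeans over a permuted first axis), broadcast back
  ci_nt <- colMeans(aperm(array(X, dim = c(N, S * V, T_)),
                          c(2, 1, 3)))                    # [N, T]
  ci <- aperm(array(ci_nt, dim = c(N, T_, S, V)), c(1, 3, 4, 2))
  mv <- colMeans(aperm(X, c(3, 1, 2, 4)))                 # [N, S, T] (mean over v)
  param <- aperm(array(mv, dim = c(N, S, T_, V)), c(1, 2, 4, 3)) - ci
  ms <- colMeans(aperm(X, c(2, 1, 3, 4)))                 # [N, V, T] (mean over s)
  visual <- aperm(array(ms, dim = c(N, V, T_, S)), c(1, 4, 2, 3)) - ci
  interaction <- X - ci - param - visual
  structure(list(
    parts = list(condition_independent = ci, parameter = param,
                 visual = visual, interaction = interaction),
    dims = d
  ), class = "marginalized_data")
}

#' @export
print.marginalized_data <- function(x, ...) {
  v <- vapply(x$parts, function(p) sum(p^2), numeric(1))
  pct <- 100 * v / sum(v)
  cat("Marginalized tensor; variance split (%):\n")
  print(round(pct, 1))
  invisible(x)
}
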