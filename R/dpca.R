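#' Demixed principal component analysis of a population rate tensor
#'
#' Fits demixed PCA by per-marginalization reduced-rank ridge regression.
#' With `X` the `N x (S*V*T)` unfolding of the centered PSTH tensor and
#' `X_phi` its marginalized parts, each marginalization's loss
#' `||X_phi - F_phi D_phi X||^2 + lambda ||F_phi D_phi||^2` is minimized over
#' rank-`q` maps: the full-rank ridge solution is
#' `A_phi = X_phi X' (X X' + lambda I)^-1`; rank reduction truncates the SVD
#' of `A_phi X`, the decoder `D_phi` comes from the truncation and the
#' encoder `F_phi` has unit-norm columns. Decoding axes are not constrained
#' to be mutually orthogonal — that freedom is what allows demixing. In the
#' single-marginalization limit with `lambda = 0` the solution coincides
#' with ordinary PCA.
#'
#' Components are ordered globally by explained variance and sign-fixed so
#' that the time-averaged projection of the first condition is >= 0.
#'
#' @param x a centered `rate_tensor` (from [build_rate_tensor()]) or a
#'   [population_recording()] (averaged and centered automatically).
#' @param q components kept per marginalization: a scalar (default 10) or a
#'   named vector over the four marginalizations.
#' @param lambda ridge strength; `NULL` (default) uses the numerical
#'   stabilizer `1e-6 * ||X||^2 / length(X)`. `lambda = 0` requires
#'   `N <= S*V*T` and a full-rank unfolding.
#' @return An object of class `"dpca"` with elements `D` and `F` (decoder /
#'   encoder axes per marginalization), `components` (a data frame with
#'   global order, marginalization and variance fraction of each component),
#'   `projections` (`[n_components, S, V, T]` condition projections),
#'   `cumvar_dpca`, `cumvar_pca`, `marg_var` (`||X_phi||^2`), `total_var`,
#'   `lambda`, `design`, and the fitted tensor.
#' @examples
#' spec <- effect_spec(seed = 3)
#' rec <- simulate_population(reach_design(), 30, spec)
#' fit <- dpca(rec, q = 3)
#' summary(fit)
#' @export
dpca <- function(x, q = 10L, lambda = NULL) {
  tensor <- if (inherits(x, "population_recording")) build_rate_tensor(x)
            else x
  stopifnot(inherits(tensor, "rate_tensor"))
  abort_if(!tensor$centered, "dpca() needs a centered tensor")
  X <- tensor$X
  d <- dim(X)
  N <- d[1]; M <- prod(d[-1])
  Xm <- unfold_tensor(X)
  total_var <- sum(Xm^2)
  if (is.null(lambda)) lambda <- 1e-6 * total_var / length(Xm)
  abort_if(lambda < 0, "lambda must be >= 0")
  if (length(q) == 1L) {
    q <- stats::setNames(rep(as.integer(q), 4L), MARGINALIZATIONS)
  } else {
    abort_if(!setequal(names(q), MARGINALIZATIONS),
             "q must be a scalar or named over the four marginalizations")
    q <- vapply(MARGINALIZATIONS, function(m) as.integer(q[[m]]), integer(1))
    names(q) <- MARGINALIZATIONS
  }
  abort_if(any(q < 1L) || any(q > min(N, M)),
           "q per marginalization must lie in 1..min(N, S*V*T)")

  marg <- marginalize(tensor)
  marg_var <- vapply(marg$parts, function(p) sum(p^2), numeric(1))

  C <- tcrossprod(Xm) + diag(lambda, N)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop(paste("X X' + lambda I is singular (N > S*V*T or rank-deficient",
               "data); use lambda > 0"), call. = FALSE))
  if (lambda == 0 && N > M)
    stop("with lambda = 0 the ridge normal matrix is singular when N > S*V*T; use lambda > 0",
         call. = FALSE)

  D <- list(); F_ <- list()
  comp_tab <- NULL
  for (phi in MARGINALIZATIONS) {
    Xphi <- unfold_tensor(marg$parts[[phi]])
    A <- (Xphi %*% t(Xm)) %*% Cinv
    AX <- A %*% Xm
    qphi <- q[[phi]]
    sv <- svd(AX, nu = qphi, nv = 0)
    U <- sv$u                       # N x q, orthonormal columns
    Dphi <- t(U) %*% A              # q x N decoding axes
    D[[phi]] <- Dphi
    F_[[phi]] <- U
    var_phi <- rowSums((Dphi %*% Xm)^2)
    comp_tab <- rbind(comp_tab, data.frame(
      marginalization = phi, local_index = seq_len(qphi),
      variance = var_phi, stringsAsFactors = FALSE))
  }
  ord <- order(comp_tab$variance, decreasing = TRUE)
  comp_tab <- comp_tab[ord, , drop = FALSE]
  comp_tab$component <- seq_len(nrow(comp_tab))
  comp_tab$variance_fraction <- comp_tab$variance / total_var
  rownames(comp_tab) <- NULL

  # global decoder matrix in component order; sign convention per component
  n_comp <- nrow(comp_tab)
  D_all <- matrix(0, n_comp, N)
  F_all <- matrix(0, N, n_comp)
  for (i in seq_len(n_comp)) {
    phi <- comp_tab$marginalization[i]; j <- comp_tab$local_index[i]
    D_all[i, ] <- D[[phi]][j, ]
    F_all[, i] <- F_[[phi]][, j]
  }
  proj_flat <- D_all %*% Xm                       # n_comp x (S*V*T)
  proj <- array(proj_flat, dim = c(n_comp, d[2], d[3], d[4]))
  for (i in seq_len(n_comp)) {
    if (mean(proj[i, 1, 1, ]) < 0) {
      D_all[i, ] <- -D_all[i, ]; F_all[, i] <- -F_all[, i]
      proj[i, , , ] <- -proj[i, , , ]
      phi <- comp_tab$marginalization[i]; j <- comp_tab$local_index[i]
      D[[phi]][j, ] <- -D[[phi]][j, ]; F_[[phi]][, j] <- -F_[[phi]][, j]
    }
  }

  # cumulative variance: reconstruction-based, so dPCA can never beat PCA
  cum_dpca <- numeric(n_comp)
  Xhat <- matrix(0, N, M)
  for (i in seq_len(n_comp)) {
    Xhat <- Xhat + F_all[, i, drop = FALSE] %*% (D_all[i, , drop = FALSE] %*% Xm)
    cum_dpca[i] <- 1 - sum((Xm - Xhat)^2) / total_var
  }
  sv_pca <- svd(Xm, nu = 0, nv = 0)$d
  cum_pca <- cumsum(sv_pca^2) / sum(sv_pca^2)

  structure(list(
    D = D, F = F_, D_all = D_all, F_all = F_all,
    components = comp_tab[, c("component", "marginalization", "local_index",
                              "variance", "variance_fraction")],
    projections = proj,
    cumvar_dpca = cum_dpca,
    cumvar_pca = cum_pca,
    marg_var = marg_var,
    total_var = total_var,
    lambda = lambda,
    q = q,
    design = tensor$design,
    tensor = tensor
  ), class = "dpca")
}

#' Principal component analysis baseline of a rate tensor
#'
#' Ordinary PCA on the `N x (S*V*T)` unfolding of the centered tensor, used
#' as the compression reference against which demixed PCA is judged.
#'
#' @param x a centered `rate_tensor` or `population_recording`.
#' @param q number of components (default `min(N, S*V*T)`).
#' @return List with `axes` (`N x q`, orthonormal), `variances` (per
#'   component), `cumulative_variance` (fractions, non-decreasing).
#' @export
population_pca <- function(x, q = NULL) {
  tensor <- if (inherits(x, "population_recording")) build_rate_tensor(x)
            else x
  stopifnot(inherits(tensor, "rate_tensor"), tensor$centered)
  Xm <- unfold_tensor(tensor$X)
  kmax <- min(dim(Xm))
  if (is.null(q)) q <- kmax
  abort_if(q < 1L || q > kmax, "q must lie in 1..min(N, S*V*T)")
  sv <- svd(Xm, nu = q, nv = 0)
  vars <- sv$d^2
  list(axes = sv$u,
       variances = vars[seq_len(q)],
       cumulative_variance = cumsum(vars)[seq_len(q)] / sum(vars))
}

#' Signal-variance split across marginalizations
#'
#' Fraction of the centered PSTH variance attributed to each
#' marginalization, as a percentage: `||X_phi||^2 / sum ||X_psi||^2 * 100`.
#' When trial-resolved data are available the split can subtract the
#' trial-sampling noise that a finite trial count leaks into every
#' marginalization (noise in the condition means distributes across the
#' marginalizations in proportion to their degrees of freedom); this is the
#' default, since the raw split of a trial-averaged tensor is biased toward
#' the high-dof marginalizations at realistic firing rates.
#'
#' @param x a `dpca` fit, a `rate_tensor`, or a `marginalized_data` object.
#' @param noise `"auto"` (subtract when trial data are present), `"subtract"`,
#'   or `"none"` (raw shares).
#' @return Named numeric vector of percentages (full precision; attribute
#'   `"rounded"` carries the integer report values, attribute `"noise"` the
#'   mode used).
#' @export
explained_variance_split <- function(x, noise = c("auto", "subtract", "none")) {
  noise <- match.arg(noise)
  recording <- NULL
  if (inherits(x, "dpca")) {
    marg_var <- x$marg_var
    dims <- dim(x$tensor$X)
    recording <- x$tensor$recording
  } else if (inherits(x, "rate_tensor")) {
    m <- marginalize(x)
    marg_var <- vapply(m$parts, function(p) sum(p^2), numeric(1))
    dims <- dim(x$X)
    recording <- x$recording
  } else if (inherits(x, "marginalized_data")) {
    marg_var <- vapply(x$parts, function(p) sum(p^2), numeric(1))
    dims <- x$dims
  } else stop("unsupported input", call. = FALSE)

  do_sub <- noise == "subtract" ||
    (noise == "auto" && !is.null(recording) && recording$trial_range[1] >= 2L)
  if (do_sub) {
    abort_if(is.null(recording),
             "noise subtraction needs the trial-resolved recording")
    abort_if(recording$trial_range[1] < 2L,
             "noise subtraction needs >= 2 trials per condition")
    S <- dims[2]; V <- dims[3]; T_ <- dims[4]
    # variance of each condition-mean entry, estimated from trial scatter
    r <- recording$rates
    K <- array(recording$n_trials, dim = dim(r)[1:3])
    mu <- colMeans(aperm(r, c(5, 1, 2, 3, 4)), na.rm = TRUE)
    ssq <- colSums(aperm(r, c(5, 1, 2, 3, 4))^2, na.rm = TRUE)
    Kfull <- array(K, dim = dim(mu))
    var_mean <- (ssq - Kfull * mu^2) / (Kfull - 1) / Kfull
    total_noise <- sum(pmax(var_mean, 0))
    dof <- c(condition_independent = T_ - 1,
             parameter = (S - 1) * T_,
             visual = (V - 1) * T_,
             interaction = (S - 1) * (V - 1) * T_)
    noise_phi <- dof / (S * V * T_) * total_noise
    marg_var <- pmax(marg_var - noise_phi[names(marg_var)], 0)
  }
  pct <- 100 * marg_var / sum(marg_var)
  structure(pct, rounded = round(pct), noise = if (do_sub) "subtract" else "none")
}

#' Condition projections of fitted components
#'
#' Projects each condition's PSTH time series onto the decoding axes,
#' yielding `S * V` curves per component (for the reach design, the six
#' condition lines of the component panels).
#'
#' @param fit a `dpca` object.
#' @param x optional `rate_tensor` to project (defaults to the fitted one).
#' @return Array `[n_components, S, V, T]`.
#' @export
project_conditions <- function(fit, x = NULL) {
  stopifnot(inherits(fit, "dpca"))
  if (is.null(x)) return(fit$projections)
  tensor <- if (inherits(x, "population_recording")) build_rate_tensor(x)
            else x
  Xm <- unfold_tensor(tensor$X)
  d <- dim(tensor$X)
  array(fit$D_all %*% Xm, dim = c(nrow(fit$D_all), d[2], d[3], d[4]))
}

#' @export
print.dpca <- function(x, ...) {
  cat(sprintf("Demixed PCA fit: %d components over %d neurons (%s task)\n",
              nrow(x$components), ncol(x$D_all), x$design$name))
  cat(sprintf("  lambda = %.4g; cumulative variance at %d components: %.1f%% (PCA %.1f%%)\n",
              x$lambda, nrow(x$components),
              100 * x$cumvar_dpca[nrow(x$components)],
              100 * x$cumvar_pca[min(nrow(x$components), length(x$cumvar_pca))]))
  invisible(x)
}

#' @export
summary.dpca <- function(object, ...) {
  split <- explained_variance_split(object)
  top <- do.call(rbind, lapply(MARGINALIZATIONS, function(phi) {
    rows <- object$components[object$components$marginalization == phi, ]
    rows[which.max(rows$variance), ]
  }))
  out <- list(variance_split = split, top_components = top,
              cumvar_dpca = object$cumvar_dpca, cumvar_pca = object$cumvar_pca,
              n_components = nrow(object$components))
  class(out) <- "summary.dpca"
  out
}

#' @export
print.summary.dpca <- function(x, ...) {
  cat("Signal variance split (%):\n")
  print(attr(x$variance_split, "rounded"))
  cat("\nLeading component per marginalization:\n")
  print(x$top_components, row.names = FALSE)
  q <- x$n_components
  cat(sprintf("\nCumulative variance at %d components: dPCA %.1f%%, PCA %.1f%%\n",
              q, 100 * x$cumvar_dpca[q],
              100 * x$cumvar_pca[min(q, length(x$cumvar_pca))]))
  invisible(x)
}

#' @export
coef.dpca <- function(object, ...) {
  labels <- sprintf("%s.%d", object$components$marginalization,
                    object$components$local_index)
  D <- object$D_all; rownames(D) <- labels
  F_ <- object$F_all; colnames(F_) <- labels
  list(decoder = D, encoder = F_)
}

#' @export
predict.dpca <- function(object, newdata = NULL, ...) {
  project_conditions(object, newdata)
}

#' Plot the leading component projections of a dPCA fit
#'
#' One panel per marginalization, each showing the `S * V` condition
#' projections of that marginalization's leading component over trial time.
#' For dual-aligned designs a vertical dashed line marks the epoch boundary.
#'
#' @param x a `dpca` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dpca <- function(x, ...) {
  design <- x$design
  t_ms <- design$bin_starts_ms
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  S <- length(design$parameter_levels); V <- length(design$visual_levels)
  for (phi in MARGINALIZATIONS) {
    rows <- x$components[x$components$marginalization == phi, ]
    i <- rows$component[which.max(rows$variance)]
    curves <- matrix(x$projections[i, , , ], nrow = S * V, byrow = FALSE)
    graphics::matplot(t_ms, t(curves), type = "l",
                      lty = rep(seq_len(V), each = S), col = seq_len(S),
                      xlab = "time (ms)", ylab = "projection (a.u.)",
                      main = sprintf("%s (comp %d, %.0f%%)", phi, i,
                                     100 * rows$variance_fraction[which.max(rows$variance)]),
                      ...)
    if (!is.null(design$epoch_boundary))
      graphics::abline(v = t_ms[design$epoch_boundary], lty = 2)
  }
  invisible(x)
}
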