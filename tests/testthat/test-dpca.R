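test_that("PCA baseline matches a brute-force Gram-matrix eigendecomposition", {
  X <- random_centered_tensor(20, 3, 2, 10, seed = 1)
  tx <- as_rate_tensor(X, small_reach(10))
  p <- population_pca(tx)
  ev <- eigen(tcrossprod(matrix(X, nrow = 20)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(p$variances, ev[seq_along(p$variances)], tolerance = 1e-8)
  expect_true(all(diff(p$cumulative_variance) >= -1e-12))
  expect_equal(p$cumulative_variance[20], 1, tolerance = 1e-12)
  # rank-1 input: one component carries everything
  X1 <- outer(rnorm(20), rnorm(60))
  X1 <- X1 - rowMeans(X1)
  tx1 <- as_rate_tensor(array(X1, dim = c(20, 3, 2, 10)), small_reach(10))
  expect_equal(population_pca(tx1)$cumulative_variance[1], 1,
               tolerance = 1e-10)
  expect_error(population_pca(tx, q = 100), "must lie")
})

test_that("single-marginalization data with lambda = 0 reduces dPCA to PCA", {
  # condition-independent-only tensor with full row rank (N < T)
  set.seed(2)
  N <- 12; T_ <- 40
  B <- matrix(rnorm(N * T_), N, T_)
  B <- B - rowMeans(B)
  X <- aperm(array(B, dim = c(N, T_, 3, 2)), c(1, 3, 4, 2))
  tx <- as_rate_tensor(X, small_reach(T_))
  fit <- dpca(tx, q = 4, lambda = 0)
  p <- population_pca(tx, q = 4)
  # the leading 4 components are all condition-independent and span the
  # same axes as PCA (signs are free)
  top <- fit$components[1:4, ]
  expect_true(all(top$marginalization == "condition_independent"))
  D_top <- fit$D_all[1:4, ]
  P_dpca <- crossprod(D_top / sqrt(rowSums(D_top^2)))
  P_pca <- tcrossprod(p$axes[, 1:4])
  expect_lt(max(abs(P_dpca - P_pca)), 1e-6)
  expect_equal(fit$cumvar_dpca[1:4], p$cumulative_variance, tolerance = 1e-6)
})

test_that("dPCA cumulative variance never exceeds PCA's", {
  # the bound holds for any data, including noisy Poisson trials
  rec <- suppressWarnings(
    simulate_population(small_reach(), 25,
                        effect_spec(seed = 3, trials = c(5, 8))))
  fit <- dpca(rec, q = 5)
  k <- length(fit$cumvar_dpca)
  expect_true(all(fit$cumvar_dpca <= fit$cumvar_pca[seq_len(k)] + 1e-9))
  # on demixable (mild-noise) data the gap stays within 2% at 15 components
  rec2 <- simulate_population(
    small_reach(), 25,
    effect_spec(seed = 3, noise = "gaussian", sigma_hz = 0.5,
                trials = c(5, 8)))
  fit2 <- dpca(rec2, q = 5)
  expect_lt(fit2$cumvar_pca[15] - fit2$cumvar_dpca[15], 0.02)
})

test_that("the rank-q ridge solution beats any q-column PCA readout per marginalization", {
  # brute force on a 10-neuron instance: compare the dPCA reconstruction
  # error of each marginalization against every choice of q axes from the
  # leading PCA basis
  X <- random_centered_tensor(10, 3, 2, 8, seed = 4)
  tx <- as_rate_tensor(X, small_reach(8))
  q <- 2L
  fit <- dpca(tx, q = q, lambda = 0)
  Xm <- matrix(X, nrow = 10)
  U <- population_pca(tx, q = 6)$axes
  marg <- marginalize(tx)
  for (phi in names(marg$parts)) {
    Xphi <- matrix(marg$parts[[phi]], nrow = 10)
    err_dpca <- sum((Xphi - fit$F[[phi]] %*% (fit$D[[phi]] %*% Xm))^2)
    errs_pca <- apply(utils::combn(6, q), 2, function(cols) {
      Uc <- U[, cols, drop = FALSE]
      sum((Xphi - Uc %*% (t(Uc) %*% Xm))^2)
    })
    expect_lte(err_dpca, min(errs_pca) + 1e-8)
  }
})

test_that("planted marginalization shares are recovered by the fit", {
  spec <- noiseless_spec(seed = 5)
  rec <- simulate_population(small_reach(), 40, spec)
  fit <- dpca(rec, q = 4)
  split <- explained_variance_split(fit, noise = "none")
  expect_equal(unname(as.numeric(split)), c(58, 24, 11, 7),
               tolerance = 1e-4)
  expect_equal(sum(split), 100, tolerance = 1e-9)
})

test_that("fits are invariant to neuron order and to silent neurons", {
  X <- random_centered_tensor(15, 3, 2, 8, seed = 6)
  d <- small_reach(8)
  fit <- dpca(as_rate_tensor(X, d), q = 3)
  perm <- sample(15)
  fit_p <- dpca(as_rate_tensor(X[perm, , , , drop = FALSE], d), q = 3)
  expect_equal(fit_p$components$variance, fit$components$variance,
               tolerance = 1e-6)
  expect_equal(fit_p$projections, fit$projections, tolerance = 1e-4)
  # a neuron that is zero after centering adds a zero decoder weight
  X0 <- array(0, dim = c(16, 3, 2, 8))
  X0[1:15, , , ] <- X
  fit_s <- dpca(as_rate_tensor(X0, d), q = 3)
  expect_equal(fit_s$components$variance, fit$components$variance,
               tolerance = 1e-6)
  expect_lt(max(abs(fit_s$D_all[, 16])), 1e-6)
})

test_that("condition projections have the documented geometry", {
  spec <- noiseless_spec(seed = 7)
  rec <- simulate_population(small_reach(), 20, spec)
  fit <- dpca(rec, q = 2)
  # reach design: S * V = 6 curves per component
  expect_equal(dim(fit$projections)[2:3], c(3L, 2L))
  # sign convention: time-averaged projection of the first condition >= 0
  for (i in seq_len(nrow(fit$components)))
    expect_gte(mean(fit$projections[i, 1, 1, ]), 0)
  # a visual component separates light vs dark but is identical across
  # parameter levels (noiseless planted structure)
  vis <- leading <- fit$components$component[
    fit$components$marginalization == "visual"][1]
  pv <- fit$projections[vis, , , ]
  expect_lt(max(abs(pv[1, 1, ] - pv[2, 1, ])),
            0.05 * max(abs(pv)))
  expect_gt(max(abs(pv[1, 1, ] - pv[1, 2, ])), 0.2 * max(abs(pv)))
  # projecting the marginalized part instead of the full tensor changes the
  # demixed projection only marginally
  tx <- build_rate_tensor(rec)
  m <- marginalize(tx)
  vis_part <- as_rate_tensor(m$parts$visual, tx$design)
  pv2 <- project_conditions(fit, vis_part)[vis, , , ]
  expect_lt(max(abs(pv2 - pv)), 0.1 * max(abs(pv)))
})

test_that("degenerate solver inputs are rejected with guidance", {
  X <- random_centered_tensor(30, 2, 2, 3, seed = 8)  # N > S*V*T
  d <- task_design("t", parameter_levels = c("a", "b"), window = c(0, 120))
  expect_error(dpca(as_rate_tensor(X, d), q = 2, lambda = 0),
               "lambda > 0|singular")
  expect_error(dpca(as_rate_tensor(X, d), q = 50), "q per marginalization")
})
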