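test_that("pairwise distances are metric and match the 3-4-5 toy", {
  ws <- small_warped()
  d <- pairwise_distances(ws)
  keep <- !is.na(d[, 1])
  dd <- d[keep, keep]
  expect_equal(dd, t(dd))
  expect_true(all(diag(dd) == 0))
  # triangle inequality on a random triple
  set.seed(1)
  idx <- sample(nrow(dd), 3)
  expect_lte(dd[idx[1], idx[2]], dd[idx[1], idx[3]] + dd[idx[3], idx[2]] + 1e-9)

  # 2-neuron toy: conditions (0,0) vs (3,4) are 5 apart
  expect_equal(sqrt(sum((c(0, 0) - c(3, 4))^2)), 5)
})

test_that("imputation is the identity without missing cells and recovers planted regressions", {
  ws <- small_warped()
  ct <- condition_tensor(ws)
  if (all(ct$mask)) {
    ct2 <- impute_missing(ct)
    expect_equal(ct2$xbar, ct$xbar)
  }
  # plant data exactly from the per-bin regression model and delete a cell
  stims <- stimulus_levels()
  n_u <- 3; nb <- 4
  x <- array(NA_real_, c(2, n_u, 8, 2, nb))
  beta <- array(runif(n_u * nb * 4), c(4, n_u, nb))
  for (si in 1:8) for (qi in 1:2) for (u in 1:n_u) for (b in 1:nb) {
    z <- c(1, stims[si], qi - 1, stims[si] * (qi - 1))
    x[, u, si, qi, b] <- sum(z * beta[, u, b])
  }
  xbar <- array(NA_real_, c(n_u, 8, 2, nb))
  for (si in 1:8) for (qi in 1:2) xbar[, si, qi, ] <- x[1, , si, qi, ]
  mask <- matrix(TRUE, 8, 2)
  mask[3, 1] <- FALSE
  truth <- xbar[, 3, 1, ]
  x[, , 3, 1, ] <- NA
  xbar[, 3, 1, ] <- NA
  ct3 <- structure(
    list(x = x, xbar = xbar, mask = mask,
         n_per_condition = matrix(2L, 8, 2), stimulus_set = stims,
         choices = c("nacl_side", "sucrose_side")),
    class = "condition_tensor"
  )
  ct3i <- impute_missing(ct3)
  expect_equal(ct3i$xbar[, 3, 1, ], truth, tolerance = 1e-8)
})

test_that("marginalizations sum exactly to the centered condition means", {
  ws <- small_warped()
  ct <- impute_missing(condition_tensor(ws))
  mg <- tastemix:::marginalize(ct$xbar)
  recon <- Reduce(`+`, mg$phis)
  expect_lt(max(abs(recon - mg$x)), 1e-10)
})

test_that("unregularized dPCA equals the reduced-rank least-squares oracle", {
  set.seed(4)
  n_u <- 5; S <- 4; Q <- 2; Tt <- 6
  xbar <- array(rnorm(n_u * S * Q * Tt), c(n_u, S, Q, Tt))
  ct <- structure(
    list(x = array(NA, c(2, n_u, S, Q, Tt)), xbar = xbar,
         mask = matrix(TRUE, S, Q), n_per_condition = matrix(2L, S, Q),
         stimulus_set = seq_len(S) * 10, choices = c("nacl_side", "sucrose_side")),
    class = "condition_tensor"
  )
  fit <- fit_dpca(ct, mu = 0, n_components = 2, noise = "none")
  mg <- tastemix:::marginalize(xbar)
  X <- mg$x
  # oracle: rank-q minimizer of ||Xphi - M X|| via SVD of the OLS fit
  P <- t(X) %*% MASS::ginv(X %*% t(X)) %*% X
  for (nm in names(mg$phis)) {
    Xphi <- mg$phis[[nm]]
    fitted_oracle <- local({
      Yhat <- Xphi %*% P
      sv <- svd(Yhat)
      u <- sv$u[, 1:2, drop = FALSE]
      u %*% t(u) %*% Yhat
    })
    fitted_ours <- fit$fits[[nm]]$F %*% fit$fits[[nm]]$D %*% X
    expect_lt(max(abs(fitted_ours - fitted_oracle)), 1e-8)
  }
})

test_that("zero choice variance gives a null choice marginalization", {
  set.seed(6)
  n_u <- 4; S <- 8; Tt <- 5
  base <- array(rnorm(n_u * S * Tt), c(n_u, S, 1, Tt))
  xbar <- array(NA_real_, c(n_u, S, 2, Tt))
  xbar[, , 1, ] <- base[, , 1, ]
  xbar[, , 2, ] <- base[, , 1, ]
  ct <- structure(
    list(x = array(NA, c(2, n_u, S, 2, Tt)), xbar = xbar,
         mask = matrix(TRUE, S, 2), n_per_condition = matrix(2L, S, 2),
         stimulus_set = stimulus_levels(), choices = c("nacl_side", "sucrose_side")),
    class = "condition_tensor"
  )
  mg <- tastemix:::marginalize(xbar)
  expect_lt(max(abs(mg$phis$choice)), 1e-12)
  fit <- fit_dpca(ct, mu = 0, noise = "none")
  proj <- dpca_project(xbar, fit$choice_axis)
  # projections along the (null) choice marginalization differ only via other marginalizations
  expect_true(all(is.finite(proj$projection)))
})

test_that("stimulus-axis projection is monotone in the mixture during sampling", {
  ws <- default_warped()
  ct <- impute_missing(condition_tensor(ws))
  fit <- fit_dpca(ct, mu = 0.1)
  proj <- dpca_project(ct$xbar, fit$stimulus_axis)
  wins <- warped_windows(ws$axis)
  samp <- proj[proj$bin %in% wins$sampling & proj$choice_index == 2, ]
  m <- tapply(samp$projection, samp$stimulus_index, mean)
  expect_gt(stats::cor(as.numeric(names(m)), as.vector(m), method = "spearman"), 0.7)
})

test_that("projection is linear and overlap is a scale-invariant cosine", {
  set.seed(8)
  a <- array(rnorm(3 * 2 * 2 * 4), c(3, 2, 2, 4))
  b <- array(rnorm(3 * 2 * 2 * 4), c(3, 2, 2, 4))
  ax <- rnorm(3)
  pa <- dpca_project(a, ax)$projection
  pb <- dpca_project(b, ax)$projection
  pab <- dpca_project(a * 2 + b * 3, ax)$projection
  expect_equal(pab, 2 * pa + 3 * pb, tolerance = 1e-12)
  # unit-vector axis picks out that neuron's activity
  e2 <- c(0, 1, 0)
  expect_equal(dpca_project(a, e2)$projection, as.vector(a[2, , , ]))

  expect_equal(axis_overlap(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_equal(axis_overlap(c(2, 0), c(0, 3)), 0)
  u <- rnorm(5)
  expect_equal(axis_overlap(u, u), 1)
  expect_equal(axis_overlap(u, -4 * u), 1)
  expect_error(axis_overlap(u, rep(0, 5)), "zero")
})

test_that("regularization search prefers shrinkage for noisy data and is seeded", {
  ws <- small_warped()
  ct <- condition_tensor(ws)
  if (any(!ct$mask)) {
    expect_message(res <- select_regularization(ct), "default")
  } else {
    r1 <- select_regularization(ct, seed = 5)
    r2 <- select_regularization(ct, seed = 5)
    expect_equal(r1$mu, r2$mu)
  }
})
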