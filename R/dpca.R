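#' Pairwise Euclidean distances between (stimulus, time) condition states
#'
#' Each correct-trial PSTH state — one stimulus at one warped-axis bin —
#' is a point in neuron space; the full pairwise distance matrix over all
#' stimulus x time points exposes the population trajectory geometry
#' (graded separation by mixture at sampling, binary separation by choice
#' before the lateral lick).
#'
#' @param ws A `warped_session` with PSTHs.
#' @return A symmetric matrix with dimnames `"<stim>@<bin>"`; rows whose
#'   PSTH cell is missing are `NA`.
#' @export
pairwise_distances <- function(ws) {
  stims <- ws$stimulus_set
  nb <- dim(ws$psth)[4]
  n_u <- dim(ws$psth)[3]
  # states: (stim x bin) rows, neurons as columns; correct trials only
  states <- matrix(NA_real_, length(stims) * nb, n_u)
  labs <- character(length(stims) * nb)
  i <- 0
  for (si in seq_along(stims)) {
    for (b in seq_len(nb)) {
      i <- i + 1
      states[i, ] <- ws$psth[si, "correct", , b]
      labs[i] <- sprintf("%g@%d", stims[si], b)
    }
  }
  d <- as.matrix(stats::dist(states))
  dimnames(d) <- list(labs, labs)
  d
}

#' Assemble the condition tensor for demixed PCA
#'
#' Organizes single-trial warped rates into an array
#' `(trial, neuron, stimulus, choice, time)` with trial-averaged means
#' `(neuron, stimulus, choice, time)` and a missing-condition mask.
#' Conditions with exactly one trial have it duplicated (so split-based
#' regularization search remains defined); conditions with no trials are
#' left missing for [impute_missing()].
#'
#' @param ws A `warped_session`.
#' @param smoothed Use smoothed single-trial rates (default `TRUE`, the
#'   same preprocessing as the PSTH figures).
#' @return A `condition_tensor` list: `x` (5-d array with NA padding),
#'   `xbar` (condition means), `mask` (stimulus x choice, TRUE = observed),
#'   `n_per_condition`, `stimulus_set`.
#' @export
condition_tensor <- function(ws, smoothed = TRUE) {
  tensor <- if (smoothed) ws$tensor_smooth else ws$tensor_raw
  tr <- ws$trials
  stims <- ws$stimulus_set
  choices <- c("nacl_side", "sucrose_side")
  n_u <- dim(tensor)[2]
  nb <- dim(tensor)[3]
  idx <- lapply(seq_along(stims), function(si) {
    lapply(seq_along(choices), function(qi) {
      which(tr$stim_pct_sucrose == stims[si] & tr$choice == choices[qi])
    })
  })
  n_per <- matrix(
    vapply(unlist(idx, recursive = FALSE), length, integer(1)),
    nrow = length(stims), byrow = TRUE,
    dimnames = list(stims, choices)
  )
  max_tr <- max(2L, max(n_per))
  x <- array(NA_real_, dim = c(max_tr, n_u, length(stims), 2, nb))
  xbar <- array(NA_real_, dim = c(n_u, length(stims), 2, nb))
  for (si in seq_along(stims)) {
    for (qi in 1:2) {
      sel <- idx[[si]][[qi]]
      if (length(sel) == 1) sel <- c(sel, sel) # duplicate single-trial conditions
      if (length(sel) >= 2) {
        x[seq_along(sel), , si, qi, ] <- tensor[sel, , , drop = FALSE]
        xbar[, si, qi, ] <- apply(tensor[sel, , , drop = FALSE], c(2, 3), mean)
      }
    }
  }
  structure(
    list(
      x = x, xbar = xbar, mask = n_per > 0, n_per_condition = n_per,
      stimulus_set = stims, choices = choices
    ),
    class = "condition_tensor"
  )
}

#' Impute missing (stimulus, choice) condition means by linear regression
#'
#' For each neuron and time bin with missing conditions, fits
#' `y(t) = b0(t) + b1(t) stim + b2(t) choice + b3(t) stim:choice` to the
#' available single trials (choice coded 0 = NaCl side, 1 = sucrose side)
#' and fills missing condition means with the model prediction. Observed
#' cells are untouched. Bins where the 4-coefficient model is unfittable
#' fall back to the neuron's mean over observed conditions.
#'
#' @param ct A [condition_tensor()].
#' @return The tensor with `xbar` completed and an `imputed` mask attached.
#' @export
impute_missing <- function(ct) {
  if (all(ct$mask)) {
    ct$imputed <- !ct$mask
    return(ct)
  }
  stims <- ct$stimulus_set
  n_u <- dim(ct$xbar)[1]
  nb <- dim(ct$xbar)[4]
  # trial-level design over observed cells
  rows <- list()
  for (si in seq_along(stims)) {
    for (qi in 1:2) {
      if (!ct$mask[si, qi]) next
      for (k in which(!is.na(ct$x[, 1, si, qi, 1]))) {
        rows[[length(rows) + 1]] <- c(k, si, qi)
      }
    }
  }
  rows <- do.call(rbind, rows)
  stim_v <- stims[rows[, 2]]
  choice_v <- rows[, 3] - 1 # 0 = nacl_side, 1 = sucrose_side
  Z <- cbind(1, stim_v, choice_v, stim_v * choice_v)
  # responses: (obs trials) x (units * bins)
  Y <- matrix(NA_real_, nrow(rows), n_u * nb)
  for (i in seq_len(nrow(rows))) {
    Y[i, ] <- as.vector(ct$x[rows[i, 1], , rows[i, 2], rows[i, 3], ])
  }
  qr_z <- qr(Z)
  fallback <- qr_z$rank < 4
  if (fallback) {
    message("imputation design rank-deficient; falling back to condition-marginal means")
    marg <- apply(ct$xbar, c(1, 4), mean, na.rm = TRUE) # unit x bin
  } else {
    beta <- qr.coef(qr_z, Y) # 4 x (units*bins)
  }
  missing_cells <- which(!ct$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(missing_cells))) {
    si <- missing_cells[r, 1]
    qi <- missing_cells[r, 2]
    if (fallback) {
      ct$xbar[, si, qi, ] <- marg
    } else {
      z0 <- c(1, stims[si], qi - 1, stims[si] * (qi - 1))
      pred <- as.vector(z0 %*% beta)
      ct$xbar[, si, qi, ] <- matrix(pred, n_u, nb)
    }
  }
  ct$imputed <- !ct$mask
  ct
}

# Flatten xbar (unit x S x Q x T) into unit x (S*Q*T) and the four joined
# marginalizations of the centered matrix: time (t), stimulus (s + st),
# choice (q + qt), interaction (sq + sqt). Their sum reconstructs the
# centered matrix exactly.
marginalize <- function(xbar) {
  dm <- dim(xbar)
  n_u <- dm[1]; S <- dm[2]; Q <- dm[3]; Tt <- dm[4]
  grand <- apply(xbar, 1, mean)
  xc <- sweep(xbar, 1, grand)
  m_t <- apply(xc, c(1, 4), mean) # unit x T
  m_st <- apply(xc, c(1, 2, 4), mean) # unit x S x T (avg over q)
  m_qt <- apply(xc, c(1, 3, 4), mean) # unit x Q x T (avg over s)
  full <- function(a) {
    # broadcast to unit x S x Q x T then flatten columns in (t fastest, then q, then s)? use consistent order
    out <- array(0, dm)
    if (length(dim(a)) == 2) { # unit x T
      for (si in 1:S) for (qi in 1:Q) out[, si, qi, ] <- a
    } else if (all(dim(a) == c(n_u, S, Tt))) {
      for (qi in 1:Q) out[, , qi, ] <- a
    } else {
      for (si in 1:S) out[, si, , ] <- a
    }
    out
  }
  x_t <- full(m_t)
  x_s <- full(m_st) - x_t
  x_q <- full(m_qt) - x_t
  x_sq <- xc - full(m_st) - full(m_qt) + x_t
  flat <- function(a) matrix(a, n_u, S * Q * Tt)
  list(
    x = flat(xc),
    phis = list(
      time = flat(x_t), stimulus = flat(x_s),
      choice = flat(x_q), interaction = flat(x_sq)
    ),
    dims = dm, grand = grand
  )
}

# Symmetric pseudo-square-root-inverse of K (for the ridge RRR solve).
sym_sqrt_inv <- function(K, tol = 1e-10) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 0)
  if (!any(pos)) stop("matrix has no positive eigenvalues")
  list(
    inv_sqrt = e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / sqrt(e$values[pos])),
    rank = sum(pos)
  )
}

#' Fit demixed PCA to a condition tensor
#'
#' Decomposes the centered trial-averaged matrix into the four joined
#' marginalizations (time; stimulus with stimulus x time; choice with
#' choice x time; stimulus x choice with the triple interaction), then for
#' each marginalization minimizes the ridge-regularized reduced-rank loss
#' `||X_phi - F D X||^2 + SQT ||F D C^{1/2}||^2 + mu ||F D||^2` over
#' encoder F and decoder D of rank `n_components`. The noise covariance
#' `C` is, by default, the average over marginalizations of
#' `X_phi X_phi^T / SQT` (set `noise = "none"` for C = 0). Principal axes
#' are the decoder rows maximizing projected variance, sign-oriented so
#' the stimulus projection correlates positively with %Sucrose and the
#' sucrose-side choice projects positive.
#'
#' @param ct An imputation-complete [condition_tensor()] (imputed on the
#'   fly if needed).
#' @param mu Ridge regularization (default 0).
#' @param n_components Rank per marginalization (default 3).
#' @param noise `"marginal"` (printed average-covariance formula) or
#'   `"none"`.
#' @return A `dpca_fit`: per-marginalization encoders/decoders, principal
#'   `stimulus_axis` and `choice_axis` (unit-norm), explained variance,
#'   and bookkeeping needed by [dpca_project()].
#' @export
fit_dpca <- function(ct, mu = 0, n_components = 3L, noise = c("marginal", "none")) {
  noise <- match.arg(noise)
  if (any(is.na(ct$xbar))) ct <- impute_missing(ct)
  mg <- marginalize(ct$xbar)
  X <- mg$x
  SQT <- ncol(X)
  n_u <- nrow(X)
  q <- min(n_components, n_u)
  C <- matrix(0, n_u, n_u)
  if (noise == "marginal") {
    for (phi in mg$phis) C <- C + phi %*% t(phi) / SQT
    C <- C / length(mg$phis)
  }
  K <- X %*% t(X) + SQT * C + mu * diag(n_u)
  ssi <- sym_sqrt_inv(K)
  fits <- purrr::imap(mg$phis, function(Xphi, name) {
    B <- (Xphi %*% t(X)) %*% ssi$inv_sqrt # = Xphi X' K^{-1/2}
    sv <- svd(B, nu = q, nv = q)
    keep <- seq_len(q)
    Fenc <- sv$u[, keep, drop = FALSE]
    # M = U_q U_q' B K^{-1/2}; D = F' M = (U_q' B) K^{-1/2}
    Ddec <- (t(Fenc) %*% B) %*% ssi$inv_sqrt
    proj <- Ddec %*% X
    var_by_row <- apply(proj, 1, stats::var)
    principal <- which.max(var_by_row)
    axis <- as.vector(Ddec[principal, ])
    list(
      F = Fenc, D = Ddec, axis = axis,
      explained = sum(diag((Fenc %*% Ddec %*% X) %*% t(X))),
      marg_var = sum(Xphi^2)
    )
  })
  dm <- mg$dims
  # sign conventions
  orient <- function(axis, target) {
    v <- as.vector(axis %*% matrix(ct$xbar, dm[1]))
    # correlate projection with target over conditions (NA when degenerate)
    s <- suppressWarnings(stats::cor(v, target))
    if (!is.na(s) && s < 0) -axis else axis
  }
  cond_grid <- expand.grid(
    s = seq_len(dm[2]), q = seq_len(dm[3]), t = seq_len(dm[4])
  ) # matches array flattening order (s fastest? no: unit is dim 1; flatten keeps s,q,t column-major order)
  stim_target <- ct$stimulus_set[cond_grid$s]
  choice_target <- cond_grid$q - 1
  stim_axis <- orient(fits$stimulus$axis, stim_target)
  choice_axis <- orient(fits$choice$axis, choice_target)
  unitize <- function(v) v / sqrt(sum(v^2))
  structure(
    list(
      fits = fits,
      stimulus_axis = unitize(stim_axis),
      choice_axis = unitize(choice_axis),
      mu = mu,
      n_components = q,
      noise = noise,
      dims = dm,
      stimulus_set = ct$stimulus_set,
      grand_mean = mg$grand
    ),
    class = "dpca_fit"
  )
}

#' Split-half search for the dPCA regularization strength
#'
#' Splits trials of every (stimulus, choice) condition in half, fits dPCA
#' on one half's condition means over a grid of `mu`, and scores
#' reconstruction error of the held-out half's means; returns the grid
#' minimizer. Deterministic given `seed`.
#'
#' @param ct A [condition_tensor()] whose conditions all have >= 2 trials
#'   (single-trial conditions are duplicated on assembly; empty conditions
#'   make the search fall back to `default_mu` with a message).
#' @param mu_grid Candidate values.
#' @param n_components Rank per marginalization.
#' @param seed Split seed.
#' @param default_mu Fallback when the split is undefined.
#' @return A list `mu`, `errors` (tibble over the grid).
#' @export
select_regularization <- function(ct, mu_grid = c(0, 1e-4, 1e-3, 1e-2, 0.1, 1, 10) * 1,
                                  n_components = 3L, seed = 1L, default_mu = 1e-3) {
  if (any(!ct$mask)) {
    message("conditions with no trials present; using default mu = ", default_mu)
    return(list(mu = default_mu, errors = NULL))
  }
  withr::local_seed(seed)
  dm <- dim(ct$xbar)
  half_bar <- function(which_half, assign) {
    out <- array(NA_real_, dm)
    for (si in seq_len(dm[2])) {
      for (qi in seq_len(dm[3])) {
        ks <- which(!is.na(ct$x[, 1, si, qi, 1]))
        sel <- ks[assign[[paste(si, qi)]] == which_half]
        if (length(sel) == 0) sel <- ks[1]
        out[, si, qi, ] <- apply(ct$x[sel, , si, qi, , drop = FALSE], c(2, 5), mean)
      }
    }
    out
  }
  assign <- list()
  for (si in seq_len(dm[2])) {
    for (qi in seq_len(dm[3])) {
      ks <- which(!is.na(ct$x[, 1, si, qi, 1]))
      assign[[paste(si, qi)]] <- sample(rep(1:2, length.out = length(ks)))
    }
  }
  train_bar <- half_bar(1, assign)
  test_bar <- half_bar(2, assign)
  ct_train <- ct
  ct_train$xbar <- train_bar
  mg_test <- marginalize(test_bar)
  errors <- vapply(mu_grid, function(mu) {
    fit <- fit_dpca(ct_train, mu = mu, n_components = n_components)
    mg_train <- marginalize(train_bar)
    recon <- Reduce(`+`, purrr::map(names(fit$fits), function(nm) {
      fit$fits[[nm]]$F %*% fit$fits[[nm]]$D %*% mg_train$x
    }))
    sum((mg_test$x - recon)^2)
  }, numeric(1))
  list(
    mu = mu_grid[which.min(errors)],
    errors = tibble::tibble(mu = mu_grid, error = errors)
  )
}

#' Project condition-mean activity onto a demixed axis
#'
#' @param xbar Condition-mean array `(unit, stimulus, choice, time)` (e.g.,
#'   from a [condition_tensor()], possibly of a different session than the
#'   fit, sharing the unit dimension).
#' @param axis Numeric unit-space vector (e.g., `fit$stimulus_axis`).
#' @return A tibble `stimulus, choice, bin, projection` (NA conditions
#'   dropped).
#' @export
dpca_project <- function(xbar, axis) {
  dm <- dim(xbar)
  if (length(axis) != dm[1]) stop("axis and activity disagree on the unit dimension")
  flat <- matrix(xbar, dm[1])
  v <- as.vector(axis %*% flat)
  grid <- expand.grid(
    s = seq_len(dm[2]), q = seq_len(dm[3]), t = seq_len(dm[4])
  )
  out <- tibble::tibble(
    stimulus_index = grid$s,
    choice_index = grid$q,
    bin = grid$t,
    projection = v
  )
  out[!is.na(out$projection), ]
}

#' Absolute cosine similarity between two axes
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return `|u . v| / (||u|| ||v||)`, in \[0, 1\].
#' @export
axis_overlap <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("overlap undefined for a zero vector")
  abs(sum(u * v)) / (nu * nv)
}
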