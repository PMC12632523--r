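#' Dynamics and integration configuration for the constrained rate network
#'
#' The network integrates `tau dh/dt = -h + m(x) + Wrec f(h + b) + eta`
#' with forward Euler at `alpha = dt / tau = 0.2`, where
#' `f(z) = min(max(z, 0), 80)` is the capped-rectified transfer whose
#' output is read as a firing rate (Hz), `m(x) = A2 tanh(A1 x)` embeds the
#' 2-dimensional mixture stimulus, and `eta` is per-step internal Gaussian
#' noise of SD `0.05 / alpha` (entering the update multiplied by `alpha`,
#' i.e., an effective per-step SD of 0.05). A decision unit
#' `tau dz/dt = -z + wz' f(h + b)` is integrated in parallel;
#' `c = tanh(z)` is the choice activity. Trials last 5.9 s; the stimulus
#' is on from 1 s after trial start for 1.2 s; the decision window covers
#' the 0.1 s up to the decision time 3.9 s after stimulus onset.
#'
#' @param alpha Euler step `dt / tau`.
#' @param dt Step size (s); `tau` is implied.
#' @param rate_cap Transfer saturation (Hz).
#' @param sigma_eta Internal-noise SD (`0.05 / alpha`).
#' @param trial_length,stim_onset,stim_duration,decision_time Seconds on
#'   the model clock.
#' @param embed_width Hidden width of the stimulus embedding.
#' @return An `rnn_config` list (including derived `n_steps` and the
#'   step index sets for the stimulus, pre-stimulus and decision windows).
#' @export
rnn_config <- function(alpha = 0.2, dt = 0.05, rate_cap = 80,
                       sigma_eta = 0.05 / alpha,
                       trial_length = 5.9, stim_onset = 1.0,
                       stim_duration = 1.2, decision_time = 4.9,
                       embed_width = 100L) {
  stopifnot(alpha > 0, rate_cap > 0, decision_time <= trial_length)
  n_steps <- round(trial_length / dt)
  times <- (1:n_steps) * dt
  structure(
    list(
      alpha = alpha, dt = dt, tau = dt / alpha, rate_cap = rate_cap,
      sigma_eta = sigma_eta, trial_length = trial_length,
      stim_onset = stim_onset, stim_duration = stim_duration,
      decision_time = decision_time, embed_width = as.integer(embed_width),
      n_steps = n_steps, times = times,
      stim_steps = which(times - dt >= stim_onset - 1e-9 &
                           times - dt < stim_onset + stim_duration - 1e-9),
      win0_steps = which(times <= stim_onset + 1e-9),
      winD_steps = which(times >= decision_time - 0.1 - 1e-9 &
                           times <= decision_time + 1e-9),
      target_steps = 1:117
    ),
    class = "rnn_config"
  )
}

#' Capped-rectified transfer function
#'
#' `f(z) = min(max(z, 0), cap)`: rectified-linear with saturation at the
#' rate cap (80 Hz by default), applied elementwise; the output is
#' interpreted as a firing rate.
#'
#' @param z Numeric vector/matrix.
#' @param cap Saturation value (Hz).
#' @return Clipped values, same shape.
#' @export
rnn_transfer <- function(z, cap = 80) {
  pmin(pmax(z, 0), cap)
}

#' Embed a mixture stimulus into unit space
#'
#' `m(x) = A2 tanh(A1 x)` where `x = c(%Sucrose, %NaCl) / 100` (e.g., the
#' 25/75 mixture is `c(0.25, 0.75)`); the off-stimulus input is the zero
#' vector, which maps to zero.
#'
#' @param x A 2-vector, or a 2 x K matrix of stimuli in columns.
#' @param A1 `embed_width x 2` matrix.
#' @param A2 `N x embed_width` matrix.
#' @return An N-vector (or N x K matrix) of input currents.
#' @export
stimulus_embed <- function(x, A1, A2) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(A1)) stop("stimulus dimension mismatch")
  out <- A2 %*% tanh(A1 %*% x)
  if (ncol(out) == 1) as.vector(out) else out
}

# %Sucrose values -> 2 x K stimulus matrix.
stim_matrix <- function(s) {
  rbind(s / 100, 1 - s / 100)
}

#' Initialize network parameters
#'
#' `Nu = round(5.88 Nc)` unconstrained units accompany the `Nc`
#' constrained ones (N = Nc + Nu). Embedding matrices start N(0, 1),
#' recurrent weights N(0, 0.1/N) with the diagonal (self-connections)
#' fixed at zero, readout weights N(0, 1/N), bias and initial activity at
#' zero. `h0` is a single trainable vector shared across stimuli.
#'
#' @param n_constrained `Nc`, the number of PSTH-constrained units.
#' @param config An [rnn_config()].
#' @param seed Integer seed for the initialization draws.
#' @return An `rnn_params` list: `A1`, `A2`, `Wrec`, `b`, `wz`, `h0`,
#'   `Nc`, `Nu`, `N`.
#' @export
rnn_init <- function(n_constrained, config = rnn_config(), seed = 1L) {
  withr::local_seed(seed)
  Nc <- as.integer(n_constrained)
  Nu <- as.integer(round(5.88 * Nc))
  N <- Nc + Nu
  H <- config$embed_width
  Wrec <- matrix(stats::rnorm(N * N, 0, sqrt(0.1 / N)), N, N)
  diag(Wrec) <- 0
  structure(
    list(
      A1 = matrix(stats::rnorm(H * 2), H, 2),
      A2 = matrix(stats::rnorm(N * H), N, H),
      Wrec = Wrec,
      b = numeric(N),
      wz = stats::rnorm(N, 0, sqrt(1 / N)),
      h0 = numeric(N),
      Nc = Nc, Nu = Nu, N = N
    ),
    class = "rnn_params"
  )
}

#' One Euler step of the network dynamics
#'
#' `h <- h + alpha (-h + m + Wrec f(h + b) + eta)` and
#' `z <- z + alpha (-z + wz' f(h + b))`, with rates `r = f(h + b)` taken
#' from the pre-update state driving both recurrence and the decision
#' unit.
#'
#' @param state List with `h` (N x K matrix) and `z` (length-K vector).
#' @param m Input current (N x K matrix or N-vector; 0 when the stimulus
#'   is off).
#' @param params An `rnn_params`.
#' @param config An `rnn_config`.
#' @param eta Internal noise (N x K matrix, or 0).
#' @param clamp Optional integer vector of 1-based unit indices whose
#'   rates are clamped to zero (virtual ablation).
#' @return Updated state list with `h`, `z`, `r` (rates after the step)
#'   and `c = tanh(z)`.
#' @export
euler_step <- function(state, m, params, config, eta = 0, clamp = integer(0)) {
  a <- config$alpha
  phi <- rnn_transfer(state$h + params$b, config$rate_cap)
  if (length(clamp) > 0) phi[clamp, ] <- 0
  h <- (1 - a) * state$h + a * (m + params$Wrec %*% phi + eta)
  z <- (1 - a) * state$z + a * as.vector(crossprod(phi, params$wz))
  if (!all(is.finite(h))) stop("non-finite network state (training divergence)")
  r <- rnn_transfer(h + params$b, config$rate_cap)
  if (length(clamp) > 0) r[clamp, ] <- 0
  list(h = h, z = z, r = r, c = tanh(z))
}

# Batched noiseless-stimulus forward pass used in training: K = number of
# stimuli, internal noise eta supplied as an array (N x K x n_steps) or NULL.
# Returns full state trajectories needed for BPTT.
rnn_forward_train <- function(params, config, stim_s, eta = NULL) {
  N <- params$N
  K <- length(stim_s)
  n <- config$n_steps
  X <- stim_matrix(stim_s)
  M_on <- stimulus_embed(X, params$A1, params$A2)
  H <- array(0, c(N, K, n + 1))
  Z <- matrix(0, K, n + 1)
  H[, , 1] <- params$h0
  h <- matrix(params$h0, N, K)
  z <- numeric(K)
  a <- config$alpha
  on <- logical(n)
  on[config$stim_steps] <- TRUE
  for (i in seq_len(n)) {
    phi <- rnn_transfer(h + params$b, config$rate_cap)
    e <- if (is.null(eta)) 0 else eta[, , i]
    drive <- params$Wrec %*% phi + e
    if (on[i]) drive <- drive + M_on
    h <- (1 - a) * h + a * drive
    z <- (1 - a) * z + a * as.vector(crossprod(phi, params$wz))
    H[, , i + 1] <- h
    Z[, i + 1] <- z
  }
  if (!all(is.finite(H))) stop("non-finite network state (training divergence)")
  list(H = H, Z = Z, X = X, M_on = M_on, on = on)
}

#' Training loss of the constrained network
#'
#' `L = lambda_beh L_beh + lambda_neu L_neu` where the behavioral term
#' penalizes choice activity `c` away from 0 in the pre-stimulus window
#' and away from the stimulus's correct sign `gamma` (+1 for
#' predominantly-sucrose mixtures) in the decision window, and the neural
#' term is the mean squared error between the constrained units' rates
#' over steps 1..117 and the session's correct-trial PSTH targets. Both
#' terms are normalized by their total number of summands.
#'
#' @param fwd A forward pass from `rnn_forward_train()`.
#' @param params An `rnn_params`.
#' @param config An `rnn_config`.
#' @param targets Array `(stimulus, constrained unit, 117 bins)` of target
#'   PSTHs (Hz).
#' @param gamma Length-K vector of target decision signs.
#' @param lambda_beh,lambda_neu Loss weights (defaults 150 and 1).
#' @return List `L`, `L_beh`, `L_neu`.
#' @export
rnn_loss <- function(fwd, params, config, targets, gamma,
                     lambda_beh = 150, lambda_neu = 1) {
  Nc <- params$Nc
  K <- ncol(fwd$X)
  ts <- config$target_steps
  C <- tanh(fwd$Z)
  beta_beh <- K * (length(config$win0_steps) + length(config$winD_steps))
  l_beh <- (sum(C[, config$win0_steps + 1]^2) +
              sum((C[, config$winD_steps + 1] - gamma)^2)) / beta_beh
  beta_neu <- K * length(ts) * Nc
  R <- rnn_transfer(fwd$H[seq_len(Nc), , ts + 1, drop = FALSE] +
                      params$b[seq_len(Nc)], config$rate_cap)
  rho <- aperm(targets, c(2, 1, 3)) # (unit, stim, bin)
  l_neu <- sum((R - rho)^2) / beta_neu
  list(
    L = lambda_beh * l_beh + lambda_neu * l_neu,
    L_beh = l_beh, L_neu = l_neu
  )
}

# Analytic gradients of the training loss by backpropagation through time.
# Returns the loss and gradients for every trainable parameter.
rnn_loss_and_grad <- function(params, config, stim_s, targets, gamma, eta = NULL,
                              lambda_beh = 150, lambda_neu = 1) {
  fwd <- rnn_forward_train(params, config, stim_s, eta)
  N <- params$N
  Nc <- params$Nc
  K <- length(stim_s)
  n <- config$n_steps
  a <- config$alpha
  cap <- config$rate_cap
  loss <- rnn_loss(fwd, params, config, targets, gamma, lambda_beh, lambda_neu)

  ts <- config$target_steps
  beta_beh <- K * (length(config$win0_steps) + length(config$winD_steps))
  beta_neu <- K * length(ts) * Nc
  rho <- aperm(targets, c(2, 1, 3))

  # direct loss gradients at each step
  gH <- array(0, c(N, K, n + 1)) # dL/dh_i (state index i+1)
  gZ <- matrix(0, K, n + 1)
  gb <- numeric(N)
  in_target <- logical(n)
  in_target[ts] <- TRUE
  for (i in ts) {
    pre <- matrix(fwd$H[seq_len(Nc), , i + 1], Nc, K) + params$b[seq_len(Nc)]
    r <- pmin(pmax(pre, 0), cap)
    dr <- (lambda_neu * 2 / beta_neu) * (r - matrix(rho[, , match(i, ts)], Nc, K))
    d <- dr * (pre > 0 & pre < cap)
    gH[seq_len(Nc), , i + 1] <- d
    gb[seq_len(Nc)] <- gb[seq_len(Nc)] + rowSums(d)
  }
  cmat <- tanh(fwd$Z)
  for (i in config$win0_steps) {
    dc <- (lambda_beh * 2 / beta_beh) * cmat[, i + 1]
    gZ[, i + 1] <- gZ[, i + 1] + dc * (1 - cmat[, i + 1]^2)
  }
  for (i in config$winD_steps) {
    dc <- (lambda_beh * 2 / beta_beh) * (cmat[, i + 1] - gamma)
    gZ[, i + 1] <- gZ[, i + 1] + dc * (1 - cmat[, i + 1]^2)
  }

  gW <- matrix(0, N, N)
  gwz <- numeric(N)
  gM <- matrix(0, N, K)
  Wt <- t(params$Wrec)
  for (i in n:1) {
    ah <- gH[, , i + 1]
    az <- gZ[, i + 1]
    pre_prev <- fwd$H[, , i] + params$b
    phi_prev <- pmin(pmax(pre_prev, 0), cap)
    mask_prev <- (pre_prev > 0 & pre_prev < cap)
    G <- mask_prev * (a * (Wt %*% ah) + a * outer(params$wz, az))
    gH[, , i] <- gH[, , i] + (1 - a) * ah + G
    gZ[, i] <- gZ[, i] + (1 - a) * az
    gW <- gW + a * ah %*% t(phi_prev)
    gwz <- gwz + a * as.vector(phi_prev %*% az)
    gb <- gb + rowSums(G)
    if (fwd$on[i]) gM <- gM + a * ah
  }
  diag(gW) <- 0
  P <- params$A1 %*% fwd$X
  Th <- tanh(P)
  gA2 <- gM %*% t(Th)
  gP <- (t(params$A2) %*% gM) * (1 - Th^2)
  gA1 <- gP %*% t(fwd$X)
  gh0 <- rowSums(gH[, , 1])

  list(
    loss = loss,
    grads = list(A1 = gA1, A2 = gA2, Wrec = gW, b = gb, wz = gwz, h0 = gh0),
    fwd = fwd
  )
}

#' Correct-trial PSTH targets for network training
#'
#' Extracts the smoothed correct-trial PSTHs of the first `Nc` units from
#' a `warped_session`, mapped bin-for-bin onto model steps 1..117
#' (stimulus onset at 1 s = step 20, decision at 4.9 s = step 98,
#' assuming the session's mean inter-event interval).
#'
#' @param ws A `warped_session`.
#' @param n_constrained Number of units to constrain (first `Nc` units).
#' @return Array `(stimulus, unit, bin)`; errors if any correct-trial
#'   PSTH cell is missing.
#' @export
psth_targets <- function(ws, n_constrained) {
  Nc <- n_constrained
  tg <- ws$psth[, "correct", seq_len(Nc), , drop = FALSE]
  tg <- array(tg, dim = dim(tg)[c(1, 3, 4)])
  if (any(is.na(tg))) {
    stop("missing correct-trial PSTH for some (stimulus, unit); cannot build targets")
  }
  tg
}

#' Train the data-constrained network on a session
#'
#' Minimizes the joint behavioral + neural loss by
#' backpropagation-through-time with Adam (learning rate 0.01, global
#' gradient-norm clipping at 1.0), presenting each of the 8 mixtures once
#' per iteration with noiseless stimulus input and active internal noise.
#' Training stops after `max_iters` iterations (2000 by default) or when
#' the loss drops below `loss_stop` (1 by default). The recurrent
#' diagonal stays zero throughout.
#'
#' @param ws A `warped_session` providing correct-trial PSTH targets.
#' @param n_constrained `Nc`; defaults to all units in the session.
#' @param config An [rnn_config()].
#' @param seed Seed for initialization and training noise.
#' @param max_iters,loss_stop Stopping rule.
#' @param lr,grad_clip Adam learning rate and gradient-norm clip.
#' @param lambda_beh,lambda_neu Loss weights.
#' @param internal_noise Keep internal noise active during training
#'   iterations (default `TRUE`).
#' @param verbose Print loss every 100 iterations.
#' @return An `rnn_fit` list: trained `params`, `config`, `loss_history`
#'   tibble, `targets`, `stimulus_set`, `gamma`, `n_iters`.
#' @export
rnn_train <- function(ws, n_constrained = dim(ws$tensor_raw)[2],
                      config = rnn_config(), seed = 1L,
                      max_iters = 2000L, loss_stop = 1,
                      lr = 0.01, grad_clip = 1.0,
                      lambda_beh = 150, lambda_neu = 1,
                      internal_noise = TRUE, verbose = FALSE) {
  withr::local_seed(seed)
  stim_s <- ws$stimulus_set
  K <- length(stim_s)
  gamma <- ifelse(stim_s > 50, 1, -1)
  targets <- psth_targets(ws, n_constrained)
  params <- rnn_init(n_constrained, config, seed = sample.int(2^31 - 1, 1))
  N <- params$N
  mom <- lapply(params[c("A1", "A2", "Wrec", "b", "wz", "h0")], function(p) p * 0)
  vel <- mom
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  history <- numeric(max_iters)
  n_it <- max_iters
  for (it in seq_len(max_iters)) {
    eta <- if (internal_noise) {
      array(stats::rnorm(N * K * config$n_steps, 0, config$sigma_eta),
            c(N, K, config$n_steps))
    } else {
      NULL
    }
    lg <- rnn_loss_and_grad(params, config, stim_s, targets, gamma, eta,
                            lambda_beh, lambda_neu)
    history[it] <- lg$loss$L
    g <- lg$grads
    gnorm <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
    if (gnorm > grad_clip) g <- lapply(g, function(x) x * grad_clip / gnorm)
    for (nm in names(g)) {
      mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
      vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1^it)
      vhat <- vel[[nm]] / (1 - b2^it)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    diag(params$Wrec) <- 0
    if (verbose && it %% 100 == 0) {
      message(sprintf("iter %d: L = %.4f", it, history[it]))
    }
    if (history[it] < loss_stop) {
      n_it <- it
      break
    }
  }
  structure(
    list(
      params = params, config = config,
      loss_history = tibble::tibble(iter = seq_len(n_it), loss = history[seq_len(n_it)]),
      targets = targets, stimulus_set = stim_s, gamma = gamma,
      n_iters = n_it,
      lambda_beh = lambda_beh, lambda_neu = lambda_neu
    ),
    class = "rnn_fit"
  )
}

#' @export
print.rnn_fit <- function(x, ...) {
  cat(sprintf(
    "<rnn_fit: Nc=%d Nu=%d, %d iterations, final loss %.4f>\n",
    x$params$Nc, x$params$Nu, x$n_iters,
    x$loss_history$loss[nrow(x$loss_history)]
  ))
  invisible(x)
}

#' Simulate trials from a trained network
#'
#' Runs batches of single trials with persistent input noise: at every
#' step the stimulus vector (zero when off) is perturbed as `x + eps`
#' with `eps ~ N(0, sigma)` per element, passed through the embedding,
#' while internal noise stays active. The choice is the sign of the mean
#' choice activity `c` over the decision window (positive = sucrose side;
#' an exact 0 falls to the NaCl side).
#'
#' @param params An `rnn_params`.
#' @param config An `rnn_config`.
#' @param stim_s %Sucrose per trial (length K = number of trials).
#' @param input_sigma Input-noise SD `sigma`.
#' @param seed Integer seed (internal + input noise).
#' @param clamp 1-based unit indices whose rates are clamped to zero.
#' @return List: `rates` array `(trial, unit, step)` over steps 1..117,
#'   `c` matrix `(trial, step)`, `choice` character vector, `stim_s`.
#' @export
simulate_trials <- function(params, config, stim_s, input_sigma = 0,
                            seed = 1L, clamp = integer(0)) {
  withr::local_seed(seed)
  N <- params$N
  K <- length(stim_s)
  n <- config$n_steps
  a <- config$alpha
  X_on <- stim_matrix(stim_s)
  on <- logical(n)
  on[config$stim_steps] <- TRUE
  h <- matrix(params$h0, N, K)
  z <- numeric(K)
  ts <- config$target_steps
  rates <- array(NA_real_, c(K, N, length(ts)))
  cmat <- matrix(NA_real_, K, n)
  for (i in seq_len(n)) {
    phi <- rnn_transfer(h + params$b, config$rate_cap)
    if (length(clamp) > 0) phi[clamp, ] <- 0
    x <- if (on[i]) X_on else matrix(0, 2, K)
    if (input_sigma > 0) {
      x <- x + matrix(stats::rnorm(2 * K, 0, input_sigma), 2, K)
    }
    m <- stimulus_embed(x, params$A1, params$A2)
    eta <- matrix(stats::rnorm(N * K, 0, config$sigma_eta), N, K)
    h <- (1 - a) * h + a * (m + params$Wrec %*% phi + eta)
    z <- (1 - a) * z + a * as.vector(crossprod(phi, params$wz))
    cmat[, i] <- tanh(z)
    if (i %in% ts) {
      r <- rnn_transfer(h + params$b, config$rate_cap)
      if (length(clamp) > 0) r[clamp, ] <- 0
      rates[, , match(i, ts)] <- t(r)
    }
  }
  cbar <- rowMeans(cmat[, config$winD_steps, drop = FALSE])
  choice <- ifelse(cbar > 0, "sucrose_side", "nacl_side")
  list(rates = rates, c = cmat, choice = choice, stim_s = stim_s)
}

#' Write / read a trained network as JSON
#'
#' Plain-text checkpoint of all parameter matrices, the dynamics
#' configuration and the loss history.
#'
#' @param fit An `rnn_fit`.
#' @param path Output file.
#' @return `path`, invisibly (`read_rnn` returns the `rnn_fit`).
#' @export
write_rnn <- function(fit, path) {
  payload <- list(
    params = lapply(fit$params[c("A1", "A2", "Wrec", "b", "wz", "h0")], unclass),
    Nc = fit$params$Nc, Nu = fit$params$Nu, N = fit$params$N,
    config = unclass(fit$config),
    loss_history = fit$loss_history,
    stimulus_set = fit$stimulus_set,
    gamma = fit$gamma,
    n_iters = fit$n_iters
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rnn
#' @export
read_rnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- structure(
    list(
      A1 = as.matrix(p$params$A1), A2 = as.matrix(p$params$A2),
      Wrec = as.matrix(p$params$Wrec), b = as.numeric(p$params$b),
      wz = as.numeric(p$params$wz), h0 = as.numeric(p$params$h0),
      Nc = as.integer(p$Nc), Nu = as.integer(p$Nu), N = as.integer(p$N)
    ),
    class = "rnn_params"
  )
  cfg <- do.call(rnn_config, p$config[c(
    "alpha", "dt", "rate_cap", "sigma_eta", "trial_length",
    "stim_onset", "stim_duration", "decision_time", "embed_width"
  )])
  structure(
    list(
      params = params, config = cfg,
      loss_history = tibble::as_tibble(p$loss_history),
      targets = NULL, stimulus_set = p$stimulus_set,
      gamma = p$gamma, n_iters = p$n_iters
    ),
    class = "rnn_fit"
  )
}
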