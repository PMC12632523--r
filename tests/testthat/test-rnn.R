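test_that("transfer function rectifies and saturates at the rate cap", {
  expect_equal(rnn_transfer(-5), 0)
  expect_equal(rnn_transfer(100), 80)
  expect_equal(rnn_transfer(37.2), 37.2)
  expect_equal(rnn_transfer(c(-1, 0, 80, 81)), c(0, 0, 80, 80))
})

test_that("stimulus embedding follows m(x) = A2 tanh(A1 x)", {
  A1 <- matrix(c(1, -1, 0.5, 2), 2, 2)
  A2 <- matrix(c(1, 0, 2, -1, 3, 0.5), 3, 2)
  x <- c(0.25, 0.75)
  expect_equal(stimulus_embed(x, A1, A2), as.vector(A2 %*% tanh(A1 %*% x)))
  expect_equal(stimulus_embed(c(0, 0), A1, A2), rep(0, 3))
  # mixture encoding: 100/0 is [1, 0]
  expect_equal(tastemix:::stim_matrix(100), matrix(c(1, 0), 2, 1))
  expect_equal(tastemix:::stim_matrix(25), matrix(c(0.25, 0.75), 2, 1))
  expect_error(stimulus_embed(c(1, 2, 3), A1, A2), "mismatch")
})

test_that("unit-count bookkeeping follows Nu = round(5.88 Nc)", {
  p <- rnn_init(27, rnn_config(embed_width = 4), seed = 1)
  expect_equal(p$Nu, 159)
  expect_equal(p$N, 186)
  expect_true(all(diag(p$Wrec) == 0))
})

test_that("euler_step matches a hand-computed 2-unit update", {
  cfg <- rnn_config(embed_width = 2)
  params <- list(
    A1 = diag(2), A2 = diag(2),
    Wrec = matrix(c(0, 0.5, -0.3, 0), 2, 2), b = c(0.1, -0.2),
    wz = c(1, 2), h0 = c(0, 0), Nc = 1L, Nu = 1L, N = 2L
  )
  st <- list(h = matrix(c(1, 2), 2, 1), z = 0.5)
  m <- c(0.3, 0.4)
  new <- euler_step(st, m, params, cfg, eta = 0)
  phi <- pmin(pmax(c(1, 2) + params$b, 0), 80)
  h_exp <- 0.8 * c(1, 2) + 0.2 * (m + params$Wrec %*% phi)
  z_exp <- 0.8 * 0.5 + 0.2 * sum(params$wz * phi)
  expect_equal(as.vector(new$h), as.vector(h_exp))
  expect_equal(new$z, z_exp)
  expect_equal(new$c, tanh(z_exp))
  # zero everything stays zero
  st0 <- list(h = matrix(0, 2, 1), z = 0)
  params0 <- params
  params0$Wrec <- matrix(0, 2, 2); params0$b <- c(0, 0); params0$wz <- c(0, 0)
  new0 <- euler_step(st0, c(0, 0), params0, cfg, eta = 0)
  expect_equal(as.vector(new0$h), c(0, 0))
  expect_equal(new0$z, 0)
})

test_that("with no recurrence the state converges geometrically to m(x)", {
  cfg <- rnn_config(embed_width = 2)
  N <- 3
  params <- list(
    A1 = matrix(0, 2, 2), A2 = matrix(0, N, 2),
    Wrec = matrix(0, N, N), b = rep(0, N), wz = rep(0, N),
    h0 = rep(0, N), Nc = 1L, Nu = 2L, N = N
  )
  m <- c(5, -2, 1)
  h <- matrix(0, N, 1)
  st <- list(h = h, z = 0)
  for (i in 1:10) st <- euler_step(st, m, params, cfg, eta = 0)
  # closed form: h_k = m (1 - (1 - alpha)^k)
  expect_equal(as.vector(st$h), m * (1 - 0.8^10), tolerance = 1e-12)
  for (i in 1:200) st <- euler_step(st, m, params, cfg, eta = 0)
  expect_equal(as.vector(st$h), m, tolerance = 1e-9)
})

test_that("analytic BPTT gradients match central finite differences", {
  set.seed(7)
  cfg <- rnn_config(embed_width = 4, trial_length = 0.6, stim_onset = 0.1,
                    stim_duration = 0.2, decision_time = 0.5)
  cfg$target_steps <- 1:cfg$n_steps
  params <- rnn_init(1, cfg, seed = 3) # 3 constrained-free units -> N = 7
  # move pre-activations off the rectifier kink (subgradient choice there)
  params$b <- rnorm(params$N, 0.3, 0.5)
  params$h0 <- rnorm(params$N, 0, 0.5)
  stim_s <- c(0, 45, 100)
  gamma <- ifelse(stim_s > 50, 1, -1)
  targets <- array(runif(3 * 1 * cfg$n_steps, 0, 10), c(3, 1, cfg$n_steps))
  eta <- array(rnorm(params$N * 3 * cfg$n_steps, 0, cfg$sigma_eta),
               c(params$N, 3, cfg$n_steps))
  lg <- tastemix:::rnn_loss_and_grad(params, cfg, stim_s, targets, gamma, eta)
  loss_of <- function(p) {
    rnn_loss(tastemix:::rnn_forward_train(p, cfg, stim_s, eta), p, cfg, targets, gamma)$L
  }
  h <- 1e-6
  for (nm in c("A1", "A2", "Wrec", "b", "wz", "h0")) {
    g <- lg$grads[[nm]]
    idx <- sample(length(g), min(5, length(g)))
    if (nm == "Wrec") { # diagonal is a constraint, its gradient is masked
      off <- which(row(params$Wrec) != col(params$Wrec))
      idx <- sample(off, 5)
    }
    for (i in idx) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
      num <- (loss_of(p1) - loss_of(p2)) / (2 * h)
      ana <- g[i]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-8), 1e-4)
    }
  }
})

test_that("loss terms vanish on exactly-matching rates and choices", {
  cfg <- rnn_config(embed_width = 2)
  params <- rnn_init(2, cfg, seed = 5)
  stim_s <- stimulus_levels()
  gamma <- ifelse(stim_s > 50, 1, -1)
  fwd <- tastemix:::rnn_forward_train(params, cfg, stim_s)
  # targets equal to the model's own rates -> L_neu = 0
  R <- array(NA_real_, c(8, params$Nc, 117))
  for (i in 1:117) {
    R[, , i] <- t(pmin(pmax(
      matrix(fwd$H[1:params$Nc, , i + 1], params$Nc) + params$b[1:params$Nc],
      0), 80))
  }
  l <- rnn_loss(fwd, params, cfg, R, gamma)
  expect_equal(l$L_neu, 0, tolerance = 1e-20)
  # c identically matching the targets -> L_beh = 0
  fwd0 <- fwd
  fwd0$Z <- matrix(0, 8, cfg$n_steps + 1)
  fwd0$Z[, cfg$winD_steps + 1] <- atanh(gamma * (1 - 1e-15))
  l0 <- rnn_loss(fwd0, params, cfg, R, gamma)
  expect_lt(l0$L_beh, 1e-10)
})

test_that("training reduces the loss and keeps invariants", {
  ws <- small_warped()
  fit <- fixture("small_rnn", function() {
    rnn_train(small_warped(), n_constrained = 3, seed = 8, max_iters = 250)
  })
  h <- fit$loss_history$loss
  sm <- stats::filter(h, rep(1 / 50, 50), sides = 1)
  sm <- sm[!is.na(sm)]
  # smoothed loss trend is decreasing overall
  expect_lt(sm[length(sm)], sm[1] * 0.9)
  expect_true(all(diag(fit$params$Wrec) == 0))
  sim <- simulate_trials(fit$params, fit$config, c(0, 100), 0.2, seed = 2)
  expect_true(all(sim$rates >= 0 & sim$rates <= 80))
  expect_true(all(abs(tanh(sim$c)) < 1))
})

test_that("simulation is deterministic given the seed and wz = 0 kills the choice", {
  t <- toy_rnn()
  s1 <- simulate_trials(t$fit$params, t$fit$config, c(0, 50, 100), 0.3, seed = 4)
  s2 <- simulate_trials(t$fit$params, t$fit$config, c(0, 50, 100), 0.3, seed = 4)
  expect_identical(s1$rates, s2$rates)
  expect_identical(s1$choice, s2$choice)
  p0 <- t$fit$params
  p0$wz <- rep(0, p0$N)
  s0 <- simulate_trials(p0, t$fit$config, rep(50, 6), 0.3, seed = 4)
  expect_true(all(s0$c == 0))
  expect_equal(unique(s0$choice), "nacl_side") # c = 0 falls to the NaCl side
})

test_that("a trained toy model chooses correctly for all mixtures without noise", {
  t <- toy_rnn()
  sim <- simulate_trials(t$fit$params, t$fit$config, stimulus_levels(), 0, seed = 1)
  correct <- (sim$stim_s > 50) == (sim$choice == "sucrose_side")
  expect_gte(mean(correct[abs(sim$stim_s - 50) >= 15]), 5 / 6)
})

test_that("model checkpoints round-trip through JSON", {
  t <- toy_rnn()
  path <- withr::local_tempfile(fileext = ".json")
  write_rnn(t$fit, path)
  back <- read_rnn(path)
  expect_equal(back$params$Wrec, t$fit$params$Wrec, tolerance = 1e-12)
  expect_equal(back$params$wz, t$fit$params$wz, tolerance = 1e-12)
  s1 <- simulate_trials(t$fit$params, t$fit$config, c(0, 100), 0.2, seed = 9)
  s2 <- simulate_trials(back$params, back$config, c(0, 100), 0.2, seed = 9)
  expect_identical(s1$choice, s2$choice)
  expect_equal(s1$rates, s2$rates)
})
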