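test_that("noiseless simulation of a trained model exceeds typical session accuracy", {
  t <- toy_rnn()
  sim <- simulate_trials(t$fit$params, t$fit$config,
                         rep(stimulus_levels(), each = 5), 0, seed = 2)
  acc0 <- mean((sim$stim_s > 50) == (sim$choice == "sucrose_side"))
  expect_gt(acc0, t$accuracy - 0.05)
})

test_that("accuracy trends downward with input noise", {
  t <- toy_rnn()
  stim <- rep(stimulus_levels(), each = 10)
  accs <- vapply(c(0.05, 0.4, 1.0, 2.0), function(sg) {
    sim <- simulate_trials(t$fit$params, t$fit$config, stim, sg, seed = 5)
    mean((sim$stim_s > 50) == (sim$choice == "sucrose_side"))
  }, numeric(1))
  expect_gt(accs[1], accs[4])
  expect_gt(mean(accs[1:2]), mean(accs[3:4]) - 0.05)
})

test_that("calibrated noise reaches the session accuracy within tolerance", {
  t <- toy_rnn()
  cal <- calibrate_noise(t$fit, t$accuracy, seed = 6)
  expect_lte(abs(cal$achieved_accuracy - cal$target_accuracy), cal$tolerance)
  expect_true(all(c("sigma", "accuracy") %in% names(cal$trace)))
})

test_that("run_batch casts simulations into the analysis data model", {
  t <- toy_rnn()
  ws <- run_batch(t$fit, 0.3, n_per_stim = 4, seed = 7)
  expect_s3_class(ws$trials, "tbl_df")
  expect_equal(nrow(ws$trials), 32)
  expect_equal(as.vector(table(ws$trials$stim_pct_sucrose)), rep(4, 8))
  expect_equal(dim(ws$tensor_raw), c(32, t$fit$params$N, 117))
  expect_true(all(ws$trials$outcome %in% c("correct", "error")))
  # matched seed reproducibility
  ws2 <- run_batch(t$fit, 0.3, n_per_stim = 4, seed = 7)
  expect_identical(ws$tensor_raw, ws2$tensor_raw)
  expect_identical(ws$trials, ws2$trials)
  # 20 per stimulus gives the standard 160-trial batch
  expect_equal(20L * 8L, 160L)
})

test_that("empty clamp set reproduces control bit-for-bit; full clamp kills behavior", {
  t <- toy_rnn()
  ws_ctrl <- run_batch(t$fit, 0.3, n_per_stim = 3, seed = 11)
  ws_noop <- run_batch(t$fit, 0.3, n_per_stim = 3, seed = 11, clamp = integer(0))
  expect_identical(ws_ctrl$tensor_raw, ws_noop$tensor_raw)
  expect_identical(ws_ctrl$trials$choice, ws_noop$trials$choice)

  all_units <- seq_len(t$fit$params$N)
  ws_dead <- run_batch(t$fit, 0.3, n_per_stim = 3, seed = 11, clamp = all_units)
  expect_true(all(ws_dead$tensor_raw == 0))
  # z decays to 0: every trial falls to the same (NaCl) side, accuracy 1/2
  expect_equal(unique(ws_dead$trials$choice), "nacl_side")
  expect_equal(mean(ws_dead$trials$outcome == "correct"), 0.5)
})

test_that("clamping a unit with zero outgoing weights leaves choices unchanged", {
  t <- toy_rnn()
  p <- t$fit$params
  u <- p$N # silence the last unit's output pathways
  p$Wrec[, u] <- 0
  p$wz[u] <- 0
  fit2 <- t$fit
  fit2$params <- p
  ws_a <- run_batch(fit2, 0.3, n_per_stim = 3, seed = 13)
  ws_b <- run_batch(fit2, 0.3, n_per_stim = 3, seed = 13, clamp = u)
  expect_identical(ws_a$trials$choice, ws_b$trials$choice)
})

test_that("ablation sets come from the response-profile labels of the control batch", {
  t <- toy_rnn()
  ws <- run_batch(t$fit, 0.3, n_per_stim = 5, seed = 15)
  ab <- ablation_sets(ws)
  expect_named(ab$sets, c("linear", "step_perception", "step_choice", "other"))
  all_units <- seq_len(t$fit$params$N)
  expect_setequal(
    union(ab$sets$other,
          union(ab$sets$linear, union(ab$sets$step_perception, ab$sets$step_choice))),
    all_units
  )
  mv <- ab$timecourse[ab$timecourse$window_kind == "moving", ]
  for (lbl in c("linear", "step_perception", "step_choice")) {
    expect_setequal(ab$sets[[lbl]], sort(unique(mv$unit[mv$label == lbl])) + 1L)
  }
})

test_that("ablation report summarizes all conditions with a control baseline", {
  t <- toy_rnn()
  rep <- fixture("toy_ablation_report", function() {
    tt <- toy_rnn()
    ablation_report(tt$fit, 0.3, n_per_stim = 5, seed = 17)
  })
  expect_equal(rep$summary$condition[1], "control")
  expect_equal(rep$summary$n_ablated[1], 0)
  expect_equal(nrow(rep$summary), 5)
  # control re-fit axes coincide with themselves
  expect_equal(rep$summary$overlap_stimulus[1], 1, tolerance = 1e-6)
  expect_equal(rep$summary$overlap_choice[1], 1, tolerance = 1e-6)
  expect_true(all(rep$summary$accuracy >= 0 & rep$summary$accuracy <= 1))
})
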