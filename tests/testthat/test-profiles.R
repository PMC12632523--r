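profile_of <- function(rates) {
  tibble::tibble(stimulus = stimulus_levels(), rate = rates,
                 n_trials = rep(10L, 8))
}

test_that("line fit matches OLS when unconstrained fit is feasible, else projects", {
  set.seed(2)
  s <- stimulus_levels()
  r <- 2 + 0.05 * s + rnorm(8, 0, 0.3)
  fit <- fit_line(profile_of(r))
  ols <- stats::lm(r ~ s)
  expect_equal(fit$p1, unname(stats::coef(ols)[2]), tolerance = 1e-9)
  expect_equal(fit$p2, unname(stats::coef(ols)[1]), tolerance = 1e-9)

  # exactly-linear nonnegative data: SSE 0, accepted as a perfect fit
  fit0 <- fit_line(profile_of(1 + 0.02 * s))
  expect_equal(fit0$sse, 0, tolerance = 1e-18)
  expect_equal(fit0$p_value, 0)

  # constant profile: no improvement over the null
  fitc <- fit_line(profile_of(rep(4, 8)))
  expect_equal(fitc$fstat, 0)
  expect_equal(fitc$degenerate, "constant")

  # infeasible OLS (negative at s = 0) is projected onto the boundary
  r_neg <- -1 + 0.05 * s + c(0.01, -0.01, 0, 0, 0, 0, 0, 0)
  fitb <- fit_line(profile_of(r_neg))
  expect_gte(min(fitb$p1 * c(0, 100) + fitb$p2), -1e-9)
  # boundary fit is optimal among feasible candidates: compare to a grid oracle
  grid <- expand.grid(p1 = seq(0, 0.1, length.out = 120),
                      p2 = seq(0, 2, length.out = 120))
  ok <- grid$p1 * 0 + grid$p2 >= 0 & grid$p1 * 100 + grid$p2 >= 0
  sse_grid <- min(vapply(which(ok), function(i) {
    sum((r_neg - (grid$p1[i] * s + grid$p2[i]))^2)
  }, numeric(1)))
  expect_lte(fitb$sse, sse_grid + 1e-6)
})

test_that("step fit enumerates inflections exactly", {
  r <- c(2, 2, 2, 2, 9, 9, 9, 9)
  fit <- fit_step(profile_of(r))
  expect_equal(fit$p3, 50)
  expect_equal(fit$p1, 2)
  expect_equal(fit$p2, 9)
  expect_equal(fit$sse, 0)

  fitc <- fit_step(profile_of(rep(3, 8)))
  expect_equal(fitc$fstat, 0)

  # arbitrary profiles: chosen inflection matches brute force over {40,50,60}
  set.seed(9)
  s <- stimulus_levels()
  for (rep in 1:30) {
    r <- runif(8, 0, 20)
    fit <- fit_step(profile_of(r))
    brute <- sapply(c(40, 50, 60), function(p3) {
      sum((r[s < p3] - mean(r[s < p3]))^2) + sum((r[s >= p3] - mean(r[s >= p3]))^2)
    })
    expect_equal(fit$sse, min(brute), tolerance = 1e-12)
    expect_equal(fit$p3, c(40, 50, 60)[which.min(brute)])
  }
})

test_that("template selection agrees with a direct SSE + F-tail oracle", {
  set.seed(14)
  s <- stimulus_levels()
  for (rep in 1:40) {
    r <- pmax(0, 5 + cumsum(rnorm(8, 0, 2)))
    cl <- classify_profile(profile_of(r), profile_of(r))
    sse_null <- sum((r - mean(r))^2)
    ols <- stats::lm(r ~ s)
    sse_line <- if (all(stats::fitted(ols) >= -1e-12)) sum(stats::resid(ols)^2) else NA
    f_of <- function(sse2, np) (sse_null - sse2) / sse2 * (8 - np) / (np - 1)
    if (!is.na(sse_line) && sse_line > 1e-12) {
      expect_equal(cl$fit_line$fstat, f_of(sse_line, 2), tolerance = 1e-9)
      expect_equal(cl$fit_line$p_value,
                   stats::pf(f_of(sse_line, 2), 1, 6, lower.tail = FALSE),
                   tolerance = 1e-9)
    }
  }
})

test_that("classification disambiguates step-perception from step-choice via error trials", {
  corr <- profile_of(c(2, 2, 2, 2, 9, 9, 9, 9))
  # mirrored error profile: the unit follows the chosen side
  err_mirror <- profile_of(c(9, 9, 9, 9, 2, 2, 2, 2))
  expect_equal(classify_profile(corr, err_mirror)$label, "step_choice")
  # same-sign error profile: perceptual category
  err_same <- profile_of(c(2, 2, 2, 2, 9, 9, 9, 9))
  expect_equal(classify_profile(corr, err_same)$label, "step_perception")
  # missing error side: not sub-classified
  err_missing <- profile_of(c(2, 2, 2, 2, NA, NA, NA, NA))
  expect_equal(classify_profile(corr, err_missing)$label, "step_unresolved")
  # incomplete correct profile: other
  inc <- profile_of(c(NA, 2, 2, 2, 9, 9, 9, 9))
  expect_equal(classify_profile(inc, err_same)$label, "other")
  expect_true(classify_profile(inc, err_same)$incomplete)
  # clean line
  lin <- profile_of(1 + 0.05 * stimulus_levels())
  expect_equal(classify_profile(lin, lin)$label, "linear")
})

test_that("type-I error of template assignment is near 0.005 per template", {
  set.seed(25)
  n_rep <- 10000
  labels <- character(n_rep)
  for (i in seq_len(n_rep)) {
    r <- rnorm(8, 10, 1)
    labels[i] <- classify_profile(profile_of(r), profile_of(rnorm(8, 10, 1)))$label
  }
  p_lin <- mean(labels == "linear")
  p_step <- mean(labels %in% c("step_perception", "step_choice", "step_unresolved"))
  # each template's false-positive rate is alpha = 0.005 (pre-selection);
  # after winner-takes-the-larger-F the per-template rate stays below alpha
  # and their sum is near 2 * alpha
  expect_lt(p_lin, 0.005 + 3 * sqrt(0.005 * 0.995 / n_rep))
  expect_lt(p_step, 0.005 + 3 * sqrt(0.005 * 0.995 / n_rep))
  expect_gt(p_lin + p_step, 0.002)
  expect_lt(p_lin + p_step, 0.012)
})

test_that("moving windows tile the axis as 29 four-bin windows plus one single bin", {
  ws <- small_warped()
  tc <- coding_timecourse(ws)
  mv <- tc[tc$window_kind == "moving" & tc$unit == 0, ]
  expect_equal(nrow(mv), 30)
  widths <- mv$window_end_bin - mv$window_start_bin + 1
  expect_equal(sum(widths == 4), 29)
  expect_equal(sum(widths == 1), 1)
  expect_equal(mv$window_end_bin[30], 117)
  expect_true(all(c("sampling", "delay") %in% tc$window_kind))
})

test_that("ground-truth coding labels are recovered on the default session", {
  g <- default_generated()
  ws <- default_warped()
  tc <- fixture("default_timecourse", function() coding_timecourse(default_warped()))
  gt <- g$ground_truth
  mv <- tc[tc$window_kind == "moving", ]
  recovered <- vapply(seq_len(nrow(gt)), function(i) {
    u <- gt$unit[i]
    type <- gt$coding_type[i]
    if (!type %in% c("linear", "step_perception", "step_choice")) return(NA)
    labs <- mv$label[mv$unit == u]
    if (type == "linear") return(any(labs == "linear"))
    # step units: count either sub-type plus unresolved as shape recovery,
    # sub-type correctness checked separately below
    any(labs == type)
  }, logical(1))
  expect_gte(mean(recovered, na.rm = TRUE), 0.8)

  # flat units never earn a coding label
  flat <- gt$unit[gt$coding_type == "other_flat"]
  expect_true(all(mv$label[mv$unit %in% flat] %in% c("other", "step_unresolved")))
})

test_that("step sub-types are not confused when error trials are plentiful", {
  g <- fixture("errorful_generated", function() {
    # flat psychometric: half the trials are errors, both sides populated
    suppressMessages(generate_session(gen_config(
      n_trials = 160L, n_units = 10L, seed = 101L,
      psycho_params = c(0.6, 0.02, 50, 0.4),
      coding_mix = c(linear = 0, step_perception = 0.5, step_choice = 0.5,
                     other_responsive = 0, other_flat = 0)
    )))
  })
  ws <- build_psths(g$session)
  tc <- coding_timecourse(ws)
  mv <- tc[tc$window_kind == "moving", ]
  gt <- g$ground_truth
  # confusion is checked where the step tuning is strongly expressed
  # (a weakly-expressed window can flip the sign of the error-trial
  # difference by sampling noise, a property of the rule itself)
  for (i in seq_len(nrow(gt))) {
    sel <- mv$unit == gt$unit[i] & !is.na(mv$delta_correct) &
      abs(mv$delta_correct) >= 3
    labs <- mv$label[sel]
    wrong <- setdiff(c("step_perception", "step_choice"), gt$coding_type[i])
    expect_equal(sum(labs == wrong), 0)
  }
})

test_that("multiplex summary partitions coding units over label combinations", {
  tc <- fixture("default_timecourse", function() coding_timecourse(default_warped()))
  ms <- multiplex_summary(tc)
  expect_equal(nrow(ms), 7)
  expect_equal(sum(ms$n_units), attr(ms, "n_coding"))
  # all-other timecourse gives all-zero counts
  tc0 <- tc
  tc0$label <- "other"
  ms0 <- multiplex_summary(tc0)
  expect_equal(sum(ms0$n_units), 0)
})
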