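# Memoized fixtures shared across test files (generated once per run).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# Default-scale synthetic session: the generator's study conditions.
default_generated <- function() {
  fixture("default_generated", function() {
    suppressMessages(generate_session(gen_config(seed = 42L)))
  })
}

default_warped <- function() {
  fixture("default_warped", function() build_psths(default_generated()$session))
}

# Small, fast session for structural tests.
small_generated <- function() {
  fixture("small_generated", function() {
    suppressMessages(generate_session(gen_config(
      n_trials = 80L, n_units = 6L, seed = 7L
    )))
  })
}

small_warped <- function() {
  fixture("small_warped", function() build_psths(small_generated()$session))
}

# A quickly-trained reduced network for simulation/ablation plumbing tests.
toy_rnn <- function() {
  fixture("toy_rnn", function() {
    g <- suppressMessages(generate_session(gen_config(
      n_trials = 100L, n_units = 5L, seed = 12L
    )))
    ws <- build_psths(g$session)
    list(
      fit = rnn_train(ws, n_constrained = 5, seed = 21L, max_iters = 400L),
      session = g$session,
      accuracy = mean(g$session$trials$outcome == "correct")
    )
  })
}

# Hand-built two-trial session used by the I/O tests.
tiny_session <- function() {
  trials <- tibble::tibble(
    trial = 0:1,
    stim_pct_sucrose = c(100, 0),
    choice = c("sucrose_side", "nacl_side"),
    outcome = c("correct", "correct"),
    t_central = c(1.0, 1.0),
    t_lateral = c(4.5, 5.2)
  )
  spikes <- tibble::tibble(
    unit = c(0L, 0L, 0L),
    trial = c(0L, 0L, 1L),
    spike_time = c(0.5, 2.25, 3.1)
  )
  new_session(trials, spikes, session_id = "tiny")
}
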