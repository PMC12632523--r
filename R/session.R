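#' Construct a behavioral-electrophysiology session
#'
#' A session bundles one recording (or simulation) of the taste-mixture
#' two-alternative-choice task: a trial table and long-format spike times.
#' All times are in seconds on a per-trial clock; the first central lick
#' (`t_central`, stimulus sampling onset) and first lateral lick
#' (`t_lateral`, decision execution) are stored per trial so downstream
#' event-warping stays independent of the raw data.
#'
#' @param trials A data frame with columns `trial` (0-based integer),
#'   `stim_pct_sucrose` (%Sucrose of the mixture, one of
#'   0, 25, 35, 45, 55, 65, 75, 100), `choice`
#'   (`"sucrose_side"`/`"nacl_side"`), `outcome` (`"correct"`/`"error"`),
#'   `t_central`, `t_lateral` (seconds).
#' @param spikes A data frame with columns `unit` (0-based integer),
#'   `trial` (0-based integer), `spike_time` (seconds). May have zero rows.
#' @param session_id Character identifier.
#' @param n_units Number of units; defaults to `max(spikes$unit) + 1`
#'   (0 when there are no spikes). Unit ids must form a contiguous
#'   0-based range within `0:(n_units - 1)`.
#' @return A `taste_session` object: a list with `session_id`, `trials`
#'   (tibble), `spikes` (tibble) and `n_units`.
#' @export
new_session <- function(trials, spikes, session_id = "session", n_units = NULL) {
  trials <- tibble::as_tibble(trials)
  spikes <- tibble::as_tibble(spikes)
  if (is.null(n_units)) {
    n_units <- if (nrow(spikes) > 0) max(spikes$unit) + 1L else 0L
  }
  s <- structure(
    list(
      session_id = session_id,
      trials = trials,
      spikes = spikes,
      n_units = as.integer(n_units)
    ),
    class = "taste_session"
  )
  validate_session(s)
}

#' @export
print.taste_session <- function(x, ...) {
  cat(sprintf(
    "<taste_session '%s': %d trials, %d units, %d spikes>\n",
    x$session_id, nrow(x$trials), x$n_units, nrow(x$spikes)
  ))
  invisible(x)
}

stimulus_levels <- function() c(0, 25, 35, 45, 55, 65, 75, 100)

#' Validate a session against the task's structural invariants
#'
#' Checks that stimuli come from the 8-mixture set, lateral licks follow
#' central licks, the recorded outcome is consistent with stimulus and
#' choice (`correct` iff choice matches the predominant mixture component),
#' spike times are finite and nondecreasing per unit/trial, and spike rows
#' refer to existing trials and a contiguous 0-based unit range.
#'
#' @param session A `taste_session`.
#' @return The session, invisibly-validated (errors on violation).
#' @export
validate_session <- function(session) {
  tr <- session$trials
  req <- c("trial", "stim_pct_sucrose", "choice", "outcome", "t_central", "t_lateral")
  missing_cols <- setdiff(req, names(tr))
  if (length(missing_cols) > 0) {
    stop("trials table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sp <- session$spikes
  missing_sp <- setdiff(c("unit", "trial", "spike_time"), names(sp))
  if (length(missing_sp) > 0) {
    stop("spikes table is missing column(s): ", paste(missing_sp, collapse = ", "))
  }
  if (nrow(tr) > 0) {
    bad_stim <- !tr$stim_pct_sucrose %in% stimulus_levels()
    if (any(bad_stim)) {
      stop(
        "invalid stimulus value(s) in trial(s) ",
        paste(tr$trial[bad_stim], collapse = ", ")
      )
    }
    if (!all(tr$choice %in% c("sucrose_side", "nacl_side"))) {
      stop("choice must be 'sucrose_side' or 'nacl_side'")
    }
    if (!all(tr$outcome %in% c("correct", "error"))) {
      stop("outcome must be 'correct' or 'error'")
    }
    bad_t <- !(tr$t_lateral > tr$t_central)
    if (any(bad_t)) {
      stop(
        "t_lateral must exceed t_central; violated in trial(s) ",
        paste(tr$trial[bad_t], collapse = ", ")
      )
    }
    expected <- ifelse(tr$stim_pct_sucrose > 50, "sucrose_side", "nacl_side")
    expected_outcome <- ifelse(tr$choice == expected, "correct", "error")
    bad_o <- tr$outcome != expected_outcome
    if (any(bad_o)) {
      stop(
        "outcome inconsistent with stimulus and choice in trial(s) ",
        paste(tr$trial[bad_o], collapse = ", ")
      )
    }
    if (anyDuplicated(tr$trial)) stop("duplicate trial indices")
  }
  if (nrow(sp) > 0) {
    if (!all(is.finite(sp$spike_time))) stop("non-finite spike times")
    if (!all(sp$trial %in% tr$trial)) {
      stop("spike rows refer to nonexistent trial(s)")
    }
    if (any(sp$unit < 0) || any(sp$unit >= session$n_units)) {
      stop("unit ids must lie in 0:(n_units - 1)")
    }
    ord <- order(sp$unit, sp$trial, seq_len(nrow(sp)))
    sp_ord <- sp[ord, ]
    grp <- paste(sp_ord$unit, sp_ord$trial)
    same <- grp[-1] == grp[-length(grp)]
    dec <- diff(sp_ord$spike_time) < 0 & same
    if (any(dec)) {
      i <- which(dec)[1] + 1
      stop(sprintf(
        "non-monotone spike times for unit %d, trial %d",
        sp_ord$unit[i], sp_ord$trial[i]
      ))
    }
  }
  session
}

#' Read a session from plain-text trial and spike files
#'
#' @param trials_path CSV with header
#'   `trial,stim_pct_sucrose,choice,outcome,t_central,t_lateral`.
#' @param spikes_path CSV with header `unit,trial,spike_time` (may contain
#'   only the header).
#' @param session_id Identifier to attach; defaults to the trials file stem.
#' @return A validated [new_session()] object.
#' @export
read_session <- function(trials_path, spikes_path,
                         session_id = sub("\\.[^.]*$", "", basename(trials_path))) {
  if (!file.exists(trials_path)) stop("trials file not found: ", trials_path)
  if (!file.exists(spikes_path)) stop("spikes file not found: ", spikes_path)
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  spikes <- utils::read.csv(spikes_path, stringsAsFactors = FALSE)
  if (nrow(spikes) == 0) {
    spikes <- tibble::tibble(unit = integer(), trial = integer(), spike_time = double())
  }
  trials$trial <- as.integer(trials$trial)
  if (nrow(spikes) > 0) {
    spikes$unit <- as.integer(spikes$unit)
    spikes$trial <- as.integer(spikes$trial)
  }
  new_session(trials, spikes, session_id = session_id)
}

#' Write a session to a directory as plain-text files
#'
#' Writes `trials.csv`, `spikes.csv` and a small `manifest.json`
#' (session id, unit and trial counts, file names). Times are written at
#' full precision so that [read_session()] round-trips exactly.
#'
#' @param session A `taste_session`.
#' @param dir Output directory (created if absent).
#' @return The paths written, invisibly.
#' @export
write_session <- function(session, dir) {
  validate_session(session)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  tp <- file.path(dir, "trials.csv")
  sp <- file.path(dir, "spikes.csv")
  tr <- session$trials
  # full-precision times: format via as.character (R uses 15 significant digits,
  # round-trips doubles written by the generator)
  write_full_precision <- function(df, path) {
    df2 <- as.data.frame(lapply(df, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else col
    }), stringsAsFactors = FALSE)
    names(df2) <- names(df)
    utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  }
  write_full_precision(tr, tp)
  write_full_precision(session$spikes, sp)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(
      session_id = session$session_id,
      n_units = session$n_units,
      n_trials = nrow(session$trials),
      trials_file = basename(tp),
      spikes_file = basename(sp)
    ),
    mp,
    auto_unbox = TRUE
  )
  invisible(c(trials = tp, spikes = sp, manifest = mp))
}
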