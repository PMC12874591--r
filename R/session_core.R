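#' @keywords internal
"_PACKAGE"

# Canonical trial-event column order for the on-disk trials table.
.trial_cols <- c("trial_index", "trial_type", "outcome",
                 "odor_on", "odor_off", "port_exit",
                 "water_port_entry", "water_valve_open")

.trial_types <- c("go", "nogo", "catch")
.outcomes <- c("correct", "error")

#' Construct a session object
#'
#' A session bundles the per-trial behavioral events of one recording with the
#' spike trains of all simultaneously recorded neurons. Times are seconds on a
#' single per-session clock; all analysis windows stated in milliseconds are
#' converted to seconds once, inside [task_epoch()].
#'
#' @param session_id,animal_id identifiers.
#' @param trials data.frame with columns `trial_index`, `trial_type`
#'   (`go`/`nogo`/`catch`), `outcome` (`correct`/`error`), and event times in
#'   seconds: `odor_on`, `odor_off`, `port_exit`, `water_port_entry`,
#'   `water_valve_open` (the water columns are `NA` when the event did not
#'   occur, e.g. on go-error trials). The pre-trial inter-trial interval ends
#'   at `odor_on` (odor-port entry opens the valve), so `iti_end` is derived,
#'   not stored.
#' @param spikes named list, one sorted numeric vector of spike times per
#'   neuron.
#' @param validate check invariants (default `TRUE`).
#' @return object of class `odorgng_session` with derived
#'   `behavioral_accuracy`: correct go/no-go trials over all non-catch trials
#'   (catch trials are unrewarded regardless of choice and excluded).
#' @export
new_session <- function(session_id, animal_id, trials, spikes, validate = TRUE) {
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trial_cols, names(trials))
  if (length(missing_cols)) {
    stop("trials table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  trials <- trials[order(trials$trial_index), .trial_cols, drop = FALSE]
  trials$iti_end <- trials$odor_on
  rownames(trials) <- NULL
  if (length(spikes) && (is.null(names(spikes)) || anyDuplicated(names(spikes)))) {
    stop("spikes must be a named list with unique neuron ids")
  }
  spikes <- lapply(spikes, as.numeric)
  noncatch <- trials$trial_type != "catch"
  acc <- if (any(noncatch)) {
    mean(trials$outcome[noncatch] == "correct")
  } else NA_real_
  x <- structure(
    list(session_id = session_id, animal_id = animal_id,
         trials = trials, spikes = spikes,
         behavioral_accuracy = acc),
    class = "odorgng_session")
  if (validate) validate_session(x)
  x
}

#' Validate session invariants
#'
#' Checks event ordering (`odor_on < odor_off <= port_exit`), the 300 ms
#' pre-reward wait (`water_valve_open - water_port_entry = 0.3` whenever both
#' are present), spike-time monotonicity, label values, and trial-index
#' uniqueness.
#'
#' @param x an `odorgng_session`.
#' @param tol numerical tolerance on the pre-reward wait, seconds.
#' @return `x`, invisibly; stops with a validation error naming the offending
#'   trial or neuron otherwise.
#' @export
validate_session <- function(x, tol = 1e-6) {
  tr <- x$trials
  if (anyDuplicated(tr$trial_index)) stop("validation error: duplicate trial_index")
  if (!all(tr$trial_type %in% .trial_types)) {
    stop("validation error: unknown trial_type")
  }
  if (!all(tr$outcome %in% .outcomes)) stop("validation error: unknown outcome")
  bad <- which(!(tr$odor_on < tr$odor_off & tr$odor_off <= tr$port_exit))
  if (length(bad)) {
    stop("validation error: event order violated at trial_index ",
         tr$trial_index[bad[1]])
  }
  has_valve <- !is.na(tr$water_valve_open)
  if (any(has_valve & is.na(tr$water_port_entry))) {
    stop("validation error: water_valve_open without water_port_entry")
  }
  wait <- tr$water_valve_open[has_valve] - tr$water_port_entry[has_valve]
  if (length(wait) && any(abs(wait - 0.3) > tol)) {
    stop("validation error: pre-reward wait != 0.3 s at trial_index ",
         tr$trial_index[has_valve][which(abs(wait - 0.3) > tol)[1]])
  }
  for (nid in names(x$spikes)) {
    s <- x$spikes[[nid]]
    if (is.unsorted(s)) stop("validation error: unsorted spike times for neuron ", nid)
  }
  invisible(x)
}

#' @export
print.odorgng_session <- function(x, ...) {
  tr <- x$trials
  cat("<odorgng_session> ", x$session_id, " (animal ", x$animal_id, ")\n", sep = "")
  cat("  trials: ", nrow(tr), " (",
      sum(tr$trial_type == "go"), " go, ",
      sum(tr$trial_type == "nogo"), " no-go, ",
      sum(tr$trial_type == "catch"), " catch)\n", sep = "")
  cat("  behavioral accuracy:", round(x$behavioral_accuracy, 3), "\n")
  cat("  neurons:", length(x$spikes), "\n")
  invisible(x)
}

#' Write a session to a directory
#'
#' The container is a directory with `trials.csv` (one row per trial, water
#' columns empty when absent), `spikes.csv` (`neuron_id`, `spike_time`), and
#' `metadata.json` (`session_id`, `animal_id`). Event and spike values
#' round-trip exactly through [read_session()].
#'
#' @param x an `odorgng_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(x, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tr <- x$trials[, .trial_cols]
  num_cols <- setdiff(.trial_cols, c("trial_index", "trial_type", "outcome"))
  for (cc in num_cols) tr[[cc]] <- format_time(tr[[cc]])
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  nid <- rep(names(x$spikes), lengths(x$spikes))
  st <- unlist(x$spikes, use.names = FALSE)
  utils::write.csv(
    data.frame(neuron_id = nid,
               spike_time = format_time(if (is.null(st)) numeric(0) else st)),
    file.path(path, "spikes.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(session_id = x$session_id, animal_id = x$animal_id,
         neuron_ids = as.list(names(x$spikes))),
    file.path(path, "metadata.json"), auto_unbox = TRUE)
  invisible(path)
}

# full binary precision without scientific notation surprises
format_time <- function(t) {
  out <- vapply(t, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
  }, character(1))
  out
}

#' Read a session from a directory
#'
#' Inverse of [write_session()]; validates all invariants on load.
#'
#' @param path directory containing `trials.csv`, `spikes.csv`,
#'   `metadata.json`.
#' @return an `odorgng_session`.
#' @export
read_session <- function(path) {
  tfile <- file.path(path, "trials.csv")
  sfile <- file.path(path, "spikes.csv")
  mfile <- file.path(path, "metadata.json")
  for (f in c(tfile, sfile, mfile)) {
    if (!file.exists(f)) stop("parse error: missing ", f)
  }
  tr <- utils::read.csv(tfile, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trial_cols, names(tr))
  if (length(missing_cols)) {
    stop("parse error: trials.csv lacks columns ",
         paste(missing_cols, collapse = ", "))
  }
  sp <- utils::read.csv(sfile, stringsAsFactors = FALSE,
                        colClasses = c(neuron_id = "character",
                                       spike_time = "numeric"))
  meta <- jsonlite::read_json(mfile, simplifyVector = TRUE)
  ids <- if (!is.null(meta$neuron_ids)) {
    as.character(meta$neuron_ids)
  } else unique(sp$neuron_id)
  unknown <- setdiff(sp$neuron_id, ids)
  if (length(unknown)) {
    stop("parse error: spikes.csv has neuron ", unknown[1],
         " absent from metadata")
  }
  spikes <- split(sp$spike_time, factor(sp$neuron_id, levels = ids))
  new_session(meta$session_id, meta$animal_id, tr, as.list(spikes))
}

# ---- epochs -----------------------------------------------------------------

# Behavioral epochs, defined once. Offsets are seconds relative to
# `align_event`; `end_event` (when non-NA) makes the epoch end trial-specific
# (e.g. nose poking ends at that trial's odor-port exit).
.epoch_defs <- list(
  baseline_iti      = list(align_event = "iti_end",          start_offset = -0.2, end_offset = 0,    end_event = NA),
  pre_odor_baseline = list(align_event = "odor_on",          start_offset = -1.2, end_offset = -1.0, end_event = NA),
  odor_presentation = list(align_event = "odor_on",          start_offset = 0,    end_offset = 0.5,  end_event = NA),
  nose_poking       = list(align_event = "odor_on",          start_offset = 0,    end_offset = 0,    end_event = "port_exit"),
  late_nose_poking  = list(align_event = "odor_on",          start_offset = 0.5,  end_offset = 0,    end_event = "port_exit"),
  pre_exit          = list(align_event = "port_exit",        start_offset = -0.3, end_offset = 0,    end_event = NA),
  moving            = list(align_event = "port_exit",        start_offset = 0,    end_offset = 0,    end_event = "water_port_entry"),
  waiting           = list(align_event = "water_port_entry", start_offset = 0,    end_offset = 0.3,  end_event = NA),
  drinking          = list(align_event = "water_valve_open", start_offset = 0,    end_offset = 1.0,  end_event = NA)
)

#' Behavioral epoch definitions
#'
#' Single source of window bounds for every analysis stage: the 200 ms
#' pre-trial baseline, the 1200--1000 ms pre-odor baseline used by the
#' population-distance threshold, odor presentation (0--500 ms), nose poking
#' and its late phase, the 300 ms pre-exit window, moving, the 300 ms waiting
#' epoch before the water valve opens, and the first 1000 ms of drinking.
#'
#' @param name one of `baseline_iti`, `pre_odor_baseline`, `odor_presentation`,
#'   `nose_poking`, `late_nose_poking`, `pre_exit`, `moving`, `waiting`,
#'   `drinking`.
#' @return list with `name`, `align_event`, `start_offset`, `end_offset`,
#'   `end_event` (`NA` unless the epoch ends at a trial-specific event).
#' @export
task_epoch <- function(name) {
  name <- match.arg(name, names(.epoch_defs))
  c(list(name = name), .epoch_defs[[name]])
}

#' Resolve an epoch to absolute per-trial windows
#'
#' @param epoch a [task_epoch()] (or a list with the same fields).
#' @param trials trial table (rows of a session's `trials`).
#' @return data.frame with `start`, `end` (seconds, session clock); `NA` rows
#'   where a required event is absent on that trial.
#' @export
epoch_windows <- function(epoch, trials) {
  a <- trials[[epoch$align_event]]
  start <- a + epoch$start_offset
  if (!is.na(epoch$end_event)) {
    end <- trials[[epoch$end_event]] + epoch$end_offset
  } else {
    end <- a + epoch$end_offset
  }
  bad <- !is.na(start) & !is.na(end) & start >= end
  start[bad] <- NA_real_
  end[bad] <- NA_real_
  data.frame(start = start, end = end)
}

# ---- alignment --------------------------------------------------------------

#' Align a spike train to events
#'
#' For each event time, returns spike times relative to that event that fall
#' in the half-open window `[start, end)`. A spike on a shared boundary of
#' adjacent windows is therefore counted once.
#'
#' @param spike_times sorted numeric vector, seconds.
#' @param event_times numeric vector of alignment events (may be empty).
#' @param window numeric length-2, `c(start, end)` relative seconds,
#'   `start < end`.
#' @return list, one numeric vector of relative times per event.
#' @export
align_spikes <- function(spike_times, event_times, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  lapply(event_times, function(ev) {
    if (is.na(ev)) return(numeric(0))
    lo <- findInterval(ev + window[1], spike_times, left.open = TRUE) + 1L
    hi <- findInterval(ev + window[2], spike_times, left.open = TRUE)
    if (hi < lo) numeric(0) else spike_times[lo:hi] - ev
  })
}

#' Filter trials with a minimum-count rule
#'
#' Every analyzed condition requires at least `min_trials` trials (default 5);
#' a condition below the minimum yields a typed refusal that downstream stages
#' interpret as "neuron/condition excluded" rather than an error.
#'
#' @param session an `odorgng_session` (or a trial data.frame).
#' @param condition logical vector over trials, or a predicate
#'   `function(trials)` returning one.
#' @param min_trials minimum subset size.
#' @return the matching trial subset (data.frame), or an `odorgng_refusal`.
#' @export
trial_filter <- function(session, condition, min_trials = 5L) {
  trials <- if (inherits(session, "odorgng_session")) session$trials else session
  keep <- if (is.function(condition)) condition(trials) else condition
  keep[is.na(keep)] <- FALSE
  sub <- trials[keep, , drop = FALSE]
  if (nrow(sub) < min_trials) {
    return(refusal(sprintf("only %d trials match (minimum %d)",
                           nrow(sub), min_trials)))
  }
  sub
}

#' @rdname trial_filter
#' @param reason character explanation.
#' @export
refusal <- function(reason) {
  structure(list(reason = reason), class = "odorgng_refusal")
}

#' @rdname trial_filter
#' @param x object to test.
#' @export
is_refusal <- function(x) inherits(x, "odorgng_refusal")

#' @export
print.odorgng_refusal <- function(x, ...) {
  cat("<refusal>", x$reason, "\n")
  invisible(x)
}

# Convenience predicates over the trial table
#' @rdname trial_filter
#' @param type,outcome values to match (`NULL` = any).
#' @export
trials_of <- function(session, type = NULL, outcome = NULL) {
  trials <- if (inherits(session, "odorgng_session")) session$trials else session
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(type)) keep <- keep & trials$trial_type %in% type
  if (!is.null(outcome)) keep <- keep & trials$outcome %in% outcome
  trials[keep, , drop = FALSE]
}
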