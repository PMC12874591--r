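# Synthetic go/no-go sessions with known ground truth.
#
# The generator reproduces the task timeline (500 ms odor, 2 s response
# window, 300 ms pre-reward wait, 3 s ITI, one catch trial in ten) and four
# neuron archetypes observed in cortical amygdala recordings: late-phase
# go-cue responders, waiting-epoch phasic responders (also go-cue preferring),
# drinking-epoch ramping responders, and untuned units. Spikes are an
# inhomogeneous Poisson process over piecewise-linear rate profiles, sampled
# by thinning so the ceiling is exact.

#' Task configuration
#'
#' Defaults are the study conditions: 500 ms odor, 3 s inter-trial interval,
#' 2 s response window, 300 ms pre-reward wait, catch trials once in ten,
#' nose-poke duration medians (IQR) of 927 (745--1123) ms on go trials and
#' 758 (660--910) ms on no-go trials, and 85% behavioral accuracy (trained
#' animals hold above 80%).
#'
#' @param n_trials number of trials in the session.
#' @param p_go probability a non-catch trial is a go trial.
#' @param catch_every every `catch_every`-th trial is an odorless catch trial.
#' @param odor_duration,iti,response_window,pre_reward_wait task timing,
#'   seconds.
#' @param go_poke_median,go_poke_iqr,nogo_poke_median,nogo_poke_iqr nose-poke
#'   duration summaries, seconds; realized as a log-normal matched to the
#'   median and IQR, truncated below at the odor duration (the animal must
#'   hold through odor presentation).
#' @param accuracy probability a non-catch trial is correct.
#' @param move_time_mean mean odor-port-exit to water-port-entry travel time,
#'   seconds.
#' @return list of class `odorgng_task_config`.
#' @export
task_config <- function(n_trials = 240L, p_go = 0.5, catch_every = 10L,
                        odor_duration = 0.5, iti = 3.0,
                        response_window = 2.0, pre_reward_wait = 0.3,
                        go_poke_median = 0.927, go_poke_iqr = c(0.745, 1.123),
                        nogo_poke_median = 0.758, nogo_poke_iqr = c(0.660, 0.910),
                        accuracy = 0.85, move_time_mean = 0.4) {
  stopifnot(n_trials >= 1, accuracy > 0, accuracy <= 1,
            p_go > 0, p_go < 1, catch_every >= 2)
  structure(list(n_trials = as.integer(n_trials), p_go = p_go,
                 catch_every = as.integer(catch_every),
                 odor_duration = odor_duration, iti = iti,
                 response_window = response_window,
                 pre_reward_wait = pre_reward_wait,
                 go_poke_median = go_poke_median, go_poke_iqr = go_poke_iqr,
                 nogo_poke_median = nogo_poke_median,
                 nogo_poke_iqr = nogo_poke_iqr,
                 accuracy = accuracy, move_time_mean = move_time_mean),
            class = "odorgng_task_config")
}

.archetype_labels <- c("go_cue_late", "waiting_phasic", "drinking_ramp", "untuned")

#' Neuron response archetype
#'
#' Piecewise-linear firing-rate profiles anchored to trial events. Profiles
#' are linear between knots so thinning ceilings and expected counts are
#' exact.
#'
#' * `go_cue_late`: baseline everywhere except a plateau at `peak_rate` from
#'   `odor_on + onset` (default 0.5 s, the late nose-poking phase) to the
#'   odor-port exit, on go trials only.
#' * `waiting_phasic`: a go-cue plateau at `baseline + cue_gain * (peak -
#'   baseline)` during late nose-poking, plus a transient bump to `peak_rate`
#'   after water-port entry that decays before the valve opens.
#' * `drinking_ramp`: a linear ramp starting `ramp_lead` (default 0.2 s)
#'   before the water valve opens, sustained `sustain` (default 0.4 s) into
#'   drinking, and firing suppressed below baseline during the rest of the
#'   trial.
#' * `untuned`: constant baseline.
#'
#' @param label archetype name.
#' @param baseline_rate,peak_rate Hz. Defaults (3--4 Hz baseline, 20--25 Hz
#'   peak) are conventional cortical values, configurable, not claims about
#'   any dataset.
#' @param ... per-label shape overrides (`onset`, `rise`, `decay`, `cue_gain`,
#'   `bump_rise`, `bump_end`, `ramp_lead`, `sustain`, `suppress`).
#' @return list of class `odorgng_archetype`.
#' @export
neuron_archetype <- function(label = .archetype_labels,
                             baseline_rate = NULL, peak_rate = NULL, ...) {
  label <- match.arg(label)
  defaults <- switch(label,
    go_cue_late    = list(baseline_rate = 3, peak_rate = 20,
                          onset = 0.5, rise = 0.05, decay = 0.1),
    waiting_phasic = list(baseline_rate = 3, peak_rate = 25,
                          onset = 0.5, rise = 0.05, cue_gain = 0.6,
                          bump_rise = 0.08, bump_end = 0.25),
    drinking_ramp  = list(baseline_rate = 4, peak_rate = 20,
                          ramp_lead = 0.2, sustain = 0.4, decay = 0.2,
                          suppress = 0.5),
    untuned        = list(baseline_rate = 4, peak_rate = 4))
  ov <- list(...)
  if (!is.null(baseline_rate)) ov$baseline_rate <- baseline_rate
  if (!is.null(peak_rate)) ov$peak_rate <- peak_rate
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) stop("unknown parameters for ", label, ": ",
                            paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, ov)
  if (p$baseline_rate < 0 || p$peak_rate < 0) stop("rates must be >= 0")
  structure(c(list(label = label), p), class = "odorgng_archetype")
}

# strictly increasing knot positions for approx()
.fix_knots <- function(xs, ys) {
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  for (i in seq_along(xs)[-1]) {
    if (xs[i] <= xs[i - 1]) xs[i] <- xs[i - 1] + 1e-6
  }
  list(x = xs, y = ys)
}

#' Archetype firing rate at given times of one trial
#'
#' @param archetype an [neuron_archetype()].
#' @param trial one row of a session trial table (list or 1-row data.frame).
#' @param t numeric vector of times, seconds (session clock).
#' @return numeric vector of rates, Hz (finite, `>= 0`).
#' @export
archetype_rate <- function(archetype, trial, t) {
  b <- archetype$baseline_rate
  p <- archetype$peak_rate
  type <- trial$trial_type
  on <- trial$odor_on
  exit <- trial$port_exit
  entry <- trial$water_port_entry
  valve <- trial$water_valve_open

  if (archetype$label == "untuned") return(rep(b, length(t)))

  if (archetype$label == "go_cue_late") {
    if (!identical(type, "go")) return(rep(b, length(t)))
    k <- .fix_knots(
      c(on + archetype$onset - archetype$rise, on + archetype$onset,
        exit, exit + archetype$decay),
      c(b, p, p, b))
    return(stats::approx(k$x, k$y, xout = t, rule = 2)$y)
  }

  if (archetype$label == "waiting_phasic") {
    if (!identical(type, "go")) return(rep(b, length(t)))
    pl <- b + archetype$cue_gain * (p - b)
    xs <- c(on + archetype$onset - archetype$rise, on + archetype$onset,
            exit, exit + 0.1)
    ys <- c(b, pl, pl, b)
    if (!is.na(entry)) {
      xs <- c(xs, entry, entry + archetype$bump_rise, entry + archetype$bump_end)
      ys <- c(ys, b, p, b)
    }
    k <- .fix_knots(xs, ys)
    return(stats::approx(k$x, k$y, xout = t, rule = 2)$y)
  }

  # drinking_ramp
  sb <- archetype$suppress * b
  if (!is.na(valve)) {
    # suppression releases just before the ramp so the rate is already above
    # baseline at the ramp onset (ramp_lead before the valve opens)
    k <- .fix_knots(
      c(on - 0.1, on, valve - archetype$ramp_lead - 0.05,
        valve - archetype$ramp_lead, valve,
        valve + archetype$sustain, valve + archetype$sustain + archetype$decay),
      c(b, sb, sb, b, p, p, b))
  } else {
    k <- .fix_knots(c(on - 0.1, on, exit + 0.5, exit + 0.7),
                    c(b, sb, sb, b))
  }
  stats::approx(k$x, k$y, xout = t, rule = 2)$y
}

#' Inhomogeneous Poisson spike times by thinning
#'
#' Candidate events are drawn homogeneously at `rate_max` and retained with
#' probability `rate_fn(t) / rate_max`, so counts over any subinterval are
#' Poisson with mean equal to the integrated rate. Uses R's current RNG
#' stream.
#'
#' @param rate_fn vectorized rate function, Hz.
#' @param interval `c(start, end)` seconds.
#' @param rate_max ceiling; `rate_fn` must not exceed it (checked on the
#'   candidates) and must be nonnegative.
#' @return sorted numeric vector of spike times.
#' @export
poisson_spikes <- function(rate_fn, interval, rate_max) {
  stopifnot(length(interval) == 2, interval[1] <= interval[2], rate_max >= 0)
  len <- interval[2] - interval[1]
  if (len == 0 || rate_max == 0) return(numeric(0))
  n <- stats::rpois(1, rate_max * len)
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, interval[1], interval[2]))
  r <- rate_fn(cand)
  if (any(r < 0)) stop("negative rate")
  if (any(r > rate_max * (1 + 1e-9))) stop("rate exceeds ceiling")
  cand[stats::runif(n) < r / rate_max]
}

# log-normal matched to (median, IQR), truncated below at min_val
.draw_poke <- function(n, median, iqr, min_val) {
  mu <- log(median)
  sdlog <- log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))
  out <- stats::rlnorm(n, mu, sdlog)
  bad <- which(out < min_val)
  while (length(bad)) {
    out[bad] <- stats::rlnorm(length(bad), mu, sdlog)
    bad <- bad[out[bad] < min_val]
  }
  out
}

.draw_move <- function(n, mean, max_val) {
  shape <- 9
  out <- stats::rgamma(n, shape = shape, scale = mean / shape)
  bad <- which(out > max_val)
  while (length(bad)) {
    out[bad] <- stats::rgamma(length(bad), shape = shape, scale = mean / shape)
    bad <- bad[out[bad] > max_val]
  }
  out
}

#' Simulate a session with ground truth
#'
#' Builds the trial timeline (types, outcomes, event times) from a
#' [task_config()], then generates each neuron's spike train from its
#' archetype's rate profile by Poisson thinning. Identical seeds give
#' bit-identical output.
#'
#' Error-trial semantics: a go error is a failure to enter the water port
#' within the response window (no water events); a no-go error is a false
#' alarm (water-port entry present, valve never opens). Catch trials are
#' odorless and unrewarded regardless of choice; they are recorded with
#' outcome `correct` and excluded from behavioral accuracy.
#'
#' @param task a [task_config()].
#' @param archetypes list of `list(archetype, count)` pairs.
#' @param seed integer seed.
#' @param session_id,animal_id identifiers.
#' @return list with `session` (an `odorgng_session`) and `truth` (class
#'   `odorgng_ground_truth`: per-neuron labels/parameters and the latent
#'   per-session rate functions, retained for tests).
#' @export
simulate_session <- function(task, archetypes, seed,
                             session_id = sprintf("sim%06d", seed %% 1000000L),
                             animal_id = "simulated") {
  stopifnot(inherits(task, "odorgng_task_config"))
  if (task$n_trials < 1) stop("zero trials")
  set.seed(as.integer(seed %% .Machine$integer.max))

  n <- task$n_trials
  idx <- seq_len(n)
  is_catch <- idx %% task$catch_every == 0
  type <- ifelse(is_catch, "catch",
                 ifelse(stats::runif(n) < task$p_go, "go", "nogo"))
  outcome <- ifelse(is_catch, "correct",
                    ifelse(stats::runif(n) < task$accuracy, "correct", "error"))
  # does the animal perform the go behavior (enter the water port)?
  go_behavior <- (type == "go" & outcome == "correct") |
    (type == "nogo" & outcome == "error") |
    (is_catch & stats::runif(n) < 0.5)
  poke_is_go_like <- ifelse(is_catch, go_behavior, type == "go")
  poke <- numeric(n)
  poke[poke_is_go_like] <- .draw_poke(sum(poke_is_go_like),
                                      task$go_poke_median, task$go_poke_iqr,
                                      task$odor_duration + 0.02)
  poke[!poke_is_go_like] <- .draw_poke(sum(!poke_is_go_like),
                                       task$nogo_poke_median, task$nogo_poke_iqr,
                                       task$odor_duration + 0.02)
  move <- .draw_move(n, task$move_time_mean,
                     task$response_window - task$odor_duration - 0.05)

  odor_on <- numeric(n)
  odor_off <- numeric(n)
  port_exit <- numeric(n)
  entry <- rep(NA_real_, n)
  valve <- rep(NA_real_, n)
  trial_end <- numeric(n)
  cursor <- 0
  for (i in idx) {
    odor_on[i] <- cursor + task$iti
    odor_off[i] <- odor_on[i] + task$odor_duration
    port_exit[i] <- odor_on[i] + poke[i]
    last <- port_exit[i]
    if (go_behavior[i]) {
      entry[i] <- port_exit[i] + move[i]
      last <- entry[i] + 0.5
      if (type[i] == "go" && outcome[i] == "correct") {
        valve[i] <- entry[i] + task$pre_reward_wait
        last <- valve[i] + 1.5   # drinking
      }
    }
    trial_end[i] <- last
    cursor <- trial_end[i]
  }
  trials <- data.frame(trial_index = idx - 1L, trial_type = type,
                       outcome = outcome, odor_on = odor_on,
                       odor_off = odor_off, port_exit = port_exit,
                       water_port_entry = entry, water_valve_open = valve,
                       stringsAsFactors = FALSE)
  session_end <- cursor + task$iti

  # expand archetype list to per-neuron assignments
  arch_list <- list()
  for (a in archetypes) {
    arch <- a[[1]]
    cnt <- a[[2]]
    stopifnot(inherits(arch, "odorgng_archetype"), cnt >= 0)
    arch_list <- c(arch_list, rep(list(arch), cnt))
  }
  n_neuron <- length(arch_list)
  ids <- sprintf("n%03d", seq_len(n_neuron))

  make_rate_fn <- function(arch) {
    force(arch)
    function(t) {
      out <- rep(arch$baseline_rate, length(t))
      j <- findInterval(t, odor_on - 1.0)
      ok <- which(j >= 1 & t <= trial_end[pmax(j, 1)] + 1.0)
      if (length(ok)) {
        for (jj in unique(j[ok])) {
          sel <- ok[j[ok] == jj]
          out[sel] <- archetype_rate(arch, trials[jj, ], t[sel])
        }
      }
      out
    }
  }

  spikes <- vector("list", n_neuron)
  rate_fns <- vector("list", n_neuron)
  for (k in seq_len(n_neuron)) {
    arch <- arch_list[[k]]
    fn <- make_rate_fn(arch)
    ceiling_rate <- max(arch$baseline_rate, arch$peak_rate) + 1e-9
    spikes[[k]] <- poisson_spikes(fn, c(0, session_end), ceiling_rate)
    rate_fns[[k]] <- fn
  }
  names(spikes) <- ids
  names(rate_fns) <- ids

  truth <- structure(
    list(labels = data.frame(neuron_id = ids,
                             label = vapply(arch_list, `[[`, "", "label"),
                             stringsAsFactors = FALSE),
         archetypes = stats::setNames(arch_list, ids),
         rate_fns = rate_fns,
         trial_end = trial_end,
         session_end = session_end),
    class = "odorgng_ground_truth")

  session <- new_session(session_id, animal_id, trials, spikes)
  list(session = session, truth = truth)
}

#' Write ground truth next to a session container
#'
#' @param truth an `odorgng_ground_truth`.
#' @param path session directory.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  params <- lapply(truth$archetypes, function(a) a[names(a) != "label"])
  jsonlite::write_json(
    list(labels = truth$labels, params = params),
    file.path(path, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
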