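# Sliding-bin auROC selectivity with permutation nulls.
#
# The central statistic: for each sliding bin, the area under the ROC curve
# of an ideal observer discriminating per-trial firing between a bin and the
# baseline epoch (or between go and no-go trials in the same bin), rescaled
# to auROC = 2 * (ROCarea - 0.5) in [-1, 1]. Significance is a label
# permutation test at alpha = 0.01, run separately for excitation and
# inhibition.

#' ROC area between two rate samples
#'
#' Probability that a randomly chosen value of the preferred sample exceeds a
#' randomly chosen value of the reference sample, with half credit for ties
#' (the Mann-Whitney U statistic over the product of sample sizes).
#'
#' @param preferred,reference nonempty numeric vectors (per-trial rates or
#'   counts).
#' @return value in `[0, 1]`.
#' @export
roc_area <- function(preferred, reference) {
  np <- length(preferred)
  nr <- length(reference)
  if (np == 0 || nr == 0) stop("empty sample")
  r <- rank(c(preferred, reference))
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  u / (np * nr)
}

#' Normalized auROC
#'
#' `2 * (roc_area - 0.5)`: -1 is the strongest possible preference for the
#' reference condition, +1 for the preferred condition, 0 indistinguishable.
#' Antisymmetric under swapping the samples.
#'
#' @inheritParams roc_area
#' @return value in `[-1, 1]`.
#' @export
auroc <- function(preferred, reference) {
  2 * (roc_area(preferred, reference) - 0.5)
}

# 0/1 membership matrix (n_total x n_perm): each column marks which pooled
# values land in the "preferred" group for one permutation. Group sizes are
# preserved. Reused across the bins of one series (the permutation is over
# trial labels, shared by construction).
perm_assignments <- function(n_total, n_pref, n_perm) {
  m <- matrix(0, n_total, n_perm)
  for (b in seq_len(n_perm)) m[sample.int(n_total, n_pref), b] <- 1
  m
}

#' Permutation test for an auROC value
#'
#' Pools the two samples, reassigns values to groups at random preserving
#' group sizes, and recomputes the auROC for each permutation. One-sided
#' p-values in each direction with the add-one correction, so p = 0 is
#' impossible: `p_exc = (1 + #\{perm >= observed\}) / (1 + n_permutations)`
#' and analogously for `p_inh` with `<=`.
#'
#' @inheritParams roc_area
#' @param n_permutations 1000 by convention (500 for response-dynamics
#'   summaries).
#' @param assignments optional precomputed [perm_assignments()] matrix
#'   (`n_total x n_permutations`), used to share one permutation set across
#'   the bins of a series.
#' @return list: `auroc`, `p_exc`, `p_inh`, `n_permutations`.
#' @export
permutation_test <- function(preferred, reference, n_permutations = 1000L,
                             assignments = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  np <- length(preferred)
  nr <- length(reference)
  if (np == 0 || nr == 0) stop("empty sample")
  r <- rank(c(preferred, reference))
  obs_u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  if (is.null(assignments)) {
    assignments <- perm_assignments(np + nr, np, n_permutations)
  }
  perm_u <- as.numeric(crossprod(assignments, r)) - np * (np + 1) / 2
  tol <- 1e-9
  p_exc <- (1 + sum(perm_u >= obs_u - tol)) / (1 + n_permutations)
  p_inh <- (1 + sum(perm_u <= obs_u + tol)) / (1 + n_permutations)
  list(auroc = 2 * (obs_u / (np * nr) - 0.5), p_exc = p_exc, p_inh = p_inh,
       n_permutations = n_permutations)
}

#' Sliding-bin auROC series for one neuron
#'
#' Counts spikes in 100 ms sliding bins (20 ms step) aligned to an event and
#' contrasts each bin against the baseline epoch (`vs_baseline`) or against
#' the no-go trials in the same bin (`go_vs_nogo`). Baseline reference counts
#' are taken in sub-windows of the sliding-bin width tiled across the
#' baseline epoch (the 200 ms pre-trial baseline yields two 100 ms reference
#' counts per trial), so the two samples are compared at equal exposure with
#' the same integer support. Bins whose
#' center falls after a trial's odor-port exit are dropped from that trial's
#' samples when `end_event` is set, so late bins only aggregate trials still
#' in the epoch; a bin with fewer than `min_trials` remaining is `NA`.
#'
#' @param session an `odorgng_session`.
#' @param neuron_id neuron to analyze.
#' @param trials trial subset for the (preferred) condition, typically from
#'   [trial_filter()]; a refusal propagates.
#' @param align_event event column name, e.g. `"odor_on"` or
#'   `"water_port_entry"`.
#' @param window `c(start, end)` seconds relative to the event; the default
#'   nose-poking window gives bin centers 0 to 1.8 s (91 bins).
#' @param baseline_epoch a [task_epoch()] (default `baseline_iti`); used for
#'   the `vs_baseline` contrast.
#' @param contrast `"vs_baseline"` or `"go_vs_nogo"`.
#' @param reference_trials trial subset for the reference condition
#'   (`go_vs_nogo` only).
#' @param n_permutations permutations per bin.
#' @param width,step sliding-bin geometry, seconds.
#' @param end_event per-trial truncation event (default `"port_exit"` when
#'   aligning to `odor_on`, none otherwise), or `NA` to disable.
#' @param min_trials per-bin minimum sample size.
#' @return list of class `odorgng_auroc_series`: `neuron_id`, `bin_centers`,
#'   `auroc`, `p_exc`, `p_inh`, `n` (per-bin preferred-sample size),
#'   `contrast`, `n_permutations`, `width`, `step`. Refusals from
#'   `trial_filter` are returned unchanged.
#' @export
sliding_auroc <- function(session, neuron_id, trials,
                          align_event = "odor_on",
                          window = c(0, 1.8),
                          baseline_epoch = task_epoch("baseline_iti"),
                          contrast = c("vs_baseline", "go_vs_nogo"),
                          reference_trials = NULL,
                          n_permutations = 1000L,
                          width = 0.100, step = 0.020,
                          end_event = if (align_event == "odor_on") "port_exit" else NA,
                          min_trials = 5L) {
  contrast <- match.arg(contrast)
  if (is_refusal(trials)) return(trials)
  if (contrast == "go_vs_nogo" && is_refusal(reference_trials)) {
    return(reference_trials)
  }
  spk <- session$spikes[[neuron_id]]
  if (is.null(spk)) stop("unknown neuron ", neuron_id)

  bin_counts <- function(tr) {
    aligned <- align_spikes(spk, tr[[align_event]],
                            c(window[1] - width / 2, window[2] + width / 2))
    sliding_counts(aligned, window, width = width, step = step)
  }
  sc_pref <- bin_counts(trials)
  centers <- sc_pref$window_centers

  # per-(trial, bin) inclusion under the truncation event
  inclusion <- function(tr) {
    if (is.na(end_event) || is.null(end_event)) {
      matrix(TRUE, nrow(tr), length(centers))
    } else {
      lim <- tr[[end_event]] - tr[[align_event]]
      outer(lim, centers, function(l, cc) is.na(l) | cc <= l)
    }
  }
  inc_pref <- inclusion(trials)

  if (contrast == "vs_baseline") {
    # Exposure matching: tile the baseline epoch into sub-windows of the
    # sliding-bin width, so reference counts are integers from the same
    # exposure as the bin counts and the rank statistic is exchangeable
    # under a stationary null. (Rescaling a longer baseline count instead
    # changes the count support and mis-calibrates the test.)
    bw <- epoch_windows(baseline_epoch, trials)
    dur <- bw$end - bw$start
    k <- max(1L, floor(min(dur, na.rm = TRUE) / width))
    if (min(dur, na.rm = TRUE) >= width) {
      ref_rows <- do.call(rbind, lapply(seq_len(k), function(m) {
        lo <- bw$end - m * width
        cnt <- vapply(seq_len(nrow(trials)), function(i) {
          if (is.na(lo[i])) return(NA_real_)
          sum(spk >= lo[i] & spk < lo[i] + width)
        }, numeric(1))
        cbind(trial = seq_len(nrow(trials)), count = cnt)
      }))
    } else {
      base <- epoch_count(spk, trials, baseline_epoch)
      ref_rows <- cbind(trial = seq_len(nrow(trials)),
                        count = base$count * (width / base$duration))
    }
    ref_counts <- matrix(ref_rows[, "count"], nrow(ref_rows), length(centers))
    inc_ref <- inc_pref[ref_rows[, "trial"], , drop = FALSE] &
      !is.na(ref_rows[, "count"])
  } else {
    sc_ref <- bin_counts(reference_trials)
    ref_counts <- sc_ref$counts
    inc_ref <- inclusion(reference_trials)
  }

  nb <- length(centers)
  au <- rep(NA_real_, nb)
  p_exc <- rep(NA_real_, nb)
  p_inh <- rep(NA_real_, nb)
  nn <- integer(nb)
  assign_cache <- list()
  for (j in seq_len(nb)) {
    pref <- sc_pref$counts[inc_pref[, j], j]
    ref <- ref_counts[inc_ref[, j], j]
    nn[j] <- length(pref)
    if (length(pref) < min_trials || length(ref) < min_trials) next
    key <- paste(length(pref), length(ref))
    if (is.null(assign_cache[[key]])) {
      assign_cache[[key]] <- perm_assignments(length(pref) + length(ref),
                                              length(pref), n_permutations)
    }
    res <- permutation_test(pref, ref, n_permutations,
                            assignments = assign_cache[[key]])
    au[j] <- res$auroc
    p_exc[j] <- res$p_exc
    p_inh[j] <- res$p_inh
  }
  structure(list(neuron_id = neuron_id, bin_centers = centers, auroc = au,
                 p_exc = p_exc, p_inh = p_inh, n = nn, contrast = contrast,
                 n_permutations = n_permutations, width = width, step = step),
            class = "odorgng_auroc_series")
}

# maximal runs of TRUE in a logical vector (NA counts as FALSE);
# returns data.frame(start, end, length)
sig_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Classify cue selectivity from vs-baseline series
#'
#' A neuron is go-cue selective if its go-correct vs-baseline series has at
#' least `run_length` (default 5, i.e. 100 ms) consecutive bins with
#' `p_exc < alpha` during the nose-poking window; no-go analogously. A neuron
#' qualifying in both is labeled by the longer run (ties broken by the larger
#' peak auROC).
#'
#' @param series_go,series_nogo `odorgng_auroc_series` (vs-baseline, aligned
#'   to odor onset) for go-correct and no-go-correct trials; a refusal on
#'   either side disables that side.
#' @param alpha significance level (0.01).
#' @param run_length required consecutive significant bins.
#' @return list of class `odorgng_selectivity_label`: `neuron_id`, `label`
#'   (`go_cue_selective` / `nogo_cue_selective` / `none`), `qualifying_run`
#'   (start/end bin indices or `NULL`).
#' @export
classify_cue_selective <- function(series_go, series_nogo, alpha = 0.01,
                                   run_length = 5L) {
  best_run <- function(series) {
    if (is_refusal(series) || is.null(series)) return(NULL)
    runs <- sig_runs(series$p_exc < alpha)
    runs <- runs[runs$length >= run_length, , drop = FALSE]
    if (!nrow(runs)) return(NULL)
    best <- runs[which.max(runs$length), ]
    best$peak <- max(series$auroc[best$start:best$end], na.rm = TRUE)
    best
  }
  rg <- best_run(series_go)
  rn <- best_run(series_nogo)
  nid <- if (!is_refusal(series_go) && !is.null(series_go)) {
    series_go$neuron_id
  } else if (!is_refusal(series_nogo) && !is.null(series_nogo)) {
    series_nogo$neuron_id
  } else NA_character_
  label <- "none"
  run <- NULL
  if (!is.null(rg) && is.null(rn)) {
    label <- "go_cue_selective"; run <- rg
  } else if (is.null(rg) && !is.null(rn)) {
    label <- "nogo_cue_selective"; run <- rn
  } else if (!is.null(rg) && !is.null(rn)) {
    go_wins <- rg$length > rn$length ||
      (rg$length == rn$length && rg$peak >= rn$peak)
    label <- if (go_wins) "go_cue_selective" else "nogo_cue_selective"
    run <- if (go_wins) rg else rn
  }
  structure(list(neuron_id = nid, label = label,
                 qualifying_run = if (is.null(run)) NULL else
                   c(start = run$start, end = run$end)),
            class = "odorgng_selectivity_label")
}

#' Response-shape measures from an auROC series
#'
#' Three summaries of a neuron's significant excitatory response: the time of
#' center of mass (auROC-weighted mean of significant bin times), the
#' qualifying run (the maximal block of >= `run_length` consecutive
#' significant bins containing the bin nearest the center of mass), its
#' duration (`run_length_bins * step + (width - step)`, i.e. the span of
#' window coverage), and the onset (center of the run's first bin).
#'
#' @param series an `odorgng_auroc_series`.
#' @param alpha significance level on `p_exc`.
#' @param run_length minimum consecutive significant bins for a duration.
#' @param weighted auROC-weight the center of mass (default); `FALSE` uses
#'   the unweighted mean of significant bin times.
#' @return list of class `odorgng_response_measures`: `center_of_mass`,
#'   `onset`, `duration` (seconds; onset/duration `NA` when no qualifying run
#'   contains the center of mass), `run` (bin indices or `NULL`). A refusal
#'   if the series has no significant bins.
#' @export
response_measures <- function(series, alpha = 0.01, run_length = 5L,
                              weighted = TRUE) {
  if (is_refusal(series)) return(series)
  sig <- !is.na(series$p_exc) & series$p_exc < alpha
  if (!any(sig)) return(refusal("no significant bins"))
  tt <- series$bin_centers[sig]
  ww <- if (weighted) series$auroc[sig] else rep(1, sum(sig))
  com <- sum(tt * ww) / sum(ww)
  runs <- sig_runs(sig)
  runs <- runs[runs$length >= run_length, , drop = FALSE]
  onset <- NA_real_
  duration <- NA_real_
  run <- NULL
  if (nrow(runs)) {
    nearest <- which.min(abs(series$bin_centers - com))
    containing <- runs[runs$start <= nearest & runs$end >= nearest, , drop = FALSE]
    if (nrow(containing)) {
      run <- containing[1, ]
      onset <- series$bin_centers[run$start]
      duration <- run$length * series$step + (series$width - series$step)
    }
  }
  structure(list(neuron_id = series$neuron_id, center_of_mass = com,
                 onset = onset, duration = duration,
                 run = if (is.null(run)) NULL else
                   c(start = run$start, end = run$end)),
            class = "odorgng_response_measures")
}

#' Classify reward-epoch selectivity by center of mass
#'
#' For series aligned to the water-port entry on go-correct trials (analysis
#' window entry to 1000 ms after the valve opens), a neuron is
#' waiting-selective if its center of mass lies in the 300 ms waiting epoch
#' (entry to valve opening) and drinking-selective if it lies in the drinking
#' epoch (valve opening to +1000 ms).
#'
#' @param measures an `odorgng_response_measures` (or refusal).
#' @param waiting_window,drinking_window seconds relative to water-port
#'   entry.
#' @return list of class `odorgng_reward_label`: `neuron_id`, `label`
#'   (`waiting_selective` / `drinking_selective` / `none`).
#' @export
classify_reward_selective <- function(measures,
                                      waiting_window = c(0, 0.3),
                                      drinking_window = c(0.3, 1.3)) {
  if (is_refusal(measures)) {
    return(structure(list(neuron_id = NA_character_, label = "none"),
                     class = "odorgng_reward_label"))
  }
  com <- measures$center_of_mass
  label <- if (com >= waiting_window[1] && com < waiting_window[2]) {
    "waiting_selective"
  } else if (com >= drinking_window[1] && com < drinking_window[2]) {
    "drinking_selective"
  } else "none"
  structure(list(neuron_id = measures$neuron_id, label = label),
            class = "odorgng_reward_label")
}

#' Epoch auROC per neuron group with ANOVA comparison
#'
#' For each neuron, computes one whole-epoch auROC (per-trial epoch rate vs
#' per-trial baseline rate) with permutation significance, then compares the
#' distributions across neuron groups by one-way ANOVA with Tukey's post hoc
#' test. Neurons with fewer than `min_trials` trials in the condition are
#' excluded.
#'
#' @param session an `odorgng_session`.
#' @param groups named list of neuron-id vectors.
#' @param trials trial subset defining the condition (e.g. go-correct).
#' @param epoch analysis epoch (default the full nose-poking epoch).
#' @param baseline_epoch baseline epoch.
#' @param n_permutations permutations per neuron.
#' @param alpha significance level.
#' @param min_trials minimum trial count.
#' @return list of class `odorgng_epoch_auroc_table`: `table` (data.frame
#'   `neuron_id`, `group`, `auroc`, `p_exc`, `p_inh`, `significance`),
#'   `anova_p`, `tukey` (matrix from [stats::TukeyHSD()] or `NULL`), or a
#'   refusal when fewer than 2 groups have >= 2 neurons.
#' @export
epoch_auroc_table <- function(session, groups, trials,
                              epoch = task_epoch("nose_poking"),
                              baseline_epoch = task_epoch("baseline_iti"),
                              n_permutations = 1000L, alpha = 0.01,
                              min_trials = 5L) {
  if (is_refusal(trials)) return(trials)
  rows <- list()
  for (g in names(groups)) {
    for (nid in groups[[g]]) {
      spk <- session$spikes[[nid]]
      if (is.null(spk)) next
      if (nrow(trials) < min_trials) next
      pref <- epoch_rate(spk, trials, epoch)
      ref <- epoch_rate(spk, trials, baseline_epoch)
      ok <- !is.na(pref) & !is.na(ref)
      if (sum(ok) < min_trials) next
      res <- permutation_test(pref[ok], ref[ok], n_permutations)
      sig <- if (res$p_exc < alpha) "excited" else
        if (res$p_inh < alpha) "inhibited" else "ns"
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = nid, group = g, auroc = res$auroc,
        p_exc = res$p_exc, p_inh = res$p_inh, significance = sig,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(refusal("no neurons passed the trial minimum"))
  counts <- table(tab$group)
  if (sum(counts >= 2) < 2) {
    return(structure(list(table = tab, anova_p = NA_real_, tukey = NULL),
                     class = "odorgng_epoch_auroc_table"))
  }
  fit <- stats::aov(auroc ~ group, data = tab)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tukey <- stats::TukeyHSD(fit)$group
  structure(list(table = tab, anova_p = anova_p, tukey = tukey),
            class = "odorgng_epoch_auroc_table")
}
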