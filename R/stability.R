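# Trial-progression and covariate correlation analyses with shuffle
# significance: are go-cue responses stable across a session, and are they
# independent of odor-sampling duration?

#' Stability of the go-cue response across trial order
#'
#' Correlates each go-correct trial's nose-poking-epoch firing rate (minus
#' the neuron's whole-session mean inter-trial-interval rate, a constant
#' offset kept for axis comparability) with the order of the go trial from
#' the start of the session. Significance is judged against 1000
#' trial-shuffled correlations: below their 0.5th percentile is a negative
#' correlation, above the 99.5th a positive one (a two-tailed 1% criterion).
#'
#' @param session an `odorgng_session`.
#' @param neuron_id neuron to analyze.
#' @param n_shuffles shuffled datasets (1000).
#' @param epoch rate epoch (default the go-cue nose-poking epoch).
#' @param min_trials minimum go-correct trials (10).
#' @return list of class `odorgng_stability`: `neuron_id`, `r`,
#'   `shuffle_bounds` (0.5th/99.5th percentiles), `label`
#'   (`negative`/`ns`/`positive`), `n_trials`; a refusal below the trial
#'   minimum. Constant rates give `r = NA`, label `ns`.
#' @export
trial_order_stability <- function(session, neuron_id, n_shuffles = 1000L,
                                  epoch = task_epoch("nose_poking"),
                                  min_trials = 10L) {
  go_tr <- trials_of(session, type = "go", outcome = "correct")
  if (nrow(go_tr) < min_trials) {
    return(refusal(sprintf("only %d go-correct trials (minimum %d)",
                           nrow(go_tr), min_trials)))
  }
  spk <- session$spikes[[neuron_id]]
  if (is.null(spk)) stop("unknown neuron ", neuron_id)
  rate <- epoch_rate(spk, go_tr, epoch) - iti_mean_rate(session, neuron_id)
  ord <- seq_len(nrow(go_tr))
  if (stats::sd(rate) == 0) {
    return(structure(list(neuron_id = neuron_id, r = NA_real_,
                          shuffle_bounds = c(NA_real_, NA_real_),
                          label = "ns", n_trials = length(ord)),
                     class = "odorgng_stability"))
  }
  r <- stats::cor(rate, ord)
  shuf <- vapply(seq_len(n_shuffles), function(b) {
    stats::cor(sample(rate), ord)
  }, numeric(1))
  bounds <- stats::quantile(shuf, c(0.005, 0.995), names = FALSE)
  label <- if (r < bounds[1]) "negative" else
    if (r > bounds[2]) "positive" else "ns"
  structure(list(neuron_id = neuron_id, r = r, shuffle_bounds = bounds,
                 label = label, n_trials = length(ord)),
            class = "odorgng_stability")
}

#' Whole-session mean inter-trial-interval firing rate
#'
#' Mean rate over the gaps between the end of one trial's events and the next
#' trial's odor-port entry.
#'
#' @inheritParams trial_order_stability
#' @return Hz (scalar).
#' @export
iti_mean_rate <- function(session, neuron_id) {
  tr <- session$trials
  spk <- session$spikes[[neuron_id]]
  last_event <- pmax(tr$port_exit,
                     ifelse(is.na(tr$water_port_entry), -Inf, tr$water_port_entry + 0.5),
                     ifelse(is.na(tr$water_valve_open), -Inf, tr$water_valve_open + 1.5))
  gap_start <- c(0, last_event[-nrow(tr)])
  gap_end <- tr$odor_on
  ok <- gap_end > gap_start
  total_time <- sum(gap_end[ok] - gap_start[ok])
  n <- sum(vapply(which(ok), function(i) {
    sum(spk >= gap_start[i] & spk < gap_end[i])
  }, numeric(1)))
  n / total_time
}

#' Correlation between epoch firing rate and a per-trial covariate
#'
#' Pearson correlation (with the standard t-based p-value) between a
#' per-trial epoch rate and a behavioral covariate such as the nose-poking
#' (odor sampling) duration, pooled across trials for one neuron. A Spearman
#' variant is available by flag.
#'
#' @param session an `odorgng_session`.
#' @param neuron_id neuron to analyze.
#' @param trials trial subset.
#' @param covariate numeric per-trial covariate (seconds), or a function of
#'   the trial table (default: nose-poking duration).
#' @param epoch rate epoch (default the late nose-poking phase).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_trials minimum trial count (10).
#' @return list: `r`, `p`, `n`; a refusal below the minimum.
#' @export
rate_covariate_correlation <- function(session, neuron_id, trials,
                                       covariate = function(tr) tr$port_exit - tr$odor_on,
                                       epoch = task_epoch("late_nose_poking"),
                                       method = c("pearson", "spearman"),
                                       min_trials = 10L) {
  method <- match.arg(method)
  if (is_refusal(trials)) return(trials)
  cov <- if (is.function(covariate)) covariate(trials) else covariate
  spk <- session$spikes[[neuron_id]]
  if (is.null(spk)) stop("unknown neuron ", neuron_id)
  rate <- epoch_rate(spk, trials, epoch)
  ok <- !is.na(rate) & !is.na(cov)
  if (sum(ok) < min_trials) {
    return(refusal(sprintf("only %d usable trials (minimum %d)",
                           sum(ok), min_trials)))
  }
  if (stats::sd(cov[ok]) == 0) stop("zero-variance covariate")
  if (stats::sd(rate[ok]) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ct <- stats::cor.test(rate[ok], cov[ok], method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
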