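# Binned and smoothed firing-rate estimation.
#
# Conventions: 20 ms bins, Gaussian smoothing with a 60 ms kernel (SD), and
# 100 ms sliding windows advanced in 20 ms steps, timestamped at window
# centers. Smoothing is display/regression plumbing only; all selectivity
# statistics operate on raw counts.

#' Peri-event time histogram
#'
#' Bins aligned spike times at `bin_width` and optionally smooths each
#' trial's count vector with a Gaussian kernel. The kernel is truncated to
#' the analysis window and renormalized per source bin, so the total spike
#' count in the window is conserved exactly and rates show no spurious dips
#' at window edges.
#'
#' @param aligned list of per-trial relative spike times (from
#'   [align_spikes()]).
#' @param window `c(start, end)` relative seconds.
#' @param bin_width seconds, default 0.020.
#' @param smoothing_sd Gaussian SD in seconds; 0 disables smoothing. The
#'   60 ms kernel of the analysis convention is interpreted as SD = 60 ms;
#'   pass `fwhm = TRUE` to interpret it as full width at half maximum
#'   instead.
#' @param fwhm logical, see `smoothing_sd`.
#' @return list of class `odorgng_binned_rate`: `bin_centers`, `rate` (trials
#'   x bins matrix, Hz), `mean` (trial-averaged Hz), `bin_width`,
#'   `smoothing_sd`.
#' @export
compute_peth <- function(aligned, window, bin_width = 0.020,
                         smoothing_sd = 0.060, fwhm = FALSE) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  stopifnot(length(window) == 2, window[1] < window[2])
  if (fwhm && smoothing_sd > 0) smoothing_sd <- smoothing_sd / 2.3548200450309493
  edges <- seq(window[1], window[2], by = bin_width)
  nb <- length(edges) - 1L
  centers <- edges[-length(edges)] + bin_width / 2
  counts <- t(vapply(aligned, function(s) {
    bincount(s, edges)
  }, numeric(nb)))
  if (length(aligned) == 1L) counts <- matrix(counts, nrow = 1L)
  if (smoothing_sd > 0) {
    counts <- counts %*% smoothing_matrix(centers, smoothing_sd)
  }
  rate <- counts / bin_width
  structure(list(bin_centers = centers, rate = rate,
                 mean = colMeans(rate), bin_width = bin_width,
                 smoothing_sd = smoothing_sd),
            class = "odorgng_binned_rate")
}

# counts per half-open bin [edge_i, edge_{i+1})
bincount <- function(x, edges) {
  if (!length(x)) return(numeric(length(edges) - 1L))
  idx <- findInterval(x, edges, left.open = FALSE)
  idx <- idx[idx >= 1L & idx <= length(edges) - 1L & x < edges[length(edges)]]
  tabulate(idx, nbins = length(edges) - 1L)
}

# row-stochastic Gaussian kernel matrix: mass of each source bin is
# redistributed over the window, conserving totals under truncation
smoothing_matrix <- function(centers, sd) {
  d <- outer(centers, centers, "-")
  g <- exp(-d^2 / (2 * sd^2))
  g / rowSums(g)
}

#' Sliding-window spike counts
#'
#' Counts in half-open windows `[center - width/2, center + width/2)` whose
#' centers advance in `step` increments across `window`; the window centered
#' at 0 sits on the alignment event.
#'
#' @inheritParams compute_peth
#' @param width window width, seconds (default 0.100).
#' @param step center spacing, seconds (default 0.020).
#' @return list of class `odorgng_sliding_counts`: `window_centers`, `counts`
#'   (trials x windows integer matrix), `width`, `step`.
#' @export
sliding_counts <- function(aligned, window, width = 0.100, step = 0.020) {
  stopifnot(width >= step, length(window) == 2, window[1] <= window[2])
  centers <- seq(window[1], window[2], by = step)
  nw <- length(centers)
  lo <- centers - width / 2
  hi <- centers + width / 2
  counts <- t(vapply(aligned, function(s) {
    if (!length(s)) return(integer(nw))
    # count in [lo, hi) = #(s < hi) - #(s < lo)
    findInterval(hi, s, left.open = TRUE) -
      findInterval(lo, s, left.open = TRUE)
  }, integer(nw)))
  if (length(aligned) == 1L) counts <- matrix(counts, nrow = 1L)
  structure(list(window_centers = centers, counts = counts,
                 width = width, step = step),
            class = "odorgng_sliding_counts")
}

#' Per-trial firing rate in a behavioral epoch
#'
#' The epoch is resolved per trial (so epochs ending at a trial-specific
#' event, e.g. the odor-port exit, use that trial's realized duration) and
#' the rate is the spike count over the realized duration.
#'
#' @param spike_times sorted spike times, seconds (session clock).
#' @param trials trial table rows.
#' @param epoch a [task_epoch()].
#' @return numeric vector, Hz per trial; `NA` where the epoch is undefined on
#'   a trial (missing event).
#' @export
epoch_rate <- function(spike_times, trials, epoch) {
  w <- epoch_windows(epoch, trials)
  dur <- w$end - w$start
  if (any(!is.na(dur) & dur <= 0)) stop("zero-duration epoch")
  vapply(seq_len(nrow(w)), function(i) {
    if (is.na(w$start[i]) || is.na(w$end[i])) return(NA_real_)
    n <- sum(spike_times >= w$start[i] & spike_times < w$end[i])
    n / dur[i]
  }, numeric(1))
}

#' Per-trial spike count in a behavioral epoch
#'
#' @inheritParams epoch_rate
#' @return list with `count` and `duration` vectors per trial.
#' @export
epoch_count <- function(spike_times, trials, epoch) {
  w <- epoch_windows(epoch, trials)
  count <- vapply(seq_len(nrow(w)), function(i) {
    if (is.na(w$start[i]) || is.na(w$end[i])) return(NA_real_)
    sum(spike_times >= w$start[i] & spike_times < w$end[i])
  }, numeric(1))
  list(count = count, duration = w$end - w$start)
}
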