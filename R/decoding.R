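# Pseudo-population single-trial go/no-go decoding with a linear SVM.
#
# Neurons recorded in different sessions are concatenated into pseudo-trials
# matched only by trial type and within-type chronological order (the k-th
# correct go trial of each neuron forms pseudo-trial k), 40 trials per type
# from the start of the session. Accuracy is 10-fold cross-validated;
# chance is 50% for the two balanced classes.

#' Build a pseudo-population of sliding-window spike counts
#'
#' @param sessions an `odorgng_session` or list of sessions.
#' @param window `c(start, end)` seconds relative to `align_event`.
#' @param n_per_type pseudo-trials per trial type (40, taken from the start
#'   of each session).
#' @param width,step sliding-window geometry, seconds.
#' @param align_event alignment event column.
#' @return list of class `odorgng_pseudopopulation`: `counts` (array
#'   `[2*n_per_type, neurons, windows]`), `labels` (`go`/`nogo` per
#'   pseudo-trial), `window_centers`, `neuron_ids`, `dropped` (neurons with
#'   too few trials), `behavioral_accuracy` (mean over sessions).
#' @export
build_pseudopopulation <- function(sessions, window = c(-0.2, 1.8),
                                   n_per_type = 40L, width = 0.100,
                                   step = 0.020, align_event = "odor_on") {
  if (inherits(sessions, "odorgng_session")) sessions <- list(sessions)
  centers <- seq(window[1], window[2], by = step)
  nw <- length(centers)
  mats <- list()
  dropped <- character(0)
  acc <- vapply(sessions, `[[`, numeric(1), "behavioral_accuracy")
  for (s in sessions) {
    go_tr <- trials_of(s, type = "go", outcome = "correct")
    ng_tr <- trials_of(s, type = "nogo", outcome = "correct")
    enough <- nrow(go_tr) >= n_per_type && nrow(ng_tr) >= n_per_type
    for (nid in names(s$spikes)) {
      key <- paste(s$session_id, nid, sep = "/")
      if (!enough) {
        dropped <- c(dropped, key)
        next
      }
      spk <- s$spikes[[nid]]
      cnt <- function(tr) {
        aligned <- align_spikes(spk, tr[[align_event]][seq_len(n_per_type)],
                                c(window[1] - width / 2, window[2] + width / 2))
        sliding_counts(aligned, window, width = width, step = step)$counts
      }
      mats[[key]] <- rbind(cnt(go_tr), cnt(ng_tr))  # (2*n, nw)
    }
  }
  if (!length(mats)) stop("no neuron has enough trials")
  counts <- array(0, dim = c(2L * n_per_type, length(mats), nw),
                  dimnames = list(NULL, names(mats), NULL))
  for (i in seq_along(mats)) counts[, i, ] <- mats[[i]]
  structure(list(counts = counts,
                 labels = rep(c("go", "nogo"), each = n_per_type),
                 window_centers = centers, neuron_ids = names(mats),
                 dropped = dropped,
                 behavioral_accuracy = mean(acc, na.rm = TRUE)),
            class = "odorgng_pseudopopulation")
}

#' Cross-validated linear-SVM decoding accuracy
#'
#' Stratified k-fold cross-validation of a linear-kernel SVM (cost fixed at
#' the conventional default, C = 1): the trials are partitioned into k equal
#' parts, each part is tested once on a classifier trained on the rest, and
#' the mean held-out accuracy over the folds is the decoding accuracy. Fold
#' assignment uses the caller's RNG state and precedes any computation on the
#' features.
#'
#' @param X trials x neurons numeric matrix.
#' @param labels factor-like vector with two classes.
#' @param k folds (10).
#' @param cost SVM regularization constant.
#' @return list: `accuracy` (%), `fold_accuracy` (per fold, %), `sd` (over
#'   folds).
#' @export
decode <- function(X, labels, k = 10L, cost = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need two classes")
  n <- nrow(X)
  fold <- integer(n)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  acc <- vapply(seq_len(k), function(f) {
    test <- which(fold == f)
    train <- which(fold != f)
    Xtr <- X[train, , drop = FALSE]
    keep <- apply(Xtr, 2, function(v) stats::sd(v) > 0)
    if (!any(keep)) return(50)
    fit <- e1071::svm(Xtr[, keep, drop = FALSE], labels[train],
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- stats::predict(fit, X[test, keep, drop = FALSE])
    100 * mean(pred == labels[test])
  }, numeric(1))
  list(accuracy = mean(acc), fold_accuracy = acc, sd = stats::sd(acc))
}

#' Decoding accuracy over time
#'
#' Runs the cross-validated decoder in every sliding window and reports the
#' first window at which accuracy reaches the animals' behavioral accuracy.
#'
#' @param pp an `odorgng_pseudopopulation`.
#' @param k folds.
#' @param cost SVM cost.
#' @param behavioral_accuracy reference level in percent (default taken from
#'   the pseudo-population's sessions).
#' @return list of class `odorgng_decoding_result`: `window_centers`,
#'   `accuracy` (%), `sd` (over folds), `behavioral_accuracy`, `chance`
#'   (50), `crossing_time` (seconds, `NA` when never reached).
#' @export
decode_time_course <- function(pp, k = 10L, cost = 1,
                               behavioral_accuracy = 100 * pp$behavioral_accuracy) {
  nw <- length(pp$window_centers)
  acc <- numeric(nw)
  sdv <- numeric(nw)
  for (j in seq_len(nw)) {
    res <- decode(pp$counts[, , j, drop = TRUE], pp$labels, k = k, cost = cost)
    acc[j] <- res$accuracy
    sdv[j] <- res$sd
  }
  cross <- which(acc >= behavioral_accuracy)
  structure(list(window_centers = pp$window_centers, accuracy = acc,
                 sd = sdv, behavioral_accuracy = behavioral_accuracy,
                 chance = 50,
                 crossing_time = if (length(cross)) {
                   pp$window_centers[cross[1]]
                 } else NA_real_),
            class = "odorgng_decoding_result")
}

#' Decoding accuracy versus population size
#'
#' For each size, decodes with `n_resamples` random neuron subsets at one
#' fixed window and averages the accuracy.
#'
#' @param pp an `odorgng_pseudopopulation`.
#' @param window_center window to decode at, seconds (nearest center used).
#' @param sizes neuron counts to sweep.
#' @param n_resamples random subsets per size (20).
#' @param k folds.
#' @param cost SVM cost.
#' @return data.frame: `size`, `accuracy` (mean %), `sd` (over subsets).
#' @export
decode_vs_population_size <- function(pp, window_center, sizes,
                                      n_resamples = 20L, k = 10L, cost = 1) {
  j <- which.min(abs(pp$window_centers - window_center))
  X <- pp$counts[, , j, drop = TRUE]
  n_neuron <- ncol(X)
  if (any(sizes > n_neuron)) stop("size exceeds available neurons")
  out <- lapply(sizes, function(sz) {
    accs <- vapply(seq_len(n_resamples), function(b) {
      sel <- sample.int(n_neuron, sz)
      decode(X[, sel, drop = FALSE], pp$labels, k = k, cost = cost)$accuracy
    }, numeric(1))
    data.frame(size = sz, accuracy = mean(accs), sd = stats::sd(accs))
  })
  do.call(rbind, out)
}
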