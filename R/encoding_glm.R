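# Encoding model: lagged binary task-event predictors regressed on smoothed
# firing rates, with per-variable relative contributions.
#
# Six predictor groups tile the period from odor onset to 500 ms after the
# odor-port exit: odor presentation lags (25 bins x go/no-go), late
# nose-poking lags anchored at odor offset (22 go / 13 no-go bins, the
# condition medians of the offset-to-exit period), and pre-exit lags
# (-300 to 0 ms, 15 bins x go/no-go). The model is an identity-link Gaussian
# regression of the smoothed rate (a multiple linear regression), and each
# variable's relative contribution is the normalized drop in 5-fold
# cross-validated explained variance when the variable is excluded.

.glm_groups <- c("go_early", "nogo_early", "go_late", "nogo_late",
                 "pre_go_exit", "pre_nogo_exit")

#' Build the encoding-model design matrix for one neuron
#'
#' Rows are 20 ms bins concatenated over trials, restricted to the period
#' from odor onset to 500 ms after the odor-port exit. Each predictor column
#' is a binary indicator of one lag after its group's anchoring event on
#' trials of its condition (lag support is truncated at the odor-port exit on
#' early-exit trials), then z-scored over all rows. The response is the
#' neuron's smoothed firing rate per bin.
#'
#' @param session an `odorgng_session`.
#' @param neuron_id neuron to model.
#' @param trials trial subset (default: all correct go and no-go trials).
#' @param bin_width seconds (0.020).
#' @param smoothing_sd Gaussian smoothing SD for the response, seconds.
#' @param pre_window pre-exit predictor window length, seconds (0.3, 0.2 or
#'   0.1, giving 15/10/5 lag columns per condition).
#' @param late_bins named lag counts for the late nose-poking groups
#'   (defaults `c(go = 22, nogo = 13)`, the canonical architecture for the
#'   task's median poke durations).
#' @param tail_after_exit row support after the odor-port exit, seconds.
#' @return list of class `odorgng_design`: `X` (raw binary), `X_norm`
#'   (z-scored), `y` (Hz), `trial_id` (per row), `bin_index` (per row, from
#'   odor onset), `groups` (named list of column indices), `n_trials`.
#' @export
build_design_matrix <- function(session, neuron_id, trials = NULL,
                                bin_width = 0.020, smoothing_sd = 0.060,
                                pre_window = 0.3,
                                late_bins = c(go = 22L, nogo = 13L),
                                tail_after_exit = 0.5) {
  if (is.null(trials)) {
    trials <- trials_of(session, type = c("go", "nogo"), outcome = "correct")
  }
  if (is_refusal(trials)) return(trials)
  spk <- session$spikes[[neuron_id]]
  if (is.null(spk)) stop("unknown neuron ", neuron_id)
  n_pre <- as.integer(round(pre_window / bin_width))
  n_early <- 25L
  late_anchor <- 25L  # first bin after the 500 ms odor presentation
  cols <- list(
    go_early = n_early, nogo_early = n_early,
    go_late = as.integer(late_bins[["go"]]),
    nogo_late = as.integer(late_bins[["nogo"]]),
    pre_go_exit = n_pre, pre_nogo_exit = n_pre)
  offsets <- cumsum(c(0, unlist(cols)))
  p <- offsets[length(offsets)]
  groups <- stats::setNames(
    lapply(seq_along(cols), function(i) (offsets[i] + 1L):offsets[i + 1L]),
    names(cols))

  xs <- list(); ys <- list(); tid <- list(); bidx <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    poke <- tr$port_exit - tr$odor_on
    nbin <- floor((poke + tail_after_exit) / bin_width)
    if (nbin < 1) next
    j <- 0:(nbin - 1L)                      # bin index from odor onset
    centers <- (j + 0.5) * bin_width
    cond <- tr$trial_type                   # "go" or "nogo"
    Xi <- matrix(0, nbin, p)
    early_g <- paste0(if (cond == "go") "go" else "nogo", "_early")
    late_g <- paste0(if (cond == "go") "go" else "nogo", "_late")
    pre_g <- paste0("pre_", if (cond == "go") "go" else "nogo", "_exit")
    # odor-presentation lags: bin j == lag, lags 0..24
    lag <- j[j < n_early]
    Xi[cbind(lag + 1L, groups[[early_g]][lag + 1L])] <- 1
    # late nose-poking lags anchored at odor offset, truncated at exit
    nl <- cols[[late_g]]
    lag2 <- j[j >= late_anchor & j < late_anchor + nl & centers <= poke]
    if (length(lag2)) {
      Xi[cbind(lag2 + 1L, groups[[late_g]][lag2 - late_anchor + 1L])] <- 1
    }
    # pre-exit lags: the n_pre bins before the exit bin
    e <- round(poke / bin_width)
    lag3 <- j[j >= e - n_pre & j < e]
    if (length(lag3)) {
      Xi[cbind(lag3 + 1L, groups[[pre_g]][e - lag3])] <- 1
    }
    # response: smoothed rate on this trial's bins
    aligned <- align_spikes(spk, tr$odor_on, c(0, nbin * bin_width))
    counts <- bincount(aligned[[1]], seq(0, nbin * bin_width, by = bin_width))
    if (smoothing_sd > 0 && nbin > 1) {
      counts <- as.numeric(counts %*% smoothing_matrix(centers, smoothing_sd))
    }
    xs[[length(xs) + 1L]] <- Xi
    ys[[length(ys) + 1L]] <- counts / bin_width
    tid[[length(tid) + 1L]] <- rep(tr$trial_index, nbin)
    bidx[[length(bidx) + 1L]] <- j
  }
  X <- do.call(rbind, xs)
  colnames(X) <- unlist(lapply(names(cols), function(g) {
    paste0(g, "_", seq_len(cols[[g]]))
  }))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  X_norm <- sweep(X, 2, mu, "-")
  nz <- sdv > 0
  X_norm[, nz] <- sweep(X_norm[, nz, drop = FALSE], 2, sdv[nz], "/")
  structure(list(X = X, X_norm = X_norm, y = unlist(ys),
                 trial_id = unlist(tid), bin_index = unlist(bidx),
                 groups = groups, n_trials = nrow(trials)),
            class = "odorgng_design")
}

# least squares with intercept; tiny ridge fallback on rank deficiency
ls_fit <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  if (nrow(Xi) < ncol(Xi)) {
    stop("fewer rows than columns; include more trials")
  }
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    xtx <- crossprod(Xi)
    lam <- 1e-8 * mean(diag(xtx))
    beta <- solve(xtx + lam * diag(ncol(Xi)), crossprod(Xi, y))
    beta <- as.numeric(beta)
    attr(beta, "ridge") <- TRUE
  } else {
    beta <- qr.coef(qr_x, y)
  }
  names(beta) <- colnames(Xi)
  beta
}

#' Fit the full encoding model
#'
#' Ordinary least squares of the smoothed rate on all normalized predictors
#' plus an intercept. With noiseless responses constructed from known
#' coefficients, recovers them to numerical tolerance.
#'
#' @param design an `odorgng_design` (or a plain matrix with `y` supplied).
#' @param y response override.
#' @return list of class `odorgng_glm_fit`: `beta0`, `beta` (per predictor
#'   column), `fitted`, `r_squared` (in-sample).
#' @export
fit_full <- function(design, y = NULL) {
  X <- if (inherits(design, "odorgng_design")) design$X_norm else design
  if (is.null(y)) y <- design$y
  beta <- ls_fit(X, y)
  fitted <- as.numeric(cbind(1, X) %*% beta)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else NA_real_
  structure(list(beta0 = beta[1], beta = beta[-1], fitted = fitted,
                 r_squared = r2),
            class = "odorgng_glm_fit")
}

# assign trials to k folds (uses the caller's RNG state)
make_folds <- function(trial_id, k) {
  ids <- unique(trial_id)
  if (length(ids) < k) stop("fewer trials than folds")
  shuffled <- sample(ids)
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(ids)),
                             shuffled)
  unname(fold_of[as.character(trial_id)])
}

#' Cross-validated encoding-model machinery
#'
#' Fits the full model on k trial-wise folds (folds partition trials, never
#' bins) and retains per-fold coefficients and held-out rows, so partial
#' models (zeroed or refitted coefficient sets) can be scored without
#' repeating the regression.
#'
#' @param design an `odorgng_design`.
#' @param k folds (5).
#' @param fold_assign optional per-row fold assignment (for reproducibility;
#'   default drawn from the current RNG state).
#' @param lasso fit per-fold coefficients by lasso (`glmnet`) at the
#'   MSE-minimizing lambda chosen by 5-fold cross-validation instead of
#'   ordinary least squares.
#' @return list of class `odorgng_glm_cv`: `folds` (per fold: `beta`
#'   including intercept, `test` row indices), `design`, `r2_full`,
#'   `fold_assign`.
#' @export
glm_cv <- function(design, k = 5L, fold_assign = NULL, lasso = FALSE) {
  stopifnot(inherits(design, "odorgng_design"))
  X <- design$X_norm
  y <- design$y
  if (is.null(fold_assign)) fold_assign <- make_folds(design$trial_id, k)
  lambda <- NULL
  if (lasso) {
    cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = fold_assign,
                               standardize = FALSE)
    lambda <- cvfit$lambda.min
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold_assign == f)
    train <- which(fold_assign != f)
    if (lasso) {
      fit <- glmnet::glmnet(X[train, , drop = FALSE], y[train], alpha = 1,
                            lambda = lambda, standardize = FALSE)
      beta <- c(as.numeric(fit$a0), as.numeric(fit$beta))
    } else {
      beta <- as.numeric(ls_fit(X[train, , drop = FALSE], y[train]))
    }
    list(beta = beta, test = test)
  })
  obj <- structure(list(folds = folds, design = design, k = k,
                        fold_assign = fold_assign, lasso = lasso),
                   class = "odorgng_glm_cv")
  obj$r2_full <- cv_r2_zeroed(obj, integer(0))
  obj
}

# pooled held-out R^2 with an optional set of predictor columns zeroed
# (no-refit partial models); SST about the overall response mean
cv_r2_zeroed <- function(cv, zero_cols) {
  X <- cv$design$X_norm
  y <- cv$design$y
  sse <- 0
  for (f in cv$folds) {
    beta <- f$beta
    if (length(zero_cols)) beta[zero_cols + 1L] <- 0
    yhat <- beta[1] + as.numeric(X[f$test, , drop = FALSE] %*% beta[-1])
    sse <- sse + sum((y[f$test] - yhat)^2)
  }
  1 - sse / sum((y - mean(y))^2)
}

# pooled held-out R^2 refitting each fold without the given columns
cv_r2_refit <- function(cv, drop_cols) {
  X <- cv$design$X_norm
  y <- cv$design$y
  keep <- setdiff(seq_len(ncol(X)), drop_cols)
  sse <- 0
  for (f in cv$folds) {
    train <- setdiff(seq_along(y), f$test)
    beta <- ls_fit(X[train, keep, drop = FALSE], y[train])
    yhat <- beta[1] + as.numeric(X[f$test, keep, drop = FALSE] %*% beta[-1])
    sse <- sse + sum((y[f$test] - yhat)^2)
  }
  1 - sse / sum((y - mean(y))^2)
}

#' Cross-validated explained variance of the full model
#'
#' `R^2 = 1 - SSE/SST` pooled over held-out bins of trial-wise folds; may be
#' negative for uninformative models.
#'
#' @inheritParams glm_cv
#' @return numeric scalar.
#' @export
cross_validated_R2 <- function(design, k = 5L, fold_assign = NULL) {
  glm_cv(design, k = k, fold_assign = fold_assign)$r2_full
}

#' Relative contribution of each behavioral variable
#'
#' For each of the six predictor groups, the drop in cross-validated
#' explained variance when the group is excluded, normalized over groups:
#' `(1 - R2_p,i / R2_f) / sum_j (1 - R2_p,j / R2_f)`, with negative terms set
#' to zero before normalization. Exclusion is by zeroing the group's fitted
#' coefficients (`no_refit`, the default), by re-estimating without the
#' group's columns (`refit`), or by zeroing lasso-fitted coefficients
#' (`no_refit_lasso`).
#'
#' @param cv an `odorgng_glm_cv` (fit with `lasso = TRUE` for
#'   `no_refit_lasso`), or an `odorgng_design` (a cv fit is built with the
#'   current RNG state).
#' @param mode exclusion approach.
#' @return list of class `odorgng_contributions`: `contribution` (named,
#'   sums to 1 when any term is positive), `drop` (raw `1 - R2_p/R2_f`),
#'   `r2_full`, `r2_partial`, `mode`; a refusal when `R2_f <= 0`.
#' @export
relative_contributions <- function(cv, mode = c("no_refit", "refit",
                                                "no_refit_lasso")) {
  mode <- match.arg(mode)
  if (inherits(cv, "odorgng_design")) {
    cv <- glm_cv(cv, lasso = (mode == "no_refit_lasso"))
  }
  if (mode == "no_refit_lasso" && !isTRUE(cv$lasso)) {
    stop("no_refit_lasso requires glm_cv(..., lasso = TRUE)")
  }
  r2f <- cv$r2_full
  if (is.na(r2f) || r2f <= 0) {
    return(refusal("full-model cross-validated R^2 is not positive"))
  }
  groups <- cv$design$groups
  r2p <- vapply(groups, function(colsg) {
    if (mode == "refit") cv_r2_refit(cv, colsg) else cv_r2_zeroed(cv, colsg)
  }, numeric(1))
  drop <- 1 - r2p / r2f
  pos <- pmax(drop, 0)
  contribution <- if (sum(pos) > 0) pos / sum(pos) else pos
  structure(list(contribution = contribution, drop = drop, r2_full = r2f,
                 r2_partial = r2p, mode = mode),
            class = "odorgng_contributions")
}

#' Significance of relative contributions by random-coefficient controls
#'
#' Control distribution: the performance drop from zeroing 10% of all
#' predictor columns chosen uniformly at random (roughly one group's worth),
#' repeated `n_controls` times under the no-refit scheme. A variable whose
#' observed drop exceeds the control mean + 2 SD is labeled `positive`,
#' below mean - 2 SD `negative`, otherwise `ns`.
#'
#' @param cv an `odorgng_glm_cv`.
#' @param n_controls control draws (1000).
#' @param frac fraction of predictor columns zeroed per control (0.10).
#' @return list of class `odorgng_contribution_significance`: `significance`
#'   (named labels), `drop` (observed per group), `control_mean`,
#'   `control_sd`; a refusal when `R2_f <= 0`.
#' @export
contribution_significance <- function(cv, n_controls = 1000L, frac = 0.10) {
  stopifnot(inherits(cv, "odorgng_glm_cv"))
  r2f <- cv$r2_full
  if (is.na(r2f) || r2f <= 0) {
    return(refusal("full-model cross-validated R^2 is not positive"))
  }
  p <- ncol(cv$design$X_norm)
  m <- as.integer(ceiling(frac * p))
  ctrl <- vapply(seq_len(n_controls), function(b) {
    1 - cv_r2_zeroed(cv, sample.int(p, m)) / r2f
  }, numeric(1))
  mu <- mean(ctrl)
  sdv <- stats::sd(ctrl)
  drop <- vapply(cv$design$groups, function(colsg) {
    1 - cv_r2_zeroed(cv, colsg) / r2f
  }, numeric(1))
  sig <- ifelse(drop > mu + 2 * sdv, "positive",
                ifelse(drop < mu - 2 * sdv, "negative", "ns"))
  structure(list(significance = sig, drop = drop,
                 control_mean = mu, control_sd = sdv),
            class = "odorgng_contribution_significance")
}

#' Contribution robustness to the pre-exit window length
#'
#' Rebuilds the design with pre-exit windows of 100/200/300 ms (5/10/15 lag
#' columns per condition) and recomputes contributions for each setting.
#'
#' @param session an `odorgng_session`.
#' @param neuron_id neuron to model.
#' @param trials trial subset (default correct go/no-go).
#' @param pre_windows window lengths, seconds.
#' @param k folds.
#' @param mode exclusion approach.
#' @return named list of `odorgng_contributions`, one per window length.
#' @export
window_robustness <- function(session, neuron_id, trials = NULL,
                              pre_windows = c(0.1, 0.2, 0.3), k = 5L,
                              mode = "no_refit") {
  out <- lapply(pre_windows, function(w) {
    dm <- build_design_matrix(session, neuron_id, trials, pre_window = w)
    relative_contributions(glm_cv(dm, k = k), mode = mode)
  })
  names(out) <- paste0(pre_windows * 1000, "ms")
  out
}
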