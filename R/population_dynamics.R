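# Population trajectory analysis: condition x time auROC matrix, projection
# onto the leading principal components of the nose-poking epoch, and
# go/no-go trajectory separation against a pre-odor baseline threshold.

#' Assemble the population auROC matrix
#'
#' Stacks per-neuron vs-baseline auROC series into a (2 conditions x 91 time
#' bins) x N matrix: rows 1..91 are the go-condition bins, rows 92..182 the
#' no-go bins. Neurons whose series is a refusal (or contains missing bins)
#' are dropped, never imputed.
#'
#' @param series_go,series_nogo named lists of `odorgng_auroc_series` (or
#'   refusals), indexed by neuron.
#' @return list of class `odorgng_population_matrix`: `matrix` (182 x N),
#'   `bin_centers`, `neuron_ids`.
#' @export
build_population_matrix <- function(series_go, series_nogo) {
  ids <- intersect(names(series_go), names(series_nogo))
  cols <- list()
  centers <- NULL
  for (nid in ids) {
    sg <- series_go[[nid]]
    sn <- series_nogo[[nid]]
    if (is_refusal(sg) || is_refusal(sn)) next
    if (anyNA(sg$auroc) || anyNA(sn$auroc)) next
    if (is.null(centers)) {
      centers <- sg$bin_centers
    } else if (!isTRUE(all.equal(centers, sg$bin_centers))) {
      stop("inconsistent bin grids across neurons")
    }
    if (!isTRUE(all.equal(sg$bin_centers, sn$bin_centers))) {
      stop("inconsistent bin grids between conditions")
    }
    cols[[nid]] <- c(sg$auroc, sn$auroc)
  }
  if (!length(cols)) stop("no usable neurons")
  m <- do.call(cbind, cols)
  structure(list(matrix = m, bin_centers = centers,
                 neuron_ids = names(cols)),
            class = "odorgng_population_matrix")
}

#' Principal-component projection of the population matrix
#'
#' Column-centers the matrix and extracts components by singular value
#' decomposition. The component sign convention makes the largest-magnitude
#' loading positive, so results are deterministic across platforms. The two
#' condition blocks of rows are returned as 3-D (by default) trajectories.
#'
#' @param pop an `odorgng_population_matrix` (or plain matrix with an even
#'   number of rows).
#' @param n_components retained components (3).
#' @return list of class `odorgng_trajectory`: `go`, `nogo` (bins x
#'   components scores), `components` (N x components loadings), `center`
#'   (column means), `variance_explained` (fraction per retained component),
#'   `bin_centers`.
#' @export
pca_project <- function(pop, n_components = 3L) {
  m <- if (inherits(pop, "odorgng_population_matrix")) pop$matrix else pop
  centers <- if (inherits(pop, "odorgng_population_matrix")) pop$bin_centers else NULL
  if (ncol(m) < n_components) stop("need at least ", n_components, " neurons")
  ctr <- colMeans(m)
  xc <- sweep(m, 2, ctr, "-")
  if (all(abs(xc) < 1e-12)) stop("constant matrix: zero variance")
  sv <- svd(xc)
  total_var <- sum(sv$d^2)
  comp <- sv$v[, seq_len(n_components), drop = FALSE]
  # sign convention: largest |loading| positive per component
  for (i in seq_len(ncol(comp))) {
    j <- which.max(abs(comp[, i]))
    if (comp[j, i] < 0) comp[, i] <- -comp[, i]
  }
  scores <- xc %*% comp
  ve <- (sv$d^2 / total_var)[seq_len(n_components)]
  nb <- nrow(m) %/% 2L
  even <- nrow(m) %% 2L == 0L
  structure(list(go = if (even) scores[seq_len(nb), , drop = FALSE],
                 nogo = if (even) scores[nb + seq_len(nb), , drop = FALSE],
                 scores = scores,
                 components = comp, center = ctr,
                 variance_explained = ve,
                 bin_centers = centers),
            class = "odorgng_trajectory")
}

#' Project new observations into a fitted subspace
#'
#' Used to carry baseline-epoch population vectors into the nose-poking
#' subspace, so the distance threshold lives in the same coordinates.
#'
#' @param trajectory an `odorgng_trajectory` from [pca_project()].
#' @param new_matrix rows x N matrix on the same neuron order.
#' @return rows x components score matrix.
#' @export
project_into <- function(trajectory, new_matrix) {
  sweep(new_matrix, 2, trajectory$center, "-") %*% trajectory$components
}

#' Condition separation with a baseline threshold
#'
#' Per-bin Euclidean distance between the go and no-go trajectories in the
#' retained subspace, compared against the distances of the same pipeline run
#' on the pre-odor baseline window (1200--1000 ms before odor-port entry):
#' a bin is significant when its distance exceeds the baseline mean + 2 SD.
#'
#' @param trajectory an `odorgng_trajectory`.
#' @param baseline_matrix (2 x n_baseline_bins) x N population matrix for the
#'   baseline window (same neuron order), typically from
#'   [build_population_matrix()] on `pre_odor_baseline`-window series; it is
#'   projected into the fitted subspace via [project_into()].
#' @return list of class `odorgng_distance_series`: `bin_centers`,
#'   `distance`, `baseline_mean`, `baseline_sd`, `significant` (logical
#'   mask).
#' @export
trajectory_distance <- function(trajectory, baseline_matrix) {
  d <- sqrt(rowSums((trajectory$go - trajectory$nogo)^2))
  bm <- if (inherits(baseline_matrix, "odorgng_population_matrix")) {
    baseline_matrix$matrix
  } else baseline_matrix
  nbb <- nrow(bm) / 2
  proj <- project_into(trajectory, bm)
  bd <- sqrt(rowSums((proj[seq_len(nbb), , drop = FALSE] -
                        proj[nbb + seq_len(nbb), , drop = FALSE])^2))
  mu <- mean(bd)
  sdv <- stats::sd(bd)
  if (!is.finite(sdv) || sdv == 0) stop("baseline SD is zero")
  structure(list(bin_centers = trajectory$bin_centers, distance = d,
                 baseline_mean = mu, baseline_sd = sdv,
                 baseline_distance = bd,
                 significant = d > mu + 2 * sdv),
            class = "odorgng_distance_series")
}
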