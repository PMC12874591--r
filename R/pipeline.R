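# Session-level wrappers: run a module over all neurons of a session with
# per-neuron seeded RNG so neuron-level results do not depend on analysis
# order.

#' Derive a per-neuron seed
#'
#' Deterministic 31-bit stream split: neuron-level analyses seed their RNG
#' with `derive_seed(base_seed, i)` so results are independent of the order
#' in which neurons are processed.
#'
#' @param seed base integer seed.
#' @param i stream index (e.g. neuron position).
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 2654435) %% 2147483647 + 1)
}

#' Cue-selectivity classification for every neuron of a session
#'
#' For each neuron: vs-baseline sliding auROC series on the nose-poking
#' window (bin centers 0--1.8 s, 91 bins) for go-correct and no-go-correct
#' trials, then the five-consecutive-bin selectivity rule.
#'
#' @param session an `odorgng_session`.
#' @param seed base seed for the permutation tests.
#' @param n_permutations permutations per bin (1000).
#' @param window analysis window, seconds from odor onset.
#' @param alpha significance level.
#' @param truncate_at_exit drop a trial from bins past its odor-port exit
#'   (the nose-poking convention; disable for the population matrix).
#' @return list: `labels` (data.frame `neuron_id`, `label`, `run_start`,
#'   `run_end`), `series_go`, `series_nogo` (named lists of series or
#'   refusals).
#' @export
cue_selectivity_pipeline <- function(session, seed, n_permutations = 1000L,
                                     window = c(0, 1.8), alpha = 0.01,
                                     truncate_at_exit = TRUE) {
  go_tr <- trial_filter(session, function(tr) {
    tr$trial_type == "go" & tr$outcome == "correct"
  })
  ng_tr <- trial_filter(session, function(tr) {
    tr$trial_type == "nogo" & tr$outcome == "correct"
  })
  ids <- names(session$spikes)
  series_go <- list()
  series_nogo <- list()
  rows <- list()
  end_event <- if (truncate_at_exit) "port_exit" else NA
  for (i in seq_along(ids)) {
    nid <- ids[i]
    set.seed(derive_seed(seed, i))
    sg <- sliding_auroc(session, nid, go_tr, align_event = "odor_on",
                        window = window, n_permutations = n_permutations,
                        end_event = end_event)
    sn <- sliding_auroc(session, nid, ng_tr, align_event = "odor_on",
                        window = window, n_permutations = n_permutations,
                        end_event = end_event)
    series_go[[nid]] <- sg
    series_nogo[[nid]] <- sn
    lab <- classify_cue_selective(sg, sn, alpha = alpha)
    rows[[i]] <- data.frame(
      neuron_id = nid, label = lab$label,
      run_start = if (is.null(lab$qualifying_run)) NA_integer_ else
        lab$qualifying_run[["start"]],
      run_end = if (is.null(lab$qualifying_run)) NA_integer_ else
        lab$qualifying_run[["end"]],
      stringsAsFactors = FALSE)
  }
  list(labels = do.call(rbind, rows), series_go = series_go,
       series_nogo = series_nogo)
}

#' Reward-epoch selectivity for every neuron of a session
#'
#' Aligns go-correct trials to the water-port entry (analysis window entry to
#' 1000 ms after the valve opens), computes vs-baseline series, response
#' measures, and the center-of-mass epoch classification.
#'
#' @inheritParams cue_selectivity_pipeline
#' @param n_permutations permutations per bin (500, the response-dynamics
#'   convention).
#' @return data.frame: `neuron_id`, `label`, `center_of_mass`, `onset`,
#'   `duration`.
#' @export
reward_selectivity_pipeline <- function(session, seed,
                                        n_permutations = 500L,
                                        alpha = 0.01) {
  go_tr <- trial_filter(session, function(tr) {
    tr$trial_type == "go" & tr$outcome == "correct" &
      !is.na(tr$water_valve_open)
  })
  ids <- names(session$spikes)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    nid <- ids[i]
    set.seed(derive_seed(seed, 100000L + i))
    series <- sliding_auroc(session, nid, go_tr,
                            align_event = "water_port_entry",
                            window = c(0, 1.3),
                            n_permutations = n_permutations,
                            end_event = NA)
    m <- response_measures(series, alpha = alpha)
    lab <- classify_reward_selective(m)
    rows[[i]] <- data.frame(
      neuron_id = nid, label = lab$label,
      center_of_mass = if (is_refusal(m)) NA_real_ else m$center_of_mass,
      onset = if (is_refusal(m)) NA_real_ else m$onset,
      duration = if (is_refusal(m)) NA_real_ else m$duration,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Population trajectory analysis for a session
#'
#' Builds the (2 x 91) x N vs-baseline auROC matrix on the nose-poking
#' window (no per-trial truncation, so every neuron contributes all 91
#' bins), fits the 3-component subspace, projects the pre-odor baseline
#' window into it, and thresholds the go/no-go separation at the baseline
#' mean + 2 SD.
#'
#' @inheritParams cue_selectivity_pipeline
#' @param n_permutations permutations per bin (500; the p-values are carried
#'   but the matrix uses the auROC values themselves).
#' @param n_components retained principal components.
#' @return list: `population` (`odorgng_population_matrix`), `trajectory`
#'   (`odorgng_trajectory`), `distance` (`odorgng_distance_series`).
#' @export
population_pipeline <- function(session, seed, n_permutations = 500L,
                                n_components = 3L) {
  go_tr <- trial_filter(session, function(tr) {
    tr$trial_type == "go" & tr$outcome == "correct"
  })
  ng_tr <- trial_filter(session, function(tr) {
    tr$trial_type == "nogo" & tr$outcome == "correct"
  })
  ids <- names(session$spikes)
  run_series <- function(window, offset) {
    sg <- list(); sn <- list()
    for (i in seq_along(ids)) {
      nid <- ids[i]
      set.seed(derive_seed(seed, offset + i))
      sg[[nid]] <- sliding_auroc(session, nid, go_tr, window = window,
                                 n_permutations = n_permutations,
                                 end_event = NA)
      sn[[nid]] <- sliding_auroc(session, nid, ng_tr, window = window,
                                 n_permutations = n_permutations,
                                 end_event = NA)
    }
    build_population_matrix(sg, sn)
  }
  pop <- run_series(c(0, 1.8), 200000L)
  base <- run_series(c(-1.2, -1.0), 300000L)
  traj <- pca_project(pop, n_components = n_components)
  dist <- trajectory_distance(traj, base)
  list(population = pop, trajectory = traj, distance = dist)
}
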