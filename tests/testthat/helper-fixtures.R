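# Shared simulated fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 120-trial session with 3 neurons of each archetype
fx_mixed <- function() {
  get_fixture("fx_mixed", function() {
    simulate_session(
      task_config(n_trials = 120L),
      list(list(neuron_archetype("go_cue_late"), 3L),
           list(neuron_archetype("waiting_phasic"), 3L),
           list(neuron_archetype("drinking_ramp"), 3L),
           list(neuron_archetype("untuned"), 3L)),
      seed = 11)
  })
}

# 200-trial session with strong late responders and untuned units, for the
# encoding model and decoding
fx_glm <- function() {
  get_fixture("fx_glm", function() {
    simulate_session(
      task_config(n_trials = 200L),
      list(list(neuron_archetype("go_cue_late"), 2L),
           list(neuron_archetype("untuned"), 2L)),
      seed = 3)
  })
}

# hand-built auROC series for shape-measure tests
fake_series <- function(centers, auroc_vals, p_exc,
                        p_inh = rep(1, length(centers)),
                        width = 0.1, step = 0.02) {
  structure(list(neuron_id = "fake", bin_centers = centers,
                 auroc = auroc_vals, p_exc = p_exc, p_inh = p_inh,
                 n = rep(10L, length(centers)), contrast = "vs_baseline",
                 n_permutations = 1000L, width = width, step = step),
            class = "odorgng_auroc_series")
}

# brute-force ROC area: all pairs, half credit for ties
brute_roc_area <- function(pref, ref) {
  s <- 0
  for (p in pref) for (r in ref) {
    s <- s + if (p > r) 1 else if (p == r) 0.5 else 0
  }
  s / (length(pref) * length(ref))
}
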