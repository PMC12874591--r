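#!/usr/bin/env Rscript
# Simulate the study sessions used by every downstream analysis: the
# go/no-go task timeline with the four neuron archetypes (late-phase go-cue
# responders, waiting-epoch phasic responders, drinking-epoch ramps, and
# untuned units), written to results/sessions/ as plain-text containers with
# ground truth alongside.

library(odorgng)

seed <- 20260901L
out_dir <- "results/sessions"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

task <- task_config(n_trials = 240L)
archetypes <- list(
  list(neuron_archetype("go_cue_late"), 12L),
  list(neuron_archetype("waiting_phasic"), 6L),
  list(neuron_archetype("drinking_ramp"), 8L),
  list(neuron_archetype("untuned"), 24L))

sessions <- list()
for (k in 1:3) {
  sim <- simulate_session(task, archetypes, seed = derive_seed(seed, k),
                          session_id = sprintf("session%02d", k),
                          animal_id = sprintf("mouse%02d", (k + 1) %/% 2))
  path <- file.path(out_dir, sim$session$session_id)
  write_session(sim$session, path)
  write_ground_truth(sim$truth, path)
  sessions[[k]] <- sim
  cat(sprintf(
    "%s: %d trials (%d go / %d no-go / %d catch), accuracy %.3f, %d neurons\n",
    sim$session$session_id, nrow(sim$session$trials),
    sum(sim$session$trials$trial_type == "go"),
    sum(sim$session$trials$trial_type == "nogo"),
    sum(sim$session$trials$trial_type == "catch"),
    sim$session$behavioral_accuracy, length(sim$session$spikes)))
}

# task-level summaries against the configured conditions
all_trials <- do.call(rbind, lapply(sessions, function(x) x$session$trials))
go_poke <- with(all_trials[all_trials$trial_type == "go", ],
                port_exit - odor_on)
ng_poke <- with(all_trials[all_trials$trial_type == "nogo", ],
                port_exit - odor_on)
cat(sprintf("go poke median %.0f ms (IQR %.0f-%.0f); no-go median %.0f ms\n",
            1000 * median(go_poke), 1000 * quantile(go_poke, 0.25),
            1000 * quantile(go_poke, 0.75), 1000 * median(ng_poke)))
cat("sessions written to", out_dir, "\n")
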