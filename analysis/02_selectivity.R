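#!/usr/bin/env Rscript
# Cue and reward selectivity: sliding-bin auROC vs baseline with permutation
# significance, the 5-consecutive-bin cue-selectivity rule, response-shape
# measures aligned to the water-port entry, and the per-group epoch auROC
# comparison.

library(odorgng)

seed <- 20260902L
dir.create("results", showWarnings = FALSE)
session_dirs <- list.dirs("results/sessions", recursive = FALSE)
stopifnot(length(session_dirs) > 0)

cue_rows <- list()
reward_rows <- list()
for (d in session_dirs) {
  s <- read_session(d)
  truth <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                               simplifyVector = TRUE)$labels
  cs <- cue_selectivity_pipeline(s, seed = derive_seed(seed, 1L))
  rs <- reward_selectivity_pipeline(s, seed = derive_seed(seed, 2L))
  cue_rows[[d]] <- cbind(session = s$session_id, cs$labels,
                         truth = truth$label)
  reward_rows[[d]] <- cbind(session = s$session_id, rs,
                            truth = truth$label)
}
cue <- do.call(rbind, cue_rows)
reward <- do.call(rbind, reward_rows)
write.csv(cue, "results/cue_selectivity.csv", row.names = FALSE)
write.csv(reward, "results/reward_selectivity.csv", row.names = FALSE)

cat("go-cue selective:",
    sum(cue$label == "go_cue_selective"), "of", nrow(cue),
    sprintf("(%.1f%%)\n", 100 * mean(cue$label == "go_cue_selective")))
print(table(truth = cue$truth, label = cue$label))
cat("\nreward selectivity (center-of-mass epoch):\n")
print(table(truth = reward$truth, label = reward$label))
drink <- reward[reward$label == "drinking_selective" &
                  reward$truth == "drinking_ramp", ]
cat(sprintf(
  "\ndrinking responders: mean onset %+.0f ms relative to valve opening, mean duration %.0f ms\n",
  1000 * (mean(drink$onset) - 0.3), 1000 * mean(drink$duration)))

# per-group whole-epoch auROC with ANOVA/Tukey (late nose-poking, go cue)
s <- read_session(session_dirs[1])
truth <- jsonlite::read_json(file.path(session_dirs[1], "ground_truth.json"),
                             simplifyVector = TRUE)$labels
groups <- split(truth$neuron_id, truth$label)
go_tr <- trial_filter(s, function(tr) tr$trial_type == "go" &
                        tr$outcome == "correct")
set.seed(derive_seed(seed, 3L))
tab <- epoch_auroc_table(s, groups, go_tr,
                         epoch = task_epoch("late_nose_poking"))
write.csv(tab$table, "results/epoch_auroc_by_group.csv", row.names = FALSE)
cat(sprintf("\ngroup comparison (one-way ANOVA): p = %.2g\n", tab$anova_p))
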