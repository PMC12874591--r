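#!/usr/bin/env Rscript
# Pseudo-population decoding: linear-SVM go/no-go classification in sliding
# windows (10-fold CV, 40 trials per type pooled across sessions), the time
# at which accuracy reaches the behavioral level, and the population-size
# sweep at that window.

library(odorgng)

seed <- 20260905L
dir.create("results", showWarnings = FALSE)
session_dirs <- list.dirs("results/sessions", recursive = FALSE)
sessions <- lapply(session_dirs, read_session)

pp <- build_pseudopopulation(sessions, window = c(-0.2, 1.8))
cat(sprintf("pseudo-population: %d neurons x %d pseudo-trials\n",
            length(pp$neuron_ids), length(pp$labels)))

set.seed(derive_seed(seed, 1L))
tc <- decode_time_course(pp)
write.csv(data.frame(window_center = tc$window_centers,
                     accuracy = tc$accuracy, sd = tc$sd),
          "results/decoding_time_course.csv", row.names = FALSE)
cat(sprintf("behavioral accuracy %.1f%%; decoding first reaches it %.0f ms after odor onset\n",
            tc$behavioral_accuracy, 1000 * tc$crossing_time))

sweep_at <- if (is.na(tc$crossing_time)) 0.8 else tc$crossing_time + 0.1
set.seed(derive_seed(seed, 2L))
sizes <- unique(pmin(c(1L, 5L, 10L, 20L, 35L, length(pp$neuron_ids)),
                     length(pp$neuron_ids)))
ps <- decode_vs_population_size(pp, sweep_at, sizes)
write.csv(ps, "results/decoding_vs_population_size.csv", row.names = FALSE)
cat(sprintf("accuracy vs population size at %.2f s:\n", sweep_at))
print(ps, row.names = FALSE)
enough <- ps$size[ps$accuracy >= tc$behavioral_accuracy]
if (length(enough)) {
  cat(sprintf("about %d neurons suffice to account for behavioral accuracy\n",
              min(enough)))
}
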