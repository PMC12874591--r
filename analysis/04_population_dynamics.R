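#!/usr/bin/env Rscript
# Population trajectories: the (2 x 91) x N vs-baseline auROC matrix,
# 3-component PCA subspace, and the go/no-go separation against the
# pre-odor baseline threshold.

library(odorgng)

seed <- 20260904L
dir.create("results", showWarnings = FALSE)
session_dirs <- list.dirs("results/sessions", recursive = FALSE)
s <- read_session(session_dirs[1])

res <- population_pipeline(s, seed = derive_seed(seed, 1L),
                           n_permutations = 500L)

traj <- data.frame(
  bin_center = rep(res$trajectory$bin_centers, 2),
  condition = rep(c("go", "nogo"), each = length(res$trajectory$bin_centers)),
  rbind(res$trajectory$go, res$trajectory$nogo))
names(traj)[3:5] <- paste0("pc", 1:3)
write.csv(traj, "results/population_trajectory.csv", row.names = FALSE)

dist_tab <- data.frame(bin_center = res$distance$bin_centers,
                       distance = res$distance$distance,
                       significant = res$distance$significant)
write.csv(dist_tab, "results/population_distance.csv", row.names = FALSE)

cat(sprintf("population matrix: %d x %d (conditions x bins, neurons)\n",
            nrow(res$population$matrix), ncol(res$population$matrix)))
cat(sprintf("variance explained by 3 PCs: %.1f%%\n",
            100 * sum(res$trajectory$variance_explained)))
sig_t <- dist_tab$bin_center[dist_tab$significant]
cat(sprintf("go/no-go separation exceeds baseline mean + 2SD from %.0f ms after odor onset (peak at %.0f ms)\n",
            1000 * min(sig_t),
            1000 * dist_tab$bin_center[which.max(dist_tab$distance)]))
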