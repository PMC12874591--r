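test_that("roc_area equals the brute-force pairwise oracle", {
  expect_equal(roc_area(c(4, 5, 6), c(1, 2, 3)), 1.0)
  expect_equal(roc_area(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_area(c(1, 2), c(0, 1)), 0.875)
  expect_error(roc_area(numeric(0), 1:3), "empty")

  set.seed(17)
  for (rep in 1:200) {
    np <- sample(2:12, 1)
    nr <- sample(2:12, 1)
    # integer-valued samples so ties are frequent, as with spike counts
    pref <- sample(0:5, np, replace = TRUE)
    ref <- sample(0:5, nr, replace = TRUE)
    expect_equal(roc_area(pref, ref), brute_roc_area(pref, ref))
  }
})

test_that("auroc scaling, bounds, and antisymmetry", {
  expect_equal(auroc(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(auroc(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(auroc(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(18)
  for (rep in 1:50) {
    pref <- rpois(8, 3)
    ref <- rpois(6, 3)
    a <- auroc(pref, ref)
    expect_true(a >= -1 && a <= 1)
    expect_equal(auroc(ref, pref), -a)
  }
})

test_that("permutation p-values are valid and add-one corrected", {
  # complete separation with samples large enough that no random
  # reassignment reproduces the observed grouping: extreme rank
  set.seed(20)
  res <- permutation_test(101:110, 1:10, 1000L)
  expect_equal(res$p_exc, 1 / 1001)   # observed exceeds every permutation
  expect_equal(res$auroc, 1)

  res2 <- permutation_test(rep(2, 6), rep(2, 6), 500L)
  expect_equal(res2$p_exc, 1)
  expect_equal(res2$p_inh, 1)

  expect_error(permutation_test(1:3, 1:3, 0L), "n_permutations")

  # permutations preserve group sizes
  m <- odorgng:::perm_assignments(10, 4, 50)
  expect_true(all(colSums(m) == 4))
})

test_that("sliding auROC flags the late-phase go-cue response and not null cells", {
  sim <- fx_mixed()
  s <- sim$session
  go_tr <- trial_filter(s, function(tr) tr$trial_type == "go" &
                          tr$outcome == "correct")
  late_id <- sim$truth$labels$neuron_id[sim$truth$labels$label == "go_cue_late"][1]
  untuned_id <- sim$truth$labels$neuron_id[sim$truth$labels$label == "untuned"][1]

  set.seed(31)
  sg <- sliding_auroc(s, late_id, go_tr, n_permutations = 500L)
  expect_length(sg$bin_centers, 91L)
  late_bins <- sg$bin_centers >= 0.6 & sg$bin_centers <= 0.9
  expect_true(all(sg$p_exc[late_bins] < 0.01))
  expect_true(all(sg$auroc[late_bins] > 0.5))
  # pre-odor-onset response direction is null near t = 0
  expect_gt(sg$p_exc[1], 0.01)

  # go vs no-go contrast shows the cue preference in the late phase
  ng_tr <- trial_filter(s, function(tr) tr$trial_type == "nogo" &
                          tr$outcome == "correct")
  set.seed(32)
  gvn <- sliding_auroc(s, late_id, go_tr, contrast = "go_vs_nogo",
                       reference_trials = ng_tr, n_permutations = 500L)
  expect_true(all(gvn$auroc[late_bins] > 0.3, na.rm = TRUE))
  expect_gt(mean(gvn$p_exc[late_bins] < 0.01, na.rm = TRUE), 0.8)
  # but not during early odor presentation (both cues sampled identically)
  early_bins <- gvn$bin_centers <= 0.3
  expect_lt(mean(gvn$p_exc[early_bins] < 0.01, na.rm = TRUE), 0.3)

  # a refusal propagates as exclusion
  few <- trial_filter(s, function(tr) tr$trial_type == "go" &
                        tr$outcome == "error", min_trials = 1000L)
  expect_true(is_refusal(sliding_auroc(s, untuned_id, few)))
})

test_that("cue-selectivity classification applies the 5-consecutive-bin rule", {
  centers <- seq(0, 1.8, by = 0.02)
  p <- rep(1, 91)
  a <- rep(0, 91)
  p[10:14] <- 0.001; a[10:14] <- 0.6      # exactly 5 consecutive bins
  lab <- classify_cue_selective(fake_series(centers, a, p), NULL)
  expect_equal(lab$label, "go_cue_selective")
  expect_equal(unname(lab$qualifying_run), c(10L, 14L))

  p4 <- rep(1, 91); a4 <- rep(0, 91)
  p4[10:13] <- 0.001; a4[10:13] <- 0.6    # 4 bins: below threshold
  expect_equal(classify_cue_selective(fake_series(centers, a4, p4), NULL)$label,
               "none")

  # dual qualification: longer run wins; equal runs go to larger peak auROC
  pn <- rep(1, 91); an <- rep(0, 91)
  pn[30:40] <- 0.001; an[30:40] <- 0.4
  lab2 <- classify_cue_selective(fake_series(centers, a, p),
                                 fake_series(centers, an, pn))
  expect_equal(lab2$label, "nogo_cue_selective")
  pn2 <- rep(1, 91); an2 <- rep(0, 91)
  pn2[30:34] <- 0.001; an2[30:34] <- 0.9
  lab3 <- classify_cue_selective(fake_series(centers, a, p),
                                 fake_series(centers, an2, pn2))
  expect_equal(lab3$label, "nogo_cue_selective")
})

test_that("response measures follow the stated center-of-mass conventions", {
  centers <- seq(0, 0.4, by = 0.02)
  p <- rep(1, length(centers)); a <- rep(0, length(centers))
  sig <- which(centers >= 0.10 - 1e-9 & centers <= 0.18 + 1e-9)
  p[sig] <- 0.001; a[sig] <- 0.5
  m <- response_measures(fake_series(centers, a, p))
  expect_equal(m$onset, 0.10)
  expect_equal(m$center_of_mass, 0.14)
  expect_equal(m$duration, 0.18)   # 5 bins x 20 ms step + 80 ms window excess

  # asymmetric weights pull the center of mass toward larger auROC
  a2 <- a; a2[sig] <- c(0.9, 0.2, 0.2, 0.2, 0.2)
  m2 <- response_measures(fake_series(centers, a2, p))
  expect_lt(m2$center_of_mass, 0.14)
  # the unweighted variant restores the midpoint
  m3 <- response_measures(fake_series(centers, a2, p), weighted = FALSE)
  expect_equal(m3$center_of_mass, 0.14)

  # significant bins but no 5-bin run: center of mass still returned
  p5 <- rep(1, length(centers)); a5 <- rep(0, length(centers))
  p5[3:5] <- 0.001; a5[3:5] <- 0.5
  m4 <- response_measures(fake_series(centers, a5, p5))
  expect_false(is_refusal(m4))
  expect_true(is.na(m4$duration) && is.na(m4$onset))
  expect_equal(m4$center_of_mass, centers[4])

  expect_true(is_refusal(response_measures(
    fake_series(centers, a5, rep(1, length(centers))))))
})

test_that("reward-epoch classification by center of mass recovers archetypes", {
  m_wait <- list(neuron_id = "x", center_of_mass = 0.1, onset = 0,
                 duration = 0.2)
  class(m_wait) <- "odorgng_response_measures"
  expect_equal(classify_reward_selective(m_wait)$label, "waiting_selective")
  m_drink <- list(neuron_id = "x", center_of_mass = 0.5, onset = 0.3,
                  duration = 0.4)
  class(m_drink) <- "odorgng_response_measures"
  expect_equal(classify_reward_selective(m_drink)$label, "drinking_selective")
  m_out <- list(neuron_id = "x", center_of_mass = 1.4, onset = NA,
                duration = NA)
  class(m_out) <- "odorgng_response_measures"
  expect_equal(classify_reward_selective(m_out)$label, "none")

  # full pipeline on the mixed fixture: reward archetypes recovered
  sim <- fx_mixed()
  rm <- reward_selectivity_pipeline(sim$session, seed = 5)
  truth <- sim$truth$labels$label
  expect_true(all(rm$label[truth == "waiting_phasic"] == "waiting_selective"))
  expect_true(all(rm$label[truth == "drinking_ramp"] == "drinking_selective"))
  # drinking responders: onset before the valve opens (entry + 0.3), duration
  # on the few-hundred-ms scale
  dr <- rm[truth == "drinking_ramp", ]
  expect_true(all(dr$onset < 0.3))
  expect_true(all(dr$duration > 0.2 & dr$duration < 1.2))
})

test_that("epoch auROC table separates neuron groups by ANOVA", {
  sim <- get_fixture("fx_groups", function() {
    simulate_session(
      task_config(n_trials = 150L),
      list(list(neuron_archetype("waiting_phasic"), 8L),
           list(neuron_archetype("drinking_ramp"), 8L),
           list(neuron_archetype("untuned"), 8L)),
      seed = 41)
  })
  s <- sim$session
  labels <- sim$truth$labels
  groups <- split(labels$neuron_id, labels$label)
  go_tr <- trial_filter(s, function(tr) tr$trial_type == "go" &
                          tr$outcome == "correct")
  set.seed(77)
  tab <- epoch_auroc_table(s, groups, go_tr,
                           epoch = task_epoch("late_nose_poking"),
                           n_permutations = 300L)
  expect_s3_class(tab$table, "data.frame")
  by_group <- tapply(tab$table$auroc, tab$table$group, median)
  expect_gt(by_group[["waiting_phasic"]], by_group[["drinking_ramp"]])
  expect_lt(tab$anova_p, 0.05)
  expect_true(!is.null(tab$tukey))

  # a condition below the five-trial minimum refuses
  few <- trial_filter(s, function(tr) tr$trial_type == "go" &
                        tr$outcome == "error", min_trials = 1000L)
  expect_true(is_refusal(epoch_auroc_table(s, groups, few)))
})
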