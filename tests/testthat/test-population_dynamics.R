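make_series <- function(nid, centers, vals) {
  structure(list(neuron_id = nid, bin_centers = centers, auroc = vals,
                 p_exc = rep(1, length(centers)),
                 p_inh = rep(1, length(centers)),
                 n = rep(10L, length(centers)), contrast = "vs_baseline",
                 n_permutations = 500L, width = 0.1, step = 0.02),
            class = "odorgng_auroc_series")
}

test_that("population matrix stacks conditions over neurons without imputation", {
  centers <- seq(0, 1.8, by = 0.02)
  sg <- list(a = make_series("a", centers, rep(0.2, 91)),
             b = make_series("b", centers, rep(-0.1, 91)),
             c = refusal("too few trials"))
  sn <- list(a = make_series("a", centers, rep(0.0, 91)),
             b = make_series("b", centers, rep(0.3, 91)),
             c = make_series("c", centers, rep(0.3, 91)))
  pop <- build_population_matrix(sg, sn)
  expect_equal(dim(pop$matrix), c(182L, 2L))
  expect_equal(pop$neuron_ids, c("a", "b"))
  # entries are the series values, bit-exactly
  expect_identical(pop$matrix[, "a"], c(sg$a$auroc, sn$a$auroc))

  sg$b$bin_centers <- centers + 0.01
  expect_error(build_population_matrix(sg, sn), "inconsistent bin grids")
})

test_that("PCA matches a covariance eigendecomposition oracle", {
  set.seed(51)
  m <- matrix(rnorm(5 * 4), 5, 4) # 5 observations (rows), 4 neurons
  m[1, ] <- m[1, ] + 3
  tr <- pca_project(m, n_components = 3L)
  ev <- eigen(stats::cov(m))
  # variance explained (svd uses n, eigen of cov uses n-1; ratios agree)
  expect_equal(tr$variance_explained,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-10)
  # loadings agree up to sign
  for (i in 1:3) {
    expect_equal(abs(tr$components[, i]), abs(ev$vectors[, i]),
                 tolerance = 1e-10)
  }
  # sign convention: largest-magnitude loading positive
  for (i in 1:3) {
    expect_gt(tr$components[which.max(abs(tr$components[, i])), i], 0)
  }
  # full-rank projection reproduces the centered data
  tr_full <- pca_project(m, n_components = 4L)
  centered <- sweep(m, 2, colMeans(m), "-")
  recon <- tr_full$scores %*% t(tr_full$components)
  expect_equal(recon, centered, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(tr_full$variance_explained), 1)

  # rank-1 matrix: first component explains everything
  r1 <- outer(1:6, c(1, 2, 3, 4)) + 0
  tr1 <- pca_project(r1, n_components = 3L)
  expect_equal(tr1$variance_explained[1], 1, tolerance = 1e-10)

  expect_error(pca_project(matrix(1, 6, 4)), "zero variance")
  expect_error(pca_project(matrix(rnorm(12), 6, 2)), "at least 3")
})

test_that("trajectory distance: identity, homogeneity, rotation invariance", {
  set.seed(52)
  centers <- seq(0, 1.8, by = 0.02)
  base_centers <- seq(-1.2, -1.0, by = 0.02)
  n_neuron <- 12
  go_block <- matrix(rnorm(91 * n_neuron, sd = 0.1), 91, n_neuron)

  # identical go/no-go responses: distance 0 everywhere, nothing significant
  m_same <- rbind(go_block, go_block)
  traj <- pca_project(m_same, 3L)
  traj$bin_centers <- centers
  baseline <- matrix(rnorm(2 * 11 * n_neuron, sd = 0.05), 22, n_neuron)
  d <- trajectory_distance(traj, baseline)
  expect_equal(d$distance, rep(0, 91), tolerance = 1e-10)
  expect_false(any(d$significant))

  # homogeneity: doubling the matrix doubles every distance
  m_diff <- rbind(go_block, go_block + matrix(rnorm(91 * n_neuron, sd = 0.2),
                                              91, n_neuron))
  t1 <- pca_project(m_diff, 3L)
  t2 <- pca_project(2 * m_diff, 3L)
  d1 <- trajectory_distance(t1, baseline)
  d2 <- trajectory_distance(t2, 2 * baseline)
  expect_equal(d2$distance, 2 * d1$distance, tolerance = 1e-10)
  expect_identical(d2$significant, d1$significant)

  # distance is invariant to orthogonal rotation of the retained subspace
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  t_rot <- t1
  t_rot$go <- t1$go %*% qr_q
  t_rot$nogo <- t1$nogo %*% qr_q
  t_rot$components <- t1$components %*% qr_q
  d_rot <- trajectory_distance(t_rot, baseline)
  expect_equal(d_rot$distance, d1$distance, tolerance = 1e-10)

  # degenerate baseline is an error, not a silent threshold
  expect_error(trajectory_distance(t1, matrix(0, 22, n_neuron)),
               "baseline SD")
})

test_that("simulated populations diverge only in the late nose-poking phase", {
  sim <- get_fixture("fx_pop", function() {
    simulate_session(
      task_config(n_trials = 150L),
      list(list(neuron_archetype("go_cue_late"), 10L),
           list(neuron_archetype("untuned"), 20L)),
      seed = 61)
  })
  res <- population_pipeline(sim$session, seed = 62, n_permutations = 100L)
  expect_equal(dim(res$population$matrix), c(182L, 30L))
  d <- res$distance
  sig_times <- d$bin_centers[d$significant]
  # separation emerges after odor sampling begins, in the late phase,
  # and persists through the median poke duration
  expect_gt(min(sig_times), 0.3)
  expect_true(any(sig_times > 0.5 & sig_times < 0.9))
  # early odor presentation remains near baseline separation
  early <- d$bin_centers <= 0.3
  expect_lt(mean(d$significant[early]), 0.2)

  # deterministic under a fixed seed
  res2 <- population_pipeline(sim$session, seed = 62, n_permutations = 100L)
  expect_identical(res$population$matrix, res2$population$matrix)
  expect_identical(res$distance$distance, res2$distance$distance)
})
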