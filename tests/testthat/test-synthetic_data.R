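test_that("simulation is bit-identical under a fixed seed", {
  archs <- list(list(neuron_archetype("go_cue_late"), 2L),
                list(neuron_archetype("untuned"), 1L))
  a <- simulate_session(task_config(n_trials = 60L), archs, seed = 7)
  b <- simulate_session(task_config(n_trials = 60L), archs, seed = 7)
  expect_identical(a$session$trials, b$session$trials)
  expect_identical(a$session$spikes, b$session$spikes)
  c <- simulate_session(task_config(n_trials = 60L), archs, seed = 8)
  expect_false(identical(a$session$spikes, c$session$spikes))
})

test_that("poke durations reproduce the configured medians and IQRs", {
  # ~2000 go trials; the log-normal is parameterized by (median, IQR)
  sim <- simulate_session(task_config(n_trials = 2340L, p_go = 0.95),
                          list(), seed = 31)
  tr <- sim$session$trials
  go <- tr[tr$trial_type == "go", ]
  expect_gt(nrow(go), 1800)
  poke <- go$port_exit - go$odor_on
  expect_lt(abs(median(poke) - 0.927), 0.030)
  q <- quantile(poke, c(0.25, 0.75), names = FALSE)
  expect_lt(abs(q[1] - 0.745), 0.040)
  expect_lt(abs(q[2] - 1.123), 0.060)
  # no-go poke durations follow their own distribution
  ng <- tr[tr$trial_type == "nogo", ]
  if (nrow(ng) >= 50) {
    expect_lt(abs(median(ng$port_exit - ng$odor_on) - 0.758), 0.08)
  }
  # realized accuracy close to configured
  expect_lt(abs(sim$session$behavioral_accuracy - 0.85), 0.03)
  # animals hold the nose poke at least through odor presentation
  expect_true(all(poke >= 0.5))
})

test_that("archetype rate profiles honor their anchoring events", {
  arch_u <- neuron_archetype("untuned", baseline_rate = 5)
  tr_go <- list(trial_type = "go", odor_on = 10, odor_off = 10.5,
                port_exit = 10.9, water_port_entry = 11.3,
                water_valve_open = 11.6)
  tt <- seq(9, 13, by = 0.05)
  expect_equal(archetype_rate(arch_u, tr_go, tt), rep(5, length(tt)))

  arch_g <- neuron_archetype("go_cue_late")
  # plateau during late nose-poking on go trials
  expect_equal(archetype_rate(arch_g, tr_go, c(10.6, 10.85)),
               rep(arch_g$peak_rate, 2))
  # baseline during odor presentation (before the 500 ms onset)
  expect_equal(archetype_rate(arch_g, tr_go, 10.2), arch_g$baseline_rate)
  # baseline on a no-go trial even in the late phase (go-cue preference)
  tr_ng <- within(tr_go, {trial_type <- "nogo"
                          water_port_entry <- NA_real_
                          water_valve_open <- NA_real_})
  expect_equal(archetype_rate(arch_g, as.list(tr_ng), 10.7),
               arch_g$baseline_rate)

  # drinking ramp is already above baseline 180 ms before the valve opens
  arch_d <- neuron_archetype("drinking_ramp")
  expect_gt(archetype_rate(arch_d, tr_go, 11.6 - 0.18), arch_d$baseline_rate)
  # and suppressed below baseline during nose poking
  expect_lt(archetype_rate(arch_d, tr_go, 10.7), arch_d$baseline_rate)

  # waiting-phasic bump peaks in the waiting epoch and decays before reward
  arch_w <- neuron_archetype("waiting_phasic")
  expect_equal(archetype_rate(arch_w, tr_go, 11.3 + 0.08), arch_w$peak_rate)
  expect_equal(archetype_rate(arch_w, tr_go, 11.58), arch_w$baseline_rate,
               tolerance = 0.2)
})

test_that("poisson_spikes has Poisson counts and passes time rescaling", {
  set.seed(99)
  s <- poisson_spikes(function(t) rep(10, length(t)), c(0, 100), 10)
  expect_lt(abs(length(s) - 1000), 3 * sqrt(1000))
  expect_false(is.unsorted(s))

  expect_length(poisson_spikes(function(t) rep(0, length(t)), c(0, 10), 0), 0)
  expect_error(poisson_spikes(function(t) rep(-1, length(t)), c(0, 10), 5),
               "negative rate")
  expect_error(poisson_spikes(function(t) rep(9, length(t)), c(0, 10), 5),
               "ceiling")

  # time-rescaling: with rate r(t), the transformed ISIs are Exp(1)
  rate_fn <- function(t) 8 + 6 * sin(2 * pi * t / 7)
  grid <- seq(0, 200, by = 0.001)
  cum <- c(0, cumsum((rate_fn(grid[-1]) + rate_fn(grid[-length(grid)])) / 2 *
                       diff(grid)))
  set.seed(7)
  pass <- vapply(1:40, function(b) {
    s <- poisson_spikes(rate_fn, c(0, 200), 14)
    lam <- approx(grid, cum, xout = s)$y
    stats::ks.test(diff(lam), "pexp", 1)$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 38)
})

test_that("ground truth labels every simulated neuron exactly once", {
  sim <- fx_mixed()
  expect_setequal(sim$truth$labels$neuron_id, names(sim$session$spikes))
  expect_false(anyDuplicated(sim$truth$labels$neuron_id) > 0)
  expect_setequal(unique(sim$truth$labels$label),
                  c("go_cue_late", "waiting_phasic", "drinking_ramp",
                    "untuned"))
  # retained latent rate functions are finite and nonnegative
  fn <- sim$truth$rate_fns[[1]]
  tt <- seq(0, sim$truth$session_end, length.out = 500)
  expect_true(all(is.finite(fn(tt))) && all(fn(tt) >= 0))
})
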