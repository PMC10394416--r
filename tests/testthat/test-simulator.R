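test_that("STDP update rules match the printed constants", {
  p <- stdp_params()
  tau <- p$tau_stdp
  expect_equal(stdp_potentiate(1, -tau, p), 1 + 0.007 * exp(-1))
  expect_equal(stdp_potentiate(1, 0, p), 1 + 0.007)
  expect_equal(stdp_potentiate(2, -100 * tau, p), 2, tolerance = 1e-12)
  expect_error(stdp_potentiate(1, tau, p), "delta_t <= 0")
  expect_equal(stdp_depress(1, tau, p), 1 - 0.003 * exp(-1))
  expect_equal(stdp_depress(0, tau, p), 0)
  expect_equal(stdp_depress(3, 100 * tau, p), 3, tolerance = 1e-12)
  expect_error(stdp_depress(1, -tau, p), "delta_t > 0")
})

test_that("intrinsic noise has the Euler-Maruyama moments", {
  w <- rep(1, 1e5)
  expect_identical(apply_intrinsic_noise(w, 0.01, noise_params(0, 0)), w)
  set.seed(40)
  w1 <- apply_intrinsic_noise(w, 0.01, noise_params(0.1, 0))
  expect_lt(abs(sd(w1) - 0.1 * sqrt(0.01)) / (0.1 * sqrt(0.01)), 0.02)
  set.seed(41)
  w2 <- apply_intrinsic_noise(rep(0, 1e5), 0.01, noise_params(0, 0.5))
  expect_true(all(w2 >= 0))
  expect_gt(mean(w2), 0)
  # clipped half-normal mean: add*sqrt(dt)/sqrt(2*pi)
  expect_lt(abs(mean(w2) - 0.5 * sqrt(0.01) / sqrt(2 * pi)), 0.001)
})

test_that("heterosynaptic scaling preserves ratios and the target total", {
  expect_equal(heterosynaptic_scale(c(1, 3), 8), c(2, 6))
  w <- c(0.5, 1.5, 2)
  expect_equal(heterosynaptic_scale(w, sum(w)), w)
  set.seed(42)
  v <- runif(50)
  sv <- heterosynaptic_scale(v, 13)
  expect_equal(sum(sv), 13)
  expect_equal(sv / sv[1], v / v[1])
  expect_warning(z <- heterosynaptic_scale(rep(0, 5), 1), "skipped")
  expect_true(attr(z, "skipped"))
})

test_that("input spike trains follow their protocols", {
  silent <- generate_input_spikes(stimulus_protocol("silent"), 10, 20)
  expect_true(all(lengths(silent) == 0))
  set.seed(43)
  po <- generate_input_spikes(stimulus_protocol("poisson", 10, 1), 100, 1)
  expect_lt(abs(length(po[[1]]) - 1000), 3 * sqrt(1000))
  pe <- generate_input_spikes(stimulus_protocol("periodic", 200, 1), 1, 1)
  expect_true(length(pe[[1]]) %in% c(200, 201))
  expect_equal(diff(pe[[1]]), rep(1 / 200, length(pe[[1]]) - 1))
  # half the inputs stimulated
  half <- generate_input_spikes(stimulus_protocol("poisson", 10, 0.5), 1, 10)
  expect_equal(sum(lengths(half) > 0), 5)
  expect_error(generate_input_spikes(stimulus_protocol("poisson", 2000, 1),
                                     1, 1, dt = 1e-3), "unresolvable")
})

test_that("LIF reproduces the constant-drive inter-spike-interval closed form", {
  np <- neuron_params()
  none <- simulate_lif(np, rep(0.5, 100),
                       rep(list(numeric(0)), 100), duration = 0.1)
  expect_length(none, 0)
  dt <- 1e-4
  sp <- simulate_lif(np, numeric(0), list(), duration = 0.2, dt = dt,
                     i_const = 15)
  isi_theory <- np$tau_m * log(15 / (15 - np$threshold))
  expect_gt(length(sp), 10)
  expect_true(all(abs(diff(sp) - isi_theory) <= dt + 1e-12))
  # a single suprathreshold input fires the neuron on every presynaptic spike
  times <- c(0.01, 0.05, 0.09)
  sp2 <- simulate_lif(neuron_params(n_inputs = 1), 15, list(times),
                      duration = 0.1, dt = dt)
  expect_length(sp2, 3)
  expect_true(all(abs(sp2 - times) <= dt + 1e-12))
})

test_that("population simulation is an identity when all dynamics are off", {
  np <- neuron_params(n_inputs = 20, n_neurons = 10)
  res <- run_simulation(np, noise = noise_params(0, 0),
                        protocol = stimulus_protocol("poisson", 10, 0.5),
                        duration = 0.5, seed = 5, stdp_on = FALSE)
  set.seed(5)
  W0 <- matrix(runif(200, 0, 1), 10, 20)
  expect_equal(res$final_weights, W0, tolerance = 1e-12)
})

test_that("simulation results are deterministic per seed", {
  np <- neuron_params(n_inputs = 20, n_neurons = 10)
  a <- run_simulation(np, protocol = stimulus_protocol("periodic", 200, 0.5),
                      duration = 0.5, seed = 9)
  b <- run_simulation(np, protocol = stimulus_protocol("periodic", 200, 0.5),
                      duration = 0.5, seed = 9)
  d <- run_simulation(np, protocol = stimulus_protocol("periodic", 200, 0.5),
                      duration = 0.5, seed = 10)
  expect_identical(a$final_weights, b$final_weights)
  expect_identical(a$spike_counts, b$spike_counts)
  expect_false(identical(a$final_weights, d$final_weights))
})

test_that("single-synapse pairing matches a hand-stepped STDP oracle", {
  # one neuron, one suprathreshold input at 1 kHz: every presynaptic event
  # first suffers depression against the previous postsynaptic spike (1 ms
  # gap), then triggers a spike and coincidence potentiation (+c_p)
  seed <- 77
  w0 <- 20
  isi <- 1e-3
  duration <- 0.01
  res <- run_simulation(
    neuron_params(n_inputs = 1, n_neurons = 1),
    stdp_params(), noise_params(0, 0),
    stimulus_protocol("periodic", 1000, 1),
    duration = duration, seed = seed,
    init_weights = matrix(w0, 1, 1), dt_noise = duration,
    scaling_on = FALSE)
  set.seed(seed)
  phase <- runif(1) * isi
  n_ev <- floor((duration - phase) / isi) + 1
  p <- stdp_params()
  w <- stdp_potentiate(w0, 0, p)  # first event: no previous post spike
  if (n_ev > 1) for (k in 2:n_ev)
    w <- stdp_potentiate(stdp_depress(w, isi, p), 0, p)
  expect_equal(res$spike_counts[1], n_ev)
  expect_equal(res$final_weights[1, 1], w, tolerance = 1e-12)
})

test_that("pure multiplicative noise follows the geometric-Brownian law", {
  np <- neuron_params(n_inputs = 100, n_neurons = 100)
  res <- run_simulation(np, noise = noise_params(0.15, 0),
                        protocol = stimulus_protocol("silent"),
                        duration = 10, seed = 13,
                        init_weights = matrix(1, 100, 100),
                        stdp_on = FALSE, scaling_on = FALSE)
  lw <- log(as.numeric(res$final_weights))
  expect_true(all(is.finite(lw)))
  v_theory <- 0.15^2 * 10
  expect_lt(abs(var(lw) - v_theory) / v_theory, 0.1)
})

test_that("scaling conserves each neuron's total conductance at every snapshot", {
  np <- neuron_params(n_inputs = 30, n_neurons = 50)
  res <- run_simulation(np, noise = noise_params(0.2, 0.05),
                        protocol = stimulus_protocol("poisson", 20, 0.5),
                        duration = 2, seed = 14, snapshot_interval = 0.5)
  expect_true(all(res$final_weights >= 0))
  rel_err <- abs(rowSums(res$final_weights) - res$target_totals) /
    res$target_totals
  expect_lt(max(rel_err), 1e-9)
  for (r in seq_len(nrow(res$snapshots))) {
    W <- matrix(res$snapshots[r, ], 50, 30, byrow = TRUE)
    rel <- abs(rowSums(W) - res$target_totals) / res$target_totals
    expect_lt(max(rel), 1e-9)
  }
})

test_that("stimulating zero inputs reduces HFS to the silent condition", {
  np <- neuron_params(n_inputs = 30, n_neurons = 20)
  hfs0 <- run_simulation(np, protocol = stimulus_protocol("periodic", 200, 0),
                         duration = 1, seed = 21)
  silent <- run_simulation(np, protocol = stimulus_protocol("silent"),
                           duration = 1, seed = 21)
  expect_identical(hfs0$final_weights, silent$final_weights)
  expect_true(all(hfs0$spike_counts == 0))
})

test_that("weights stay non-negative under strong additive noise", {
  res <- run_simulation(neuron_params(n_inputs = 50, n_neurons = 20),
                        noise = noise_params(0.3, 2),
                        protocol = stimulus_protocol("silent"),
                        duration = 2, seed = 15, scaling_on = FALSE,
                        stdp_on = FALSE)
  expect_gte(min(res$final_weights), 0)
})
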