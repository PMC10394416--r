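#' STDP parameters
#'
#' Exponential-window spike-timing-dependent plasticity with additive
#' potentiation and multiplicative depression. A pre-before-post pairing at
#' separation `|dt|` adds `c_p * exp(-|dt|/tau)` to the weight; a
#' post-before-pre pairing multiplies it by `1 - c_d * exp(-|dt|/tau)`.
#'
#' @param c_p Potentiation increment in pS (default 0.007).
#' @param c_d Relative depression strength, dimensionless in `[0, 1)`
#'   (default 0.003).
#' @param tau_stdp_ms STDP window time constant in ms (default 0.5).
#' @return List of class `"stdp_params"` (times stored in seconds).
#' @export
stdp_params <- function(c_p = 0.007, c_d = 0.003, tau_stdp_ms = 0.5) {
  stopifnot(c_p >= 0, c_d >= 0, c_d < 1, tau_stdp_ms > 0)
  structure(list(c_p = c_p, c_d = c_d, tau_stdp = tau_stdp_ms / 1000),
            class = "stdp_params")
}

#' Intrinsic noise parameters
#'
#' Activity-independent weight fluctuations: a multiplicative (Kesten-type)
#' Gaussian term whose strength is a proportion of the current weight per
#' second, and an additive Gaussian term in absolute units (pS) per second.
#'
#' @param mult_strength Multiplicative strength, /sqrt(s) scaling per second
#'   (default 0.2).
#' @param add_strength Additive strength, pS per second (default 0.01).
#' @return List of class `"noise_params"`.
#' @export
noise_params <- function(mult_strength = 0.2, add_strength = 0.01) {
  stopifnot(mult_strength >= 0, add_strength >= 0)
  structure(list(mult_strength = mult_strength, add_strength = add_strength),
            class = "noise_params")
}

#' Neuron / population parameters
#'
#' @param tau_m_ms Membrane time constant in ms (default 10).
#' @param threshold_mv Firing threshold above rest in mV (default 10).
#' @param n_inputs Synapses per neuron (default 100).
#' @param n_neurons Population size (default 1000).
#' @param k_gain Synaptic coupling in mV per pS of weight: each presynaptic
#'   spike bumps the membrane by `k_gain * w`. Default 1, calibrated so that
#'   ~20 near-coincident average-weight (0.5 pS) inputs reach threshold.
#' @return List of class `"neuron_params"` (times in seconds).
#' @export
neuron_params <- function(tau_m_ms = 10, threshold_mv = 10, n_inputs = 100L,
                          n_neurons = 1000L, k_gain = 1) {
  stopifnot(tau_m_ms > 0, threshold_mv > 0, n_inputs >= 1, n_neurons >= 1,
            k_gain > 0)
  structure(list(tau_m = tau_m_ms / 1000, threshold = threshold_mv,
                 n_inputs = as.integer(n_inputs),
                 n_neurons = as.integer(n_neurons), k_gain = k_gain),
            class = "neuron_params")
}

#' Stimulation protocol
#'
#' @param kind `"silent"` (no input), `"poisson"` (Poisson trains) or
#'   `"periodic"` (fixed inter-spike interval, random phase per input).
#' @param rate_hz Input rate in Hz; must be 0 iff `kind = "silent"`.
#' @param stim_proportion Fraction of inputs receiving the stimulus in
#'   `[0, 1]`; the rest stay silent.
#' @return List of class `"stimulus_protocol"`.
#' @export
stimulus_protocol <- function(kind = c("silent", "poisson", "periodic"),
                              rate_hz = 0, stim_proportion = 0.5) {
  kind <- match.arg(kind)
  if ((kind == "silent") != (rate_hz == 0))
    stop("rate_hz must be 0 exactly when kind is 'silent'", call. = FALSE)
  stopifnot(rate_hz >= 0, stim_proportion >= 0, stim_proportion <= 1)
  structure(list(kind = kind, rate = rate_hz,
                 stim_proportion = stim_proportion),
            class = "stimulus_protocol")
}

#' Single STDP potentiation update
#'
#' Pre-before-post pairing (`delta_t = t_pre - t_post <= 0`):
#' `w' = w + c_p * exp(-|delta_t| / tau_stdp)`. Coincidence (`delta_t = 0`)
#' gives the maximal increment `c_p`.
#'
#' @param w Weight (pS).
#' @param delta_t Pairing interval in seconds, `<= 0`.
#' @param params An [stdp_params()].
#' @return Updated weight.
#' @export
stdp_potentiate <- function(w, delta_t, params = stdp_params()) {
  if (any(delta_t > 0))
    stop("potentiation requires delta_t <= 0 (pre before post)", call. = FALSE)
  w + params$c_p * exp(-abs(delta_t) / params$tau_stdp)
}

#' Single STDP depression update
#'
#' Post-before-pre pairing (`delta_t = t_pre - t_post > 0`):
#' `w' = w * (1 - c_d * exp(-delta_t / tau_stdp))`. Multiplicative, so zero
#' weights stay zero and weights never turn negative for `c_d < 1`.
#'
#' @inheritParams stdp_potentiate
#' @param delta_t Pairing interval in seconds, `> 0`.
#' @return Updated weight.
#' @export
stdp_depress <- function(w, delta_t, params = stdp_params()) {
  if (any(delta_t <= 0))
    stop("depression requires delta_t > 0 (post before pre)", call. = FALSE)
  w * (1 - params$c_d * exp(-delta_t / params$tau_stdp))
}

#' One Euler–Maruyama step of the intrinsic noise process
#'
#' `w' = w * (1 + mult * sqrt(dt) * xi1) + add * sqrt(dt) * xi2` with
#' independent standard normal `xi` per synapse; negative results are clipped
#' to zero.
#'
#' @param weights Numeric vector of weights.
#' @param dt Step length in seconds.
#' @param params A [noise_params()].
#' @return Updated weights.
#' @export
apply_intrinsic_noise <- function(weights, dt, params = noise_params()) {
  stopifnot(dt > 0)
  n <- length(weights)
  w <- weights * (1 + params$mult_strength * sqrt(dt) * rnorm(n)) +
    params$add_strength * sqrt(dt) * rnorm(n)
  pmax(w, 0)
}

#' Uniform heterosynaptic scaling
#'
#' Rescales a neuron's weight vector so its total equals `target_total`,
#' preserving all ratios. This is the homeostatic constraint keeping the total
#' synaptic conductance of a neuron constant. An all-zero vector cannot be
#' scaled; it is returned unchanged with attribute `skipped = TRUE`.
#'
#' @param weights Non-negative weight vector.
#' @param target_total Desired total (> 0).
#' @return Scaled weights (sum exactly `target_total` up to machine
#'   precision).
#' @export
heterosynaptic_scale <- function(weights, target_total) {
  stopifnot(target_total > 0)
  s <- sum(weights)
  if (s == 0) {
    warning("all-zero weights: scaling skipped", call. = FALSE)
    attr(weights, "skipped") <- TRUE
    return(weights)
  }
  weights * (target_total / s)
}

#' Generate input spike trains for a protocol
#'
#' The first `floor(stim_proportion * n_inputs)` inputs are stimulated
#' (Poisson at `rate` or periodic with random phase); the rest are silent.
#'
#' @param protocol A [stimulus_protocol()].
#' @param duration Seconds.
#' @param n_inputs Number of inputs.
#' @param dt Optional resolution check: rates above `1/dt` cannot be resolved
#'   by a stepped integrator and raise an error.
#' @return List of `n_inputs` numeric vectors of spike times (seconds).
#' @export
generate_input_spikes <- function(protocol, duration, n_inputs, dt = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"), duration > 0)
  if (!is.null(dt) && protocol$rate > 1 / dt)
    stop("rate exceeds 1/dt: unresolvable at this step size", call. = FALSE)
  n_stim <- floor(protocol$stim_proportion * n_inputs)
  trains <- rep(list(numeric(0)), n_inputs)
  if (protocol$kind == "silent" || n_stim == 0) return(trains)
  isi <- 1 / protocol$rate
  for (i in seq_len(n_stim)) {
    if (protocol$kind == "periodic") {
      phase <- runif(1) * isi
      trains[[i]] <- seq(phase, duration, by = isi)
    } else {
      # Poisson: draw a comfortable surplus of exponential gaps, then trim
      n_exp <- ceiling(protocol$rate * duration + 4 * sqrt(protocol$rate * duration) + 10)
      t <- cumsum(rexp(n_exp, protocol$rate))
      while (t[length(t)] < duration)
        t <- c(t, t[length(t)] + cumsum(rexp(n_exp, protocol$rate)))
      trains[[i]] <- t[t <= duration]
    }
  }
  trains
}

#' Reference leaky integrate-and-fire simulation
#'
#' Stepped LIF integrator used for unit-scale verification: the membrane
#' potential decays exponentially towards `i_const` with time constant
#' `tau_m`, presynaptic spikes at input `i` add `k_gain * w[i]`
#' instantaneously (delta-current coupling), and reaching threshold emits a
#' spike and resets to rest. The population simulator ([run_simulation()])
#' integrates the same dynamics event-exactly in compiled code.
#'
#' @param neuron A [neuron_params()].
#' @param weights Weight vector (length `n_inputs`).
#' @param spike_trains List of presynaptic spike-time vectors (seconds), from
#'   [generate_input_spikes()].
#' @param duration Seconds.
#' @param dt Step (s); must satisfy `dt <= 0.1 * tau_m`.
#' @param i_const Constant drive expressed as the steady-state potential it
#'   sustains (mV); the closed-form inter-spike interval under suprathreshold
#'   constant drive is `tau_m * log(I / (I - theta))`.
#' @return Numeric vector of postsynaptic spike times.
#' @export
simulate_lif <- function(neuron, weights, spike_trains, duration,
                         dt = 1e-4, i_const = 0) {
  stopifnot(inherits(neuron, "neuron_params"), dt <= 0.1 * neuron$tau_m)
  n_steps <- ceiling(duration / dt)
  # per-step increments from presynaptic spikes
  incr <- numeric(n_steps)
  for (i in seq_along(spike_trains)) {
    if (length(spike_trains[[i]]) == 0) next
    steps <- pmin(pmax(ceiling(spike_trains[[i]] / dt), 1L), n_steps)
    for (s in steps) incr[s] <- incr[s] + neuron$k_gain * weights[i]
  }
  decay <- exp(-dt / neuron$tau_m)
  drive <- i_const * (1 - decay)
  V <- 0
  out <- numeric(0)
  for (s in seq_len(n_steps)) {
    V <- V * decay + drive + incr[s]
    if (V >= neuron$threshold) {
      out <- c(out, s * dt)
      V <- 0
    }
  }
  out
}

#' Run the population weight-dynamics simulation
#'
#' Full model: a population of independent LIF neurons, each with `n_inputs`
#' synapses, evolving under (i) the stimulation protocol, (ii) exponential-
#' window STDP with additive potentiation / multiplicative depression
#' (nearest-neighbour pairing), (iii) intrinsic multiplicative + additive
#' Gaussian noise, and (iv) uniform heterosynaptic scaling that keeps each
#' neuron's total conductance at its initial value. Spiking dynamics are
#' integrated event-exactly; noise and scaling are applied every `dt_noise`
#' seconds. Deterministic given `seed`.
#'
#' @param neuron,stdp,noise,protocol Parameter objects (see
#'   [neuron_params()], [stdp_params()], [noise_params()],
#'   [stimulus_protocol()]).
#' @param duration Simulated seconds (default 20).
#' @param seed Integer seed.
#' @param init_weights Optional `n_neurons x n_inputs` matrix of initial
#'   weights; default i.i.d. Uniform(0, 2 * `w_mean`).
#' @param w_mean Mean initial weight in pS (default 0.5).
#' @param dt_noise Noise/scaling substep in seconds (default 0.01).
#' @param stdp_on,scaling_on Toggles for the STDP and scaling stages.
#' @param snapshot_interval If > 0, record the full weight vector every this
#'   many seconds (rounded to the noise grid).
#' @return Object of class `"sim_result"`: `final_weights` (matrix),
#'   `spike_counts`, `snapshots` (rows = times) with `snapshot_times`,
#'   `target_totals`, the parameter objects and `seed`.
#' @export
run_simulation <- function(neuron = neuron_params(), stdp = stdp_params(),
                           noise = noise_params(),
                           protocol = stimulus_protocol("silent"),
                           duration = 20, seed = 1L, init_weights = NULL,
                           w_mean = 0.5, dt_noise = 0.01, stdp_on = TRUE,
                           scaling_on = TRUE, snapshot_interval = 0) {
  stopifnot(duration > 0, dt_noise > 0)
  set.seed(as.integer(seed))
  if (is.null(init_weights)) {
    init_weights <- matrix(runif(neuron$n_neurons * neuron$n_inputs,
                                 0, 2 * w_mean),
                           neuron$n_neurons, neuron$n_inputs)
  }
  stopifnot(nrow(init_weights) == neuron$n_neurons,
            ncol(init_weights) == neuron$n_inputs,
            all(init_weights >= 0))
  n_steps <- round(duration / dt_noise)
  snap_steps <- integer(0)
  if (snapshot_interval > 0) {
    every <- max(1L, round(snapshot_interval / dt_noise))
    snap_steps <- seq(every, n_steps, by = every)
  }
  proto_code <- match(protocol$kind, c("silent", "poisson", "periodic")) - 1L
  res <- sim_core(init_weights, proto_code, protocol$rate,
                  protocol$stim_proportion, duration, dt_noise,
                  noise$mult_strength, noise$add_strength,
                  isTRUE(stdp_on), stdp$c_p, stdp$c_d, stdp$tau_stdp,
                  neuron$tau_m, neuron$threshold, neuron$k_gain,
                  isTRUE(scaling_on), as.integer(snap_steps))
  structure(list(final_weights = res$weights,
                 spike_counts = res$spike_counts,
                 snapshots = res$snapshots,
                 snapshot_times = snap_steps * dt_noise,
                 target_totals = rowSums(init_weights),
                 neuron = neuron, stdp = stdp, noise = noise,
                 protocol = protocol, duration = duration,
                 dt_noise = dt_noise, stdp_on = isTRUE(stdp_on),
                 scaling_on = isTRUE(scaling_on), seed = as.integer(seed)),
            class = "sim_result")
}

#' Run the three-protocol suite
#'
#' Three simulations sharing every parameter and differing only in the input:
#' `silent` (no input), `control` (Poisson at `control_rate`, default 10 Hz)
#' and `hfs` (periodic at `hfs_rate`, default 200 Hz — high-frequency
#' stimulation). Each run gets its own seed derived from `seed` so the suites
#' are reproducible as a unit.
#'
#' @inheritParams run_simulation
#' @param stim_proportion Fraction of stimulated inputs for the driven
#'   protocols.
#' @param control_rate,hfs_rate Input rates (Hz).
#' @return Named list of class `"protocol_suite"` with elements `silent`,
#'   `control`, `hfs` (each a `"sim_result"`).
#' @export
run_protocol_suite <- function(neuron = neuron_params(),
                               stdp = stdp_params(), noise = noise_params(),
                               stim_proportion = 0.5, control_rate = 10,
                               hfs_rate = 200, duration = 20, seed = 1L,
                               w_mean = 0.5, dt_noise = 0.01,
                               scaling_on = TRUE) {
  protos <- list(
    silent = stimulus_protocol("silent", 0, stim_proportion),
    control = stimulus_protocol("poisson", control_rate, stim_proportion),
    hfs = stimulus_protocol("periodic", hfs_rate, stim_proportion))
  out <- lapply(seq_along(protos), function(i)
    run_simulation(neuron, stdp, noise, protos[[i]], duration,
                   seed = as.integer(seed) + (i - 1L) * 1009L,
                   w_mean = w_mean, dt_noise = dt_noise,
                   scaling_on = scaling_on))
  names(out) <- names(protos)
  structure(out, class = "protocol_suite")
}

#' Lognormal generation demo: uniform start, multiplicative noise only
#'
#' The minimal intrinsic-plasticity experiment: feed a Uniform(0, 1) weight
#' population into the model with only multiplicative noise active (no STDP,
#' no additive noise, no scaling) and watch the distribution turn lognormal.
#' Snapshots allow tracking the goodness of the lognormal fit over time.
#'
#' @param n_synapses Total synapse count (default 10^4).
#' @param mult_strength Multiplicative noise strength per second.
#' @param duration Seconds (default 100).
#' @param snapshot_interval Seconds between snapshots (default `duration/10`).
#' @param seed Integer seed.
#' @param dt_noise Noise substep (s).
#' @return A `"sim_result"` whose rows of `snapshots` are the weight
#'   population at each snapshot time.
#' @export
run_generation_demo <- function(n_synapses = 1e4, mult_strength = 0.2,
                                duration = 100, snapshot_interval = NULL,
                                seed = 1L, dt_noise = 0.01) {
  if (is.null(snapshot_interval)) snapshot_interval <- duration / 10
  n_inputs <- 100L
  n_neurons <- as.integer(ceiling(n_synapses / n_inputs))
  run_simulation(
    neuron = neuron_params(n_inputs = n_inputs, n_neurons = n_neurons),
    stdp = stdp_params(), noise = noise_params(mult_strength, 0),
    protocol = stimulus_protocol("silent"), duration = duration,
    seed = seed, w_mean = 0.5, dt_noise = dt_noise, stdp_on = FALSE,
    scaling_on = FALSE, snapshot_interval = snapshot_interval)
}
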