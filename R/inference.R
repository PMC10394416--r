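PARAM_NAMES <- c("stim_proportion", "mult_strength", "add_strength",
                 "tau_stdp_ms", "pot_rate", "dep_rate_rel")

#' Uniform prior box over the six plasticity parameters
#'
#' The inferable parameters are: the proportion of inputs receiving
#' stimulation, the proportional strength of multiplicative noise per second,
#' the absolute strength of additive noise per second, the STDP timescale in
#' ms, the absolute rate of potentiation (pS) and the relative rate of
#' depression. Prior ranges are not constrained by published estimates and
#' must be chosen per study; the defaults span biologically sensible decades.
#'
#' @param lower,upper Named or positional numeric vectors of length 6 in the
#'   order `stim_proportion, mult_strength, add_strength, tau_stdp_ms,
#'   pot_rate, dep_rate_rel`.
#' @return Object of class `"prior_box"`.
#' @export
prior_box <- function(lower = c(0, 0, 0, 0.1, 0, 0),
                      upper = c(1, 0.5, 0.1, 50, 0.05, 0.5)) {
  lower <- setNames(as.numeric(lower), PARAM_NAMES)
  upper <- setNames(as.numeric(upper), PARAM_NAMES)
  if (any(lower >= upper))
    stop("prior_box: lower must be < upper elementwise", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "prior_box")
}

#' Reduced-scale simulation settings used during inference
#'
#' Per-candidate simulations run a smaller population and shorter duration
#' than a presentation run; the final MAP validation can use full scale.
#'
#' @param n_neurons,n_inputs Population shape (default 100 x 50).
#' @param duration Simulated seconds per protocol (default 0.8).
#' @param dt_noise Noise substep (s).
#' @param w_mean Mean initial weight (pS).
#' @param n_bins Bin count for the lognormal feature fits.
#' @return List of class `"inference_settings"`.
#' @export
inference_settings <- function(n_neurons = 100L, n_inputs = 50L,
                               duration = 0.8, dt_noise = 0.02, w_mean = 0.5,
                               n_bins = 25L) {
  structure(list(n_neurons = as.integer(n_neurons),
                 n_inputs = as.integer(n_inputs), duration = duration,
                 dt_noise = dt_noise, w_mean = w_mean,
                 n_bins = as.integer(n_bins)),
            class = "inference_settings")
}

theta_suite <- function(theta, settings, seed) {
  run_protocol_suite(
    neuron = neuron_params(n_inputs = settings$n_inputs,
                           n_neurons = settings$n_neurons),
    stdp = stdp_params(c_p = theta[["pot_rate"]],
                       c_d = theta[["dep_rate_rel"]],
                       tau_stdp_ms = theta[["tau_stdp_ms"]]),
    noise = noise_params(theta[["mult_strength"]], theta[["add_strength"]]),
    stim_proportion = theta[["stim_proportion"]],
    duration = settings$duration, seed = seed, w_mean = settings$w_mean,
    dt_noise = settings$dt_noise)
}

#' Summary features of a protocol suite
#'
#' Per protocol, the simulated weights are rescaled to the target mean spine
#' size (the bridge from model weights in pS to measured areas in um^2:
#' multiplying a sample by `c` shifts the fitted lognormal `mu` by `log(c)`
#' and leaves `sigma` unchanged) and a lognormal is fitted; the six features
#' are `(mu, sigma)` for silent, control and HFS.
#'
#' @param suite A `"protocol_suite"` (or list of three `"sim_result"`s named
#'   silent/control/hfs).
#' @param target_means Optional named numeric: target mean per protocol; if
#'   `NULL`, no rescaling.
#' @param n_bins Bin count for the fits.
#' @return Named numeric of length 6 (`mu_silent`, `sigma_silent`,
#'   `mu_control`, `sigma_control`, `mu_hfs`, `sigma_hfs`), with attribute
#'   `valid` = FALSE if any fit failed.
#' @export
summarize_suite <- function(suite, target_means = NULL, n_bins = 30L) {
  protos <- c("silent", "control", "hfs")
  feats <- numeric(0)
  valid <- TRUE
  for (p in protos) {
    w <- as.numeric(suite[[p]]$final_weights)
    w <- w[w > 0]
    if (length(w) < 100) { valid <- FALSE; w <- c(w, rep(NA_real_, 100)) }
    if (!is.null(target_means) && valid)
      w <- w * (target_means[[p]] / mean(w))
    fit <- if (valid) fit_lognormal_sample(w, n_bins) else
      list(mu = NA_real_, sigma = NA_real_, r2 = NaN, converged = FALSE)
    if (!isTRUE(fit$converged) || !is.finite(fit$mu) || !is.finite(fit$sigma))
      valid <- FALSE
    feats <- c(feats, fit$mu, fit$sigma)
  }
  names(feats) <- as.vector(rbind(paste0("mu_", protos),
                                  paste0("sigma_", protos)))
  attr(feats, "valid") <- valid
  feats
}

#' Sequential rejection-ABC over the plasticity parameters
#'
#' Simulation-based inference with a rejection core: round 1 samples the
#' uniform prior; every round simulates the three-protocol suite for each
#' candidate, computes the six lognormal summary features, and keeps the
#' fraction `eps` of candidates closest to the observed features under
#' Euclidean distance standardized by the round-1 feature spreads. Subsequent
#' rounds propose from Gaussian perturbations of the weighted survivors,
#' truncated to the prior box, with Beaumont-style importance weights
#' correcting for the proposal so the sequential posterior stays consistent
#' with plain rejection sampling. The final survivors are resampled by weight
#' to `n_posterior` draws. The interface (observed features in, posterior
#' draws and MAP out) is the same one a neural posterior-estimation backend
#' would present, so such a backend can be slotted in behind it.
#'
#' @param observed Named numeric of 6 observed features (see
#'   [summarize_suite()]).
#' @param prior A [prior_box()].
#' @param rounds Number of sequential rounds (default 5).
#' @param sims_per_round Simulations per round (default 3200).
#' @param seed Integer seed.
#' @param eps Acceptance fraction per round (default 0.1).
#' @param n_posterior Size of the resampled posterior (default 10000).
#' @param settings An [inference_settings()].
#' @param target_means Passed to [summarize_suite()] for each candidate.
#' @param perturb_scale Multiplier on the survivors' per-dimension weighted
#'   sd for the proposal kernel (default `sqrt(2)`, the optimality rule for
#'   Gaussian ABC-PMC kernels).
#' @param verbose Print per-round progress.
#' @return Object of class `"posterior_samples"`: `draws`
#'   (`n_posterior x 6`), `map`, `survivors`, `distances`, `rounds_run`,
#'   `sims_per_round`, `prior`, `feature_sds`, `observed`.
#' @export
sequential_infer <- function(observed, prior = prior_box(), rounds = 5,
                             sims_per_round = 3200, seed = 1L, eps = 0.1,
                             n_posterior = 10000,
                             settings = inference_settings(),
                             target_means = NULL, perturb_scale = sqrt(2),
                             verbose = FALSE) {
  stopifnot(rounds >= 1, sims_per_round >= 50, eps > 0, eps <= 1)
  obs <- as.numeric(observed)[1:6]
  seed <- as.integer(seed)
  d <- length(PARAM_NAMES)
  lower <- prior$lower; upper <- prior$upper
  survivors <- NULL
  weights <- NULL
  feat_sds <- NULL
  sim_counter <- 0L
  for (r in seq_len(rounds)) {
    set.seed(seed + 7919L * r)
    theta_mat <- matrix(NA_real_, sims_per_round, d,
                        dimnames = list(NULL, PARAM_NAMES))
    from_prior <- r == 1 || is.null(survivors)
    if (from_prior) {
      for (j in seq_len(d))
        theta_mat[, j] <- runif(sims_per_round, lower[j], upper[j])
    } else {
      wvar <- vapply(seq_len(d), function(j) {
        m <- sum(weights * survivors[, j])
        sum(weights * (survivors[, j] - m)^2)
      }, numeric(1))
      sds <- perturb_scale * sqrt(wvar)
      sds <- pmax(sds, 0.01 * (upper - lower))
      pick <- sample(nrow(survivors), sims_per_round, replace = TRUE,
                     prob = weights)
      for (i in seq_len(sims_per_round)) {
        base <- survivors[pick[i], ]
        prop <- rnorm(d, base, sds)
        for (try in 1:100) {
          if (all(prop >= lower & prop <= upper)) break
          prop <- rnorm(d, base, sds)
        }
        theta_mat[i, ] <- pmin(pmax(prop, lower), upper)
      }
    }
    feats <- matrix(NA_real_, sims_per_round, 6)
    for (i in seq_len(sims_per_round)) {
      sim_counter <- sim_counter + 1L
      f <- summarize_suite(
        theta_suite(theta_mat[i, ], settings,
                    seed = seed + 104729L + sim_counter),
        target_means = target_means, n_bins = settings$n_bins)
      if (isTRUE(attr(f, "valid"))) feats[i, ] <- f
    }
    ok <- rowSums(is.na(feats)) == 0
    if (!any(ok))
      stop("all simulations in round ", r, " produced invalid features",
           call. = FALSE)
    if (r == 1) {
      feat_sds <- apply(feats[ok, , drop = FALSE], 2, sd)
      feat_sds[!is.finite(feat_sds) | feat_sds == 0] <- 1
    }
    dist <- rep(Inf, sims_per_round)
    z <- sweep(feats[ok, , drop = FALSE], 2, obs, "-")
    z <- sweep(z, 2, feat_sds, "/")
    dist[ok] <- sqrt(rowSums(z^2))
    n_keep <- max(1L, floor(eps * sims_per_round))
    keep <- order(dist)[seq_len(n_keep)]
    new_surv <- theta_mat[keep, , drop = FALSE]
    if (from_prior) {
      new_w <- rep(1 / n_keep, n_keep)
    } else {
      # importance weight: uniform prior over Gaussian mixture proposal
      new_w <- vapply(seq_len(n_keep), function(i) {
        k <- rep(1, nrow(survivors))
        for (j in seq_len(d))
          k <- k * dnorm(new_surv[i, j], survivors[, j], sds[j])
        1 / sum(weights * k)
      }, numeric(1))
      new_w <- new_w / sum(new_w)
    }
    survivors <- new_surv
    weights <- new_w
    if (verbose)
      message(sprintf("round %d: kept %d, median distance %.3f", r, n_keep,
                      stats::median(dist[keep])))
    last_dist <- dist[keep]
  }
  set.seed(seed + 15485863L)
  idx <- sample(nrow(survivors), n_posterior, replace = TRUE, prob = weights)
  draws <- survivors[idx, , drop = FALSE]
  post <- structure(list(draws = draws, survivors = survivors,
                         weights = weights, distances = last_dist,
                         rounds_run = rounds,
                         sims_per_round = sims_per_round, prior = prior,
                         feature_sds = feat_sds, observed = obs,
                         map = NULL),
                    class = "posterior_samples")
  post$map <- map_estimate(post)
  post
}

#' Maximum a posteriori estimate from posterior draws
#'
#' Mode of a product-Gaussian kernel density estimate over the draws,
#' located by scoring the density at the distinct draws and polishing the
#' best one by mean-shift iteration. The per-dimension bandwidth is 3x the
#' Silverman rule: the raw Silverman bandwidth leaves the kernel-estimate
#' mode too variable for a reliable point estimate, while the oversmoothed
#' density still separates well-spaced posterior modes. Dimensions with zero
#' spread are fixed at their value.
#'
#' @param posterior A `"posterior_samples"` object or a draws matrix
#'   (>= 1000 draws recommended; >= 1 required).
#' @return Named numeric vector of length 6 (or ncol of the draws).
#' @export
map_estimate <- function(posterior) {
  draws <- if (inherits(posterior, "posterior_samples")) posterior$draws
           else as.matrix(posterior)
  n <- nrow(draws); d <- ncol(draws)
  sds <- apply(draws, 2, sd)
  live <- which(sds > 0)
  out <- draws[1, ]
  if (length(live) == 0) return(out)
  x <- draws[, live, drop = FALSE]
  bw <- vapply(seq_along(live), function(j)
    3 * 1.06 * sds[live[j]] * n^(-1 / (4 + length(live))), numeric(1))
  kernels <- unique(x)
  if (nrow(kernels) > 5000)
    kernels <- kernels[seq(1, nrow(kernels), length.out = 5000), ,
                       drop = FALSE]
  centers <- kernels
  if (nrow(centers) > 1000)
    centers <- centers[seq(1, nrow(centers), length.out = 1000), ,
                       drop = FALSE]
  kde_at <- function(pt) {
    wts <- rep(1, nrow(kernels))
    for (j in seq_along(pt))
      wts <- wts * dnorm((kernels[, j] - pt[j]) / bw[j])
    wts
  }
  dens <- apply(centers, 1, function(p) sum(kde_at(p)))
  best <- centers[which.max(dens), ]
  for (it in 1:50) {  # mean-shift polish toward the density maximum
    wts <- kde_at(best)
    if (sum(wts) == 0) break
    new <- colSums(kernels * wts) / sum(wts)
    if (max(abs(new - best)) < 1e-12) { best <- new; break }
    best <- new
  }
  out[live] <- best
  out
}

#' Marginal densities of the posterior
#'
#' Normalised 1-D histograms per parameter and 2-D histograms for all
#' parameter pairs, over the prior box (or the draw range if no prior is
#' attached).
#'
#' @param posterior A `"posterior_samples"` object or draws matrix.
#' @param n_bins Bins per dimension (default 30).
#' @return List with `single` (named list of `data.frame(center, density)`)
#'   and `pairwise` (named list of `list(x_centers, y_centers, density)`).
#' @export
marginals <- function(posterior, n_bins = 30L) {
  draws <- if (inherits(posterior, "posterior_samples")) posterior$draws
           else as.matrix(posterior)
  pr <- if (inherits(posterior, "posterior_samples")) posterior$prior else NULL
  d <- ncol(draws)
  nms <- colnames(draws) %||% paste0("p", seq_len(d))
  lims <- lapply(seq_len(d), function(j) {
    if (!is.null(pr)) c(pr$lower[j], pr$upper[j]) else range(draws[, j])
  })
  single <- lapply(seq_len(d), function(j) {
    lo <- lims[[j]][1]; hi <- lims[[j]][2]
    if (hi <= lo) hi <- lo + 1e-12
    edges <- seq(lo, hi, length.out = n_bins + 1)
    width <- (hi - lo) / n_bins
    idx <- pmin(pmax(floor((draws[, j] - lo) / width) + 1L, 1L), n_bins)
    dens <- tabulate(idx, n_bins) / (nrow(draws) * width)
    data.frame(center = edges[-(n_bins + 1)] + width / 2, density = dens)
  })
  names(single) <- nms
  pairs <- utils::combn(d, 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(pr2) {
    j1 <- pr2[1]; j2 <- pr2[2]
    lo1 <- lims[[j1]][1]; w1 <- (lims[[j1]][2] - lo1) / n_bins
    lo2 <- lims[[j2]][1]; w2 <- (lims[[j2]][2] - lo2) / n_bins
    i1 <- pmin(pmax(floor((draws[, j1] - lo1) / w1) + 1L, 1L), n_bins)
    i2 <- pmin(pmax(floor((draws[, j2] - lo2) / w2) + 1L, 1L), n_bins)
    h <- matrix(tabulate((i2 - 1L) * n_bins + i1, n_bins * n_bins),
                n_bins, n_bins) / (nrow(draws) * w1 * w2)
    list(x_centers = lo1 + w1 * (seq_len(n_bins) - 0.5),
         y_centers = lo2 + w2 * (seq_len(n_bins) - 0.5), density = h)
  })
  names(pairwise) <- vapply(pairs, function(p) paste(nms[p], collapse = ":"),
                            "")
  list(single = single, pairwise = pairwise)
}

#' Re-simulate at the MAP and compare with the observation
#'
#' Runs the protocol suite at the MAP parameter vector, rescales each
#' protocol's weights to the observed mean, and reports the r-squared between
#' the observed and simulated binned densities evaluated on the observed bin
#' grid — the "dashed vs solid" closed-loop check that the inferred
#' parameters actually reproduce the observed distributions.
#'
#' @param map Named parameter vector (6 entries, see [prior_box()]).
#' @param observed_weights Named list (`silent`, `control`, `hfs`) of observed
#'   weight/size samples.
#' @param settings An [inference_settings()] controlling the re-simulation
#'   scale.
#' @param seed Integer seed.
#' @param n_bins Bin count for the comparison grid.
#' @return Named numeric `c(silent = r2, control = r2, hfs = r2)`.
#' @export
simulate_map_and_compare <- function(map, observed_weights,
                                     settings = inference_settings(),
                                     seed = 1L, n_bins = 30L) {
  suite <- theta_suite(map, settings, seed = as.integer(seed))
  out <- vapply(c("silent", "control", "hfs"), function(p) {
    obs <- observed_weights[[p]]
    obs <- obs[obs > 0]
    binned <- bin_and_normalize(obs, n_bins)
    w <- as.numeric(suite[[p]]$final_weights)
    w <- w[w > 0]
    w <- w * (mean(obs) / mean(w))
    sim_d <- density_on_grid(w, binned$edges)
    r_squared(binned$density, sim_d)
  }, numeric(1))
  out
}

# integral-normalised density of `x` on a fixed equal-width edge grid;
# out-of-range mass is clamped into the end bins so the integral stays 1
density_on_grid <- function(x, edges) {
  nb <- length(edges) - 1L
  width <- edges[2] - edges[1]
  idx <- pmin(pmax(floor((x - edges[1]) / width) + 1L, 1L), nb)
  tabulate(idx, nb) / (length(x) * width)
}
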