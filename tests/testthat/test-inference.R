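test_that("summary features shift by log(c) under mean rescaling", {
  set.seed(50)
  w <- matrix(rlnorm(5000, -1, 0.5), 100, 50)
  suite <- list(silent = list(final_weights = w),
                control = list(final_weights = w),
                hfs = list(final_weights = w))
  f0 <- summarize_suite(suite)
  expect_true(attr(f0, "valid"))
  expect_equal(f0[["mu_silent"]], f0[["mu_hfs"]])
  expect_equal(f0[["sigma_silent"]], f0[["sigma_control"]])
  cur_mean <- mean(w)
  f1 <- summarize_suite(suite, target_means = list(silent = cur_mean,
                                                   control = 2 * cur_mean,
                                                   hfs = cur_mean))
  expect_equal(f1[["mu_silent"]], f0[["mu_silent"]])
  expect_equal(f1[["mu_control"]] - f0[["mu_control"]], log(2),
               tolerance = 1e-6)
  expect_equal(f1[["sigma_control"]], f0[["sigma_control"]],
               tolerance = 1e-6)
})

test_that("with selection disabled the posterior returns the prior", {
  st <- tiny_settings()
  obs <- summarize_suite(spinedyn:::theta_suite(theta_reference(), st,
                                                seed = 1))
  post <- sequential_infer(obs, rounds = 1, sims_per_round = 2000, eps = 1,
                           n_posterior = 10000, seed = 3, settings = st)
  pr <- post$prior
  for (p in colnames(post$draws)) {
    u <- (post$draws[, p] - pr$lower[p]) / (pr$upper[p] - pr$lower[p])
    ks <- suppressWarnings(stats::ks.test(u, "punif")$statistic)
    expect_lt(unname(ks), 0.05)
  }
})

test_that("sequential inference is deterministic per seed", {
  st <- tiny_settings()
  obs <- summarize_suite(spinedyn:::theta_suite(theta_reference(), st,
                                                seed = 2))
  a <- sequential_infer(obs, rounds = 2, sims_per_round = 60,
                        n_posterior = 500, seed = 11, settings = st)
  b <- sequential_infer(obs, rounds = 2, sims_per_round = 60,
                        n_posterior = 500, seed = 11, settings = st)
  expect_identical(a$draws, b$draws)
  expect_identical(a$map, b$map)
  # draws never leave the prior box
  pr <- a$prior
  for (p in colnames(a$draws)) {
    expect_gte(min(a$draws[, p]), pr$lower[p])
    expect_lte(max(a$draws[, p]), pr$upper[p])
  }
})

test_that("MAP estimation finds modes of known densities", {
  set.seed(52)
  g <- matrix(rnorm(5000 * 2, mean = c(2, -1)), ncol = 2, byrow = TRUE)
  m <- map_estimate(g)
  expect_lt(abs(m[1] - 2), 0.1)
  expect_lt(abs(m[2] - (-1)), 0.1)
  # bimodal: the heavier mode wins
  bi <- cbind(c(rnorm(3500, 0, 0.2), rnorm(1500, 3, 0.2)))
  expect_lt(abs(map_estimate(bi)[1] - 0), 0.15)
  # degenerate draws collapse to the point
  flat <- matrix(rep(c(0.3, 7), each = 50), ncol = 2)
  expect_equal(unname(map_estimate(flat)), c(0.3, 7))
})

test_that("marginals are normalised and preserve correlation structure", {
  set.seed(53)
  u <- matrix(runif(6000), ncol = 6,
              dimnames = list(NULL, spinedyn:::PARAM_NAMES))
  mg <- marginals(u, n_bins = 20)
  for (m in mg$single) {
    width <- diff(m$center[1:2])
    expect_lt(abs(sum(m$density * width) - 1), 1e-9)
    expect_lt(max(abs(m$density - 1)) , 0.5)  # flat within sampling noise
  }
  expect_length(mg$pairwise, 15)
  # strongly correlated pair shows up in the 2-D histogram
  z <- rnorm(3000)
  xy <- cbind(z, 0.9 * z + sqrt(1 - 0.81) * rnorm(3000))
  m2 <- marginals(xy, n_bins = 25)$pairwise[[1]]
  gx <- rep(m2$x_centers, times = 25); gy <- rep(m2$y_centers, each = 25)
  wts <- as.numeric(m2$density); wts <- wts / sum(wts)
  mx <- sum(gx * wts); my <- sum(gy * wts)
  rho <- sum((gx - mx) * (gy - my) * wts) /
    sqrt(sum((gx - mx)^2 * wts) * sum((gy - my)^2 * wts))
  expect_lt(abs(rho - 0.9), 0.05)
})

test_that("MAP re-simulation matches the observation it was fitted to", {
  st <- inference_settings(n_neurons = 20L)
  theta <- theta_reference()
  suite <- spinedyn:::theta_suite(theta, st, seed = 60)
  obs_w <- lapply(suite, function(s) as.numeric(s$final_weights))
  # same parameters, same seed: the comparison is exact
  r2_same <- simulate_map_and_compare(theta, obs_w, st, seed = 60)
  expect_true(all(r2_same > 1 - 1e-9))
  # a prior-corner parameter vector fits visibly worse
  corner <- c(stim_proportion = 1, mult_strength = 0.5, add_strength = 0.1,
              tau_stdp_ms = 50, pot_rate = 0.05, dep_rate_rel = 0.5)
  r2_corner <- simulate_map_and_compare(corner, obs_w, st, seed = 61)
  expect_lt(min(r2_corner), min(r2_same) - 0.05)
})
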