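test_that("log moments match hand-computed values", {
  expect_equal(unname(log_moments(rep(exp(1), 5))), c(1, 0))
  expect_equal(unname(log_moments(c(1, exp(2)))), c(1, sd(c(0, 2))))
  expect_error(log_moments(c(1, -1)), "positive")
  expect_error(log_moments(2), "at least 2")
  set.seed(1)
  lm0 <- log_moments(rlnorm(1e5, -1, 0.5))
  expect_lt(abs(lm0[["mu0"]] - (-1)), 0.01)
  expect_lt(abs(lm0[["sigma0"]] - 0.5), 0.01)
})

test_that("binned densities integrate to one and are flat for uniform data", {
  set.seed(2)
  for (x in list(rlnorm(500, -1, 0.5), rexp(77), runif(1234))) {
    b <- bin_and_normalize(x, 17)
    expect_lt(abs(sum(b$density * b$width) - 1), 1e-9)
    expect_true(all(b$density >= 0))
    expect_true(all(diff(b$edges) > 0))
  }
  b <- bin_and_normalize(runif(1e6), 10)
  expect_true(all(abs(b$density - 1) < 0.02))
  b2 <- bin_and_normalize(c(1, 1, 2, 2), 2)
  expect_equal(b2$density[1], b2$density[2])
  expect_error(bin_and_normalize(rep(3, 10), 5), "degenerate")
})

test_that("r-squared reproduces hand computations and edge cases", {
  obs <- c(0.2, 0.5, 0.9, 0.1)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  # SS_res = 2, SS_tot = 0.5 -> 1 - 4 = -3
  expect_equal(r_squared(c(0, 1), c(1, 0)), -3)
  expect_true(is.nan(r_squared(c(1, 1), c(1, 2))))
})

test_that("lognormal fit recovers an analytically generated density", {
  edges <- seq(qlnorm(0.001, -1, 0.5), qlnorm(0.999, -1, 0.5),
               length.out = 51)
  centers <- edges[-51] + diff(edges) / 2
  binned <- structure(list(edges = edges, centers = centers,
                           width = diff(edges)[1],
                           density = dlnorm(centers, -1, 0.5),
                           counts = NULL, n = 50L),
                      class = "binned_density")
  fit <- fit_lognormal(binned, init = c(-0.7, 0.8))
  expect_true(fit$converged)
  expect_lt(abs(fit$mu - (-1)), 1e-6)
  expect_lt(abs(fit$sigma - 0.5), 1e-6)
  expect_gt(fit$r2, 1 - 1e-6)
})

test_that("lognormal fit recovers parameters from samples", {
  set.seed(3)
  fit <- fit_lognormal_sample(rlnorm(1e4, -1, 0.5), 30)
  expect_lt(abs(fit$mu - (-1)), 0.05)
  expect_lt(abs(fit$sigma - 0.5), 0.05)
  expect_gt(fit$r2, 0.95)
})

test_that("degenerate samples are flagged, not raised", {
  fit <- fit_lognormal_sample(rep(1, 100))
  expect_false(fit$converged)
  expect_true(is.nan(fit$r2))
})

test_that("gaussian fit in log-space matches the lognormal parameters", {
  # exact bump: a * exp(-((x-b)/c)^2) sampled on a grid
  x <- seq(-3, 1, length.out = 40)
  binned <- structure(list(edges = c(x - 0.05, max(x) + 0.05), centers = x,
                           width = 0.1,
                           density = 0.8 * exp(-((x + 1) / 0.7)^2),
                           counts = NULL, n = 40L),
                      class = "binned_density")
  g <- fit_gaussian_binned(binned)
  expect_lt(abs(g$a - 0.8), 1e-6)
  expect_lt(abs(g$b - (-1)), 1e-6)
  expect_lt(abs(g$c - 0.7), 1e-6)
  expect_gt(g$r2, 1 - 1e-6)

  set.seed(4)
  g2 <- fit_gaussian_log(rlnorm(1e4, -1, 0.5), 30)
  expect_lt(abs(g2$b - (-1)), 0.05)
  expect_lt(abs(g2$c - 0.5 * sqrt(2)), 0.1)
  expect_gt(g2$r2, 0.95)
})

test_that("contamination with large outliers degrades the log-Gaussian fit", {
  set.seed(5)
  clean <- rlnorm(1e4, -1, 0.5)
  contaminated <- c(rlnorm(9500, -1, 0.5), rlnorm(500, 1.0, 0.3))
  expect_lt(fit_gaussian_log(contaminated, 30)$r2,
            fit_gaussian_log(clean, 30)$r2)
})

test_that("sample skewness matches closed forms and sign conventions", {
  expect_equal(sample_skewness(c(1, 2, 3)), 0)
  set.seed(6)
  x <- rlnorm(1e5, 0, 0.5)
  s2 <- exp(0.25)
  expect_lt(abs(sample_skewness(x) - (s2 + 2) * sqrt(s2 - 1)), 0.1)
  y <- 10 - rexp(5000)  # mirrored exponential: left tail
  expect_lt(sample_skewness(y), 0)
  expect_true(is.nan(sample_skewness(rep(2, 10))))
})

test_that("skewness agrees with the independent e1071 implementation", {
  library(e1071)
  set.seed(7)
  for (x in list(rlnorm(500), rexp(50), runif(201)))
    expect_equal(sample_skewness(x), e1071::skewness(x, type = 2),
                 tolerance = 1e-12)
})

test_that("AIC tournament identifies the generating family", {
  set.seed(8)
  cmp <- compare_aic(rlnorm(500, -1, 0.5))
  expect_identical(cmp$best, "lognormal")
  expect_equal(min(cmp$delta_aic), 0)
  expect_identical(names(which.min(cmp$aic)), cmp$best)
  # Weibull shape 5 is nearly symmetric: clearly not lognormal
  wins <- vapply(1:10, function(s) {
    set.seed(100 + s)
    compare_aic(rweibull(500, shape = 5))$best
  }, "")
  expect_gt(mean(wins == "weibull"), 0.5)
})

test_that("AIC comparison is invariant to equal-likelihood candidates", {
  set.seed(9)
  x <- rlnorm(200, -1, 0.5)
  cmp <- compare_aic(x)
  # cross-check the lognormal AIC against the closed-form MLE
  lx <- log(x)
  mu <- mean(lx); s <- sqrt(mean((lx - mu)^2))
  ll <- sum(dlnorm(x, mu, s, log = TRUE))
  expect_equal(cmp$aic[["lognormal"]], 4 - 2 * ll, tolerance = 1e-3)
})

test_that("pooled and per-cell fits agree for identically generated cells", {
  set.seed(10)
  sizes <- rlnorm(300, -1, 0.5)
  tab <- data.frame(animal_id = "a1",
                    cell_id = rep(c("c1", "c2", "c3"), each = 300),
                    dataset = "abGC", layer = "IML", age = 21L,
                    side_or_group = "contra", spine_type = NA_character_,
                    head_area_um2 = rep(sizes, 3))
  pooled <- fit_condition(tab, "pooled")
  per_cell <- fit_condition(tab, "per_cell")
  expect_equal(nrow(pooled), 1L)
  expect_equal(nrow(per_cell), 3L)
  expect_true(all(abs(per_cell$mu - pooled$mu) < 0.05))
})

test_that("per-cell fits on synthetic data are uniformly good", {
  tab <- generate_spine_table(small_abgc_config(seed = 12))
  per_cell <- fit_condition(tab, "per_cell")
  expect_true(all(per_cell$n >= 60))
  # the majority of per-cell fits are good; occasional small-sample cells
  # fall below, as in real per-cell data
  expect_gt(mean(per_cell$r2 > 0.8), 0.75)
  expect_gt(stats::median(per_cell$r2), 0.85)
  expect_gt(min(per_cell$r2), 0)
  expect_true(all(per_cell$skewness > 0))
})

test_that("undersized conditions are skipped with a warning", {
  tab <- data.frame(animal_id = "a1",
                    cell_id = c(rep("c1", 5), "c2", "c2"),
                    dataset = "abGC",
                    layer = c(rep("IML", 5), "MML", "MML"), age = 21L,
                    side_or_group = "ipsi", spine_type = NA_character_,
                    head_area_um2 = c(0.3, 0.4, 0.5, 0.35, 0.6, 0.2, 0.25))
  expect_warning(res <- fit_condition(tab, "pooled"), "fewer than 3")
  expect_equal(nrow(res), 1L)
})
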