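#' Log-moments of a positive sample
#'
#' Mean and standard deviation of the natural logarithms of the sizes. These
#' are the method-of-moments lognormal parameters and serve as the starting
#' point of the nonlinear least-squares fit.
#'
#' @param sizes Strictly positive numeric vector, length >= 2.
#' @return Named numeric `c(mu0, sigma0)`.
#' @export
log_moments <- function(sizes) {
  if (length(sizes) < 2) stop("need at least 2 sizes", call. = FALSE)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all sizes must be finite and strictly positive", call. = FALSE)
  lx <- log(sizes)
  c(mu0 = mean(lx), sigma0 = sd(lx))
}

#' Integral-normalised histogram of sizes
#'
#' Bins the sample into `n_bins` equal-width bins spanning `[min, max]` and
#' divides the counts by the histogram's integral, so that
#' `sum(density * width) == 1`. This normalised binned density is the substrate
#' all curve fits work on: because raw head areas span multiple scales,
#' absolute counts are not comparable across cells.
#'
#' @param sizes Numeric vector, length >= 2.
#' @param n_bins Number of bins (>= 3), or `"auto"` for the Freedman–Diaconis
#'   rule clamped to `[10, 50]`.
#' @return An object of class `"binned_density"`: list with `edges`, `centers`,
#'   `width`, `density`, `counts`, `n`.
#' @export
bin_and_normalize <- function(sizes, n_bins = "auto") {
  if (length(sizes) < 2) stop("need at least 2 values", call. = FALSE)
  rng <- range(sizes)
  if (diff(rng) <= 0)
    stop("degenerate range: all values identical", call. = FALSE)
  if (identical(n_bins, "auto")) n_bins <- fd_bins(sizes)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("need at least 2 bins", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  width <- diff(rng) / n_bins
  idx <- pmin(pmax(floor((sizes - rng[1]) / width) + 1L, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  dens <- counts / (sum(counts) * width)  # integral exactly 1
  structure(list(edges = edges,
                 centers = edges[-(n_bins + 1L)] + width / 2,
                 width = width, density = dens, counts = counts,
                 n = length(sizes)),
            class = "binned_density")
}

# Freedman-Diaconis bin count, clamped so densities stay stable from
# per-cell samples (n ~ 60) up to pooled ones (n ~ 1e4+)
fd_bins <- function(sizes) {
  iqr <- diff(quantile(sizes, c(0.25, 0.75), names = FALSE))
  if (iqr <= 0) return(10L)
  h <- 2 * iqr / length(sizes)^(1 / 3)
  k <- ceiling(diff(range(sizes)) / h)
  as.integer(min(50L, max(10L, k)))
}

#' Coefficient of determination
#'
#' `r2 = 1 - SS_res / SS_tot` between an observed and a fitted vector. Can be
#' negative for fits worse than the mean; returns `NaN` when the observed
#' vector has zero total variation.
#'
#' @param observed,fitted Equal-length numeric vectors, length >= 2.
#' @return Scalar r-squared (<= 1).
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NaN)
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Least-squares lognormal fit to a normalised binned density
#'
#' Fits the lognormal probability density
#' \deqn{f(x) = \frac{1}{x\,\sigma\sqrt{2\pi}}
#'   \exp\!\left(-\frac{(\ln x - \mu)^2}{2\sigma^2}\right)}
#' to the bin-center densities by nonlinear least squares
#' (Levenberg–Marquardt), initialised at the log-moments of the sample.
#' `sigma` is constrained to `(1e-4, 10)` to exclude degenerate optima; `mu`
#' is unconstrained. Non-convergence is flagged (`converged = FALSE`,
#' `r2 = NaN`), never raised, so batch per-cell fitting always completes.
#'
#' @param binned A [bin_and_normalize()] result.
#' @param init Numeric `c(mu0, sigma0)` starting point, e.g. from
#'   [log_moments()].
#' @return Object of class `"lognormal_fit"`: `mu`, `sigma`, `r2`, `n`,
#'   `init_mu`, `init_sigma`, `converged`.
#' @export
fit_lognormal <- function(binned, init) {
  stopifnot(inherits(binned, "binned_density"), length(init) == 2)
  df <- data.frame(x = binned$centers, y = binned$density)
  start <- list(mu = unname(init[1]),
                sigma = min(max(unname(init[2]), 2e-4), 9.99))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ dlnorm(x, meanlog = mu, sdlog = sigma),
                      data = df, start = start,
                      lower = c(mu = -Inf, sigma = 1e-4),
                      upper = c(mu = Inf, sigma = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(mu = NA_real_, sigma = NA_real_, r2 = NaN,
                          n = binned$n, init_mu = start$mu,
                          init_sigma = start$sigma, converged = FALSE),
                     class = "lognormal_fit"))
  }
  co <- coef(fit)
  structure(list(mu = unname(co["mu"]), sigma = unname(co["sigma"]),
                 r2 = r_squared(df$y, fitted(fit)), n = binned$n,
                 init_mu = start$mu, init_sigma = start$sigma,
                 converged = TRUE),
            class = "lognormal_fit")
}

#' One-call lognormal fit to a raw sample
#'
#' Convenience wrapper: log-moments, integral-normalised binning, then
#' [fit_lognormal()].
#'
#' @param sizes Strictly positive sample.
#' @param n_bins Passed to [bin_and_normalize()].
#' @return A `"lognormal_fit"`.
#' @export
fit_lognormal_sample <- function(sizes, n_bins = "auto") {
  init <- log_moments(sizes)
  binned <- tryCatch(bin_and_normalize(sizes, n_bins), error = function(e) NULL)
  if (is.null(binned))
    return(structure(list(mu = NA_real_, sigma = NA_real_, r2 = NaN,
                          n = length(sizes), init_mu = init[[1]],
                          init_sigma = init[[2]], converged = FALSE),
                     class = "lognormal_fit"))
  fit_lognormal(binned, init)
}

#' Gaussian fit to log-transformed sizes
#'
#' A lognormal sample becomes Gaussian under the log, so fitting the bump
#' `a * exp(-((x - b) / c)^2)` to the normalised histogram of `ln(sizes)` is a
#' second, independent route to lognormality: `b` estimates the log-mean and
#' `c = sigma * sqrt(2)` the spread. Deviations from the Gaussian in
#' log-space (e.g. an overabundance of large spines to the right of the peak)
#' show up directly as a depressed r-squared.
#'
#' @param sizes Strictly positive sample, n >= 10.
#' @param n_bins Passed to [bin_and_normalize()].
#' @return Object of class `"gaussian_log_fit"`: `a`, `b`, `c`, `r2`, `n`,
#'   `converged`.
#' @export
fit_gaussian_log <- function(sizes, n_bins = "auto") {
  if (length(sizes) < 10) stop("need n >= 10", call. = FALSE)
  if (any(sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  lx <- log(sizes)
  binned <- tryCatch(bin_and_normalize(lx, n_bins), error = function(e) NULL)
  if (is.null(binned))
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_, r2 = NaN,
                          n = length(sizes), converged = FALSE),
                     class = "gaussian_log_fit"))
  fit_gaussian_binned(binned, n = length(sizes))
}

#' Gaussian bump fit to an already-binned density
#'
#' @param binned A [bin_and_normalize()] result (in whatever domain).
#' @param n Sample size to record.
#' @return A `"gaussian_log_fit"`.
#' @export
fit_gaussian_binned <- function(binned, n = binned$n) {
  df <- data.frame(x = binned$centers, y = binned$density)
  m <- sum(df$x * df$y) / sum(df$y)
  s <- sqrt(sum((df$x - m)^2 * df$y) / sum(df$y))
  start <- list(a = max(df$y), b = m, c = max(s * sqrt(2), 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-((x - b) / c)^2), data = df,
                      start = start,
                      lower = c(a = 1e-12, b = -Inf, c = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_, r2 = NaN,
                          n = n, converged = FALSE),
                     class = "gaussian_log_fit"))
  co <- coef(fit)
  structure(list(a = unname(co["a"]), b = unname(co["b"]),
                 c = unname(co["c"]), r2 = r_squared(df$y, fitted(fit)),
                 n = n, converged = TRUE),
            class = "gaussian_log_fit")
}

#' Adjusted Fisher–Pearson sample skewness
#'
#' Bias-corrected skewness
#' `g1 * sqrt(n (n-1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`, computed on the
#' raw (untransformed) sizes. Positive values mean a right/heavy upper tail;
#' a lognormal sample has population skewness
#' `(exp(s^2) + 2) * sqrt(exp(s^2) - 1)`.
#'
#' @param sizes Numeric vector, n >= 3.
#' @return Scalar skewness; `NaN` for zero variance.
#' @export
sample_skewness <- function(sizes) {
  n <- length(sizes)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  d <- sizes - mean(sizes)
  m2 <- mean(d^2)
  if (m2 == 0) return(NaN)
  g1 <- mean(d^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Log-domain shape diagnostics
#'
#' @param sizes Strictly positive sample.
#' @return List with `skewness` (of the raw sizes) and `sigma_log` (sd of the
#'   natural logs — the "sigma" width measure of the distribution).
#' @export
shape_diagnostics <- function(sizes) {
  list(skewness = sample_skewness(sizes), sigma_log = sd(log(sizes)))
}

#' AIC tournament: lognormal vs gamma vs Weibull
#'
#' Maximum-likelihood fits of the three candidate right-skewed families on the
#' raw sample; each has k = 2 parameters, so `AIC = 4 - 2 log L` and the
#' comparison reduces to the likelihood. A candidate whose MLE fails gets
#' `AIC = +Inf` and stays in the table.
#'
#' @param sizes Strictly positive sample, n >= 20.
#' @return Object of class `"model_comparison"`: named `aic` vector
#'   (`lognormal`, `gamma`, `weibull`), `delta_aic` (vs the minimum), `best`.
#' @export
compare_aic <- function(sizes) {
  if (length(sizes) < 20) stop("need n >= 20", call. = FALSE)
  if (any(sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  families <- c(lognormal = "lnorm", gamma = "gamma", weibull = "weibull")
  aic <- vapply(families, function(fam) {
    f <- tryCatch(fitdistrplus::fitdist(sizes, fam, method = "mle"),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$aic)) Inf else f$aic
  }, numeric(1))
  delta <- aic - min(aic)
  structure(list(aic = aic, delta_aic = delta,
                 best = names(aic)[which.min(aic)]),
            class = "model_comparison")
}

#' Fit every condition (or cell) of a spine table
#'
#' Pooled level concatenates all spines of a condition (layer x age x
#' hemisphere for abGC; group x age for CA1) and fits once; per-cell level
#' fits each cell independently with its own bin edges. Each row carries the
#' lognormal fit, shape diagnostics, and (when `n >= 20`) the AIC tournament.
#' Cells below `min_n` spines are retained but flagged. Empty conditions are
#' skipped with a warning.
#'
#' @param table A spine table (see [generate_spine_table()]).
#' @param level `"pooled"` or `"per_cell"`.
#' @param n_bins Passed to the fitters.
#' @param min_n Flagging threshold for small samples (default 20).
#' @param types Optional subset of `spine_type` values to keep (CA1); `NULL`
#'   keeps everything except `"other"`, which is excluded from analysis.
#' @return data.frame with one row per condition or cell: condition columns,
#'   `n`, `mu`, `sigma`, `r2`, `b`, `c`, `r2_gauss`, `skewness`, `sigma_log`,
#'   `aic_lognormal`, `aic_gamma`, `aic_weibull`, `best_model`, `flagged`.
#' @export
fit_condition <- function(table, level = c("pooled", "per_cell"),
                          n_bins = "auto", min_n = 20L, types = NULL) {
  level <- match.arg(level)
  if (nrow(table) == 0) stop("empty spine table", call. = FALSE)
  if (!is.null(types)) {
    table <- table[table$spine_type %in% types, , drop = FALSE]
  } else if (!all(is.na(table$spine_type))) {
    table <- table[is.na(table$spine_type) | table$spine_type != "other", ,
                   drop = FALSE]
  }
  layer_chr <- ifelse(is.na(table$layer), "-", table$layer)
  unit <- if (level == "pooled") {
    interaction(table$dataset, layer_chr, table$age, table$side_or_group,
                drop = TRUE, lex.order = TRUE)
  } else {
    factor(table$cell_id)
  }
  pieces <- split(seq_len(nrow(table)), unit)
  rows <- lapply(names(pieces), function(key) {
    idx <- pieces[[key]]
    sizes <- table$head_area_um2[idx]
    if (length(sizes) < 3) {
      warning("skipping '", key, "': fewer than 3 spines", call. = FALSE)
      return(NULL)
    }
    fit <- fit_lognormal_sample(sizes, n_bins)
    gfit <- if (length(sizes) >= 10) fit_gaussian_log(sizes, n_bins) else
      list(a = NA_real_, b = NA_real_, c = NA_real_, r2 = NaN)
    diag <- shape_diagnostics(sizes)
    cmp <- if (length(sizes) >= 20) compare_aic(sizes) else
      list(aic = c(lognormal = NA_real_, gamma = NA_real_,
                   weibull = NA_real_), best = NA_character_)
    first <- idx[1]
    data.frame(unit = key,
               dataset = table$dataset[first], layer = table$layer[first],
               age = table$age[first],
               side_or_group = table$side_or_group[first],
               cell_id = if (level == "per_cell") table$cell_id[first]
                         else NA_character_,
               n = length(sizes), mu = fit$mu, sigma = fit$sigma, r2 = fit$r2,
               b = gfit$b, c = gfit$c, r2_gauss = gfit$r2,
               skewness = diag$skewness, sigma_log = diag$sigma_log,
               aic_lognormal = cmp$aic[["lognormal"]],
               aic_gamma = cmp$aic[["gamma"]],
               aic_weibull = cmp$aic[["weibull"]],
               best_model = cmp$best,
               flagged = length(sizes) < min_n || !is.finite(fit$r2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no condition had enough spines to fit", call. = FALSE)
  rownames(out) <- NULL
  out
}
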