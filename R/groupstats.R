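#' Two-group Mann–Whitney comparison
#'
#' Two-sided Mann–Whitney U (rank-sum) test, the comparison used between
#' hemispheres (stimulated vs control) and between genotype groups. Exact
#' p-values when the combined sample is small (n + m <= 20) and tie-free;
#' otherwise the normal approximation with tie correction.
#'
#' @param x,y Numeric samples, each n >= 3.
#' @param metric Optional metric name recorded in the result.
#' @return data.frame of class `"spine_test"`: `test_name`, `statistic`,
#'   `p_value`, `groups`, `n_per_group`, `metric`.
#' @export
two_group_test <- function(x, y, metric = NA_character_) {
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs n >= 3", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact))
  test_result("mann_whitney", unname(wt$statistic), wt$p.value,
              groups = "x|y",
              n_per_group = paste(length(x), length(y), sep = "|"),
              metric = metric)
}

#' Repeated-measures comparison across the three layers
#'
#' Friedman rank test on a cells x layers matrix. The three layer samples of
#' one cell are measurements on the same cell, i.e. repeated measures, so an
#' independent-groups test would be wrong here. Cells with any missing layer
#' are dropped (count reported via attribute `n_dropped`).
#'
#' @param mat Numeric matrix, rows = cells, columns = layers (>= 3 complete
#'   rows required).
#' @param metric Optional metric name.
#' @return A `"spine_test"` data.frame (chi-squared statistic).
#' @export
repeated_layers_test <- function(mat, metric = NA_character_) {
  mat <- as.matrix(mat)
  keep <- complete.cases(mat)
  n_dropped <- sum(!keep)
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 3) stop("need >= 3 complete cells", call. = FALSE)
  ft <- friedman.test(mat)
  stat <- unname(ft$statistic); pv <- ft$p.value
  if (is.nan(stat)) { stat <- 0; pv <- 1 }  # every row fully tied
  out <- test_result("friedman", stat, pv,
                     groups = paste(colnames(mat) %||%
                                      paste0("L", seq_len(ncol(mat))),
                                    collapse = "|"),
                     n_per_group = paste(rep(nrow(mat), ncol(mat)),
                                         collapse = "|"),
                     metric = metric)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Multi-group comparison across cell ages
#'
#' Kruskal–Wallis H test (with tie correction) across two or more independent
#' groups, used for cell-age / culture-age comparisons. A fully degenerate
#' input (all values tied everywhere) yields `p = NaN`, flagged rather than
#' raised.
#'
#' @param groups List of numeric samples (>= 2 groups, each n >= 3).
#' @param metric Optional metric name.
#' @return A `"spine_test"` data.frame.
#' @export
multi_age_test <- function(groups, metric = NA_character_) {
  if (length(groups) < 2 || any(vapply(groups, length, 1L) < 3))
    stop("need >= 2 groups with n >= 3 each", call. = FALSE)
  if (length(unique(unlist(groups))) == 1L) {
    return(test_result("kruskal_wallis", NaN, NaN,
                       groups = paste(names(groups) %||%
                                        seq_along(groups), collapse = "|"),
                       n_per_group = paste(vapply(groups, length, 1L),
                                           collapse = "|"),
                       metric = metric))
  }
  kt <- kruskal.test(groups)
  test_result("kruskal_wallis", unname(kt$statistic), kt$p.value,
              groups = paste(names(groups) %||% seq_along(groups),
                             collapse = "|"),
              n_per_group = paste(vapply(groups, length, 1L), collapse = "|"),
              metric = metric)
}

#' Bonferroni–Holm adjustment of post hoc p-values
#'
#' Step-down Holm correction: sort ascending, multiply the i-th smallest by
#' `(m - i + 1)`, enforce monotonicity, cap at 1. Adjusted values are always
#' `>=` the raw ones.
#'
#' @param p_values Numeric vector in `[0, 1]`, optionally named by comparison.
#' @param alpha Rejection level (default 0.05).
#' @return data.frame of class `"posthoc_table"`: `comparison`, `p_raw`,
#'   `p_holm`, `reject`.
#' @export
holm_adjust <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- p.adjust(p_values, method = "holm")
  structure(data.frame(
    comparison = names(p_values) %||% as.character(seq_along(p_values)),
    p_raw = unname(p_values), p_holm = unname(adj),
    reject = unname(adj < alpha), stringsAsFactors = FALSE),
    class = c("posthoc_table", "data.frame"), alpha = alpha)
}

#' Comparison battery over a per-cell metrics table
#'
#' Dispatches the design-appropriate nonparametric test on one metric column
#' of a [fit_condition()] per-cell table and, when the omnibus test is
#' significant at `alpha`, runs Holm-corrected pairwise post hoc rank-sum
#' tests:
#' * `"hemisphere"` / `"group"`: two-group Mann–Whitney on `side_or_group`.
#' * `"layer"`: Friedman repeated-measures across IML/MML/OML, pairing the
#'   layer values that belong to the same cell (matched by cell index within
#'   condition).
#' * `"age"`: Kruskal–Wallis across ages, all pairwise post hocs.
#'
#' @param metrics Per-cell metrics data.frame (needs the condition columns and
#'   the chosen metric).
#' @param design One of `"hemisphere"`, `"group"`, `"layer"`, `"age"`.
#' @param metric Metric column name (e.g. `"r2"`, `"skewness"`, `"sigma_log"`).
#' @param alpha Significance level gating the post hocs (default 0.05).
#' @return List with `omnibus` (a `"spine_test"`) and `posthoc` (a
#'   `"posthoc_table"` or `NULL`).
#' @export
run_comparison_suite <- function(metrics, design, metric = "r2",
                                 alpha = 0.05) {
  if (!metric %in% names(metrics))
    stop("metric column not found: ", metric, call. = FALSE)
  vals <- metrics[[metric]]
  if (all(!is.finite(vals)))
    stop("metric column is empty/non-finite: ", metric, call. = FALSE)
  keep <- is.finite(vals)
  metrics <- metrics[keep, , drop = FALSE]
  vals <- vals[keep]
  design <- match.arg(design, c("hemisphere", "group", "layer", "age"))
  if (design %in% c("hemisphere", "group")) {
    sides <- unique(metrics$side_or_group)
    if (length(sides) != 2)
      stop("two-group design needs exactly 2 levels of side_or_group",
           call. = FALSE)
    omni <- two_group_test(vals[metrics$side_or_group == sides[1]],
                           vals[metrics$side_or_group == sides[2]],
                           metric = metric)
    omni$groups <- paste(sides, collapse = "|")
    return(list(omnibus = omni, posthoc = NULL))
  }
  if (design == "layer") {
    # same-cell matching: i-th cell of a (age, side) condition in each layer
    metrics$cell_rank <- stats::ave(seq_len(nrow(metrics)),
                                    metrics$age, metrics$side_or_group,
                                    metrics$layer, FUN = seq_along)
    wide <- split(metrics, list(metrics$age, metrics$side_or_group,
                                metrics$cell_rank), drop = TRUE)
    layers <- sort(unique(metrics$layer))
    mat <- t(vapply(wide, function(d) {
      vapply(layers, function(l) {
        v <- d[[metric]][d$layer == l]
        if (length(v) == 1) v else NA_real_
      }, numeric(1))
    }, numeric(length(layers))))
    colnames(mat) <- layers
    omni <- repeated_layers_test(mat, metric = metric)
    post <- NULL
    if (is.finite(omni$p_value) && omni$p_value < alpha) {
      pairs <- utils::combn(layers, 2, simplify = FALSE)
      p <- vapply(pairs, function(pr) {
        cc <- complete.cases(mat[, pr])
        suppressWarnings(wilcox.test(mat[cc, pr[1]], mat[cc, pr[2]],
                                     paired = TRUE)$p.value)
      }, numeric(1))
      names(p) <- vapply(pairs, paste, "", collapse = " vs ")
      post <- holm_adjust(p, alpha)
    }
    return(list(omnibus = omni, posthoc = post))
  }
  # age design
  ages <- sort(unique(metrics$age))
  groups <- lapply(ages, function(a) vals[metrics$age == a])
  names(groups) <- ages
  omni <- multi_age_test(groups, metric = metric)
  post <- NULL
  if (is.finite(omni$p_value) && omni$p_value < alpha) {
    pairs <- utils::combn(as.character(ages), 2, simplify = FALSE)
    p <- vapply(pairs, function(pr) {
      suppressWarnings(wilcox.test(groups[[pr[1]]],
                                   groups[[pr[2]]])$p.value)
    }, numeric(1))
    names(p) <- vapply(pairs, paste, "", collapse = " vs ")
    post <- holm_adjust(p, alpha)
  }
  list(omnibus = omni, posthoc = post)
}

test_result <- function(test_name, statistic, p_value, groups, n_per_group,
                        metric) {
  structure(data.frame(test_name = test_name, statistic = statistic,
                       p_value = p_value, groups = groups,
                       n_per_group = n_per_group, metric = metric,
                       stringsAsFactors = FALSE),
            class = c("spine_test", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
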