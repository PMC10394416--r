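#' Configuration for the synthetic spine-table generator
#'
#' Builds the full set of knobs needed to emulate the statistical structure of
#' the two spine datasets the analysis pipeline targets: adult-born dentate
#' granule cells (`dataset = "abGC"`: 3 molecular layers x 3 cell ages x 2
#' hemispheres, with plasticity-induced shifts of the lognormal parameters in
#' the stimulated hemisphere) and CA1 pyramidal cells from release-blocked
#' cultures (`dataset = "CA1"`: 2 groups x 3 culture ages x spine types with
#' fixed type proportions and a size cutoff separating mushroom from thin).
#'
#' Head areas within a condition are i.i.d. LogNormal(`mu`, `sigma`) (area in
#' um^2, log-parameters dimensionless). The per-condition log-mean and log-sd
#' are `mu`/`sigma` multiplied by the condition's entry in `mu_effects` /
#' `sigma_effects` (multiplicative shifts; 1 = no effect). Defaults are
#' illustrative, not estimates from any experimental fit: experimental
#' per-condition lognormal parameters are not published in machine-readable
#' form.
#'
#' @param dataset `"abGC"` or `"CA1"`.
#' @param mu Baseline log-mean of head area (default -1.0, i.e. median
#'   ~0.37 um^2).
#' @param sigma Baseline log-sd (default 0.5). Must be > 0.
#' @param cells_per_condition Number of cells generated per condition.
#' @param spines_per_cell_range Integer `c(min, max)`; each cell's spine count
#'   is drawn uniformly from this range. `min` must be >= 10.
#' @param mu_effects,sigma_effects Named numeric vectors of multiplicative
#'   shifts applied per condition. Names are condition keys as produced by
#'   `condition_key()` (e.g. `"abGC.MML.28.ipsi"`); missing conditions get 1.
#'   `NULL` installs the package defaults: for abGC, sigma inflated in the
#'   stimulated (ipsilateral) MML and deflated in the ipsilateral IML/OML,
#'   matching the qualitative direction of homosynaptic broadening and
#'   heterosynaptic narrowing; for CA1, no effects.
#' @param type_proportions CA1 only: named fractions for
#'   mushroom/thin/stubby/other, summing to 1. Default 0.2285/0.2373/0.5116/
#'   0.0226.
#' @param mushroom_thin_cutoff CA1 only: head area (um^2) separating mushroom
#'   (>= cutoff) from thin (< cutoff) among non-stubby, non-other spines.
#'   `NULL` (default) picks, per condition, the quantile of the generating
#'   lognormal that makes the expected mushroom:thin split agree with
#'   `type_proportions`.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A list of class `"generator_config"`.
#' @seealso [generate_spine_table()]
#' @export
generator_config <- function(dataset = c("abGC", "CA1"),
                             mu = -1.0, sigma = 0.5,
                             cells_per_condition = 12,
                             spines_per_cell_range = c(60L, 105L),
                             mu_effects = NULL, sigma_effects = NULL,
                             type_proportions = c(mushroom = 0.2285,
                                                  thin = 0.2373,
                                                  stubby = 0.5116,
                                                  other = 0.0226),
                             mushroom_thin_cutoff = NULL,
                             seed = 1L) {
  dataset <- match.arg(dataset)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be strictly positive", call. = FALSE)
  spines_per_cell_range <- as.integer(round(spines_per_cell_range))
  if (length(spines_per_cell_range) != 2L ||
      spines_per_cell_range[1] < 10L ||
      spines_per_cell_range[1] > spines_per_cell_range[2])
    stop("`spines_per_cell_range` must be c(min, max) with 10 <= min <= max",
         call. = FALSE)
  if (dataset == "CA1") {
    if (any(type_proportions < 0) ||
        abs(sum(type_proportions) - 1) > 1e-9)
      stop("`type_proportions` must be non-negative and sum to 1", call. = FALSE)
    stopifnot(all(c("mushroom", "thin", "stubby", "other") %in%
                    names(type_proportions)))
  }
  conds <- condition_grid(dataset)
  keys <- condition_key(conds)
  if (is.null(sigma_effects)) {
    sigma_effects <- setNames(rep(1, length(keys)), keys)
    if (dataset == "abGC") {
      # stimulated hemisphere: LTP broadens MML, heterosynaptic LTD narrows
      # flanking IML/OML; effects confined to cell ages with developed plasticity
      for (age in c(28, 35)) {
        sigma_effects[sprintf("abGC.MML.%d.ipsi", age)] <- 1.20
        sigma_effects[sprintf("abGC.IML.%d.ipsi", age)] <- 0.85
        sigma_effects[sprintf("abGC.OML.%d.ipsi", age)] <- 0.85
      }
    }
  }
  if (is.null(mu_effects)) {
    mu_effects <- setNames(rep(1, length(keys)), keys)
    if (dataset == "abGC") {
      # slight median growth in the potentiated layer (mu < 0, so multiply down)
      for (age in c(28, 35))
        mu_effects[sprintf("abGC.MML.%d.ipsi", age)] <- 0.9
    }
  }
  structure(list(dataset = dataset, mu = mu, sigma = sigma,
                 cells_per_condition = as.integer(cells_per_condition),
                 spines_per_cell_range = spines_per_cell_range,
                 mu_effects = mu_effects, sigma_effects = sigma_effects,
                 type_proportions = type_proportions,
                 mushroom_thin_cutoff = mushroom_thin_cutoff,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Condition grid for a dataset
#'
#' The abGC design crosses 3 dentate molecular layers (IML/MML/OML) with cell
#' age (21/28/35 days post-injection) and hemisphere (ipsi = stimulated,
#' contra = control). The CA1 design crosses genotype group (dko = blocked
#' release, control) with culture age (7/14/21 days in vitro); spine types are
#' assigned within cells, not crossed here.
#'
#' @param dataset `"abGC"` or `"CA1"`.
#' @return A data.frame with columns `dataset`, `layer`, `age`,
#'   `side_or_group` (one row per condition).
#' @export
condition_grid <- function(dataset = c("abGC", "CA1")) {
  dataset <- match.arg(dataset)
  if (dataset == "abGC") {
    g <- expand.grid(layer = c("IML", "MML", "OML"),
                     age = c(21L, 28L, 35L),
                     side_or_group = c("ipsi", "contra"),
                     stringsAsFactors = FALSE)
  } else {
    g <- expand.grid(layer = NA_character_,
                     age = c(7L, 14L, 21L),
                     side_or_group = c("dko", "control"),
                     stringsAsFactors = FALSE)
  }
  cbind(dataset = dataset, g, stringsAsFactors = FALSE)
}

#' Canonical condition key string
#'
#' @param cond data.frame with columns `dataset`, `layer`, `age`,
#'   `side_or_group`.
#' @return Character vector like `"abGC.MML.28.ipsi"` / `"CA1.14.dko"`.
#' @export
condition_key <- function(cond) {
  ifelse(is.na(cond$layer),
         sprintf("%s.%d.%s", cond$dataset, cond$age, cond$side_or_group),
         sprintf("%s.%s.%d.%s", cond$dataset, cond$layer, cond$age,
                 cond$side_or_group))
}

effect_for <- function(effects, key) {
  if (is.null(effects) || is.na(match(key, names(effects)))) 1 else
    unname(effects[key])
}

#' Generate a synthetic spine table
#'
#' Draws, for every condition in the design, `cells_per_condition` cells with
#' uniform-random spine counts, and head areas i.i.d. LogNormal with the
#' condition's (shifted) log-parameters. For the CA1 dataset each spine is
#' additionally labelled mushroom/thin/stubby/other: stubby and other are
#' assigned by proportion independently of size, and the remaining spines are
#' split by the mushroom/thin area cutoff (see [assign_spine_types()]).
#' Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A data.frame (one row per spine) with columns `animal_id`,
#'   `cell_id`, `dataset`, `layer`, `age`, `side_or_group`, `spine_type`,
#'   `head_area_um2`.
#' @export
generate_spine_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  conds <- condition_grid(config$dataset)
  keys <- condition_key(conds)
  out <- vector("list", nrow(conds))
  set.seed(config$seed)
  for (i in seq_len(nrow(conds))) {
    key <- keys[i]
    mu_c <- config$mu * effect_for(config$mu_effects, key)
    sd_c <- config$sigma * effect_for(config$sigma_effects, key)
    rows <- vector("list", config$cells_per_condition)
    for (cell in seq_len(config$cells_per_condition)) {
      n_sp <- sample(seq(config$spines_per_cell_range[1],
                         config$spines_per_cell_range[2]), 1L)
      areas <- rlnorm(n_sp, meanlog = mu_c, sdlog = sd_c)
      if (config$dataset == "CA1") {
        types <- assign_spine_types(areas, config, mu = mu_c, sigma = sd_c)
      } else {
        types <- rep(NA_character_, n_sp)
      }
      rows[[cell]] <- data.frame(
        animal_id = sprintf("a%02d", ((cell - 1L) %% 6L) + 1L),
        cell_id = sprintf("%s.c%03d", key, cell),
        dataset = conds$dataset[i], layer = conds$layer[i],
        age = conds$age[i], side_or_group = conds$side_or_group[i],
        spine_type = types, head_area_um2 = areas,
        stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Assign spine types to head areas (CA1 scheme)
#'
#' Stubby and "other" spines are assigned by their configured proportions,
#' independently of size. The remaining spines reproduce the size-based
#' classification artifact seen in type-resolved data: area >= cutoff is
#' mushroom, area < cutoff is thin, so the two types partition the non-stubby
#' population at a sharp size boundary.
#'
#' @param areas Positive head areas (um^2).
#' @param config A [generator_config()] (uses `type_proportions` and
#'   `mushroom_thin_cutoff`).
#' @param mu,sigma Log-parameters of the generating condition; used only to
#'   derive the default cutoff quantile when `mushroom_thin_cutoff` is `NULL`.
#' @return Character vector of types, same length as `areas`.
#' @export
assign_spine_types <- function(areas, config, mu = config$mu,
                               sigma = config$sigma) {
  stopifnot(all(areas > 0))
  p <- config$type_proportions
  n <- length(areas)
  p_sizefree <- p[["stubby"]] + p[["other"]]
  # size-independent draw: stubby / other / size-classified
  u <- runif(n)
  type <- rep(NA_character_, n)
  type[u < p[["stubby"]]] <- "stubby"
  type[u >= p[["stubby"]] & u < p_sizefree] <- "other"
  cutoff <- config$mushroom_thin_cutoff
  if (is.null(cutoff)) {
    # quantile such that P(area >= cutoff) among non-stubby matches the
    # mushroom share of the mushroom+thin mass
    frac_mushroom <- p[["mushroom"]] / (p[["mushroom"]] + p[["thin"]])
    cutoff <- qlnorm(1 - frac_mushroom, meanlog = mu, sdlog = sigma)
  }
  open <- is.na(type)
  type[open] <- ifelse(areas[open] >= cutoff, "mushroom", "thin")
  type
}

#' Uniform initial weights
#'
#' Initial synaptic weight vectors for the simulator are drawn uniformly; the
#' generation experiment feeds such a flat distribution into the
#' multiplicative-noise process and watches it become lognormal.
#'
#' @param n Number of weights.
#' @param lo,hi Bounds, `0 <= lo < hi`.
#' @param seed Integer seed.
#' @return Numeric vector of `n` i.i.d. Uniform(lo, hi) draws.
#' @export
generate_uniform_weights <- function(n, lo = 0, hi = 1, seed = 1L) {
  if (!(lo >= 0 && lo < hi)) stop("need 0 <= lo < hi", call. = FALSE)
  set.seed(as.integer(seed))
  runif(n, lo, hi)
}

#' Write / read a spine table as CSV
#'
#' @param table Spine table data.frame.
#' @param path File path.
#' @return `read_spine_table` returns the table; `write_spine_table` returns
#'   `path` invisibly.
#' @export
write_spine_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spine_table
#' @export
read_spine_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "cell_id", "dataset", "layer", "age",
                "side_or_group", "spine_type", "head_area_um2")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("spine table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(tab$head_area_um2)) || any(tab$head_area_um2 <= 0))
    stop("head_area_um2 must be finite and strictly positive", call. = FALSE)
  tab
}
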