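#' Read a YAML or JSON configuration file
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json", call. = FALSE)
}

write_manifest <- function(out_dir, config, seed, files) {
  manifest <- list(
    package = "spinedyn",
    version = as.character(utils::packageVersion("spinedyn")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    digests = as.list(tools::md5sum(files)))
  names(manifest$digests) <- basename(files)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' End-to-end distribution-fitting study
#'
#' Generates (or loads) a spine table, fits every condition pooled and every
#' cell individually, runs the design-appropriate nonparametric comparison
#' battery on the per-cell metrics, and writes all outputs plus a manifest
#' with config snapshot, seed and file digests.
#'
#' @param generator A [generator_config()], or `NULL` if `table_path` given.
#' @param table_path Optional CSV path of an existing spine table
#'   (schema of [write_spine_table()]).
#' @param out_dir Output directory (created if missing).
#' @param n_bins Binning rule for the fits.
#' @param metrics Per-cell metric columns compared across conditions.
#' @param alpha Significance level.
#' @return Invisibly, a list with the pooled and per-cell tables, the stats
#'   report, and output file paths.
#' @export
run_fit_study <- function(generator = generator_config("abGC"),
                          table_path = NULL, out_dir = tempfile("fitstudy"),
                          n_bins = "auto",
                          metrics = c("r2", "skewness", "sigma_log"),
                          alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(table_path)) {
    table <- read_spine_table(table_path)
    seed <- NA_integer_
  } else {
    table <- generate_spine_table(generator)
    seed <- generator$seed
  }
  pooled <- fit_condition(table, "pooled", n_bins = n_bins)
  per_cell <- fit_condition(table, "per_cell", n_bins = n_bins)
  dataset <- table$dataset[1]
  designs <- if (dataset == "abGC") c("hemisphere", "layer", "age") else
    c("group", "age")
  stat_rows <- list(); post_rows <- list()
  for (m in metrics) {
    for (dg in designs) {
      res <- tryCatch(run_comparison_suite(per_cell, dg, m, alpha),
                      error = function(e) NULL)
      if (is.null(res)) next
      row <- res$omnibus
      row$design <- dg
      stat_rows[[paste(m, dg)]] <- row
      if (!is.null(res$posthoc)) {
        ph <- res$posthoc
        ph$design <- dg; ph$metric <- m
        post_rows[[paste(m, dg)]] <- ph
      }
    }
  }
  stats_tab <- do.call(rbind, stat_rows)
  posthoc_tab <- if (length(post_rows)) do.call(rbind, post_rows) else
    data.frame()
  files <- c(file.path(out_dir, "spine_table.csv"),
             file.path(out_dir, "pooled_fits.csv"),
             file.path(out_dir, "per_cell_fits.csv"),
             file.path(out_dir, "stats.csv"),
             file.path(out_dir, "posthoc.csv"))
  write.csv(table, files[1], row.names = FALSE)
  write.csv(pooled, files[2], row.names = FALSE)
  write.csv(per_cell, files[3], row.names = FALSE)
  write.csv(stats_tab, files[4], row.names = FALSE)
  write.csv(posthoc_tab, files[5], row.names = FALSE)
  config <- if (is.null(table_path))
    unclass(generator) else list(table_path = table_path)
  manifest <- write_manifest(out_dir, config, seed, files)
  invisible(list(table = table, pooled = pooled, per_cell = per_cell,
                 stats = stats_tab, posthoc = posthoc_tab,
                 files = c(files, manifest), out_dir = out_dir))
}

#' End-to-end model study: protocol suite, inference, MAP validation
#'
#' Runs the three-protocol weight-dynamics simulation, fits the final
#' distributions, optionally runs sequential ABC against the suite's own
#' summary features (or supplied observed features) and validates the MAP by
#' re-simulation. All outputs are CSV/JSON plus a manifest.
#'
#' @param neuron,stdp,noise Simulator parameter objects.
#' @param stim_proportion,duration,seed,w_mean,dt_noise Passed to
#'   [run_protocol_suite()].
#' @param infer Run the inference stage (default FALSE: simulate + fit only).
#' @param observed_features Optional observed 6-feature vector; default uses
#'   the simulated suite's features (closed loop).
#' @param prior,rounds,sims_per_round,settings Inference controls (see
#'   [sequential_infer()]); defaults are desk-scale.
#' @param out_dir Output directory.
#' @return Invisibly: list with the suite, per-protocol fit table, posterior
#'   (or NULL), map r2 vector (or NULL), and file paths.
#' @export
run_model_study <- function(neuron = neuron_params(), stdp = stdp_params(),
                            noise = noise_params(), stim_proportion = 0.5,
                            duration = 20, seed = 1L, w_mean = 0.5,
                            dt_noise = 0.01, infer = FALSE,
                            observed_features = NULL, prior = prior_box(),
                            rounds = 3, sims_per_round = 200,
                            settings = inference_settings(),
                            out_dir = tempfile("modelstudy")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  suite <- run_protocol_suite(neuron, stdp, noise, stim_proportion,
                              duration = duration, seed = seed,
                              w_mean = w_mean, dt_noise = dt_noise)
  fits <- do.call(rbind, lapply(names(suite), function(p) {
    w <- as.numeric(suite[[p]]$final_weights)
    w <- w[w > 0]
    fit <- fit_lognormal_sample(w)
    data.frame(protocol = p, n = length(w), mu = fit$mu, sigma = fit$sigma,
               r2 = fit$r2, skewness = sample_skewness(w),
               mean_weight = mean(w),
               spikes_total = sum(suite[[p]]$spike_counts),
               stringsAsFactors = FALSE)
  }))
  files <- file.path(out_dir, "protocol_fits.csv")
  write.csv(fits, files[1], row.names = FALSE)
  posterior <- NULL; map_r2 <- NULL
  if (infer) {
    feats <- observed_features %||% summarize_suite(suite)
    posterior <- sequential_infer(feats, prior, rounds, sims_per_round,
                                  seed = seed, settings = settings)
    pfile <- file.path(out_dir, "posterior_draws.csv")
    write.csv(as.data.frame(posterior$draws), pfile, row.names = FALSE)
    mfile <- file.path(out_dir, "map.json")
    jsonlite::write_json(as.list(posterior$map), mfile, auto_unbox = TRUE,
                         digits = NA)
    obs_w <- lapply(suite, function(s) as.numeric(s$final_weights))
    map_r2 <- simulate_map_and_compare(posterior$map, obs_w, settings,
                                       seed = seed + 17L)
    rfile <- file.path(out_dir, "map_validation.csv")
    write.csv(data.frame(protocol = names(map_r2), r2 = as.numeric(map_r2)),
              rfile, row.names = FALSE)
    files <- c(files, pfile, mfile, rfile)
  }
  config <- list(n_neurons = neuron$n_neurons, n_inputs = neuron$n_inputs,
                 stim_proportion = stim_proportion, duration = duration,
                 mult_strength = noise$mult_strength,
                 add_strength = noise$add_strength, c_p = stdp$c_p,
                 c_d = stdp$c_d, tau_stdp_s = stdp$tau_stdp, infer = infer,
                 rounds = if (infer) rounds else NULL,
                 sims_per_round = if (infer) sims_per_round else NULL)
  manifest <- write_manifest(out_dir, config, as.integer(seed), files)
  invisible(list(suite = suite, fits = fits, posterior = posterior,
                 map_r2 = map_r2, files = c(files, manifest),
                 out_dir = out_dir))
}
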