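#' Read / write observed series as CSV
#'
#' The on-disk schema is two CSV files: `observations.csv` with columns
#' `time, individual_id, log_size` (one row per sampled individual) and
#' `densities.csv` with `time, density[, sample_count]` (one row per
#' observation year). Lines starting with `#` are ignored.
#'
#' @param obs_path Path to the per-individual observations CSV.
#' @param dens_path Path to the per-year densities CSV.
#' @param obs An [observed_series()].
#' @return `read_observations()` returns an [observed_series()];
#'   `write_observations()` returns the paths invisibly.
#' @export
read_observations <- function(obs_path, dens_path) {
  sizes <- readr::read_csv(obs_path, comment = "#",
                           show_col_types = FALSE)
  densities <- readr::read_csv(dens_path, comment = "#",
                               show_col_types = FALSE)
  for (col in c("time", "individual_id", "log_size")) {
    if (!col %in% names(sizes))
      rlang::abort(sprintf("%s is missing required column `%s`",
                           obs_path, col))
  }
  for (col in c("time", "density")) {
    if (!col %in% names(densities))
      rlang::abort(sprintf("%s is missing required column `%s`",
                           dens_path, col))
  }
  if (!is.numeric(sizes$log_size) || !is.numeric(sizes$time))
    rlang::abort("`time` and `log_size` must be numeric")
  if (!is.numeric(densities$density) || !is.numeric(densities$time))
    rlang::abort("`time` and `density` must be numeric")
  observed_series(sizes, densities)
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, obs_path, dens_path) {
  stopifnot(is_observed_series(obs))
  readr::write_csv(obs$sizes, obs_path)
  readr::write_csv(obs$densities, dens_path)
  invisible(c(obs_path, dens_path))
}

#' Write the generating truth of a simulated dataset
#'
#' Stores the true kernel parameters, seed and sampling configuration of a
#' simulator-produced series as JSON, for later validation.
#'
#' @param obs An [observed_series()] carrying provenance.
#' @param path Output JSON path.
#' @export
write_truth_json <- function(obs, path) {
  stopifnot(is_observed_series(obs))
  pr <- obs$provenance
  if (is.null(pr$true_params))
    rlang::abort("this series carries no generating truth")
  jsonlite::write_json(
    list(variant = pr$true_params$variant,
         theta = unname(pr$true_params$theta),
         names = names(pr$true_params$theta),
         seed = pr$seed, config = unclass(pr$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Log-size of a cylindrical plant
#'
#' Field measurements of globose or columnar plants are commonly reduced
#' to the volume of a cylinder; the model works on the log of that volume.
#'
#' @param diameter,height Measurements in a common length unit.
#' @return `log(pi * (diameter / 2)^2 * height)`.
#' @export
cylinder_log_volume <- function(diameter, height) {
  if (any(diameter <= 0) || any(height <= 0))
    rlang::abort("`diameter` and `height` must be > 0")
  log(pi * (diameter / 2)^2 * height)
}

#' Map a linearly accumulating disturbance index to time
#'
#' Chronosequence studies replace time with space: sites at different
#' disturbance intensities stand for one population's temporal stages.
#' Under the assumption that the index accumulates linearly, repeated
#' measurements at reference sites give the annual accumulation rate
#' (`mean index difference / elapsed years`), and each study site's years
#' since disturbance onset is `index / rate`.
#'
#' @param repeat_measures Tibble with columns `site`, `index_first`,
#'   `index_second`, `elapsed_years` -- two measurements of the index at
#'   each reference site.
#' @param site_index Tibble with columns `site`, `index` for the study
#'   sites to be placed on the time axis.
#' @return `site_index` with added columns `years_since_onset` and the
#'   estimated `annual_rate` (same value in every row).
#' @examples
#' ref <- tibble::tibble(site = c("a", "b"), index_first = c(1, 2),
#'                       index_second = c(3.4, 4.4), elapsed_years = 12)
#' map_disturbance_to_time(ref, tibble::tibble(site = "s1", index = 1))
#' @export
map_disturbance_to_time <- function(repeat_measures, site_index) {
  need <- c("site", "index_first", "index_second", "elapsed_years")
  miss <- setdiff(need, names(repeat_measures))
  if (length(miss))
    rlang::abort(sprintf("`repeat_measures` is missing: %s",
                         paste(miss, collapse = ", ")))
  if (!all(c("site", "index") %in% names(site_index)))
    rlang::abort("`site_index` needs columns `site` and `index`")
  if (nrow(repeat_measures) < 1)
    rlang::abort("need at least one reference site with two measurements")
  if (any(repeat_measures$elapsed_years <= 0))
    rlang::abort("`elapsed_years` must be > 0")
  if (any(site_index$index < 0))
    rlang::abort("disturbance index must be >= 0")
  rate <- mean(repeat_measures$index_second - repeat_measures$index_first) /
    mean(repeat_measures$elapsed_years)
  if (rate <= 0)
    rlang::abort("no directional trend: the mean index change is not positive")
  dplyr::mutate(tibble::as_tibble(site_index),
                years_since_onset = .data$index / rate,
                annual_rate = rate)
}

#' Run the full simulate-fit-validate pipeline
#'
#' Draws an artificial species, generates a noisy observation series,
#' fits it by multi-start composite likelihood across the `w` sweep,
#' computes accuracy metrics against the truth and writes all artifacts
#' (`observations.csv`, `densities.csv`, `truth.json`, `fits.json`,
#' `metrics.csv`, `manifest.json`) to `out_dir`. Deterministic given
#' `seed`.
#'
#' @param config Named list (or path to a JSON/YAML file) with entries
#'   `seed`, `out_dir`, and optionally `mesh` (`lower`, `upper`, `n`),
#'   `intervals` (path), `sampling` (arguments of [sampling_config()]),
#'   `w_values`, `error_levels`, `replicates`, `sigma_d`, `rules`
#'   (arguments of [plausibility_rules()]), `control`.
#' @return Invisibly, a list with the dataset, fits, metrics and manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$out_dir)) rlang::abort("config needs `out_dir`")
  seed <- config$seed
  if (is.null(seed)) {
    seed <- sample.int(1e6, 1)
    rlang::inform(sprintf("no seed in config; generated seed %d", seed))
  }
  if (!is.null(config$intervals) && !file.exists(config$intervals))
    rlang::abort(sprintf("bounds file not found: %s", config$intervals))
  mesh <- do.call(size_mesh, config$mesh %||% list())
  intervals <- if (is.null(config$intervals)) default_intervals()
    else read_intervals_json(config$intervals)
  sconf <- do.call(sampling_config, config$sampling %||% list())
  w_values <- config$w_values %||% c(0, 1, 10, 100, 1000)
  rules <- do.call(plausibility_rules, config$rules %||% list())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  set.seed(seed)
  truth <- draw_species(intervals, mesh, horizon = sconf$horizon,
                        initial_density = sconf$initial_density)
  obs <- make_dataset(truth, sconf, mesh)
  plan <- start_plan(truth, error_levels = config$error_levels %||% c(0, 5, 10, 25, 50),
                     replicates = config$replicates %||% 10, bounds = intervals)
  fits <- fit_multistart(obs, plan, intervals, w_values = w_values,
                         mesh = mesh, sigma_d = config$sigma_d %||% 0.3,
                         control = config$control %||% list())
  tt <- obs_times(obs)
  metrics <- purrr::map2_dfr(fits$fit, seq_len(nrow(fits)), function(f, i) {
    dplyr::bind_cols(
      tibble::tibble(fit_id = fits$start_id[i], w = fits$w[i]),
      fit_metrics(f, obs),
      tibble::tibble(label = screen_plausibility(f, rules,
                                                 t = seq(min(tt), max(tt)))))
  })

  paths <- file.path(config$out_dir,
                     c("observations.csv", "densities.csv", "truth.json",
                       "fits.json", "metrics.csv", "manifest.json"))
  names(paths) <- c("obs", "dens", "truth", "fits", "metrics", "manifest")
  write_observations(obs, paths["obs"], paths["dens"])
  write_truth_json(obs, paths["truth"])
  jsonlite::write_json(
    purrr::map2(fits$fit, seq_len(nrow(fits)), function(f, i) {
      list(start_id = fits$start_id[i], error_pct = fits$error_pct[i],
           w = fits$w[i], converged = fits$converged[i], l = fits$l[i],
           l_n = fits$l_n[i], l_d = fits$l_d[i], scale0 = fits$scale0[i],
           theta = unname(f$params$theta))
    }),
    paths["fits"], auto_unbox = TRUE, digits = NA)
  readr::write_csv(metrics, paths["metrics"])
  cfg_hash <- rlang::hash(list(config = config, seed = seed))
  manifest <- list(
    package = "vitalrecon",
    version = as.character(utils::packageVersion("vitalrecon")),
    seed = seed, config_hash = cfg_hash,
    n_failed_runs = attr(fits, "n_failed"),
    files = as.list(tools::md5sum(paths[names(paths) != "manifest"])))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE)
  invisible(list(truth = truth, obs = obs, fits = fits, metrics = metrics,
                 manifest = manifest, paths = paths))
}

#' @rdname run_pipeline
#' @param path Path to a `.json` or `.yaml`/`.yml` configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path)) {
    rlang::check_installed("yaml")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
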