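#' Parameter intervals for drawing artificial species
#'
#' A `species_intervals` table holds one `(lower, upper)` pair per kernel
#' scalar. It plays two roles: the sampling box for [draw_species()] and
#' the box constraints for [fit_single()] / [fit_multistart()].
#'
#' `default_intervals()` loads this package's reference intervals (shipped
#' in `inst/extdata/default_intervals.json`). They are this
#' implementation's choice of a box "ample enough" that each vital rate can
#' increase, decrease, or stay flat with size and with time, while drawn
#' species remain demographically viable over a century.
#'
#' @param lower,upper Numeric vectors of per-parameter bounds in canonical
#'   order ([param_names()]).
#' @param variant Model variant the intervals refer to.
#' @return A `species_intervals` tibble with columns `term`, `lower`,
#'   `upper`.
#' @export
species_intervals <- function(lower, upper,
                              variant = c("standard", "bounded_survival")) {
  variant <- match.arg(variant)
  k <- param_count(variant)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != k || length(upper) != k)
    rlang::abort(sprintf("need %d lower and upper bounds for %s", k, variant))
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    rlang::abort("bounds must be finite")
  if (any(lower > upper)) rlang::abort("every lower bound must be <= upper")
  nm <- param_names(variant)
  spreads <- match(c("g_sd", "o_sd"), nm)
  if (any(lower[spreads] <= 0))
    rlang::abort("spread lower bounds must be > 0")
  out <- tibble::tibble(term = nm, lower = lower, upper = upper)
  class(out) <- c("species_intervals", class(out))
  attr(out, "variant") <- variant
  out
}

#' @rdname species_intervals
#' @export
default_intervals <- function(variant = c("standard", "bounded_survival")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", "default_intervals.json",
                      package = "vitalrecon", mustWork = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- param_names(variant)
  i <- match(nm, obj$term)
  if (anyNA(i)) rlang::abort("intervals file is missing parameters")
  species_intervals(obj$lower[i], obj$upper[i], variant)
}

#' @rdname species_intervals
#' @param path JSON file with fields `term`, `lower`, `upper`.
#' @export
read_intervals_json <- function(path, variant = c("standard", "bounded_survival")) {
  variant <- match.arg(variant)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- param_names(variant)
  i <- match(nm, obj$term)
  if (anyNA(i))
    rlang::abort(sprintf("intervals file lacks parameter(s): %s",
                         paste(nm[is.na(i)], collapse = ", ")))
  species_intervals(obj$lower[i], obj$upper[i], variant)
}

intervals_variant <- function(intervals) {
  v <- attr(intervals, "variant")
  if (is.null(v)) if (nrow(intervals) == 16) "standard" else "bounded_survival"
  else v
}

#' Sampling design for simulated observation series
#'
#' Captures how an artificial population is observed: the number of sparse
#' observation years, the simulated horizon, the lognormal noise on sampled
#' counts, the sampling effort and the density at the start of the
#' simulation.
#'
#' @param n_times Number of observation years (default 10).
#' @param horizon Length of the simulated period in years (default 100;
#'   observation years are drawn in `1..horizon`).
#' @param sigma_c Log-scale of the lognormal noise on sampled counts, whose
#'   arithmetic mean is the (effort-scaled) population density; 0 means
#'   exact counts.
#' @param effort Sampling-effort multiplier: expected count =
#'   `effort * density`. Constant across years, so counts are proportional
#'   to density.
#' @param initial_density Population density at year 0.
#' @return A `sampling_config` list.
#' @export
sampling_config <- function(n_times = 10, horizon = 100, sigma_c = 0.3,
                            effort = 1, initial_density = 250) {
  n_times <- as.integer(n_times); horizon <- as.integer(horizon)
  if (is.na(n_times) || n_times < 2) rlang::abort("`n_times` must be >= 2")
  if (is.na(horizon) || horizon < n_times)
    rlang::abort("`horizon` must be >= `n_times`")
  if (sigma_c < 0) rlang::abort("`sigma_c` must be >= 0")
  if (effort <= 0 || initial_density <= 0)
    rlang::abort("`effort` and `initial_density` must be > 0")
  structure(list(n_times = n_times, horizon = horizon, sigma_c = sigma_c,
                 effort = effort, initial_density = initial_density),
            class = "sampling_config")
}

#' Draw a random artificial species
#'
#' Each kernel scalar is drawn uniformly within its interval; the draw is
#' accepted only if the species passes a viability screen: its stable
#' structure at year 0 is computable and the deterministic century-long
#' density trajectory (initialized at `initial_density`) stays within
#' `density_range`, i.e. the population neither collapses below observable
#' abundance nor explodes. Most uniform draws from an ample box describe
#' populations that crash or blow up within a century, so expect on the
#' order of tens of rejections per accepted species.
#'
#' @param intervals A [species_intervals()] table.
#' @param mesh A [size_mesh()] used for the viability screen.
#' @param horizon Horizon (years) over which viability is screened.
#' @param initial_density Density at year 0 used for the screen (match the
#'   [sampling_config()] you will simulate with).
#' @param density_range Admissible density range along the trajectory.
#' @param max_tries Consecutive non-viable draws tolerated before erroring.
#' @return A viable [kernel_params()] draw.
#' @export
draw_species <- function(intervals, mesh = size_mesh(), horizon = 100,
                         initial_density = 250,
                         density_range = c(5, 25000), max_tries = 100) {
  variant <- intervals_variant(intervals)
  for (try in seq_len(max_tries)) {
    theta <- stats::runif(nrow(intervals), intervals$lower, intervals$upper)
    params <- kernel_params(theta, variant)
    if (is_viable(params, mesh, horizon, initial_density, density_range))
      return(params)
  }
  rlang::abort(sprintf(
    paste("no viable species in %d draws; consider narrower intervals or a",
          "wider `density_range`"), max_tries))
}

is_viable <- function(params, mesh, horizon, initial_density, density_range) {
  tr <- tryCatch(
    simulate_series(params, mesh, 0, horizon, initial_density),
    error = function(e) NULL)
  !is.null(tr) && all(is.finite(tr$densities)) &&
    min(tr$densities) >= density_range[1] &&
    max(tr$densities) <= density_range[2]
}

#' Draw sparse observation years
#'
#' Distinct integer years sampled uniformly without replacement from
#' `1..horizon`, returned sorted; the sparse, unsystematic sampling typical
#' of historical series.
#'
#' @param config A [sampling_config()].
#' @return Sorted integer vector of length `config$n_times`.
#' @export
draw_observation_times <- function(config = sampling_config()) {
  stopifnot(inherits(config, "sampling_config"))
  sort(sample.int(config$horizon, config$n_times, replace = FALSE))
}

#' Sample an observed count for a given density
#'
#' Lognormal sampling noise with arithmetic mean equal to the target
#' (`meanlog = log(density) - sigma_c^2 / 2`), rounded to the nearest
#' integer. A nonpositive density is a degenerate population and yields 0
#' with a warning.
#'
#' @param density Target mean count (typically `effort * density`).
#' @param sigma_c Lognormal log-scale; 0 gives `round(density)` exactly.
#' @return A nonnegative integer count.
#' @export
sample_count <- function(density, sigma_c = 0.3) {
  if (sigma_c < 0) rlang::abort("`sigma_c` must be >= 0")
  if (density <= 0) {
    rlang::warn("nonpositive density: returning a count of 0")
    return(0L)
  }
  if (sigma_c == 0) return(as.integer(round(density)))
  as.integer(round(stats::rlnorm(1, meanlog = log(density) - sigma_c^2 / 2,
                                 sdlog = sigma_c)))
}

#' Monte-Carlo draws of individual log-sizes from a size structure
#'
#' Treats the (normalized) piecewise-constant structure as the probability
#' density of log-size: a mesh cell is drawn with probability proportional
#' to its density value, then the size is uniform within the cell.
#'
#' @param n A [size_structure()] with positive total density.
#' @param count Number of individuals to draw.
#' @return Numeric vector of `count` log-sizes within the mesh range.
#' @export
sample_sizes <- function(n, count) {
  stopifnot(is_size_structure(n))
  count <- as.integer(count)
  if (count == 0) return(numeric(0))
  if (total_density(n) <= 0)
    rlang::abort("cannot sample sizes from a zero-mass structure")
  mesh <- n$mesh
  cells <- sample.int(mesh$n, count, replace = TRUE, prob = n$values)
  mesh$lower + (cells - 1 + stats::runif(count)) * mesh$h
}

#' Generate a full artificial observation dataset
#'
#' The complete validation protocol: simulate the deterministic trajectory
#' of `params` over the horizon (stable initialization at year 0), draw
#' sparse observation years, then at each one sample a lognormal-noisy
#' count and that many Monte-Carlo log-sizes from the year's structure.
#' The observed density is the sampled count divided by the effort.
#'
#' @param params A [kernel_params()] object (the "true" species).
#' @param config A [sampling_config()].
#' @param mesh A [size_mesh()].
#' @param seed Optional integer seed for reproducible datasets.
#' @return An `observed_series` (see [observed_series()]) carrying the true
#'   parameters, config and seed as provenance.
#' @export
make_dataset <- function(params, config = sampling_config(),
                         mesh = size_mesh(), seed = NULL) {
  stopifnot(is_kernel_params(params), inherits(config, "sampling_config"))
  if (!is.null(seed)) set.seed(seed)
  trajectory <- simulate_series(params, mesh, t0 = 0,
                                horizon = config$horizon,
                                initial_density = config$initial_density)
  times <- draw_observation_times(config)
  obs <- purrr::map(times, function(tm) {
    st <- structure_at(trajectory, tm)
    dens <- total_density(st)
    count <- sample_count(config$effort * dens, config$sigma_c)
    list(time = tm, count = count, density = count / config$effort,
         sizes = sample_sizes(st, count))
  })
  sizes <- purrr::map_dfr(obs, function(o) {
    tibble::tibble(time = o$time,
                   individual_id = seq_len(length(o$sizes)),
                   log_size = o$sizes)
  })
  densities <- purrr::map_dfr(obs, function(o) {
    tibble::tibble(time = o$time, density = o$density,
                   sample_count = o$count)
  })
  observed_series(sizes, densities,
                  provenance = list(true_params = params, config = config,
                                    seed = seed, mesh = mesh))
}
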