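# Shared fixtures: all built in code, nothing on disk.

quick_mesh <- function(n = 50) size_mesh(0, 10, n)

# kernel_params with every scalar zero (spreads positive) and named overrides
make_params <- function(..., variant = "standard") {
  th <- stats::setNames(rep(0, param_count(variant)), param_names(variant))
  th["g_sd"] <- 0.5
  th["o_sd"] <- 0.4
  over <- list(...)
  stopifnot(all(names(over) %in% names(th)))
  th[names(over)] <- unlist(over)
  kernel_params(th, variant)
}

# a fixed viable artificial species used across tests (deterministic draw)
demo_species <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      withr::with_seed(7, {
        cache <<- draw_species(default_intervals(), quick_mesh())
      })
    }
    cache
  }
})

# random parameter vector inside the default interval box
random_species_theta <- function() {
  iv <- default_intervals()
  stats::runif(nrow(iv), iv$lower, iv$upper)
}

# wrap a plain nonnegative matrix as a kernel_matrix (for eigen oracles)
as_kernel <- function(m, mesh, time = 0) {
  structure(m, time = time, mesh = mesh,
            class = c("kernel_matrix", "matrix"))
}

# trajectory object with externally prescribed structures (for closed-form
# likelihood tests)
fake_trajectory <- function(structures, times, mesh) {
  structure(list(times = times, structures = structures,
                 densities = colSums(structures) * mesh$h, mesh = mesh,
                 lambda0 = NA_real_, params = NULL),
            class = "ipm_trajectory")
}

# noise-free dataset generated from the SAME generative model the fit
# assumes (trajectory initialized at the first listed observation year):
# counts are round(effort * density), sizes are Monte-Carlo draws
dataset_from_trajectory <- function(params, mesh, times, effort = 1) {
  trajectory <- simulate_series(params, mesh, t0 = times[1],
                                horizon = max(times) - times[1],
                                initial_density = 250)
  rows <- lapply(times, function(tm) {
    st <- vitalrecon:::structure_at(trajectory, tm)
    dens <- total_density(st)
    count <- round(effort * dens)
    list(time = tm, density = dens, count = count,
         sizes = sample_sizes(st, count))
  })
  sizes <- dplyr::bind_rows(lapply(rows, function(o)
    tibble::tibble(time = o$time, individual_id = seq_len(o$count),
                   log_size = o$sizes)))
  densities <- dplyr::bind_rows(lapply(rows, function(o)
    tibble::tibble(time = o$time, density = o$density,
                   sample_count = o$count)))
  observed_series(sizes, densities,
                  provenance = list(true_params = params))
}

# small noisy dataset for fast likelihood/fit tests
small_dataset <- function(params = demo_species(), seed = 5) {
  make_dataset(params, sampling_config(n_times = 5, horizon = 30),
               quick_mesh(), seed = seed)
}
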