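#' Observed series of size structures and densities
#'
#' The input data for the inverse fit: at each of several (sparse) years,
#' the log-sizes of the sampled individuals and the population density in
#' individuals per unit area. Years are snapped to integers (the model
#' projects annually); duplicated years in the density table are an error.
#'
#' @param sizes Tibble/data frame with columns `time`, `individual_id`,
#'   `log_size` (one row per sampled individual; may be empty for a year).
#' @param densities Tibble/data frame with columns `time`, `density` and
#'   optionally `sample_count`; one row per observation year.
#' @param provenance Optional list (true parameters, seed, config) attached
#'   by the simulator for validation runs.
#' @return An `observed_series` object.
#' @export
observed_series <- function(sizes, densities, provenance = NULL) {
  need_s <- c("time", "individual_id", "log_size")
  need_d <- c("time", "density")
  miss <- setdiff(need_s, names(sizes))
  if (length(miss))
    rlang::abort(sprintf("`sizes` is missing column(s): %s",
                         paste(miss, collapse = ", ")))
  miss <- setdiff(need_d, names(densities))
  if (length(miss))
    rlang::abort(sprintf("`densities` is missing column(s): %s",
                         paste(miss, collapse = ", ")))
  sizes <- tibble::as_tibble(sizes)
  densities <- tibble::as_tibble(densities)
  if (nrow(densities) < 1) rlang::abort("need at least one observation year")
  for (col in c("time", "density")) {
    if (!is.numeric(densities[[col]]))
      rlang::abort(sprintf("`densities$%s` must be numeric", col))
  }
  if (nrow(sizes) && !is.numeric(sizes$log_size))
    rlang::abort("`sizes$log_size` must be numeric")
  snap <- function(tt) as.integer(round(tt))
  if (nrow(sizes) && any(sizes$time != snap(sizes$time)))
    rlang::inform("non-integer observation times snapped to nearest year")
  sizes$time <- snap(sizes$time)
  densities$time <- snap(densities$time)
  if (anyDuplicated(densities$time))
    rlang::abort("duplicated observation years in `densities`")
  if (is.unsorted(densities$time)) {
    rlang::warn("observation years were unsorted; sorting")
    densities <- dplyr::arrange(densities, .data$time)
  }
  if (any(densities$density < 0)) rlang::abort("densities must be >= 0")
  extra <- setdiff(unique(sizes$time), densities$time)
  if (length(extra))
    rlang::abort(sprintf("size observations at year(s) %s lack a density row",
                         paste(extra, collapse = ", ")))
  structure(list(sizes = sizes, densities = densities,
                 provenance = provenance),
            class = "observed_series")
}

is_observed_series <- function(x) inherits(x, "observed_series")

obs_times <- function(obs) obs$densities$time

#' @export
print.observed_series <- function(x, ...) {
  cat(sprintf("<observed_series> %d years (%g-%g), %d individuals\n",
              nrow(x$densities), min(x$densities$time),
              max(x$densities$time), nrow(x$sizes)))
  if (!is.null(x$provenance$true_params))
    cat("  carries true generating parameters (validation run)\n")
  invisible(x)
}

# Map observed individuals to mesh cells; clip out-of-range sizes to the
# nearest cell and count the clips (> 5% clipped suggests a too-narrow mesh).
prepare_obs <- function(obs, mesh) {
  stopifnot(is_observed_series(obs), is_size_mesh(mesh))
  times <- obs_times(obs)
  sz <- obs$sizes
  clipped <- 0L
  cells <- integer(0)
  tidx <- integer(0)
  if (nrow(sz)) {
    out <- sz$log_size < mesh$lower | sz$log_size > mesh$upper
    clipped <- sum(out)
    if (clipped > 0.05 * nrow(sz))
      rlang::warn(sprintf(
        "%d of %d observed sizes fall outside the mesh; consider widening it",
        clipped, nrow(sz)))
    cells <- mesh_cell(mesh, sz$log_size)
    tidx <- match(sz$time, times)
  }
  list(times = as.integer(times), cells = as.integer(cells),
       tidx = as.integer(tidx), densities = obs$densities$density,
       n_clipped = clipped)
}
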