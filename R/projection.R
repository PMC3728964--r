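#' Size structure of the population
#'
#' A size structure holds the density of individuals over log-size
#' (individuals per unit area per unit log-size) at the nodes of a mesh,
#' stamped with the year it refers to. Integrating it over log-size
#' ([total_density()]) gives the population density.
#'
#' @param values Nonnegative density values at the mesh nodes.
#' @param mesh A [size_mesh()].
#' @param time Year the structure refers to.
#' @return A `size_structure` object.
#' @export
size_structure <- function(values, mesh, time = 0) {
  stopifnot(is_size_mesh(mesh))
  values <- as.numeric(values)
  if (length(values) != mesh$n)
    rlang::abort("`values` length must equal the number of mesh nodes")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    rlang::abort("`values` must be finite and nonnegative")
  structure(list(values = values, mesh = mesh, time = as.numeric(time)),
            class = "size_structure")
}

is_size_structure <- function(x) inherits(x, "size_structure")

#' @export
print.size_structure <- function(x, ...) {
  cat(sprintf("<size_structure> t = %g, density = %.4g on %s\n",
              x$time, total_density(x), format(x$mesh)))
  invisible(x)
}

#' @export
as_tibble.size_structure <- function(x, ...) {
  tibble::tibble(time = x$time, node = x$mesh$nodes, n_value = x$values)
}

#' Population density carried by a size structure
#'
#' Midpoint quadrature of the structure over log-size:
#' `sum(n(x_i) * h)`, in individuals per unit area.
#'
#' @param n A [size_structure()].
#' @return A single nonnegative number.
#' @export
total_density <- function(n) {
  stopifnot(is_size_structure(n))
  sum(n$values) * n$mesh$h
}

#' Project a size structure one year forward
#'
#' Applies the discretized kernel: `n'(y_i) = sum_j K(i, j) n(x_j)`, the
#' one-year IPM step. The result is stamped one year after the input.
#'
#' @param n A [size_structure()].
#' @param K A `kernel_matrix` from [evaluate_kernel()] on the same mesh.
#' @return The projected [size_structure()].
#' @export
project <- function(n, K) {
  stopifnot(is_size_structure(n), inherits(K, "kernel_matrix"))
  if (!same_mesh(n$mesh, kernel_mesh(K)))
    rlang::abort("structure and kernel were built on different meshes")
  size_structure(as.numeric(unclass(K) %*% n$values), n$mesh, n$time + 1)
}

#' Stable (asymptotic) size structure and growth rate of a kernel
#'
#' Dominant eigenpair of the nonnegative kernel matrix, computed by power
#' iteration with per-step normalization (tolerance `1e-10`, up to
#' `max_iter` iterations). The returned structure is normalized to total
#' density 1; `lambda` is the asymptotic annual growth rate. Used to
#' initialize trajectories under the assumption that the environment was
#' constant before the first observation.
#'
#' @param K A `kernel_matrix`.
#' @param tol Convergence tolerance on the iterate (sup-norm).
#' @param max_iter Maximum power iterations.
#' @return A list with `structure` (a [size_structure()], density 1),
#'   `lambda`, `residual` (relative eigen-residual) and `iterations`.
#' @export
stable_structure <- function(K, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(K, "kernel_matrix"))
  mesh <- kernel_mesh(K)
  st <- cpp_stable(unclass(K), mesh$h, tol, as.integer(max_iter))
  if (!isTRUE(st$converged))
    rlang::abort(sprintf(
      "power iteration did not converge in %d iterations (residual %.3g)",
      max_iter, as.numeric(st$residual)))
  list(structure = size_structure(st$values, mesh, attr(K, "time")),
       lambda = st$lambda, residual = st$residual, iterations = st$iterations)
}

#' Simulate a deterministic trajectory of the time-varying IPM
#'
#' Starts from the stable structure of the kernel at `t0` (scaled to
#' `initial_density`) and iterates the annual kernel, re-evaluated at each
#' integer year, for `horizon` years.
#'
#' @param params A [kernel_params()] object.
#' @param mesh A [size_mesh()].
#' @param t0 First year of the trajectory.
#' @param horizon Number of annual steps (>= 0).
#' @param initial_density Population density at `t0` (the stable structure
#'   supplies the shape; the kernel alone does not fix the absolute scale).
#' @return An `ipm_trajectory`: list with `times`, `structures` (N x
#'   (horizon+1) matrix of density values), `densities`, `mesh`, `lambda0`.
#' @examples
#' p <- kernel_params(c(0, 0.2, 0, 0, 0.6, 0.9, 0, 0, 0.5,
#'                      -2, 0.3, 0, 0, 1, 0, 0.4))
#' tr <- simulate_series(p, size_mesh(0, 10, 50), t0 = 0, horizon = 10)
#' tr$densities
#' @export
simulate_series <- function(params, mesh, t0 = 0, horizon = 100,
                            initial_density = 1) {
  stopifnot(is_kernel_params(params), is_size_mesh(mesh))
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 0) rlang::abort("`horizon` must be >= 0")
  if (initial_density < 0) rlang::abort("`initial_density` must be >= 0")
  sim <- cpp_simulate(theta_padded(params), mesh$nodes, mesh$h, t0, horizon,
                      initial_density,
                      params$variant == "bounded_survival", TRUE, 30,
                      1e-10, 10000L)
  if (!isTRUE(sim$converged))
    rlang::abort("stable structure at t0 did not converge; cannot initialize")
  structure(
    list(times = t0 + 0:horizon, structures = sim$structures,
         densities = as.numeric(sim$densities), mesh = mesh,
         lambda0 = sim$lambda0, params = params),
    class = "ipm_trajectory"
  )
}

#' @export
print.ipm_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ipm_trajectory> years %g-%g, density %.4g -> %.4g (lambda at t0 = %.4f)\n",
    min(x$times), max(x$times), x$densities[1],
    x$densities[length(x$densities)], x$lambda0))
  invisible(x)
}

structure_at <- function(trajectory, time) {
  i <- match(time, trajectory$times)
  if (is.na(i)) rlang::abort(sprintf("trajectory does not cover year %g", time))
  size_structure(trajectory$structures[, i], trajectory$mesh, time)
}

#' Tidy a trajectory
#'
#' @param x An `ipm_trajectory`.
#' @param ... Unused.
#' @return A tibble `(time, node, n_value)`; per-year densities are in
#'   [trajectory_densities()].
#' @export
as_tibble.ipm_trajectory <- function(x, ...) {
  tidyr::expand_grid(time = x$times, node = x$mesh$nodes) |>
    dplyr::mutate(n_value = as.numeric(x$structures))
}

#' Per-year density summary of a trajectory
#'
#' @param trajectory An `ipm_trajectory`.
#' @return A tibble `(time, density)`.
#' @export
trajectory_densities <- function(trajectory) {
  tibble::tibble(time = trajectory$times, density = trajectory$densities)
}
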