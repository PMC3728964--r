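#' Perturb kernel parameters for a multi-start plan
#'
#' Each scalar is multiplied by `1 + e` with `e` uniform in
#' `[-error_pct, +error_pct] / 100`, then clipped into its bounds (spreads
#' are floored at a small positive value when no bounds are given). With
#' `error_pct = 0` the parameters are returned unchanged.
#'
#' @param params A [kernel_params()] object.
#' @param error_pct Relative perturbation amplitude in percent (>= 0).
#' @param bounds Optional [species_intervals()] to clip into.
#' @return A perturbed [kernel_params()].
#' @export
perturb_initial <- function(params, error_pct, bounds = NULL) {
  stopifnot(is_kernel_params(params))
  if (error_pct < 0) rlang::abort("`error_pct` must be >= 0")
  th <- unname(params$theta)
  if (error_pct > 0)
    th <- th * (1 + stats::runif(length(th), -error_pct, error_pct) / 100)
  spreads <- match(c("g_sd", "o_sd"), param_names(params$variant))
  if (!is.null(bounds)) {
    th <- pmin(pmax(th, bounds$lower), bounds$upper)
  } else {
    th[spreads] <- pmax(th[spreads], 1e-6)
  }
  kernel_params(th, params$variant)
}

#' Multi-start plan around a set of base parameters
#'
#' The reference design uses one exact start plus `replicates` perturbed
#' starts at each nonzero error level -- with the defaults, 1 + 10 x 4 = 41
#' starts, probing how accurate the initial guess must be.
#'
#' @param base A [kernel_params()] object the starts are built around.
#' @param error_levels Percent error levels; level 0 contributes a single
#'   exact start.
#' @param replicates Perturbed starts per nonzero level.
#' @param bounds Optional [species_intervals()] the starts are clipped into.
#' @param seed Optional seed for reproducible perturbations.
#' @return A `start_plan` tibble with columns `start_id`, `error_pct`,
#'   `init` (list column of [kernel_params()]).
#' @export
start_plan <- function(base, error_levels = c(0, 5, 10, 25, 50),
                       replicates = 10, bounds = NULL, seed = NULL) {
  stopifnot(is_kernel_params(base))
  if (any(error_levels < 0)) rlang::abort("error levels must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map_dfr(error_levels, function(e) {
    reps <- if (e == 0) 1L else as.integer(replicates)
    tibble::tibble(error_pct = rep(e, reps))
  })
  if (nrow(rows) < 1) rlang::abort("the plan must contain at least one start")
  rows$start_id <- seq_len(nrow(rows))
  rows$init <- purrr::map(rows$error_pct, perturb_initial,
                          params = base, bounds = bounds)
  out <- rows[, c("start_id", "error_pct", "init")]
  class(out) <- c("start_plan", class(out))
  out
}

# indices of the slopes that multiply raw time; on the optimizer's internal
# scale they are multiplied by the horizon so all parameters are O(1)
time_slope_idx <- function(variant) {
  i <- c(3L, 4L, 7L, 8L, 12L, 13L, 15L)
  if (variant == "bounded_survival") i <- c(i, 18L)
  i
}

to_internal <- function(theta, variant, t_scale) {
  i <- time_slope_idx(variant)
  theta[i] <- theta[i] * t_scale
  theta
}

from_internal <- function(theta, variant, t_scale) {
  i <- time_slope_idx(variant)
  theta[i] <- theta[i] / t_scale
  theta
}

#' Fit the kernel parameters to one observed series
#'
#' Bounded quasi-Newton (`L-BFGS-B`) maximization of the composite
#' log-likelihood from a single starting point. The initial population
#' density `scale0` is profiled as an extra nuisance parameter (on the log
#' scale); kernel parameters are optimized on an internal scale with time
#' slopes premultiplied by the horizon, and reported on the natural scale.
#' Non-convergence is not an error: the best point found is returned with
#' `converged = FALSE`, a reportable outcome of its own.
#'
#' @param obs An [observed_series()].
#' @param init Starting [kernel_params()] (must lie within `bounds`).
#' @param bounds A [species_intervals()] giving the box constraints.
#' @param w Density weight of the composite likelihood.
#' @param mesh A [size_mesh()].
#' @param sigma_d Density observation log-scale.
#' @param control List of optimizer controls: `maxit` (default 300),
#'   `factr` (default 1e7), `scale0_span` (multiplicative span of the
#'   `scale0` box around the first observed density, default 30).
#' @return An `ipm_fit` object.
#' @export
fit_single <- function(obs, init, bounds, w = 1, mesh = size_mesh(),
                       sigma_d = 0.3, control = list()) {
  stopifnot(is_observed_series(obs), is_kernel_params(init))
  variant <- init$variant
  if (nrow(bounds) != param_count(variant))
    rlang::abort("`bounds` do not match the parameter count of `init`")
  pre <- prepare_obs(obs, mesh)
  t_scale <- max(pre$times)
  bounded <- variant == "bounded_survival"

  lo <- to_internal(bounds$lower, variant, t_scale)
  hi <- to_internal(bounds$upper, variant, t_scale)
  th0 <- pmin(pmax(unname(init$theta), bounds$lower), bounds$upper)
  th0 <- to_internal(th0, variant, t_scale)

  d1 <- obs$densities$density[1]
  if (d1 <= 0) d1 <- max(mean(obs$densities$density), 1e-6)
  span <- control$scale0_span %||% 30
  lo <- c(lo, log(d1 / span))
  hi <- c(hi, log(d1 * span))
  par0 <- c(th0, log(d1))

  k <- param_count(variant)
  # parameters with a zero-width box are held fixed, not optimized
  free <- which(hi > lo)
  full_par <- function(par) { out <- par0; out[free] <- par; out }
  negloglik <- function(par) {
    p <- full_par(par)
    th <- from_internal(p[seq_len(k)], variant, t_scale)
    if (bounded) pad <- th else pad <- c(th, 0, 0)
    v <- cpp_composite(pad, mesh$nodes, mesh$h, pre$times, pre$cells - 1L,
                       pre$tidx - 1L, pre$densities, w, sigma_d,
                       exp(p[k + 1]), bounded, TRUE, 30)
    if (!is.finite(v[1])) 1e10 else -v[1]
  }

  f0 <- negloglik(par0[free])
  if (f0 >= 1e10)
    rlang::abort("composite likelihood is -Inf at the start; try another start")

  res <- stats::optim(par0[free], negloglik, method = "L-BFGS-B",
                      lower = lo[free], upper = hi[free],
                      control = list(maxit = control$maxit %||% 300,
                                     factr = control$factr %||% 1e7))
  best <- full_par(if (res$value <= f0) res$par else par0[free])
  theta_hat <- from_internal(best[seq_len(k)], variant, t_scale)
  params_hat <- kernel_params(theta_hat, variant)
  scale0_hat <- exp(best[k + 1])
  cl <- composite_loglik(params_hat, obs, w = w, mesh = mesh,
                         sigma_d = sigma_d, scale0 = scale0_hat)
  structure(
    list(params = params_hat, scale0 = scale0_hat, loglik = cl,
         converged = res$convergence == 0 && res$value < 1e10,
         iterations = unname(res$counts["function"]),
         message = res$message %||% "", init = init, bounds = bounds,
         w = w, mesh = mesh, sigma_d = sigma_d),
    class = "ipm_fit"
  )
}

#' @export
print.ipm_fit <- function(x, ...) {
  cat(sprintf("<ipm_fit> w = %g, l = %.4f (%s), scale0 = %.4g\n",
              x$w, x$loglik$l,
              if (x$converged) "converged" else "NOT converged", x$scale0))
  invisible(x)
}

#' @describeIn fit_single Tidy the fitted parameters: one row per scalar
#'   with its box constraints.
#' @param x An `ipm_fit`.
#' @param ... Unused.
#' @export
tidy.ipm_fit <- function(x, ...) {
  est <- unname(x$params$theta)
  tibble::tibble(term = names(x$params$theta), estimate = est,
                 lower = x$bounds$lower, upper = x$bounds$upper,
                 at_bound = x$bounds$lower == est | x$bounds$upper == est)
}

#' @describeIn fit_single One-row fit summary (likelihood decomposition,
#'   convergence, nuisance scale).
#' @export
glance.ipm_fit <- function(x, ...) {
  tibble::tibble(l = x$loglik$l, l_n = x$loglik$l_n, l_d = x$loglik$l_d,
                 w = x$w, converged = x$converged,
                 iterations = x$iterations, scale0 = x$scale0,
                 n_clipped = x$loglik$n_clipped)
}

#' Multi-start fits across a sweep of density weights
#'
#' Runs [fit_single()] for every (start, w) combination. Starts whose
#' likelihood is degenerate (or that error) are logged and counted, not
#' fatal -- unless every start fails. Results are sorted by decreasing
#' likelihood within each `w`.
#'
#' @param obs An [observed_series()].
#' @param plan A [start_plan()].
#' @param bounds A [species_intervals()].
#' @param w_values Density weights to sweep (default
#'   `c(0, 1, 10, 100, 1000)`).
#' @inheritParams fit_single
#' @return An `ipm_fits` tibble: one row per completed fit with columns
#'   `start_id`, `error_pct`, `w`, `converged`, `l`, `l_n`, `l_d`,
#'   `scale0`, `fit` (list of `ipm_fit`); the number of failed runs is in
#'   `attr(, "n_failed")`.
#' @export
fit_multistart <- function(obs, plan, bounds,
                           w_values = c(0, 1, 10, 100, 1000),
                           mesh = size_mesh(), sigma_d = 0.3,
                           control = list()) {
  stopifnot(inherits(plan, "start_plan"))
  grid <- tidyr::expand_grid(w = as.numeric(w_values),
                             start_id = plan$start_id)
  failures <- 0L
  rows <- purrr::pmap(grid, function(w, start_id) {
    init <- plan$init[[match(start_id, plan$start_id)]]
    fit <- tryCatch(
      fit_single(obs, init, bounds, w = w, mesh = mesh, sigma_d = sigma_d,
                 control = control),
      error = function(e) {
        rlang::inform(sprintf("start %d (w = %g) failed: %s", start_id, w,
                              conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) { failures <<- failures + 1L; return(NULL) }
    tibble::tibble(
      start_id = start_id,
      error_pct = plan$error_pct[match(start_id, plan$start_id)],
      w = w, converged = fit$converged, l = fit$loglik$l,
      l_n = fit$loglik$l_n, l_d = fit$loglik$l_d, scale0 = fit$scale0,
      fit = list(fit))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    rlang::abort(sprintf("all %d runs failed", nrow(grid)))
  out <- dplyr::arrange(out, .data$w, dplyr::desc(.data$l))
  attr(out, "n_failed") <- failures
  class(out) <- c("ipm_fits", class(out))
  out
}

#' Group multi-start fits into distinct solutions
#'
#' Within each `w`, two fits belong to the same solution when their
#' likelihoods differ by less than `l_tol` and the largest
#' interval-width-normalized parameter difference is below `param_tol`.
#' Clustering is greedy from the best likelihood down, so the result does
#' not depend on the input order.
#'
#' @param fits An `ipm_fits` tibble from [fit_multistart()].
#' @param bounds The [species_intervals()] used for normalization.
#' @param param_tol Normalized L-infinity parameter tolerance.
#' @param l_tol Likelihood tolerance.
#' @param converged_only Drop non-converged fits first (default `TRUE`).
#' @return A tibble of solutions: `w`, `cluster`, `n_runs`, `l`,
#'   `start_id`, `fit` (best member of each cluster).
#' @export
cluster_solutions <- function(fits, bounds, param_tol = 0.05, l_tol = 1.0,
                              converged_only = TRUE) {
  stopifnot(inherits(fits, "ipm_fits") || is.data.frame(fits))
  if (converged_only) fits <- dplyr::filter(fits, .data$converged)
  if (!nrow(fits)) rlang::abort("no converged fits to cluster")
  width <- pmax(bounds$upper - bounds$lower, 1e-12)
  thetas <- purrr::map(fits$fit, ~ unname(.x$params$theta))
  key <- vapply(thetas, function(th) paste(signif(th, 10), collapse = ","), "")
  ord <- order(fits$w, -fits$l, key, fits$start_id)
  fits <- fits[ord, ]
  thetas <- thetas[ord]
  out <- list()
  for (wv in unique(fits$w)) {
    idx <- which(fits$w == wv)
    reps <- integer(0)
    members <- integer(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      assigned <- FALSE
      for (c in seq_along(reps)) {
        r <- reps[c]
        d <- max(abs(thetas[[i]] - thetas[[r]]) / width)
        if (d < param_tol && abs(fits$l[i] - fits$l[r]) < l_tol) {
          members[j] <- c; assigned <- TRUE; break
        }
      }
      if (!assigned) { reps <- c(reps, i); members[j] <- length(reps) }
    }
    out[[length(out) + 1]] <- tibble::tibble(
      w = wv, cluster = seq_along(reps),
      n_runs = as.integer(table(factor(members, seq_along(reps)))),
      l = fits$l[reps], start_id = fits$start_id[reps],
      fit = fits$fit[reps])
  }
  dplyr::bind_rows(out)
}
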