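#' Pearson correlations between true and reconstructed vital-rate surfaces
#'
#' Survival, the growth conditional-mean and the fecundity surfaces of the
#' two parameter sets are evaluated on a common size-by-time grid and
#' compared by Pearson correlation of the flattened surfaces. Growth is
#' compared via its conditional mean (a Pearson correlation of full
#' conditional densities is ill-defined). If a surface is constant the
#' correlation is undefined; the convention here is 1 when both surfaces
#' are constant and (numerically) equal, 0 otherwise, with
#' `constant_flag = TRUE`.
#'
#' @param true_params,est_params [kernel_params()] objects; variants may
#'   differ (surfaces, not parameters, are compared).
#' @param x Log-size grid (default 50 nodes across the mesh range).
#' @param t Time grid (typically every integer year of the observation
#'   window).
#' @return A one-row tibble: `r_s`, `r_g`, `r_f`, `constant_flag`.
#' @export
vitalrate_correlations <- function(true_params, est_params,
                                   x = seq(0, 10, length.out = 50),
                                   t = 0:100) {
  a <- vital_rate_surfaces(true_params, x, t)
  b <- vital_rate_surfaces(est_params, x, t)
  flag <- FALSE
  corr <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) {
      flag <<- TRUE
      return(if (isTRUE(all.equal(u, v))) 1 else 0)
    }
    stats::cor(u, v)
  }
  tibble::tibble(r_s = corr(a$survival, b$survival),
                 r_g = corr(a$growth_mean, b$growth_mean),
                 r_f = corr(a$fecundity, b$fecundity),
                 constant_flag = flag)
}

#' Correlation between reconstructed and observed densities
#'
#' Pearson correlation over the observation years between the densities of
#' a reconstructed trajectory and the observed ones. Undefined (with a
#' warning) below 3 observation years or for constant series.
#'
#' @param trajectory An `ipm_trajectory` covering the observation years.
#' @param obs An [observed_series()].
#' @return A single correlation (or `NA` when undefined).
#' @export
density_correlation <- function(trajectory, obs) {
  stopifnot(inherits(trajectory, "ipm_trajectory"), is_observed_series(obs))
  tt <- obs_times(obs)
  if (length(tt) < 3) {
    rlang::warn("fewer than 3 observation years: r_d is undefined")
    return(NA_real_)
  }
  pred <- trajectory$densities[match(tt, trajectory$times)]
  if (anyNA(pred)) rlang::abort("trajectory does not cover all observation years")
  if (stats::sd(pred) == 0 || stats::sd(obs$densities$density) == 0) {
    rlang::warn("constant density series: r_d is undefined")
    return(NA_real_)
  }
  stats::cor(pred, obs$densities$density)
}

#' Overall accuracy score r_m
#'
#' Arithmetic mean of the three vital-rate surface correlations and the
#' density correlation -- the single-number summary of how well a solution
#' reconstructs the species.
#'
#' @param metrics A list, one-row data frame or named vector containing
#'   `r_s`, `r_g`, `r_f`, `r_d`.
#' @return `(r_s + r_g + r_f + r_d) / 4`.
#' @export
mean_correlation <- function(metrics) {
  need <- c("r_s", "r_g", "r_f", "r_d")
  metrics <- as.list(metrics)
  if (!all(need %in% names(metrics)))
    rlang::abort("`metrics` must contain r_s, r_g, r_f and r_d")
  vals <- vapply(metrics[need], as.numeric, numeric(1))
  if (anyNA(vals)) rlang::abort("all four correlations must be present")
  mean(vals)
}

#' All accuracy metrics of a fit against the generating truth
#'
#' Convenience wrapper for validation runs: computes `r_s`, `r_g`, `r_f`
#' on the observation window, reconstructs the fitted trajectory (stable
#' initialization at the first observation year, fitted `scale0`) for
#' `r_d`, and averages into `r_m`.
#'
#' @param fit An `ipm_fit`.
#' @param obs The [observed_series()] that was fitted (must carry or be
#'   accompanied by the truth).
#' @param true_params The generating [kernel_params()]; defaults to the
#'   provenance stored in `obs`.
#' @param n_x Size-grid resolution for the surface correlations.
#' @return A one-row tibble `r_s`, `r_g`, `r_f`, `r_d`, `r_m`.
#' @export
fit_metrics <- function(fit, obs, true_params = NULL, n_x = 50) {
  stopifnot(inherits(fit, "ipm_fit"), is_observed_series(obs))
  if (is.null(true_params)) true_params <- obs$provenance$true_params
  if (is.null(true_params))
    rlang::abort("no true parameters available (pass `true_params`)")
  tt <- obs_times(obs)
  mesh <- fit$mesh
  vr <- vitalrate_correlations(
    true_params, fit$params,
    x = seq(mesh$lower, mesh$upper, length.out = n_x),
    t = seq(min(tt), max(tt)))
  trajectory <- simulate_series(fit$params, mesh, t0 = min(tt),
                                horizon = max(tt) - min(tt),
                                initial_density = fit$scale0)
  r_d <- density_correlation(trajectory, obs)
  dplyr::mutate(vr[, c("r_s", "r_g", "r_f")], r_d = r_d,
                r_m = mean_correlation(list(r_s = .data$r_s, r_g = .data$r_g,
                                            r_f = .data$r_f, r_d = r_d)))
}

#' Biological plausibility rules
#'
#' Coarse knowledge of the species used to discard "type-1" solutions:
#' optima whose reconstructed biology contradicts what is known (e.g. in
#' most plants fecundity increases with size; cactus seedlings survive
#' poorly). `"+"` / `"-"` demand an increasing / decreasing average trend
#' of the rate with size, `"none"` demands no strong size dependence
#' (|correlation of the surface with size| <= 0.5), `"unconstrained"`
#' disables the rule.
#'
#' @param survival_size,fecundity_size Expected sign of the size relation.
#' @param max_seedling_survival Optional admissible upper bound on survival
#'   at the smallest modeled size (checked at every time).
#' @return A `plausibility_rules` list.
#' @export
plausibility_rules <- function(survival_size = "unconstrained",
                               fecundity_size = "unconstrained",
                               max_seedling_survival = NULL) {
  ok <- c("+", "-", "none", "unconstrained")
  if (!survival_size %in% ok || !fecundity_size %in% ok)
    rlang::abort('signs must be one of "+", "-", "none", "unconstrained"')
  if (!is.null(max_seedling_survival) &&
      (max_seedling_survival <= 0 || max_seedling_survival > 1))
    rlang::abort("`max_seedling_survival` must be in (0, 1]")
  structure(list(survival_size = survival_size,
                 fecundity_size = fecundity_size,
                 max_seedling_survival = max_seedling_survival),
            class = "plausibility_rules")
}

#' Screen a solution against biological plausibility rules
#'
#' Labels a fitted (or candidate) parameter set `"plausible"` or `"type1"`
#' over an evaluation grid. Sign rules compare the average partial trend
#' of the rate surface along size; `"none"` flags strong size dependence,
#' operationalized on the linear-predictor scale as |size slope at the
#' mid-grid time| x sd(size grid) > 0.5 logit (survival) or log
#' (fecundity) units; the seedling rule checks survival at the smallest
#' grid size across all times. The label is advisory: biologically
#' plausible but wrong ("type-2") solutions are by definition undetectable
#' without the truth.
#'
#' @param fit An `ipm_fit` or [kernel_params()] object.
#' @param rules A [plausibility_rules()] object.
#' @param x,t Evaluation grid (defaults: 50 sizes over the fit's mesh and
#'   years 0..100).
#' @return `"plausible"` or `"type1"`.
#' @export
screen_plausibility <- function(fit, rules, x = NULL, t = 0:100) {
  params <- if (inherits(fit, "ipm_fit")) fit$params else fit
  stopifnot(is_kernel_params(params), inherits(rules, "plausibility_rules"))
  if (is.null(x)) {
    mesh <- if (inherits(fit, "ipm_fit")) fit$mesh else size_mesh()
    x <- seq(mesh$lower, mesh$upper, length.out = 50)
  }
  surf <- vital_rate_surfaces(params, x, t)
  bad <- sign_violated(surf, params, "survival", rules$survival_size, x, t) ||
    sign_violated(surf, params, "fecundity", rules$fecundity_size, x, t)
  if (!bad && !is.null(rules$max_seedling_survival)) {
    seedling <- surf[surf$x == min(surf$x), "survival", drop = TRUE]
    if (max(seedling) > rules$max_seedling_survival) bad <- TRUE
  }
  if (bad) "type1" else "plausible"
}

sign_violated <- function(surf, params, rate, rule, x, t) {
  if (rule == "unconstrained") return(FALSE)
  if (rule == "none") {
    # strength of the size effect on the predictor (logit/log) scale:
    # slope at the mid-grid time, per standard deviation of the size grid
    i <- if (rate == "survival") c(2L, 4L) else c(11L, 13L)
    slope <- params$theta[i[1]] + params$theta[i[2]] * mean(range(t))
    return(abs(slope) * stats::sd(x) > 0.5)
  }
  # mean finite-difference of the rate surface along size, over all times
  d <- surf |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(trend = mean(diff(.data[[rate]]) / diff(.data$x)),
                     .groups = "drop")
  trend <- mean(d$trend)
  (rule == "+" && trend < 0) || (rule == "-" && trend > 0)
}

#' Select the working solution from a multi-start sweep
#'
#' Implements the empirically supported selection rule: within each `w`
#' keep the highest-likelihood converged fit that passes the plausibility
#' screen, then prefer the smallest nonzero `w` that produced one (falling
#' back to `w = 0`, then to the best fit overall if nothing is plausible).
#'
#' @param fits An `ipm_fits` tibble from [fit_multistart()].
#' @param rules A [plausibility_rules()] object.
#' @param t Time grid for the screening surfaces.
#' @return One row of `fits` (with an added `label` column), or `NULL`
#'   when `fits` is empty.
#' @export
select_solution <- function(fits, rules = plausibility_rules(), t = 0:100) {
  if (!nrow(fits)) return(NULL)
  fits <- dplyr::filter(fits, .data$converged)
  if (!nrow(fits)) rlang::abort("no converged fits to select from")
  fits$label <- vapply(fits$fit, screen_plausibility, "", rules = rules, t = t)
  plausible <- dplyr::filter(fits, .data$label == "plausible")
  if (!nrow(plausible)) {
    rlang::warn("no plausible solution; returning the best fit overall")
    return(fits[which.max(fits$l), ])
  }
  ws <- sort(unique(plausible$w))
  wsel <- if (any(ws > 0)) min(ws[ws > 0]) else 0
  cand <- dplyr::filter(plausible, .data$w == wsel)
  cand[which.max(cand$l), ]
}
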