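#' Vital-rate functions of the kernel
#'
#' Evaluate the four vital-rate functions defined by a [kernel_params()]
#' object at arbitrary log-sizes and times. These are the continuous
#' functions that [evaluate_kernel()] discretizes.
#'
#' @param x,y Log-sizes (`x` current size, `y` size next year). Vectorized.
#' @param t Time in years.
#' @param params A [kernel_params()] object.
#' @return `survival_fn()` a probability in `[0, 1]`; `growth_fn()` and
#'   `offspring_size_fn()` probability densities per unit log-size;
#'   `fecundity_count_fn()` an expected newborn count (>= 0).
#' @examples
#' p <- kernel_params(c(0, 0, 0, 0, 0, 1, 0, 0, 0.5, 0, 0, 0, 0, 1, 0, 0.4))
#' survival_fn(3, 10, p) # logistic(0) = 0.5
#' fecundity_count_fn(3, 10, p) # exp(0) = 1
#' @name vital_rates
NULL

check_xt <- function(x, t) {
  if (anyNA(x) || any(!is.finite(x)) || anyNA(t) || any(!is.finite(t)))
    rlang::abort("log-size and time must be finite")
}

lin_pred <- function(x, t, a) a[1] + a[2] * x + (a[3] + a[4] * x) * t

#' @rdname vital_rates
#' @export
survival_fn <- function(x, t, params) {
  stopifnot(is_kernel_params(params))
  check_xt(x, t)
  th <- params$theta
  s <- stats::plogis(lin_pred(x, t, th[1:4]))
  if (params$variant == "bounded_survival")
    s <- s * stats::plogis(-(th["smax_b1"] + th["smax_b2"] * t))
  unname(s)
}

#' @rdname vital_rates
#' @export
growth_fn <- function(y, x, t, params) {
  stopifnot(is_kernel_params(params))
  check_xt(c(x, y), t)
  th <- params$theta
  if (th["g_sd"] <= 0) rlang::abort("growth spread must be > 0")
  unname(stats::dnorm(y, mean = lin_pred(x, t, th[5:8]), sd = th["g_sd"]))
}

#' @rdname vital_rates
#' @param cap Upper cap on the log-link predictor of fecundity; predictors
#'   above it are clipped (with a warning) to keep counts finite.
#' @export
fecundity_count_fn <- function(x, t, params, cap = 30) {
  stopifnot(is_kernel_params(params))
  check_xt(x, t)
  eta <- lin_pred(x, t, params$theta[10:13])
  if (any(eta > cap)) {
    rlang::warn(sprintf("fecundity predictor clipped at %g for %d value(s)",
                        cap, sum(eta > cap)))
    eta <- pmin(eta, cap)
  }
  unname(exp(eta))
}

#' @rdname vital_rates
#' @export
offspring_size_fn <- function(y, t, params) {
  stopifnot(is_kernel_params(params))
  check_xt(y, t)
  th <- params$theta
  if (th["o_sd"] <= 0) rlang::abort("offspring-size spread must be > 0")
  unname(stats::dnorm(y, mean = th["o_int"] + th["o_time"] * t, sd = th["o_sd"]))
}

#' Vital-rate surfaces on a size-by-time grid
#'
#' Tidy evaluation of survival, the growth conditional mean, and fecundity
#' over a grid; the common currency for plotting, Pearson-correlation
#' accuracy metrics and plausibility screening.
#'
#' @param params A [kernel_params()] object.
#' @param x Log-size grid (vector).
#' @param t Time grid in years (vector).
#' @return A tibble with columns `x`, `t`, `survival`, `growth_mean`,
#'   `fecundity`.
#' @export
vital_rate_surfaces <- function(params, x, t) {
  stopifnot(is_kernel_params(params))
  th <- params$theta
  grid <- tidyr::expand_grid(t = as.numeric(t), x = as.numeric(x))
  dplyr::mutate(
    grid,
    survival = survival_fn(.data$x, .data$t, params),
    growth_mean = lin_pred(.data$x, .data$t, th[5:8]),
    fecundity = exp(pmin(lin_pred(.data$x, .data$t, th[10:13]), 30))
  )[, c("x", "t", "survival", "growth_mean", "fecundity")]
}
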