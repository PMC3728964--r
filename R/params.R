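#' Kernel parameters of the time-varying IPM
#'
#' All four vital rates are driven by linear predictors in log-size `x` and
#' time `t` (years), `a0 + a1*x + a2*t + a3*x*t`, through rate-specific
#' links:
#'
#' * survival: logistic link (probability);
#' * growth: identity link for the conditional mean log-size next year,
#'   with a constant Gaussian residual spread;
#' * fecundity: log link for the expected newborns per individual per year;
#' * offspring size: identity link for the mean newborn log-size (time
#'   trend only -- newborn size cannot depend on parent size in the
#'   `f1 * f2` kernel factorization), constant Gaussian spread.
#'
#' The `standard` variant has 16 free scalars. The `bounded_survival`
#' variant multiplies survival by a time-varying ceiling
#' `s_max(t) = 1 / (1 + exp(beta1 + beta2 * t))`, adding 2 scalars (18
#' total); it avoids effectively immortal large individuals in long-lived
#' species.
#'
#' @param theta Numeric vector of length [param_count()] in canonical order
#'   (see [param_names()]): survival block, growth block, fecundity block,
#'   offspring-size block, then `beta1`, `beta2` for the bounded variant.
#' @param variant `"standard"` or `"bounded_survival"`.
#' @return A `kernel_params` object.
#' @examples
#' p <- kernel_params(c(-1, 0.3, 0.01, 0, 0.5, 0.9, 0, 0, 0.5,
#'                      -2, 0.3, 0, 0, 1, 0, 0.4))
#' p
#' @export
kernel_params <- function(theta, variant = c("standard", "bounded_survival")) {
  variant <- match.arg(variant)
  theta <- as.numeric(theta)
  k <- param_count(variant)
  if (length(theta) != k)
    rlang::abort(sprintf("`theta` must have length %d for the %s variant, got %d",
                         k, variant, length(theta)))
  if (anyNA(theta) || any(!is.finite(theta)))
    rlang::abort("`theta` must be finite")
  if (theta[9] <= 0) rlang::abort("growth spread (element 9) must be > 0")
  if (theta[16] <= 0) rlang::abort("offspring-size spread (element 16) must be > 0")
  names(theta) <- param_names(variant)
  structure(list(theta = theta, variant = variant), class = "kernel_params")
}

#' Number of free kernel parameters for a model variant
#'
#' @param variant `"standard"` (16 scalars) or `"bounded_survival"` (18).
#' @return Integer parameter count.
#' @examples
#' param_count("standard")
#' param_count("bounded_survival")
#' @export
param_count <- function(variant = c("standard", "bounded_survival")) {
  variant <- match.arg(variant)
  if (variant == "standard") 16L else 18L
}

#' Canonical parameter names
#'
#' @inheritParams param_count
#' @return Character vector of parameter names in canonical order.
#' @export
param_names <- function(variant = c("standard", "bounded_survival")) {
  variant <- match.arg(variant)
  nm <- c("s_int", "s_size", "s_time", "s_sizetime",
          "g_int", "g_size", "g_time", "g_sizetime", "g_sd",
          "f_int", "f_size", "f_time", "f_sizetime",
          "o_int", "o_time", "o_sd")
  if (variant == "bounded_survival") nm <- c(nm, "smax_b1", "smax_b2")
  nm
}

is_kernel_params <- function(x) inherits(x, "kernel_params")

# pad the 16-vector with dummy bounded entries for the C++ layout
theta_padded <- function(params) {
  th <- unname(params$theta)
  if (params$variant == "standard") th <- c(th, 0, 0)
  th
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("<kernel_params> %s variant, %d parameters\n",
              x$variant, length(x$theta)))
  print(round(x$theta, 5))
  invisible(x)
}

#' @describeIn kernel_params Tidy a `kernel_params` into a tibble with one
#'   row per scalar (`block`, `term`, `value`).
#' @param x A `kernel_params` object.
#' @param ... Unused.
#' @export
tidy.kernel_params <- function(x, ...) {
  nm <- names(x$theta)
  block <- dplyr::case_when(
    startsWith(nm, "s_") ~ "survival",
    startsWith(nm, "g_") ~ "growth",
    startsWith(nm, "f_") ~ "fecundity",
    startsWith(nm, "o_") ~ "offspring_size",
    TRUE ~ "survival_ceiling"
  )
  tibble::tibble(block = block, term = nm, value = unname(x$theta))
}

#' Serialize / deserialize kernel parameters as flat JSON
#'
#' The JSON object holds `variant`, the flat `theta` vector in canonical
#' order and the matching `names`, so files are self-describing.
#'
#' @param params A `kernel_params` object.
#' @param path File path.
#' @return `write_params_json()` returns `path` invisibly;
#'   `read_params_json()` returns a `kernel_params`.
#' @export
write_params_json <- function(params, path) {
  stopifnot(is_kernel_params(params))
  jsonlite::write_json(
    list(variant = params$variant, theta = unname(params$theta),
         names = names(params$theta)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$variant) || is.null(obj$theta))
    rlang::abort("params JSON must contain `variant` and `theta`")
  kernel_params(obj$theta, obj$variant)
}
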