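#' Discretized IPM kernel at a given time
#'
#' Assembles the kernel matrix `K(i, j) = k(y_i, x_j, t) * h` on a midpoint
#' mesh, where `k = s * g + f1 * f2` combines survival times the growth
#' transition density with fecundity times the offspring-size density.
#'
#' Eviction -- probability mass of `g` or `f2` falling outside the mesh --
#' is corrected by truncate-and-renormalize: each growth column and the
#' offspring-size vector are rescaled to unit within-mesh mass, so
#' survivors and newborn counts are conserved. Set
#' `correct_eviction = FALSE` to obtain the raw midpoint discretization.
#'
#' @param params A [kernel_params()] object.
#' @param mesh A [size_mesh()].
#' @param t Evaluation time in years.
#' @param correct_eviction Apply the truncate-and-renormalize correction
#'   (default `TRUE`).
#' @param cap Cap on the fecundity log-link predictor.
#' @return A `kernel_matrix`: an N x N numeric matrix with attributes
#'   `time` and `mesh`.
#' @examples
#' m <- size_mesh(0, 10, 50)
#' p <- kernel_params(c(40, 0, 0, 0, 0, 1, 0, 0, 0.5,
#'                      -30, 0, 0, 0, 1, 0, 0.4))
#' K <- evaluate_kernel(p, m, t = 0)
#' range(colSums(K)) # survival ~ 1, fecundity ~ 0: columns sum to ~1
#' @export
evaluate_kernel <- function(params, mesh, t, correct_eviction = TRUE, cap = 30) {
  stopifnot(is_kernel_params(params), is_size_mesh(mesh))
  check_xt(0, t)
  K <- cpp_kernel(theta_padded(params), mesh$nodes, mesh$h, t,
                  params$variant == "bounded_survival", correct_eviction, cap)
  if (any(!is.finite(K)) || any(K < 0))
    rlang::abort("kernel evaluation produced non-finite or negative entries")
  structure(K, time = t, mesh = mesh, class = c("kernel_matrix", "matrix"))
}

kernel_mesh <- function(K) attr(K, "mesh")

#' @export
print.kernel_matrix <- function(x, ...) {
  m <- kernel_mesh(x)
  cat(sprintf("<kernel_matrix> %d x %d at t = %g on %s\n",
              nrow(x), ncol(x), attr(x, "time"), format(m)))
  invisible(x)
}
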