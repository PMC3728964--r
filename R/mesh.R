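#' Discretization mesh for the log-size axis
#'
#' The IPM integral is discretized by the midpoint rule on `n` equal cells
#' spanning `[lower, upper]` on the log-size axis. Nodes are cell midpoints
#' and every node carries the same quadrature weight `h = (upper - lower)/n`.
#'
#' @param lower,upper Bounds of the modeled log-size range.
#' @param n Number of mesh cells (default 100; 50 is adequate for quick
#'   exploratory fits).
#' @return A `size_mesh` object: list with `nodes`, `h`, `lower`, `upper`, `n`.
#' @examples
#' m <- size_mesh(0, 10, 50)
#' sum(rep(1, m$n) * m$h) # quadrature of a unit density = width of the range
#' @export
size_mesh <- function(lower = 0, upper = 10, n = 100) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1,
            length(upper) == 1, is.finite(lower), is.finite(upper))
  if (!(lower < upper)) rlang::abort("`lower` must be < `upper`")
  n <- as.integer(n)
  if (is.na(n) || n < 2) rlang::abort("`n` must be an integer >= 2")
  h <- (upper - lower) / n
  structure(
    list(nodes = lower + h * (seq_len(n) - 0.5), h = h,
         lower = lower, upper = upper, n = n),
    class = "size_mesh"
  )
}

#' @export
print.size_mesh <- function(x, ...) {
  cat(sprintf("<size_mesh> %d midpoint nodes on [%g, %g], h = %g\n",
              x$n, x$lower, x$upper, x$h))
  invisible(x)
}

#' @export
format.size_mesh <- function(x, ...) {
  sprintf("size_mesh(%g, %g, %d)", x$lower, x$upper, x$n)
}

# index of the mesh cell containing log-size x (clipped into range)
mesh_cell <- function(mesh, x) {
  idx <- floor((x - mesh$lower) / mesh$h) + 1L
  pmin(pmax(idx, 1L), mesh$n)
}

is_size_mesh <- function(x) inherits(x, "size_mesh")

same_mesh <- function(a, b) {
  is_size_mesh(a) && is_size_mesh(b) &&
    a$n == b$n && isTRUE(all.equal(a$lower, b$lower)) &&
    isTRUE(all.equal(a$upper, b$upper))
}
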