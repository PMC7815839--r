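#' Inverse-distance descriptor and its Jacobian
#'
#' Maps an N-atom Cartesian geometry to the vector of inverse interatomic
#' distances 1/||r_a - r_b|| over all pairs a < b (pair order is that of
#' `utils::combn(N, 2)`). The descriptor is invariant under rigid
#' translations and rotations, which is what makes it a suitable input space
#' for gradient-domain kernel regression. The Jacobian maps Cartesian
#' perturbations (flattened atom-major, length 3N) to descriptor
#' perturbations.
#'
#' @param config a [molecular_configuration()] or an N x 3 coordinate matrix.
#' @param jacobian if `TRUE` (default) also return the Jacobian.
#' @return list with `d` (length N(N-1)/2 descriptor, 1/angstrom), `pairs`
#'   (2 x N(N-1)/2 index matrix) and, when requested, `J`
#'   (N(N-1)/2 x 3N Jacobian).
#' @export
compute_descriptor <- function(config, jacobian = TRUE) {
  x <- if (inherits(config, "molecular_configuration"))
    config$coordinates else as.matrix(config)
  n <- nrow(x)
  if (is.null(n) || n < 2L)
    stop("descriptor requires at least two atoms")
  pairs <- utils::combn(n, 2L)
  m <- ncol(pairs)
  a <- pairs[1L, ]; b <- pairs[2L, ]
  du <- x[a, , drop = FALSE] - x[b, , drop = FALSE]
  r2 <- rowSums(du * du)
  if (any(r2 < 1e-16)) {
    k <- which(r2 < 1e-16)[1L]
    stop(sprintf("degenerate geometry: atoms %d and %d coincide",
                 a[k], b[k]))
  }
  r <- sqrt(r2)
  d <- 1 / r
  out <- list(d = d, pairs = pairs)
  if (jacobian) {
    J <- matrix(0, m, 3L * n)
    g <- -du / (r2 * r)          # d(1/r)/d r_a, rows are pairs
    for (k in 1:3) {
      J[cbind(seq_len(m), 3L * (a - 1L) + k)] <- g[, k]
      J[cbind(seq_len(m), 3L * (b - 1L) + k)] <- -g[, k]
    }
    out$J <- J
  }
  out
}

# flatten N x 3 coordinates atom-major into length-3N vector and back
.flatten_coords <- function(x) as.vector(t(x))
.unflatten_coords <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

# column index map for applying permutation p to a flattened 3N vector:
# column 3(p[i]-1)+k of the permuted Jacobian equals column 3(i-1)+k of the
# Jacobian evaluated at the permuted geometry
.perm_col_index <- function(p) {
  as.vector(vapply(p, function(a) 3L * (a - 1L) + 1:3, integer(3)))
}
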