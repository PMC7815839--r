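#' Matern 5/2 kernel
#'
#' The covariance family used for gradient-domain force-field regression:
#' \deqn{k(d) = (1 + \sqrt{5}d/\sigma + 5d^2/(3\sigma^2))\,
#'   e^{-\sqrt{5}d/\sigma}.}
#' It is exactly twice differentiable, the minimum smoothness required for
#' force-force covariances (second derivatives of the kernel).
#'
#' @param d non-negative distance(s) in descriptor space.
#' @param sigma positive length-scale.
#' @return kernel value(s) in (0, 1], with k(0) = 1.
#' @export
matern52_kernel <- function(d, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a single positive number")
  if (any(d < 0)) stop("distances must be non-negative")
  a <- sqrt(5) / sigma
  (1 + a * d + a^2 * d^2 / 3) * exp(-a * d)
}

# k'(d)/d  (finite at d = 0): -(a^2/3)(1 + a d) exp(-a d)
.matern52_g1 <- function(d, sigma) {
  a <- sqrt(5) / sigma
  -(a^2 / 3) * (1 + a * d) * exp(-a * d)
}

# (d/dd)[k'(d)/d] / d  (finite at d = 0): (a^4/3) exp(-a d)
.matern52_g2 <- function(d, sigma) {
  a <- sqrt(5) / sigma
  (a^4 / 3) * exp(-a * d)
}

# cross Hessian d^2 k / dD dD' evaluated at u = D - D' (length-m vector):
# H(u) = -g1(|u|) I - g2(|u|) u u^T ; returned as function application on a
# matrix W (m x q): H %*% W, avoiding the explicit m x m matrix
.matern52_hess_apply <- function(u, sigma, W) {
  d <- sqrt(sum(u * u))
  -.matern52_g1(d, sigma) * W -
    .matern52_g2(d, sigma) * (u %*% (crossprod(u, W)))
}
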