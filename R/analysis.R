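#' Signed dihedral angle
#'
#' IUPAC sign convention: looking from atom j toward atom k, the angle is
#' the rotation of the i-j bond projection onto the k-l bond projection,
#' positive clockwise; computed with the atan2 cross-product formula.
#' Planar trans is 180 degrees, planar cis is 0.
#'
#' @param coords N x 3 coordinate matrix.
#' @param i,j,k,l four distinct 1-based atom indices.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(coords, i, j, k, l) {
  idx <- c(i, j, k, l)
  if (anyDuplicated(idx)) stop("dihedral indices must be distinct")
  x <- as.matrix(coords)
  b1 <- x[j, ] - x[i, ]
  b2 <- x[k, ] - x[j, ]
  b3 <- x[l, ] - x[k, ]
  if (sqrt(sum(b2 * b2)) < 1e-10 ||
      sum(.cross3(b1, b2)^2) < 1e-16 || sum(.cross3(b2, b3)^2) < 1e-16)
    stop("degenerate geometry: collinear atoms in dihedral definition")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2 * b2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Free-energy surface from sampled collective variables
#'
#' Boltzmann inversion of a 1-D or 2-D histogram:
#' \eqn{F = -k_B T \ln(\rho / \rho_{max})} on occupied bins, so the minimum
#' of F is 0. Empty bins are masked (NA), never imputed: an unvisited
#' region has an undefined, not an infinite-looking, free energy.
#'
#' @param samples numeric vector (1-D) or two-column matrix/data.frame (2-D)
#'   of collective-variable samples.
#' @param bins bin count per axis (scalar or length-2), or a list of
#'   explicit break vectors.
#' @param T temperature, K.
#' @return object of class `free_energy_surface`: bin edges, midpoints,
#'   counts, `F` values (kcal/mol, NA on empty bins), and `T`.
#' @export
free_energy_surface <- function(samples, bins = 50, T = 300) {
  if (T <= 0) stop("temperature must be positive")
  X <- if (is.null(dim(samples))) matrix(as.numeric(samples), ncol = 1L)
       else as.matrix(samples)
  if (!nrow(X)) stop("at least one sample is required")
  ndim <- ncol(X)
  if (!ndim %in% 1:2) stop("samples must be 1-D or 2-D")
  edges <- vector("list", ndim)
  if (is.list(bins)) {
    edges <- bins
  } else {
    nb <- rep_len(bins, ndim)
    for (d in seq_len(ndim)) {
      rng <- range(X[, d])
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      edges[[d]] <- seq(rng[1], rng[2], length.out = nb[d] + 1L)
    }
  }
  idx <- lapply(seq_len(ndim), function(d) {
    i <- findInterval(X[, d], edges[[d]], rightmost.closed = TRUE)
    i[i < 1L | i > length(edges[[d]]) - 1L] <- NA_integer_
    i
  })
  nb <- vapply(edges, function(e) length(e) - 1L, integer(1))
  counts <- array(0L, nb)
  ok <- Reduce(`&`, lapply(idx, function(i) !is.na(i)))
  flat <- idx[[1L]][ok]
  if (ndim == 2L) flat <- flat + nb[1L] * (idx[[2L]][ok] - 1L)
  tab <- tabulate(flat, nbins = prod(nb))
  counts[] <- tab
  rho <- counts / sum(counts)
  Fv <- array(NA_real_, nb)
  occ <- counts > 0L
  Fv[occ] <- -thermal_energy(T) * log(rho[occ] / max(rho))
  mids <- lapply(edges, function(e) (e[-1L] + e[-length(e)]) / 2)
  if (ndim == 1L) { counts <- as.vector(counts); Fv <- as.vector(Fv) }
  structure(list(edges = edges, midpoints = mids, counts = counts,
                 F = Fv, T = T, n = sum(counts)),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf(paste0("Free-energy surface: %d-D, %s bins, %d samples,",
                     " T = %g K, max F = %.3f kcal/mol\n"),
              length(x$edges),
              paste(if (is.null(dim(x$F))) length(x$F) else dim(x$F),
                    collapse = " x "),
              x$n, x$T, max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Time-resolved angle histogram
#'
#' Bins an angle time series on a (time, angle) grid; the default bin sizes
#' (5 ps x 6 degrees) are those used to visualise transient rotor
#' localization. Column sums equal the number of frames per time window.
#'
#' @param angles angle series, degrees in (-180, 180].
#' @param dt frame spacing, fs (uniform).
#' @param time_bin time bin width, ps (default 5).
#' @param angle_bin angle bin width, degrees (default 6).
#' @return list with `counts` (angle bins x time bins), `time_edges` (ps),
#'   `angle_edges` (degrees).
#' @export
time_angle_histogram <- function(angles, dt, time_bin = 5, angle_bin = 6) {
  if (dt <= 0) stop("dt must be positive")
  if (anyNA(angles)) stop("angle series contains NA (non-uniform series?)")
  t_ps <- (seq_along(angles) - 1L) * dt * 1e-3
  te <- seq(0, max(t_ps) + time_bin, by = time_bin)
  ae <- seq(-180, 180, by = angle_bin)
  ti <- findInterval(t_ps, te, rightmost.closed = TRUE)
  wrapped <- .wrap_angle(angles)
  ai <- findInterval(wrapped, ae, rightmost.closed = TRUE)
  counts <- matrix(0L, length(ae) - 1L, length(te) - 1L)
  tab <- tabulate(ai + (length(ae) - 1L) * (ti - 1L),
                  nbins = length(counts))
  counts[] <- tab
  list(counts = counts, time_edges = te, angle_edges = ae)
}

# wrap to (-180, 180]
.wrap_angle <- function(a) {
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Unwrap an angle series by shortest-path increments
#'
#' @param angles wrapped series, degrees.
#' @return continuous series with jumps of more than 180 degrees removed.
#' @export
unwrap_angles <- function(angles) {
  d <- diff(angles)
  d <- d - 360 * round(d / 360)
  c(angles[1L], angles[1L] + cumsum(d))
}

#' Detect transient localized rotor states
#'
#' Finds maximal time intervals during which the wrapped angle stays within
#' `tolerance` of one well center for at least `min_duration` (closed
#' interval semantics: a dwell exactly `min_duration` long counts). This is
#' the operational criterion for "the rotor stopped rotating": free
#' rotation yields no records, a pinned rotor yields long ones.
#'
#' @param angles angle series, degrees.
#' @param dt frame spacing, fs.
#' @param wells well-center angles, degrees.
#' @param tolerance half-width of the capture window, degrees (default 30).
#' @param min_duration minimum dwell, fs (default 1000 fs = 1 ps).
#' @return data.frame with one row per localized state: `start` and
#'   `duration` (ps), `well` (index), `mean_angle` (degrees); attributes
#'   `count`, `mean_duration`, `max_duration` (ps) and the detection
#'   parameters.
#' @export
detect_localized_states <- function(angles, dt, wells = c(-120, 0, 120),
                                    tolerance = 30, min_duration = 1000) {
  if (!length(wells)) stop("well list must be non-empty")
  if (min_duration < dt) stop("min_duration must be at least dt")
  w <- .wrap_angle(angles)
  # distance to nearest well (circular)
  dmat <- vapply(wells, function(wc) {
    d <- abs(.wrap_angle(w - wc)); d
  }, numeric(length(w)))
  dmat <- matrix(dmat, ncol = length(wells))
  nearest <- max.col(-dmat)
  inside <- dmat[cbind(seq_along(w), nearest)] <= tolerance
  lab <- ifelse(inside, nearest, 0L)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  recs <- list()
  for (s in seq_along(r$values)) {
    if (r$values[s] == 0L) next
    dur <- (r$lengths[s] - 1L) * dt
    if (dur + 1e-9 < min_duration) next
    seg <- w[starts[s]:ends[s]]
    wc <- wells[r$values[s]]
    recs[[length(recs) + 1L]] <-
      data.frame(start = (starts[s] - 1L) * dt * 1e-3,
                 duration = dur * 1e-3,
                 well = r$values[s],
                 mean_angle = wc + mean(.wrap_angle(seg - wc)))
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(start = numeric(0), duration = numeric(0),
               well = integer(0), mean_angle = numeric(0))
  attr(out, "count") <- nrow(out)
  attr(out, "mean_duration") <- if (nrow(out)) mean(out$duration) else NA_real_
  attr(out, "max_duration") <- if (nrow(out)) max(out$duration) else NA_real_
  attr(out, "parameters") <- list(wells = wells, tolerance = tolerance,
                                  min_duration = min_duration, dt = dt)
  out
}

#' Fit a power law to interaction-energy data
#'
#' Ordinary least squares of \eqn{\log|E|} against \eqn{\log r} restricted
#' to `r >= r_min` (the free-attractive-regime window). Returns the decay
#' exponent `n` (positive for a decaying magnitude, i.e. E ~ A r^-n) and
#' amplitude `A`. The energies inside the window must not change sign.
#'
#' @param r separations, A. @param E energies, kcal/mol.
#' @param r_min window start, A (default 3.8).
#' @param r_max optional window end, A.
#' @return object of class `power_law_fit` with `n`, `A`, `window`,
#'   `residuals` and the number of points used.
#' @export
fit_power_law <- function(r, E, r_min = 3.8, r_max = Inf) {
  keep <- which(r >= r_min & r <= r_max & is.finite(E) & E != 0)
  if (length(keep) < 3L)
    stop("need at least 3 points with r inside the fit window")
  Ew <- E[keep]; rw <- r[keep]
  if (length(unique(sign(Ew))) > 1L)
    stop(paste("energies change sign inside the fit window; move r_min",
               "outside the repulsive/crossing region"))
  fit <- stats::lm(log(abs(Ew)) ~ log(rw))
  n <- -unname(stats::coef(fit)[2L])
  A <- exp(unname(stats::coef(fit)[1L]))
  structure(list(n = n, A = A, sign = sign(Ew[1L]),
                 window = c(r_min = r_min, r_max = r_max),
                 residuals = stats::residuals(fit),
                 npoints = length(keep)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(paste0("Power-law fit: |E| = A r^-n with n = %.4f,",
                     " A = %.6g (%d points, window [%g, %g] A)\n"),
              x$n, x$A, x$npoints, x$window[1L], x$window[2L]))
  invisible(x)
}

#' Drude-oscillator polarizability model
#'
#' One pair of parameters per fragment: static dipole polarizability
#' `alpha0` and characteristic frequency `omega0` give the
#' imaginary-frequency polarizability
#' \eqn{\alpha(i\omega) = \alpha_0 \omega_0^2 / (\omega_0^2 + \omega^2)},
#' positive and monotonically decreasing.
#'
#' @param alpha0 static polarizability, A^3.
#' @param omega0 characteristic frequency, 1/fs.
#' @return object of class `drude_oscillator`.
#' @export
drude_oscillator <- function(alpha0, omega0) {
  if (alpha0 <= 0 || omega0 <= 0)
    stop("alpha0 and omega0 must be positive")
  structure(list(alpha0 = alpha0, omega0 = omega0),
            class = "drude_oscillator")
}

#' @param osc a `drude_oscillator`. @param omega imaginary frequency, 1/fs.
#' @rdname drude_oscillator
#' @export
drude_alpha <- function(osc, omega) {
  osc$alpha0 * osc$omega0^2 / (osc$omega0^2 + omega^2)
}

#' Casimir-Polder C6 dispersion coefficient
#'
#' \deqn{C_6^{AB} = \frac{3\hbar}{\pi}\int_0^\infty
#'   \alpha_A(i\omega)\,\alpha_B(i\omega)\,d\omega,}
#' evaluated by Gauss-Legendre quadrature on the half-line mapped through
#' \eqn{\omega = \omega_s t/(1-t)}. For Drude oscillators the integral has
#' the London closed forms used as test oracles:
#' \eqn{C_6 = (3/2)\,\alpha_A\alpha_B\,\hbar\omega_A\omega_B/(\omega_A +
#' \omega_B)} (and \eqn{(3/4)\hbar\omega_0\alpha_0^2} for identical
#' fragments).
#'
#' @param A,B `drude_oscillator` objects.
#' @param nodes quadrature nodes (default 200).
#' @return C6 in kcal/mol * A^6.
#' @export
casimir_polder_c6 <- function(A, B, nodes = 200L) {
  stopifnot(inherits(A, "drude_oscillator"), inherits(B, "drude_oscillator"))
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  ws <- sqrt(A$omega0 * B$omega0)       # map scale, 1/fs
  t <- gl$x
  omega <- ws * t / (1 - t)
  jac <- ws / (1 - t)^2
  integrand <- drude_alpha(A, omega) * drude_alpha(B, omega) * jac
  (3 * .hbar_kcalmol_fs / pi) * sum(gl$w * integrand)
}

#' London dispersion energy from a C6 coefficient
#'
#' \eqn{E_{vdW}(R) = -C_6 / R^6}: attractive (negative) for all positive
#' inputs.
#'
#' @param C6 dispersion coefficient, kcal/mol * A^6.
#' @param R fragment separation(s), A.
#' @return energy in kcal/mol (vectorized over R).
#' @export
vdw_energy <- function(C6, R) {
  if (any(R <= 0)) stop("separation must be positive")
  -C6 / R^6
}

#' Polarizability from an effective van der Waals radius
#'
#' Uses the scaling law \eqn{\alpha \propto R_{vdW}^7}: small dilations of
#' a molecule's effective radius translate into large polarizability gains
#' (7th-power amplification), which is the mechanism by which thermal and
#' quantum geometry fluctuations strengthen dispersion interactions.
#'
#' @param R_vdW effective radius (or radii), A; must be positive.
#' @param scale proportionality constant (default 1; A^3 per A^7).
#' @return polarizability value(s), `scale * R^7`.
#' @export
polarizability_from_radius <- function(R_vdW, scale = 1) {
  if (any(R_vdW <= 0)) stop("effective radius must be positive")
  scale * R_vdW^7
}

#' Effective molecular radius
#'
#' Mass-weighted radius of gyration plus a fixed offset (default 1.7 A, an
#' atomic van der Waals shell). This is a documented geometric proxy for
#' the molecule's van der Waals extent: it preserves the dilation scaling
#' that the \eqn{\alpha \propto R^7} law amplifies, without any electronic
#' structure input.
#'
#' @param config a [molecular_configuration()] or N x 3 coordinate matrix
#'   (equal masses assumed for a bare matrix).
#' @param offset additive shell radius, A.
#' @return effective radius, A.
#' @export
effective_radius <- function(config, offset = 1.7) {
  if (inherits(config, "molecular_configuration")) {
    x <- config$coordinates
    m <- tryCatch(atomic_masses(config$species),
                  error = function(e) rep(1, nrow(x)))
  } else {
    x <- as.matrix(config)
    m <- rep(1, nrow(x))
  }
  cm <- colSums(x * m) / sum(m)
  rg <- sqrt(sum(m * rowSums(sweep(x, 2L, cm)^2)) / sum(m))
  rg + offset
}

#' Ensemble polarizability increment
#'
#' Percentage gain of the ensemble-averaged polarizability over a reference
#' geometry, with per-configuration polarizabilities from the
#' \eqn{\alpha \propto R^7} law on effective radii (or, when full 3 x 3
#' tensors are supplied, from the mean isotropic polarizability
#' \eqn{\mathrm{Tr}(\alpha)/3}). Because \eqn{R^7} is convex, symmetric
#' radius fluctuations alone already give a positive increment; ensembles
#' with dilated mean radii (quantum sampling) gain more.
#'
#' @param ensemble list of configurations (or numeric vector of effective
#'   radii, or list of 3 x 3 polarizability tensors).
#' @param reference reference configuration (or radius, or tensor).
#' @param offset passed to [effective_radius()].
#' @return increment in percent: `100 * (mean(alpha)/alpha_ref - 1)`.
#' @export
ensemble_polarizability_increment <- function(ensemble, reference,
                                              offset = 1.7) {
  alpha_of <- function(obj) {
    if (is.matrix(obj) && identical(dim(obj), c(3L, 3L)))
      return(sum(diag(obj)) / 3)
    if (is.numeric(obj) && length(obj) == 1L)
      return(polarizability_from_radius(obj))
    polarizability_from_radius(effective_radius(obj, offset))
  }
  if (is.numeric(ensemble) && is.null(dim(ensemble))) {
    vals <- polarizability_from_radius(ensemble)
  } else {
    if (!length(ensemble)) stop("ensemble must be non-empty")
    vals <- vapply(ensemble, alpha_of, numeric(1))
  }
  aref <- alpha_of(reference)
  if (aref <= 0) stop("reference polarizability must be positive")
  100 * (mean(vals) / aref - 1)
}

#' Ensemble-averaged interaction-energy scan
#'
#' For each separation on `R_grid`, evaluates a pair potential over paired
#' members of two configuration ensembles held at that separation and
#' reports the mean and standard error. `pairing = "zip"` pairs member i of
#' A with member i of B (ensembles must have equal length);
#' `pairing = "cross"` averages over all pairs.
#'
#' @param ensembleA,ensembleB lists of configurations (any objects the
#'   `pair_potential` accepts).
#' @param pair_potential function `(R, confA, confB) -> energy` (kcal/mol).
#' @param R_grid separations to scan, A.
#' @param pairing `"zip"` (default) or `"cross"`.
#' @return data.frame with columns `R`, `mean`, `se`, `n`.
#' @export
ensemble_interaction_scan <- function(ensembleA, ensembleB, pair_potential,
                                      R_grid, pairing = c("zip", "cross")) {
  pairing <- match.arg(pairing)
  if (!length(ensembleA) || !length(ensembleB))
    stop("ensembles must be non-empty")
  if (pairing == "zip" && length(ensembleA) != length(ensembleB))
    stop("zipped pairing requires ensembles of equal length")
  idx <- if (pairing == "zip")
    cbind(seq_along(ensembleA), seq_along(ensembleB))
  else as.matrix(expand.grid(seq_along(ensembleA), seq_along(ensembleB)))
  out <- lapply(R_grid, function(R) {
    e <- vapply(seq_len(nrow(idx)), function(r)
      pair_potential(R, ensembleA[[idx[r, 1L]]], ensembleB[[idx[r, 2L]]]),
      numeric(1))
    data.frame(R = R, mean = mean(e),
               se = stats::sd(e) / sqrt(length(e)), n = length(e))
  })
  do.call(rbind, out)
}

#' Dispersion pair potential from effective radii
#'
#' Builds a `(R, confA, confB) -> energy` closure for
#' [ensemble_interaction_scan()]: each configuration's effective radius
#' gives a Drude polarizability via the \eqn{\alpha \propto R^7} law, the
#' pair C6 follows from the two-oscillator London formula, and the energy
#' is \eqn{-C_6/R^6} (optionally with an exponential wall).
#'
#' @param omega0 Drude frequency shared by the fragments, 1/fs.
#' @param alpha_scale proportionality constant of the radius law.
#' @param offset passed to [effective_radius()].
#' @param wall_B,wall_s optional repulsive wall parameters (0 disables).
#' @return a pair-potential function.
#' @export
make_dispersion_pair_potential <- function(omega0 = 0.05, alpha_scale = 0.01,
                                           offset = 1.7, wall_B = 0,
                                           wall_s = 3) {
  force(omega0); force(alpha_scale); force(offset)
  function(R, confA, confB) {
    ra <- if (is.numeric(confA) && length(confA) == 1L) confA
          else effective_radius(confA, offset)
    rb <- if (is.numeric(confB) && length(confB) == 1L) confB
          else effective_radius(confB, offset)
    aA <- polarizability_from_radius(ra, alpha_scale)
    aB <- polarizability_from_radius(rb, alpha_scale)
    C6 <- 1.5 * aA * aB * .hbar_kcalmol_fs * omega0 / 2
    vdw_energy(C6, R) + wall_B * exp(-wall_s * R)
  }
}
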