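#' Analytic model potentials
#'
#' A `model_pes` is an analytic potential-energy surface with an exact
#' gradient. These surfaces stand in for high-level quantum-chemistry
#' reference data: each one isolates a single interaction mechanism
#' (torsional barrier switching, steep power-law attraction, partial-charge
#' electrostatics, dispersion-corrected bonding) so that the dynamics and
#' analysis machinery can be exercised and tested against closed forms.
#'
#' Every surface evaluates on an N x 3 coordinate block (some coordinates may
#' be generalized rather than Cartesian; see the individual constructors) and
#' carries default masses (amu) and a reference geometry `x0`.
#'
#' @param pes a `model_pes` object.
#' @param coords coordinate matrix of shape `pes$natoms` x 3 (a plain
#'   numeric vector of the right length is accepted and reshaped).
#' @return `evaluate_pes` returns a list with `energy` (kcal/mol) and
#'   `gradient` (same shape as `coords`, kcal/mol/A).
#' @name model_pes
NULL

.new_pes <- function(name, params, natoms, masses, x0, species, evalfun,
                     eval_batch = NULL) {
  structure(list(name = name, params = params, natoms = natoms,
                 masses = masses, x0 = x0, species = species,
                 eval = evalfun, eval_batch = eval_batch),
            class = "model_pes")
}

#' @export
print.model_pes <- function(x, ...) {
  cat("Model PES '", x$name, "': ", x$natoms, " coordinate block(s)\n",
      sep = "")
  invisible(x)
}

#' @rdname model_pes
#' @export
evaluate_pes <- function(pes, coords) {
  stopifnot(inherits(pes, "model_pes"))
  x <- if (is.matrix(coords)) coords
       else matrix(coords, ncol = 3L, byrow = TRUE)
  if (!identical(dim(x), c(pes$natoms, 3L)))
    stop(sprintf("coordinates must be %d x 3 for PES '%s'",
                 pes$natoms, pes$name))
  out <- pes$eval(x)
  if (!is.finite(out$energy)) stop("PES evaluated outside its domain")
  out
}

#' Isotropic harmonic surface
#'
#' \eqn{V = \sum_i k_i (x_i - c_i)^2 / 2} over all 3N coordinates; the
#' workhorse for closed-form checks (equipartition, quantum harmonic
#' oscillator energies, ring-polymer Gaussian statistics).
#'
#' @param k force constant(s), kcal/mol/A^2; recycled over coordinates.
#' @param center equilibrium coordinates (N x 3 matrix or scalar).
#' @param mass particle mass(es), amu.
#' @param natoms number of particles (default 1).
#' @return a `model_pes`.
#' @export
harmonic_pes <- function(k = 100, center = 0, mass = 1, natoms = 1L) {
  x0 <- if (is.matrix(center)) center else
    matrix(center, natoms, 3L)
  kmat <- matrix(k, natoms, 3L)
  kflat <- as.vector(t(kmat))
  cflat <- as.vector(t(x0))
  .new_pes("harmonic", list(k = kmat, center = x0), natoms,
           rep_len(mass, natoms), x0, rep("X", natoms),
           function(x) {
             dx <- x - x0
             list(energy = sum(kmat * dx * dx) / 2, gradient = kmat * dx)
           },
           eval_batch = function(Q) {
             D <- sweep(Q, 2L, cflat)
             G <- sweep(D, 2L, kflat, `*`)
             list(energy = rowSums(G * D) / 2, gradient = G)
           })
}

#' Quartic double well with optional tilt
#'
#' \eqn{V(x) = h\,[(x^2 - x_0^2)/x_0^2]^2 + t\,x} on the x-coordinate of a
#' single particle, harmonic (stiffness `k_transverse`) in y and z. The
#' barrier between wells (at `t = 0`) is `height`; a non-zero tilt `t`
#' biases the occupancy, giving an analytic Boltzmann well-occupancy ratio
#' to test thermostatted sampling against.
#'
#' @param height barrier height, kcal/mol.
#' @param x0 well position, A.
#' @param tilt linear bias, kcal/mol/A.
#' @param k_transverse stiffness of the spectator y/z coordinates.
#' @param mass particle mass, amu.
#' @return a `model_pes`.
#' @export
double_well_pes <- function(height = 1, x0 = 1, tilt = 0,
                            k_transverse = 50, mass = 1) {
  .new_pes("doublewell",
           list(height = height, x0 = x0, tilt = tilt,
                k_transverse = k_transverse),
           1L, mass, matrix(c(-x0, 0, 0), 1L), "X",
           function(x) {
             u <- (x[1, 1]^2 - x0^2) / x0^2
             e <- height * u^2 + tilt * x[1, 1] +
               k_transverse * (x[1, 2]^2 + x[1, 3]^2) / 2
             g <- matrix(0, 1L, 3L)
             g[1, 1] <- 4 * height * u * x[1, 1] / x0^2 + tilt
             g[1, 2:3] <- k_transverse * x[1, 2:3]
             list(energy = e, gradient = g)
           },
           eval_batch = function(Q) {
             u <- (Q[, 1L]^2 - x0^2) / x0^2
             e <- height * u^2 + tilt * Q[, 1L] +
               k_transverse * (Q[, 2L]^2 + Q[, 3L]^2) / 2
             G <- cbind(4 * height * u * Q[, 1L] / x0^2 + tilt,
                        k_transverse * Q[, 2L], k_transverse * Q[, 3L])
             list(energy = e, gradient = G)
           })
}

#' Morse dimer with damped dispersion tail
#'
#' Two atoms interacting through
#' \eqn{V(r) = D_e(1 - e^{-a(r - r_e)})^2 - D_e - f(r)\,C_6 r^{-6}} with a
#' Fermi damping function \eqn{f(r) = 1/(1 + e^{-(r - r_d)/w_d})} switching
#' the dispersion tail off at short range (the undamped \eqn{-C_6 r^{-6}}
#' diverges as \eqn{r \to 0}). The default parameters describe a weakly
#' anharmonic carbon-like dimer used as the training-data workhorse for the
#' force-field module.
#'
#' @param De well depth, kcal/mol. @param a Morse range parameter, 1/A.
#' @param re equilibrium distance, A. @param C6 dispersion coefficient,
#'   kcal/mol*A^6. @param damp_r0,damp_w Fermi damping midpoint and width, A.
#' @param species two element symbols (default carbon dimer).
#' @return a `model_pes`.
#' @export
morse_dimer_pes <- function(De = 100, a = 2, re = 1.4, C6 = 50,
                            damp_r0 = 1.0, damp_w = 0.15,
                            species = c("C", "C")) {
  mass <- atomic_masses(species)
  x0 <- rbind(c(0, 0, 0), c(re, 0, 0))
  .new_pes("morse_c6",
           list(De = De, a = a, re = re, C6 = C6,
                damp_r0 = damp_r0, damp_w = damp_w),
           2L, mass, x0, species,
           function(x) {
             dr <- x[1, ] - x[2, ]
             r <- sqrt(sum(dr * dr))
             if (r < 1e-10) stop("degenerate geometry: atoms coincide")
             ex <- exp(-a * (r - re))
             f <- 1 / (1 + exp(-(r - damp_r0) / damp_w))
             e <- De * (1 - ex)^2 - De - f * C6 / r^6
             dVdr <- 2 * De * (1 - ex) * a * ex -
               (f * (1 - f) / damp_w) * C6 / r^6 + 6 * f * C6 / r^7
             g1 <- dVdr * dr / r
             list(energy = e, gradient = rbind(g1, -g1))
           },
           eval_batch = function(Q) {
             D <- Q[, 1:3, drop = FALSE] - Q[, 4:6, drop = FALSE]
             r <- sqrt(rowSums(D * D))
             if (any(r < 1e-10)) stop("degenerate geometry: atoms coincide")
             ex <- exp(-a * (r - re))
             f <- 1 / (1 + exp(-(r - damp_r0) / damp_w))
             e <- De * (1 - ex)^2 - De - f * C6 / r^6
             dVdr <- 2 * De * (1 - ex) * a * ex -
               (f * (1 - f) / damp_w) * C6 / r^6 + 6 * f * C6 / r^7
             g1 <- D * (dVdr / r)
             list(energy = e, gradient = cbind(g1, -g1))
           })
}

#' Bond-coupled methyl-rotor model parameters
#'
#' Encodes the mechanism by which ring-bond dilation switches a methyl
#' torsional surface from six-fold to three-fold symmetry: at the reference
#' bond length the rotor sees only a tiny six-fold barrier `V6ref`; dilating
#' the adjacent ring bond by `deltad > 0` grows a three-fold term at rate
#' `V3coupling`, while the bond itself is harmonic with stiffness `kbond`.
#' The neighbouring ring bond shortens quasi-linearly with slope `-s` (used
#' by the synthetic generator to emit the correlated bond pair).
#'
#' Default calibration: `V6ref = 0.024` kcal/mol (the coupled-cluster
#' toluene barrier) and `V3coupling = 25` kcal/mol/A, chosen so that the
#' three-fold barrier the quantum rotor actually experiences -- the
#' ring-polymer average of `V3coupling * max(deltad, 0)` at 300 K, about
#' 0.02 A -- is ~0.5 kcal/mol, i.e. the reported barrier scale comparable
#' to kBT that hinders the rotation. `kbond = 470` kcal/mol/A^2 (aromatic
#' C-C stretch), rotor moment of inertia 3.2 amu*A^2 and bond reduced mass
#' 6 amu.
#'
#' @param V6ref six-fold barrier at reference bond length, kcal/mol.
#' @param V3coupling three-fold amplitude growth rate, kcal/mol/A.
#' @param kbond harmonic bond stiffness, kcal/mol/A^2.
#' @param d0 reference bond length, A.
#' @param s anticorrelation slope of the companion bond (dimensionless).
#' @param inertia rotor moment of inertia, amu*A^2.
#' @param mu_bond bond-stretch reduced mass, amu.
#' @return named list of validated parameters.
#' @export
rotor_params <- function(V6ref = 0.024, V3coupling = 25, kbond = 470,
                         d0 = 1.397, s = 1.0, inertia = 3.2,
                         mu_bond = 6.0) {
  if (V6ref <= 0) stop("V6ref must be positive")
  if (V3coupling < 0 || kbond <= 0 || inertia <= 0 || mu_bond <= 0)
    stop("invalid rotor parameters")
  list(V6ref = V6ref, V3coupling = V3coupling, kbond = kbond, d0 = d0,
       s = s, inertia = inertia, mu_bond = mu_bond)
}

#' Methyl-rotor torsional energy
#'
#' \deqn{V(\theta, \delta d) = \frac{V_6}{2}(1 - \cos 6\theta)
#'  + \frac{V_3 \max(\delta d, 0)}{2}(1 - \cos 3\theta)
#'  + \frac{k}{2}\delta d^2.}
#' At `deltad = 0` the surface is 60-degree periodic with barrier `V6ref`;
#' the barrier is non-decreasing in `deltad` and for
#' `deltad ~ 0.55/V3coupling` the three-fold term dominates.
#'
#' @param theta torsional angle in degrees (radians are used internally).
#' @param deltad bond dilation relative to the reference length, A.
#' @param params a [rotor_params()] list.
#' @return torsional energy in kcal/mol (vectorized over `theta`/`deltad`).
#' @export
rotor_potential <- function(theta, deltad = 0, params = rotor_params()) {
  th <- theta * pi / 180
  a3 <- params$V3coupling * pmax(deltad, 0)
  (params$V6ref / 2) * (1 - cos(6 * th)) + (a3 / 2) * (1 - cos(3 * th)) +
    (params$kbond / 2) * deltad^2
}

#' Dynamical surface for the bond-coupled rotor
#'
#' Embeds [rotor_potential()] in a two-block generalized-coordinate system
#' that the MD/PIMD engine can propagate: block 1 carries the torsional
#' angle in radians (x-component; effective mass = moment of inertia in
#' amu*A^2, so the angle is treated as a length-like coordinate), block 2
#' carries the bond dilation `deltad` in angstrom (mass = bond reduced
#' mass). The four unused components are harmonically restrained spectators.
#'
#' @param params a [rotor_params()] list.
#' @param k_spectator restraint on unused components, kcal/mol/A^2.
#' @return a `model_pes` with `natoms = 2` generalized blocks.
#' @export
rotor_pes <- function(params = rotor_params(), k_spectator = 50) {
  x0 <- matrix(0, 2L, 3L)
  .new_pes("rotor", c(params, list(k_spectator = k_spectator)), 2L,
           c(params$inertia, params$mu_bond), x0, c("Q", "Q"),
           function(x) {
             th <- x[1, 1]; dd <- x[2, 1]
             a3 <- params$V3coupling * max(dd, 0)
             e <- (params$V6ref / 2) * (1 - cos(6 * th)) +
               (a3 / 2) * (1 - cos(3 * th)) +
               (params$kbond / 2) * dd^2 +
               k_spectator * (sum(x[, 2:3]^2)) / 2
             g <- k_spectator * x
             g[1, 1] <- 3 * params$V6ref * sin(6 * th) +
               1.5 * a3 * sin(3 * th)
             g[2, 1] <- (params$V3coupling / 2) * (1 - cos(3 * th)) *
               (dd > 0) + params$kbond * dd
             list(energy = e, gradient = g)
           },
           eval_batch = function(Q) {
             th <- Q[, 1L]; dd <- Q[, 4L]
             a3 <- params$V3coupling * pmax(dd, 0)
             sp <- Q[, c(2L, 3L, 5L, 6L), drop = FALSE]
             e <- (params$V6ref / 2) * (1 - cos(6 * th)) +
               (a3 / 2) * (1 - cos(3 * th)) +
               (params$kbond / 2) * dd^2 + k_spectator * rowSums(sp^2) / 2
             G <- k_spectator * Q
             G[, 1L] <- 3 * params$V6ref * sin(6 * th) +
               1.5 * a3 * sin(3 * th)
             G[, 4L] <- (params$V3coupling / 2) * (1 - cos(3 * th)) *
               (dd > 0) + params$kbond * dd
             list(energy = e, gradient = G)
           })
}

#' Steep power-law attraction toy parameters
#'
#' A one-dimensional stand-in for the donor-acceptor interaction between a
#' lone pair and an antibonding orbital: an exponential repulsive wall plus
#' an \eqn{-A r^{-11}} attraction whose log-log tail slope is exactly -11.
#' The wall amplitude is fixed by requiring a single minimum at `r_eq`.
#'
#' @param A attraction amplitude, kcal/mol*A^11.
#' @param steepness wall exponent, 1/A.
#' @param r_eq equilibrium separation, A.
#' @param dihedral_coupling amplitude in [0, 1) by which a companion
#'   dihedral angle (degrees) modulates the attraction:
#'   \eqn{A_{eff} = A [1 - c(1 - \cos\phi)/2]}.
#' @return named parameter list.
#' @export
npistar_params <- function(A = 1.4e5, steepness = 8, r_eq = 2.9,
                           dihedral_coupling = 0.5) {
  if (A <= 0 || steepness <= 0 || r_eq <= 0) stop("invalid parameters")
  if (dihedral_coupling < 0 || dihedral_coupling >= 1)
    stop("dihedral_coupling must be in [0, 1)")
  B <- 11 * A * r_eq^(-12) / (steepness * exp(-steepness * r_eq))
  list(A = A, steepness = steepness, r_eq = r_eq,
       dihedral_coupling = dihedral_coupling, wall_B = B)
}

#' Donor-acceptor toy interaction energy
#'
#' \eqn{E(r) = B e^{-s r} - A_{eff} r^{-11}}, negative (attractive) in the
#' tail and repulsive inside `r_eq`; on log-log axes the magnitude of the
#' tail decays with slope -11.
#'
#' @param r separation(s) in A; must be positive.
#' @param params an [npistar_params()] list.
#' @param dihedral optional companion dihedral angle, degrees.
#' @return energy in kcal/mol (vectorized over r).
#' @export
npistar_toy_energy <- function(r, params = npistar_params(), dihedral = 0) {
  if (any(r <= 0)) stop("separation must be positive")
  Aeff <- params$A *
    (1 - params$dihedral_coupling * (1 - cos(dihedral * pi / 180)) / 2)
  params$wall_B * exp(-params$steepness * r) - Aeff * r^(-11)
}

#' Dynamical two-atom embedding of the donor-acceptor toy
#'
#' @param params an [npistar_params()] list.
#' @return a `model_pes` with two atoms (O and C) interacting through
#'   [npistar_toy_energy()].
#' @export
npistar_pes <- function(params = npistar_params()) {
  species <- c("O", "C")
  x0 <- rbind(c(0, 0, 0), c(params$r_eq, 0, 0))
  .new_pes("npistar", params, 2L, atomic_masses(species), x0, species,
           function(x) {
             dr <- x[1, ] - x[2, ]
             r <- sqrt(sum(dr * dr))
             if (r < 0.3) stop("separation below the model's domain")
             e <- params$wall_B * exp(-params$steepness * r) -
               params$A * r^(-11)
             dVdr <- -params$steepness * params$wall_B *
               exp(-params$steepness * r) + 11 * params$A * r^(-12)
             g1 <- dVdr * dr / r
             list(energy = e, gradient = rbind(g1, -g1))
           })
}

#' Partial-charge electrostatic toy
#'
#' Models the attraction between a partially negative oxygen and a partially
#' positive hydrogen: \eqn{E(d) = k_C q_O q_H / d + B e^{-s d}}, with a
#' short-range wall keeping the surface bounded below. A geometric map links
#' a companion dihedral (degrees) to the separation:
#' \eqn{d(\phi) = d_{min} + \Delta (1 - \cos\phi)/2}.
#'
#' @param q_O,q_H partial charges, e (opposite signs give attraction).
#' @param d_min closest-approach separation of the geometric map, A.
#' @param d_range separation swing of the geometric map, A.
#' @param wall_B,wall_s repulsive wall amplitude (kcal/mol) and exponent (1/A).
#' @return named parameter list.
#' @export
chargepair_params <- function(q_O = -0.55, q_H = 0.25, d_min = 2.4,
                              d_range = 1.6, wall_B = 4e4, wall_s = 4) {
  list(q_O = q_O, q_H = q_H, d_min = d_min, d_range = d_range,
       wall_B = wall_B, wall_s = wall_s)
}

#' @rdname chargepair_params
#' @param d separation(s), A.
#' @param params a [chargepair_params()] list.
#' @export
chargepair_energy <- function(d, params = chargepair_params()) {
  if (any(d <= 0)) stop("separation must be positive")
  .coulomb_k * params$q_O * params$q_H / d +
    params$wall_B * exp(-params$wall_s * d)
}

#' @rdname chargepair_params
#' @param dihedral dihedral angle(s), degrees.
#' @export
chargepair_distance <- function(dihedral, params = chargepair_params()) {
  params$d_min + params$d_range * (1 - cos(dihedral * pi / 180)) / 2
}

#' @rdname chargepair_params
#' @export
chargepair_pes <- function(params = chargepair_params()) {
  species <- c("O", "H")
  # equilibrium of wall + Coulomb
  x0 <- rbind(c(0, 0, 0), c(params$d_min, 0, 0))
  .new_pes("chargepair", params, 2L, atomic_masses(species), x0, species,
           function(x) {
             dr <- x[1, ] - x[2, ]
             r <- sqrt(sum(dr * dr))
             if (r < 0.3) stop("separation below the model's domain")
             cc <- .coulomb_k * params$q_O * params$q_H
             e <- cc / r + params$wall_B * exp(-params$wall_s * r)
             dVdr <- -cc / r^2 -
               params$wall_s * params$wall_B * exp(-params$wall_s * r)
             g1 <- dVdr * dr / r
             list(energy = e, gradient = rbind(g1, -g1))
           })
}

#' Overlap of two normalized isotropic Gaussians
#'
#' Closed-form overlap integral \eqn{\int \phi_1(x - r)\phi_2(x)\,d^3x} of
#' two L2-normalized isotropic 3-D Gaussians of widths `w1`, `w2` separated
#' by `r`:
#' \deqn{S(r) = \left(\frac{2 w_1 w_2}{w_1^2 + w_2^2}\right)^{3/2}
#'   \exp\!\left(-\frac{r^2}{2(w_1^2 + w_2^2)}\right).}
#' Maximal at `r = 0` and strictly decreasing in `r`; a minimal surrogate
#' for the orbital-overlap origin of steep donor-acceptor attraction.
#'
#' @param r separation(s), A. @param w1,w2 positive Gaussian widths, A.
#' @return overlap value(s).
#' @export
gaussian_overlap <- function(r, w1, w2) {
  if (w1 <= 0 || w2 <= 0) stop("widths must be positive")
  s2 <- w1^2 + w2^2
  (2 * w1 * w2 / s2)^1.5 * exp(-r^2 / (2 * s2))
}

#' Relax a geometry on a model surface
#'
#' Gradient-based minimization (BFGS with the surface's analytic gradient)
#' from the given start. Used to obtain the true reference (0 K) geometry
#' of a surface, which for anharmonic or tail-corrected potentials does not
#' coincide with any single parameter such as a Morse `re`.
#'
#' @param pes a `model_pes`.
#' @param x0 starting coordinates (default the surface's reference).
#' @param maxit iteration cap.
#' @return list with `coordinates` (N x 3), `energy` (kcal/mol) and the
#'   final gradient norm.
#' @export
relax_geometry <- function(pes, x0 = NULL, maxit = 500L) {
  x <- if (is.null(x0)) pes$x0 else x0
  fn <- function(v) evaluate_pes(pes, .unflatten_coords(v))$energy
  gr <- function(v)
    .flatten_coords(evaluate_pes(pes, .unflatten_coords(v))$gradient)
  opt <- stats::optim(.flatten_coords(x), fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  g <- gr(opt$par)
  list(coordinates = .unflatten_coords(opt$par), energy = opt$value,
       gradient_norm = sqrt(sum(g * g)))
}

#' Boltzmann-sample a training set from a model surface
#'
#' Metropolis random-walk sampling of \eqn{\exp(-V/k_B T)} over the
#' surface's coordinates. The proposal width is adapted toward ~40%
#' acceptance during burn-in and then frozen, so the chain is exactly
#' reproducible from `seed`. Every retained record carries the surface's
#' energy and exact forces (negative analytic gradient), which is what the
#' gradient-domain trainer consumes.
#'
#' @param pes a `model_pes`.
#' @param T temperature, K.
#' @param n number of configurations to retain.
#' @param seed integer RNG seed.
#' @param burn_in discarded leading sweeps (default 500).
#' @param thinning keep one sweep in `thinning` (default 5).
#' @param step initial proposal standard deviation, A (adapted; default
#'   derived from the temperature).
#' @param x0 starting coordinates (default the surface's reference geometry).
#' @return a [ff_dataset()] with provenance (generator, seed, temperature,
#'   acceptance rate).
#' @export
sample_training_set <- function(pes, T, n, seed, burn_in = 500L,
                                thinning = 5L, step = NULL, x0 = NULL) {
  stopifnot(inherits(pes, "model_pes"))
  if (T <= 0) stop("temperature must be positive")
  if (n < 1) stop("n must be >= 1")
  kT <- thermal_energy(T)
  x <- if (is.null(x0)) pes$x0 else x0
  if (is.null(step)) step <- 0.1
  .with_seed(seed, {
    e <- evaluate_pes(pes, x)$energy
    nacc <- 0L; nprop <- 0L
    # burn-in with step adaptation every 50 sweeps
    win_acc <- 0L
    for (it in seq_len(burn_in)) {
      prop <- x + matrix(stats::rnorm(length(x), 0, step), nrow(x))
      ep <- tryCatch(evaluate_pes(pes, prop)$energy, error = function(.) Inf)
      if (stats::runif(1) < exp(-(ep - e) / kT)) {
        x <- prop; e <- ep; win_acc <- win_acc + 1L
      }
      if (it %% 50L == 0L) {
        rate <- win_acc / 50
        step <- step * exp(rate - 0.4)   # drift toward ~40% acceptance
        win_acc <- 0L
      }
    }
    configs <- vector("list", n)
    for (i in seq_len(n)) {
      for (s in seq_len(thinning)) {
        prop <- x + matrix(stats::rnorm(length(x), 0, step), nrow(x))
        ep <- tryCatch(evaluate_pes(pes, prop)$energy,
                       error = function(.) Inf)
        nprop <- nprop + 1L
        if (stats::runif(1) < exp(-(ep - e) / kT)) {
          x <- prop; e <- ep; nacc <- nacc + 1L
        }
      }
      ev <- evaluate_pes(pes, x)
      configs[[i]] <- molecular_configuration(pes$species, x,
                                              energy = ev$energy,
                                              forces = -ev$gradient)
    }
    rate <- nacc / nprop
    if (rate < 0.15 || rate > 0.85)
      warning(sprintf(paste0("Metropolis acceptance rate %.2f outside",
                             " [0.15, 0.85]; sampling may be non-ergodic"),
                      rate))
    ff_dataset(configs,
               provenance = list(generator = pes$name, seed = seed,
                                 temperature = T, acceptance = rate,
                                 burn_in = burn_in, thinning = thinning))
  })
}
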