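#' @title Classical and path-integral molecular dynamics
#' @description
#' Langevin dynamics on any model surface or trained force field, with the
#' quantum statistics of the nuclei included through the ring-polymer
#' (path-integral) formalism: each nucleus is represented by P coupled
#' replicas ("beads"); P = 1 reduces exactly to classical Langevin dynamics.
#' Propagation uses an OBABO splitting with a per-normal-mode Langevin
#' thermostat (mode friction 2*omega_k, centroid friction
#' 1/thermostat_time) and the exact free-ring-polymer normal-mode evolution.
#' Internally the bead system is sampled at the ring-polymer temperature
#' P*T with full physical forces and spring frequency omega_P = P/(beta*hbar)
#' (normal-mode frequencies omega_k = 2 omega_P sin(k pi / P)).
#' @name dynamics
NULL

# normal-mode transform: orthonormal P x P matrix C (q_nm = C %*% q_beads)
# and the ring-polymer frequency index k per row
.normal_modes <- function(P) {
  j <- 0:(P - 1L)
  C <- matrix(0, P, P)
  kidx <- numeric(P)
  C[1L, ] <- 1 / sqrt(P)
  row <- 2L
  kmax <- if (P %% 2L == 0L) P %/% 2L - 1L else (P - 1L) %/% 2L
  for (k in seq_len(kmax)) {
    C[row, ] <- sqrt(2 / P) * cos(2 * pi * j * k / P)
    kidx[row] <- k; row <- row + 1L
    C[row, ] <- sqrt(2 / P) * sin(2 * pi * j * k / P)
    kidx[row] <- k; row <- row + 1L
  }
  if (P %% 2L == 0L) {
    C[row, ] <- (-1)^j / sqrt(P)
    kidx[row] <- P / 2
  }
  list(C = C, k = kidx)
}

# wrap a model_pes or forcefield_model as an MD system providing batched
# bead evaluation on a P x n coordinate matrix (atom-major flattening)
.as_system <- function(object, x0 = NULL, masses = NULL) {
  if (inherits(object, "model_pes")) {
    natoms <- object$natoms
    eb <- object$eval_batch
    ev <- object$eval
    batch <- if (!is.null(eb)) eb else function(Q) {
      res <- apply(Q, 1L, function(row) ev(.unflatten_coords(row)),
                   simplify = FALSE)
      list(energy = vapply(res, `[[`, numeric(1), "energy"),
           gradient = do.call(rbind, lapply(res, function(r)
             .flatten_coords(r$gradient))))
    }
    list(natoms = natoms, species = object$species,
         masses = if (is.null(masses)) object$masses else masses,
         x0 = if (is.null(x0)) object$x0 else x0,
         eval_batch = batch, label = object$name)
  } else if (inherits(object, "forcefield_model")) {
    natoms <- length(object$species)
    batch <- function(Q) {
      res <- apply(Q, 1L, function(row) {
        p <- predict(object, .unflatten_coords(row))
        list(energy = p$energy, gradient = -p$forces)
      }, simplify = FALSE)
      list(energy = vapply(res, `[[`, numeric(1), "energy"),
           gradient = do.call(rbind, lapply(res, function(r)
             .flatten_coords(r$gradient))))
    }
    x0d <- if (is.null(x0)) object$training$coords[[1L]] else x0
    list(natoms = natoms, species = object$species,
         masses = if (is.null(masses)) atomic_masses(object$species)
                  else masses,
         x0 = x0d, eval_batch = batch, label = "forcefield")
  } else stop("system must be a model_pes or forcefield_model")
}

#' Initialize a path-integral MD state
#'
#' Beads start at the classical geometry (optionally dressed with the
#' free-ring-polymer thermal spread in the internal modes); momenta are
#' Maxwell-Boltzmann at the ring-polymer temperature (P*T, which for P = 1
#' is the physical temperature).
#'
#' @param system a `model_pes` or `forcefield_model`.
#' @param T temperature, K. @param P bead count (>= 1).
#' @param seed integer RNG seed.
#' @param x0 optional starting geometry (N x 3); defaults to the system's.
#' @param spread if `TRUE`, sample internal ring-polymer modes from their
#'   free-polymer Gaussian.
#' @return object of class `pimd_state`.
#' @export
init_state <- function(system, T, P, seed, x0 = NULL, spread = FALSE) {
  if (!is.numeric(P) || P < 1) stop("bead count P must be >= 1")
  P <- as.integer(P)
  if (T <= 0) stop("temperature must be positive")
  sysm <- .as_system(system, x0 = x0)
  n <- 3L * sysm$natoms
  mdof <- rep(sysm$masses, each = 3L)
  nm <- .normal_modes(P)
  kT_int <- .kB * T * .kcalmol_to_internal
  beta_hbar <- .hbar_kcalmol_fs / (.kB * T)      # fs
  omegaP <- P / beta_hbar
  omega_k <- 2 * omegaP * sin(nm$k * pi / P)
  .with_seed(seed, {
    q <- matrix(rep(.flatten_coords(sysm$x0), each = P), P, n)
    if (spread && P > 1L) {
      qn <- nm$C %*% q
      for (r in which(omega_k > 0)) {
        sd_r <- sqrt(P * kT_int / (mdof * omega_k[r]^2))
        qn[r, ] <- qn[r, ] + stats::rnorm(n, 0, sd_r)
      }
      q <- crossprod(nm$C, qn)
    }
    p <- matrix(stats::rnorm(P * n), P, n) *
      rep(sqrt(mdof * kT_int * P), each = P)
    structure(list(q = q, p = p, masses = sysm$masses, mdof = mdof,
                   T = T, P = P, nm = nm, omega_k = omega_k,
                   omegaP = omegaP, natoms = sysm$natoms,
                   species = sysm$species, seed = seed),
              class = "pimd_state")
  })
}

#' @export
print.pimd_state <- function(x, ...) {
  cat(sprintf("PIMD state: P = %d beads, %d atoms, T = %g K\n",
              x$P, x$natoms, x$T))
  invisible(x)
}

#' Centroid (bead-averaged) coordinates of a state
#' @param state a `pimd_state`.
#' @return N x 3 matrix.
#' @export
centroid <- function(state) .unflatten_coords(colMeans(state$q))

# one OBABO step; internals shared with run_trajectory's inline loop
.obabo_coeffs <- function(state, dt, thermostat_time, thermostat) {
  gamma <- 2 * state$omega_k
  gamma[state$omega_k == 0] <-
    if (thermostat && is.finite(thermostat_time) && thermostat_time > 0)
      1 / thermostat_time else 0
  if (!thermostat) gamma[] <- 0
  c1 <- exp(-gamma * dt / 2)
  kT_int <- .kB * state$T * .kcalmol_to_internal
  sd_base <- sqrt(state$mdof * kT_int * state$P)   # per dof
  list(c1 = c1, c2 = sqrt(1 - c1^2), sd_base = sd_base)
}

#' Advance a PIMD state by one OBABO step
#'
#' Half Langevin (normal modes), half momentum kick with the physical
#' forces, exact free-ring-polymer evolution for `dt`, second kick, second
#' Langevin half. With `P = 1` and the thermostat off this is exactly
#' velocity Verlet on the physical surface.
#'
#' @param state a `pimd_state`. @param system the surface or model to
#'   propagate on. @param dt time step, fs. @param thermostat_time centroid
#'   thermostat time constant, fs (`Inf` disables centroid friction).
#' @param thermostat logical; `FALSE` disables all friction/noise (NVE).
#' @return the advanced `pimd_state`.
#' @export
pimd_step <- function(state, system, dt, thermostat_time = 100,
                      thermostat = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  sysm <- .as_system(system)
  co <- .obabo_coeffs(state, dt, thermostat_time, thermostat)
  st <- .pimd_steps(state, sysm, dt, co, nsteps = 1L, stride = 1L,
                    record = FALSE)
  st$state
}

# core propagation loop; records estimator rows every `stride` steps
.pimd_steps <- function(state, sysm, dt, co, nsteps, stride,
                        record = TRUE, store_beads = FALSE) {
  P <- state$P; n <- ncol(state$q)
  C <- state$nm$C
  omega <- state$omega_k
  mdof <- state$mdof
  conv <- .kcalmol_to_internal
  q <- state$q; p <- state$p
  osc <- omega > 0
  coswt <- cos(omega * dt); sinwt <- sin(omega * dt)
  mw <- outer(omega, mdof)                 # P x n, m*omega per mode row
  kT <- .kB * state$T                       # kcal/mol
  nrec <- if (record) nsteps %/% stride + 1L else 0L
  est <- if (record)
    matrix(NA_real_, nrec, 6L,
           dimnames = list(NULL, c("time", "potential", "spring",
                                   "kin_prim", "kin_vir", "kin_cl")))
    else NULL
  cent <- if (record) matrix(NA_real_, nrec, n) else NULL
  beads <- if (record && store_beads) array(NA_real_, c(nrec, P, n)) else NULL

  ev <- sysm$eval_batch(q)
  G <- ev$gradient                          # kcal/mol/A
  status <- "ok"
  rec_row <- 0L
  record_frame <- function(step) {
    rec_row <<- rec_row + 1L
    qc <- colMeans(q)
    dq <- sweep(q, 2L, qc)
    # estimator spring term (m omega_P^2 / (2P)) sum (q_j - q_{j+1})^2:
    # the beta-convention spring frequency is omega_P/sqrt(P), computed in
    # internal units (amu A^2 fs^-2) then converted to kcal/mol
    spring_kcal <- if (P > 1L) {
      dd <- q - q[c(2:P, 1L), , drop = FALSE]
      (0.5 * state$omegaP^2 / P *
         sum(sweep(dd * dd, 2L, mdof, `*`))) / conv
    } else 0
    est[rec_row, ] <<- c(step * dt,
                         mean(ev$energy),
                         spring_kcal,
                         n * P * kT / 2 - spring_kcal,
                         n * kT / 2 + sum(dq * G) / (2 * P),
                         sum(sweep(p * p, 2L, mdof, `/`)) / (2 * P * conv))
    cent[rec_row, ] <<- qc
    if (!is.null(beads)) beads[rec_row, , ] <<- q
  }
  if (record) record_frame(0L)

  for (step in seq_len(nsteps)) {
    # O: half thermostat in normal modes
    if (any(co$c1 < 1)) {
      pn <- C %*% p
      noise <- matrix(stats::rnorm(P * n), P, n)
      pn <- pn * co$c1 + noise * co$c2 *
        rep(co$sd_base, each = P)
      p <- crossprod(C, pn)
    }
    # B: half kick (convert forces to internal units)
    p <- p - (dt / 2) * G * conv
    # A: exact free-ring-polymer evolution in normal modes
    qn <- C %*% q; pn <- C %*% p
    if (any(!osc)) {
      r0 <- which(!osc)
      qn[r0, ] <- qn[r0, ] + dt * sweep(pn[r0, , drop = FALSE], 2L, mdof,
                                        `/`)
    }
    if (any(osc)) {
      ro <- which(osc)
      qo <- qn[ro, , drop = FALSE]; po <- pn[ro, , drop = FALSE]
      mwo <- mw[ro, , drop = FALSE]
      qn[ro, ] <- qo * coswt[ro] + (po / mwo) * sinwt[ro]
      pn[ro, ] <- po * coswt[ro] - qo * mwo * sinwt[ro]
    }
    q <- crossprod(C, qn); p <- crossprod(C, pn)
    # B: second half kick
    ev <- sysm$eval_batch(q)
    G <- ev$gradient
    if (!all(is.finite(G)) || !all(is.finite(ev$energy))) {
      dump <- tempfile(paste0("nqemd-abort-", sysm$label, "-"),
                       fileext = ".xyz")
      utils::write.table(q, dump, row.names = FALSE, col.names = FALSE)
      status <- "nan_abort"
      warning(sprintf(paste0("non-finite forces/energy at step %d;",
                             " propagation aborted, bead frame dumped to",
                             " %s"), step, dump))
      break
    }
    p <- p - (dt / 2) * G * conv
    # O: second half thermostat
    if (any(co$c1 < 1)) {
      pn <- C %*% p
      noise <- matrix(stats::rnorm(P * n), P, n)
      pn <- pn * co$c1 + noise * co$c2 * rep(co$sd_base, each = P)
      p <- crossprod(C, pn)
    }
    if (record && step %% stride == 0L) record_frame(step)
  }
  state$q <- q; state$p <- p
  list(state = state, status = status,
       est = if (record) as.data.frame(est[seq_len(rec_row), , drop = FALSE])
             else NULL,
       cent = if (record) cent[seq_len(rec_row), , drop = FALSE] else NULL,
       beads = if (!is.null(beads)) beads[seq_len(rec_row), , ,
                                          drop = FALSE] else NULL)
}

#' Run a (PI)MD trajectory
#'
#' Thermostatted OBABO propagation with estimator records every `stride`
#' steps. Defaults follow the package's standard protocol: time step 0.2 fs
#' at 300 K. `steps = 0` yields a single-frame trajectory of the initial
#' state. If the surface returns non-finite energies mid-run, the
#' trajectory is truncated and returned with `status = "nan_abort"` (with a
#' warning naming a diagnostic bead dump).
#'
#' @param system a `model_pes` or `forcefield_model`.
#' @param steps number of integration steps.
#' @param dt time step, fs. @param T temperature, K. @param P bead count.
#' @param seed master RNG seed (initialization and thermostat streams are
#'   derived from it and recorded in the provenance).
#' @param stride store one frame every `stride` steps.
#' @param thermostat_time centroid thermostat constant, fs.
#' @param thermostat logical; `FALSE` runs NVE.
#' @param x0 optional starting geometry. @param spread passed to
#'   [init_state()]. @param store_beads keep bead-resolved frames.
#' @return object of class `nqe_trajectory` with fields `times`, `centroid`
#'   (frames x N x 3), optional `beads`, `est` (estimator data.frame with
#'   potential, spring, primitive and centroid-virial kinetic energies in
#'   kcal/mol), `status`, and full provenance.
#' @export
run_trajectory <- function(system, steps, dt = 0.2, T = 300, P = 1,
                           seed = 1, stride = 10, thermostat_time = 100,
                           thermostat = TRUE, x0 = NULL, spread = P > 1,
                           store_beads = FALSE) {
  if (dt <= 0) stop("dt must be positive")
  if (steps < 0) stop("steps must be >= 0")
  sysm <- .as_system(system, x0 = x0)
  init_seed <- seed
  prop_seed <- (as.numeric(seed) + 1013904223) %% 2147483647
  state <- init_state(system, T, P, init_seed, x0 = x0, spread = spread)
  co <- .obabo_coeffs(state, dt, thermostat_time, thermostat)
  out <- .with_seed(prop_seed,
                    .pimd_steps(state, sysm, dt, co, nsteps = as.integer(steps),
                                stride = as.integer(stride), record = TRUE,
                                store_beads = store_beads))
  nfr <- nrow(out$est)
  cent_arr <- array(NA_real_, c(nfr, sysm$natoms, 3L))
  for (k in 1:3)
    cent_arr[, , k] <- out$cent[, seq(k, by = 3L,
                                      length.out = sysm$natoms),
                                drop = FALSE]
  structure(list(
    dt = dt, stride = stride, T = T, P = P,
    times = out$est$time,
    centroid = cent_arr,
    beads = out$beads,
    est = out$est,
    species = sysm$species, masses = sysm$masses,
    seed = seed, status = out$status,
    state = out$state,
    provenance = list(system = sysm$label, dt = dt, steps = steps, T = T,
                      P = P, stride = stride, seed = seed,
                      init_seed = init_seed, prop_seed = prop_seed,
                      thermostat_time = thermostat_time,
                      thermostat = thermostat)),
    class = "nqe_trajectory")
}

#' @export
print.nqe_trajectory <- function(x, ...) {
  cat(sprintf(paste0("Trajectory: %d frames (dt = %g fs, stride = %d),",
                     " P = %d, T = %g K, status = %s\n"),
              length(x$times), x$dt, x$stride, x$P, x$T, x$status))
  invisible(x)
}

# centroid coordinates of frame i as N x 3
.traj_frame <- function(traj, i)
  matrix(traj$centroid[i, , ], ncol = 3L)

#' Quantum kinetic-energy estimators from a trajectory
#'
#' Averages the primitive estimator
#' \eqn{3NP/(2\beta) - \langle E_{spring}\rangle} and the centroid-virial
#' estimator \eqn{3N/(2\beta) + \langle \sum_j (q_j - \bar q)\cdot
#' \nabla V(q_j)\rangle / (2P)} over the recorded frames, with block-average
#' standard errors. For P = 1 both reduce to classical equipartition
#' (3N/2) kT.
#'
#' @param traj an `nqe_trajectory`.
#' @param discard_fraction leading fraction of frames dropped as
#'   equilibration (default 0.2).
#' @param nblocks number of blocks for the standard error (default 20).
#' @return list with `primitive`, `virial`, `potential`, `total_primitive`,
#'   `total_virial`, each a `c(mean, se)` pair (kcal/mol), plus `nframes`.
#' @export
kinetic_estimators <- function(traj, discard_fraction = 0.2, nblocks = 20) {
  stopifnot(inherits(traj, "nqe_trajectory"))
  est <- traj$est
  if (!nrow(est)) stop("trajectory carries no estimator records")
  keep <- est[seq(from = max(1L, floor(discard_fraction * nrow(est)) + 1L),
                  to = nrow(est)), , drop = FALSE]
  bstat <- function(v) {
    nb <- min(nblocks, max(2L, length(v) %/% 5L))
    blocks <- tapply(v, cut(seq_along(v), nb, labels = FALSE), mean)
    c(mean = mean(v), se = stats::sd(blocks) / sqrt(length(blocks)))
  }
  prim <- bstat(keep$kin_prim)
  vir <- bstat(keep$kin_vir)
  pot <- bstat(keep$potential)
  tot_p <- bstat(keep$kin_prim + keep$potential)
  tot_v <- bstat(keep$kin_vir + keep$potential)
  list(primitive = prim, virial = vir, potential = pot,
       total_primitive = tot_p, total_virial = tot_v,
       nframes = nrow(keep))
}

#' Exact quantum harmonic-oscillator thermal energy
#'
#' \eqn{E = (\hbar\omega/2)\coth(\beta\hbar\omega/2)} per degree of
#' freedom: the closed form that converged PIMD total energies must
#' approach as the bead number grows.
#'
#' @param omega angular frequency, 1/fs. @param T temperature, K.
#' @return energy per degree of freedom, kcal/mol.
#' @export
qho_energy <- function(omega, T) {
  x <- .hbar_kcalmol_fs * omega / (2 * .kB * T)
  (.hbar_kcalmol_fs * omega / 2) / tanh(x)
}

#' Bead-convergence ramp
#'
#' Runs the standard incremental-bead protocol P in {1, 4, 8, 16, 32} and
#' reports the centroid-virial total energy per P; convergence is declared
#' when successive values change by less than `tol` (relative).
#'
#' @param system surface or model. @param P_values bead counts to ramp.
#' @param tol relative convergence tolerance (default 0.01).
#' @param ... passed to [run_trajectory()].
#' @return data.frame with P, total virial energy, its SE, and a
#'   `converged_P` attribute (NA if never within tolerance).
#' @export
bead_ramp <- function(system, P_values = c(1L, 4L, 8L, 16L, 32L),
                      tol = 0.01, ...) {
  res <- lapply(P_values, function(P) {
    traj <- run_trajectory(system, P = P, ...)
    ke <- kinetic_estimators(traj)
    c(P = P, energy = unname(ke$total_virial["mean"]),
      se = unname(ke$total_virial["se"]))
  })
  df <- as.data.frame(do.call(rbind, res))
  conv <- NA_integer_
  if (nrow(df) > 1L) {
    rel <- abs(diff(df$energy)) / pmax(abs(df$energy[-1L]), 1e-12)
    hit <- which(rel < tol)
    if (length(hit)) conv <- df$P[hit[1L] + 1L]
  }
  attr(df, "converged_P") <- conv
  df
}
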