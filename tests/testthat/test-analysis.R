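test_that("dihedral angles follow the IUPAC convention", {
  trans <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))
  expect_equal(dihedral_angle(trans, 1, 2, 3, 4), 180)
  cis <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(dihedral_angle(cis, 1, 2, 3, 4), 0)
  # right-handed quarter twist; oracle: the atan2 cross-product formula
  # evaluated by hand gives +90 (b1=(-1,0,0), b2=(0,1,0), b3=(0,0,1);
  # n1=(0,0,-1)x? -> atan2(|b2| b1.(b2 x b3), (b1 x b2).(b2 x b3)) = +90)
  twist <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))
  expect_equal(dihedral_angle(twist, 1, 2, 3, 4), 90)
  expect_equal(dihedral_angle(twist, 4, 3, 2, 1), 90)  # reversal symmetry
  expect_equal(dihedral_angle(twist[c(4, 2, 3, 1), ], 1, 2, 3, 4), -90)
  coll <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(dihedral_angle(coll, 1, 2, 3, 4), "collinear")
  expect_error(dihedral_angle(trans, 1, 2, 2, 4), "distinct")
})

test_that("free-energy surfaces invert Boltzmann statistics", {
  kT <- thermal_energy(300)
  # two-state occupancy p1/p2 gives dF = -kT log(p1/p2) exactly
  s <- c(rep(0.5, 300), rep(1.5, 100))
  fes <- free_energy_surface(s, bins = list(c(0, 1, 2)), T = 300)
  expect_equal(fes$F[2] - fes$F[1], -kT * log(100 / 300))
  expect_equal(min(fes$F, na.rm = TRUE), 0)
  expect_equal(sum(fes$counts), 400)

  # flat density -> F ~ 0 everywhere within sampling noise
  set.seed(8)
  u <- runif(200000)
  fesu <- free_energy_surface(u, bins = 10, T = 300)
  expect_lt(max(fesu$F), 0.02)

  # empty bins are masked, never zero-filled
  fes2 <- free_energy_surface(c(0.1, 0.9), bins = list(c(0, 0.25, 0.5, 1)),
                              T = 300)
  expect_true(is.na(fes2$F[2]))
  expect_equal(fes2$F[c(1, 3)], c(0, 0))

  # 2-D surfaces carry their axes
  xy <- cbind(rnorm(5000), rnorm(5000))
  f2 <- free_energy_surface(xy, bins = 12, T = 250)
  expect_equal(dim(f2$F), c(12L, 12L))
  expect_equal(sum(f2$counts), 5000)

  # all-identical samples occupy a single bin at F = 0
  f1 <- free_energy_surface(rep(2.5, 10), bins = 5, T = 300)
  expect_equal(sum(f1$counts > 0), 1L)
  expect_equal(f1$F[f1$counts > 0], 0)
  expect_error(free_energy_surface(numeric(0)), "sample")
})

test_that("adding uniform counts shifts the surface by a bin-independent
          constant only", {
  set.seed(9)
  s <- rnorm(20000)
  edges <- list(seq(-3, 3, length.out = 21))
  f1 <- free_energy_surface(s, bins = edges, T = 300)
  extra <- rep(f1$midpoints[[1]], each = 50)   # 50 samples per bin
  f2 <- free_energy_surface(c(s, extra), bins = edges, T = 300)
  occ <- which(f1$counts > 0)
  shift <- -thermal_energy(300) *
    log((f1$counts[occ] + 50) / sum(f1$counts + 50)) -
    (-thermal_energy(300) * log(f1$counts[occ] / sum(f1$counts)))
  # the realized F differences between the two surfaces vary across bins
  # exactly as the count transformation predicts, i.e. F2 equals the
  # recomputed Boltzmann inversion of the shifted counts
  rho2 <- (f1$counts + 50) / sum(f1$counts + 50)
  expected <- -thermal_energy(300) * log(rho2 / max(rho2))
  expect_equal(as.vector(f2$F), as.vector(expected))
})

test_that("time-angle histograms use the 5 ps x 6 degree grid and conserve
          frame counts", {
  n <- 4000; dt <- 10                     # 40 ps at 10 fs frames
  const <- rep(33, n)
  h <- time_angle_histogram(const, dt)
  expect_equal(diff(h$angle_edges)[1], 6)
  expect_equal(diff(h$time_edges)[1], 5)
  expect_equal(sum(rowSums(h$counts) > 0), 1L)
  # column sums equal the frames per 5 ps window
  expect_true(all(colSums(h$counts)[1:8] == 500))
  # uniform rotation covers the angle bins nearly uniformly per column
  rot <- nqemd:::.wrap_angle((1:n) * 0.77)
  h2 <- time_angle_histogram(rot, dt)
  expect_gt(min(rowSums(h2$counts)), 0)
  expect_error(time_angle_histogram(c(1, NA, 3), 10), "NA")
})

test_that("localized-state detection finds constructed dwells with closed
          boundary semantics", {
  dt <- 10                                 # fs per frame
  free <- seq(0, 360 * 20, by = 2.5)       # fast free rotation
  none <- detect_localized_states(free, dt, wells = c(-120, 0, 120),
                                  min_duration = 1000)
  expect_equal(attr(none, "count"), 0L)

  # a 4 ps dwell at the 120-degree well embedded in free rotation
  dwell <- c(free[1:500], rep(121, 400), free[501:1000])
  rec <- detect_localized_states(dwell, dt, wells = c(-120, 0, 120),
                                 min_duration = 1000)
  expect_equal(attr(rec, "count"), 1L)
  expect_equal(rec$well, 3L)
  expect_equal(rec$duration, (400 - 1) * dt * 1e-3)  # ~4 ps
  expect_equal(rec$mean_angle, 121)

  # dwell one frame shorter than min_duration -> no record (closed
  # interval); guard frames sit at the 60-degree transition state, outside
  # every capture window
  exact_len <- 101L                        # (101-1)*10 fs = 1000 fs exactly
  guard <- rep(60, 50)
  ok <- c(guard, rep(0, exact_len), guard)
  short <- c(guard, rep(0, exact_len - 1L), guard)
  expect_equal(attr(detect_localized_states(ok, dt, min_duration = 1000),
                    "count"), 1L)
  expect_equal(attr(detect_localized_states(short, dt, min_duration = 1000),
                    "count"), 0L)
  expect_error(detect_localized_states(free, dt, wells = numeric(0)),
               "non-empty")
  # wrapped-angle bookkeeping: a dwell straddling the -180/180 seam
  seam <- c(free[1:300], rep(c(-179, 179), 100), free[301:600])
  recs <- detect_localized_states(seam, dt, wells = c(180),
                                  min_duration = 1000)
  expect_equal(attr(recs, "count"), 1L)
})

test_that("power-law fits are exact on noiseless data for any exponent and
          robust to multiplicative noise", {
  r <- seq(4, 10, length.out = 50)
  for (n_true in c(1, 3, 6, 11, 20)) {
    f <- fit_power_law(r, -7 * r^(-n_true), r_min = 3.8)
    expect_equal(f$n, n_true, tolerance = 1e-10)
    expect_equal(f$A, 7, tolerance = 1e-9)
  }
  # 5% multiplicative noise, 200 replicates: median exponent within 0.3
  set.seed(14)
  nhat <- replicate(200, {
    E <- -5 * r^(-11) * exp(rnorm(length(r), 0, 0.05))
    fit_power_law(r, E)$n
  })
  expect_lt(abs(median(nhat) - 11), 0.3)
  # sign changes inside the window are refused with advice
  bad <- -5 * r^(-11); bad[25] <- abs(bad[25])
  expect_error(fit_power_law(r, bad), "sign")
  expect_error(fit_power_law(r[1:2], bad[1:2]), "3 points")
  # points left of r_min are excluded from the fit
  rr <- c(1, 2, r); EE <- c(5, 1, -5 * r^(-11))
  expect_equal(fit_power_law(rr, EE)$n, 11, tolerance = 1e-10)
})

test_that("Casimir-Polder quadrature matches the London closed forms over a
          parameter sweep", {
  set.seed(6)
  worst <- 0
  for (i in 1:100) {
    a0 <- runif(2, 0.5, 20); w0 <- runif(2, 0.01, 0.4)
    A <- drude_oscillator(a0[1], w0[1])
    B <- drude_oscillator(a0[2], w0[2])
    c6 <- casimir_polder_c6(A, B)
    london <- 1.5 * a0[1] * a0[2] * hbar_ref * w0[1] * w0[2] /
      (w0[1] + w0[2])
    worst <- max(worst, abs(c6 - london) / london)
  }
  expect_lt(worst, 1e-6)
  # identical oscillators: C6 = (3/4) hbar w0 alpha0^2
  A <- drude_oscillator(10.3, 0.08)
  expect_equal(casimir_polder_c6(A, A), 0.75 * hbar_ref * 0.08 * 10.3^2,
               tolerance = 1e-8)
  # symmetry
  B <- drude_oscillator(3.1, 0.21)
  expect_equal(casimir_polder_c6(A, B), casimir_polder_c6(B, A))
  expect_error(drude_oscillator(-1, 0.1), "positive")
})

test_that("the R^-6 dispersion energy scales and signs correctly", {
  expect_equal(vdw_energy(100, 4) / vdw_energy(100, 2), 2^-6)
  expect_equal(vdw_energy(200, 3), 2 * vdw_energy(100, 3))
  expect_true(all(vdw_energy(5, c(1, 2, 10)) < 0))
  expect_error(vdw_energy(5, 0), "positive")
})

test_that("polarizability increments follow the R^7 law: zero at identity,
          (s^7 - 1) under dilation, positive under symmetric fluctuation", {
  set.seed(21)
  ref <- molecular_configuration(c("C", "C", "H"),
                                 rbind(c(0, 0, 0), c(1.4, 0, 0),
                                       c(2.2, 0.9, 0)))
  ens_same <- rep(list(ref), 20)
  expect_equal(ensemble_polarizability_increment(ens_same, ref), 0)
  s <- 1.03
  ens_dil <- lapply(1:20, function(i)
    molecular_configuration(ref$species, ref$coordinates * s))
  # uniform dilation scales the gyration radius by s; with the additive
  # shell the radius scales less than s, so the increment is bounded by
  # 100 (s^7 - 1) and must still be positive
  inc <- ensemble_polarizability_increment(ens_dil, ref)
  expect_gt(inc, 0)
  expect_lt(inc, 100 * (s^7 - 1))
  # pure radii interface: exact scaling law
  expect_equal(ensemble_polarizability_increment(rep(2 * s, 5), 2),
               100 * (s^7 - 1), tolerance = 1e-10)
  # symmetric radius fluctuations: convexity of R^7 gives a positive
  # increment matching a direct Monte-Carlo average
  rr <- 3 + rnorm(5000, 0, 0.1)
  inc_mc <- 100 * (mean(rr^7) / 3^7 - 1)
  expect_equal(ensemble_polarizability_increment(rr, 3), inc_mc)
  expect_gt(inc_mc, 0)
  expect_error(ensemble_polarizability_increment(rr, 0), "positive")
})

test_that("ensemble interaction scans average pair energies with standard
          errors and honor the pairing mode", {
  pot <- make_dispersion_pair_potential(omega0 = 0.05, alpha_scale = 0.01)
  Rg <- c(5, 6, 8)
  # degenerate ensembles reproduce the single-geometry curve with zero SE
  ensA <- rep(list(3.0), 10); ensB <- rep(list(3.2), 10)
  sc <- ensemble_interaction_scan(ensA, ensB, pot, Rg)
  expect_equal(sc$mean, vapply(Rg, function(R) pot(R, 3.0, 3.2),
                               numeric(1)))
  expect_equal(sc$se, rep(0, 3))
  # dilated (quantum-like) ensemble is pointwise more attractive
  set.seed(3)
  base <- as.list(3 + abs(rnorm(50, 0, 0.05)))
  dil <- lapply(base, function(r) r * 1.02)
  s0 <- ensemble_interaction_scan(base, base, pot, Rg)
  s1 <- ensemble_interaction_scan(dil, dil, pot, Rg)
  expect_true(all(s1$mean < s0$mean))
  # SE shrinks with ensemble size at fixed distribution
  small <- ensemble_interaction_scan(base[1:10], base[1:10], pot, 6)
  big <- ensemble_interaction_scan(base, base, pot, 6)
  expect_lt(big$se, small$se)
  # cross pairing uses all pairs; zip demands equal lengths
  cr <- ensemble_interaction_scan(base[1:4], base[1:5], pot, 6,
                                  pairing = "cross")
  expect_equal(cr$n, 20L)
  expect_error(ensemble_interaction_scan(base[1:4], base[1:5], pot, 6),
               "equal length")
})

test_that("quantum delocalization flattens the double-well free-energy
          barrier relative to matched classical sampling", {
  dw <- double_well_pes(height = 1.0, x0 = 0.7, mass = 1)
  barrier <- function(traj) {
    x <- traj$centroid[-(1:2000), 1, 1]
    fes <- free_energy_surface(x, bins = list(seq(-1.5, 1.5, by = 0.1)),
                               T = 300)
    max(fes$F[abs(fes$midpoints[[1]]) < 0.2], na.rm = TRUE)
  }
  cl <- run_trajectory(dw, steps = 500000, dt = 0.4, T = 300, P = 1,
                       seed = 7, stride = 10, thermostat_time = 50)
  qm <- run_trajectory(dw, steps = 500000, dt = 0.4, T = 300, P = 16,
                       seed = 8, stride = 10, thermostat_time = 50)
  # reference values from the seeded pair: classical ~1.05, quantum ~0.98
  expect_lt(barrier(qm), barrier(cl))
  expect_equal(barrier(cl), 1.05, tolerance = 0.1)
})

test_that("angle unwrapping removes 360-degree jumps by shortest path", {
  a <- c(170, 179, -179, -170, -179, 179)
  u <- unwrap_angles(a)
  expect_equal(diff(u), c(9, 2, 9, -9, -2))
  expect_equal(nqemd:::.wrap_angle(u), a)
})
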