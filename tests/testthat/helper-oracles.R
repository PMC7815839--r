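# shared fixtures and independent oracles used across test files

kB_ref <- 0.001987204259                     # kcal/mol/K
hbar_ref <- 1.054571817e-34 * 6.02214076e23 / 4184 * 1e15  # kcal/mol*fs

# central finite-difference gradient of f at N x 3 coords
fd_gradient <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (a in seq_len(nrow(x))) for (k in 1:3) {
    xp <- x; xp[a, k] <- xp[a, k] + h
    xm <- x; xm[a, k] <- xm[a, k] - h
    g[a, k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# analytic stationary bead covariance (per dof) of a ring polymer in a
# harmonic well: normal-mode Gaussian integrals mapped back to bead space
rp_covariance_analytic <- function(omega0, mass, T, P) {
  nm <- nqemd:::.normal_modes(P)
  beta_hbar <- hbar_ref / (kB_ref * T)
  omegaP <- P / beta_hbar
  omk <- 2 * omegaP * sin(nm$k * pi / P)
  kT_int <- kB_ref * T * 4.184e-4
  covnm <- P * kT_int / (mass * (omk^2 + omega0^2))
  t(nm$C) %*% diag(covnm, P) %*% nm$C
}

# fraction of angle samples within +/-30 degrees of the three-fold minima
threefold_fraction <- function(ang) {
  d <- pmin(abs(nqemd:::.wrap_angle(ang)),
            abs(nqemd:::.wrap_angle(ang - 120)),
            abs(nqemd:::.wrap_angle(ang + 120)))
  mean(d <= 30)
}

# small Boltzmann-sampled Morse-dimer dataset shared by force-field tests
morse_train_test <- function(n_train = 40, n_test = 20, seed = 42) {
  ds <- sample_training_set(morse_dimer_pes(), T = 300,
                            n = n_train + n_test, seed = seed)
  list(train = ff_dataset(ds$configurations[seq_len(n_train)]),
       test = ds$configurations[n_train + seq_len(n_test)])
}
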