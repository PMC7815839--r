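test_that("inverse-distance descriptor matches its definition and symmetries", {
  # two atoms 2 A apart -> single entry 1/r = 0.5
  x <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(compute_descriptor(x)$d, 0.5)

  set.seed(1)
  y <- matrix(rnorm(12), 4, 3)
  d0 <- compute_descriptor(y)
  # rigid translation leaves the descriptor unchanged
  expect_equal(compute_descriptor(sweep(y, 2, c(3, -1, 7), `+`))$d, d0$d)
  # rigid rotation too
  th <- 0.63
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(compute_descriptor(y %*% R)$d, d0$d, tolerance = 1e-12)

  # swapping two atoms permutes pair entries exactly as brute-force
  # re-enumeration of all pairs predicts
  p <- c(2L, 1L, 3L, 4L)
  dp <- compute_descriptor(y[p, ])$d
  pairs <- combn(4, 2)
  brute <- apply(pairs, 2, function(ab)
    1 / sqrt(sum((y[p[ab[1]], ] - y[p[ab[2]], ])^2)))
  expect_equal(dp, brute)

  # coincident atoms are a degenerate geometry naming the pair
  z <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_error(compute_descriptor(z), "atoms 1 and 2 coincide")
  expect_error(compute_descriptor(matrix(0, 1, 3)), "at least two atoms")
})

test_that("descriptor Jacobian matches central finite differences", {
  set.seed(7)
  x <- matrix(rnorm(9), 3, 3)
  d0 <- compute_descriptor(x)
  h <- 1e-6
  for (a in 1:3) for (k in 1:3) {
    xp <- x; xp[a, k] <- xp[a, k] + h
    xm <- x; xm[a, k] <- xm[a, k] - h
    fd <- (compute_descriptor(xp, jacobian = FALSE)$d -
             compute_descriptor(xm, jacobian = FALSE)$d) / (2 * h)
    expect_equal(d0$J[, 3 * (a - 1) + k], fd, tolerance = 1e-6)
  }
})

test_that("Matern 5/2 kernel has unit normalization, decay and closed form", {
  expect_identical(matern52_kernel(0, 1.7), 1)
  # strict monotone decay to zero
  d <- seq(0, 40, by = 0.25)
  k <- matern52_kernel(d, 2)
  expect_true(all(diff(k) < 0))
  expect_lt(k[length(k)], 1e-8)
  # plug-in value at d = sigma
  expect_equal(matern52_kernel(3, 3),
               (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)))
  expect_error(matern52_kernel(1, 0), "sigma")
  expect_error(matern52_kernel(-1, 1), "non-negative")
})

test_that("assembled train matrix equals nested finite differences of the
          symmetrized kernel", {
  set.seed(4)
  coords <- list(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3) + 1)
  perms <- list(1:3, c(2L, 1L, 3L))
  sigma <- 3
  K <- nqemd:::.assemble_kernel_matrix(coords, sigma, perms)
  ksym <- function(x, y) {
    mean(vapply(perms, function(p) {
      u <- compute_descriptor(x[p, ], jacobian = FALSE)$d -
        compute_descriptor(y, jacobian = FALSE)$d
      matern52_kernel(sqrt(sum(u^2)), sigma)
    }, numeric(1)))
  }
  h <- 1e-4
  pert <- function(m, c, s) {
    mm <- m
    mm[ceiling(c / 3), ((c - 1) %% 3) + 1] <-
      mm[ceiling(c / 3), ((c - 1) %% 3) + 1] + s * h
    mm
  }
  Kfd <- matrix(0, 18, 18)
  for (i in 1:2) for (a in 1:9) for (j in 1:2) for (b in 1:9) {
    xi <- coords[[i]]; xj <- coords[[j]]
    Kfd[(i - 1) * 9 + a, (j - 1) * 9 + b] <-
      (ksym(pert(xi, a, 1), pert(xj, b, 1)) -
         ksym(pert(xi, a, 1), pert(xj, b, -1)) -
         ksym(pert(xi, a, -1), pert(xj, b, 1)) +
         ksym(pert(xi, a, -1), pert(xj, b, -1))) / (4 * h * h)
  }
  expect_lt(max(abs(K - Kfd)) / max(abs(K)), 1e-4)
})

test_that("training interpolates forces and energies at training points", {
  pes <- morse_dimer_pes()
  ds <- sample_training_set(pes, T = 300, n = 1, seed = 5)
  m <- train_forcefield(ds, sigma = 5, lambda = 1e-10)
  p <- predict(m, ds$configurations[[1]])
  expect_lt(max(abs(p$forces - ds$configurations[[1]]$forces)), 1e-6)
  # energy offset puts the training energy back exactly for M = 1
  expect_lt(abs(p$energy - ds$configurations[[1]]$energy), 1e-8)
})

test_that("training coefficients equal a hand-assembled dense-system solve", {
  mt <- morse_train_test(n_train = 2, n_test = 0, seed = 9)
  ds <- mt$train
  sigma <- 4; lambda <- 1e-8
  m <- train_forcefield(ds, sigma = sigma, lambda = lambda)
  # independent dense assembly + generic solver
  coords <- lapply(ds$configurations, `[[`, "coordinates")
  K <- nqemd:::.assemble_kernel_matrix(coords, sigma, list(1:2))
  y <- unlist(lapply(ds$configurations, function(cf) as.vector(t(cf$forces))))
  alpha_ref <- solve(K + diag(lambda, nrow(K)), y)
  expect_equal(as.vector(m$alpha), alpha_ref, tolerance = 1e-6)
})

test_that("permutation-symmetrized models are exactly invariant", {
  # species-symmetric dimer with a swap permutation
  pes <- morse_dimer_pes()
  ds <- sample_training_set(pes, T = 300, n = 8, seed = 13)
  grp <- permutation_group(list(c(2L, 1L)), species = ds$species)
  m <- train_forcefield(ds, sigma = 5, lambda = 1e-8, group = grp)
  set.seed(2)
  x <- ds$configurations[[3]]$coordinates + matrix(rnorm(6, 0, 0.05), 2)
  e1 <- predict(m, x)$energy
  e2 <- predict(m, x[c(2, 1), ])$energy
  expect_lt(abs(e1 - e2), 1e-8)
})

test_that("predicted forces are the negative analytic gradient of the
          predicted energy", {
  mt <- morse_train_test(n_train = 15, n_test = 0, seed = 21)
  m <- train_forcefield(mt$train, sigma = 5, lambda = 1e-8)
  set.seed(3)
  for (rep in 1:3) {
    x <- mt$train$configurations[[rep]]$coordinates +
      matrix(rnorm(6, 0, 0.04), 2)
    p <- predict(m, x)
    g <- fd_gradient(function(z) predict(m, z)$energy, x)
    expect_lt(max(abs(-g - p$forces)) / max(abs(p$forces)), 1e-5)
  }
})

test_that("training-point force residuals shrink monotonically as lambda
          drops", {
  mt <- morse_train_test(n_train = 10, n_test = 0, seed = 31)
  resid_for <- function(lambda) {
    m <- train_forcefield(mt$train, sigma = 5, lambda = lambda)
    max(vapply(mt$train$configurations, function(cf)
      max(abs(predict(m, cf)$forces - cf$forces)), numeric(1)))
  }
  r <- vapply(c(1e-2, 1e-5, 1e-8), resid_for, numeric(1))
  expect_true(all(diff(r) < 0))
  # residuals are small relative to the O(50 kcal/mol/A) training forces
  expect_lt(r[3], 0.2)
})

test_that("held-out accuracy on the Morse-dimer fixture stays below the
          reference-run threshold", {
  mt <- morse_train_test(n_train = 40, n_test = 20, seed = 42)
  m <- train_forcefield(mt$train, sigma = 5, lambda = 1e-8)
  fmae <- mean(vapply(mt$test, function(cf)
    mean(abs(predict(m, cf)$forces - cf$forces)), numeric(1)))
  emae <- mean(vapply(mt$test, function(cf)
    abs(predict(m, cf)$energy - cf$energy), numeric(1)))
  # reference run of this fixture: force MAE ~0.03, energy MAE ~0.002
  expect_lt(fmae, 0.08)
  expect_lt(emae, 0.02)
})

test_that("training validates its inputs", {
  mt <- morse_train_test(n_train = 4, n_test = 0, seed = 2)
  expect_error(train_forcefield(mt$train, sigma = -1), "sigma")
  expect_error(train_forcefield(mt$train, sigma = 5, lambda = -1), "lambda")
  expect_error(train_forcefield(mt$train, sigma = 5, memory_budget = 10),
               "memory")
  noF <- ff_dataset(lapply(mt$train$configurations, function(cf)
    molecular_configuration(cf$species, cf$coordinates, energy = cf$energy)))
  expect_error(train_forcefield(noF, sigma = 5), "forces")
  m <- train_forcefield(mt$train, sigma = 5, lambda = 1e-8)
  expect_error(predict(m, molecular_configuration(c("O", "O"),
                                                  diag(3)[1:2, ])),
               "species mismatch")
})

test_that("duplicated training rows make the lambda = 0 system singular
          with a condition estimate", {
  pes <- morse_dimer_pes()
  ds <- sample_training_set(pes, T = 300, n = 1, seed = 5)
  dup <- ff_dataset(rep(ds$configurations, 2))
  expect_error(train_forcefield(dup, sigma = 5, lambda = 0),
               "singular.*condition estimate")
})

test_that("hyperparameter grid search recovers the generating length-scale
          and honors its tie-break", {
  # noiseless kernel-drawn data: predictions of a model with known sigma
  mt <- morse_train_test(n_train = 12, n_test = 0, seed = 17)
  gen <- train_forcefield(mt$train, sigma = 6, lambda = 1e-10)
  relabeled <- lapply(mt$train$configurations, function(cf) {
    p <- predict(gen, cf)
    molecular_configuration(cf$species, cf$coordinates,
                            energy = p$energy, forces = p$forces)
  })
  ds <- ff_dataset(relabeled)
  sel <- select_hyperparameters(ds, sigma_grid = c(0.5, 6, 40),
                                lambda_grid = 1e-10, split_seed = 3)
  expect_equal(sel$sigma, 6)
  # single-element grids come back unchanged
  sel1 <- select_hyperparameters(ds, 3.3, 1e-7, split_seed = 1)
  expect_equal(sel1$sigma, 3.3)
  expect_equal(sel1$lambda, 1e-7)
  # deterministic given the split seed; the log records every candidate
  sel2 <- select_hyperparameters(ds, sigma_grid = c(0.5, 6, 40),
                                 lambda_grid = 1e-10, split_seed = 3)
  expect_identical(sel$log, sel2$log)
  expect_equal(nrow(sel$log), 3L)
  expect_error(select_hyperparameters(ds, numeric(0), 1, split_seed = 1),
               "non-empty")
})
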