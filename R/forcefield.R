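#' Train a symmetrized gradient-domain force field
#'
#' Kernel ridge regression on forces: the model is the analytic gradient
#' field of a single scalar function by construction (energy conservation as
#' an inductive bias), and the kernel is averaged over a user-supplied
#' permutation group so predictions are exactly invariant under the declared
#' atom exchanges. The training system has one row per Cartesian force
#' component (3N per configuration, M configurations); its blocks are second
#' derivatives of the permutation-averaged Matern 5/2 kernel taken through
#' the inverse-distance descriptor chain rule. Energies, when present, only
#' set the additive offset `c` (mean predicted energy matched to mean
#' reference energy): a gradient-domain fit determines the energy up to a
#' constant.
#'
#' @param dataset a [ff_dataset()]; every configuration must carry forces.
#' @param sigma kernel length-scale (> 0), descriptor units (1/angstrom).
#' @param lambda ridge regularization (>= 0) added to the kernel diagonal.
#' @param group optional [permutation_group()]; default is the identity.
#' @param memory_budget refuse to assemble a kernel matrix larger than this
#'   many bytes (default 2 GB); the system is dense of size (3NM)^2.
#' @return object of class `forcefield_model`.
#' @references The training-set size study behind the default of ~1000
#'   configurations for real molecules is summarised in the package vignette.
#' @export
train_forcefield <- function(dataset, sigma, lambda = 1e-10, group = NULL,
                             memory_budget = 2e9) {
  stopifnot(inherits(dataset, "ff_dataset"))
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0")
  M <- length(dataset)
  N <- length(dataset$species)
  nb <- 3L * N
  ntot <- nb * M
  if (8 * as.numeric(ntot)^2 > memory_budget)
    stop(sprintf(paste0("training system of size %d x %d exceeds the memory",
                        " budget (%.2g bytes); reduce M or raise",
                        " memory_budget"), ntot, ntot, memory_budget))
  hasF <- vapply(dataset$configurations,
                 function(cf) !is.null(cf$forces), logical(1))
  if (!all(hasF)) stop("every training configuration must carry forces")
  perms <- .group_elements(group, N)
  nG <- length(perms)

  coords <- lapply(dataset$configurations, `[[`, "coordinates")
  desc <- lapply(dataset$configurations, compute_descriptor)
  K <- .assemble_kernel_matrix(coords, sigma, perms, desc = desc)

  y <- unlist(lapply(dataset$configurations,
                     function(cf) .flatten_coords(cf$forces)))
  sol <- .solve_spd(K, y, lambda)
  alpha <- sol$alpha

  model <- structure(list(
    species = dataset$species,
    training = list(desc = desc, coords = lapply(dataset$configurations,
                                                 `[[`, "coordinates")),
    alpha = matrix(alpha, nrow = nb),
    # W_j = J_j alpha_j, the only training quantity prediction needs
    W = vapply(seq_len(M),
               function(j) as.vector(desc[[j]]$J %*%
                                       alpha[(j - 1L) * nb + seq_len(nb)]),
               numeric(length(desc[[1L]]$d))),
    sigma = sigma, lambda = lambda, group = perms,
    offset = 0, jitter = sol$jitter), class = "forcefield_model")
  if (is.matrix(model$W) == FALSE)  # single-pair descriptor: keep matrix form
    model$W <- matrix(model$W, nrow = 1L)

  E <- vapply(dataset$configurations,
              function(cf) if (is.null(cf$energy)) NA_real_ else cf$energy,
              numeric(1))
  if (any(is.finite(E))) {
    keep <- which(is.finite(E))
    raw <- vapply(keep, function(i)
      .predict_raw(model, dataset$configurations[[i]]$coordinates)$energy,
      numeric(1))
    model$offset <- mean(E[keep] - raw)
  }
  model
}

# force-force covariance (Gram) matrix of the permutation-averaged kernel:
# blocks K_ij = (1/|G|) sum_P Jt(P x_i)^T H(D(P x_i) - D(x_j)) J(x_j)
.assemble_kernel_matrix <- function(coords, sigma, perms, desc = NULL) {
  M <- length(coords)
  nb <- 3L * nrow(coords[[1L]])
  nG <- length(perms)
  if (is.null(desc)) desc <- lapply(coords, compute_descriptor)
  pdesc <- lapply(coords, function(xi) {
    lapply(perms, function(p) {
      dp <- compute_descriptor(xi[p, , drop = FALSE])
      J <- matrix(0, nrow(dp$J), ncol(dp$J))
      J[, .perm_col_index(p)] <- dp$J
      list(d = dp$d, J = J)
    })
  })
  K <- matrix(0, nb * M, nb * M)
  for (i in seq_len(M)) {
    ri <- (i - 1L) * nb + seq_len(nb)
    for (j in seq_len(M)) {
      cj <- (j - 1L) * nb + seq_len(nb)
      blk <- matrix(0, nb, nb)
      for (g in seq_len(nG)) {
        u <- pdesc[[i]][[g]]$d - desc[[j]]$d
        HJ <- .matern52_hess_apply(u, sigma, desc[[j]]$J)
        blk <- blk + crossprod(pdesc[[i]][[g]]$J, HJ)
      }
      K[ri, cj] <- blk / nG
    }
  }
  (K + t(K)) / 2
}

# Cholesky solve of (K + lambda I) alpha = y with escalating jitter fallback
.solve_spd <- function(K, y, lambda) {
  n <- nrow(K)
  A <- K + diag(lambda, n)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  jitter <- 0
  if (is.null(ch)) {
    if (lambda == 0) {
      kap <- kappa(K, exact = FALSE)
      stop(sprintf(paste0("kernel system is singular at lambda = 0",
                          " (condition estimate %.3g); use lambda > 0"), kap))
    }
    scale <- mean(diag(K))
    jitter <- 1e-10 * scale
    repeat {
      ch <- tryCatch(chol(A + diag(jitter, n)), error = function(e) NULL)
      if (!is.null(ch)) break
      jitter <- jitter * 10
      if (jitter > 1e-2 * scale)
        stop("kernel system could not be factorized even with jitter")
    }
    warning(sprintf("kernel factorization needed jitter %.3g", jitter))
  }
  list(alpha = backsolve(ch, forwardsolve(t(ch), y)), jitter = jitter)
}

# energy/forces before the offset; x is an N x 3 matrix
.predict_raw <- function(model, x) {
  perms <- model$group
  nG <- length(perms)
  M <- ncol(model$alpha)
  sigma <- model$sigma
  energy <- 0
  force_flat <- numeric(3L * nrow(x))
  for (p in perms) {
    dp <- compute_descriptor(x[p, , drop = FALSE])
    colidx <- .perm_col_index(p)
    acc <- numeric(length(dp$d))   # sum_j H(u_j) W_j
    for (j in seq_len(M)) {
      u <- dp$d - model$training$desc[[j]]$d
      d <- sqrt(sum(u * u))
      w <- model$W[, j]
      energy <- energy + .matern52_g1(d, sigma) * sum(u * w)
      acc <- acc - .matern52_g1(d, sigma) * w -
        .matern52_g2(d, sigma) * u * sum(u * w)
    }
    fp <- crossprod(dp$J, acc)     # length 3N, in permuted coordinates
    ftmp <- numeric(length(force_flat))
    ftmp[colidx] <- fp
    force_flat <- force_flat + ftmp
  }
  list(energy = energy / nG,
       forces = .unflatten_coords(force_flat / nG))
}

#' Predict energy and forces from a trained force field
#'
#' Returned forces are analytically the negative gradient of the returned
#' energy (one scalar function underlies both), a property verified in the
#' package tests by central finite differences.
#'
#' @param object a `forcefield_model` from [train_forcefield()].
#' @param config a [molecular_configuration()] or N x 3 coordinate matrix
#'   with the model's species.
#' @param ... unused.
#' @return list with `energy` (kcal/mol) and `forces` (N x 3, kcal/mol/A).
#' @export
predict.forcefield_model <- function(object, config, ...) {
  if (inherits(config, "molecular_configuration")) {
    if (!identical(config$species, object$species))
      stop("species mismatch between model and configuration")
    x <- config$coordinates
  } else {
    x <- as.matrix(config)
    if (nrow(x) != length(object$species))
      stop("species mismatch: coordinate matrix has wrong number of atoms")
  }
  out <- .predict_raw(object, x)
  out$energy <- out$energy + object$offset
  out
}

#' @export
print.forcefield_model <- function(x, ...) {
  cat("Gradient-domain force field:", ncol(x$alpha), "training configurations,",
      length(x$species), "atoms, |G| =", length(x$group), "\n")
  cat(sprintf("  sigma = %g, lambda = %g, energy offset c = %g kcal/mol\n",
              x$sigma, x$lambda, x$offset))
  invisible(x)
}

#' Grid search for kernel hyperparameters
#'
#' Splits the dataset into training and validation parts (deterministically
#' from `split_seed`), trains one model per (sigma, lambda) grid pair and
#' returns the pair minimizing validation force mean-absolute-error. Ties
#' are broken toward the smallest sigma, then the smallest lambda.
#'
#' @param dataset a [ff_dataset()] with forces on every member.
#' @param sigma_grid,lambda_grid non-empty numeric candidate vectors.
#' @param split_seed integer seed controlling the validation split.
#' @param validation_fraction fraction held out for validation (default 0.25).
#' @param group optional [permutation_group()] passed to training.
#' @return list with `sigma`, `lambda` and `log` (a data.frame of all
#'   candidates with their validation force MAE; failed fits carry NA).
#' @export
select_hyperparameters <- function(dataset, sigma_grid, lambda_grid,
                                   split_seed,
                                   validation_fraction = 0.25,
                                   group = NULL) {
  if (!length(sigma_grid) || !length(lambda_grid))
    stop("hyperparameter grids must be non-empty")
  M <- length(dataset)
  nval <- max(1L, round(validation_fraction * M))
  if (M - nval < 1L) stop("dataset too small for a validation split")
  idx <- .with_seed(split_seed, sample.int(M, nval))
  train_ds <- ff_dataset(dataset$configurations[-idx],
                         units = dataset$units,
                         provenance = dataset$provenance)
  val <- dataset$configurations[idx]

  grid <- expand.grid(sigma = sort(sigma_grid), lambda = sort(lambda_grid))
  grid <- grid[order(grid$sigma, grid$lambda), , drop = FALSE]
  mae <- rep(NA_real_, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    fit <- tryCatch(
      train_forcefield(train_ds, grid$sigma[k], grid$lambda[k], group = group),
      error = function(e) NULL)
    if (is.null(fit)) next
    err <- vapply(val, function(cf) {
      p <- predict(fit, cf)
      mean(abs(p$forces - cf$forces))
    }, numeric(1))
    mae[k] <- mean(err)
  }
  if (all(is.na(mae)))
    stop("all hyperparameter candidates were numerically singular")
  best <- which(mae == min(mae, na.rm = TRUE))[1L]
  list(sigma = grid$sigma[best], lambda = grid$lambda[best],
       log = cbind(grid, force_mae = mae, split_seed = split_seed))
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
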