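#' Molecular configuration
#'
#' The universal unit of I/O and prediction: a set of atoms with Cartesian
#' coordinates and, optionally, a potential energy and per-atom forces.
#'
#' @param species character vector of element symbols, length N.
#' @param coordinates N x 3 numeric matrix, angstrom.
#' @param energy optional scalar potential energy, kcal/mol.
#' @param forces optional N x 3 numeric matrix, kcal/mol/A.
#' @return object of class `molecular_configuration`.
#' @export
molecular_configuration <- function(species, coordinates,
                                    energy = NULL, forces = NULL) {
  coordinates <- as.matrix(coordinates)
  n <- length(species)
  if (!is.character(species) || n < 1L)
    stop("species must be a non-empty character vector")
  if (!is.numeric(coordinates) || nrow(coordinates) != n ||
      ncol(coordinates) != 3L)
    stop("coordinates must be an N x 3 numeric matrix matching species")
  if (!all(is.finite(coordinates)))
    stop("coordinates must be finite")
  if (!is.null(energy)) {
    if (!is.numeric(energy) || length(energy) != 1L || !is.finite(energy))
      stop("energy must be a single finite number (kcal/mol)")
    energy <- as.numeric(energy)
  }
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    if (!is.numeric(forces) || !identical(dim(forces), dim(coordinates)))
      stop("forces must have the same shape as coordinates")
    if (!all(is.finite(forces))) stop("forces must be finite")
  }
  structure(list(species = species, coordinates = unname(coordinates),
                 energy = energy, forces = if (is.null(forces)) NULL
                                           else unname(forces)),
            class = "molecular_configuration")
}

#' @export
print.molecular_configuration <- function(x, ...) {
  cat("Molecular configuration:", length(x$species), "atoms (",
      paste(unique(x$species), collapse = " "), ")\n")
  if (!is.null(x$energy)) cat("  energy:", format(x$energy), "kcal/mol\n")
  cat("  forces:", if (is.null(x$forces)) "absent" else "present", "\n")
  invisible(x)
}

#' Force-field dataset
#'
#' A sequence of configurations sharing one species list, with units and
#' provenance metadata. Training a force field requires every member to carry
#' forces; energies are needed only for the model's additive offset.
#'
#' @param configurations list of [molecular_configuration()] objects with
#'   identical species vectors.
#' @param units named list of unit labels (defaults record the package's
#'   internal conventions).
#' @param provenance named list (generator name, seed or source file, ...).
#' @return object of class `ff_dataset`.
#' @export
ff_dataset <- function(configurations,
                       units = list(length = "angstrom", energy = "kcal/mol",
                                    forces = "kcal/mol/angstrom"),
                       provenance = list()) {
  if (!length(configurations)) stop("dataset must contain configurations")
  ok <- vapply(configurations, inherits, logical(1), "molecular_configuration")
  if (!all(ok)) stop("all members must be molecular_configuration objects")
  sp <- configurations[[1L]]$species
  same <- vapply(configurations, function(cf) identical(cf$species, sp),
                 logical(1))
  if (!all(same))
    stop("all configurations must share species identity and ordering")
  structure(list(configurations = configurations, species = sp,
                 units = units, provenance = provenance),
            class = "ff_dataset")
}

#' @export
length.ff_dataset <- function(x) length(x$configurations)

#' @export
print.ff_dataset <- function(x, ...) {
  cat("Force-field dataset:", length(x), "configurations of",
      length(x$species), "atoms\n")
  hasE <- all(vapply(x$configurations,
                     function(cf) !is.null(cf$energy), logical(1)))
  hasF <- all(vapply(x$configurations,
                     function(cf) !is.null(cf$forces), logical(1)))
  cat("  energies:", if (hasE) "present" else "incomplete",
      "| forces:", if (hasF) "present" else "incomplete", "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               unlist(lapply(x$provenance, format)),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# stack dataset into arrays (M x N x 3 etc.); internal
.dataset_arrays <- function(ds) {
  M <- length(ds)
  N <- length(ds$species)
  R <- array(NA_real_, c(M, N, 3L))
  Fa <- array(NA_real_, c(M, N, 3L))
  E <- rep(NA_real_, M)
  for (i in seq_len(M)) {
    cf <- ds$configurations[[i]]
    R[i, , ] <- cf$coordinates
    if (!is.null(cf$forces)) Fa[i, , ] <- cf$forces
    if (!is.null(cf$energy)) E[i] <- cf$energy
  }
  list(z = atomic_numbers(ds$species), R = R, E = E, F = Fa)
}

#' Permutation group over atom indices
#'
#' Houses the permutational-symmetry prior of a force-field model: a set of
#' index maps (1-based, each a bijection on 1..N) under which the molecule is
#' physically indistinguishable. The identity is always included; every
#' member must preserve the species labelling.
#'
#' @param permutations list of integer vectors, each a permutation of 1..N.
#' @param species optional character vector; when given, each permutation is
#'   checked to leave the species list unchanged.
#' @return object of class `permutation_group`.
#' @export
permutation_group <- function(permutations = list(), species = NULL) {
  if (!is.list(permutations)) permutations <- list(permutations)
  perms <- lapply(permutations, as.integer)
  if (length(perms)) {
    n <- length(perms[[1L]])
    for (p in perms) {
      if (length(p) != n || !setequal(p, seq_len(n)))
        stop("each permutation must be a bijection on 1..N")
      if (!is.null(species) && !identical(species[p], species))
        stop("permutation does not preserve the species list")
    }
    id <- seq_len(n)
    if (!any(vapply(perms, identical, logical(1), id)))
      perms <- c(list(id), perms)
  }
  structure(list(permutations = perms), class = "permutation_group")
}

#' @export
print.permutation_group <- function(x, ...) {
  cat("Permutation group with", max(1L, length(x$permutations)),
      "element(s)\n")
  invisible(x)
}

# group elements for an N-atom system; empty group means {identity}
.group_elements <- function(group, n) {
  if (is.null(group) || !length(group$permutations)) return(list(seq_len(n)))
  if (length(group$permutations[[1L]]) != n)
    stop("permutation group size does not match atom count")
  group$permutations
}
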