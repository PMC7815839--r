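#' Read and write force-field dataset archives
#'
#' The archive dialect is that of published gradient-domain force-field
#' datasets: a zip of named arrays with `z` (atomic numbers, length N), `R`
#' (M x N x 3 coordinates, angstrom), `E` (M energies, kcal/mol) and `F`
#' (M x N x 3 forces, kcal/mol/A); optional `theory`/`name` metadata
#' entries are ignored on read. `read_dataset` validates shapes and
#' finiteness and reports every violation at once. Extended-XYZ files
#' (`.xyz`) are accepted as an alternative multi-frame container.
#'
#' @param path archive path (`.npz`) or extended-XYZ path (`.xyz`).
#' @return a [ff_dataset()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.xyz$", path)) {
    configs <- read_extxyz(path)
    return(ff_dataset(configs, provenance = list(source = path)))
  }
  arr <- .npz_read(path)
  problems <- character(0)
  for (nm in c("z", "R", "E", "F"))
    if (is.null(arr[[nm]]))
      problems <- c(problems, sprintf("missing array '%s'", nm))
  if (length(problems))
    stop("invalid dataset archive:\n  ", paste(problems, collapse = "\n  "))
  z <- as.integer(round(arr$z))
  N <- length(z)
  R <- arr$R; E <- as.vector(arr$E); Fa <- arr$F
  if (length(dim(R)) != 3L || dim(R)[2L] != N || dim(R)[3L] != 3L)
    problems <- c(problems, sprintf(
      "R has shape (%s); expected (M, %d, 3)",
      paste(dim(R), collapse = ", "), N))
  if (!identical(dim(Fa), dim(R)))
    problems <- c(problems, sprintf(
      "F has shape (%s); expected the shape of R (%s)",
      paste(dim(Fa), collapse = ", "), paste(dim(R), collapse = ", ")))
  if (length(E) != dim(R)[1L])
    problems <- c(problems,
                  sprintf("E has length %d; expected M = %d",
                          length(E), dim(R)[1L]))
  if (!length(problems)) {
    bad_e <- which(!is.finite(E))
    if (length(bad_e))
      problems <- c(problems,
                    sprintf("non-finite energy at record(s) %s",
                            paste(utils::head(bad_e, 10L), collapse = ", ")))
    bad_r <- which(apply(!is.finite(R), 1L, any))
    if (length(bad_r))
      problems <- c(problems,
                    sprintf("non-finite coordinates at record(s) %s",
                            paste(utils::head(bad_r, 10L), collapse = ", ")))
    bad_f <- which(apply(!is.finite(Fa), 1L, any))
    if (length(bad_f))
      problems <- c(problems,
                    sprintf("non-finite forces at record(s) %s",
                            paste(utils::head(bad_f, 10L), collapse = ", ")))
  }
  if (length(problems))
    stop("invalid dataset archive:\n  ", paste(problems, collapse = "\n  "))
  species <- element_symbols(z)
  configs <- lapply(seq_len(dim(R)[1L]), function(i)
    molecular_configuration(species,
                            matrix(R[i, , ], ncol = 3L),
                            energy = E[i],
                            forces = matrix(Fa[i, , ], ncol = 3L)))
  ff_dataset(configs, provenance = list(source = path))
}

#' @param dataset a [ff_dataset()]; every member needs energy and forces.
#' @rdname read_dataset
#' @export
write_dataset <- function(path, dataset) {
  stopifnot(inherits(dataset, "ff_dataset"))
  arrs <- .dataset_arrays(dataset)
  if (anyNA(arrs$E) || anyNA(arrs$F))
    stop("dataset members must all carry energies and forces for archiving")
  .npz_write(path, list(z = as.integer(arrs$z), R = arrs$R, E = arrs$E,
                        F = arrs$F))
  invisible(path)
}
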