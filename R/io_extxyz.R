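#' Read and write extended-XYZ files
#'
#' The extended-XYZ dialect used here stores the atom count on line 1, a
#' key=value comment line with a `Properties=` column descriptor (and an
#' `energy=` entry when present), then one line per atom with the element
#' symbol, Cartesian coordinates and, optionally, force columns. Floating
#' values are written with 17 significant digits so that write/read
#' round-trips are lossless.
#'
#' @param path file path.
#' @return `read_extxyz` returns a list of [molecular_configuration()]
#'   objects (one per frame).
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("extxyz parse error at line %d: expected atom count", i))
    if (i + 1L + n > length(lines))
      stop(sprintf(paste0("extxyz parse error at line %d: file truncated",
                          " (%d atom lines expected)"), i + 2L, n))
    comment <- lines[i + 1L]
    has_forces <- grepl("forces", comment, fixed = TRUE)
    energy <- NULL
    em <- regmatches(comment,
                     regexpr("energy=[-+0-9.eE]+", comment))
    if (length(em) && nzchar(em))
      energy <- as.numeric(sub("energy=", "", em))
    species <- character(n)
    coords <- matrix(NA_real_, n, 3L)
    forces <- if (has_forces) matrix(NA_real_, n, 3L) else NULL
    for (a in seq_len(n)) {
      ln <- i + 1L + a
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
      need <- if (has_forces) 7L else 4L
      if (length(tok) < need)
        stop(sprintf("extxyz parse error at line %d: expected %d fields",
                     ln, need))
      species[a] <- tok[1L]
      coords[a, ] <- suppressWarnings(as.numeric(tok[2:4]))
      if (has_forces)
        forces[a, ] <- suppressWarnings(as.numeric(tok[5:7]))
      if (anyNA(coords[a, ]) || (has_forces && anyNA(forces[a, ])))
        stop(sprintf("extxyz parse error at line %d: non-numeric field", ln))
    }
    configs[[length(configs) + 1L]] <-
      molecular_configuration(species, coords, energy = energy,
                              forces = forces)
    i <- i + 2L + n
  }
  if (!length(configs)) stop("no configurations found in ", path)
  configs
}

#' @param configs a [molecular_configuration()], a list of them, or a
#'   [ff_dataset()].
#' @rdname read_extxyz
#' @export
write_extxyz <- function(path, configs) {
  if (inherits(configs, "molecular_configuration")) configs <- list(configs)
  if (inherits(configs, "ff_dataset")) configs <- configs$configurations
  fmt <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    n <- length(cf$species)
    props <- if (is.null(cf$forces)) "Properties=species:S:1:pos:R:3"
             else "Properties=species:S:1:pos:R:3:forces:R:3"
    comment <- props
    if (!is.null(cf$energy))
      comment <- paste0(comment, " energy=", fmt(cf$energy))
    writeLines(c(as.character(n), comment), con)
    for (a in seq_len(n)) {
      row <- c(cf$species[a], fmt(cf$coordinates[a, ]),
               if (!is.null(cf$forces)) fmt(cf$forces[a, ]))
      writeLines(paste(row, collapse = " "), con)
    }
  }
  invisible(path)
}
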