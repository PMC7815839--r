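# Minimal NumPy .npy (v1.0) and stored-.npz support.
#
# The published force-field datasets are distributed as named-array
# archives (zip files of .npy members). No installed R package reads that
# container, so this file implements the small subset needed: little-endian
# float/int arrays, C order, plus an uncompressed ("stored") zip writer
# with a table-driven CRC32. Reading accepts deflated members too, via
# utils::unzip.

.npy_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))))
    stop("not a .npy file: ", path)
  ver <- readBin(con, "raw", 2L)
  hlen <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                  endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1L]])
  shape <- shape[!is.na(shape)]
  n <- if (length(shape)) prod(shape) else 1L
  data <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<i8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "<i2" = readBin(con, "integer", n, size = 2L, endian = "little"),
    "|i1" = readBin(con, "integer", n, size = 1L, endian = "little"),
    "|u1" = readBin(con, "integer", n, size = 1L, signed = FALSE,
                    endian = "little"),
    stop("unsupported .npy dtype '", descr, "' in ", path))
  if (length(shape) <= 1L) return(as.vector(data))
  if (fortran) array(data, dim = shape)
  else aperm(array(data, dim = rev(shape)), rev(seq_along(shape)))
}

.npy_write <- function(path, x) {
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  if (is.integer(x)) {
    descr <- "<i4"
    flat <- as.integer(if (is.null(dim(x))) x
                       else aperm(x, rev(seq_along(shape))))
    size <- 4L
  } else {
    descr <- "<f8"
    flat <- as.double(if (is.null(dim(x))) x
                      else aperm(x, rev(seq_along(shape))))
    size <- 8L
  }
  shape_str <- if (length(shape) == 1L) paste0("(", shape, ",)")
               else paste0("(", paste(shape, collapse = ", "), ")")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape_str)
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(flat, con, size = size, endian = "little")
  invisible(path)
}

# table-driven CRC32 (IEEE 802.3 polynomial) on a raw vector; the 32-bit
# state is kept as two 16-bit words because R's bitwXor only covers 2^31
.crc32_table <- local({
  hi <- NULL; lo <- NULL
  function() {
    if (is.null(hi)) {
      h <- integer(256); l <- integer(256)
      for (i in 0:255) {
        chi <- 0L; clo <- i
        for (k in 1:8) {
          odd <- clo %% 2L
          clo <- clo %/% 2L + (chi %% 2L) * 0x8000L
          chi <- chi %/% 2L
          if (odd) {
            chi <- bitwXor(chi, 0xEDB8L)
            clo <- bitwXor(clo, 0x8320L)
          }
        }
        h[i + 1L] <- chi; l[i + 1L] <- clo
      }
      hi <<- h; lo <<- l
    }
    list(hi = hi, lo = lo)
  }
})

.crc32 <- function(bytes) {
  tab <- .crc32_table()
  chi <- 0xFFFFL; clo <- 0xFFFFL
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwXor(clo %% 256L, b[i])
    nlo <- clo %/% 256L + (chi %% 256L) * 256L
    nhi <- chi %/% 256L
    chi <- bitwXor(nhi, tab$hi[idx + 1L])
    clo <- bitwXor(nlo, tab$lo[idx + 1L])
  }
  chi <- bitwXor(chi, 0xFFFFL)
  clo <- bitwXor(clo, 0xFFFFL)
  chi * 65536 + clo
}

.u16_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
.u32_raw <- function(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))

# write entries (named list name -> raw payload) as a stored zip
.zip_write_stored <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  crcs <- numeric(0)
  pos <- 0
  for (nm in names(entries)) {
    data <- entries[[nm]]
    crc <- .crc32(data)
    name_raw <- charToRaw(nm)
    hdr <- c(.u32_raw(0x04034b50), .u16_raw(20), .u16_raw(0), .u16_raw(0),
             .u16_raw(0), .u16_raw(0x21), .u32_raw(crc),
             .u32_raw(length(data)), .u32_raw(length(data)),
             .u16_raw(length(name_raw)), .u16_raw(0))
    writeBin(hdr, con)
    writeBin(name_raw, con)
    writeBin(data, con)
    offsets <- c(offsets, pos)
    crcs <- c(crcs, crc)
    pos <- pos + length(hdr) + length(name_raw) + length(data)
  }
  cd_start <- pos
  cd_len <- 0
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    data <- entries[[i]]
    name_raw <- charToRaw(nm)
    cd <- c(.u32_raw(0x02014b50), .u16_raw(20), .u16_raw(20), .u16_raw(0),
            .u16_raw(0), .u16_raw(0), .u16_raw(0x21), .u32_raw(crcs[i]),
            .u32_raw(length(data)), .u32_raw(length(data)),
            .u16_raw(length(name_raw)), .u16_raw(0), .u16_raw(0),
            .u16_raw(0), .u16_raw(0), .u32_raw(0), .u32_raw(offsets[i]))
    writeBin(cd, con)
    writeBin(name_raw, con)
    cd_len <- cd_len + length(cd) + length(name_raw)
  }
  eocd <- c(.u32_raw(0x06054b50), .u16_raw(0), .u16_raw(0),
            .u16_raw(length(entries)), .u16_raw(length(entries)),
            .u32_raw(cd_len), .u32_raw(cd_start), .u16_raw(0))
  writeBin(eocd, con)
  invisible(path)
}

.npz_write <- function(path, arrays) {
  tmp <- tempfile()
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  entries <- list()
  for (nm in names(arrays)) {
    f <- file.path(tmp, paste0(nm, ".npy"))
    .npy_write(f, arrays[[nm]])
    entries[[paste0(nm, ".npy")]] <- readBin(f, "raw", file.size(f))
  }
  .zip_write_stored(path, entries)
}

.npz_read <- function(path) {
  tmp <- tempfile()
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- utils::unzip(path, exdir = tmp)
  out <- list()
  for (f in files) {
    nm <- sub("\\.npy$", "", basename(f))
    out[[nm]] <- .npy_read(f)
  }
  out
}
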