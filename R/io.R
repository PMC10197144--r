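# Stack I/O: minimal baseline TIFF (uncompressed, float32, one strip per
# page, little-endian) plus a JSON sidecar for axial coordinates and model
# metadata. No installed R package reads/writes TIFF in this stack, so the
# baseline subset is implemented here; files are readable by any standard
# TIFF reader.

tiff_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) { # SHORT packed into the low half of the value field
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write / read a float32 multi-page TIFF
#'
#' `write_tiff()` stores a numeric matrix or 3-D array (pages along the
#' third dimension) as an uncompressed 32-bit-float grayscale TIFF, one
#' strip per page. `read_tiff()` reads such files (baseline little-endian
#' subset) back into an array.
#'
#' @param data Numeric matrix or 3-D array. Rows map to TIFF rows.
#' @param path File path.
#' @return `write_tiff()` the path invisibly; `read_tiff()` a 3-D array
#'   (x, y, pages).
#' @export
write_tiff <- function(data, path) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a matrix or 3-D array.")
  }
  d <- dim(data)
  w <- d[2]; h <- d[1]; pages <- d[3]
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  page_bytes <- 4L * w * h
  ifd_off <- integer(pages)
  data_off <- integer(pages)
  pos <- 8L
  for (p in seq_len(pages)) {
    ifd_off[p] <- pos
    data_off[p] <- pos + ifd_size
    pos <- data_off[p] + page_bytes
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off[1], con, size = 4, endian = "little")
  for (p in seq_len(pages)) {
    writeBin(n_entries, con, size = 2, endian = "little")
    tiff_entry(con, 256L, 4L, 1L, w)            # ImageWidth
    tiff_entry(con, 257L, 4L, 1L, h)            # ImageLength
    tiff_entry(con, 258L, 3L, 1L, 32L)          # BitsPerSample
    tiff_entry(con, 259L, 3L, 1L, 1L)           # Compression: none
    tiff_entry(con, 262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    tiff_entry(con, 273L, 4L, 1L, data_off[p])  # StripOffsets
    tiff_entry(con, 278L, 4L, 1L, h)            # RowsPerStrip
    tiff_entry(con, 279L, 4L, 1L, page_bytes)   # StripByteCounts
    tiff_entry(con, 339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
    writeBin(if (p < pages) ifd_off[p + 1] else 0L, con, size = 4,
             endian = "little")
    # row-major pixel order: transpose so rows are contiguous
    writeBin(as.numeric(t(data[, , p])), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_tiff
#' @export
read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_mark <- readChar(con, 2)
  if (order_mark != "II") abort("only little-endian ('II') TIFF is supported.")
  magic <- readBin(con, "integer", size = 2, endian = "little")
  if (magic != 42L) abort("not a TIFF file.")
  next_ifd <- readBin(con, "integer", size = 4, endian = "little")
  pages <- list()
  while (next_ifd != 0L) {
    seek(con, next_ifd)
    n <- readBin(con, "integer", size = 2, endian = "little")
    tags <- list()
    for (i in seq_len(n)) {
      tag <- readBin(con, "integer", size = 2, endian = "little")
      type <- readBin(con, "integer", size = 2, endian = "little")
      count <- readBin(con, "integer", size = 4, endian = "little")
      raw_val <- readBin(con, "raw", n = 4)
      val <- if (type == 3L && count == 1L) {
        sum(as.integer(raw_val[1:2]) * c(1L, 256L))
      } else {
        sum(as.numeric(as.integer(raw_val)) * 256^(0:3))
      }
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val)
    }
    next_ifd <- readBin(con, "integer", size = 4, endian = "little")
    gv <- function(t, default = NULL) {
      e <- tags[[as.character(t)]]
      if (is.null(e)) default else e$value
    }
    if (gv(259L, 1L) != 1L) abort("compressed TIFF is not supported.")
    if (gv(258L, 1L) != 32L || gv(339L, 1L) != 3L) {
      abort("only 32-bit float samples are supported.")
    }
    w <- gv(256L); h <- gv(257L)
    if (tags[["273"]]$count != 1L) abort("multi-strip pages are not supported.")
    seek(con, gv(273L))
    px <- readBin(con, "numeric", n = w * h, size = 4, endian = "little")
    pages[[length(pages) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
  }
  if (!length(pages)) abort("no pages found.")
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) all(dim(p) == d), logical(1)))) {
    abort("pages differ in size.")
  }
  array(unlist(pages), dim = c(d, length(pages)))
}

#' Write / read an intensity stack with its JSON sidecar
#'
#' The stack's cube goes to a float32 multi-page TIFF; axial coordinates,
#' scattering length, decay flag and pixel size go to `<path>.json`.
#' `read_stack()` restores an `edof_stack` (32-bit rounding applies to the
#' intensities).
#'
#' @param stack An `edof_stack` with the full cube retained.
#' @param path TIFF path (sidecar at `paste0(path, ".json")`).
#' @return `write_stack()` the path invisibly; `read_stack()` an
#'   `edof_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "edof_stack"))
  if (is.null(stack$data)) abort("stack has no full cube (keep_stack = FALSE).")
  write_tiff(stack$data, path)
  meta <- list(
    z_um = stack$z_um,
    ls_um = if (is.finite(stack$ls_um)) stack$ls_um else "Inf",
    decay_applied = stack$decay_applied,
    pixel_um = stack$pixel_um
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  data <- read_tiff(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ls_um <- if (identical(meta$ls_um, "Inf")) Inf else as.numeric(meta$ls_um)
  as_stack(data, z_um = as.numeric(meta$z_um), ls_um = ls_um,
           decay_applied = isTRUE(meta$decay_applied),
           pixel_um = as.numeric(meta$pixel_um))
}

#' Run manifest for reproducible command-line runs
#'
#' Records the configuration snapshot, seed, package version, input/output
#' file MD5 hashes and a timestamp; every CLI run writes exactly one.
#'
#' @param config Named list: the configuration snapshot.
#' @param seed Integer seed of the run (or `NULL`).
#' @param inputs,outputs Character vectors of file paths to hash.
#' @param path Where to write the manifest JSON; `NULL` returns the list.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(config, seed = NULL, inputs = character(),
                         outputs = character(), path = NULL) {
  hash <- function(fs) {
    fs <- fs[file.exists(fs)]
    if (!length(fs)) return(NULL)
    as.list(tools::md5sum(fs))
  }
  m <- list(
    tool = "edofpupil",
    version = as.character(utils::packageVersion("edofpupil")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_md5 = hash(inputs),
    output_md5 = hash(outputs)
  )
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(m))
  }
  m
}
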