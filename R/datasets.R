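# Labeled dataset container and its on-disk format.
#
# A labeled dataset pairs marker images with the code bits and pose they
# were generated from.  On disk it is a single file: a magic string, a JSON
# header describing every array, then the raw little-endian arrays
# (doubles, so the round-trip is bit-exact).  A plain-text JSON variant
# exists for small shipped fixtures.

DATASET_MAGIC <- "BTLD1"
DATASET_SOURCES <- c("rendergan", "hm3d", "hmli", "hmbg", "idealistic", "real")

#' Labeled marker dataset
#'
#' @param images Array of images, dim `c(resolution, resolution, n)`,
#'   values in \[-1, 1\].
#' @param bits Integer matrix `n x n_bits` of code bits in \{0, 1\}.
#' @param pose Numeric matrix `n x 6` with columns yaw, pitch, roll,
#'   center_row, center_col, radius.
#' @param provenance List with `source` (one of `r
#'   paste(DATASET_SOURCES, collapse = ", ")`), `config_hash`, `seed`.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(images, bits, pose, provenance) {
  if (is.matrix(bits)) storage.mode(bits) <- "integer"
  d <- dim(images)
  if (length(d) != 3 || d[1] != d[2]) {
    stop("images: expected a (resolution, resolution, n) array")
  }
  n <- d[3]
  if (!is.matrix(bits) || nrow(bits) != n) {
    stop("count mismatch: images hold ", n, " samples but bits ",
         if (is.matrix(bits)) nrow(bits) else length(bits))
  }
  if (!all(bits %in% c(0L, 1L))) stop("bits: values must be 0/1")
  if (!is.matrix(pose) || nrow(pose) != n || ncol(pose) != 6) {
    stop("count mismatch: pose must be an n x 6 matrix")
  }
  if (n > 0 && (min(images) < -1 - 1e-9 || max(images) > 1 + 1e-9)) {
    stop("images: values must lie in [-1, 1]")
  }
  if (!is.list(provenance) || is.null(provenance$source) ||
      !provenance$source %in% DATASET_SOURCES) {
    stop("provenance: needs a source in ", paste(DATASET_SOURCES, collapse = "/"))
  }
  colnames(pose) <- c("yaw", "pitch", "roll", "center_row", "center_col", "radius")
  structure(list(images = images, bits = bits, pose = pose,
                 provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<labeled_dataset> %d samples, %dx%d, %d bits, source %s\n",
              d[3], d[1], d[2], ncol(x$bits), x$provenance$source))
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds A [labeled_dataset()].
#' @export
dataset_size <- function(ds) dim(ds$images)[3]

#' Take a subset of a dataset
#' @param ds A [labeled_dataset()].
#' @param idx Sample indices.
#' @export
dataset_subset <- function(ds, idx) {
  labeled_dataset(ds$images[, , idx, drop = FALSE],
                  ds$bits[idx, , drop = FALSE],
                  ds$pose[idx, , drop = FALSE],
                  ds$provenance)
}

#' Write a labeled dataset to disk
#'
#' The default binary layout is magic string, 4-byte header length, JSON
#' header (array shapes, provenance), then images (doubles), bits (bytes)
#' and pose (doubles), all little-endian.  Doubles are stored at full
#' 64-bit width so `read_dataset(write_dataset(ds))` is bit-exact.
#' `format = "json"` writes the same content as plain text, for small
#' fixtures.
#'
#' @param ds A [labeled_dataset()].
#' @param path Output path.
#' @param format `"bin"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("bin", "json")) {
  stopifnot(inherits(ds, "labeled_dataset"))
  format <- match.arg(format)
  n <- dataset_size(ds)
  header <- list(magic = DATASET_MAGIC, version = 1L,
                 images_dim = dim(ds$images), bits_dim = dim(ds$bits),
                 pose_dim = dim(ds$pose), provenance = ds$provenance)
  if (format == "json") {
    payload <- c(header, list(images = as.numeric(ds$images),
                              bits = as.integer(ds$bits),
                              pose = as.numeric(ds$pose)))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(DATASET_MAGIC), con)
  hraw <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17)))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  if (n > 0) {
    writeBin(as.numeric(ds$images), con, size = 8L, endian = "little")
    writeBin(as.raw(as.integer(ds$bits)), con)
    writeBin(as.numeric(ds$pose), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a labeled dataset from disk
#'
#' @param path File written by [write_dataset()] (either format; detected
#'   from the content).
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  head4 <- readBin(path, "raw", 5)
  if (rawToChar(head4) == DATASET_MAGIC) return(read_dataset_bin(path))
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) NULL)
  if (is.null(payload) || !identical(payload$magic, DATASET_MAGIC)) {
    stop("format error: not a labeled-dataset file: ", path)
  }
  assemble_dataset(payload, payload$images, payload$bits, payload$pose)
}

read_dataset_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", nchar(DATASET_MAGIC))
  hlen <- readBin(con, "integer", 1, size = 4L, endian = "little")
  if (length(hlen) != 1 || is.na(hlen) || hlen <= 0 || hlen > 1e7) {
    stop("format error: corrupt header in ", path)
  }
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (!identical(header$version, 1L)) {
    stop("format error: unsupported dataset version ", header$version)
  }
  nim <- prod(header$images_dim)
  images <- readBin(con, "numeric", nim, size = 8L, endian = "little")
  bits <- as.integer(readBin(con, "raw", prod(header$bits_dim)))
  pose <- readBin(con, "numeric", prod(header$pose_dim), size = 8L,
                  endian = "little")
  if (length(images) != nim || length(pose) != prod(header$pose_dim)) {
    stop("format error: truncated file ", path)
  }
  assemble_dataset(header, images, bits, pose)
}

assemble_dataset <- function(header, images, bits, pose) {
  idim <- as.integer(header$images_dim)
  bdim <- as.integer(header$bits_dim)
  pdim <- as.integer(header$pose_dim)
  if (idim[3] != bdim[1] || idim[3] != pdim[1]) {
    stop("count mismatch: header declares ", idim[3], " images, ",
         bdim[1], " bit rows and ", pdim[1], " pose rows")
  }
  labeled_dataset(array(as.numeric(images), idim),
                  matrix(as.integer(bits), bdim[1], bdim[2]),
                  matrix(as.numeric(pose), pdim[1], pdim[2]),
                  as.list(header$provenance))
}

pose_to_params <- function(pose_row, n_bits = 12L,
                           bits = integer(n_bits)) {
  tag_params(bits = bits, yaw = pose_row[1], pitch = pose_row[2],
             roll = pose_row[3], center_row = pose_row[4],
             center_col = pose_row[5], radius = pose_row[6], n_bits = n_bits)
}

#' Audit dataset labels with the reference decoder
#'
#' Decodes (a sample of) the images using their stored pose and reports the
#' fraction whose decoded bits match the stored label exactly.
#'
#' @param ds A [labeled_dataset()].
#' @param sample_n Maximum number of samples to audit.
#' @param seed Seed for the audit subsample.
#' @return Fraction of exact label matches.
#' @export
audit_labels <- function(ds, sample_n = 500, seed = 1) {
  n <- dataset_size(ds)
  idx <- if (n <= sample_n) seq_len(n) else with_seed(seed, sample.int(n, sample_n))
  ok <- vapply(idx, function(i) {
    p <- pose_to_params(ds$pose[i, ], ncol(ds$bits))
    identical(reference_decode(ds$images[, , i], p), as.integer(ds$bits[i, ]))
  }, logical(1))
  mean(ok)
}
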