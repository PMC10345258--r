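## Minimal baseline TIFF I/O (uncompressed, little-endian, single plane).
##
## The deployment environment ships no R raster-I/O package, so the package
## carries its own codec for the three raster kinds it exchanges:
##   - 8-bit RGB images            (write_tiff type "uint8", H x W x 3)
##   - 16-bit instance/label maps  (type "uint16", integer matrix)
##   - 32-bit float probability maps (type "float32", numeric matrix)
## Readers are validated against an independent implementation in the test
## suite. Compressed or tiled TIFFs are out of scope and rejected.

u16le <- function(v) as.vector(rbind(as.raw(v %% 256L), as.raw(v %/% 256L)))
u32le <- function(v) {
  v <- as.numeric(v)
  as.vector(rbind(as.raw(v %% 256), as.raw((v %/% 256) %% 256),
                  as.raw((v %/% 65536) %% 256), as.raw((v %/% 16777216) %% 256)))
}

#' Write an uncompressed baseline TIFF
#'
#' @param x image data: H x W x 3 array in \[0,1\] for `"uint8"` RGB, an
#'   integer matrix for `"uint16"`, or a numeric matrix for `"float32"`.
#' @param path output file path.
#' @param type sample encoding.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, type = c("uint8", "uint16", "float32")) {
  type <- match.arg(type)
  if (type == "uint8") {
    stopifnot(length(dim(x)) == 3L, dim(x)[3] == 3L)
    H <- dim(x)[1]; W <- dim(x)[2]; spp <- 3L; bits <- 8L; fmt <- 1L
    v <- as.integer(round(pmin(pmax(x, 0), 1) * 255))
    dim(v) <- dim(x)
    pix <- as.raw(aperm(v, c(3, 2, 1)))  # sample-interleaved, row-major
  } else if (type == "uint16") {
    stopifnot(is.matrix(x))
    H <- nrow(x); W <- ncol(x); spp <- 1L; bits <- 16L; fmt <- 1L
    v <- as.integer(x)
    if (any(v < 0L | v > 65535L)) stop("uint16 TIFF: values out of range")
    dim(v) <- dim(x)
    pix <- u16le(as.vector(t(v)))
  } else {
    stopifnot(is.matrix(x))
    H <- nrow(x); W <- ncol(x); spp <- 1L; bits <- 32L; fmt <- 3L
    pix <- writeBin(as.vector(t(x)), raw(), size = 4L, endian = "little")
  }
  ## tag triplets: id, tiff type (3 = SHORT, 4 = LONG), value or offset
  entries <- list()
  add <- function(id, tt, count, value, extra = NULL) {
    entries[[length(entries) + 1L]] <<- list(id = id, tt = tt, count = count,
                                             value = value, extra = extra)
  }
  nbits <- rep(bits, spp)
  add(256L, 4L, 1L, W)
  add(257L, 4L, 1L, H)
  if (spp == 1L) add(258L, 3L, 1L, bits) else add(258L, 3L, spp, NA,
                                                  u16le(nbits))
  add(259L, 3L, 1L, 1L)                        # no compression
  add(262L, 3L, 1L, if (spp == 3L) 2L else 1L) # RGB / BlackIsZero
  add(273L, 4L, 1L, NA, "strip")               # strip offset, patched below
  add(277L, 3L, 1L, spp)
  add(278L, 4L, 1L, H)
  add(279L, 4L, 1L, length(pix))
  add(284L, 3L, 1L, 1L)                        # chunky planar config
  if (fmt != 1L) add(339L, 3L, 1L, fmt)
  n <- length(entries)
  ifd_start <- 8L
  extra_start <- ifd_start + 2L + 12L * n + 4L
  extra <- raw(0)
  for (i in seq_len(n)) {
    e <- entries[[i]]
    if (!is.null(e$extra) && is.raw(e$extra)) {
      entries[[i]]$value <- extra_start + length(extra)
      extra <- c(extra, e$extra)
    }
  }
  data_start <- extra_start + length(extra)
  for (i in seq_len(n)) {
    if (identical(entries[[i]]$extra, "strip")) entries[[i]]$value <- data_start
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42L, 0L))), con)
  writeBin(u32le(ifd_start), con)
  writeBin(u16le(n), con)
  for (e in entries) {
    writeBin(u16le(e$id), con)
    writeBin(u16le(e$tt), con)
    writeBin(u32le(e$count), con)
    writeBin(u32le(e$value), con)
  }
  writeBin(u32le(0L), con)  # no further IFDs
  if (length(extra)) writeBin(extra, con)
  writeBin(pix, con)
  invisible(path)
}

read_u <- function(raw, off, nbytes) {
  ## little-endian unsigned integer as double
  sum(as.numeric(raw[off + seq_len(nbytes)]) * 256^(seq_len(nbytes) - 1))
}

#' Read an uncompressed baseline TIFF written by [write_tiff()]
#'
#' Also reads equivalent files from other tools as long as they are
#' uncompressed, little-endian, strip-based and chunky-planar.
#'
#' @param path file path.
#' @return an H x W x 3 array in \[0,1\] (8-bit RGB), an integer matrix
#'   (8/16-bit single channel) or a numeric matrix (32-bit float).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!identical(rawToChar(raw[1:2]), "II") || read_u(raw, 2, 2) != 42) {
    stop(path, ": not a little-endian TIFF", call. = FALSE)
  }
  ifd <- read_u(raw, 4, 4)
  n <- read_u(raw, ifd, 2)
  tags <- list()
  tsize <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  for (i in seq_len(n)) {
    off <- ifd + 2 + 12 * (i - 1)
    id <- read_u(raw, off, 2)
    tt <- read_u(raw, off + 2, 2)
    count <- read_u(raw, off + 4, 4)
    esz <- tsize[tt]
    nb <- esz * count
    voff <- if (nb <= 4) off + 8 else read_u(raw, off + 8, 4)
    vals <- vapply(seq_len(count), function(j) {
      read_u(raw, voff + (j - 1) * esz, esz)
    }, numeric(1))
    tags[[as.character(id)]] <- vals
  }
  gt <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  W <- gt(256); H <- gt(257)
  bits <- gt(258, 1)[1]
  comp <- gt(259, 1)
  spp <- gt(277, 1)
  fmt <- gt(339, 1)[1]
  planar <- gt(284, 1)
  if (comp != 1) stop(path, ": compressed TIFF not supported", call. = FALSE)
  if (planar != 1) stop(path, ": planar TIFF not supported", call. = FALSE)
  offs <- gt(273); counts <- gt(279, rep(H * W * spp * bits / 8, length(offs)))
  pix <- raw(0)
  for (i in seq_along(offs)) {
    pix <- c(pix, raw[offs[i] + seq_len(counts[i])])
  }
  npx <- H * W * spp
  if (fmt == 3 && bits == 32) {
    v <- readBin(pix, "numeric", n = npx, size = 4L, endian = "little")
    return(matrix(v, H, W, byrow = TRUE))
  }
  if (bits == 8) {
    v <- as.integer(pix)
  } else if (bits == 16) {
    v <- readBin(pix, "integer", n = npx, size = 2L, signed = FALSE,
                 endian = "little")
  } else {
    stop(path, ": unsupported bit depth ", bits, call. = FALSE)
  }
  if (spp == 1) return(matrix(v, H, W, byrow = TRUE))
  if (spp != 3) stop(path, ": unsupported samples per pixel ", spp)
  a <- array(v, c(3, W, H))
  aperm(a, c(3, 2, 1)) / 255
}
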