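# Minimal MRC/MRCS I/O: mode-2 (32-bit float) volumes and stacks with the
# standard 1024-byte header, little-endian, pixel size stored in cella/mx.
# This is a deliberately small subset of the MRC2014 layout sufficient for
# movie stacks and 2D spectra; extended headers are not written and are
# skipped on read.

#' Write a matrix or image stack to an MRC/MRCS file
#'
#' @param data A numeric matrix (single image) or a list of equally sized
#'   matrices (stack; use an `.mrcs` path by convention).
#' @param path Output file path.
#' @param pixel_size Pixel size in Angstrom, stored in the header cell.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, pixel_size = 1) {
  if (is.matrix(data)) data <- list(data)
  stopifnot(length(data) >= 1, all(vapply(data, is.matrix, TRUE)))
  nx <- nrow(data[[1]]); ny <- ncol(data[[1]]); nz <- length(data)
  if (!all(vapply(data, function(f) all(dim(f) == c(nx, ny)), TRUE))) {
    stop("all frames must have identical dimensions", call. = FALSE)
  }
  vals <- unlist(data, use.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz, 2L, 0L, 0L, 0L, nx, ny, nz))       # words 1-10
  wf(c(nx, ny, nz) * pixel_size)                      # cella
  wf(c(90, 90, 90))                                   # cellb
  wi(c(1L, 2L, 3L))                                   # mapc/mapr/maps
  wf(c(min(vals), max(vals), mean(vals)))             # dmin/dmax/dmean
  wi(c(0L, 0L))                                       # ispg, nsymbt
  wi(rep(0L, 25L))                                    # extra, words 25-49
  wf(c(0, 0, 0))                                      # origin, words 50-52
  writeChar("MAP ", con, nchars = 4, eos = NULL)      # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)    # little-endian stamp
  wf(stats::sd(vals))                                 # rms
  wi(1L)                                              # nlabl
  lab <- formatC("icemotion", width = -80)
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeBin(raw(720), con)                             # remaining labels
  wf(vals)
  invisible(path)
}

#' Read an MRC/MRCS file written in mode 2
#'
#' @param path File path.
#' @return A list with elements `frames` (list of matrices), `pixel_size`
#'   (Angstrom) and `dims` (nx, ny, nz).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4, endian = "little")
  h1 <- ri(10)
  nx <- h1[1]; ny <- h1[2]; nz <- h1[3]; mode <- h1[4]
  if (mode != 2L) {
    stop(sprintf("unsupported MRC mode %d (only mode 2 float is handled)",
                 mode), call. = FALSE)
  }
  cella <- rf(3)
  rf(3); ri(3); rf(3)
  ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + max(0L, nsymbt))
  vals <- rf(nx * ny * nz)
  frames <- lapply(seq_len(nz), function(z) {
    matrix(vals[((z - 1) * nx * ny + 1):(z * nx * ny)], nx, ny)
  })
  px <- if (h1[8] > 0) cella[1] / h1[8] else 1
  list(frames = frames, pixel_size = px, dims = c(nx, ny, nz))
}
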