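# Minimal MRC/MRCS (mode 2, 32-bit float, little-endian) reader and writer.
# No MRC-capable package exists in the R stack this package builds against,
# so the 1024-byte header is handled directly; only the fields the workflow
# needs (dimensions, mode, cell size) are interpreted.

#' Read an MRC/MRCS file (mode 2 float)
#'
#' @param path path to an `.mrc`/`.mrcs` file.
#' @return A list with `data` (array of dim nx x ny x nz), `spacing`
#'   (voxel/pixel size in Angstrom, from cella/mx) and `header` (named list
#'   of the parsed header fields).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mxyz <- ints[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (mode != 2) stop("only MRC mode 2 (float32) is supported; got mode ", mode)
  seek(con, 1024)
  v <- readBin(con, "numeric", n = nx * ny * nz, size = 4, endian = "little")
  spacing <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  list(data = array(v, c(nx, ny, nz)), spacing = spacing,
       header = list(nx = nx, ny = ny, nz = nz, mode = mode,
                     mx = mxyz[1], my = mxyz[2], mz = mxyz[3],
                     cella = cella))
}

#' Write an array as an MRC/MRCS file (mode 2 float)
#'
#' 2-D matrices are written as single-section volumes; a 3-D array is a
#' volume (or, for stacks, `nz` images).
#'
#' @param data numeric matrix or 3-D array.
#' @param path output path.
#' @param spacing voxel/pixel size in Angstrom (stored via cella).
#' @param is_stack logical; mark the file as an image stack (ispg = 0).
#' @export
write_mrc <- function(data, path, spacing = 1, is_stack = FALSE) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  d <- dim(data)
  stopifnot(length(d) == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")                         # n*, mode, nstart, m*
  writeBin(as.numeric(d * spacing), con, size = 4, endian = "little") # cella
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 2, 3)), con, size = 4, endian = "little")  # map
  v <- as.numeric(data)
  writeBin(as.numeric(c(min(v), max(v), mean(v))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(if (is_stack) 0L else 1L, 0L)), con, size = 4,
           endian = "little")                         # ispg, nsymbt
  writeBin(raw(100), con)                             # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little") # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)    # machst little-endian
  writeBin(as.numeric(stats::sd(v)), con, size = 4, endian = "little")
  writeBin(as.integer(0), con, size = 4, endian = "little")  # nlabl
  writeBin(raw(800), con)                             # labels
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}
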