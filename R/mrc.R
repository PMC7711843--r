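# MRC2014 (CCP-EM) volume input/output.
#
# Only the standard single-volume layout is supported: axis order
# mapc/mapr/maps = 1/2/3, data modes 0 (int8), 1 (int16), 2 (float32) and
# 6 (uint16); volumes are always written as mode 2. Voxel sizes are stored
# in the header cell dimensions in Angstrom and exposed as nm.

MRC_HEADER_BYTES <- 1024L

#' Write a volume as an MRC file
#'
#' Writes a `tomo_volume` as a little-endian MRC2014 mode-2 (32-bit float)
#' map. The voxel size is recorded in the header cell dimensions (Angstrom)
#' and the physical origin in the header origin words.
#'
#' @param vol a [tomo_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_mrc()]
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "tomo_volume"))
  d <- dim(vol$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  g <- vol$grid
  wi(d)                                   # nx ny nz
  wi(2L)                                  # mode 2 = float32
  wi(c(0L, 0L, 0L))                       # nxstart nystart nzstart
  wi(d)                                   # mx my mz
  wf(d * vol$voxel_size * 10)             # cella (Angstrom)
  wf(c(90, 90, 90))                       # cellb
  wi(c(1L, 2L, 3L))                       # mapc mapr maps
  wf(c(min(g), max(g), mean(g)))          # dmin dmax dmean
  wi(1L)                                  # ispg (volume)
  wi(0L)                                  # nsymbt
  wi(integer(2))                          # extra words 26-27
  writeChar("MRCO", con, nchars = 4, eos = NULL)  # exttyp
  wi(20140L)                              # nversion
  wi(integer(21))                         # remaining extra words
  wf(vol$origin * 10)                     # origin (Angstrom)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little endian
  wf(stats::sd(as.numeric(g)))            # rms
  wi(1L)                                  # nlabl
  lab <- sprintf("%-80s", "tomodock synthetic/processed volume")
  writeChar(substr(lab, 1, 80), con, nchars = 80, eos = NULL)
  writeBin(raw(720), con)                 # labels 2-10
  writeBin(as.numeric(g), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC volume
#'
#' Reads an MRC/CCP4-style map into a [tomo_volume()]. Grid values of
#' mode-2 files round-trip bit-exactly through [write_mrc()]. Integer modes
#' (0, 1, 6) are converted to double; any other mode is rejected with an
#' error naming the offending header field.
#'
#' @param path MRC file path.
#' @return A [tomo_volume()]; `metadata` records the header mode and pixel
#'   size in Angstrom.
#' @export
read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < MRC_HEADER_BYTES)
    stop("corrupt MRC header: file shorter than 1024 bytes")
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_raw <- readBin(con, "raw", MRC_HEADER_BYTES)
  machst <- hdr_raw[213:216]
  if (identical(as.integer(machst[1]), 0x11L)) endian <- "big"
  ri <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)], "integer",
                                 n, size = 4L, endian = endian)
  rf <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)], "numeric",
                                 n, size = 4L, endian = endian)
  nxyz <- ri(0, 3)
  mode <- ri(12, 1)
  mxyz <- ri(28, 3)
  cella <- rf(40, 3)
  mapcrs <- ri(64, 3)
  nsymbt <- ri(92, 1)
  origin <- rf(196, 3)
  map_id <- rawToChar(hdr_raw[209:212])
  if (!identical(substr(map_id, 1, 3), "MAP"))
    stop("corrupt MRC header: MAP identifier missing (field `map`)")
  if (any(nxyz < 1L))
    stop(sprintf("invalid MRC header field nx/ny/nz: grid %d x %d x %d has a zero or negative dimension",
                 nxyz[1], nxyz[2], nxyz[3]))
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop(sprintf("unsupported MRC axis order (field mapc/mapr/maps = %d/%d/%d); only 1/2/3 is supported",
                 mapcrs[1], mapcrs[2], mapcrs[3]))
  n <- prod(nxyz)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE,
                             endian = endian)),
    "2" = readBin(con, "numeric", n, size = 4L, endian = endian),
    "6" = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                             endian = endian)),
    stop(sprintf("unsupported MRC data mode (field `mode` = %d); supported modes: 0, 1, 2, 6", mode))
  )
  if (length(data) < n)
    stop("corrupt MRC file: data section shorter than nx*ny*nz voxels")
  mx <- ifelse(mxyz > 0, mxyz, nxyz)
  pix_ang <- cella[1] / mx[1]
  if (!is.finite(pix_ang) || pix_ang <= 0)
    stop("invalid MRC header field cella: non-positive voxel size")
  tomo_volume(array(data, nxyz), voxel_size = pix_ang / 10,
              origin = origin / 10,
              metadata = list(mrc_mode = mode, pixel_size_angstrom = pix_ang,
                              source = path))
}
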