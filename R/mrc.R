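#' Read an MRC2014 density map
#'
#' Parses the 1024-byte MRC header and the data block. Modes 0 (int8),
#' 1 (int16), 2 (float32) and 6 (uint16) are supported; data are returned
#' as doubles. The voxel size is taken from the cell dimensions divided
#' by the sampling (`cella / mx`) and must be isotropic.
#'
#' @param path path to an MRC file.
#' @return A [density_volume].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stop("truncated MRC header in ", path, call. = FALSE)

  endian <- "little"
  machst <- hdr_raw[213:216]  # word 54
  if (as.integer(machst[1]) == 0x11) endian <- "big"

  int_at <- function(word, n = 1)
    readBin(hdr_raw[((word - 1) * 4 + 1):((word - 1 + n) * 4)], "integer",
            n = n, size = 4, endian = endian)
  flt_at <- function(word, n = 1)
    readBin(hdr_raw[((word - 1) * 4 + 1):((word - 1 + n) * 4)], "numeric",
            n = n, size = 4, endian = endian)

  nxyz <- int_at(1, 3)
  mode <- int_at(4)
  mxyz <- int_at(8, 3)
  cella <- flt_at(11, 3)
  nsymbt <- int_at(24)
  if (any(nxyz < 1) || any(nxyz > 1e5))
    stop("implausible dimensions in MRC header (nx/ny/nz)", call. = FALSE)
  if (any(mxyz < 1)) stop("invalid sampling in MRC header (mx/my/mz)", call. = FALSE)

  voxel <- cella / mxyz
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    stop("invalid cell dimensions in MRC header (cella)", call. = FALSE)
  if (diff(range(voxel)) > 1e-4 * mean(voxel))
    stop(sprintf(
      "anisotropic voxel size in MRC header (cella/mx = %.5g, %.5g, %.5g)",
      voxel[1], voxel[2], voxel[3]), call. = FALSE)

  if (nsymbt > 0) {
    skip <- readBin(con, "raw", n = nsymbt)
    if (length(skip) < nsymbt) stop("truncated MRC file: ", path, call. = FALSE)
  }
  n <- prod(nxyz)
  data <- switch(as.character(mode),
    "0" = as.double(readBin(con, "integer", n = n, size = 1, signed = TRUE,
                            endian = endian)),
    "1" = as.double(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                            endian = endian)),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = endian),
    "6" = as.double(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                            endian = endian)),
    stop("unsupported MRC mode: ", mode, call. = FALSE))
  if (length(data) < n)
    stop("truncated MRC file: expected ", n, " voxels, got ", length(data),
         call. = FALSE)
  density_volume(array(data, dim = nxyz), voxel_size = mean(voxel))
}

#' Write a density volume as an MRC2014 map
#'
#' Writes mode-2 (float32) little-endian maps with the cell set to
#' `dim * voxel_size` and the min/max/mean/rms statistics filled in.
#'
#' @param v a [density_volume].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(v, path) {
  stopifnot(is_density_volume(v))
  d <- dim(v$data)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")

  vals <- v$data
  wi(d)                       # nx ny nz
  wi(2L)                      # mode: float32
  wi(c(0L, 0L, 0L))           # nxstart
  wi(d)                       # mx my mz
  wf(d * v$voxel_size)        # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))
  wi(1L)                      # ispg: volume
  wi(0L)                      # nsymbt
  wi(rep(0L, 2))              # extra words 25-26
  writeChar("    ", con, nchars = 4, eos = NULL)  # exttyp (unset)
  wi(20140L)                  # nversion
  wi(rep(0L, 21))             # remaining extra words
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sqrt(mean((vals - mean(vals))^2)))             # rms
  wi(1L)                      # nlabl
  lab <- formatC("tomatch", width = -80)
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(strrep(" ", 80 * 9), con, nchars = 80 * 9, eos = NULL)
  wf(vals)
  invisible(path)
}
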