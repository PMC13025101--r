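# Portable spectrum container: one little-endian float64 binary file holding
# all quadrature components (column-major, components last) plus a JSON
# sidecar header with the shape, acquisition metadata and noise sigma.

#' Export / import a spectrum in the portable container format
#'
#' `exportSpectrum` writes `<stem>.bin` (float64, little-endian,
#' column-major) and `<stem>.json` (shape, complex-point counts, zero-fill
#' factors, apodization, quadrature layout, sigma-noise, byte order).
#' `importSpectrum` restores the [NMRSpectrum-class]; the round trip is
#' exact.
#'
#' @param spectrum an [NMRSpectrum-class].
#' @param stem file stem (no extension).
#' @return `importSpectrum` returns the restored [NMRSpectrum-class];
#'   `exportSpectrum` the stem, invisibly.
#' @export
exportSpectrum <- function(spectrum, stem) {
  g <- spectrum@grid
  meta <- list(format = "p3nmr-spectrum-1", byteOrder = "little",
               dtype = "float64", dim = dim(spectrum@components),
               points = g@points, zeroFill = g@zeroFill, apod = g@apod,
               sigmaNoise = spectrum@sigmaNoise)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(spectrum@components), con, size = 8L, endian = "little")
  invisible(stem)
}

#' @rdname exportSpectrum
#' @export
importSpectrum <- function(stem) {
  metaPath <- paste0(stem, ".json")
  if (!file.exists(metaPath)) stop("missing sidecar header: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (!identical(meta$format, "p3nmr-spectrum-1"))
    stop("unrecognized container format in ", metaPath)
  nDims <- length(meta$dim) - 1L
  if (!nDims %in% c(1L, 2L, 3L))
    stop("unsupported spectrum dimensionality: ", nDims, "D")
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = prod(meta$dim), size = 8L, endian = "little")
  if (length(x) != prod(meta$dim))
    stop("binary payload shorter than the header-declared shape (",
         length(x), " of ", prod(meta$dim), " values)")
  grid <- acqGrid(meta$points, meta$zeroFill, meta$apod)
  sn <- if (is.null(meta$sigmaNoise) || is.na(meta$sigmaNoise)) NA_real_
        else as.numeric(meta$sigmaNoise)
  newSpectrum(array(x, dim = meta$dim), grid, sn)
}
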