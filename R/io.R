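#' Write a raw image to disk
#'
#' Writes the pixel array as a 16-bit grayscale TIFF (pixel values rounded to
#' integer digital units and clipped to `[0, 65535]`) or as a lossless
#' float64 NPY raster, plus a JSON sidecar (`<path>.json`) holding the
#' preset, the breast mask (run-length encoded), and the provenance chain.
#'
#' @param image a [raw_image()].
#' @param path output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.npy`).
#' @return `path`, invisibly.
#' @export
write_raw_image <- function(image, path) {
  stopifnot(inherits(image, "raw_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- pmin(pmax(round(image$pixels), 0), 65535)
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16)
  } else if (ext == "npy") {
    write_npy(image$pixels, path)
  } else stop("unsupported raster format: .", ext)
  mask_rle <- rle(as.vector(image$mask))
  sidecar <- list(id = image$id,
                  preset = unclass(image$preset),
                  shape = dim(image$pixels),
                  mask_rle = list(lengths = mask_rle$lengths,
                                  values = mask_rle$values),
                  provenance = image$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a raw image from disk
#'
#' Reads a 16-bit TIFF or float64 NPY raster written by [write_raw_image()]
#' (pixel data passed through unprocessed) together with its JSON sidecar.
#' 8-bit TIFF input is rejected.  DICOM is not supported by this build;
#' supply TIFF or NPY.
#'
#' @param path raster path.
#' @param preset optional [system_preset()] override when the sidecar is
#'   missing.
#' @return A [raw_image()].
#' @export
load_raw_image <- function(path, preset = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom"))
    stop("DICOM input is not supported; convert to 16-bit TIFF or NPY")
  px <- if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (!is.null(bits) && bits < 16)
      stop("expected a 16-bit TIFF, got ", bits, "-bit")
    attributes(x) <- list(dim = dim(x))
    x * 1.0
  } else if (ext == "npy") {
    read_npy(path)
  } else stop("unsupported raster format: .", ext)
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    preset <- system_preset(sc$preset$name, sc$preset$pixel_pitch,
                            sc$preset$gain, sc$preset$offset,
                            sc$preset$electronic_sigma, sc$preset$roi_side)
    mask <- matrix(inverse.rle(list(lengths = sc$mask_rle$lengths,
                                    values = sc$mask_rle$values)),
                   sc$shape[1], sc$shape[2])
    prov <- sc$provenance
    if (is.data.frame(prov)) prov <- split(prov, seq_len(nrow(prov)))
    raw_image(px, mask, preset, provenance = as.list(prov), id = sc$id)
  } else {
    if (is.null(preset))
      stop("no sidecar metadata found; supply a preset override")
    raw_image(px, matrix(1, nrow(px), ncol(px)), preset,
              id = tools::file_path_sans_ext(basename(path)))
  }
}

#' Minimal NPY v1.0 writer (float64, C order)
#'
#' @param x numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  stopifnot(is.matrix(x))
  hdr <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                 nrow(x), ncol(x))
  total <- 10 + nchar(hdr) + 1
  pad <- (64 - total %% 64) %% 64
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1, 0))), con)
  writeBin(as.integer(nchar(hdr)), con, size = 2, endian = "little")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(t(x)), con, size = 8, endian = "little")
  invisible(path)
}

#' Minimal NPY v1.0 reader (float64/uint16, C or Fortran order)
#'
#' @param path NPY file path.
#' @return numeric matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], c(as.raw(0x93), charToRaw("NUMPY"))))
    stop("not an NPY file")
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little",
                  signed = FALSE)
  hdr <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", hdr)
  fortran <- grepl("'fortran_order':\\s*True", hdr)
  shp <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", hdr)
  dims <- as.integer(strsplit(gsub("\\s", "", shp), ",")[[1]])
  if (length(dims) != 2) stop("only 2D NPY arrays are supported")
  n <- prod(dims)
  vals <- switch(descr,
    "<f8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "<u2" = readBin(con, "integer", n, size = 2, endian = "little",
                    signed = FALSE),
    stop("unsupported NPY dtype: ", descr))
  if (fortran) matrix(vals, dims[1], dims[2])
  else t(matrix(vals, dims[2], dims[1]))
}
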