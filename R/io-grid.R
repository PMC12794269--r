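#' Read a multi-page TIFF stack as a voxel grid
#'
#' Pages are stacked along z in file order; within a page, rows map to y
#' and columns to x (permute with `axis_order` for microscopes using a
#' different convention). If a `<path>.json` sidecar written by
#' [write_tiff_stack()] is present, its intensity scale factor is
#' re-applied so values round-trip.
#'
#' @param path TIFF file.
#' @param spacing length-3 voxel spacing (um) attached verbatim.
#' @param axis_order permutation of `c(1, 2, 3)` applied to the (x, y, z)
#'   axes after loading.
#' @return A [voxel_grid] with origin (0, 0, 0).
#' @export
read_tiff_stack <- function(path, spacing = c(0.65, 0.65, 2.0),
                            axis_order = c(1L, 2L, 3L)) {
  if (!file.exists(path)) stop("read_tiff_stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("read_tiff_stack: no pages in ", path)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L)
      stop("read_tiff_stack: page ", i, " has non-scalar pixels")
    if (!identical(dim(pages[[i]]), dim(pages[[1]])))
      stop("read_tiff_stack: page ", i, " shape differs from page 1")
  }
  scale <- 1
  mode <- "plain"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$scale)) scale <- as.numeric(meta$scale)
    if (!is.null(meta$mode)) mode <- meta$mode
  }
  if (mode == "integer") {
    # integer-valued stacks are stored as raw UInt32 samples: re-read
    # undecoded so the values round-trip exactly
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); nz <- length(pages)
  d <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) d[, , k] <- t(pages[[k]])
  d <- d * scale
  if (!identical(as.integer(axis_order), 1:3)) d <- aperm(d, axis_order)
  voxel_grid(d, spacing[axis_order], c(0, 0, 0))
}

#' Write a voxel grid as a multi-page TIFF stack
#'
#' Intensities are stored as 32-bit samples. Non-negative
#' integer-valued data (the common case for acquisition-like stacks)
#' are written as raw UInt32 values and round-trip exactly; general
#' real-valued data are scaled into `[0, 1]` by a power-of-two factor
#' and round-trip to 32-bit quantization (relative error < 1e-9). The
#' encoding, scale and grid calibration go into a `<path>.json`
#' sidecar.
#'
#' @param grid a [voxel_grid].
#' @param path output TIFF file.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (min(grid$data) < 0)
    stop("write_tiff_stack: negative intensities are not representable")
  integral <- all(grid$data == round(grid$data)) && max(grid$data) < 2^31
  if (integral) {
    mode <- "integer"; scale <- 1
    d <- grid$data / 4294967295
  } else {
    mode <- "scaled"
    scale <- 2^ceiling(log2(max(grid$data, 1)))
    d <- grid$data / scale
  }
  pages <- lapply(seq_len(dim(d)[3]), function(k) t(d[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(mode = mode, scale = scale, spacing = grid$spacing,
         origin = grid$origin, channel_name = grid$channel_name),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

vti_encode <- function(raw_bytes) {
  header <- writeBin(length(raw_bytes), raw(), size = 8,
                     endian = "little", useBytes = TRUE)
  paste0(jsonlite::base64_enc(header), jsonlite::base64_enc(raw_bytes))
}

vti_decode <- function(txt) {
  txt <- gsub("[[:space:]]", "", txt)
  # UInt64 header (8 bytes) occupies the first 12 base64 characters
  header <- jsonlite::base64_dec(substr(txt, 1, 12))
  nbytes <- sum(as.numeric(header) * 256^(0:7))
  data <- jsonlite::base64_dec(substr(txt, 13, nchar(txt)))
  if (length(data) < nbytes) stop("structured grid: truncated data array")
  readBin(data[seq_len(nbytes)], "double", n = nbytes / 8, size = 8,
          endian = "little")
}

#' Write a voxel grid as an XML ImageData (VTI-style) file
#'
#' Lossless structured-grid container used for all intermediate volumes:
#' data (Float64, base64-encoded), spacing and origin round-trip exactly
#' through [read_grid()].
#'
#' @param grid a [voxel_grid].
#' @param path output file (conventionally `.vti`).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  ext <- sprintf("0 %d 0 %d 0 %d", d[1] - 1L, d[2] - 1L, d[3] - 1L)
  payload <- vti_encode(writeBin(as.numeric(grid$data), raw(), size = 8,
                                 endian = "little"))
  doc <- xml2::xml_new_root(
    "VTKFile", type = "ImageData", version = "1.0",
    byte_order = "LittleEndian", header_type = "UInt64")
  img <- xml2::xml_add_child(
    doc, "ImageData", WholeExtent = ext,
    Origin = paste(sprintf("%.17g", grid$origin), collapse = " "),
    Spacing = paste(sprintf("%.17g", grid$spacing), collapse = " "))
  piece <- xml2::xml_add_child(img, "Piece", Extent = ext)
  pd <- xml2::xml_add_child(piece, "PointData",
                            Scalars = "intensity")
  arr <- xml2::xml_add_child(pd, "DataArray", type = "Float64",
                             Name = "intensity", format = "binary",
                             NumberOfComponents = "1")
  xml2::xml_set_attr(arr, "ChannelName", grid$channel_name)
  xml2::xml_text(arr) <- payload
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an XML ImageData (VTI-style) file written by [write_grid()]
#'
#' @param path input file.
#' @return A [voxel_grid].
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("read_grid: no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path, options = c("NOBLANKS", "HUGE")),
                  error = function(e) stop("read_grid: not a structured-grid file: ",
                                           path, " (", conditionMessage(e), ")"))
  img <- xml2::xml_find_first(doc, "//ImageData")
  if (inherits(img, "xml_missing"))
    stop("read_grid: no ImageData element in ", path)
  ext <- as.integer(strsplit(xml2::xml_attr(img, "WholeExtent"), " +")[[1]])
  dims <- c(ext[2] - ext[1] + 1L, ext[4] - ext[3] + 1L, ext[6] - ext[5] + 1L)
  origin <- as.numeric(strsplit(xml2::xml_attr(img, "Origin"), " +")[[1]])
  spacing <- as.numeric(strsplit(xml2::xml_attr(img, "Spacing"), " +")[[1]])
  arr <- xml2::xml_find_first(doc, "//DataArray[@Name='intensity']")
  vals <- vti_decode(xml2::xml_text(arr))
  if (length(vals) != prod(dims))
    stop("read_grid: data length ", length(vals), " does not match extent ",
         prod(dims), " in ", path)
  ch <- xml2::xml_attr(arr, "ChannelName")
  voxel_grid(array(vals, dims), spacing, origin,
             if (is.na(ch)) "" else ch)
}
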