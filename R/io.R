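# Image and volume I/O: grayscale/RGB PNG and TIFF images for the
# transparency protocol, multi-page TIFF and NRRD volumes for stacks.
# Intensities are kept in floating point in memory; integer exports embed
# the quantization scale in the file description so round trips restore
# detector units.

REC601 <- c(0.299, 0.587, 0.114)

otc_meta_json <- function(...) {
  jsonlite::toJSON(list(opticlear = list(...)), auto_unbox = TRUE, digits = NA)
}

otc_meta_parse <- function(description) {
  if (is.null(description)) return(NULL)
  meta <- tryCatch(jsonlite::fromJSON(description), error = function(e) NULL)
  if (is.list(meta)) meta$opticlear else NULL
}

#' Write a 2-D intensity image
#'
#' TIFF (`.tif`/`.tiff`) supports 8/16-bit integer and 32-bit float
#' exports; PNG supports 8-bit.  Integer exports quantize
#' `round(pmax(v, 0) * (2^bits - 1) / max_value)` and record the scale in
#' the file so [read_gray_image()] restores detector units; the
#' quantization step is `max_value / (2^bits - 1)`.
#'
#' @param image Numeric matrix.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @param bits 8, 16 or `"float32"` (TIFF only).  Default 16 for TIFF,
#'   8 for PNG.
#' @param max_value Intensity mapped to the top code; defaults to the image
#'   maximum.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, bits = NULL, max_value = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) otc_stop("image must be a numeric matrix", "otc_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!is.null(bits) && !identical(as.numeric(bits), 8)) {
      otc_stop("PNG export supports 8 bits only", "otc_io_error")
    }
    mv <- if (is.null(max_value)) max(image, 1e-12) else max_value
    png::writePNG(clip01(image / mv), path)
  } else if (ext %in% c("tif", "tiff")) {
    if (is.null(bits)) bits <- 16
    if (identical(bits, "float32")) {
      write_tiff(image, path, bits = "float32",
                 description = otc_meta_json(kind = "image"))
    } else {
      bits <- as.numeric(bits)
      if (!bits %in% c(8, 16)) otc_stop("bits must be 8, 16 or 'float32'", "otc_io_error")
      mv <- if (is.null(max_value)) max(image, 1e-12) else max_value
      scale <- (2^bits - 1) / mv
      dn <- pmin(round(pmax(image, 0) * scale), 2^bits - 1)
      write_tiff(dn, path, bits = sprintf("uint%d", bits),
                 description = otc_meta_json(kind = "image", scale = scale))
    }
  } else {
    otc_stop(sprintf("unsupported image extension '%s'", ext), "otc_io_error")
  }
  invisible(path)
}

rgb_to_luminance <- function(arr) {
  arr[, , 1] * REC601[1] + arr[, , 2] * REC601[2] + arr[, , 3] * REC601[3]
}

#' Read a 2-D intensity image
#'
#' Reads grayscale or RGB PNG/TIFF.  RGB is converted to luminance with
#' Rec. 601 weights (0.299, 0.587, 0.114).  Integer data are promoted to
#' floating point without rescaling (an 8-bit PNG yields values in
#' 0..255), except that TIFF files written by [write_gray_image()] carry
#' their quantization scale and are restored to detector units.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) otc_stop(sprintf("file not found: %s", path), "otc_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] >= 3L) img <- rgb_to_luminance(img) else img <- img[, , 1]
    }
    img * (2^depth - 1)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- read_tiff(path)
    page <- pages[[1L]]
    if (length(dim(page)) == 3L) page <- rgb_to_luminance(page)
    meta <- otc_meta_parse(attr(pages, "description"))
    if (!is.null(meta$scale)) page <- page / meta$scale
    page
  } else {
    otc_stop(sprintf("unsupported image extension '%s'", ext), "otc_io_error")
  }
}

#' Load a blank/sample image pair from disk
#'
#' @param blank_path,sample_path Paths to the blank (no-sample) and sample
#'   acquisitions; any format [read_gray_image()] accepts.
#' @param thickness_mm Sample thickness L in mm.
#' @param sample_id,condition Labels for the pair.
#' @return A [transmittance_pair()].
#' @export
load_image_pair <- function(blank_path, sample_path, thickness_mm,
                            sample_id = "sample", condition = "unknown") {
  blank <- read_gray_image(blank_path)
  sample <- read_gray_image(sample_path)
  transmittance_pair(blank, sample, thickness_mm,
                     sample_id = sample_id, condition = condition)
}

#' Export a fluorescence stack to a render-ready volume file
#'
#' Multi-page TIFF (`format = "tiff"`) or NRRD (`format = "nrrd"`), both
#' losslessly within the stored dtype and carrying the voxel spacing:
#' TIFF in this package's JSON description, NRRD in its `spacings` field.
#' `dtype = "float32"` stores values verbatim in single precision;
#' `"uint16"` stores rounded values (caller scales into 0..65535, e.g. via
#' [adjust_contrast_linear()] with `max_out = 65535`).
#'
#' @param stack A [fluorescence_stack()].
#' @param path Output path; extension is not consulted, `format` decides.
#' @param format `"tiff"` (default) or `"nrrd"`.
#' @param dtype `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @seealso [read_volume()]
#' @export
export_volume <- function(stack, path, format = c("tiff", "nrrd"),
                          dtype = c("float32", "uint16", "double")) {
  format <- match.arg(format)
  dtype <- match.arg(dtype)
  if (dtype == "double" && format != "nrrd") {
    otc_stop("dtype 'double' is only available for NRRD export", "otc_io_error")
  }
  if (!inherits(stack, "fluorescence_stack")) otc_stop("stack must be a fluorescence_stack", "otc_invalid_input")
  if (format == "tiff") {
    desc <- otc_meta_json(kind = "volume", channel = stack$channel,
                          spacing_um = stack$voxel_spacing_um)
    bits <- if (dtype == "float32") "float32" else "uint16"
    if (dtype == "uint16" && max(stack$voxels) > 65535) {
      otc_stop("values exceed the uint16 range; rescale before export", "otc_io_error")
    }
    write_tiff(stack$voxels, path, bits = bits, description = desc)
  } else {
    write_nrrd(stack, path, dtype = dtype)
  }
  invisible(path)
}

#' Read a volume written by [export_volume()]
#'
#' @param path Path to a multi-page TIFF or NRRD volume.
#' @param format `"auto"` (default; NRRD magic is sniffed), `"tiff"` or
#'   `"nrrd"`.
#' @return A [fluorescence_stack()] with spacing and channel restored when
#'   present in the file.
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") {
    head <- readBin(path, "raw", n = 4)
    format <- if (identical(rawToChar(head), "NRRD")) "nrrd" else "tiff"
  }
  if (format == "nrrd") return(read_nrrd(path))
  pages <- read_tiff(path)
  d <- c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]]))
  vox <- array(0, dim = d)
  for (z in seq_len(d[1])) vox[z, , ] <- pages[[z]]
  meta <- otc_meta_parse(attr(pages, "description"))
  fluorescence_stack(vox,
    channel = if (!is.null(meta$channel)) meta$channel else "",
    voxel_spacing_um = if (!is.null(meta$spacing_um)) as.numeric(meta$spacing_um) else c(1, 1, 1))
}

#' Write / read NRRD volumes
#'
#' Raw-encoded little-endian NRRD (format 0004) with per-axis spacings in
#' micrometers.  Data are stored x-fastest as the format prescribes; the
#' in-memory `(z, y, x)` axis order is restored on read.
#'
#' @param stack A [fluorescence_stack()].
#' @param path File path.
#' @param dtype `"float32"`, `"double"` or `"uint16"`.
#' @return `path` invisibly for the writer; a [fluorescence_stack()] for
#'   the reader.
#' @export
write_nrrd <- function(stack, path, dtype = c("float32", "double", "uint16")) {
  dtype <- match.arg(dtype)
  if (!inherits(stack, "fluorescence_stack")) otc_stop("stack must be a fluorescence_stack", "otc_invalid_input")
  d <- dim(stack$voxels)  # (z, y, x)
  type_name <- switch(dtype, float32 = "float", double = "double", uint16 = "uint16")
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "NRRD0004",
    "# generated by the opticlear package",
    sprintf("type: %s", type_name),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[3], d[2], d[1]),          # x y z, fastest first
    sprintf("spacings: %.10g %.10g %.10g", stack$voxel_spacing_um[3],
            stack$voxel_spacing_um[2], stack$voxel_spacing_um[1]),
    "encoding: raw",
    "endian: little",
    sprintf("content: %s", stack$channel),
    ""
  )
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  vals <- as.vector(aperm(stack$voxels, c(3, 2, 1)))  # x fastest
  if (dtype == "uint16") {
    vals <- round(vals)
    if (any(vals < 0) || any(vals > 65535)) otc_stop("values outside uint16 range", "otc_io_error")
    writeBin(raw2_le(vals), con)
  } else {
    writeBin(as.double(vals), con, size = if (dtype == "float32") 4 else 8,
             endian = "little")
  }
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10))
  hdr_end <- NA
  prev <- 0
  for (i in nl) {
    if (i == prev + 1) { hdr_end <- i; break }
    prev <- i
  }
  if (is.na(hdr_end)) otc_stop("malformed NRRD: no end of header", "otc_io_error")
  lines <- strsplit(rawToChar(bytes[1:(hdr_end - 1)]), "\n")[[1]]
  if (!startsWith(lines[1], "NRRD")) otc_stop("not an NRRD file", "otc_io_error")
  fields <- list()
  for (ln in lines[-1]) {
    if (startsWith(ln, "#")) next
    kv <- regmatches(ln, regexec("^([^:]+): (.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[kv[2]]] <- kv[3]
  }
  sizes <- as.integer(strsplit(fields$sizes, " ")[[1]])  # x y z
  spac <- if (!is.null(fields$spacings)) as.numeric(strsplit(fields$spacings, " ")[[1]]) else c(1, 1, 1)
  if (!identical(fields$encoding, "raw")) otc_stop("only raw NRRD encoding supported", "otc_io_error")
  data <- bytes[(hdr_end + 1):length(bytes)]
  n <- prod(sizes)
  vals <- switch(fields$type,
    float = readBin(data, "double", n = n, size = 4, endian = "little"),
    double = readBin(data, "double", n = n, size = 8, endian = "little"),
    uint16 = {
      m <- matrix(as.numeric(data[seq_len(2 * n)]), nrow = 2)
      m[1, ] + 256 * m[2, ]
    },
    otc_stop(sprintf("unsupported NRRD type '%s'", fields$type), "otc_io_error"))
  vox <- aperm(array(vals, dim = sizes), c(3, 2, 1))  # back to (z, y, x)
  fluorescence_stack(vox,
    channel = if (!is.null(fields$content)) fields$content else "",
    voxel_spacing_um = rev(spac))
}
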