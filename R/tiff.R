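# Minimal baseline TIFF codec (little-endian, uncompressed, grayscale or
# interleaved RGB, multi-page).  No TIFF library is available in the target
# R environment, so the subset of TIFF 6.0 this package needs is
# implemented here: enough to exchange 8/16-bit integer and 32-bit float
# single-channel images and stacks with standard readers.

TIFF_SHORT <- 3L
TIFF_LONG <- 4L
TIFF_ASCII <- 2L

raw2_le <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256))
}

raw4_le <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

int_from_le <- function(bytes) {
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

tiff_entry <- function(tag, type, count, value_bytes) {
  stopifnot(length(value_bytes) <= 4)
  c(raw2_le(tag), raw2_le(type), raw4_le(count),
    value_bytes, raw(4 - length(value_bytes)))
}

pixel_bytes <- function(values, bits, sample_format) {
  if (sample_format == 3L) {
    writeBin(as.double(values), raw(), size = 4, endian = "little")
  } else if (bits == 16L) {
    raw2_le(values)
  } else {
    as.raw(as.integer(values))
  }
}

#' Write a grayscale multi-page TIFF
#'
#' Writes pages as uncompressed little-endian baseline TIFF, one strip per
#' page.  `bits = "float32"` stores IEEE 754 single-precision values
#' verbatim; `"uint8"`/`"uint16"` store rounded integer values (the caller
#' is responsible for scaling into range).  An optional description string
#' (this package stores a small JSON with scale and voxel spacing) is
#' attached to the first page.
#'
#' @param pages A numeric matrix, a list of matrices, or a 3-D array in
#'   `(z, y, x)` order (each z-plane becomes a page).
#' @param path Output path.
#' @param bits `"uint16"` (default), `"uint8"` or `"float32"`.
#' @param description Optional ASCII string for the ImageDescription tag.
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(pages, path, bits = c("uint16", "uint8", "float32"),
                       description = NULL) {
  bits <- match.arg(bits)
  if (is.matrix(pages)) pages <- list(pages)
  if (is.array(pages) && length(dim(pages)) == 3L) {
    arr <- pages
    pages <- lapply(seq_len(dim(arr)[1]), function(z) matrix(arr[z, , ], dim(arr)[2], dim(arr)[3]))
  }
  if (!is.list(pages) || !all(vapply(pages, is.matrix, logical(1)))) {
    otc_stop("pages must be a matrix, list of matrices, or 3-D array", "otc_io_error")
  }
  nbits <- switch(bits, uint8 = 8L, uint16 = 16L, float32 = 32L)
  sfmt <- if (bits == "float32") 3L else 1L
  bytes_pp <- nbits / 8L
  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0)) else raw(0)
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), raw2_le(42L)), con)
  offset <- 8
  writeBin(raw4_le(offset), con)
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    h <- nrow(m); w <- ncol(m)
    use_desc <- p == 1L && length(desc_raw) > 0
    n_entries <- 10L + as.integer(use_desc)
    ifd_size <- 2 + 12 * n_entries + 4
    desc_off <- offset + ifd_size
    data_off <- desc_off + if (use_desc) length(desc_raw) else 0
    data_size <- h * w * bytes_pp
    pad <- data_size %% 2
    next_off <- if (p < length(pages)) data_off + data_size + pad else 0

    entries <- list(
      tiff_entry(256L, TIFF_LONG, 1L, raw4_le(w)),
      tiff_entry(257L, TIFF_LONG, 1L, raw4_le(h)),
      tiff_entry(258L, TIFF_SHORT, 1L, raw2_le(nbits)),
      tiff_entry(259L, TIFF_SHORT, 1L, raw2_le(1L)),
      tiff_entry(262L, TIFF_SHORT, 1L, raw2_le(1L))
    )
    if (use_desc) {
      entries <- c(entries, list(
        tiff_entry(270L, TIFF_ASCII, length(desc_raw), raw4_le(desc_off))))
    }
    entries <- c(entries, list(
      tiff_entry(273L, TIFF_LONG, 1L, raw4_le(data_off)),
      tiff_entry(277L, TIFF_SHORT, 1L, raw2_le(1L)),
      tiff_entry(278L, TIFF_LONG, 1L, raw4_le(h)),
      tiff_entry(279L, TIFF_LONG, 1L, raw4_le(data_size)),
      tiff_entry(339L, TIFF_SHORT, 1L, raw2_le(sfmt))
    ))
    writeBin(raw2_le(n_entries), con)
    for (e in entries) writeBin(e, con)
    writeBin(raw4_le(next_off), con)
    if (use_desc) writeBin(desc_raw, con)
    vals <- as.vector(t(m))  # TIFF is row-major
    if (sfmt == 1L) {
      vals <- round(vals)
      if (any(vals < 0) || any(vals > 2^nbits - 1)) {
        otc_stop(sprintf("pixel values outside the %d-bit range; scale before writing", nbits),
                 "otc_io_error")
      }
    }
    writeBin(pixel_bytes(vals, nbits, sfmt), con)
    if (pad) writeBin(raw(1), con)
    offset <- next_off
  }
  invisible(path)
}

read_tag_values <- function(bytes, type, count, value_field, all_bytes) {
  # types other than BYTE/ASCII/SHORT/LONG (e.g. RATIONAL resolutions) are
  # not needed by this package and are skipped
  size <- switch(as.character(type), `3` = 2L, `4` = 4L, `2` = 1L, `1` = 1L)
  if (is.null(size)) return(NULL)
  total <- size * count
  src <- if (total <= 4) value_field[seq_len(total)] else {
    off <- int_from_le(value_field)
    all_bytes[(off + 1):(off + total)]
  }
  if (type == TIFF_ASCII) return(rawToChar(src[src != as.raw(0)]))
  vapply(seq_len(count), function(i) {
    int_from_le(src[((i - 1) * size + 1):(i * size)])
  }, numeric(1))
}

#' Read a (subset of) TIFF file
#'
#' Reads the files produced by [write_tiff()] and, more generally,
#' little-endian uncompressed TIFFs with 8/16-bit unsigned integer or
#' 32-bit float samples, 1 (grayscale) or 3 (interleaved RGB) samples per
#' pixel, in one or more strips.  Compressed, big-endian, tiled or planar
#' files are rejected with a descriptive error.
#'
#' @param path Path to a TIFF file.
#' @return A list of pages: matrices (grayscale) or `h x w x 3` arrays
#'   (RGB), with the first page's ImageDescription (if any) in
#'   `attr(, "description")`.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) otc_stop(sprintf("file not found: %s", path), "otc_io_error")
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8) otc_stop("not a TIFF file (truncated header)", "otc_io_error")
  order_tag <- rawToChar(bytes[1:2])
  if (order_tag == "MM") otc_stop("big-endian TIFF not supported", "otc_io_error")
  if (order_tag != "II" || int_from_le(bytes[3:4]) != 42) {
    otc_stop("not a TIFF file (bad magic)", "otc_io_error")
  }
  ifd_off <- int_from_le(bytes[5:8])
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    n <- int_from_le(bytes[(ifd_off + 1):(ifd_off + 2)])
    tags <- list()
    for (i in seq_len(n)) {
      e0 <- ifd_off + 2 + (i - 1) * 12
      tag <- int_from_le(bytes[(e0 + 1):(e0 + 2)])
      type <- int_from_le(bytes[(e0 + 3):(e0 + 4)])
      count <- int_from_le(bytes[(e0 + 5):(e0 + 8)])
      val <- bytes[(e0 + 9):(e0 + 12)]
      tags[[as.character(tag)]] <- read_tag_values(bytes, type, count, val, bytes)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) otc_stop("TIFF page missing dimensions", "otc_io_error")
    nbits <- g(258, 1)[1]
    if (!is.null(g(259)) && g(259) != 1) otc_stop("compressed TIFF not supported", "otc_io_error")
    spp <- g(277, 1)
    sfmt <- g(339, 1)[1]
    if (!is.null(g(284)) && g(284) != 1) otc_stop("planar TIFF not supported", "otc_io_error")
    if (!nbits %in% c(8, 16, 32)) otc_stop(sprintf("unsupported bit depth %d", nbits), "otc_io_error")
    if (nbits == 32 && sfmt != 3) otc_stop("32-bit integer TIFF not supported", "otc_io_error")
    if (!spp %in% c(1, 3)) otc_stop("only 1- or 3-sample TIFF supported", "otc_io_error")
    if (is.null(description) && !is.null(g(270))) description <- g(270)

    offs <- g(273); counts <- g(279)
    if (is.null(offs) || is.null(counts)) otc_stop("TIFF page missing strip layout", "otc_io_error")
    data <- do.call(c, lapply(seq_along(offs), function(i) {
      bytes[(offs[i] + 1):(offs[i] + counts[i])]
    }))
    n_px <- w * h * spp
    vals <- if (nbits == 32) {
      readBin(data, "double", n = n_px, size = 4, endian = "little")
    } else if (nbits == 16) {
      m <- matrix(as.numeric(data), nrow = 2)
      m[1, ] + 256 * m[2, ]
    } else {
      as.numeric(data)
    }
    page <- if (spp == 1) {
      matrix(vals, h, w, byrow = TRUE)
    } else {
      # interleaved RGB: fastest index is channel, then column, then row
      a <- array(vals, dim = c(3, w, h))
      aperm(a, c(3, 2, 1))
    }
    pages[[length(pages) + 1L]] <- page
    nxt0 <- ifd_off + 2 + n * 12
    ifd_off <- int_from_le(bytes[(nxt0 + 1):(nxt0 + 4)])
  }
  attr(pages, "description") <- description
  pages
}
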