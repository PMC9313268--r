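# Light-sheet stack container and the processing chain: 3x3 median
# filtering, Fourier-notch destriping, linear contrast adjustment and
# maximum-intensity projection.  Axis order is (z, y, x), 1-based in R.

#' A 3-D fluorescence stack
#'
#' @param voxels 3-D numeric array in `(z, y, x)` order, finite and
#'   nonnegative.
#' @param channel Channel label (e.g. `"nuclei-405/475"`).
#' @param voxel_spacing_um Positive voxel spacing `(z, y, x)` in micrometers.
#' @return An object of class `fluorescence_stack`.
#' @export
fluorescence_stack <- function(voxels, channel = "",
                               voxel_spacing_um = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.numeric(voxels)) {
    otc_stop("voxels must be a numeric 3-D array (z, y, x)", "otc_invalid_input")
  }
  if (anyNA(voxels) || any(!is.finite(voxels)) || any(voxels < 0)) {
    otc_stop("voxel values must be finite and nonnegative", "otc_invalid_input")
  }
  if (length(voxel_spacing_um) != 3L || any(!is.finite(voxel_spacing_um)) ||
      any(voxel_spacing_um <= 0)) {
    otc_stop("voxel_spacing_um must be three positive numbers", "otc_invalid_input")
  }
  structure(list(voxels = voxels, channel = as.character(channel),
                 voxel_spacing_um = as.numeric(voxel_spacing_um)),
            class = "fluorescence_stack")
}

#' @export
print.fluorescence_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<fluorescence_stack> '%s' %d x %d x %d (z,y,x), spacing %g/%g/%g um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_spacing_um[1], x$voxel_spacing_um[2], x$voxel_spacing_um[3]))
  invisible(x)
}

as_stack_like <- function(stack) {
  if (inherits(stack, "fluorescence_stack")) return(stack)
  if (is.array(stack) && length(dim(stack)) == 3L) return(fluorescence_stack(stack))
  otc_stop("expected a fluorescence_stack or a 3-D array", "otc_invalid_input")
}

rebuild_stack <- function(stack, voxels) {
  fluorescence_stack(voxels, channel = stack$channel,
                     voxel_spacing_um = stack$voxel_spacing_um)
}

# Median of nine equal-length vectors via a 19-exchange sorting network
# (Paeth), vectorized over all pixels of a plane at once.
median9 <- function(p) {
  s <- function(a, b) {
    lo <- pmin(p[[a]], p[[b]]); hi <- pmax(p[[a]], p[[b]])
    p[[a]] <<- lo; p[[b]] <<- hi
  }
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 2); s(4, 5); s(7, 8)
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 4); s(6, 9); s(5, 8)
  s(4, 7); s(2, 5); s(3, 6)
  s(5, 8); s(5, 3); s(7, 5)
  s(5, 3)
  p[[5]]
}

median_filter_plane <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  # reflection (edge-repeat) padding
  mp <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  shifts <- list()
  k <- 1L
  for (dr in 0:2) for (dc in 0:2) {
    shifts[[k]] <- mp[dr + seq_len(nr), dc + seq_len(nc)]
    k <- k + 1L
  }
  out <- median9(shifts)
  matrix(out, nr, nc)
}

#' 3x3 median filter
#'
#' Filters each z-plane independently with a 3x3 spatial median to remove
#' salt-and-pepper noise; borders are handled by reflection padding, so
#' dimensions are unchanged.
#'
#' @param stack A [fluorescence_stack()] (or bare 3-D array) whose planes
#'   are at least 3x3.
#' @return A filtered stack of the same class and shape.
#' @export
median_filter_3x3 <- function(stack) {
  stack <- as_stack_like(stack)
  d <- dim(stack$voxels)
  if (d[2] < 3L || d[3] < 3L) {
    otc_stop("z-planes must be at least 3x3 for a 3x3 median filter", "otc_invalid_input")
  }
  out <- stack$voxels
  for (z in seq_len(d[1])) out[z, , ] <- median_filter_plane(out[z, , ])
  rebuild_stack(stack, out)
}

#' Destriping parameters
#'
#' @param stripe_axis In-plane axis along which stripe intensity is
#'   constant: `"x"` (default; stripes run along columns of each z-plane)
#'   or `"y"`.
#' @param notch_width Half-width of the suppressed frequency band, in
#'   frequency bins; the notch tapers with a Gaussian profile of this
#'   standard deviation.
#' @param damping Suppression factor in `[0, 1]`: 1 removes the band
#'   entirely, 0 leaves the plane untouched.
#' @return An object of class `destripe_params`.
#' @export
destripe_params <- function(stripe_axis = "x", notch_width = 2, damping = 1) {
  if (!stripe_axis %in% c("x", "y")) otc_stop("stripe_axis must be 'x' or 'y'", "otc_invalid_input")
  if (!is_scalar_num(notch_width) || notch_width <= 0) otc_stop("notch_width must be positive", "otc_invalid_input")
  if (!is_scalar_num(damping) || damping < 0 || damping > 1) otc_stop("damping must lie in [0, 1]", "otc_invalid_input")
  structure(list(stripe_axis = stripe_axis, notch_width = notch_width,
                 damping = damping), class = "destripe_params")
}

# Signed FFT bin frequencies in units of bins: 0, 1, ..., n/2, -(n/2-1), ..., -1
fft_bin_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n)
}

destripe_weight <- function(ny, nx, params) {
  # A stripe pattern constant along `stripe_axis` concentrates its spectral
  # energy on the line where the frequency along that axis is zero.  The
  # notch attenuates coefficients near that line (Gaussian taper across the
  # stripe-axis frequency), leaving the DC term untouched so the plane mean
  # is preserved.
  fy <- fft_bin_freq(ny); fx <- fft_bin_freq(nx)
  if (params$stripe_axis == "x") {
    taper <- exp(-(fx^2) / (2 * params$notch_width^2))
    w <- 1 - params$damping * matrix(taper, ny, nx, byrow = TRUE)
  } else {
    taper <- exp(-(fy^2) / (2 * params$notch_width^2))
    w <- 1 - params$damping * matrix(taper, ny, nx)
  }
  w[1, 1] <- 1  # DC
  w
}

#' Remove stripe artifacts with a directional Fourier notch filter
#'
#' Light-sheet stacks show dark streaks along the illumination axis where
#' opaque particles block the sheet.  This operator suppresses, in the 2-D
#' Fourier spectrum of each z-plane, the coefficients whose frequency along
#' the stripe axis is near zero (a Gaussian-tapered notch of half-width
#' `notch_width` bins scaled by `damping`), excluding the DC term.  The
#' result is clipped to nonnegative values and rescaled so each plane mean
#' is preserved exactly (clipping alone would bias it upward on planes with
#' bright structures).  It is a documented, parameterized stand-in for
#' proprietary destriping tools and is recorded as such in processing logs.
#'
#' @param stack A [fluorescence_stack()] or 3-D array.
#' @param params A [destripe_params()].
#' @return The destriped stack, clipped to nonnegative values.
#' @export
remove_stripes <- function(stack, params = destripe_params()) {
  stack <- as_stack_like(stack)
  if (!inherits(params, "destripe_params")) otc_stop("params must be destripe_params", "otc_invalid_input")
  d <- dim(stack$voxels)
  w <- destripe_weight(d[2], d[3], params)
  out <- stack$voxels
  for (z in seq_len(d[1])) {
    plane <- matrix(out[z, , ], d[2], d[3])
    spec <- stats::fft(plane) * w
    filt <- pmax(Re(stats::fft(spec, inverse = TRUE)) / (d[2] * d[3]), 0)
    # clipping negatives (ringing around bright structures) raises the mean
    # that the untouched DC term would otherwise preserve; rescale to restore
    # the plane mean exactly
    m0 <- mean(plane); m1 <- mean(filt)
    if (m1 > 0 && m0 > 0) filt <- filt * (m0 / m1)
    out[z, , ] <- filt
  }
  rebuild_stack(stack, out)
}

#' Spectral energy in the stripe band of one plane
#'
#' Diagnostic companion of [remove_stripes()]: the summed squared modulus
#' of the 2-D Fourier coefficients within `notch_width` bins of the
#' zero-frequency line along the stripe axis, excluding DC.  Destriping
#' quality is the relative reduction of this quantity.
#'
#' @param plane Numeric matrix (one z-plane, y by x).
#' @param stripe_axis `"x"` or `"y"`.
#' @param notch_width Band half-width in bins.
#' @return Summed band energy (nonnegative scalar).
#' @export
stripe_band_energy <- function(plane, stripe_axis = "x", notch_width = 2) {
  spec <- Mod(stats::fft(plane))^2
  fy <- fft_bin_freq(nrow(plane)); fx <- fft_bin_freq(ncol(plane))
  in_band <- if (stripe_axis == "x") {
    matrix(abs(fx) <= notch_width, nrow(plane), ncol(plane), byrow = TRUE)
  } else {
    matrix(abs(fy) <= notch_width, nrow(plane), ncol(plane))
  }
  in_band[1, 1] <- FALSE
  sum(spec[in_band])
}

#' Linear brightness/contrast adjustment
#'
#' Affine rescale mapping the `low` percentile of the whole stack to 0 and
#' the `high` percentile to `max_out`, clipping outside.  Percentiles are
#' computed over the full stack, not per plane, so the adjustment is
#' consistent across z.
#'
#' @param stack A [fluorescence_stack()] or 3-D array.
#' @param low,high Percentiles in `[0, 100]`, `low < high`.  Defaults
#'   `(1, 99.8)`.
#' @param max_out Output maximum (default 1; use 65535 before a 16-bit
#'   export).
#' @return The adjusted stack with values in `[0, max_out]`.
#' @export
adjust_contrast_linear <- function(stack, low = 1, high = 99.8, max_out = 1) {
  stack <- as_stack_like(stack)
  if (!is_scalar_num(low) || !is_scalar_num(high) ||
      low < 0 || high > 100 || low >= high) {
    otc_stop("percentiles must satisfy 0 <= low < high <= 100", "otc_invalid_input")
  }
  q <- stats::quantile(stack$voxels, c(low, high) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    otc_stop("degenerate intensity range: low and high percentiles coincide", "otc_degenerate_range")
  }
  rebuild_stack(stack, clip01((stack$voxels - q[1]) / (q[2] - q[1])) * max_out)
}

#' Maximum-intensity projection
#'
#' @param stack A [fluorescence_stack()] or 3-D array.
#' @param axis Axis to project along: `"z"` (default), `"y"` or `"x"`, or
#'   the corresponding index 1-3.
#' @return A 2-D matrix of per-ray maxima over the remaining two axes, in
#'   their original order.
#' @export
max_intensity_projection <- function(stack, axis = "z") {
  stack <- as_stack_like(stack)
  ax <- if (is.character(axis)) match(axis, c("z", "y", "x")) else as.integer(axis)
  if (is.na(ax) || ax < 1L || ax > 3L) otc_stop("axis must be 'z', 'y', 'x' or 1..3", "otc_invalid_input")
  apply(stack$voxels, setdiff(1:3, ax), max)
}

#' Standard stack-processing pipeline
#'
#' Applies, in order: 3x3 median filtering (optional), stripe removal
#' (optional) and linear contrast adjustment (optional) — the order used
#' for light-sheet visualization pipelines.
#'
#' @param stack A [fluorescence_stack()] or 3-D array.
#' @param median Apply the 3x3 median filter first (default `TRUE`).
#' @param destripe `NULL` to skip, or a [destripe_params()].
#' @param contrast `NULL` to skip, or `c(low, high)` percentiles.
#' @param max_out Output maximum for the contrast step.
#' @return The processed stack.
#' @export
process_stack <- function(stack, median = TRUE, destripe = destripe_params(),
                          contrast = c(1, 99.8), max_out = 1) {
  stack <- as_stack_like(stack)
  if (isTRUE(median)) stack <- median_filter_3x3(stack)
  if (!is.null(destripe)) stack <- remove_stripes(stack, destripe)
  if (!is.null(contrast)) {
    stack <- adjust_contrast_linear(stack, contrast[1], contrast[2], max_out = max_out)
  }
  stack
}
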