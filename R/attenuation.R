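# Beer-Lambert attenuation estimation from paired bright-field images with
# the randomized region-sampling protocol: a few small regions per run, many
# runs per image, several images per sample, all region-level coefficients
# pooled into one mean +/- SEM per sample.

#' Paired blank/sample transmittance images
#'
#' Bundles the two bright-field exposures of one transparency measurement:
#' the blank illumination image \eqn{I_0} (acquired without the sample) and
#' the sample image \eqn{I}, together with the light path length L.
#'
#' Individual pixels may be slightly negative when the acquisition carries
#' zero-mean read noise; region statistics handle this by flooring region
#' means, so the constructor only requires finite values.
#'
#' @param blank_image,sample_image Numeric matrices of identical dimensions,
#'   detector units.
#' @param thickness_mm Sample thickness L in mm; must be positive.
#' @param sample_id,condition Labels identifying the sample and its clearing
#'   condition (e.g. uncleared / BABB / CUBIC).
#' @return An object of class `transmittance_pair`.
#' @export
transmittance_pair <- function(blank_image, sample_image, thickness_mm,
                               sample_id = "sample", condition = "unknown") {
  if (!is.matrix(blank_image) || !is.matrix(sample_image) ||
      !is.numeric(blank_image) || !is.numeric(sample_image)) {
    otc_stop("blank_image and sample_image must be numeric matrices", "otc_invalid_input")
  }
  if (!identical(dim(blank_image), dim(sample_image))) {
    otc_stop(sprintf("image dimension mismatch: blank %dx%d vs sample %dx%d",
                     nrow(blank_image), ncol(blank_image),
                     nrow(sample_image), ncol(sample_image)),
             "otc_dimension_mismatch")
  }
  if (anyNA(blank_image) || anyNA(sample_image) ||
      any(!is.finite(blank_image)) || any(!is.finite(sample_image))) {
    otc_stop("images must contain only finite values", "otc_invalid_input")
  }
  if (!is_scalar_num(thickness_mm) || thickness_mm <= 0) {
    otc_stop("thickness_mm must be a positive number", "otc_invalid_input")
  }
  structure(list(
    blank_image = blank_image, sample_image = sample_image,
    thickness_mm = thickness_mm,
    sample_id = as.character(sample_id), condition = as.character(condition)
  ), class = "transmittance_pair")
}

#' @export
print.transmittance_pair <- function(x, ...) {
  cat(sprintf("<transmittance_pair> %s [%s], %d x %d px, L = %g mm\n",
              x$sample_id, x$condition,
              nrow(x$blank_image), ncol(x$blank_image), x$thickness_mm))
  invisible(x)
}

#' Rectangular image region
#'
#' Regions use 0-based, row-major pixel coordinates with the origin at the
#' top-left corner; the extent is half-open `[origin, origin + size)`.
#'
#' @param row_origin,col_origin 0-based origin of the region.
#' @param height_px,width_px Region extent in pixels, at least 1.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(row_origin, col_origin, height_px, width_px) {
  if (row_origin < 0 || col_origin < 0 || !is_count(height_px) || !is_count(width_px)) {
    otc_stop("region origin must be >= 0 and sizes positive integers", "otc_invalid_input")
  }
  structure(list(row_origin = as.integer(row_origin),
                 col_origin = as.integer(col_origin),
                 height_px = as.integer(height_px),
                 width_px = as.integer(width_px)),
            class = "region_spec")
}

#' Region-sampling protocol parameters
#'
#' Defaults follow the published protocol: 3 randomly placed regions per
#' run, 15 runs per image, each region covering 15% of the image (of each
#' linear dimension in `"linear"` mode; of the area, i.e. side fraction
#' `sqrt(region_fraction)`, in `"area"` mode).
#'
#' @param regions_per_run Regions drawn per run (default 3).
#' @param runs_per_image Runs executed on each image (default 15).
#' @param region_fraction Fraction of the image covered by each region
#'   (default 0.15); interpretation set by `fraction_mode`.
#' @param fraction_mode `"linear"` (default) or `"area"`.
#' @param seed Integer seed driving the whole protocol.
#' @param max_resample Attempts to replace a degenerate (dark) region before
#'   the protocol fails (default 10).
#' @return An object of class `protocol_params`.
#' @export
protocol_params <- function(regions_per_run = 3, runs_per_image = 15,
                            region_fraction = 0.15,
                            fraction_mode = c("linear", "area"),
                            seed = 1L, max_resample = 10) {
  fraction_mode <- match.arg(fraction_mode)
  if (!is_count(regions_per_run) || !is_count(runs_per_image)) {
    otc_stop("regions_per_run and runs_per_image must be positive integers", "otc_invalid_input")
  }
  if (!is_scalar_num(region_fraction) || region_fraction <= 0 || region_fraction > 1) {
    otc_stop("region_fraction must lie in (0, 1]", "otc_invalid_input")
  }
  structure(list(regions_per_run = as.integer(regions_per_run),
                 runs_per_image = as.integer(runs_per_image),
                 region_fraction = region_fraction,
                 fraction_mode = fraction_mode,
                 seed = as.integer(seed),
                 max_resample = as.integer(max_resample)),
            class = "protocol_params")
}

region_side <- function(extent, fraction, mode) {
  f <- if (mode == "area") sqrt(fraction) else fraction
  max(1L, as.integer(round_half_up(f * extent)))
}

#' Draw random measurement regions
#'
#' Draws `regions_per_run` axis-aligned regions whose sides are the rounded
#' `region_fraction` of the corresponding image dimension (half-up rounding,
#' minimum 1 px), with origins uniform over all valid placements.  Regions
#' may overlap.  The draw consumes the *current* RNG state; [run_protocol()]
#' seeds it per image.
#'
#' @param image_height_px,image_width_px Image dimensions.
#' @param params A [protocol_params()].
#' @return A list of [region_spec()] of length `regions_per_run`.
#' @export
sample_regions <- function(image_height_px, image_width_px,
                           params = protocol_params()) {
  h <- region_side(image_height_px, params$region_fraction, params$fraction_mode)
  w <- region_side(image_width_px, params$region_fraction, params$fraction_mode)
  if (h > image_height_px || w > image_width_px) {
    otc_stop("image is smaller than one measurement region", "otc_invalid_input")
  }
  lapply(seq_len(params$regions_per_run), function(i) {
    region_spec(sample.int(image_height_px - h + 1L, 1L) - 1L,
                sample.int(image_width_px - w + 1L, 1L) - 1L,
                h, w)
  })
}

#' Beer-Lambert attenuation coefficient of one region
#'
#' Computes \eqn{\mu = \ln(\bar I_0 / \bar I) / L} from the region means of
#' the blank and the sample image: one logarithm of the ratio of means, not
#' the mean of per-pixel logarithms, matching a bulk measurement of the
#' light transmitted through the patch and staying robust when single
#' pixels approach zero.  The same pixel coordinates are read from both
#' images (the blank is a position-dependent illumination field).
#'
#' The result may be slightly negative on noisy near-transparent regions;
#' it is deliberately not clipped so that averaging many regions stays
#' unbiased.  Region means are floored at `eps` before the ratio; a region
#' whose mean does not exceed `eps` raises a degenerate-region error that
#' [run_protocol()] answers by resampling.
#'
#' @param pair A [transmittance_pair()].
#' @param region A [region_spec()] fully inside the image.
#' @param eps Intensity floor in detector units (default `1e-6`).
#' @return A list with `mu` (1/mm), `mean_blank`, `mean_sample`, `region`.
#' @export
region_mu <- function(pair, region, eps = 1e-6) {
  if (!inherits(pair, "transmittance_pair")) otc_stop("pair must be a transmittance_pair", "otc_invalid_input")
  if (!inherits(region, "region_spec")) otc_stop("region must be a region_spec", "otc_invalid_input")
  h <- nrow(pair$blank_image); w <- ncol(pair$blank_image)
  r0 <- region$row_origin; c0 <- region$col_origin
  if (r0 + region$height_px > h || c0 + region$width_px > w) {
    otc_stop(sprintf("region [%d+%d, %d+%d) exceeds image bounds %dx%d",
                     r0, region$height_px, c0, region$width_px, h, w),
             "otc_region_out_of_bounds")
  }
  rows <- (r0 + 1L):(r0 + region$height_px)
  cols <- (c0 + 1L):(c0 + region$width_px)
  mean_blank <- mean(pair$blank_image[rows, cols])
  mean_sample <- mean(pair$sample_image[rows, cols])
  if (!is.finite(mean_sample) || mean_sample <= eps || !is.finite(mean_blank) || mean_blank <= eps) {
    otc_stop("degenerate region: mean intensity at or below the floor", "otc_degenerate_region")
  }
  list(mu = log(max(mean_blank, eps) / max(mean_sample, eps)) / pair$thickness_mm,
       mean_blank = mean_blank, mean_sample = mean_sample, region = region)
}

measure_one_region <- function(pair, params) {
  h <- nrow(pair$blank_image); w <- ncol(pair$blank_image)
  for (attempt in seq_len(params$max_resample + 1L)) {
    reg <- sample_regions(h, w, protocol_params(
      regions_per_run = 1, runs_per_image = 1,
      region_fraction = params$region_fraction,
      fraction_mode = params$fraction_mode))[[1L]]
    res <- tryCatch(region_mu(pair, reg), otc_degenerate_region = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  otc_stop(sprintf("image '%s': all candidate regions degenerate after %d resampling attempts",
                   pair$sample_id, params$max_resample),
           "otc_protocol_failure")
}

#' Run the full region-sampling protocol on one sample
#'
#' For each image of the sample, performs `runs_per_image` runs; each run
#' draws `regions_per_run` random regions and computes one attenuation
#' coefficient per region.  All region-level coefficients are pooled as the
#' individual measurements and collapsed to a grand mean and its standard
#' error.  At the defaults with three images this yields
#' 3 regions x 15 runs x 3 images = 135 measurements per sample.
#'
#' Each image consumes an independent RNG substream derived from
#' `params$seed` by a fixed offset, so results are reproducible and adding
#' an image never perturbs the regions drawn on earlier images.
#'
#' @param pairs A [transmittance_pair()] or list of them, all belonging to
#'   one sample (same `sample_id` and `condition`).
#' @param params A [protocol_params()].
#' @return An object of class `sample_attenuation_summary`: fields
#'   `sample_id`, `condition`, `measurements` (a data frame with one row
#'   per individual measurement), `mu_mean`, `mu_sem`, `n_measurements`.
#' @examples
#' spec <- transmittance_phantom_spec(128, 128, mu = 2, thickness_mm = 1.5)
#' pairs <- lapply(1:3, function(i) {
#'   s <- spec; s$seed <- i
#'   generate_transmittance_pair(s, sample_id = "demo")
#' })
#' run_protocol(pairs, protocol_params(seed = 42))
#' @export
run_protocol <- function(pairs, params = protocol_params()) {
  if (inherits(pairs, "transmittance_pair")) pairs <- list(pairs)
  if (length(pairs) < 1L) otc_stop("at least one image pair is required", "otc_invalid_input")
  if (!all(vapply(pairs, inherits, logical(1), "transmittance_pair"))) {
    otc_stop("pairs must be transmittance_pair objects", "otc_invalid_input")
  }
  ids <- unique(vapply(pairs, `[[`, character(1), "sample_id"))
  conds <- unique(vapply(pairs, `[[`, character(1), "condition"))
  if (length(ids) != 1L || length(conds) != 1L) {
    otc_stop("all pairs must share one sample_id and condition", "otc_invalid_input")
  }
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pair <- pairs[[i]]
    rows[[i]] <- with_seed(image_substream_seed(params$seed, i - 1L), {
      out <- vector("list", params$runs_per_image * params$regions_per_run)
      k <- 1L
      for (run in seq_len(params$runs_per_image)) {
        for (r in seq_len(params$regions_per_run)) {
          m <- measure_one_region(pair, params)
          out[[k]] <- data.frame(
            sample_id = pair$sample_id, condition = pair$condition,
            image_index = i - 1L, run_index = run - 1L, region_index = r - 1L,
            row_origin = m$region$row_origin, col_origin = m$region$col_origin,
            height_px = m$region$height_px, width_px = m$region$width_px,
            mean_blank = m$mean_blank, mean_sample = m$mean_sample,
            mu = m$mu, stringsAsFactors = FALSE)
          k <- k + 1L
        }
      }
      do.call(rbind, out)
    })
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  n <- nrow(measurements)
  mu <- measurements$mu
  structure(list(
    sample_id = ids, condition = conds, measurements = measurements,
    mu_mean = mean(mu),
    mu_sem = if (n > 1L) stats::sd(mu) / sqrt(n) else 0,
    n_measurements = n
  ), class = "sample_attenuation_summary")
}

#' @export
print.sample_attenuation_summary <- function(x, ...) {
  cat(sprintf("<sample_attenuation_summary> %s [%s]\n", x$sample_id, x$condition))
  cat(sprintf("  mu = %.4f +/- %.4f mm^-1 (mean +/- SEM, n = %d measurements)\n",
              x$mu_mean, x$mu_sem, x$n_measurements))
  invisible(x)
}
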