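# Synthetic phantoms: bright-field transmittance pairs with known attenuation
# and SPIM-like fluorescence stacks with known corruption, used as ground
# truth for the measurement protocol and the processing chain.

#' Noise models for the transmittance phantom
#'
#' `noise_none()` disables noise.  `noise_gaussian(sd)` adds zero-mean
#' Gaussian read noise with standard deviation `sd` detector units,
#' independently to the blank and the sample exposure (two separate camera
#' acquisitions).  Gaussian noise is *not* clipped at zero: it models read
#' noise after offset subtraction, and clipping would bias region means of
#' very dark samples upward, destroying attenuation recovery at high
#' \eqn{\mu L}.  `noise_poisson()` replaces each pixel with a Poisson draw
#' whose mean is the clean intensity (shot noise; intensities are then
#' interpreted as photon counts), which is nonnegative by construction.
#'
#' @param sd Standard deviation of the Gaussian read noise, detector units.
#' @return A noise-model object of class `otc_noise`.
#' @export
noise_none <- function() structure(list(type = "none"), class = "otc_noise")

#' @rdname noise_none
#' @export
noise_gaussian <- function(sd) {
  if (!is_scalar_num(sd) || sd < 0) otc_stop("gaussian noise sd must be a nonnegative number", "otc_invalid_spec")
  structure(list(type = "gaussian", sd = sd), class = "otc_noise")
}

#' @rdname noise_none
#' @export
noise_poisson <- function() structure(list(type = "poisson"), class = "otc_noise")

apply_noise <- function(img, noise) {
  switch(noise$type,
    none = img,
    gaussian = img + matrix(stats::rnorm(length(img), sd = noise$sd), nrow(img), ncol(img)),
    poisson = matrix(stats::rpois(length(img), lambda = pmax(img, 0)), nrow(img), ncol(img)),
    otc_stop(sprintf("unknown noise model '%s'", noise$type), "otc_invalid_spec")
  )
}

#' Specification of a bright-field transmittance phantom
#'
#' Describes the forward model of a paired transmitted-light acquisition: a
#' blank illumination image \eqn{I_0} (mean level `illumination` shaded by an
#' optional radial vignette) and a sample image
#' \eqn{I = I_0 e^{-\mu L}} inside the sample mask, both optionally
#' corrupted by noise.
#'
#' @param height_px,width_px Image dimensions in pixels.
#' @param mu True attenuation coefficient in 1/mm; a scalar or a
#'   `height_px` x `width_px` matrix. Must be nonnegative everywhere.
#' @param thickness_mm Sample thickness L in mm (light path length).
#' @param illumination Mean blank intensity in detector units.
#' @param vignette Vignette strength in `[0, 1)`: 0 gives flat illumination,
#'   larger values darken the corners with a cosine-fourth radial falloff.
#' @param noise A noise model from [noise_none()], [noise_gaussian()] or
#'   [noise_poisson()].
#' @param mask Optional logical matrix marking pixels occupied by tissue;
#'   default: the whole frame.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `transmittance_phantom_spec`.
#' @seealso [generate_transmittance_pair()]
#' @export
transmittance_phantom_spec <- function(height_px, width_px, mu = 1,
                                       thickness_mm = 1, illumination = 200,
                                       vignette = 0, noise = noise_none(),
                                       mask = NULL, seed = 1L) {
  if (!is_count(height_px) || !is_count(width_px)) {
    otc_stop("image dimensions must be positive integers", "otc_invalid_spec")
  }
  if (!is_scalar_num(thickness_mm) || thickness_mm <= 0) {
    otc_stop("thickness_mm must be a positive number", "otc_invalid_spec")
  }
  if (!is_scalar_num(illumination) || illumination <= 0) {
    otc_stop("illumination must be positive", "otc_invalid_spec")
  }
  if (!is_scalar_num(vignette) || vignette < 0 || vignette >= 1) {
    otc_stop("vignette must lie in [0, 1)", "otc_invalid_spec")
  }
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu < 0)) {
    otc_stop("mu must be finite and nonnegative everywhere", "otc_invalid_spec")
  }
  if (is.matrix(mu)) {
    if (!identical(dim(mu), c(as.integer(height_px), as.integer(width_px)))) {
      otc_stop("mu map dimensions must match the image dimensions", "otc_invalid_spec")
    }
  } else if (length(mu) != 1L) {
    otc_stop("mu must be a scalar or a matrix", "otc_invalid_spec")
  }
  if (!inherits(noise, "otc_noise")) otc_stop("noise must be an otc_noise object", "otc_invalid_spec")
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), c(as.integer(height_px), as.integer(width_px)))) {
      otc_stop("mask must be a logical matrix matching the image dimensions", "otc_invalid_spec")
    }
  }
  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    mu = mu, thickness_mm = thickness_mm, illumination = illumination,
    vignette = vignette, noise = noise, mask = mask, seed = as.integer(seed)
  ), class = "transmittance_phantom_spec")
}

# Radially symmetric cosine-fourth illumination falloff. 1 at the center,
# (1 - strength) at the corners; any smooth centered profile would do, this
# one is fixed for test stability.
vignette_field <- function(h, w, strength) {
  if (strength == 0) return(matrix(1, h, w))
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  r <- sqrt(outer(((seq_len(h) - cy))^2, ((seq_len(w) - cx))^2, `+`)) /
    sqrt((cy - 1)^2 + (cx - 1)^2)
  (1 - strength) + strength * cos(pmin(r, 1) * pi / 2)^4
}

#' Generate a paired blank/sample transmittance image
#'
#' Forward model of a two-exposure bright-field transparency measurement:
#' the blank image is the illumination field, the sample image is the blank
#' attenuated by \eqn{e^{-\mu L}} inside the sample mask.  Noise is applied
#' independently to the two exposures.  The true attenuation map is kept on
#' the returned pair (field `mu_true`) for recovery tests.
#'
#' @param spec A [transmittance_phantom_spec()].
#' @param sample_id,condition Labels attached to the generated pair.
#' @return A [transmittance_pair()] with extra fields `mu_true` (matrix),
#'   `mask`, and the noise-free `blank_clean`/`sample_clean` images.
#' @examples
#' spec <- transmittance_phantom_spec(64, 64, mu = 2, thickness_mm = 1.5,
#'                                    illumination = 200)
#' pair <- generate_transmittance_pair(spec)
#' range(pair$sample_image)  # 200 * exp(-3)
#' @export
generate_transmittance_pair <- function(spec, sample_id = "phantom",
                                        condition = "synthetic") {
  if (!inherits(spec, "transmittance_phantom_spec")) {
    otc_stop("spec must be a transmittance_phantom_spec", "otc_invalid_spec")
  }
  h <- spec$height_px; w <- spec$width_px
  mu_map <- if (is.matrix(spec$mu)) spec$mu else matrix(spec$mu, h, w)
  mask <- if (is.null(spec$mask)) matrix(TRUE, h, w) else spec$mask
  blank_clean <- spec$illumination * vignette_field(h, w, spec$vignette)
  atten <- exp(-mu_map * spec$thickness_mm)
  atten[!mask] <- 1  # no tissue outside the mask
  sample_clean <- blank_clean * atten
  out <- with_seed(spec$seed, {
    blank <- apply_noise(blank_clean, spec$noise)
    sample <- apply_noise(sample_clean, spec$noise)
    list(blank = blank, sample = sample)
  })
  pair <- transmittance_pair(out$blank, out$sample, spec$thickness_mm,
                             sample_id = sample_id, condition = condition)
  pair$mu_true <- mu_map
  pair$mask <- mask
  pair$blank_clean <- blank_clean
  pair$sample_clean <- sample_clean
  pair
}

#' Specification of a SPIM-like fluorescence stack phantom
#'
#' Describes a synthetic light-sheet volume: Gaussian nuclei blobs and
#' tubular vessel structures on a dark background, corrupted by a
#' multiplicative sinusoidal stripe pattern (constant along the illumination
#' axis, as cast by opaque particles blocking the sheet) and salt-and-pepper
#' impulse noise.
#'
#' @param shape_zyx Integer triple `(z, y, x)` of stack dimensions.
#' @param n_nuclei Number of Gaussian nuclei blobs.
#' @param nucleus_sigma_px Isotropic blob standard deviation, pixels.
#' @param n_vessels Number of straight tubular vessels.
#' @param vessel_radius_px Vessel tube radius, pixels.
#' @param stripe_axis In-plane axis along which stripes are constant
#'   (`"x"` or `"y"`; the light-sheet propagation axis).
#' @param stripe_amplitude Multiplicative stripe modulation depth in `[0, 1)`.
#' @param stripe_period_px Stripe period in pixels.
#' @param impulse_fraction Fraction of voxels replaced by impulse noise in
#'   `[0, 1)`; exactly `round(impulse_fraction * n_voxels)` voxels are
#'   corrupted (half to 0, half to the stack maximum).
#' @param amplitude Peak intensity of nuclei and vessels, arbitrary units.
#' @param background Constant background level added everywhere (camera
#'   offset plus autofluorescence); default 0.
#' @param seed Integer seed.
#' @return An object of class `stack_phantom_spec`.
#' @export
stack_phantom_spec <- function(shape_zyx, n_nuclei = 30, nucleus_sigma_px = 2,
                               n_vessels = 3, vessel_radius_px = 2,
                               stripe_axis = "x", stripe_amplitude = 0,
                               stripe_period_px = 8, impulse_fraction = 0,
                               amplitude = 1000, background = 0, seed = 1L) {
  if (length(shape_zyx) != 3L || !all(vapply(shape_zyx, is_count, logical(1)))) {
    otc_stop("shape_zyx must be three positive integers", "otc_invalid_spec")
  }
  if (!is_scalar_num(stripe_amplitude) || stripe_amplitude < 0 || stripe_amplitude >= 1) {
    otc_stop("stripe_amplitude must lie in [0, 1)", "otc_invalid_spec")
  }
  if (!is_scalar_num(impulse_fraction) || impulse_fraction < 0 || impulse_fraction >= 1) {
    otc_stop("impulse_fraction must lie in [0, 1)", "otc_invalid_spec")
  }
  if (!stripe_axis %in% c("x", "y")) {
    otc_stop("stripe_axis must be 'x' or 'y' (an in-plane axis)", "otc_invalid_spec")
  }
  if (!is_scalar_num(nucleus_sigma_px) || nucleus_sigma_px <= 0 ||
      !is_scalar_num(vessel_radius_px) || vessel_radius_px <= 0 ||
      !is_scalar_num(stripe_period_px) || stripe_period_px <= 0) {
    otc_stop("sigma, radius and period must be positive", "otc_invalid_spec")
  }
  if (!is.numeric(n_nuclei) || n_nuclei < 0 || !is.numeric(n_vessels) || n_vessels < 0) {
    otc_stop("object counts must be nonnegative", "otc_invalid_spec")
  }
  if (!is_scalar_num(background) || background < 0) {
    otc_stop("background must be a nonnegative number", "otc_invalid_spec")
  }
  structure(list(
    shape_zyx = as.integer(shape_zyx), n_nuclei = as.integer(n_nuclei),
    nucleus_sigma_px = nucleus_sigma_px, n_vessels = as.integer(n_vessels),
    vessel_radius_px = vessel_radius_px, stripe_axis = stripe_axis,
    stripe_amplitude = stripe_amplitude, stripe_period_px = stripe_period_px,
    impulse_fraction = impulse_fraction, amplitude = amplitude,
    background = background, seed = as.integer(seed)
  ), class = "stack_phantom_spec")
}

add_gaussian_blob <- function(vox, center, sigma, amplitude) {
  d <- dim(vox)
  half <- ceiling(3 * sigma)
  rng <- lapply(1:3, function(a) max(1, round(center[a]) - half):min(d[a], round(center[a]) + half))
  dz <- rng[[1]] - center[1]; dy <- rng[[2]] - center[2]; dx <- rng[[3]] - center[3]
  blob <- amplitude * exp(-(
    outer(outer(dz^2, dy^2, `+`), dx^2, `+`)) / (2 * sigma^2))
  vox[rng[[1]], rng[[2]], rng[[3]]] <- vox[rng[[1]], rng[[2]], rng[[3]]] + blob
  vox
}

add_tube <- function(vox, p0, p1, radius, amplitude) {
  d <- dim(vox)
  len <- sqrt(sum((p1 - p0)^2))
  n_steps <- max(2L, ceiling(len / 0.5))
  t <- seq(0, 1, length.out = n_steps)
  half <- ceiling(radius)
  off <- expand.grid(dz = -half:half, dy = -half:half, dx = -half:half)
  off <- off[off$dz^2 + off$dy^2 + off$dx^2 <= radius^2, , drop = FALSE]
  for (ti in t) {
    p <- round(p0 + ti * (p1 - p0))
    z <- p[1] + off$dz; y <- p[2] + off$dy; x <- p[3] + off$dx
    keep <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    if (any(keep)) {
      idx <- cbind(z[keep], y[keep], x[keep])
      vox[idx] <- amplitude
    }
  }
  vox
}

stripe_modulation <- function(shape, axis, amplitude, period) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  if (axis == "x") {
    # constant along x: modulation varies along y
    prof <- 1 + amplitude * sin(2 * pi * (seq_len(ny) - 1) / period)
    array(rep(rep(prof, each = nz), times = nx), dim = shape)
  } else {
    # constant along y: modulation varies along x
    prof <- 1 + amplitude * sin(2 * pi * (seq_len(nx) - 1) / period)
    array(rep(prof, each = nz * ny), dim = shape)
  }
}

#' Generate synthetic fluorescence stacks (nuclei and vessel channels)
#'
#' Builds one stack per channel: `nuclei` (Gaussian blobs, emulating a
#' nuclear stain) and `vessels` (straight tubes, emulating an endothelial
#' stain).  Both channels receive the same stripe modulation and impulse
#' corruption; the clean pre-corruption stacks are retained for
#' filter-quality tests, together with the exact indices of corrupted
#' voxels.
#'
#' @param spec A [stack_phantom_spec()].
#' @param voxel_spacing_um Voxel spacing `(z, y, x)` in micrometers.
#' @return A list of class `stack_phantom` with fluorescence stacks
#'   `nuclei` and `vessels`, their clean counterparts `nuclei_clean` /
#'   `vessels_clean`, and integer vectors `nuclei_impulse_idx` /
#'   `vessels_impulse_idx` of corrupted voxel indices.
#' @export
generate_fluorescence_stack <- function(spec, voxel_spacing_um = c(5, 1, 1)) {
  if (!inherits(spec, "stack_phantom_spec")) {
    otc_stop("spec must be a stack_phantom_spec", "otc_invalid_spec")
  }
  d <- spec$shape_zyx
  with_seed(spec$seed, {
    nuc <- array(spec$background, dim = d)
    if (spec$n_nuclei > 0) {
      centers <- cbind(stats::runif(spec$n_nuclei, 1, d[1]),
                       stats::runif(spec$n_nuclei, 1, d[2]),
                       stats::runif(spec$n_nuclei, 1, d[3]))
      for (i in seq_len(spec$n_nuclei)) {
        nuc <- add_gaussian_blob(nuc, centers[i, ], spec$nucleus_sigma_px, spec$amplitude)
      }
    }
    ves <- array(spec$background, dim = d)
    if (spec$n_vessels > 0) {
      for (i in seq_len(spec$n_vessels)) {
        p0 <- c(stats::runif(1, 1, d[1]), stats::runif(1, 1, d[2]), stats::runif(1, 1, d[3]))
        p1 <- c(stats::runif(1, 1, d[1]), stats::runif(1, 1, d[2]), stats::runif(1, 1, d[3]))
        ves <- add_tube(ves, p0, p1, spec$vessel_radius_px, spec$amplitude)
      }
    }
    corrupt <- function(clean) {
      out <- clean
      if (spec$stripe_amplitude > 0) {
        out <- out * stripe_modulation(d, spec$stripe_axis,
                                       spec$stripe_amplitude, spec$stripe_period_px)
      }
      n_bad <- round_half_up(spec$impulse_fraction * prod(d))
      idx <- integer(0)
      if (n_bad > 0) {
        idx <- sample.int(prod(d), n_bad)
        hi <- max(out, 1)
        n_pepper <- floor(n_bad / 2)
        out[idx[seq_len(n_pepper)]] <- 0
        out[idx[setdiff(seq_len(n_bad), seq_len(n_pepper))]] <- hi
      }
      list(stack = out, idx = sort(idx))
    }
    cn <- corrupt(nuc)
    cv <- corrupt(ves)
    structure(list(
      nuclei = fluorescence_stack(cn$stack, channel = "nuclei-405/475",
                                  voxel_spacing_um = voxel_spacing_um),
      vessels = fluorescence_stack(cv$stack, channel = "vessels-635/670",
                                   voxel_spacing_um = voxel_spacing_um),
      nuclei_clean = fluorescence_stack(nuc, channel = "nuclei-405/475",
                                        voxel_spacing_um = voxel_spacing_um),
      vessels_clean = fluorescence_stack(ves, channel = "vessels-635/670",
                                         voxel_spacing_um = voxel_spacing_um),
      nuclei_impulse_idx = cn$idx,
      vessels_impulse_idx = cv$idx
    ), class = "stack_phantom")
  })
}
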