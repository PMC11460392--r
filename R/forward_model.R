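# Forward measurement model: complex transmission object O (N x N), complex
# illumination probe P (M x M, M < N), scan offsets r = 1..R, and diffraction
# intensities I_r = |F(S_r(O) * P)|^2 with the unitary DFT.
#
# Coordinates are 0-based row/col top-left corners; the illuminated region of
# offset (i, j) is the half-open block [i, i+M) x [j, j+M).

#' Complex object transmission field
#'
#' @param values square complex matrix (dimensionless transmission; amplitude
#'   near or below 1, phase in radians).
#' @param pixel_size physical length per pixel (arbitrary but consistent
#'   units; used only by the spatial-frequency axis of FRC curves).
#' @return an `object_field`.
#' @export
object_field <- function(values, pixel_size = 1) {
  if (!is_square(values)) stopf("object values must be a square matrix")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stopf("object values must be finite")
  structure(list(values = as_complex(values), pixel_size = pixel_size),
            class = "object_field")
}

#' Complex probe illumination field
#'
#' @param values square complex matrix (amplitude in sqrt-photon units).
#' @param pixel_size length per pixel, same as the paired object.
#' @return a `probe_field`.
#' @export
probe_field <- function(values, pixel_size = 1) {
  if (!is_square(values)) stopf("probe values must be a square matrix")
  if (sum(Mod(values)^2) <= 0) stopf("probe must carry nonzero total power")
  structure(list(values = as_complex(values), pixel_size = pixel_size),
            class = "probe_field")
}

as_complex <- function(x) {
  if (!is.complex(x)) storage.mode(x) <- "complex"
  x
}

#' @export
print.object_field <- function(x, ...) {
  cat(sprintf("<object_field %dx%d, pixel_size=%g, |O| in [%.3g, %.3g]>\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(Mod(x$values)), max(Mod(x$values))))
  invisible(x)
}

#' @export
print.probe_field <- function(x, ...) {
  cat(sprintf("<probe_field %dx%d, pixel_size=%g, power=%.6g>\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              sum(Mod(x$values)^2)))
  invisible(x)
}

#' Scan plan
#'
#' @param offsets integer matrix with R rows and columns (row, col): 0-based
#'   top-left corners of the illuminated regions.
#' @param grid_meta list describing the generator (kind and parameters).
#' @return a `scan_plan`.
#' @export
scan_plan <- function(offsets, grid_meta = list(kind = "custom")) {
  offsets <- matrix(as.integer(offsets), ncol = 2,
                    dimnames = list(NULL, c("row", "col")))
  if (nrow(offsets) < 1) stopf("a scan plan needs at least one offset")
  structure(list(offsets = offsets, grid_meta = grid_meta),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf("<scan_plan %s, R=%d>\n", x$grid_meta$kind, nrow(x$offsets)))
  invisible(x)
}

check_plan_bounds <- function(plan, N, M) {
  hi <- N - M
  off <- plan$offsets
  bad <- which(off[, 1] < 0 | off[, 2] < 0 | off[, 1] > hi | off[, 2] > hi)
  if (length(bad))
    stopf("scan offset %d = (%d, %d) outside object bounds [0, %d]",
          bad[1], off[bad[1], 1], off[bad[1], 2], hi)
  invisible(TRUE)
}

#' Generate a scan plan
#'
#' `kind = "grid"` lays out a `rows x cols` lattice with spacing `step`
#' starting at (0, 0), optionally perturbed by uniform integer jitter in
#' `[-jitter, jitter]` per axis (jitter breaks the raster-grid ambiguity of
#' perfectly periodic scans; the default 0 keeps the plain lattice).
#' `kind = "fermat"` places `count` points on a Fermat spiral
#' r = spacing * sqrt(n) * 0.57, theta = n * 137.508 degrees, rounded to
#' integers, duplicates removed, centered in the available area.
#'
#' @param kind `"grid"` or `"fermat"`.
#' @param rows,cols,step grid parameters (step in pixels, >= 1).
#' @param jitter nonnegative integer jitter half-range for grid scans.
#' @param count,spacing Fermat parameters: number of points and the
#'   approximate nearest-neighbour spacing in pixels.
#' @param extent available offset range per axis, i.e. `N - M`; offsets are
#'   validated against `[0, extent]`.
#' @param seed integer seed (used by jitter; Fermat layout is deterministic).
#' @return a `scan_plan`.
#' @export
make_scan <- function(kind = c("grid", "fermat"), rows = 3, cols = rows,
                      step = 16, jitter = 0, count = 50, spacing = 8,
                      extent, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "grid") {
    if (step < 1) stopf("grid step must be >= 1 pixel")
    off <- as.matrix(expand.grid(row = (0:(rows - 1)) * step,
                                 col = (0:(cols - 1)) * step))
    if (jitter > 0) {
      j <- with_seed(seed, matrix(sample(-jitter:jitter, length(off),
                                         replace = TRUE), ncol = 2))
      off <- off + j
      off <- pmin(pmax(off, 0L), extent)
    }
    meta <- list(kind = "grid", rows = rows, cols = cols, step = step,
                 jitter = jitter, seed = seed)
  } else {
    if (spacing < 1) stopf("fermat spacing must be >= 1 pixel")
    # golden-angle spiral; 0.57 * spacing * sqrt(n) gives a median
    # nearest-neighbour distance close to `spacing`
    n <- seq_len(3 * count)   # oversample, keep first `count` unique points
    r <- 0.57 * spacing * sqrt(n)
    th <- n * 137.508 * pi / 180
    pts <- unique(round(cbind(r * sin(th), r * cos(th))))
    pts <- pts[seq_len(min(count, nrow(pts))), , drop = FALSE]
    if (nrow(pts) < count)
      stopf("could not place %d unique fermat points", count)
    off <- sweep(pts, 2, apply(pts, 2, min))      # shift to nonnegative
    ctr <- floor((extent - apply(off, 2, max)) / 2)
    off <- sweep(off, 2, pmax(ctr, 0), "+")
    meta <- list(kind = "fermat", count = count, spacing = spacing)
  }
  plan <- scan_plan(off, meta)
  hi <- extent
  bad <- which(plan$offsets < 0 | plan$offsets > hi)
  if (length(bad))
    stopf("scan offset index %d falls outside [0, %d]",
          ((bad[1] - 1) %% nrow(plan$offsets)) + 1, hi)
  plan
}

# Median nearest-neighbour distance between scan positions.
nn_step <- function(plan) {
  off <- plan$offsets
  if (nrow(off) < 2) stopf("nearest-neighbour step undefined for a single-position plan")
  d <- as.matrix(stats::dist(off))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

#' Linear overlap ratio of a scan plan
#'
#' Defined as `1 - step / probe_diameter`, clipped at 0, where `step` is the
#' median nearest-neighbour distance between scan positions. With the bump
#' probe, `probe_diameter = 2 * support_radius`. Decimating a grid scan by
#' factors 1, 2 and 2.5 of the step maps 75.0% to 50.0% and 37.5% overlap.
#'
#' @param plan a `scan_plan` with at least two positions.
#' @param probe_diameter probe support diameter in pixels.
#' @return overlap fraction in `[0, 1)`.
#' @export
overlap_ratio <- function(plan, probe_diameter) {
  if (probe_diameter <= 0) stopf("probe_diameter must be positive")
  max(0, 1 - nn_step(plan) / probe_diameter)
}

#' Bump-function probe
#'
#' Smooth compactly supported radial profile `exp(-1 / (1 - (r/R)^2))` inside
#' the support radius and exactly zero outside, rescaled to the requested
#' total power `sum(|P|^2)`. An optional quadratic (defocus-like) phase of
#' `phase_curvature` radians at the support edge models the wavefront
#' curvature of a real focused beam; leaving it at 0 gives the real bump
#' conventionally used as the *initial* probe estimate. A nonzero curvature
#' also breaks the centrosymmetric-conjugate (twin-image) degeneracy that a
#' purely real symmetric simulation probe would admit.
#'
#' @param M probe grid size.
#' @param support_radius support radius in pixels, `0 < radius <= M/2`.
#' @param total_power total integrated power in photons.
#' @param phase_curvature phase in radians at `r = support_radius` of the
#'   quadratic phase profile (0 = flat wavefront).
#' @return a `probe_field`.
#' @export
make_bump_probe <- function(M, support_radius, total_power = 1,
                            pixel_size = 1, phase_curvature = 0) {
  if (support_radius <= 0 || support_radius > M / 2)
    stopf("support_radius must lie in (0, M/2]")
  if (total_power <= 0) stopf("total_power must be positive")
  c0 <- (M - 1) / 2
  r2 <- outer((0:(M - 1) - c0)^2, (0:(M - 1) - c0)^2, "+") / support_radius^2
  v <- matrix(0, M, M)
  inside <- r2 < 1
  v[inside] <- exp(-1 / (1 - r2[inside]))
  v <- v * sqrt(total_power / sum(v^2))
  probe_field(v * exp(1i * phase_curvature * r2), pixel_size = pixel_size)
}

#' Particle phantom specification
#'
#' Describes a synthetic specimen: weakly absorbing disks (spherical-cap
#' thickness profile) on a vacuum background, emulating a particle-filled
#' polymer film. Amplitude contrast is the transmission drop at maximum
#' thickness; phase contrast is the (negative) phase excursion in radians at
#' maximum thickness.
#'
#' @param canvas_size object grid size N.
#' @param particle_count number of disks.
#' @param radius_range two-element range of disk radii in pixels.
#' @param amplitude_contrast transmission drop at max thickness, in `[0, 1)`.
#' @param phase_contrast phase depth at max thickness, radians, in `[0, pi)`.
#' @param background complex background transmission (vacuum = 1+0i).
#' @param margin vacuum border width in pixels: particles are placed at
#'   least this far from the canvas edge. Useful for recovery tests where
#'   the weakly illuminated periphery should hold no structure.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(canvas_size = 192, particle_count = 40,
                         radius_range = c(4, 14), amplitude_contrast = 0.15,
                         phase_contrast = 0.6, background = 1 + 0i,
                         margin = 0) {
  if (any(radius_range <= 0)) stopf("radii must be positive")
  if (amplitude_contrast < 0 || amplitude_contrast >= 1)
    stopf("amplitude_contrast must lie in [0, 1)")
  if (phase_contrast < 0 || phase_contrast >= pi)
    stopf("phase_contrast must lie in [0, pi)")
  structure(list(canvas_size = canvas_size, particle_count = particle_count,
                 radius_range = radius_range,
                 amplitude_contrast = amplitude_contrast,
                 phase_contrast = phase_contrast, background = background,
                 margin = margin),
            class = "phantom_spec")
}

#' Random particle phantom
#'
#' Places `particle_count` disks at random positions and radii. Each disk
#' carries a spherical-cap thickness profile `t(x) = sqrt(1 - (d/r)^2)`
#' (normalized to 1 at the center); the object is multiplied by
#' `exp(-mu * t) * exp(-i * dphi * t)` where `mu = -log(1 - dA)` realizes the
#' requested transmission drop `dA` and `dphi` the phase depth. Overlapping
#' particles compound multiplicatively, as thickness adds. Deterministic
#' given `seed`.
#'
#' @param spec a `phantom_spec`.
#' @param seed integer seed.
#' @param pixel_size length per pixel.
#' @return an `object_field`.
#' @export
make_particle_phantom <- function(spec, seed = 1, pixel_size = 1) {
  N <- spec$canvas_size
  amp_log <- matrix(0, N, N)   # accumulated -mu * t
  pha <- matrix(0, N, N)       # accumulated -dphi * t
  mu <- -log(1 - spec$amplitude_contrast)
  with_seed(seed, {
    for (p in seq_len(spec$particle_count)) {
      r <- runif(1, spec$radius_range[1], spec$radius_range[2])
      # centers snap to the pixel grid so each cap attains its full
      # thickness (and hence the stated contrasts) exactly
      cx <- round(runif(1, 1 + r + spec$margin, N - r - spec$margin))
      cy <- round(runif(1, 1 + r + spec$margin, N - r - spec$margin))
      lo_i <- max(1, floor(cx - r)); hi_i <- min(N, ceiling(cx + r))
      lo_j <- max(1, floor(cy - r)); hi_j <- min(N, ceiling(cy + r))
      d2 <- outer(((lo_i:hi_i) - cx)^2, ((lo_j:hi_j) - cy)^2, "+") / r^2
      t <- sqrt(pmax(0, 1 - d2))
      amp_log[lo_i:hi_i, lo_j:hi_j] <- amp_log[lo_i:hi_i, lo_j:hi_j] - mu * t
      pha[lo_i:hi_i, lo_j:hi_j] <- pha[lo_i:hi_i, lo_j:hi_j] -
        spec$phase_contrast * t
    }
  })
  vals <- spec$background * exp(amp_log) * exp(1i * pha)
  object_field(vals, pixel_size = pixel_size)
}

# Extract the M x M patch of O at 0-based offset (i, j).
extract_patch <- function(O_values, offset, M) {
  i <- offset[1] + 1; j <- offset[2] + 1
  O_values[i:(i + M - 1), j:(j + M - 1)]
}

replace_patch <- function(O_values, offset, patch) {
  M <- nrow(patch)
  i <- offset[1] + 1; j <- offset[2] + 1
  O_values[i:(i + M - 1), j:(j + M - 1)] <- patch
  O_values
}

#' Noiseless diffraction pattern at one scan offset
#'
#' Returns `|F(S_r(O) * P)|^2` with the unitary 2-D DFT: the squared Fourier
#' modulus of the exit wave formed by the probed object region. By Parseval
#' the pattern sums to the exit-wave power.
#'
#' @param O an `object_field`.
#' @param P a `probe_field` with M < N.
#' @param offset length-2 integer (row, col), 0-based top-left corner.
#' @return M x M nonnegative matrix of expected photon counts.
#' @export
diffraction_pattern <- function(O, P, offset) {
  M <- nrow(P$values); N <- nrow(O$values)
  if (M >= N) stopf("probe (%d) must be smaller than object (%d)", M, N)
  if (any(offset < 0) || any(offset > N - M))
    stopf("offset (%d, %d) out of bounds [0, %d]", offset[1], offset[2], N - M)
  exit <- extract_patch(O$values, offset, M) * P$values
  Mod(ufft2(exit))^2
}

#' Diffraction dataset container
#'
#' @param intensities M x M x R array of nonnegative counts.
#' @param plan the `scan_plan` used.
#' @param I0 photons at the origin pixel of a vacuum exposure.
#' @param noise_kind `"none"` or `"poisson"`.
#' @param seed noise seed.
#' @param pixel_size length per pixel.
#' @export
diffraction_set <- function(intensities, plan, I0, noise_kind = "none",
                            seed = NA_integer_, pixel_size = 1) {
  if (length(dim(intensities)) != 3)
    stopf("intensities must be an M x M x R array")
  if (dim(intensities)[3] != nrow(plan$offsets))
    stopf("intensity stack depth (%d) != number of offsets (%d)",
          dim(intensities)[3], nrow(plan$offsets))
  if (min(intensities) < 0) stopf("intensities must be nonnegative")
  structure(list(intensities = intensities, plan = plan, I0 = I0,
                 noise_kind = noise_kind, seed = seed,
                 pixel_size = pixel_size),
            class = "diffraction_set")
}

#' @export
print.diffraction_set <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<diffraction_set R=%d, %dx%d, I0=%.3g, noise=%s>\n",
              d[3], d[1], d[2], x$I0, x$noise_kind))
  invisible(x)
}

# Seeded Poisson counts for possibly huge means. rpois() cannot represent
# counts beyond the integer range, so means above 1e7 use the rounded normal
# approximation (relative error O(1/sqrt(lambda)) < 3e-4 at the switch).
rpois_big <- function(lambda) {
  out <- numeric(length(lambda))
  small <- lambda <= 1e7
  if (any(small)) out[small] <- rpois(sum(small), lambda[small])
  if (any(!small))
    out[!small] <- pmax(0, round(rnorm(sum(!small), lambda[!small],
                                       sqrt(lambda[!small]))))
  out
}

#' Simulate a diffraction dataset
#'
#' Rescales the probe power so that a vacuum exposure (O = 1) has exactly
#' `I0` expected photons at its zero-frequency pixel, then computes the
#' noiseless pattern at every scan offset and, if requested, draws
#' independent Poisson counts per pixel with the pattern as mean.
#'
#' @param O true `object_field`.
#' @param P `probe_field` (power is rescaled internally; the scaled probe is
#'   returned in the `probe` attribute for reference).
#' @param plan `scan_plan`.
#' @param I0 photons at the vacuum DC pixel; > 0.
#' @param noise_kind `"none"` or `"poisson"`.
#' @param seed noise seed (ignored for `"none"`).
#' @return a `diffraction_set`; attribute `probe` holds the dose-calibrated
#'   probe actually used.
#' @export
simulate_dataset <- function(O, P, plan, I0, noise_kind = c("none", "poisson"),
                             seed = 1) {
  noise_kind <- match.arg(noise_kind)
  if (I0 <= 0) stopf("I0 must be positive")
  M <- nrow(P$values); N <- nrow(O$values)
  check_plan_bounds(plan, N, M)
  # vacuum DC intensity |sum(P)|^2 / M^2 under the unitary DFT
  dc <- Mod(sum(P$values))^2 / length(P$values)
  if (dc <= 0) stopf("probe has zero DC response; cannot calibrate dose")
  Pcal <- probe_field(P$values * sqrt(I0 / dc), pixel_size = P$pixel_size)
  R <- nrow(plan$offsets)
  ints <- array(0, dim = c(M, M, R))
  for (r in seq_len(R))
    ints[, , r] <- diffraction_pattern(O, Pcal, plan$offsets[r, ])
  if (noise_kind == "poisson")
    ints <- with_seed(seed, array(rpois_big(ints), dim = dim(ints)))
  ds <- diffraction_set(ints, plan, I0 = I0, noise_kind = noise_kind,
                        seed = if (noise_kind == "poisson") seed else NA_integer_,
                        pixel_size = O$pixel_size)
  attr(ds, "probe") <- Pcal
  ds
}

#' Total illumination map of a scan
#'
#' Sum of `|P|^2` embedded at every scan offset on the object canvas; used
#' for the 1%-illumination periphery mask in FRC evaluation.
#'
#' @param P `probe_field`.
#' @param plan `scan_plan`.
#' @param N object canvas size.
#' @return N x N nonnegative matrix.
#' @export
illumination_map <- function(P, plan, N) {
  M <- nrow(P$values)
  check_plan_bounds(plan, N, M)
  acc <- matrix(0, N, N)
  p2 <- Mod(P$values)^2
  for (r in seq_len(nrow(plan$offsets))) {
    i <- plan$offsets[r, 1] + 1; j <- plan$offsets[r, 2] + 1
    acc[i:(i + M - 1), j:(j + M - 1)] <- acc[i:(i + M - 1), j:(j + M - 1)] + p2
  }
  acc
}
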