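#' 3-D PET-like image
#'
#' Lightweight container for a 3-D intensity grid in SUV units with per-axis
#' voxel spacing in millimetres. Axis 3 is the cranio-caudal direction.
#'
#' @param values numeric 3-D array, non-negative, finite (SUV).
#' @param spacing_mm numeric length-3, voxel spacing in mm.
#' @return An object of class \code{phantom_image}.
#' @export
phantom_image <- function(values, spacing_mm) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (any(!is.finite(values)))
    stop("image values must be finite")
  if (any(values < 0))
    stop("image values must be non-negative")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive numbers")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat("<phantom_image> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm; SUV range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Phantom specification
#'
#' Describes the motion-free ground truth: a warm uniform background with one
#' or more hot spherical lesions (smooth Gaussian-profile peaks), an optional
#' necrotic core, reconstruction blur (Gaussian point-spread function) and
#' count-noise scaling. Defaults follow typical clinical whole-body PET
#' reconstruction: 4.07 mm voxels and a 3.0 mm FWHM Gaussian post-filter.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing_mm numeric length-3 spacing (default 4.07 mm isotropic).
#' @param background_suv scalar background uptake.
#' @param lesion_centers_mm list of numeric length-3 world coordinates (mm).
#' @param lesion_radii_mm numeric, one radius per lesion (mm).
#' @param lesion_peak_suv numeric, one peak SUV per lesion.
#' @param necrotic_core optional \code{list(center_mm=, radius_mm=, suv=)}.
#' @param psf_fwhm_mm Gaussian PSF full width at half maximum (mm); 0 disables.
#' @param noise_scale counts per SUV for Poisson noise; 0 disables noise.
#' @param seed RNG seed used wherever the spec is consumed stochastically.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 32L),
                         voxel_spacing_mm = c(4.07, 4.07, 4.07),
                         background_suv = 1.0,
                         lesion_centers_mm = list(),
                         lesion_radii_mm = numeric(),
                         lesion_peak_suv = numeric(),
                         necrotic_core = NULL,
                         psf_fwhm_mm = 3.0,
                         noise_scale = 10,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (!is.list(lesion_centers_mm)) lesion_centers_mm <- list(lesion_centers_mm)
  nles <- length(lesion_centers_mm)
  if (length(lesion_radii_mm) != nles || length(lesion_peak_suv) != nles)
    stop("lesion_centers_mm, lesion_radii_mm and lesion_peak_suv lengths differ")
  if (any(lesion_radii_mm <= 0)) stop("all lesion radii must be > 0")
  if (any(lesion_peak_suv <= background_suv))
    stop("all lesion peak SUVs must exceed background_suv")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 background_suv = background_suv,
                 lesion_centers_mm = lesion_centers_mm,
                 lesion_radii_mm = as.numeric(lesion_radii_mm),
                 lesion_peak_suv = as.numeric(lesion_peak_suv),
                 necrotic_core = necrotic_core,
                 psf_fwhm_mm = psf_fwhm_mm,
                 noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# World coordinate (mm) of voxel centres along one axis, origin at voxel 1.
axis_coords_mm <- function(n, spacing) (seq_len(n) - 1) * spacing

# Truncated-Gaussian radial lesion profile: 1 at the centre, continuous 0 at
# r = radius (sigma = radius / 2, rescaled so the boundary value is exactly 0).
lesion_profile <- function(r, radius) {
  s <- radius / 2
  raw <- exp(-0.5 * (r / s)^2)
  floorv <- exp(-2)
  out <- (raw - floorv) / (1 - floorv)
  out[r > radius] <- 0
  pmax(out, 0)
}

# Separable Gaussian blur with edge replication (constants are preserved).
gaussian_blur3d <- function(arr, fwhm_mm, spacing_mm) {
  if (fwhm_mm <= 0) return(arr)
  dims <- dim(arr)
  for (ax in 1:3) {
    sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm[ax]
    R <- max(1L, ceiling(4 * sigma_vox))
    off <- seq(-R, R)
    # Bin-integrated Gaussian weights: exact kernel mass per voxel, which
    # stays correct when sigma is below the voxel size.
    w <- stats::pnorm(off + 0.5, 0, sigma_vox) -
      stats::pnorm(off - 0.5, 0, sigma_vox)
    w <- w / sum(w)
    n <- dims[ax]
    acc <- array(0, dims)
    for (m in seq_along(off)) {
      idx <- pmin(pmax(seq_len(n) + off[m], 1L), n)
      acc <- acc + w[m] * slice_index(arr, ax, idx)
    }
    arr <- acc
  }
  arr
}

# Reindex one axis of a 3-D array.
slice_index <- function(arr, axis, idx) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

#' Render the motion-free ground-truth phantom
#'
#' Background plus Gaussian-profile spherical lesions, optional necrotic core,
#' then PSF blur at the spec's FWHM. No noise is applied here; noise belongs to
#' the frame simulation.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A \code{\link{phantom_image}}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  xs <- axis_coords_mm(dims[1], sp[1])
  ys <- axis_coords_mm(dims[2], sp[2])
  zs <- axis_coords_mm(dims[3], sp[3])
  vol <- array(spec$background_suv, dims)
  extent <- (dims - 1) * sp
  for (l in seq_along(spec$lesion_centers_mm)) {
    ctr <- spec$lesion_centers_mm[[l]]
    rad <- spec$lesion_radii_mm[l]
    if (any(ctr - rad < 0) || any(ctr + rad > extent))
      stop("lesion ", l, " extends outside the grid")
    dx2 <- (xs - ctr[1])^2
    dy2 <- (ys - ctr[2])^2
    dz2 <- (zs - ctr[3])^2
    r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    vol <- vol + (spec$lesion_peak_suv[l] - spec$background_suv) *
      lesion_profile(r, rad)
  }
  core <- spec$necrotic_core
  if (!is.null(core)) {
    dx2 <- (xs - core$center_mm[1])^2
    dy2 <- (ys - core$center_mm[2])^2
    dz2 <- (zs - core$center_mm[3])^2
    r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    vol[r <= core$radius_mm] <- core$suv
  }
  vol <- gaussian_blur3d(vol, spec$psf_fwhm_mm, sp)
  phantom_image(pmax(vol, 0), sp)
}

#' Respiratory surrogate trace
#'
#' @param times_s strictly increasing, uniformly spaced sample times (s).
#' @param amplitudes_mm surrogate amplitude at each sample (mm).
#' @return An object of class \code{respiratory_trace}.
#' @export
respiratory_trace <- function(times_s, amplitudes_mm) {
  if (length(times_s) != length(amplitudes_mm))
    stop("times and amplitudes differ in length")
  if (length(times_s) < 2L) stop("a trace needs at least 2 samples")
  dt <- diff(times_s)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("sampling interval must be uniform")
  structure(list(times_s = as.numeric(times_s),
                 amplitudes_mm = as.numeric(amplitudes_mm)),
            class = "respiratory_trace")
}

#' @export
print.respiratory_trace <- function(x, ...) {
  cat("<respiratory_trace> ", length(x$times_s), " samples, dt = ",
      signif(x$times_s[2] - x$times_s[1], 4), " s, amplitude range [",
      signif(min(x$amplitudes_mm), 4), ", ", signif(max(x$amplitudes_mm), 4),
      "] mm\n", sep = "")
  invisible(x)
}

#' Lujan-type respiratory waveform
#'
#' Generates the surrogate amplitude \eqn{z(t) = A cos^{2n}(\pi t / \tau)},
#' which dwells near 0 mm (end-expiration) for most of each cycle, the feature
#' that makes amplitude gating data-efficient. Optional linear baseline drift
#' and seeded per-cycle amplitude jitter emulate irregular breathing.
#'
#' @param period_s breathing period \eqn{\tau} (s).
#' @param amplitude_mm peak-to-trough amplitude A (mm).
#' @param exponent_n integer \eqn{n \ge 1}; larger n lengthens the dwell.
#' @param duration_s total trace duration (s).
#' @param dt_s sampling interval (s); must be < period/8.
#' @param drift_mm_per_min linear baseline drift subtracted over time.
#' @param jitter_frac per-cycle multiplicative amplitude jitter (SD fraction).
#' @param seed RNG seed for the jitter.
#' @return A \code{\link{respiratory_trace}} with
#'   \code{floor(duration_s/dt_s)} samples starting at t = 0.
#' @export
lujan_waveform <- function(period_s, amplitude_mm, exponent_n = 2L,
                           duration_s = 120, dt_s = 0.4,
                           drift_mm_per_min = 0, jitter_frac = 0,
                           seed = 1L) {
  if (period_s <= 0 || dt_s <= 0) stop("period_s and dt_s must be positive")
  if (dt_s >= period_s / 8) stop("dt_s must be smaller than period_s / 8")
  if (exponent_n < 1 || exponent_n != round(exponent_n))
    stop("exponent_n must be an integer >= 1")
  n <- floor(duration_s / dt_s)
  t <- (seq_len(n) - 1) * dt_s
  cyc <- floor(t / period_s)
  amp_cycle <- rep(amplitude_mm, max(cyc) + 1)
  if (jitter_frac > 0) {
    set.seed(seed)
    amp_cycle <- amp_cycle * (1 + jitter_frac * stats::rnorm(length(amp_cycle)))
    amp_cycle <- pmax(amp_cycle, 0)
  }
  z <- amp_cycle[cyc + 1] * cos(pi * t / period_s)^(2 * exponent_n)
  z <- z - drift_mm_per_min * t / 60
  respiratory_trace(t, z)
}

#' Frame stack
#'
#' One simulated PET frame per trace sample, plus the trace and the motion-free
#' truth image. Frames are stored as a 4-D array \code{[x, y, z, frame]}.
#'
#' @param frames 4-D numeric array.
#' @param trace the \code{\link{respiratory_trace}} that produced the frames.
#' @param truth the motion-free \code{\link{phantom_image}}.
#' @return An object of class \code{frame_stack}.
#' @export
frame_stack <- function(frames, trace, truth) {
  if (length(dim(frames)) != 4L) stop("frames must be a 4-D array")
  if (dim(frames)[4] != length(trace$times_s))
    stop("frame count must equal trace sample count")
  if (!all(dim(frames)[1:3] == dim(truth$values)))
    stop("frames and truth differ in shape")
  structure(list(frames = frames, trace = trace, truth = truth,
                 spacing_mm = truth$spacing_mm),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat("<frame_stack> ", dim(x$frames)[4], " frames of ",
      paste(dim(x$frames)[1:3], collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

# Subvoxel shift of a 3-D array along one axis by s voxels (linear
# interpolation between the two neighbouring integer shifts, zero fill).
shift_axis <- function(arr, axis, shift_vox) {
  i0 <- floor(shift_vox)
  f <- shift_vox - i0
  a <- int_shift_axis(arr, axis, i0)
  if (f == 0) return(a)
  b <- int_shift_axis(arr, axis, i0 + 1)
  (1 - f) * a + f * b
}

int_shift_axis <- function(arr, axis, k) {
  n <- dim(arr)[axis]
  k <- as.integer(k)
  if (k == 0L) return(arr)
  out <- array(0, dim(arr))
  if (abs(k) >= n) return(out)
  src <- if (k > 0) seq_len(n - k) else seq.int(1L - k, n)
  dst <- if (k > 0) seq.int(k + 1L, n) else seq_len(n + k)
  if (axis == 1L) out[dst, , ] <- arr[src, , ]
  else if (axis == 2L) out[, dst, ] <- arr[, src, ]
  else out[, , dst] <- arr[, , src]
  out
}

#' Simulate a respiratory-motion acquisition
#'
#' Each frame is the truth image with the lesion foreground rigidly translated
#' along the motion axis by that sample's amplitude (subvoxel linear
#' interpolation over the uniform background), with optional per-frame Poisson
#' count noise. This emulates the displacement-induced blur that degrades
#' ungated PET near the diaphragm.
#'
#' @param truth motion-free \code{\link{phantom_image}}.
#' @param trace \code{\link{respiratory_trace}}; one frame per sample.
#' @param motion_axis grid axis along which the lesion moves (default 3,
#'   cranio-caudal).
#' @param lesion_mask optional logical array marking the lesion foreground,
#'   used only to estimate the background level; if \code{NULL} the background
#'   is the median voxel value.
#' @param noise_scale counts per SUV for Poisson noise; 0 disables.
#' @param seed RNG seed for the noise.
#' @return A \code{\link{frame_stack}}.
#' @export
simulate_acquisition <- function(truth, trace, motion_axis = 3L,
                                 lesion_mask = NULL, noise_scale = 0,
                                 seed = 1L) {
  stopifnot(inherits(truth, "phantom_image"),
            inherits(trace, "respiratory_trace"))
  if (!motion_axis %in% 1:3) stop("motion_axis must be 1, 2 or 3")
  vals <- truth$values
  bg <- if (is.null(lesion_mask)) stats::median(vals)
        else stats::median(vals[!lesion_mask])
  comp <- vals - bg
  sp <- truth$spacing_mm[motion_axis]
  nfr <- length(trace$times_s)
  # Lesion support must stay inside the grid under the largest shift.
  supp <- which(abs(comp) > 1e-9 * max(abs(comp), 1e-12), arr.ind = TRUE)
  if (nrow(supp) > 0) {
    rng <- range(supp[, motion_axis])
    shifts <- trace$amplitudes_mm / sp
    if (rng[1] + min(shifts) < 1 - 1e-9 ||
        rng[2] + max(shifts) > dim(vals)[motion_axis] + 1e-9)
      stop("translation pushes the lesion outside the grid")
  }
  frames <- array(0, c(dim(vals), nfr))
  if (noise_scale > 0) set.seed(seed)
  nv <- length(vals)
  for (k in seq_len(nfr)) {
    fk <- bg + shift_axis(comp, motion_axis, trace$amplitudes_mm[k] / sp)
    if (noise_scale > 0)
      fk <- stats::rpois(nv, pmax(fk, 0) * noise_scale) / noise_scale
    frames[, , , k] <- fk
  }
  frame_stack(frames, trace, truth)
}

#' Average a selection of frames into one image
#'
#' The gated and ungated images are both voxelwise means over their selected
#' frames, so they share a common SUV scale regardless of how many frames were
#' retained (the counterpart of matching acquisition statistics between
#' reconstructions).
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param selection integer frame indices; default all frames (ungated image).
#' @return A \code{\link{phantom_image}}.
#' @export
sum_frames <- function(stack, selection = seq_len(dim(stack$frames)[4])) {
  stopifnot(inherits(stack, "frame_stack"))
  nfr <- dim(stack$frames)[4]
  selection <- as.integer(selection)
  if (length(selection) == 0) stop("selection must be non-empty")
  if (any(selection < 1L | selection > nfr)) stop("frame index out of range")
  dims <- dim(stack$frames)[1:3]
  nv <- prod(dims)
  # Mean as base + mean(deviations): exact when all selected frames are
  # identical (e.g. motionless noiseless stacks), better conditioned always.
  base <- stack$frames[(selection[1] - 1) * nv + seq_len(nv)]
  acc <- numeric(nv)
  for (k in selection[-1])
    acc <- acc + (stack$frames[(k - 1) * nv + seq_len(nv)] - base)
  avg <- base + acc / length(selection)
  phantom_image(array(pmax(avg, 0), dims), stack$spacing_mm)
}
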