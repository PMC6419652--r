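#' Volume-of-interest mask
#'
#' Boolean 3-D mask produced by isocontour delineation, with the threshold and
#' reference maximum that generated it.
#'
#' @param mask logical 3-D array.
#' @param threshold_suv absolute SUV threshold applied.
#' @param suvmax_ref reference maximum used to set the threshold.
#' @param fraction isocontour fraction of \code{suvmax_ref}.
#' @param provenance list of free-form provenance fields.
#' @return An object of class \code{voi_mask}.
#' @export
voi_mask <- function(mask, threshold_suv, suvmax_ref, fraction,
                     provenance = list()) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a logical 3-D array")
  structure(list(mask = mask,
                 threshold_suv = threshold_suv,
                 suvmax_ref = suvmax_ref,
                 fraction = fraction,
                 n_voxels = sum(mask),
                 provenance = provenance),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> ", x$n_voxels, " voxels; threshold ",
      signif(x$threshold_suv, 4), " SUV (", signif(100 * x$fraction, 3),
      "% of SUVmax ", signif(x$suvmax_ref, 4), ")\n", sep = "")
  invisible(x)
}

# Offsets of the 26-neighbourhood as an integer matrix (26 x 3).
neighborhood26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# 26-connected component of `candidates` (logical array) containing `start`
# (linear index). Breadth-first expansion with a vectorised frontier.
connected_component26 <- function(candidates, start) {
  dims <- dim(candidates)
  offs <- neighborhood26()
  comp <- array(FALSE, dims)
  comp[start] <- TRUE
  frontier <- matrix(arrayInd(start, dims), ncol = 3)
  while (nrow(frontier) > 0) {
    nxt <- do.call(rbind, lapply(seq_len(nrow(offs)), function(m)
      sweep(frontier, 2, offs[m, ], "+")))
    keep <- nxt[, 1] >= 1 & nxt[, 1] <= dims[1] &
            nxt[, 2] >= 1 & nxt[, 2] <= dims[2] &
            nxt[, 3] >= 1 & nxt[, 3] <= dims[3]
    nxt <- nxt[keep, , drop = FALSE]
    if (nrow(nxt) == 0) break
    lin <- nxt[, 1] + (nxt[, 2] - 1L) * dims[1] +
      (nxt[, 3] - 1L) * dims[1] * dims[2]
    lin <- unique(lin[candidates[lin] & !comp[lin]])
    if (length(lin) == 0) break
    comp[lin] <- TRUE
    frontier <- matrix(arrayInd(lin, dims), ncol = 3)
  }
  comp
}

#' Isocontour delineation of the metabolic tumor volume
#'
#' Within an annotated seed region (minus manual exclusions), thresholds the
#' image at \code{fraction} of the regional SUVmax and keeps the 26-connected
#' component of supra-threshold voxels containing the maximum voxel. The
#' reference maximum is computed after exclusion subtraction so adjacent
#' structures (duodenal uptake, biliary stents) cannot set the threshold.
#'
#' @param image a \code{\link{phantom_image}}.
#' @param seed_mask logical array: the manually annotated tumor region.
#' @param fraction isocontour fraction of SUVmax (default 0.40).
#' @param exclusion_mask optional logical array removed from the seed region.
#' @return A \code{\link{voi_mask}}.
#' @export
isocontour_voi <- function(image, seed_mask, fraction = 0.40,
                           exclusion_mask = NULL) {
  stopifnot(inherits(image, "phantom_image"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (!all(dim(seed_mask) == dim(image$values)))
    stop("seed mask shape differs from image")
  region <- seed_mask
  if (!is.null(exclusion_mask)) {
    if (!all(dim(exclusion_mask) == dim(image$values)))
      stop("exclusion mask shape differs from image")
    region <- region & !exclusion_mask
  }
  if (!any(region)) stop("seed region is empty after exclusion subtraction")
  vals <- image$values
  suvmax <- max(vals[region])
  thr <- fraction * suvmax
  candidates <- region & (vals >= thr)
  inreg <- which(region)
  start <- inreg[which.max(vals[inreg])]
  comp <- connected_component26(candidates, start)
  voi_mask(comp, thr, suvmax, fraction,
           provenance = list(n_seed = sum(seed_mask),
                             n_excluded = if (is.null(exclusion_mask)) 0
                                          else sum(exclusion_mask)))
}

#' Metabolic tumor volume in millilitres
#'
#' @param voi a \code{\link{voi_mask}} (or a plain logical array).
#' @param spacing_mm per-axis voxel spacing in mm.
#' @return Volume in ml (n_voxels times voxel volume).
#' @export
mtv <- function(voi, spacing_mm) {
  n <- if (inherits(voi, "voi_mask")) voi$n_voxels else sum(voi)
  n * prod(spacing_mm) / 1000
}

#' Deterministic seed region for a synthetic lesion
#'
#' Emulates manual annotation: the bounding box of the ground-truth lesion
#' support, dilated by a margin, clipped to the grid. The margin must cover
#' the largest respiratory displacement so the blurred (ungated) lesion stays
#' inside the region.
#'
#' @param spec the \code{\link{phantom_spec}} that produced the truth image.
#' @param margin_vox isotropic dilation of the bounding box in voxels.
#' @param motion_extra_mm extra margin added along axis 3 in the direction of
#'   motion (mm).
#' @return A logical 3-D array.
#' @export
lesion_seed_region <- function(spec, margin_vox = 2L, motion_extra_mm = 0) {
  dims <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (l in seq_along(spec$lesion_centers_mm)) {
    ctr <- spec$lesion_centers_mm[[l]]
    rad <- spec$lesion_radii_mm[l]
    lo <- pmin(lo, ctr - rad)
    hi <- pmax(hi, ctr + rad)
  }
  hi[3] <- hi[3] + motion_extra_mm
  lo_vox <- pmax(floor(lo / sp) + 1L - margin_vox, 1L)
  hi_vox <- pmin(ceiling(hi / sp) + 1L + margin_vox, dims)
  m <- array(FALSE, dims)
  m[lo_vox[1]:hi_vox[1], lo_vox[2]:hi_vox[2], lo_vox[3]:hi_vox[3]] <- TRUE
  m
}
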