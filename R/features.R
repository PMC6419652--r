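#' Feature names, in standard reporting order
#'
#' The 35 image features reported per reconstruction: 5 standard metabolic
#' parameters, 6 first-order histogram features, 8 gray-level co-occurrence
#' (GLCM) features, 7 run-length (GLRLM) features and 9 size-zone (GLSZM)
#' features. Numeric suffixes on the entropy names are toolbox column
#' artifacts preserved verbatim in output headers.
#'
#' @return Character vector of length 35.
#' @export
table2_feature_names <- function() {
  c("MTV", "SUVmin", "SUVmax", "SUVmean", "SUVdiff",
    "Variance", "Skewness", "Kurtosis", "Entropy.image", "STD", "Energy",
    "Contrast", "Dissimilarity", "Homogeneity.1", "Homogeneity.2",
    "Correlation", "Difference Entropy.1", "Joint Entropy.2", "Sum Entropy.3",
    "Short.Run.Emphasis", "Long.Run.Emphasis",
    "Gray.Level.Non-Uniformity", "Gray.Level.Non-Uniformity.Normalized",
    "Run.Length.Non-Uniformity", "Run.Length.Non-Uniformity.Normalized",
    "Run.Percentage",
    "GrayLevelVariance", "SmallAreaHighGrayLevelEmphasis",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformityNormalized",
    "SizeZoneNonUniformity", "GrayLevelNonUniformity",
    "LargeAreaEmphasis", "ZoneVariance", "ZonePercentage")
}

#' Discretized VOI
#'
#' Integer gray-level grid: 0 outside the VOI, levels 1..n_bins inside.
#'
#' @param levels integer 3-D array.
#' @param n_bins number of gray levels.
#' @param bin_edges optional numeric vector of the bin edges used.
#' @return An object of class \code{discretized_voi}.
#' @export
discretized_voi <- function(levels, n_bins, bin_edges = NULL) {
  if (length(dim(levels)) != 3L) stop("levels must be a 3-D array")
  inv <- levels[levels > 0]
  if (length(inv) == 0) stop("discretized VOI is empty")
  if (any(inv > n_bins)) stop("levels exceed n_bins")
  structure(list(levels = levels, n_bins = as.integer(n_bins),
                 bin_edges = bin_edges),
            class = "discretized_voi")
}

#' Fixed-bin-count discretization of in-VOI intensities
#'
#' Equal-width bins spanning the in-VOI [min, max] range; a constant VOI maps
#' to level 1 everywhere. Fixed bin count (rather than fixed bin width) makes
#' the resulting texture features invariant to adding a constant to all
#' intensities.
#'
#' @param image a \code{\link{phantom_image}}.
#' @param voi a \code{\link{voi_mask}} or logical array.
#' @param n_bins number of gray levels (default 255).
#' @return A \code{\link{discretized_voi}}.
#' @export
discretize <- function(image, voi, n_bins = 255L) {
  stopifnot(inherits(image, "phantom_image"))
  mask <- if (inherits(voi, "voi_mask")) voi$mask else voi
  if (n_bins < 2L) stop("n_bins must be >= 2")
  v <- image$values[mask]
  if (length(v) == 0) stop("VOI is empty")
  lo <- min(v); hi <- max(v)
  lev <- array(0L, dim(image$values))
  if (hi == lo) {
    lev[mask] <- 1L
    edges <- c(lo, hi)
  } else {
    w <- (hi - lo) / n_bins
    lev[mask] <- pmin(as.integer(floor((v - lo) / w)) + 1L, as.integer(n_bins))
    edges <- lo + w * (0:n_bins)
  }
  discretized_voi(lev, n_bins, edges)
}

#' Standard metabolic parameters
#'
#' @param image a \code{\link{phantom_image}}.
#' @param voi a \code{\link{voi_mask}}.
#' @return List with SUVmax, SUVmin, SUVmean, SUVdiff (max - min) and MTV (ml).
#' @export
standard_params <- function(image, voi) {
  stopifnot(inherits(image, "phantom_image"))
  mask <- if (inherits(voi, "voi_mask")) voi$mask else voi
  v <- image$values[mask]
  if (length(v) == 0) stop("VOI is empty")
  list(SUVmax = max(v), SUVmin = min(v), SUVmean = mean(v),
       SUVdiff = max(v) - min(v), MTV = mtv(mask, image$spacing_mm))
}

#' First-order histogram features
#'
#' Population moments of the raw in-VOI intensities (Variance, STD,
#' Skewness = m3/m2^1.5, non-excess Kurtosis = m4/m2^2), plus entropy
#' (-sum p log2 p) and Energy (histogram uniformity, sum p^2) of the
#' fixed-bin-count histogram. A zero-variance VOI returns Skewness and
#' Kurtosis of 0 with a \code{degenerate} flag.
#'
#' @inheritParams discretize
#' @return Named list of Variance, Skewness, Kurtosis, Entropy.image, STD,
#'   Energy, plus logical \code{degenerate}.
#' @export
first_order_features <- function(image, voi, n_bins = 255L) {
  mask <- if (inherits(voi, "voi_mask")) voi$mask else voi
  v <- image$values[mask]
  if (length(v) < 2) stop("first-order features need at least 2 voxels")
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  degenerate <- m2 == 0
  if (degenerate) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((v - mu)^3) / m2^1.5
    kurt <- mean((v - mu)^4) / m2^2
  }
  d <- discretize(image, mask, n_bins)
  p <- tabulate(d$levels[d$levels > 0], nbins = d$n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  list(Variance = m2, Skewness = skew, Kurtosis = kurt,
       Entropy.image = -sum(p * log2(p)), STD = sqrt(m2),
       Energy = sum(p^2), degenerate = degenerate)
}

# The 13 unique direction offsets of the 26-neighbourhood (one per
# antipodal pair), distance 1 voxel.
direction_offsets13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

# Crop a level grid to the bounding box of the VOI (levels > 0); texture
# matrices only depend on in-VOI adjacency, so cropping is lossless.
crop_levels <- function(levels) {
  idx <- which(levels > 0, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  levels[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
         drop = FALSE]
}

# Value of levels at v + off (zero fill outside the grid).
offset_lookup <- function(levels, off) {
  out <- levels
  for (ax in 1:3) if (off[ax] != 0)
    out <- int_shift_axis(out, ax, -off[ax])
  out
}

#' Gray-level co-occurrence matrices
#'
#' One symmetrized count matrix per direction: for each of the 13 unique
#' offsets of the 26-neighbourhood (distance 1), in-VOI voxel pairs (i, j)
#' separated by that offset are counted and the transpose added.
#'
#' @param d a \code{\link{discretized_voi}}.
#' @return List of 13 square integer matrices (gray level x gray level).
#' @export
build_glcm <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  lv <- crop_levels(d$levels)
  ng <- max(lv)
  offs <- direction_offsets13()
  out <- vector("list", nrow(offs))
  for (m in seq_len(nrow(offs))) {
    nb <- offset_lookup(lv, offs[m, ])
    ok <- lv > 0 & nb > 0
    a <- lv[ok]; b <- nb[ok]
    cnt <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
    M <- matrix(cnt, ng, ng, byrow = TRUE)
    out[[m]] <- M + t(M)
  }
  out
}

# Features of one normalized GLCM (probabilities p, gray values = indices).
glcm_features_one <- function(M) {
  p <- M / sum(M)
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  nz <- p > 0
  contrast <- sum((i - j)^2 * p)
  dissim <- sum(abs(i - j) * p)
  hom1 <- sum(p / (1 + abs(i - j)))
  hom2 <- sum(p / (1 + (i - j)^2))
  corr <- if (sig2 == 0) 1 else (sum(i * j * p) - mu^2) / sig2
  jent <- -sum(p[nz] * log2(p[nz]))
  psum <- as.numeric(rowsum(p[nz], (i + j)[nz]))
  pdiff <- as.numeric(rowsum(p[nz], abs(i - j)[nz]))
  list(Contrast = contrast, Dissimilarity = dissim,
       `Homogeneity.1` = hom1, `Homogeneity.2` = hom2,
       Correlation = corr,
       `Difference Entropy.1` = -sum(pdiff * log2(pdiff)),
       `Joint Entropy.2` = jent,
       `Sum Entropy.3` = -sum(psum * log2(psum)))
}

#' GLCM texture features
#'
#' Each feature is computed per direction on the normalized symmetric matrix
#' and averaged (unweighted) over non-empty directions. A degenerate
#' single-level matrix yields Correlation 1, entropies 0.
#'
#' @param glcm list of direction matrices from \code{\link{build_glcm}}.
#' @return Named list of the 8 GLCM features.
#' @export
glcm_features <- function(glcm) {
  keep <- vapply(glcm, function(M) sum(M) > 0, logical(1))
  if (!any(keep)) stop("all direction matrices are empty")
  per <- lapply(glcm[keep], glcm_features_one)
  nm <- names(per[[1]])
  out <- lapply(nm, function(f)
    mean(vapply(per, function(x) x[[f]], numeric(1))))
  names(out) <- nm
  out
}

#' Gray-level run-length matrices
#'
#' Runs are maximal straight segments of equal-level in-VOI voxels along each
#' of the 13 directions. Entry (g, l) of a direction's matrix counts runs of
#' gray level g and length l.
#'
#' @param d a \code{\link{discretized_voi}}.
#' @return List of 13 integer matrices (gray level x run length).
#' @export
build_glrlm <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  lv <- crop_levels(d$levels)
  dims <- dim(lv)
  ng <- max(lv)
  offs <- direction_offsets13()
  out <- vector("list", nrow(offs))
  for (m in seq_len(nrow(offs))) {
    off <- offs[m, ]
    pred <- offset_lookup(lv, -off)
    starts <- which(lv > 0 & pred != lv)
    if (length(starts) == 0) { out[[m]] <- matrix(0L, ng, 1); next }
    pos <- matrix(arrayInd(starts, dims), ncol = 3)
    g <- lv[starts]
    len <- rep(1L, length(starts))
    active <- seq_along(starts)
    while (length(active) > 0) {
      nxt <- sweep(pos[active, , drop = FALSE], 2, off, "+")
      inb <- nxt[, 1] >= 1 & nxt[, 1] <= dims[1] &
             nxt[, 2] >= 1 & nxt[, 2] <= dims[2] &
             nxt[, 3] >= 1 & nxt[, 3] <= dims[3]
      ext <- logical(length(active))
      if (any(inb)) {
        lin <- nxt[inb, 1] + (nxt[inb, 2] - 1L) * dims[1] +
          (nxt[inb, 3] - 1L) * dims[1] * dims[2]
        ext[inb] <- lv[lin] == g[active[inb]]
      }
      adv <- active[ext]
      len[adv] <- len[adv] + 1L
      pos[adv, ] <- sweep(pos[adv, , drop = FALSE], 2, off, "+")
      active <- adv
    }
    maxl <- max(len)
    cnt <- tabulate((g - 1L) * maxl + len, nbins = ng * maxl)
    out[[m]] <- matrix(cnt, ng, maxl, byrow = TRUE)
  }
  out
}

glrlm_features_one <- function(R, n_voxels) {
  Nr <- sum(R)
  l <- seq_len(ncol(R))
  g_tot <- rowSums(R)
  l_tot <- colSums(R)
  list(`Short.Run.Emphasis` = sum(sweep(R, 2, l^2, "/")) / Nr,
       `Long.Run.Emphasis` = sum(sweep(R, 2, l^2, "*")) / Nr,
       `Gray.Level.Non-Uniformity` = sum(g_tot^2) / Nr,
       `Gray.Level.Non-Uniformity.Normalized` = sum(g_tot^2) / Nr^2,
       `Run.Length.Non-Uniformity` = sum(l_tot^2) / Nr,
       `Run.Length.Non-Uniformity.Normalized` = sum(l_tot^2) / Nr^2,
       `Run.Percentage` = Nr / n_voxels)
}

#' GLRLM texture features
#'
#' Standard run-length emphases and non-uniformities, computed per direction
#' and averaged over directions with at least one run.
#'
#' @param glrlm list of direction matrices from \code{\link{build_glrlm}}.
#' @param n_voxels number of in-VOI voxels (for Run Percentage).
#' @return Named list of the 7 GLRLM features.
#' @export
glrlm_features <- function(glrlm, n_voxels) {
  keep <- vapply(glrlm, function(R) sum(R) > 0, logical(1))
  if (!any(keep)) stop("all run-length matrices are empty")
  per <- lapply(glrlm[keep], glrlm_features_one, n_voxels = n_voxels)
  nm <- names(per[[1]])
  out <- lapply(nm, function(f)
    mean(vapply(per, function(x) x[[f]], numeric(1))))
  names(out) <- nm
  out
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal-level in-VOI voxels; entry
#' (g, z) counts zones of gray level g and size z voxels. Direction-free by
#' construction, so there is a single matrix.
#'
#' @param d a \code{\link{discretized_voi}}.
#' @return Integer matrix (gray level x zone size).
#' @export
build_glszm <- function(d) {
  stopifnot(inherits(d, "discretized_voi"))
  lv <- crop_levels(d$levels)
  ng <- max(lv)
  zones_g <- integer(0)
  zones_z <- integer(0)
  for (g in sort(unique(lv[lv > 0]))) {
    maskg <- lv == g
    remaining <- which(maskg)
    while (length(remaining) > 0) {
      comp <- connected_component26(maskg, remaining[1])
      zones_g <- c(zones_g, g)
      zones_z <- c(zones_z, sum(comp))
      maskg <- maskg & !comp
      remaining <- which(maskg)
    }
  }
  maxz <- max(zones_z)
  cnt <- tabulate((zones_g - 1L) * maxz + zones_z, nbins = ng * maxz)
  matrix(cnt, ng, maxz, byrow = TRUE)
}

#' GLSZM texture features
#'
#' The nine size-zone features over the normalized zone probabilities
#' p(g, z) = s(g, z) / Nz.
#'
#' @param glszm matrix from \code{\link{build_glszm}}.
#' @param n_voxels number of in-VOI voxels (for Zone Percentage).
#' @return Named list of the 9 GLSZM features.
#' @export
glszm_features <- function(glszm, n_voxels) {
  Nz <- sum(glszm)
  if (Nz == 0) stop("empty size-zone matrix")
  p <- glszm / Nz
  g <- seq_len(nrow(p))
  z <- seq_len(ncol(p))
  pg <- rowSums(p)
  pz <- colSums(p)
  mug <- sum(g * pg)
  muz <- sum(z * pz)
  g_tot <- rowSums(glszm)
  z_tot <- colSums(glszm)
  list(GrayLevelVariance = sum((g - mug)^2 * pg),
       SmallAreaHighGrayLevelEmphasis =
         sum(outer(g^2, z^2, "/") * p),
       GrayLevelNonUniformityNormalized = sum(g_tot^2) / Nz^2,
       SizeZoneNonUniformityNormalized = sum(z_tot^2) / Nz^2,
       SizeZoneNonUniformity = sum(z_tot^2) / Nz,
       GrayLevelNonUniformity = sum(g_tot^2) / Nz,
       LargeAreaEmphasis = sum(sweep(p, 2, z^2, "*")),
       ZoneVariance = sum((z - muz)^2 * pz),
       ZonePercentage = Nz / n_voxels)
}

#' Extract the full 35-feature vector for one image/VOI pair
#'
#' Standard metabolic parameters on the raw intensities, first-order histogram
#' features, and GLCM/GLRLM/GLSZM texture features on the fixed-bin-count
#' discretized VOI (default 255 bins, 26-neighbourhood, 13 directions,
#' distance 1 voxel).
#'
#' @inheritParams discretize
#' @return Named numeric vector of length 35 in \code{table2_feature_names()}
#'   order, with attribute \code{degenerate} set for zero-variance VOIs.
#' @export
extract_all <- function(image, voi, n_bins = 255L) {
  mask <- if (inherits(voi, "voi_mask")) voi$mask else voi
  std <- standard_params(image, voi)
  fo <- first_order_features(image, mask, n_bins)
  d <- discretize(image, mask, n_bins)
  nvox <- sum(mask)
  gl <- glcm_features(build_glcm(d))
  rl <- glrlm_features(build_glrlm(d), nvox)
  sz <- glszm_features(build_glszm(d), nvox)
  vals <- c(std[c("MTV", "SUVmin", "SUVmax", "SUVmean", "SUVdiff")],
            fo[c("Variance", "Skewness", "Kurtosis", "Entropy.image",
                 "STD", "Energy")],
            gl, rl, sz)
  out <- unlist(vals)
  names(out) <- c("MTV", "SUVmin", "SUVmax", "SUVmean", "SUVdiff",
                  "Variance", "Skewness", "Kurtosis", "Entropy.image",
                  "STD", "Energy", names(gl), names(rl), names(sz))
  out <- out[table2_feature_names()]
  attr(out, "degenerate") <- fo$degenerate
  out
}
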