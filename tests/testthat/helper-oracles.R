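# Independent literal-definition oracles used to cross-check the package's
# vectorised implementations. Everything here is written as plain loops over
# voxels, straight from the textbook definitions.

# The 13 unique neighbour offsets (one per antipodal pair), written out.
ORACLE_OFFSETS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(-1, 1, 0),
  c(1, 0, 1), c(-1, 0, 1),
  c(0, 1, 1), c(0, -1, 1),
  c(1, 1, 1), c(-1, 1, 1), c(1, -1, 1), c(-1, -1, 1))

in_grid <- function(p, dims) all(p >= 1) && all(p <= dims)

# GLCM by exhaustive pair enumeration (symmetric counts).
oracle_glcm_one <- function(levels, off, ng = max(levels)) {
  dims <- dim(levels)
  M <- matrix(0L, ng, ng)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      a <- levels[i, j, k]
      if (a == 0) next
      q <- c(i, j, k) + off
      if (!in_grid(q, dims)) next
      b <- levels[q[1], q[2], q[3]]
      if (b == 0) next
      M[a, b] <- M[a, b] + 1L
      M[b, a] <- M[b, a] + 1L
    }
  M
}

oracle_glcm_features_one <- function(M) {
  p <- M / sum(M)
  ng <- nrow(p)
  contrast <- 0; dissim <- 0; hom1 <- 0; hom2 <- 0; jent <- 0; sij <- 0
  psum <- numeric(2 * ng); pdiff <- numeric(ng)  # index s = i+j, d = |i-j|+1
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    px[i] <- px[i] + pij
    if (pij == 0) next
    contrast <- contrast + (i - j)^2 * pij
    dissim <- dissim + abs(i - j) * pij
    hom1 <- hom1 + pij / (1 + abs(i - j))
    hom2 <- hom2 + pij / (1 + (i - j)^2)
    jent <- jent - pij * log2(pij)
    sij <- sij + i * j * pij
    psum[i + j] <- psum[i + j] + pij
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + pij
  }
  mu <- sum((1:ng) * px)
  sig2 <- sum(((1:ng) - mu)^2 * px)
  corr <- if (sig2 == 0) 1 else (sij - mu^2) / sig2
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  list(Contrast = contrast, Dissimilarity = dissim,
       `Homogeneity.1` = hom1, `Homogeneity.2` = hom2, Correlation = corr,
       `Difference Entropy.1` = ent(pdiff), `Joint Entropy.2` = jent,
       `Sum Entropy.3` = ent(psum))
}

# Runs by literal walk: start wherever the predecessor differs, then step.
oracle_glrlm_one <- function(levels, off, ng = max(levels)) {
  dims <- dim(levels)
  runs_g <- integer(0); runs_l <- integer(0)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      g <- levels[i, j, k]
      if (g == 0) next
      prev <- c(i, j, k) - off
      if (in_grid(prev, dims) && levels[prev[1], prev[2], prev[3]] == g) next
      len <- 1L
      q <- c(i, j, k) + off
      while (in_grid(q, dims) && levels[q[1], q[2], q[3]] == g) {
        len <- len + 1L
        q <- q + off
      }
      runs_g <- c(runs_g, g); runs_l <- c(runs_l, len)
    }
  maxl <- max(runs_l, 1L)
  R <- matrix(0L, ng, maxl)
  for (m in seq_along(runs_g))
    R[runs_g[m], runs_l[m]] <- R[runs_g[m], runs_l[m]] + 1L
  R
}

oracle_glrlm_features_one <- function(R, n_voxels) {
  Nr <- sum(R)
  sre <- 0; lre <- 0
  for (g in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    sre <- sre + R[g, l] / l^2
    lre <- lre + R[g, l] * l^2
  }
  gln <- sum(rowSums(R)^2)
  rln <- sum(colSums(R)^2)
  list(`Short.Run.Emphasis` = sre / Nr, `Long.Run.Emphasis` = lre / Nr,
       `Gray.Level.Non-Uniformity` = gln / Nr,
       `Gray.Level.Non-Uniformity.Normalized` = gln / Nr^2,
       `Run.Length.Non-Uniformity` = rln / Nr,
       `Run.Length.Non-Uniformity.Normalized` = rln / Nr^2,
       `Run.Percentage` = Nr / n_voxels)
}

# Size zones by recursive flood fill over the 26-neighbourhood.
oracle_glszm <- function(levels, ng = max(levels)) {
  dims <- dim(levels)
  visited <- array(FALSE, dims)
  offs26 <- rbind(ORACLE_OFFSETS, -ORACLE_OFFSETS)
  zones_g <- integer(0); zones_z <- integer(0)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      g <- levels[i, j, k]
      if (g == 0 || visited[i, j, k]) next
      size <- 0L
      stack <- list(c(i, j, k))
      visited[i, j, k] <- TRUE
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (m in seq_len(nrow(offs26))) {
          q <- p + offs26[m, ]
          if (!in_grid(q, dims)) next
          if (visited[q[1], q[2], q[3]]) next
          if (levels[q[1], q[2], q[3]] != g) next
          visited[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
      zones_g <- c(zones_g, g); zones_z <- c(zones_z, size)
    }
  maxz <- max(zones_z)
  S <- matrix(0L, ng, maxz)
  for (m in seq_along(zones_g))
    S[zones_g[m], zones_z[m]] <- S[zones_g[m], zones_z[m]] + 1L
  S
}

oracle_glszm_features <- function(S, n_voxels) {
  Nz <- sum(S)
  glv <- 0; sahgle <- 0; lae <- 0; zv <- 0
  mug <- 0; muz <- 0
  for (g in seq_len(nrow(S))) for (z in seq_len(ncol(S))) {
    mug <- mug + g * S[g, z] / Nz
    muz <- muz + z * S[g, z] / Nz
  }
  for (g in seq_len(nrow(S))) for (z in seq_len(ncol(S))) {
    p <- S[g, z] / Nz
    glv <- glv + p * (g - mug)^2
    sahgle <- sahgle + p * g^2 / z^2
    lae <- lae + p * z^2
    zv <- zv + p * (z - muz)^2
  }
  gln <- sum(rowSums(S)^2)
  szn <- sum(colSums(S)^2)
  list(GrayLevelVariance = glv, SmallAreaHighGrayLevelEmphasis = sahgle,
       GrayLevelNonUniformityNormalized = gln / Nz^2,
       SizeZoneNonUniformityNormalized = szn / Nz^2,
       SizeZoneNonUniformity = szn / Nz,
       GrayLevelNonUniformity = gln / Nz,
       LargeAreaEmphasis = lae, ZoneVariance = zv,
       ZonePercentage = Nz / n_voxels)
}

# Full 35-feature oracle from a raw image + mask (first-order and standard
# parameters by direct sums; texture via the matrix oracles above).
oracle_extract_all <- function(values, mask, spacing, n_bins) {
  v <- values[mask]
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  lo <- min(v); hi <- max(v)
  lev <- array(0L, dim(values))
  if (hi == lo) lev[mask] <- 1L else {
    w <- (hi - lo) / n_bins
    lev[mask] <- pmin(as.integer(floor((values[mask] - lo) / w)) + 1L, n_bins)
  }
  hcnt <- numeric(n_bins)
  for (g in lev[lev > 0]) hcnt[g] <- hcnt[g] + 1
  hp <- hcnt[hcnt > 0] / n
  ng <- max(lev)
  glcm_per <- list(); glrlm_per <- list()
  for (m in seq_len(nrow(ORACLE_OFFSETS))) {
    M <- oracle_glcm_one(lev, ORACLE_OFFSETS[m, ], ng)
    if (sum(M) > 0)
      glcm_per[[length(glcm_per) + 1]] <- oracle_glcm_features_one(M)
    R <- oracle_glrlm_one(lev, ORACLE_OFFSETS[m, ], ng)
    if (sum(R) > 0)
      glrlm_per[[length(glrlm_per) + 1]] <- oracle_glrlm_features_one(R, n)
  }
  avg <- function(per) {
    nm <- names(per[[1]])
    out <- sapply(nm, function(f) mean(sapply(per, `[[`, f)))
    as.list(out)
  }
  sz <- oracle_glszm_features(oracle_glszm(lev, ng), n)
  c(list(MTV = n * prod(spacing) / 1000, SUVmin = lo, SUVmax = hi,
         SUVmean = mu, SUVdiff = hi - lo,
         Variance = m2,
         Skewness = if (m2 == 0) 0 else m3 / m2^1.5,
         Kurtosis = if (m2 == 0) 0 else m4 / m2^2,
         Entropy.image = -sum(hp * log2(hp)),
         STD = sqrt(m2), Energy = sum(hp^2)),
    avg(glcm_per), avg(glrlm_per), sz)
}

# Random discretized level grid: ~prob_in of voxels in-VOI, levels 1..ng.
random_levels <- function(dims, ng, seed, prob_in = 0.8) {
  set.seed(seed)
  repeat {
    lev <- array(ifelse(stats::runif(prod(dims)) < prob_in,
                        sample.int(ng, prod(dims), replace = TRUE), 0L),
                 dims)
    if (sum(lev > 0) >= 2) return(lev)
  }
}

# Small test phantom: one lesion, optional blur/noise, compact grid.
tiny_spec <- function(peak = 8, radius = 10, fwhm = 0, noise = 0,
                      grid = c(16L, 16L, 20L), bg = 1, seed = 1L) {
  sp <- c(4.07, 4.07, 4.07)
  ctr <- (floor(grid / 2)) * sp  # a voxel centre: the profile peak is sampled
  phantom_spec(grid_shape = grid, voxel_spacing_mm = sp, background_suv = bg,
               lesion_centers_mm = list(ctr),
               lesion_radii_mm = radius, lesion_peak_suv = peak,
               psf_fwhm_mm = fwhm, noise_scale = noise, seed = seed)
}
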