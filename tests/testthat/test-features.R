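img_from <- function(vals) phantom_image(vals, c(4.07, 4.07, 4.07))

test_that("discretization spans the in-VOI range with fixed bin count", {
  vals <- array(5, c(3, 3, 3))
  mask <- array(TRUE, c(3, 3, 3))
  d <- discretize(img_from(vals), mask, 255)
  expect_true(all(d$levels[mask] == 1L))   # constant VOI -> all level 1
  vals2 <- array(0, c(2, 1, 1)); vals2[2] <- 1
  d2 <- discretize(phantom_image(array(vals2, c(2, 1, 1)),
                                 c(1, 1, 1)), array(TRUE, c(2, 1, 1)), 2)
  expect_equal(sort(d2$levels), c(1L, 2L))
  # Uniform random values fill the 255 levels approximately uniformly
  set.seed(5)
  vals3 <- array(runif(8000), c(20, 20, 20))
  d3 <- discretize(img_from(vals3), array(TRUE, c(20, 20, 20)), 255)
  h <- tabulate(d3$levels, 255)
  chi2 <- sum((h - mean(h))^2 / mean(h))
  expect_lt(chi2, qchisq(0.999, 254))
  expect_gte(min(d3$levels), 1L)
  expect_lte(max(d3$levels), 255L)
})

test_that("first-order moments follow their analytic limits", {
  vals <- array(1, c(3, 1, 1)); vals[2] <- 2; vals[3] <- 3
  img <- phantom_image(array(vals, c(3, 1, 1)), c(1, 1, 1))
  fo <- first_order_features(img, array(TRUE, c(3, 1, 1)))
  expect_equal(fo$Skewness, 0)
  expect_equal(fo$Variance, 2 / 3)
  cn <- array(4, c(3, 3, 3))
  foc <- first_order_features(img_from(cn), array(TRUE, c(3, 3, 3)))
  expect_equal(foc$Entropy.image, 0)
  expect_equal(foc$Energy, 1)
  expect_equal(foc$Variance, 0)
  expect_true(foc$degenerate)
  # Non-excess kurtosis of a normal sample is ~3
  set.seed(11)
  vn <- array(rnorm(10000), c(100, 100, 1))
  fon <- first_order_features(phantom_image(vn - min(vn) + 0.1, c(1, 1, 1)),
                              array(TRUE, c(100, 100, 1)))
  expect_equal(fon$Kurtosis, 3, tolerance = 0.15 / 3)
})

test_that("co-occurrence counting matches exhaustive pair enumeration", {
  # Two-voxel VOI along axis 3
  lev <- array(0L, c(1, 1, 2)); lev[1, 1, 1] <- 1L; lev[1, 1, 2] <- 2L
  g <- build_glcm(discretized_voi(lev, 2))
  offs <- orgpet:::direction_offsets13()
  ax3 <- which(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 1)
  expect_equal(g[[ax3]], matrix(c(0, 1, 1, 0), 2, 2))
  for (m in setdiff(seq_len(13), ax3)) expect_equal(sum(g[[m]]), 0)
  # Constant 3x3x3 VOI: all mass on (1,1); pair count per offset is the
  # combinatorial number of in-grid pairs, doubled by symmetrization
  levc <- array(1L, c(3, 3, 3))
  gc_ <- build_glcm(discretized_voi(levc, 1))
  for (m in seq_len(13)) {
    off <- offs[m, ]
    npairs <- prod(3 - abs(off))
    expect_equal(gc_[[m]][1, 1], 2 * npairs)
  }
  # Direction sets agree up to ordering (canonicalised rows)
  canon <- function(o) apply(o, 1, function(v)
    paste(if (v[3] < 0 || (v[3] == 0 && (v[2] < 0 || (v[2] == 0 && v[1] < 0))))
      -v else v, collapse = ","))
  expect_setequal(canon(offs), canon(ORACLE_OFFSETS))
  # Random levels with empty voxels: exact match with the loop oracle
  for (seed in 1:5) {
    lev <- random_levels(c(4, 4, 4), 5, seed)
    g <- build_glcm(discretized_voi(lev, 5))
    for (m in seq_len(13)) {
      MM <- oracle_glcm_one(lev, offs[m, ], max(lev))
      expect_equal(unname(g[[m]][seq_len(nrow(MM)), seq_len(ncol(MM))]),
                   unname(MM))
    }
  }
})

test_that("GLCM features match the literal-formula oracle", {
  # Degenerate single-level matrix
  levc <- array(1L, c(3, 3, 3))
  fc <- glcm_features(build_glcm(discretized_voi(levc, 1)))
  expect_equal(fc$Contrast, 0)
  expect_equal(fc$Dissimilarity, 0)
  expect_equal(fc$`Homogeneity.1`, 1)
  expect_equal(fc$`Joint Entropy.2`, 0)
  expect_equal(fc$Correlation, 1)
  # 3-D checkerboard: along any axis every pair differs by exactly 1
  idx <- expand.grid(1:4, 1:4, 1:4)
  lev <- array(1L + (rowSums(idx) %% 2L), c(4, 4, 4))
  g <- build_glcm(discretized_voi(lev, 2))
  offs <- orgpet:::direction_offsets13()
  for (m in which(rowSums(abs(offs)) == 1)) {
    f1 <- glcm_features(g[m])
    expect_equal(f1$Contrast, 1)
    expect_equal(f1$Dissimilarity, 1)
  }
  # Random VOIs: all 8 features vs oracle within 1e-9 relative
  for (seed in 6:10) {
    lev <- random_levels(c(4, 4, 4), 6, seed)
    f <- glcm_features(build_glcm(discretized_voi(lev, 6)))
    per <- list()
    offs <- orgpet:::direction_offsets13()
    for (m in seq_len(13)) {
      MM <- oracle_glcm_one(lev, offs[m, ], max(lev))
      if (sum(MM) > 0) per[[length(per) + 1]] <- oracle_glcm_features_one(MM)
    }
    for (nm in names(f)) {
      ov <- mean(sapply(per, `[[`, nm))
      expect_equal(f[[nm]], ov, tolerance = 1e-9)
    }
  }
})

test_that("run-length matrices and features match the run-walk oracle", {
  # Single axial run of length 4
  lev <- array(1L, c(1, 1, 4))
  rl <- build_glrlm(discretized_voi(lev, 1))
  offs <- orgpet:::direction_offsets13()
  ax3 <- which(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 1)
  expect_equal(ncol(rl[[ax3]]), 4)
  expect_equal(rl[[ax3]][1, 4], 1)
  f1 <- glrlm_features(rl[ax3], n_voxels = 4)
  expect_equal(f1$`Long.Run.Emphasis`, 16)
  expect_equal(f1$`Short.Run.Emphasis`, 1 / 16)
  expect_equal(f1$`Run.Percentage`, 1 / 4)
  # All-distinct levels: every run has length 1 in every direction
  lev2 <- array(seq_len(27), c(3, 3, 3))
  f2 <- glrlm_features(build_glrlm(discretized_voi(lev2, 27)), 27)
  expect_equal(f2$`Short.Run.Emphasis`, 1)
  expect_equal(f2$`Long.Run.Emphasis`, 1)
  expect_equal(f2$`Run.Percentage`, 1)
  # Random VOIs vs oracle
  for (seed in 11:15) {
    lev <- random_levels(c(4, 4, 4), 4, seed)
    rl <- build_glrlm(discretized_voi(lev, 4))
    offs <- orgpet:::direction_offsets13()
    for (m in seq_len(13)) {
      RR <- oracle_glrlm_one(lev, offs[m, ], max(lev))
      expect_equal(sum(rl[[m]]), sum(RR))
      expect_equal(unname(rl[[m]][seq_len(nrow(RR)), seq_len(ncol(RR))]),
                   unname(RR))
    }
  }
})

test_that("size-zone matrices and features match the flood-fill oracle", {
  # One 27-voxel zone
  lev <- array(1L, c(3, 3, 3))
  sz <- glszm_features(build_glszm(discretized_voi(lev, 1)), 27)
  expect_equal(sz$ZonePercentage, 1 / 27)
  expect_equal(sz$LargeAreaEmphasis, 729)
  # All-distinct levels: all zones are singletons
  lev2 <- array(seq_len(27), c(3, 3, 3))
  sz2 <- glszm_features(build_glszm(discretized_voi(lev2, 27)), 27)
  expect_equal(sz2$ZonePercentage, 1)
  expect_equal(sz2$LargeAreaEmphasis, 1)
  # Random VOIs vs oracle
  for (seed in 16:20) {
    lev <- random_levels(c(4, 4, 4), 3, seed)
    S <- build_glszm(discretized_voi(lev, 3))
    SS <- oracle_glszm(lev, max(lev))
    expect_equal(unname(S), unname(SS))
  }
})

test_that("the full 35-feature vector is complete, named and deterministic", {
  set.seed(33)
  vals <- array(runif(125, 1, 9), c(5, 5, 5))
  mask <- array(runif(125) < 0.8, c(5, 5, 5))
  mask[3, 3, 3] <- TRUE
  img <- img_from(vals)
  fv <- extract_all(img, mask)
  expect_identical(names(fv), table2_feature_names())
  expect_length(fv, 35)
  expect_identical(fv, extract_all(img, mask))
  # Entropies non-negative, percentages in (0, 1]
  expect_gte(fv[["Entropy.image"]], 0)
  expect_gte(fv[["Joint Entropy.2"]], 0)
  expect_true(fv[["Run.Percentage"]] > 0 && fv[["Run.Percentage"]] <= 1)
  expect_true(fv[["ZonePercentage"]] > 0 && fv[["ZonePercentage"]] <= 1)
})

test_that("a degenerate constant VOI returns the flagged limit values", {
  vals <- array(3, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  fv <- extract_all(img_from(vals), mask)
  expect_true(attr(fv, "degenerate"))
  expect_equal(fv[["SUVdiff"]], 0)
  expect_equal(fv[["Entropy.image"]], 0)
  expect_equal(fv[["Joint Entropy.2"]], 0)
  expect_equal(fv[["Sum Entropy.3"]], 0)
  expect_equal(fv[["Skewness"]], 0)
  expect_equal(fv[["Kurtosis"]], 0)
})

test_that("features are invariant where they must be, and only there", {
  set.seed(44)
  vals <- array(runif(64, 2, 10), c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  img <- img_from(vals)
  fv <- extract_all(img, mask)
  # Intensity shift: all discretized texture features unchanged
  fv_shift <- extract_all(img_from(vals + 5), mask)
  tex <- setdiff(table2_feature_names(),
                 c("SUVmin", "SUVmax", "SUVmean"))
  expect_equal(fv_shift[tex], fv[tex], tolerance = 1e-9)
  # Permutation inside the VOI: first-order invariant, texture not
  set.seed(45)
  perm <- sample(64)
  vp <- array(vals[perm], c(4, 4, 4))
  fv_perm <- extract_all(img_from(vp), mask)
  first <- c("MTV", "SUVmin", "SUVmax", "SUVmean", "SUVdiff", "Variance",
             "Skewness", "Kurtosis", "Entropy.image", "STD", "Energy")
  expect_equal(fv_perm[first], fv[first], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(fv_perm[["Joint Entropy.2"]],
                                fv[["Joint Entropy.2"]], tolerance = 1e-6)))
})

test_that("the full vector matches the frozen oracle snapshot", {
  set.seed(77)
  vals <- array(runif(125, 1, 9), c(5, 5, 5))
  mask <- array(runif(125) < 0.85, c(5, 5, 5))
  mask[3, 3, 3] <- TRUE
  fv <- extract_all(img_from(vals), mask, n_bins = 16)
  oc <- oracle_extract_all(vals, mask, c(4.07, 4.07, 4.07), 16L)
  for (nm in table2_feature_names())
    expect_equal(fv[[nm]], oc[[nm]], tolerance = 1e-9, label = nm)
})
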