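test_that("shape features: counts, disks and rectangles", {
  m <- disk_mask(41, 12)
  sf <- shape_features(m, 0.5)
  expect_length(sf, 14)
  expect_named(sf, paste0(rep("", 14), nodiomics:::SHAPE_FEATURES))
  expect_lt(abs(sf[["Elongation"]] - 1), 0.05)
  # axis-aligned 20 x 10 rectangle: elongation 0.5 via the moments oracle
  r <- matrix(FALSE, 30, 30); r[6:25, 11:20] <- TRUE
  sr <- shape_features(r, 1)
  expect_lt(abs(sr[["Elongation"]] - 0.5), 0.05)
  co <- which(r, arr.ind = TRUE)
  ev <- eigen(cov(co) * (nrow(co) - 1) / nrow(co))$values
  expect_equal(sr[["MajorAxisMm"]], 4 * sqrt(ev[1]), tolerance = 1e-10)
  expect_equal(sr[["MinorAxisMm"]], 4 * sqrt(ev[2]), tolerance = 1e-10)
  expect_equal(sr[["AreaMm2"]], 200)
  expect_error(shape_features(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("shape features are stable under 90-degree rotation", {
  for (s in 1:5) {
    m <- random_blob(seed = 30 + s)
    a <- shape_features(m, 0.5)
    b <- shape_features(t(m)[ncol(m):1, ], 0.5)
    for (f in c("AreaMm2", "Elongation"))
      expect_lt(abs(a[[f]] - b[[f]]) / max(a[[f]], 1e-12), 0.02)
  }
})

test_that("first-order features match direct summation", {
  img <- matrix(0, 2, 2); img[] <- c(1, 2, 3, 4)
  msk <- matrix(TRUE, 2, 2)
  fo <- first_order_features(img, msk)
  expect_length(fo, 18)
  expect_equal(fo[["Mean"]], 2.5)
  expect_equal(fo[["Median"]], 2.5)
  expect_equal(fo[["Variance"]], 1.25)   # population variance
  # random ROIs against naive formulas
  for (s in 1:100) {
    set.seed(s)
    v <- rnorm(17)
    img <- matrix(c(v, 0, 0, 0), 5, 4)
    msk <- matrix(c(rep(TRUE, 17), rep(FALSE, 3)), 5, 4)
    fo <- first_order_features(img, msk)
    expect_equal(fo[["Mean"]], sum(v) / 17, tolerance = 1e-12)
    expect_equal(fo[["Variance"]], sum((v - mean(v))^2) / 17, tolerance = 1e-12)
    expect_equal(fo[["Energy"]], sum(v^2), tolerance = 1e-12)
    expect_equal(fo[["RootMeanSquared"]], sqrt(mean(v^2)), tolerance = 1e-12)
  }
})

test_that("a constant ROI has degenerate first-order statistics", {
  img <- matrix(7, 6, 6); msk <- matrix(TRUE, 6, 6)
  fo <- first_order_features(img, msk)
  expect_equal(fo[["Variance"]], 0)
  expect_equal(fo[["Range"]], 0)
  expect_equal(fo[["Entropy"]], 0)
  expect_equal(fo[["Uniformity"]], 1)
})

test_that("texture families have the documented counts", {
  co <- tiny_cohort(2, seed = 4, image_size = 48)
  tx <- texture_features(co$images[[1]], co$masks[[1]])
  expect_length(tx, 75)
  fams <- sub("_.*", "", names(tx))
  expect_equal(as.integer(table(fams)[c("glcm", "gldm", "glrlm", "glszm",
                                        "ngtdm")]),
               c(24L, 14L, 16L, 16L, 5L))
  expect_true(all(is.finite(tx)))
})

test_that("the GLCM equals a brute-force tally over all ordered pixel pairs", {
  # the printed 2x2 example first
  bins <- matrix(c(1L, 1L, 1L, 2L), 2, 2)
  P <- glcm_matrix(bins, 2, 1)
  expect_equal(P, brute_glcm(bins, 1, 2))
  # random small instances
  for (s in 1:100) {
    set.seed(400 + s)
    n <- sample(3:8, 1)
    msk <- matrix(runif(n * n) > 0.25, n, n)
    if (sum(msk) < 3) next
    img <- matrix(rnorm(n * n), n, n)
    nb <- sample(2:6, 1)
    bins <- discretize(img, msk, nb)
    expect_equal(glcm_matrix(bins, nb, 1), brute_glcm(bins, 1, nb))
  }
})

test_that("moment-form GLCM features match pair-list expectations", {
  # contrast = E[(g1-g2)^2], autocorrelation = E[g1 g2], etc., computed on
  # the explicit ordered-pair list -- an algebraically independent route
  for (s in 1:50) {
    set.seed(500 + s)
    n <- sample(4:8, 1)
    msk <- matrix(runif(n * n) > 0.2, n, n)
    if (sum(msk) < 4) next
    img <- matrix(rnorm(n * n), n, n)
    nb <- 4
    bins <- discretize(img, msk, nb)
    pr <- brute_glcm_pairs(bins, 1)
    if (length(pr$g1) == 0) next
    fx <- nodiomics:::glcm_features(glcm_matrix(bins, nb, 1), nb)
    expect_equal(fx[["Contrast"]], mean((pr$g1 - pr$g2)^2), tolerance = 1e-10)
    expect_equal(fx[["Autocorrelation"]], mean(pr$g1 * pr$g2), tolerance = 1e-10)
    expect_equal(fx[["DifferenceAverage"]], mean(abs(pr$g1 - pr$g2)),
                 tolerance = 1e-10)
    expect_equal(fx[["Id"]], mean(1 / (1 + abs(pr$g1 - pr$g2))), tolerance = 1e-10)
    expect_equal(fx[["JointAverage"]], mean(pr$g1), tolerance = 1e-10)
    sdp <- function(v) sqrt(mean((v - mean(v))^2))
    if (sdp(pr$g1) > 0)
      expect_equal(fx[["Correlation"]],
                   mean((pr$g1 - mean(pr$g1)) * (pr$g2 - mean(pr$g2))) /
                     (sdp(pr$g1) * sdp(pr$g2)), tolerance = 1e-10)
  }
})

test_that("a constant ROI follows the degenerate texture conventions", {
  img <- matrix(5, 8, 8); msk <- matrix(TRUE, 8, 8)
  tx <- texture_features(img, msk)
  expect_equal(tx[["glcm_Contrast"]], 0)
  expect_equal(tx[["glcm_Correlation"]], 1)
  expect_equal(tx[["ngtdm_Contrast"]], 0)
  # run matrix: a single maximal run per line, by direct enumeration
  bins <- discretize(img, msk, 32)
  expect_equal(glrlm_matrix(bins, 32), brute_glrlm(bins, 32))
})

test_that("run-length and size-zone matrices match enumeration oracles", {
  for (s in 1:60) {
    set.seed(600 + s)
    n <- sample(4:8, 1)
    msk <- matrix(runif(n * n) > 0.2, n, n)
    if (sum(msk) < 4) next
    img <- matrix(rnorm(n * n), n, n)
    nb <- sample(2:4, 1)
    bins <- discretize(img, msk, nb)
    expect_equal(glrlm_matrix(bins, nb), brute_glrlm(bins, nb))
    expect_equal(glszm_matrix(bins, nb), brute_glszm(bins, nb))
  }
})

test_that("GLDM dependence sizes match a per-pixel neighbour count", {
  for (s in 1:30) {
    set.seed(700 + s)
    n <- sample(4:7, 1)
    msk <- matrix(runif(n * n) > 0.2, n, n)
    if (sum(msk) < 4) next
    img <- matrix(rnorm(n * n), n, n)
    bins <- discretize(img, msk, 3)
    P <- gldm_matrix(bins, 3)
    # oracle: explicit loop
    O <- matrix(0, 3, 9)
    for (r in seq_len(n)) for (c in seq_len(n)) {
      if (bins[r, c] == 0) next
      dep <- 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= n &&
            bins[r2, c2] == bins[r, c]) dep <- dep + 1
      }
      O[bins[r, c], dep] <- O[bins[r, c], dep] + 1
    }
    expect_equal(P, O)
  }
})

test_that("NGTDM features match a direct per-pixel computation", {
  for (s in 1:30) {
    set.seed(800 + s)
    n <- 5
    msk <- matrix(runif(n * n) > 0.2, n, n)
    if (sum(msk) < 4) next
    img <- matrix(rnorm(n * n), n, n)
    nb <- 3
    bins <- discretize(img, msk, nb)
    got <- ngtdm_features(bins, nb)
    # oracle: explicit s_i / p_i accumulation
    si <- numeric(nb); ni <- numeric(nb)
    for (r in seq_len(n)) for (c in seq_len(n)) {
      if (bins[r, c] == 0) next
      nbv <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= n && bins[r2, c2] > 0)
          nbv <- c(nbv, bins[r2, c2])
      }
      if (length(nbv) == 0) next
      g <- bins[r, c]
      ni[g] <- ni[g] + 1
      si[g] <- si[g] + abs(g - mean(nbv))
    }
    N <- sum(ni); pi_ <- ni / N
    expect_equal(got[["Coarseness"]],
                 if (sum(pi_ * si) > 0) min(1 / sum(pi_ * si), 1e6) else 1e6,
                 tolerance = 1e-10)
    pres <- which(ni > 0)
    if (length(pres) > 1) {
      contr <- 0
      for (i in pres) for (j in pres) contr <- contr + pi_[i] * pi_[j] * (i - j)^2
      contr <- contr / (length(pres) * (length(pres) - 1)) * sum(si) / N
      expect_equal(got[["Contrast"]], contr, tolerance = 1e-10)
    }
  }
})

test_that("the filter bank has 14 stable outputs with correct flat-field response", {
  img <- matrix(3.7, 16, 16)
  fb <- filter_bank(img, spacing = 0.5)
  expect_length(fb, 14)
  expect_named(fb, nodiomics:::FILTER_NAMES)
  expect_true(all(abs(fb[["wavelet.LL1"]] - 3.7) < 1e-12))
  for (f in c("wavelet.LH1", "wavelet.HL1", "wavelet.HH1", "wavelet.HH2",
              "gradient"))
    expect_true(all(abs(fb[[f]]) < 1e-12))
  expect_error(filter_bank(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("point transforms follow their elementwise definitions", {
  img <- matrix(c(0, 1, 2, 5), 2, 2) - 3  # negative values force the shift
  fb <- filter_bank(img, spacing = 1)
  y <- img - min(img)
  expect_equal(fb[["square"]], y^2, tolerance = 1e-12)
  expect_equal(fb[["squareroot"]], sqrt(y), tolerance = 1e-12)
  expect_equal(fb[["logarithm"]], log1p(y), tolerance = 1e-12)
  expect_true(all(order(fb[["square"]]) == order(y)))  # monotone
})

test_that("the complete extraction yields exactly 1,409 uniquely named features", {
  co <- tiny_cohort(1, seed = 6, image_size = 48)
  fv <- extract_features(co$images[[1]], co$masks[[1]], co$spacing)
  expect_length(fv, 1409)
  expect_false(any(duplicated(names(fv))))
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_names())
  fv2 <- extract_features(co$images[[1]], co$masks[[1]], co$spacing)
  expect_identical(fv, fv2)
  expect_length(feature_names(), 1409)
})

test_that("first-order features ignore pixel arrangement; GLCM does not", {
  set.seed(99)
  img <- matrix(rnorm(25), 5, 5)
  msk <- matrix(TRUE, 5, 5)
  perm <- matrix(sample(img), 5, 5)
  a <- first_order_features(img, msk); b <- first_order_features(perm, msk)
  expect_equal(a, b, tolerance = 1e-12)
  ta <- texture_features(img, msk); tb <- texture_features(perm, msk)
  expect_false(isTRUE(all.equal(ta[["glcm_Contrast"]], tb[["glcm_Contrast"]])))
})

test_that("texture features are invariant to bin-preserving intensity shifts", {
  set.seed(12)
  img <- matrix(rnorm(64), 8, 8)
  msk <- matrix(runif(64) > 0.2, 8, 8)
  a <- texture_features(img, msk)
  b <- texture_features(img + 17.3, msk)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("feature tables are rectangular and complete", {
  co <- tiny_cohort(3, seed = 13, image_size = 48)
  tab <- extract_feature_table(co, filters = c("gradient", "square"))
  expect_equal(nrow(tab), 6)
  expect_equal(ncol(tab), 2 + 14 + 93 * 3)
  expect_false(anyNA(tab))
  m <- feature_matrix(tab)
  expect_identical(rownames(m), co$records$node_id)
})
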