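test_that("shape features match brute-force moments and calipers on fixtures", {
  d <- raster_disc(10)
  sf <- shape_features(d)
  expect_equal(sf[["MinorMajorRatio"]], 1, tolerance = 0.02)
  expect_equal(sf[["FormFactor"]], 1, tolerance = 0.05)
  expect_equal(sf[["Area"]], sum(d))
  expect_equal(sf[["EquivalentDiameter"]], 2 * sqrt(sum(d) / pi))

  # ellipse with semi-axes 20 (cols) x 10 (rows): full minor axis 20
  e <- raster_ellipse(20, 10)
  sf <- shape_features(e)
  oracle <- brute_moment_axes(e)
  expect_equal(sf[["MinorAxisLength"]], oracle[["minor"]])
  expect_equal(sf[["MajorAxisLength"]], oracle[["major"]])
  expect_lt(abs(sf[["MinorAxisLength"]] - 20), 0.5)
  expect_lt(abs(sf[["MinFeretDiameter"]] - 20), 1)
  expect_lt(abs(sf[["MaxFeretDiameter"]] - 40), 1)
  expect_equal(sf[["Eccentricity"]],
               sqrt(1 - (sf[["MinorAxisLength"]] / sf[["MajorAxisLength"]])^2))

  sq <- matrix(1, 11, 11)
  sf <- shape_features(sq)
  expect_equal(sf[["Extent"]], 1)
  expect_equal(sf[["Solidity"]], 1)
  expect_error(shape_features(matrix(0, 5, 5)), "empty")
})

test_that("shape features are translation invariant and rotation stable", {
  e <- raster_ellipse(14, 7)
  big <- matrix(0, 120, 120)
  big[31:(30 + nrow(e)), 41:(40 + ncol(e))] <- e
  f1 <- shape_features(e)
  f2 <- shape_features(big)
  expect_equal(f1, f2)
  # 90 degree rotation: axis lengths within 1%
  rot <- t(e)[ncol(e):1, ]
  f3 <- shape_features(rot)
  expect_equal(f3[["MinorAxisLength"]], f1[["MinorAxisLength"]],
               tolerance = 0.01)
  expect_equal(f3[["MajorAxisLength"]], f1[["MajorAxisLength"]],
               tolerance = 0.01)
})

test_that("GLCM matches hand-enumerated co-occurrences on stripe patterns", {
  # 1-px vertical stripes of two levels, horizontal offset, G = 2:
  # every pair is (0,1) or (1,0), so p(1,2) = p(2,1) = 1/2
  patch <- matrix(rep(c(0, 1), length.out = 8 * 8), 8, 8, byrow = TRUE)
  P <- glcm(patch, G = 2, offsets = list(c(0, 1)))
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  h <- haralick_features(P)
  expect_equal(h[["Contrast"]], 1)
  expect_equal(h[["InverseDifferenceMoment"]], 0.5)
  expect_equal(h[["Entropy"]], log(2))
})

test_that("constant patches take the degenerate texture limits", {
  h <- glcm_features(matrix(3.7, 9, 9))
  expect_equal(h[["Contrast"]], 0)
  expect_equal(h[["InverseDifferenceMoment"]], 1)
  expect_equal(h[["Entropy"]], 0)
  expect_equal(h[["AngularSecondMoment"]], 1)
  expect_true(all(is.finite(h)))
})

test_that("texture features are invariant to affine intensity rescaling", {
  set.seed(3)
  patch <- matrix(runif(144), 12, 12)
  mask <- matrix(runif(144) > 0.2, 12, 12)
  expect_equal(glcm_features(patch, mask),
               glcm_features(5 + 3 * patch, mask))
})

test_that("GLCM is symmetric, normalized and mask-restricted for any patch", {
  set.seed(7)
  for (i in 1:15) {
    patch <- matrix(rnorm(100), 10, 10)
    mask <- matrix(runif(100) > 0.4, 10, 10)
    if (sum(mask) < 4) next
    P <- glcm(patch, mask)
    expect_equal(sum(P), 1, tolerance = 1e-9)
    expect_equal(P, t(P))
    expect_true(all(P >= 0))
  }
  # pairs crossing the mask boundary are excluded: a masked-out stripe
  # between two constant regions yields a single-level GLCM
  patch <- matrix(rep(c(0, 9, 0), each = 15), 15, 3)
  mask <- matrix(TRUE, 15, 3)
  mask[, 2] <- FALSE
  patch[, 2] <- 9
  h <- glcm_features(patch, mask, offsets = list(c(0, 1), c(1, 0)))
  expect_equal(h[["Contrast"]], 0)
})

test_that("feature vector has exactly the 32 manifest entries, in order", {
  expect_length(feature_manifest(), 32)
  d <- raster_disc(8)
  img <- matrix(0.1, nrow(d), ncol(d))
  img[d > 0] <- 0.9
  fv <- feature_vector(d, img)
  expect_equal(names(fv), feature_manifest())
  fv2 <- feature_vector(d, img, ids = list(cell_id = "c1", histotype = "UDH"))
  expect_equal(ncol(fv2), 34)
  expect_identical(fv2[, feature_manifest()], fv)
  # determinism for a duplicate contour
  expect_identical(feature_vector(d, img), fv)
})

test_that("HG-DCIS cohorts have lower axis ratio than Normal on truth masks", {
  spec <- small_spec()
  ratio_of <- function(ht) {
    gr <- generate_roi(spec, histotype = ht, seed = 19)
    nuc <- gr$scene$nuclei
    myo <- which(nuc$type == "myoepithelial")
    mean(vapply(myo, function(i) {
      m <- gr$truth$label == i
      if (sum(m) < 20) return(NA_real_)
      ax <- brute_moment_axes(m)
      ax[["minor"]] / ax[["major"]]
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(ratio_of("HG_DCIS"), ratio_of("Normal"))
})

test_that("central size trim follows the closed-form retained count", {
  rec <- data.frame(roi_id = "r1", Area = 1:10)
  out <- trim_by_size(rec)
  expect_equal(out$Area, 2:9)
  # small n: floor(0.1 * 5) = 0 dropped from each end
  rec5 <- data.frame(roi_id = "r1", Area = c(3, 1, 4, 1, 5))
  expect_equal(trim_by_size(rec5), rec5)
  # closed form n - 2 * floor(0.1 n) against brute-force enumeration
  set.seed(5)
  for (n in 1:100) {
    rec <- data.frame(roi_id = "r1", Area = sample(n))
    expect_equal(nrow(trim_by_size(rec)), n - 2 * floor(0.1 * n))
  }
})

test_that("trim is per ROI, order preserving and monotone in fraction", {
  set.seed(9)
  rec <- data.frame(roi_id = rep(c("a", "b"), each = 20), Area = runif(40))
  t0 <- trim_by_size(rec, fraction = 0)
  expect_identical(t0, rec)
  t1 <- trim_by_size(rec, fraction = 0.1)
  t2 <- trim_by_size(rec, fraction = 0.3)
  expect_true(all(rownames(t2) %in% rownames(t1)))
  expect_equal(sum(t1$roi_id == "a"), 16)
  # retained rows keep their original relative order
  expect_true(!is.unsorted(match(rownames(t1), rownames(rec))))
  expect_error(trim_by_size(rec, fraction = 0.5), "fraction")
})
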