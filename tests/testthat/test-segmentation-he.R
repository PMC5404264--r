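test_that("center detection finds blobs and ignores flat maps", {
  expect_equal(nrow(detect_centers(matrix(0.5, 60, 60))), 0)

  g <- outer(1:100, 1:100,
             function(i, j) exp(-((i - 50)^2 + (j - 50)^2) / (2 * 6^2)))
  cand <- detect_centers(g)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt((cand$row - 50)^2 + (cand$col - 50)^2), 2)

  m <- matrix(0, 100, 120)
  m[outer(1:100, 1:120, function(i, j) (i - 50)^2 + (j - 40)^2 <= 64)] <- 1
  m[outer(1:100, 1:120, function(i, j) (i - 50)^2 + (j - 70)^2 <= 64)] <- 1
  two <- nonmax_suppress(detect_centers(m), 12)
  expect_equal(nrow(two), 2)
  d1 <- sqrt((two$row - 50)^2 + (two$col - 40)^2)
  d2 <- sqrt((two$row - 50)^2 + (two$col - 70)^2)
  expect_lt(min(d1), 5)
  expect_lt(min(d2), 5)
  expect_error(detect_centers(m, modifyList(he_params(),
                                            list(hough_radii = integer(0)))),
               "empty")
})

test_that("detection is equivariant under translation", {
  blob <- function(i0, j0) outer(1:140, 1:140, function(i, j)
    exp(-((i - i0)^2 + (j - j0)^2) / (2 * 5^2)))
  m1 <- blob(50, 60) + blob(85, 40)
  m2 <- blob(50 + 4, 60 + 7) + blob(85 + 4, 40 + 7)
  c1 <- nonmax_suppress(detect_centers(m1), 8)
  c2 <- nonmax_suppress(detect_centers(m2), 8)
  expect_equal(nrow(c1), nrow(c2))
  o1 <- c1[order(c1$row), ]
  o2 <- c2[order(c2$row), ]
  expect_equal(o2$row - o1$row, rep(4, nrow(c1)))
  expect_equal(o2$col - o1$col, rep(7, nrow(c1)))
})

test_that("non-maxima suppression keeps the strongest, separated survivors", {
  empty <- data.frame(row = integer(0), col = integer(0),
                      scale_source = character(0), response = numeric(0))
  expect_equal(nrow(nonmax_suppress(empty, 5)), 0)

  cand <- data.frame(row = c(10, 12), col = c(10, 12),
                     scale_source = "dog_small", response = c(0.9, 0.5))
  out <- nonmax_suppress(cand, 5)
  expect_equal(nrow(out), 1)
  expect_equal(out$response, 0.9)

  set.seed(12)
  cand <- data.frame(row = runif(100, 1, 200), col = runif(100, 1, 200),
                     scale_source = "dog_small", response = runif(100))
  out <- nonmax_suppress(cand, 15)
  dmat <- as.matrix(stats::dist(out[, c("row", "col")]))
  expect_true(all(dmat[upper.tri(dmat)] >= 15))
  expect_true(!is.unsorted(-out$response))
  expect_error(nonmax_suppress(cand, 0))
})

test_that("polar sampling locates boundaries and commutes with rotation", {
  expect_equal(extract_polar(matrix(2, 80, 80), c(40, 40), 32, 20)$values,
               matrix(2, 32, 20))

  disc <- raster_disc(15, pad = 25)
  ctr <- c((nrow(disc) + 1) / 2, (nrow(disc) + 1) / 2)
  p <- extract_polar(disc, ctr, 72, 30)
  steps <- apply(p$values, 1, function(v) which.max(abs(diff(v))) + 0.5)
  expect_true(all(abs(steps - 15) <= 1))

  # rotating the input by 90 degrees (4 ray steps of 16) cyclically shifts
  # the polar image by 4 rows
  set.seed(14)
  m <- matrix(runif(65 * 65), 65, 65)
  rot <- t(m)[65:1, ]
  p1 <- extract_polar(m, c(33, 33), 16, 30)
  p2 <- extract_polar(rot, c(33, 33), 16, 30)
  shifted <- p1$values[c(5:16, 1:4), ]
  expect_equal(p2$values, shifted, tolerance = 1e-12)
})

test_that("the polar snake recovers discs, ellipses and the smooth limit", {
  disc <- raster_disc(15, pad = 25)
  n <- nrow(disc)
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  con <- trace_contour(extract_polar(disc, ctr, 72, 30))
  expect_true(all(abs(con$radii - 15) <= 1))
  expect_s3_class(con, "nucleus_contour")
  expect_equal(nrow(con$vertices), 72)

  e <- raster_ellipse(20, 10, pad = 12)
  ce <- c((nrow(e) + 1) / 2, (ncol(e) + 1) / 2)
  cone <- trace_contour(extract_polar(e, ce, 72, 30))
  m <- myomorph:::rasterize_polygon(cone$vertices, dim(e))
  iou <- sum(m & e > 0) / sum(m | e > 0)
  expect_gte(iou, 0.85)

  # infinite smoothness forces a circle
  conc <- trace_contour(extract_polar(disc, ctr + 2, 72, 30),
                        smoothness_lambda = 1e9)
  expect_equal(length(unique(conc$radii)), 1)

  expect_error(trace_contour(extract_polar(matrix(1, 60, 60), c(30, 30),
                                           72, 25)),
               "no boundary evidence")
})

test_that("ROI segmentation matches truth counts and honors exclusion", {
  roi <- std_hg_roi()
  gr <- roi$gr
  cons <- segment_he_roi(roi$he0, exclusion_mask = gr$truth$exclusion)
  n_ref <- sum(gr$scene$nuclei$type != "fibroblast")
  expect_lt(abs(length(cons) - n_ref) / n_ref, 0.1)
  # all contours simple closed polygons inside the image, positive area
  for (con in cons) {
    expect_equal(nrow(con$vertices), 72)
    expect_true(all(con$vertices >= 1 & con$vertices <= 320))
    expect_gt(con$area_px, 0)
  }
  # no centroid in the exclusion zone
  for (con in cons)
    expect_false(gr$truth$exclusion[round(con$centroid[1]),
                                    round(con$centroid[2])])
  # full exclusion empties the output
  allmask <- matrix(TRUE, 320, 320)
  expect_length(segment_he_roi(roi$he0, exclusion_mask = allmask), 0)
  # determinism
  cons2 <- segment_he_roi(roi$he0, exclusion_mask = gr$truth$exclusion)
  expect_identical(lapply(cons, `[[`, "vertices"),
                   lapply(cons2, `[[`, "vertices"))
})
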