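test_that("parameter constructors enforce their invariants", {
  expect_error(class_morphology_params("Normal", 14, 1, 0.9, 0.05, 0.1, 0.9),
               "3 sd")
  expect_error(class_morphology_params("ADH", 14, 1, 0.7, 0.05, 0.1, 0.9))
  expect_error(cohort_spec(roi_size_px = 100), "roi_size")
  expect_error(cohort_spec(cases_per_class = c(Foo = 3)), "named by histotype")
  sp <- cohort_spec()
  expect_equal(sum(sp$cases_per_class), 22)
  expect_equal(unname(sp$cases_per_class), c(7, 5, 5, 5))
  expect_equal(sp$roi_size_px, 2174)
})

test_that("ROI generation is deterministic and respects the layout", {
  spec <- small_spec()
  a <- generate_roi(spec, histotype = "UDH", seed = 33)
  b <- generate_roi(spec, histotype = "UDH", seed = 33)
  expect_identical(a$truth$label, b$truth$label)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  expect_identical(a$truth$exclusion, b$truth$exclusion)

  nuc <- a$scene$nuclei
  expect_true(all(table(nuc$duct_id[nuc$type == "myoepithelial"]) >= 10))
  # every myoepithelial nucleus sits on its duct ring
  myo <- nuc[nuc$type == "myoepithelial", ]
  d <- a$scene$ducts[myo$duct_id, ]
  rad <- sqrt((myo$center_row - d$center_row)^2 +
              (myo$center_col - d$center_col)^2)
  expect_true(all(abs(rad - d$radius) < 1e-6))
  # fibroblasts flagged in the exclusion mask
  fib <- which(nuc$type == "fibroblast")
  for (i in fib) {
    ctr <- round(c(nuc$center_row[i], nuc$center_col[i]))
    expect_true(a$truth$exclusion[ctr[1], ctr[2]])
  }
})

test_that("zero ducts yields a stroma-only scene with empty nucleus truth", {
  spec <- cohort_spec(roi_size_px = 256, ducts_per_roi = 0)
  gr <- generate_roi(spec, histotype = "Normal", seed = 2)
  expect_equal(sum(gr$scene$nuclei$type %in% c("myoepithelial", "luminal")), 0)
  expect_error(generate_roi(cohort_spec(roi_size_px = 256, ducts_per_roi = 40),
                            histotype = "Normal", seed = 2),
               "infeasible packing")
})

test_that("truth-mask moments reproduce the class parameters", {
  spec <- cohort_spec(roi_size_px = 320, rois_per_case = 1, ducts_per_roi = 3,
                      nuclei_per_duct = c(12, 14))
  measure <- function(ht, seeds) {
    minors <- c(); ratios <- c()
    for (s in seeds) {
      gr <- generate_roi(spec, histotype = ht, seed = s)
      nuc <- gr$scene$nuclei
      for (i in which(nuc$type == "myoepithelial")) {
        m <- gr$truth$label == i
        if (sum(m) < 20) next
        ax <- brute_moment_axes(m)
        minors <- c(minors, ax[["minor"]])
        ratios <- c(ratios, ax[["minor"]] / ax[["major"]])
      }
    }
    list(minor = minors, ratio = ratios)
  }
  for (ht in c("Normal", "HG_DCIS")) {
    p <- default_morphology_params()[[ht]]
    mm <- measure(ht, 100 + 1:6)
    expect_gte(length(mm$minor), 200)
    # within 2 standard errors of the generating parameters
    expect_lt(abs(mean(mm$minor) - p$minor_axis_mean_px),
              2 * stats::sd(mm$minor) / sqrt(length(mm$minor)))
    expect_lt(abs(mean(mm$ratio) - p$minor_major_ratio_mean),
              2 * stats::sd(mm$ratio) / sqrt(length(mm$ratio)))
    # Normal parameters put the mean minor axis at 14 px; the mask-moment
    # estimate must agree within half a pixel
    if (ht == "Normal") expect_lt(abs(mean(mm$minor) - 14), 0.5)
  }
})

test_that("renderings align with the truth masks in both stains", {
  roi <- std_hg_roi()
  truthm <- roi$gr$truth$label > 0
  ref <- reference_stains()
  hem <- project_stain(rgb_to_od(roi$he0), ref$hematoxylin)
  iou_he <- sum((hem > 0.3) & truthm) / sum((hem > 0.3) | truthm)
  expect_gte(iou_he, 0.9)
  p630 <- render_stain(roi$gr$scene, "P63", noise_sd = 0)
  odp <- rgb_to_od(p630)
  nucmap <- pmax(project_stain(odp, ref$dab), project_stain(odp, ref$hematoxylin))
  iou_p63 <- sum((nucmap > 0.3) & truthm) / sum((nucmap > 0.3) | truthm)
  expect_gte(iou_p63, 0.9)
  expect_error(render_stain(roi$gr$scene, "PAS"))
})

test_that("noise-free rendering of a zero-contrast nucleus is flat", {
  params <- default_morphology_params()
  params$Normal$texture_contrast_level <- 0
  spec <- cohort_spec(roi_size_px = 256, rois_per_case = 1, ducts_per_roi = 1,
                      nuclei_per_duct = c(1, 1))
  gr <- generate_roi(spec, params, histotype = "Normal", seed = 9)
  img <- render_stain(gr$scene, "HE", noise_sd = 0)
  nuc <- gr$scene$nuclei
  i <- which(nuc$type == "myoepithelial")[1]
  m <- gr$truth$label == i
  for (ch in 1:3) expect_equal(stats::sd(img[, , ch][m]), 0)
})

test_that("an empty scene renders as near-uniform background", {
  spec <- cohort_spec(roi_size_px = 256, ducts_per_roi = 0)
  gr <- generate_roi(spec, histotype = "Normal", seed = 3)
  scene <- gr$scene
  scene$nuclei <- scene$nuclei[0, ]
  scene$pixels <- list()
  img <- render_stain(scene, "P63", noise_sd = 2)
  for (ch in 1:3) expect_lt(stats::sd(img[, , ch]), 2 * 1.5)
})

test_that("cohorts have the configured structure and write deterministically", {
  spec <- cohort_spec(cases_per_class = c(Normal = 1, UDH = 1, LG_DCIS = 1,
                                          HG_DCIS = 1),
                      rois_per_case = 1, ducts_per_roi = 1,
                      nuclei_per_duct = c(10, 10), roi_size_px = 256, seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  co1 <- make_cohort(spec, dir = d1)
  co2 <- make_cohort(spec, dir = d2)
  expect_equal(nrow(co1$truth_table), 40)  # 4 cases x 1 duct x 10 nuclei
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  expect_setequal(unique(co1$truth_table$histotype), histotype_levels())

  # full class structure: 22 cases split 7/5/5/5
  spec22 <- cohort_spec(rois_per_case = 1, ducts_per_roi = 1,
                        nuclei_per_duct = c(4, 5), roi_size_px = 256, seed = 4)
  co22 <- make_cohort(spec22)
  cases <- unique(co22$truth_table[c("case_id", "histotype")])
  expect_equal(nrow(cases), 22)
  expect_equal(unname(table(cases$histotype)[histotype_levels()]),
               c(7, 5, 5, 5), ignore_attr = TRUE)
})
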