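# Shared fixtures, all generated in code.

# session-level cache for expensive generated fixtures
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# rasterized disc: radius r, centered in a square matrix with padding
raster_disc <- function(r, pad = 5) {
  n <- 2 * r + 1 + 2 * pad
  c0 <- pad + r + 1
  m <- matrix(0, n, n)
  m[outer(seq_len(n), seq_len(n),
          function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)] <- 1
  m
}

# rasterized axis-aligned ellipse with semi-axes (a along cols, b along rows)
raster_ellipse <- function(a, b, pad = 5) {
  nr <- 2 * b + 1 + 2 * pad
  nc <- 2 * a + 1 + 2 * pad
  cr <- pad + b + 1
  cc <- pad + a + 1
  m <- matrix(0, nr, nc)
  m[outer(seq_len(nr), seq_len(nc),
          function(i, j) ((i - cr)^2 / b^2 + (j - cc)^2 / a^2) <= 1)] <- 1
  m
}

# brute-force moment minor/major axis lengths of a mask (independent oracle)
brute_moment_axes <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  n <- nrow(idx)
  cv <- stats::cov(idx) * (n - 1) / n
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  c(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(max(ev[2], 0)))
}

# small ROI spec used across segmentation tests
small_spec <- function(...) {
  cohort_spec(roi_size_px = 320, rois_per_case = 1, ducts_per_roi = 2,
              nuclei_per_duct = c(10, 14), ...)
}

# one HG-DCIS scene + zero-noise HE rendering, cached
std_hg_roi <- function() {
  fixture("std_hg_roi", {
    gr <- generate_roi(small_spec(), histotype = "HG_DCIS", seed = 42)
    list(gr = gr,
         he0 = render_stain(gr$scene, "HE", noise_sd = 0),
         p63 = render_stain(gr$scene, "P63", noise_sd = 2))
  })
}

# tiny pixel classifier trained on the std ROI, cached
std_pixel_classifier <- function() {
  fixture("std_pixel_classifier", {
    roi <- std_hg_roi()
    nuc <- roi$gr$scene$nuclei
    myo_ids <- nuc$nucleus_id[nuc$type == "myoepithelial"]
    lab <- matrix(2L, 320, 320)
    lab[roi$gr$truth$label %in% myo_ids] <- 1L
    train_pixel_classifier(roi$p63, lab, seed = 7, ntree = 50)
  })
}
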