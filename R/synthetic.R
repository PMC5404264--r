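# Synthetic duct-image generator: geometry scenes, stain rendering, cohorts.

#' Generate one synthetic ROI scene with ground truth
#'
#' Places non-overlapping ducts in a square tile; each duct boundary carries
#' a ring of myoepithelial nuclei (ellipses, major axis tangential, sizes
#' sampled from the class parameters). Proliferative classes (UDH, LG-DCIS,
#' HG-DCIS) additionally fill the duct interior with round luminal nuclei;
#' spindle-shaped fibroblast nuclei are scattered in the stroma and flagged
#' in the exclusion mask. Fully deterministic given the seed.
#'
#' @param spec \code{\link{cohort_spec}} (per-ROI fields are used).
#' @param params list of per-class \code{\link{class_morphology_params}}.
#' @param histotype class of this ROI.
#' @param seed integer seed for this ROI.
#' @return List with elements \code{scene} (class \code{myo_scene}: nucleus
#'   table with per-nucleus pixel lists, duct table, tile size, seed) and
#'   \code{truth} (class \code{myo_truth}: integer label image, nucleus
#'   table, logical fibroblast exclusion mask).
#' @export
generate_roi <- function(spec, params = default_morphology_params(),
                         histotype = "Normal", seed = spec$seed) {
  histotype <- match.arg(histotype, histotype_levels())
  cp <- params[[histotype]]
  n <- spec$roi_size_px
  with_seed(seed, {
    ducts <- place_ducts(n, spec$ducts_per_roi)
    nuclei <- list()
    # myoepithelial ring per duct
    for (d in seq_len(nrow(ducts))) {
      rng <- spec$nuclei_per_duct
      k <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
      nuclei[[length(nuclei) + 1]] <-
        ring_nuclei(ducts[d, ], k, cp, duct_id = d, histotype = histotype)
    }
    # luminal fill for proliferative classes
    if (histotype != "Normal") {
      for (d in seq_len(nrow(ducts)))
        nuclei[[length(nuclei) + 1]] <- luminal_nuclei(ducts[d, ], duct_id = d)
    }
    # stromal fibroblasts
    nuclei[[length(nuclei) + 1]] <- fibroblast_nuclei(n, ducts)
    nuc <- do.call(rbind, nuclei)
  })
  if (is.null(nuc)) {
    nuc <- data.frame(type = character(0), duct_id = integer(0),
                      histotype = character(0), center_row = numeric(0),
                      center_col = numeric(0), major_px = numeric(0),
                      minor_px = numeric(0), theta = numeric(0),
                      stain_factor = numeric(0), contrast_factor = numeric(0),
                      stringsAsFactors = FALSE)
  }
  # order: myoepithelial first so their truth masks win any overlap
  ord <- order(match(nuc$type, c("myoepithelial", "luminal", "fibroblast")))
  nuc <- nuc[ord, , drop = FALSE]
  nuc$nucleus_id <- seq_len(nrow(nuc))
  rownames(nuc) <- NULL

  label <- matrix(0L, n, n)
  pixels <- vector("list", nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    px <- ellipse_pixels(c(nuc$center_row[i], nuc$center_col[i]),
                         nuc$major_px[i], nuc$minor_px[i], nuc$theta[i],
                         c(n, n))
    free <- label[px] == 0L
    px <- px[free, , drop = FALSE]
    label[px] <- i
    pixels[[i]] <- px
  }
  excl <- matrix(FALSE, n, n)
  fib <- which(nuc$type == "fibroblast")
  if (length(fib)) {
    fm <- matrix(0L, n, n)
    for (i in fib) fm[pixels[[i]]] <- 1L
    fm <- EBImage::dilate(fm, EBImage::makeBrush(5, "disc"))
    excl <- as.matrix(fm) > 0
  }
  scene <- structure(list(roi_size = n, histotype = histotype, seed = seed,
                          ducts = ducts, nuclei = nuc, pixels = pixels,
                          params = cp),
                     class = "myo_scene")
  truth <- structure(list(label = label, nuclei = nuc, exclusion = excl),
                     class = "myo_truth")
  list(scene = scene, truth = truth)
}

# non-overlapping duct placement by rejection sampling
place_ducts <- function(n, k) {
  ducts <- data.frame(duct_id = integer(0), center_row = numeric(0),
                      center_col = numeric(0), radius = numeric(0))
  if (k == 0) return(ducts)
  margin <- 20
  tries <- 0
  while (nrow(ducts) < k) {
    r <- stats::runif(1, 0.13, 0.17) * n
    lo <- r + margin
    hi <- n - r - margin
    if (lo >= hi) stop("infeasible packing: duct radius exceeds tile")
    cr <- stats::runif(1, lo, hi)
    cc <- stats::runif(1, lo, hi)
    ok <- TRUE
    if (nrow(ducts)) {
      dd <- sqrt((ducts$center_row - cr)^2 + (ducts$center_col - cc)^2)
      ok <- all(dd > ducts$radius + r + 24)
    }
    if (ok) ducts[nrow(ducts) + 1, ] <- list(nrow(ducts) + 1L, cr, cc, r)
    tries <- tries + 1
    if (tries > 500 * k)
      stop("infeasible packing: could not place ", k, " ducts in a ",
           n, " px tile")
  }
  ducts
}

# ring of tangentially oriented elliptical nuclei on a duct boundary;
# angular slots sized by each nucleus's major axis so neighbors do not
# overlap whenever the ring circumference allows it
ring_nuclei <- function(duct, k, cp, duct_id, histotype) {
  minor <- pmax(3, stats::rnorm(k, cp$minor_axis_mean_px, cp$minor_axis_sd_px))
  ratio <- pmin(1, pmax(0.2, stats::rnorm(k, cp$minor_major_ratio_mean,
                                          cp$ratio_sd)))
  major <- minor / ratio
  r <- duct$radius
  ext <- major * 1.08 / r            # angular extent incl. small margin
  gap <- max(0, (2 * pi - sum(ext)) / k)
  phi <- cumsum(ext / 2 + c(0, ext[-k] / 2) + gap) + stats::runif(1, 0, 2 * pi)
  cr <- duct$center_row + r * sin(phi)
  cc <- duct$center_col + r * cos(phi)
  data.frame(type = "myoepithelial", duct_id = duct_id, histotype = histotype,
             center_row = cr, center_col = cc, major_px = major,
             minor_px = minor, theta = phi + pi / 2,
             stain_factor = stats::rlnorm(k, 0, 0.15),
             contrast_factor = stats::rlnorm(k, 0, 0.30),
             stringsAsFactors = FALSE)
}

# round-ish luminal nuclei on a jittered grid filling the duct interior
luminal_nuclei <- function(duct, duct_id, spacing = 13) {
  rin <- duct$radius - 14
  if (rin < spacing) return(NULL)
  g <- seq(-rin, rin, by = spacing)
  cen <- expand.grid(dr = g, dc = g)
  cen <- cen[sqrt(cen$dr^2 + cen$dc^2) <= rin - spacing / 2, , drop = FALSE]
  if (!nrow(cen)) return(NULL)
  k <- nrow(cen)
  jit <- matrix(stats::runif(2 * k, -2.5, 2.5), ncol = 2)
  minor <- pmax(3, stats::rnorm(k, 8, 0.8))
  ratio <- pmin(1, pmax(0.5, stats::rnorm(k, 0.85, 0.05)))
  data.frame(type = "luminal", duct_id = duct_id, histotype = NA_character_,
             center_row = duct$center_row + cen$dr + jit[, 1],
             center_col = duct$center_col + cen$dc + jit[, 2],
             major_px = minor / ratio, minor_px = minor,
             theta = stats::runif(k, 0, pi),
             stain_factor = stats::rlnorm(k, 0, 0.15),
             contrast_factor = stats::rlnorm(k, 0, 0.30),
             stringsAsFactors = FALSE)
}

# spindle-shaped stromal fibroblasts, kept clear of the ducts
fibroblast_nuclei <- function(n, ducts, density = 6 / 320^2) {
  k <- max(3, round(density * n^2))
  out <- NULL
  tries <- 0
  while (is.null(out) || nrow(out) < k) {
    cr <- stats::runif(1, 15, n - 15)
    cc <- stats::runif(1, 15, n - 15)
    clear <- TRUE
    if (nrow(ducts)) {
      dd <- sqrt((ducts$center_row - cr)^2 + (ducts$center_col - cc)^2)
      clear <- all(dd > ducts$radius + 22)
    }
    if (clear) {
      row <- data.frame(type = "fibroblast", duct_id = NA_integer_,
                        histotype = NA_character_, center_row = cr,
                        center_col = cc, major_px = 16.7, minor_px = 5,
                        theta = stats::runif(1, 0, pi),
                        stain_factor = stats::rlnorm(1, 0, 0.15),
                        contrast_factor = stats::rlnorm(1, 0, 0.30),
                        stringsAsFactors = FALSE)
      out <- rbind(out, row)
    }
    tries <- tries + 1
    if (tries > 1000 * k) break   # crowded tile: accept fewer fibroblasts
  }
  out
}

#' Render a scene as a stained RGB image
#'
#' Composes the image in optical-density space (Beer-Lambert mixing of the
#' reference stain absorbance vectors) and converts back to 8-bit RGB. In HE
#' every nucleus takes hematoxylin and the stroma a light eosin wash; in p63
#' myoepithelial nuclei take DAB (brown) while luminal and fibroblast nuclei
#' take the hematoxylin counterstain. Intra-nuclear speckle with the class's
#' texture-contrast amplitude and Gaussian pixel noise are added, seeded from
#' the scene seed (so rendering is deterministic).
#'
#' @param scene \code{myo_scene} from \code{\link{generate_roi}}.
#' @param stain \code{"HE"} or \code{"P63"}.
#' @param noise_sd Gaussian RGB noise SD in 8-bit units (default 2).
#' @param background background intensity (scalar, default 255).
#' @return row x col x 3 numeric array in [0, 255] with attributes
#'   \code{stain}, \code{histotype} and \code{noise_sd}.
#' @export
render_stain <- function(scene, stain = c("HE", "P63"), noise_sd = 2,
                         background = 255) {
  stain <- match.arg(stain)
  n <- scene$roi_size
  ref <- reference_stains()
  hem <- matrix(0, n, n)
  eos <- matrix(0, n, n)
  dab <- matrix(0, n, n)
  nuc <- scene$nuclei
  with_seed(scene$seed * 7L + ifelse(stain == "HE", 1L, 2L), {
    if (stain == "HE") eos[] <- 0.18
    for (i in seq_len(nrow(nuc))) {
      px <- scene$pixels[[i]]
      if (!nrow(px)) next
      type <- nuc$type[i]
      # per-nucleus staining variability (serial-section consistent: the
      # factors are part of the scene, shared by both renderings)
      if (type == "myoepithelial") {
        base <- scene$params$stain_intensity * nuc$stain_factor[i]
        amp <- scene$params$texture_contrast_level * nuc$contrast_factor[i]
      } else {
        base <- 0.75 * nuc$stain_factor[i]
        amp <- 0.06 * nuc$contrast_factor[i]
      }
      conc <- base * (1 + amp * stats::runif(nrow(px), -1, 1))
      if (stain == "HE") {
        hem[px] <- conc
        eos[px] <- 0.05
      } else {
        if (type == "myoepithelial") dab[px] <- conc
        else hem[px] <- 0.65 * conc / base   # hematoxylin counterstain
      }
    }
    od <- array(0, c(n, n, 3))
    for (ch in 1:3)
      od[, , ch] <- hem * ref$hematoxylin[ch] + eos * ref$eosin[ch] +
        dab * ref$dab[ch]
    img <- od_to_rgb(od, rep(background, 3))
    if (noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
  })
  img <- round(pmin(pmax(img, 0), 255))
  attr(img, "stain") <- stain
  attr(img, "histotype") <- scene$histotype
  attr(img, "noise_sd") <- noise_sd
  img
}

#' Generate a full synthetic cohort
#'
#' Builds every case/ROI of the specified cohort: a shared geometry scene per
#' ROI rendered into both stains (emulating serial sections with exact
#' cross-stain correspondence), ground-truth label images, exclusion masks
#' and the myoepithelial truth table. Optionally writes the cohort to disk
#' (HE/p63 TIFFs, exclusion-mask PNGs, truth CSV, spec JSON).
#'
#' @param spec \code{\link{cohort_spec}}.
#' @param params per-class morphology parameters.
#' @param dir optional output directory; created if missing.
#' @param noise_sd rendering noise (see \code{\link{render_stain}}).
#' @return Object of class \code{myo_cohort}: list with \code{spec},
#'   \code{rois} (each holding case/ROI ids, histotype, scene, truth and the
#'   two renderings) and \code{truth_table} (one row per myoepithelial
#'   nucleus).
#' @export
make_cohort <- function(spec, params = default_morphology_params(),
                        dir = NULL, noise_sd = 2) {
  rois <- list()
  truth_rows <- list()
  case_idx <- 0
  for (cls in names(spec$cases_per_class)) {
    for (ci in seq_len(spec$cases_per_class[[cls]])) {
      case_idx <- case_idx + 1
      case_id <- sprintf("case%02d", case_idx)
      for (ri in seq_len(spec$rois_per_case)) {
        roi_id <- sprintf("%s_roi%d", case_id, ri)
        rs <- (spec$seed %% 10000L) * 100003L + case_idx * 131L + ri * 7L
        gr <- generate_roi(spec, params, histotype = cls, seed = rs)
        he <- render_stain(gr$scene, "HE", noise_sd = noise_sd)
        p63 <- render_stain(gr$scene, "P63", noise_sd = noise_sd)
        myo <- gr$truth$nuclei[gr$truth$nuclei$type == "myoepithelial", ,
                               drop = FALSE]
        if (nrow(myo)) {
          truth_rows[[length(truth_rows) + 1]] <- data.frame(
            cell_id = sprintf("%s_d%d_n%d", roi_id, myo$duct_id,
                              myo$nucleus_id),
            duct_id = sprintf("%s_d%d", roi_id, myo$duct_id),
            roi_id = roi_id, case_id = case_id, histotype = cls,
            center_row = myo$center_row, center_col = myo$center_col,
            major_px = myo$major_px, minor_px = myo$minor_px,
            theta_rad = myo$theta, stringsAsFactors = FALSE)
        }
        rois[[roi_id]] <- list(case_id = case_id, roi_id = roi_id,
                               histotype = cls, scene = gr$scene,
                               truth = gr$truth, he = he, p63 = p63)
      }
    }
  }
  truth_table <- do.call(rbind, truth_rows)
  rownames(truth_table) <- NULL
  cohort <- structure(list(spec = spec, params = params, rois = rois,
                           truth_table = truth_table),
                      class = "myo_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.myo_cohort <- function(x, ...) {
  tt <- x$truth_table
  cat("Synthetic cohort:", length(unique(tt$case_id)), "cases,",
      length(x$rois), "ROIs,", nrow(tt), "myoepithelial nuclei\n")
  print(table(histotype = tt$histotype[!duplicated(tt$case_id)]))
  invisible(x)
}

# write a cohort to disk as TIFF/PNG/CSV/JSON
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  for (roi in cohort$rois) {
    tiff::writeTIFF(roi$he / 255, file.path(dir, paste0(roi$roi_id, "_he.tiff")))
    tiff::writeTIFF(roi$p63 / 255, file.path(dir, paste0(roi$roi_id, "_p63.tiff")))
    png::writePNG(roi$truth$exclusion * 1,
                  file.path(dir, paste0(roi$roi_id, "_exclusion.png")))
  }
  utils::write.csv(cohort$truth_table, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  sp <- cohort$spec
  jsonlite::write_json(
    list(cases_per_class = as.list(sp$cases_per_class),
         rois_per_case = sp$rois_per_case, ducts_per_roi = sp$ducts_per_roi,
         nuclei_per_duct = sp$nuclei_per_duct, roi_size_px = sp$roi_size_px,
         seed = sp$seed, n_nuclei = nrow(cohort$truth_table)),
    file.path(dir, "cohort_spec.json"), auto_unbox = TRUE)
  invisible(dir)
}
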