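# Parameter objects for the synthetic cohort generator.

#' Per-class nuclear morphology parameters
#'
#' Encodes how myoepithelial nuclear morphology shifts with histological
#' class: nuclei flatten (smaller minor axis, lower minor/major ratio) and
#' their stain texture gains contrast from Normal through HG-DCIS.
#'
#' @param histotype one of \code{histotype_levels()}.
#' @param minor_axis_mean_px,minor_axis_sd_px mean/SD of the full minor-axis
#'   length in pixels (0.46 um/px).
#' @param minor_major_ratio_mean,ratio_sd mean/SD of minor/major axis ratio.
#' @param texture_contrast_level amplitude of intra-nuclear speckle (relative
#'   OD amplitude, >= 0).
#' @param stain_intensity peak stain concentration in (0, 1].
#' @return Object of class \code{class_morphology_params}.
#' @export
class_morphology_params <- function(histotype, minor_axis_mean_px,
                                    minor_axis_sd_px, minor_major_ratio_mean,
                                    ratio_sd, texture_contrast_level,
                                    stain_intensity) {
  histotype <- match.arg(histotype, histotype_levels())
  stopifnot(minor_axis_mean_px > 0, minor_axis_sd_px >= 0,
            minor_major_ratio_mean > 0, minor_major_ratio_mean <= 1,
            ratio_sd >= 0, texture_contrast_level >= 0,
            stain_intensity > 0, stain_intensity <= 1)
  if (minor_major_ratio_mean + 3 * ratio_sd > 1 ||
      minor_major_ratio_mean - 3 * ratio_sd <= 0)
    stop("ratio mean +/- 3 sd must stay within (0, 1]")
  structure(list(histotype = histotype,
                 minor_axis_mean_px = minor_axis_mean_px,
                 minor_axis_sd_px = minor_axis_sd_px,
                 minor_major_ratio_mean = minor_major_ratio_mean,
                 ratio_sd = ratio_sd,
                 texture_contrast_level = texture_contrast_level,
                 stain_intensity = stain_intensity),
            class = "class_morphology_params")
}

#' Default per-class morphology parameters
#'
#' Effect sizes follow the observed direction of change — DCIS myoepithelial
#' nuclei are flatter and more spindle-like with higher stain contrast —
#' with a monotone trend Normal > UDH > LG-DCIS > HG-DCIS in minor axis and
#' axis ratio, and rising texture contrast. Magnitudes are package defaults
#' (the per-class feature statistics of the source cohort are not published);
#' all values are configurable.
#'
#' @return Named list of four \code{class_morphology_params}, one per class.
#' @export
default_morphology_params <- function() {
  list(
    Normal = class_morphology_params("Normal", 14.0, 1.2, 0.75, 0.05, 0.05, 0.85),
    UDH = class_morphology_params("UDH", 13.0, 1.2, 0.70, 0.05, 0.08, 0.90),
    LG_DCIS = class_morphology_params("LG_DCIS", 11.5, 1.2, 0.60, 0.05, 0.12, 0.95),
    HG_DCIS = class_morphology_params("HG_DCIS", 10.0, 1.2, 0.52, 0.05, 0.16, 1.00)
  )
}

#' Cohort layout specification
#'
#' @param cases_per_class named integer vector of cases per histotype;
#'   default 7 Normal / 5 UDH / 5 LG-DCIS / 5 HG-DCIS (22 cases).
#' @param rois_per_case ROIs (tiles) per case.
#' @param ducts_per_roi ducts placed in each ROI.
#' @param nuclei_per_duct length-2 integer range of myoepithelial nuclei per
#'   duct ring (inclusive).
#' @param roi_size_px square tile side in pixels; the real ROIs are 2174 px
#'   (1 mm at 0.46 um/px).
#' @param seed base seed; all cohort randomness derives from it.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(cases_per_class = c(Normal = 7, UDH = 5,
                                            LG_DCIS = 5, HG_DCIS = 5),
                        rois_per_case = 2, ducts_per_roi = 2,
                        nuclei_per_duct = c(10, 14), roi_size_px = 2174,
                        seed = 1) {
  if (is.null(names(cases_per_class)) ||
      !all(names(cases_per_class) %in% histotype_levels()))
    stop("cases_per_class must be named by histotype")
  if (length(nuclei_per_duct) == 1) nuclei_per_duct <- rep(nuclei_per_duct, 2)
  stopifnot(all(cases_per_class >= 1), rois_per_case >= 1, ducts_per_roi >= 0,
            all(nuclei_per_duct >= 1), nuclei_per_duct[1] <= nuclei_per_duct[2],
            roi_size_px >= 256)
  structure(list(cases_per_class = cases_per_class,
                 rois_per_case = rois_per_case,
                 ducts_per_roi = ducts_per_roi,
                 nuclei_per_duct = as.integer(nuclei_per_duct),
                 roi_size_px = as.integer(roi_size_px),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Evaluation-scale cohort specification
#'
#' The cohort layout used by the package's own end-to-end evaluation: the
#' full 22-case class structure (7/5/5/5) at a reduced tile size of 320 px
#' with 2 ROIs per case and 2 ducts per ROI, roughly 1000 myoepithelial
#' nuclei in total. Tile size is reduced from the native 2174 px so the whole
#' pipeline (two stains, pixel classification, SVM grid search) runs in
#' minutes on a single core; nucleus dimensions are kept at physical scale.
#'
#' @param seed base seed.
#' @return A \code{cohort_spec}.
#' @export
default_eval_cohort <- function(seed = 1) {
  cohort_spec(rois_per_case = 2, ducts_per_roi = 2,
              nuclei_per_duct = c(10, 14), roi_size_px = 320, seed = seed)
}

# evaluate code under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}
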