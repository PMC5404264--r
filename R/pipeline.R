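# End-to-end pipeline: simulate -> segment (both stains) -> features -> trim
# -> splits -> train -> predict -> aggregate -> evaluate.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort, trains the p63 pixel classifier on one HG-DCIS ROI,
#' segments every ROI in both stains, extracts the 32-feature vector per
#' myoepithelial nucleus (labelled with its ROI's histotype — the noisy
#' duct-level labelling of the original protocol), applies the central-80\%
#' size trim, runs the repeated split protocol with an RBF-SVM (grid search
#' on the first repetition, the selected C and gamma reused for refits),
#' aggregates cell predictions to duct (= ROI) and patient level by weighted
#' majority, and evaluates confusion matrices at all three levels for both
#' stains. Deterministic given \code{seed}.
#'
#' @param spec cohort layout (default \code{\link{default_eval_cohort}}).
#' @param params per-class morphology parameters.
#' @param split_mode,repetitions split protocol, see \code{\link{make_splits}}.
#' @param weights_mode \code{"inverse_prevalence"} (default) or
#'   \code{"uniform"} duct/patient vote weights.
#' @param noise_sd rendering noise SD.
#' @param grid SVM hyperparameter grid.
#' @param qc_rois number of ROIs used for segmentation QC (detection
#'   agreement and contour IoU).
#' @param seed master seed; every stage derives its seed from it.
#' @param stains which stain paths to run.
#' @param out_dir optional directory for artifact files (feature tables,
#'   predictions, summaries, metrics JSON, one overlay PNG).
#' @return Object of class \code{myo_pipeline_result}: per-stain metrics
#'   (cell/duct/patient confusion matrices, accuracies, kappas, two-class
#'   collapses), segmentation QC, feature tables and configuration.
#' @export
run_pipeline <- function(spec = NULL, params = default_morphology_params(),
                         split_mode = "random_cell_70_30", repetitions = 5,
                         weights_mode = c("inverse_prevalence", "uniform"),
                         noise_sd = 2, grid = svm_grid(), qc_rois = 4,
                         seed = 1, stains = c("P63", "HE"), out_dir = NULL) {
  weights_mode <- match.arg(weights_mode)
  if (is.null(spec)) spec <- default_eval_cohort(seed = seed)
  cohort <- make_cohort(spec, params, noise_sd = noise_sd)

  pix <- train_cohort_pixel_classifier(cohort, seed = seed + 1L)

  seg <- segment_cohort(cohort, pix)
  features <- lapply(stains, function(st)
    trim_by_size(cohort_features(cohort, seg, st)))
  names(features) <- stains

  metrics <- list()
  for (st in stains) {
    metrics[[st]] <- classify_and_evaluate(
      features[[st]], split_mode, repetitions, weights_mode, grid,
      seed = seed + 10L + match(st, c("P63", "HE")))
  }

  qc <- segmentation_qc(cohort, seg, n_rois = qc_rois)

  result <- structure(list(cohort_spec = spec, n_nuclei = nrow(cohort$truth_table),
                           pixel_classifier = pix, features = features,
                           metrics = metrics, qc = qc,
                           config = list(split_mode = split_mode,
                                         repetitions = repetitions,
                                         weights_mode = weights_mode,
                                         noise_sd = noise_sd, seed = seed)),
                      class = "myo_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, cohort, seg, out_dir)
  result
}

# train the pixel classifier on the first HG-DCIS ROI of the cohort
train_cohort_pixel_classifier <- function(cohort, seed) {
  idx <- which(vapply(cohort$rois, function(r) r$histotype == "HG_DCIS",
                      logical(1)))[1]
  if (is.na(idx)) idx <- 1
  roi <- cohort$rois[[idx]]
  myo_ids <- roi$truth$nuclei$nucleus_id[roi$truth$nuclei$type == "myoepithelial"]
  lab <- matrix(2L, nrow(roi$truth$label), ncol(roi$truth$label))
  lab[roi$truth$label %in% myo_ids] <- 1L
  train_pixel_classifier(roi$p63, lab, seed = seed)
}

# segment every ROI in both stains and pick myoepithelial contours by
# ground-truth identity (stand-in for the manual picking on real slides)
segment_cohort <- function(cohort, pix, he_par = he_params()) {
  lapply(cohort$rois, function(roi) {
    excl <- roi$truth$exclusion
    myo_ids <- roi$truth$nuclei$nucleus_id[roi$truth$nuclei$type ==
                                             "myoepithelial"]
    myo_region <- as.matrix(EBImage::dilate(
      matrix(as.integer(roi$truth$label %in% myo_ids),
             nrow(roi$truth$label)), EBImage::makeBrush(5, "disc"))) > 0
    p63_all <- segment_p63_roi(roi$p63, pix, exclusion_mask = excl)
    he_all <- segment_he_roi(roi$he, exclusion_mask = excl, params = he_par)
    pick <- function(cons) Filter(function(con)
      myo_region[round(con$centroid[1]), round(con$centroid[2])], cons)
    list(p63 = pick(p63_all), he = pick(he_all),
         p63_n_all = length(p63_all), he_n_all = length(he_all))
  })
}

# feature table for one stain over all ROIs
cohort_features <- function(cohort, seg, stain = c("P63", "HE")) {
  stain <- match.arg(stain)
  ref <- reference_stains()
  rows <- list()
  for (roi_id in names(cohort$rois)) {
    roi <- cohort$rois[[roi_id]]
    cons <- if (stain == "P63") seg[[roi_id]]$p63 else seg[[roi_id]]$he
    if (!length(cons)) next
    img <- if (stain == "P63") roi$p63 else roi$he
    od <- rgb_to_od(img)
    vecs <- estimate_stain_vectors(od)
    target <- if (stain == "P63") ref$dab else ref$hematoxylin
    ang <- vapply(vecs, function(v) vector_angle_deg(v, target), numeric(1))
    chan <- project_stain(od, vecs[[which.min(ang)]])
    for (i in seq_along(cons)) {
      ids <- list(cell_id = sprintf("%s_%s_c%03d", roi_id, tolower(stain), i),
                  roi_id = roi_id, case_id = roi$case_id,
                  histotype = roi$histotype)
      rows[[length(rows) + 1]] <-
        tryCatch(feature_vector(cons[[i]], chan, ids), error = function(e) NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# repeated splits -> SVM -> cell/duct/patient confusion matrices
classify_and_evaluate <- function(ft, split_mode, repetitions, weights_mode,
                                  grid, seed) {
  feats <- feature_manifest()
  splits <- make_splits(ft, split_mode, repetitions, seed = seed)
  cell_actual <- character(0); cell_pred <- character(0)
  duct_actual <- character(0); duct_pred <- character(0)
  pat_actual <- character(0); pat_pred <- character(0)
  model0 <- NULL
  for (r in seq_along(splits)) {
    tr <- splits[[r]]$train
    te <- splits[[r]]$test
    g <- if (r == 1) grid
         else list(C = model0$C, gamma = model0$gamma)
    model <- svm_classifier(ft[tr, feats], ft$histotype[tr], grid = g,
                            seed = seed + r)
    if (r == 1) model0 <- model
    pred <- predict(model, ft[te, feats])
    test_df <- ft[te, c("cell_id", "roi_id", "case_id", "histotype")]
    test_df$predicted <- pred
    cell_actual <- c(cell_actual, test_df$histotype)
    cell_pred <- c(cell_pred, pred)
    w <- if (weights_mode == "inverse_prevalence")
      inverse_prevalence_weights(ft$histotype[tr]) else NULL
    ducts <- aggregate_predictions(test_df, "roi_id", weights = w)
    duct_actual <- c(duct_actual, ducts$actual)
    duct_pred <- c(duct_pred, ducts$predicted)
    pats <- aggregate_predictions(test_df, "case_id", weights = w)
    pat_actual <- c(pat_actual, pats$actual)
    pat_pred <- c(pat_pred, pats$predicted)
  }
  level_metrics <- function(a, p) {
    cm <- confusion(a, p)
    cm2 <- collapse_classes(cm)
    list(cm = cm, accuracy = accuracy(cm), kappa = cohen_kappa(cm),
         cm2 = cm2, accuracy2 = accuracy(cm2), kappa2 = cohen_kappa(cm2))
  }
  list(cell = level_metrics(cell_actual, cell_pred),
       duct = level_metrics(duct_actual, duct_pred),
       patient = level_metrics(pat_actual, pat_pred),
       model = model0)
}

# detection agreement (all non-excluded nuclei) and myoepithelial contour IoU
segmentation_qc <- function(cohort, seg, n_rois = 4) {
  ids <- utils::head(names(cohort$rois), n_rois)
  det_he <- ref_n <- det_p63 <- numeric(length(ids))
  iou <- numeric(0)
  for (i in seq_along(ids)) {
    roi <- cohort$rois[[ids[i]]]
    nuc <- roi$truth$nuclei
    ref_n[i] <- sum(nuc$type != "fibroblast")
    det_he[i] <- seg[[ids[i]]]$he_n_all
    det_p63[i] <- length(seg[[ids[i]]]$p63)
    myo_ids <- nuc$nucleus_id[nuc$type == "myoepithelial"]
    iou <- c(iou, contour_truth_iou(roi$truth$label, seg[[ids[i]]]$he,
                                    labels = myo_ids))
  }
  list(rois = ids,
       he_detection_agreement = detection_agreement(det_he, ref_n),
       p63_detection_agreement = detection_agreement(
         det_p63, vapply(ids, function(k)
           sum(cohort$rois[[k]]$truth$nuclei$type == "myoepithelial"),
           numeric(1))),
       he_mean_iou = mean(iou))
}

#' @export
print.myo_pipeline_result <- function(x, ...) {
  cat("myomorph pipeline result —", x$n_nuclei, "myoepithelial nuclei,",
      x$config$repetitions, "x", x$config$split_mode, "\n")
  for (st in names(x$metrics)) {
    m <- x$metrics[[st]]
    cat(sprintf("  %-3s cell %5.1f%% (kappa %.2f) | duct %5.1f%% (%.2f) | patient %5.1f%% (%.2f)\n",
                st, m$cell$accuracy, m$cell$kappa, m$duct$accuracy,
                m$duct$kappa, m$patient$accuracy, m$patient$kappa))
    cat(sprintf("      benign-vs-DCIS: cell %5.1f%% | duct %5.1f%% | patient %5.1f%%\n",
                m$cell$accuracy2, m$duct$accuracy2, m$patient$accuracy2))
  }
  cat(sprintf("  QC: HE detection agreement %.1f%%, HE mean IoU %.2f, p63 detection agreement %.1f%%\n",
              x$qc$he_detection_agreement, x$qc$he_mean_iou,
              x$qc$p63_detection_agreement))
  invisible(x)
}

#' @export
summary.myo_pipeline_result <- function(object, ...) {
  print(object)
  for (st in names(object$metrics)) {
    cat("\n==", st, "patient-level confusion ==\n")
    print(object$metrics[[st]]$patient$cm)
  }
  invisible(object)
}

# artifact files: feature tables, metrics JSON, an overlay for the first ROI
write_pipeline_outputs <- function(result, cohort, seg, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  seed <- result$config$seed
  for (st in names(result$features))
    write_table(result$features[[st]],
                file.path(out_dir, sprintf("features_%s.csv", tolower(st))),
                seed = seed)
  jsonlite::write_json(pipeline_metrics_list(result),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  roi1 <- cohort$rois[[1]]
  cons <- seg[[1]]$p63
  if (length(cons)) {
    ov <- heterogeneity_overlay(roi1$p63, cons,
                                rep(roi1$histotype, length(cons)))
    png::writePNG(ov$overlay / 255, file.path(out_dir, "overlay_roi1.png"))
  }
  invisible(out_dir)
}

# flatten the metrics of a pipeline result into a plain named list
pipeline_metrics_list <- function(result) {
  out <- list(seed = result$config$seed, n_nuclei = result$n_nuclei)
  for (st in names(result$metrics)) {
    m <- result$metrics[[st]]
    for (lev in c("cell", "duct", "patient")) {
      out[[sprintf("%s_%s_accuracy", tolower(st), lev)]] <- m[[lev]]$accuracy
      out[[sprintf("%s_%s_kappa", tolower(st), lev)]] <- m[[lev]]$kappa
      out[[sprintf("%s_%s_accuracy_2class", tolower(st), lev)]] <- m[[lev]]$accuracy2
    }
  }
  out$he_detection_agreement <- result$qc$he_detection_agreement
  out$he_mean_iou <- result$qc$he_mean_iou
  out$p63_detection_agreement <- result$qc$p63_detection_agreement
  out
}
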