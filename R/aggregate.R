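# Cell -> duct -> patient aggregation: class proportions, weighted-majority
# decisions, heterogeneity overlays.

#' Per-group class proportions of cell predictions
#'
#' @param predictions data.frame with a predicted-label column and the group
#'   key column.
#' @param group name of the grouping column (e.g. \code{"duct_id"},
#'   \code{"roi_id"} or \code{"case_id"}).
#' @param label name of the predicted-label column (default
#'   \code{"predicted"}).
#' @param classes class order (default the four histotypes).
#' @return data.frame: one row per group with \code{group}, \code{n_cells}
#'   and one proportion column per class (\code{p_<class>}), each row
#'   summing to 1. Groups with zero cells are skipped with a warning.
#' @export
group_proportions <- function(predictions, group, label = "predicted",
                              classes = histotype_levels()) {
  if (!group %in% names(predictions)) stop("missing group column: ", group)
  if (!label %in% names(predictions)) stop("missing label column: ", label)
  keys <- as.character(predictions[[group]])
  if (anyNA(keys)) {
    warning("skipping cells with missing group key")
    keep <- !is.na(keys)
    predictions <- predictions[keep, , drop = FALSE]
    keys <- keys[keep]
  }
  out <- lapply(unique(keys), function(k) {
    labs <- as.character(predictions[[label]][keys == k])
    counts <- table(factor(labs, levels = classes))
    props <- as.numeric(counts) / length(labs)
    row <- data.frame(group = k, n_cells = length(labs),
                      stringsAsFactors = FALSE)
    for (i in seq_along(classes)) row[[paste0("p_", classes[i])]] <- props[i]
    row
  })
  do.call(rbind, out)
}

#' Weighted-majority decision for a group
#'
#' The group label is the class maximizing proportion x weight; ties are
#' broken toward the more severe class (Normal < UDH < LG-DCIS < HG-DCIS),
#' a clinically conservative, deterministic rule. Decisions are invariant to
#' rescaling all weights by a positive constant.
#'
#' @param proportions numeric vector of class proportions (in \code{classes}
#'   order), or one row of \code{\link{group_proportions}} output.
#' @param weights non-negative class weights, not all zero (default
#'   uniform).
#' @param classes class order.
#' @return The decided class label (character), with the winning score as
#'   attribute \code{"score"}.
#' @export
weighted_majority <- function(proportions, weights = rep(1, length(classes)),
                              classes = histotype_levels()) {
  if (is.data.frame(proportions))
    proportions <- as.numeric(proportions[paste0("p_", classes)])
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero")
  score <- proportions * weights
  best <- max(score)
  # ties toward severity: classes are ordered Normal < ... < HG, take last
  win <- max(which(score >= best - 1e-12))
  structure(classes[win], score = best)
}

#' Inverse-prevalence class weights from training labels
#'
#' Reciprocal of the training-set class frequencies, normalized to sum 1 —
#' the natural choice when nucleus counts are imbalanced across classes.
#' A uniform-weights mode is available throughout as the alternative.
#'
#' @param labels training-set class labels.
#' @param classes class order.
#' @return Numeric weight vector in class order.
#' @export
inverse_prevalence_weights <- function(labels, classes = histotype_levels()) {
  freq <- table(factor(as.character(labels), levels = classes))
  if (any(freq == 0)) freq <- freq + 1   # guard absent classes
  w <- 1 / as.numeric(freq)
  w / sum(w)
}

#' Aggregate cell predictions to decided group labels
#'
#' @param predictions data.frame with predicted labels, actual labels
#'   (\code{histotype}) and the group key.
#' @param group grouping column name.
#' @param weights class weight vector (see
#'   \code{\link{inverse_prevalence_weights}}), or NULL for uniform.
#' @param classes class order.
#' @return data.frame per group: proportions, \code{n_cells}, decided
#'   \code{predicted} label and the group's \code{actual} label (the unique
#'   histotype of its cells).
#' @export
aggregate_predictions <- function(predictions, group, weights = NULL,
                                  classes = histotype_levels()) {
  if (is.null(weights)) weights <- rep(1, length(classes))
  props <- group_proportions(predictions, group, classes = classes)
  props$predicted <- vapply(seq_len(nrow(props)), function(i)
    as.character(weighted_majority(props[i, ], weights, classes)),
    character(1))
  keys <- as.character(predictions[[group]])
  props$actual <- vapply(props$group, function(k) {
    a <- unique(as.character(predictions$histotype[keys == k]))
    if (length(a) != 1) stop("group ", k, " has mixed actual labels")
    a
  }, character(1))
  props
}

#' Class colors for heterogeneity maps
#'
#' Dark blue (Normal), light blue (UDH), light red (LG-DCIS), dark red
#' (HG-DCIS).
#'
#' @return Named list of RGB triplets in [0, 255].
#' @export
class_colors <- function() {
  list(Normal = c(0, 0, 139), UDH = c(173, 216, 230),
       LG_DCIS = c(240, 128, 128), HG_DCIS = c(139, 0, 0))
}

#' Paint classified nuclei onto an ROI image
#'
#' Fills each contour with its predicted class color on a copy of the input
#' image and returns per-duct class proportions as bar data.
#'
#' @param image RGB array.
#' @param contours list of \code{nucleus_contour}s.
#' @param labels predicted class label per contour (same length).
#' @param duct_ids optional group key per contour for the bar data.
#' @return List: \code{overlay} (RGB array, same dimensions as the input)
#'   and \code{bars} (per-duct proportions, or NULL).
#' @export
heterogeneity_overlay <- function(image, contours, labels, duct_ids = NULL) {
  if (length(contours) != length(labels))
    stop("contours and labels must have equal length")
  overlay <- image
  cols <- class_colors()
  for (i in seq_along(contours)) {
    mask <- rasterize_polygon(contours[[i]]$vertices, dim(image)[1:2])
    rgb <- cols[[labels[i]]]
    for (ch in 1:3) {
      plane <- overlay[, , ch]
      plane[mask] <- rgb[ch]
      overlay[, , ch] <- plane
    }
  }
  bars <- NULL
  if (!is.null(duct_ids) && length(contours)) {
    bars <- group_proportions(
      data.frame(predicted = labels, duct_id = duct_ids,
                 stringsAsFactors = FALSE), "duct_id")
  }
  list(overlay = overlay, bars = bars)
}
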