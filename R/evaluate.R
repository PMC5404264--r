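#' Build a confusion matrix with a fixed class order
#'
#' Rows are actual classes, columns predicted, in the supplied order.
#'
#' @param actual,predicted vectors of class labels, equal length; every label
#'   must appear in \code{classes}.
#' @param classes character vector fixing row/column order; defaults to the
#'   four histotypes in severity order.
#' @return An integer K x K matrix of class \code{confusion_matrix} with
#'   dimnames \code{list(actual = classes, predicted = classes)}.
#' @export
confusion <- function(actual, predicted, classes = histotype_levels()) {
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  bad <- setdiff(unique(c(actual, predicted)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(actual, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(actual = classes, predicted = classes))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = actual, cols = predicted), n =",
      sum(x), "\n")
  print(unclass(x), ...)
  if (sum(x) > 0)
    cat(sprintf("Accuracy %.1f%%  (kappa %.2f)\n", accuracy(x), cohen_kappa(x)))
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm square count matrix (rows actual, columns predicted).
#' @return Percentage, 100 x trace / total, rounded half-up to 1 decimal.
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix")
  round_half_up(100 * sum(diag(cm)) / n, 1)
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e), with the expected
#' agreement p_e computed from the row and column marginals.
#'
#' @param cm square count matrix.
#' @return Kappa in [-1, 1], rounded half-up to 2 decimals.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) stop("degenerate marginals: expected agreement is 1")
  round_half_up((po - pe) / (1 - pe), 2)
}

#' Collapse confusion-matrix classes under a mapping
#'
#' Sums blocks of the matrix according to a class mapping, e.g. the
#' benign-vs-DCIS collapse \{Normal, UDH\} -> Benign, \{LG, HG\} -> DCIS.
#'
#' @param cm square count matrix with class dimnames.
#' @param mapping named character vector: names are original classes, values
#'   the collapsed class each maps to. Must cover every class of \code{cm}.
#' @return A collapsed \code{confusion_matrix}; total count is preserved.
#' @export
collapse_classes <- function(cm, mapping = benign_dcis_mapping()) {
  cm <- as.matrix(cm)
  cls <- rownames(cm)
  if (is.null(cls)) stop("cm must carry class dimnames")
  if (!all(cls %in% names(mapping)))
    stop("mapping does not cover class(es): ",
         paste(setdiff(cls, names(mapping)), collapse = ", "))
  new_cls <- unique(unname(mapping[cls]))
  out <- matrix(0L, length(new_cls), length(new_cls),
                dimnames = list(actual = new_cls, predicted = new_cls))
  for (i in cls) for (j in cls)
    out[mapping[[i]], mapping[[j]]] <- out[mapping[[i]], mapping[[j]]] + cm[i, j]
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Default benign-vs-DCIS class mapping
#' @return Named character vector mapping the four histotypes to
#'   \code{"Benign"} or \code{"DCIS"}.
#' @export
benign_dcis_mapping <- function() {
  c(Normal = "Benign", UDH = "Benign", LG_DCIS = "DCIS", HG_DCIS = "DCIS")
}

#' Detection agreement between automatic and reference nucleus counts
#'
#' Per-ROI agreement is 100 x (1 - |detected - reference| / reference),
#' clipped below at 0, then averaged over ROIs. This is a relative-count-error
#' reconstruction of "segmentation accuracy" scores quoted for pathologist
#' counts; it is used here only on synthetic ground truth.
#'
#' @param detected,reference non-negative integer vectors of per-ROI nucleus
#'   counts; every reference count must be positive.
#' @return Mean agreement percentage.
#' @export
detection_agreement <- function(detected, reference) {
  if (length(detected) != length(reference))
    stop("detected and reference must have equal length")
  if (any(reference <= 0)) stop("reference counts must be positive")
  per_roi <- pmax(0, 100 * (1 - abs(detected - reference) / reference))
  mean(per_roi)
}

#' Mean best-overlap IoU between segmented contours and ground truth
#'
#' Each ground-truth nucleus is matched to the segmented contour with maximal
#' intersection-over-union; the mean best IoU over truth nuclei is returned
#' (unmatched nuclei contribute 0).
#'
#' @param truth_label integer label image of ground-truth nuclei (0 = none).
#' @param contours list of contours as returned by the segmenters.
#' @param labels optional subset of truth labels to score.
#' @return Mean IoU in [0, 1].
#' @export
contour_truth_iou <- function(truth_label, contours, labels = NULL) {
  if (is.null(labels)) labels <- setdiff(sort(unique(as.vector(truth_label))), 0)
  if (!length(labels)) stop("no ground-truth nuclei to score")
  seg <- matrix(0L, nrow(truth_label), ncol(truth_label))
  for (k in seq_along(contours)) {
    m <- rasterize_polygon(contours[[k]]$vertices, dim(truth_label))
    seg[m & seg == 0L] <- k
  }
  best <- vapply(labels, function(l) {
    tm <- truth_label == l
    hits <- seg[tm]
    hits <- hits[hits > 0L]
    if (!length(hits)) return(0)
    max(vapply(unique(hits), function(k) {
      sm <- seg == k
      sum(tm & sm) / sum(tm | sm)
    }, numeric(1)))
  }, numeric(1))
  mean(best)
}
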