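# p63 path: random-forest pixel classification plus morphological
# post-processing to extract myoepithelial (DAB-positive) nuclei.

#' Per-pixel feature stack for pixel classification
#'
#' For each RGB channel: the raw value plus, at every scale, the
#' Gaussian-smoothed value, the gradient magnitude and the Laplacian of the
#' smoothed channel — a fixed interactive-segmentation-style recipe. Stack
#' depth is therefore channels x (1 + 3 x number of scales).
#'
#' @param image RGB array (row x col x 3) or single matrix.
#' @param scales numeric vector of Gaussian scales in px (non-empty).
#' @return row x col x depth numeric array with named slices.
#' @export
pixel_features <- function(image, scales = c(1, 2.5, 5)) {
  if (!length(scales)) stop("scales must be non-empty")
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 1))
  nch <- dim(image)[3]
  depth <- nch * (1 + 3 * length(scales))
  out <- array(0, c(dim(image)[1], dim(image)[2], depth))
  nms <- character(depth)
  k <- 0
  for (ch in seq_len(nch)) {
    m <- image[, , ch]
    k <- k + 1; out[, , k] <- m; nms[k] <- sprintf("ch%d_raw", ch)
    for (s in scales) {
      sm <- as.matrix(EBImage::gblur(m, s))
      k <- k + 1; out[, , k] <- sm
      nms[k] <- sprintf("ch%d_gauss_s%g", ch, s)
      k <- k + 1; out[, , k] <- gradient_magnitude(sm)
      nms[k] <- sprintf("ch%d_gradmag_s%g", ch, s)
      k <- k + 1; out[, , k] <- laplacian(sm)
      nms[k] <- sprintf("ch%d_laplace_s%g", ch, s)
    }
  }
  dimnames(out) <- list(NULL, NULL, nms)
  out
}

gradient_magnitude <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  sqrt(gr^2 + gc^2)
}

laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lp <- matrix(0, nr, nc)
  lp[2:(nr - 1), 2:(nc - 1)] <-
    m[1:(nr - 2), 2:(nc - 1)] + m[3:nr, 2:(nc - 1)] +
    m[2:(nr - 1), 1:(nc - 2)] + m[2:(nr - 1), 3:nc] -
    4 * m[2:(nr - 1), 2:(nc - 1)]
  lp
}

#' Train the random-forest pixel classifier
#'
#' Trains a tree ensemble on the labeled pixels of one training ROI
#' (following the original protocol: one DCIS ROI is annotated and the
#' classifier is then applied to all remaining ROIs).
#'
#' @param image RGB training image.
#' @param label_mask integer matrix: 0 = unlabeled, 1 = nucleus,
#'   2 = background. Both classes must be present.
#' @param seed integer seed (forest growth is deterministic given it).
#' @param scales feature scales, see \code{\link{pixel_features}}.
#' @param ntree number of trees (default 100).
#' @param max_per_class cap on training pixels sampled per class.
#' @return Object of class \code{pixel_classifier}: the forest, the feature
#'   recipe and the training pixel accuracy.
#' @export
train_pixel_classifier <- function(image, label_mask, seed = 1,
                                   scales = c(1, 2.5, 5), ntree = 100,
                                   max_per_class = 4000) {
  labs <- sort(unique(label_mask[label_mask > 0]))
  if (!length(labs)) stop("all pixels unlabeled")
  if (length(labs) < 2) stop("label mask must contain both classes")
  feat <- pixel_features(image, scales)
  X <- matrix(feat, ncol = dim(feat)[3])
  colnames(X) <- dimnames(feat)[[3]]
  with_seed(seed, {
    idx <- unlist(lapply(c(1, 2), function(l) {
      w <- which(label_mask == l)
      if (length(w) > max_per_class) sample(w, max_per_class) else w
    }))
    y <- factor(ifelse(label_mask[idx] == 1, "nucleus", "background"),
                levels = c("background", "nucleus"))
    rf <- randomForest::randomForest(X[idx, , drop = FALSE], y, ntree = ntree)
  })
  pred <- stats::predict(rf, X[idx, , drop = FALSE])
  structure(list(forest = rf, scales = scales, ntree = ntree, seed = seed,
                 train_accuracy = mean(pred == y)),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "Random-forest pixel classifier: %d trees, scales {%s} px, training pixel accuracy %.3f\n",
    x$ntree, paste(x$scales, collapse = ", "), x$train_accuracy))
  invisible(x)
}

#' Per-pixel nucleus probability map
#'
#' @param classifier \code{pixel_classifier}.
#' @param image RGB image.
#' @return Matrix of nucleus probabilities in [0, 1].
#' @export
predict_pixel_prob <- function(classifier, image) {
  feat <- pixel_features(image, classifier$scales)
  X <- matrix(feat, ncol = dim(feat)[3])
  colnames(X) <- dimnames(feat)[[3]]
  p <- stats::predict(classifier$forest, X, type = "prob")[, "nucleus"]
  matrix(p, dim(image)[1], dim(image)[2])
}

#' Segment myoepithelial nuclei in a p63 ROI
#'
#' Thresholds the pixel-classifier probability map, fills holes, labels
#' connected components, and discards components smaller than
#' \code{min_area_px} or with centroid inside the exclusion mask. Component
#' boundaries become the nucleus contours. Touching nuclei are not split;
#' merged blobs are left to the downstream size-trim rule.
#'
#' @param image RGB p63 image.
#' @param classifier trained \code{pixel_classifier}.
#' @param exclusion_mask optional logical matrix.
#' @param prob_threshold probability cut (default 0.5).
#' @param min_area_px minimum component area (default 30 px).
#' @return List of \code{nucleus_contour}s.
#' @export
segment_p63_roi <- function(image, classifier, exclusion_mask = NULL,
                            prob_threshold = 0.5, min_area_px = 30) {
  prob <- predict_pixel_prob(classifier, image)
  contours_from_mask(prob >= prob_threshold, exclusion_mask, min_area_px)
}

# shared post-processing: binary mask -> filled, labeled, filtered contours
contours_from_mask <- function(bin, exclusion_mask = NULL, min_area_px = 30) {
  if (!any(bin)) return(list())
  filled <- EBImage::fillHull(matrix(as.integer(bin), nrow(bin)))
  lab <- EBImage::bwlabel(filled)
  labm <- as.matrix(lab)
  out <- list()
  oc <- EBImage::ocontour(lab)
  for (k in seq_along(oc)) {
    px <- which(labm == k, arr.ind = TRUE)
    if (nrow(px) < min_area_px) next
    ctr <- c(mean(px[, 1]), mean(px[, 2]))
    if (!is.null(exclusion_mask) &&
        exclusion_mask[round(ctr[1]), round(ctr[2])]) next
    # ocontour yields 0-based (dim1, dim2) vertices -> 1-based (row, col)
    v <- oc[[k]] + 1
    out[[length(out) + 1]] <-
      structure(list(vertices = cbind(row = v[, 1], col = v[, 2]),
                     centroid = ctr, area_px = nrow(px)),
                class = "nucleus_contour")
  }
  out
}
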