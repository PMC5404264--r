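# 32-feature nuclear morphometry: shape, intensity and GLCM texture.

#' The 32-feature morphometry manifest
#'
#' Fixed, ordered list of the features measured per nucleus: 13 shape
#' descriptors, 6 intensity statistics of the nuclear stain channel, and the
#' 13 classic Haralick texture features of the grey-level co-occurrence
#' matrix. The manifest is shipped as JSON under \code{inst/extdata} so an
#' alternative list can be dropped in.
#'
#' @return Character vector of 32 feature names, in canonical order.
#' @export
feature_manifest <- function() {
  path <- system.file("extdata", "feature_manifest.json", package = "myomorph")
  if (nzchar(path)) {
    return(unlist(jsonlite::fromJSON(path)$features))
  }
  c(shape_feature_names(), intensity_feature_names(), haralick_feature_names())
}

shape_feature_names <- function() {
  c("Area", "Perimeter", "MajorAxisLength", "MinorAxisLength",
    "MinorMajorRatio", "MinFeretDiameter", "MaxFeretDiameter",
    "Eccentricity", "Solidity", "Extent", "FormFactor", "Compactness",
    "EquivalentDiameter")
}

intensity_feature_names <- function() {
  c("IntensityMean", "IntensitySD", "IntensityMin", "IntensityMax",
    "IntensityMedian", "IntensityMAD")
}

haralick_feature_names <- function() {
  c("AngularSecondMoment", "Contrast", "Correlation", "SumOfSquaresVariance",
    "InverseDifferenceMoment", "SumAverage", "SumVariance", "SumEntropy",
    "Entropy", "DifferenceVariance", "DifferenceEntropy",
    "InfoMeasureCorrelation1", "InfoMeasureCorrelation2")
}

#' Shape descriptors of a nucleus mask
#'
#' Computes moment-ellipse axis lengths (4 sqrt of the eigenvalues of the
#' pixel-coordinate covariance), rotating-calipers Feret diameters on the
#' convex hull of pixel centers, chain-code perimeter (Vossepoel-Smeulders
#' weights 0.948 axial / 1.340 diagonal), Solidity against the unit-square
#' pixel hull, Extent against the bounding box, FormFactor = 4 pi A / P^2,
#' Compactness = P^2 / (4 pi A), and EquivalentDiameter = 2 sqrt(A / pi).
#'
#' @param mask logical or 0/1 matrix with a single nucleus, or a contour list
#'   with a \code{vertices} element (rasterized internally; dimension taken
#'   from the vertex bounding box unless \code{dm} is given).
#' @param dm optional output dimension when rasterizing a contour.
#' @return Named numeric vector of the 13 shape features (pixel units).
#' @export
shape_features <- function(mask, dm = NULL) {
  if (is.list(mask) && !is.null(mask$vertices)) {
    v <- mask$vertices
    if (is.null(dm)) dm <- c(ceiling(max(v[, 1])) + 2L, ceiling(max(v[, 2])) + 2L)
    mask <- rasterize_polygon(v, dm)
  }
  mask <- mask > 0
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) stop("empty mask")
  area <- n
  per <- mask_perimeter(mask)

  if (n == 1) {
    cv <- matrix(0, 2, 2)
  } else {
    cv <- stats::cov(idx) * (n - 1) / n
  }
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  ratio <- if (major > 0) minor / major else 1
  ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0

  fer <- feret_diameters(idx)

  # convex area in the same pixel-count units as the area: rasterize the
  # convex hull of the pixel squares and count covered pixel centers
  corners <- rbind(cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
                   cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
                   cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
                   cbind(idx[, 1] + 0.5, idx[, 2] + 0.5))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  hull_area <- if (nrow(hull) >= 3) {
    off <- c(min(idx[, 1]) - 2, min(idx[, 2]) - 2)
    hv <- cbind(hull[, 1] - off[1], hull[, 2] - off[2])
    dmh <- c(max(idx[, 1]) - off[1] + 2, max(idx[, 2]) - off[2] + 2)
    max(area, sum(rasterize_polygon(hv, dmh)))
  } else area
  solidity <- min(1, area / hull_area)
  bbox_area <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  extent <- area / bbox_area

  form <- if (per > 0) 4 * pi * area / per^2 else 1
  comp <- if (form > 0) 1 / form else Inf
  eqd <- 2 * sqrt(area / pi)

  out <- c(area, per, major, minor, ratio, fer["min"], fer["max"],
           ecc, solidity, extent, form, comp, eqd)
  names(out) <- shape_feature_names()
  out
}

# Chain-code perimeter via EBImage boundary tracing.
mask_perimeter <- function(mask) {
  if (sum(mask) == 1) return(4)
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask)))
  if (!length(oc)) return(4)
  p <- oc[[1]]
  if (nrow(p) < 2) return(4)
  st <- diff(rbind(p, p[1, , drop = FALSE]))
  d <- sqrt(rowSums(st^2))
  sum(0.948 * (abs(d - 1) < 1e-9) + 1.340 * (abs(d - sqrt(2)) < 1e-9))
}

# Min/max Feret (caliper) diameters over the convex hull of pixel centers.
feret_diameters <- function(idx) {
  pts <- unique(idx)
  if (nrow(pts) == 1) return(c(min = 1, max = 1))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  maxf <- max(stats::dist(hull))
  nh <- nrow(hull)
  if (nh < 3) return(c(min = 1, max = maxf))
  minf <- Inf
  for (i in seq_len(nh)) {
    a <- hull[i, ]
    b <- hull[i %% nh + 1L, ]
    v <- b - a
    len <- sqrt(sum(v^2))
    if (len == 0) next
    dd <- abs((hull[, 1] - a[1]) * v[2] - (hull[, 2] - a[2]) * v[1]) / len
    minf <- min(minf, max(dd))
  }
  c(min = minf, max = maxf)
}

#' Grey-level co-occurrence matrix of a masked patch
#'
#' Intensities inside the mask are quantized per nucleus by min-max scaling
#' to \code{G} levels; co-occurrences are accumulated only over pixel pairs
#' that are both inside the mask, symmetrized and normalized to sum 1.
#'
#' @param patch numeric intensity matrix.
#' @param mask logical matrix, same dimension.
#' @param G number of grey levels (default 8).
#' @param offsets list of integer (d_row, d_col) neighbor offsets; the default
#'   is distance 1 in the four standard directions, pooled.
#' @return G x G symmetric matrix summing to 1 (all zeros if no valid pair).
#' @export
glcm <- function(patch, mask = NULL, G = 8,
                 offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(patch), ncol(patch))
  mask <- mask > 0
  vals <- patch[mask]
  if (!length(vals)) stop("empty mask")
  lo <- min(vals)
  hi <- max(vals)
  q <- matrix(1L, nrow(patch), ncol(patch))
  if (hi > lo) {
    q[mask] <- pmin(G, floor((patch[mask] - lo) / (hi - lo) * G) + 1L)
  }
  P <- matrix(0, G, G)
  nr <- nrow(patch)
  nc <- ncol(patch)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    m1 <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(m1)) next
    a <- q[r1, c1, drop = FALSE][m1]
    b <- q[r1 + dr, c1 + dc, drop = FALSE][m1]
    cnt <- tabulate(c((a - 1L) * G + b, (b - 1L) * G + a), nbins = G * G)
    P <- P + matrix(cnt, G, G, byrow = TRUE)
  }
  s <- sum(P)
  if (s > 0) P <- P / s
  P
}

#' Haralick texture features from a GLCM
#'
#' The 13 classic co-occurrence statistics (natural logarithms). Degenerate
#' single-level patches yield the defined limits: AngularSecondMoment 1,
#' Contrast 0, InverseDifferenceMoment 1, all entropies 0; Correlation and
#' the information measures are set to 0 when a marginal variance or entropy
#' vanishes, so every value is finite.
#'
#' @param P normalized symmetric co-occurrence matrix (see \code{\link{glcm}}).
#' @return Named numeric vector of the 13 Haralick features.
#' @export
haralick_features <- function(P) {
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(G) * px)
  muy <- sum(seq_len(G) * py)
  sdx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(G) - muy)^2 * py))

  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)

  asm <- sum(P^2)
  # p_{x-y}: distribution of |i - j|, k = 0..G-1
  pd <- vapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  contrast <- sum((0:(G - 1))^2 * pd)
  corr <- if (sdx > 0 && sdy > 0)
    (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0
  ssq <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  # p_{x+y}: distribution of i + j, k = 2..2G
  ps <- vapply(2:(2 * G), function(k) sum(P[(i + j) == k]), numeric(1))
  sum_avg <- sum((2:(2 * G)) * ps)
  sum_var <- sum(((2:(2 * G)) - sum_avg)^2 * ps)
  sum_ent <- -sum(xlogx(ps))
  ent <- -sum(xlogx(P))
  diff_avg <- sum((0:(G - 1)) * pd)
  diff_var <- sum(((0:(G - 1)) - diff_avg)^2 * pd)
  diff_ent <- -sum(xlogx(pd))
  hx <- -sum(xlogx(px))
  hy <- -sum(xlogx(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * ifelse(pxy > 0, log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))

  out <- c(asm, contrast, corr, ssq, idm, sum_avg, sum_var, sum_ent, ent,
           diff_var, diff_ent, imc1, imc2)
  names(out) <- haralick_feature_names()
  out
}

#' GLCM texture sub-vector of a masked patch
#'
#' @inheritParams glcm
#' @return Named numeric vector of the 13 Haralick features.
#' @export
glcm_features <- function(patch, mask = NULL, G = 8,
                          offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  haralick_features(glcm(patch, mask, G, offsets))
}

#' Full 32-feature vector for one nucleus
#'
#' Concatenates shape, intensity and Haralick features in manifest order.
#' Intensity and texture are measured on the supplied nuclear stain channel
#' (e.g. the hematoxylin or DAB optical-density projection) restricted to the
#' nucleus mask.
#'
#' @param contour contour list with \code{vertices} (closed (row, col)
#'   polygon), or a logical mask matrix.
#' @param image numeric matrix, the nuclear stain channel, same frame as the
#'   contour coordinates.
#' @param ids optional named list/vector of identity columns (cell_id, roi_id,
#'   duct_id, case_id, histotype) prepended to the output row.
#' @return One-row data.frame: identity columns followed by the 32 features.
#' @export
feature_vector <- function(contour, image, ids = NULL) {
  if (is.list(contour) && !is.null(contour$vertices)) {
    mask <- rasterize_polygon(contour$vertices, dim(image))
  } else {
    mask <- contour > 0
  }
  if (!any(mask)) stop("contour rasterizes to an empty mask")
  sf <- shape_features(mask)
  vals <- image[mask]
  intens <- c(mean(vals),
              if (length(vals) > 1) stats::sd(vals) else 0,
              min(vals), max(vals), stats::median(vals), stats::mad(vals))
  names(intens) <- intensity_feature_names()
  hf <- glcm_features(image, mask)
  feats <- c(sf, intens, hf)[feature_manifest()]
  row <- as.data.frame(as.list(feats), stringsAsFactors = FALSE)
  if (!is.null(ids)) row <- cbind(as.data.frame(as.list(ids),
                                                stringsAsFactors = FALSE), row)
  row
}

#' Central size trim of a feature table
#'
#' Within each ROI, drops the \code{floor(fraction * n)} largest and the same
#' number of smallest nuclei by the chosen size feature, keeping the central
#' 80\% by default. This absorbs contour noise such as touching nuclei merged
#' into one oversized blob. Row order of the retained records is unchanged.
#'
#' @param records data.frame with the feature columns and a \code{roi_id}
#'   column (absent: the whole table is treated as one ROI).
#' @param fraction fraction to drop from each end, in [0, 0.5).
#' @param size_feature column used for ranking (default \code{"Area"}).
#' @return The trimmed data.frame.
#' @export
trim_by_size <- function(records, fraction = 0.10, size_feature = "Area") {
  if (fraction < 0 || fraction >= 0.5) stop("fraction must be in [0, 0.5)")
  if (!nrow(records)) return(records)
  if (!size_feature %in% names(records))
    stop("missing size feature column: ", size_feature)
  grp <- if ("roi_id" %in% names(records)) as.character(records$roi_id)
         else rep("all", nrow(records))
  keep <- rep(TRUE, nrow(records))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    n <- length(rows)
    k <- floor(fraction * n)
    if (k == 0) next
    ord <- rows[order(records[[size_feature]][rows])]
    keep[ord[seq_len(k)]] <- FALSE
    keep[ord[seq(n - k + 1, n)]] <- FALSE
  }
  records[keep, , drop = FALSE]
}
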