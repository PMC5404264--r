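# Optical-density stain model: OD conversion, stain-vector estimation
# (Macenko-style plane fit), and projection to a grey-level stain map.

#' Construct a stain vector
#'
#' A stain is represented by its unit-norm RGB absorbance (optical density)
#' direction.
#'
#' @param rgb_od numeric length-3, non-negative, not all zero.
#' @param name stain name.
#' @return Object of class \code{stain_vector}: named numeric length-3 unit
#'   vector with a \code{name} attribute.
#' @export
stain_vector <- function(rgb_od, name = "stain") {
  v <- as.numeric(rgb_od)
  if (length(v) != 3 || any(v < 0) || all(v == 0))
    stop("rgb_od must be 3 non-negative values with at least one positive")
  v <- v / sqrt(sum(v^2))
  names(v) <- c("R", "G", "B")
  attr(v, "name") <- name
  class(v) <- "stain_vector"
  v
}

#' @export
print.stain_vector <- function(x, ...) {
  cat(sprintf("stain '%s': OD (%.3f, %.3f, %.3f)\n",
              attr(x, "name"), x[1], x[2], x[3]))
  invisible(x)
}

#' Reference absorbance vectors for hematoxylin, eosin and DAB
#'
#' Standard published RGB absorbance directions used both as rendering ground
#' truth in the synthetic generator and as sanity anchors in tests.
#'
#' @return Named list of \code{stain_vector}s: \code{hematoxylin},
#'   \code{eosin}, \code{dab}.
#' @export
reference_stains <- function() {
  list(
    hematoxylin = stain_vector(c(0.650, 0.704, 0.286), "hematoxylin"),
    eosin = stain_vector(c(0.092, 0.954, 0.283), "eosin"),
    dab = stain_vector(c(0.268, 0.570, 0.776), "dab")
  )
}

#' Convert an RGB image to optical density
#'
#' OD = -log10((pixel + 1) / (background + 1)) per channel, clipped at 0, so
#' a pixel at background intensity has zero absorbance.
#'
#' @param image numeric row x col x 3 array, 8-bit scale [0, 255].
#' @param background per-channel background intensity (default 255).
#' @return row x col x 3 array of non-negative optical densities.
#' @export
rgb_to_od <- function(image, background = c(255, 255, 255)) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be a row x col x 3 array")
  if (any(background <= 0)) stop("background intensities must be positive")
  od <- image
  for (ch in 1:3)
    od[, , ch] <- pmax(0, -log10((image[, , ch] + 1) / (background[ch] + 1)))
  od
}

# inverse transform used by the renderer
od_to_rgb <- function(od, background = c(255, 255, 255)) {
  img <- od
  for (ch in 1:3)
    img[, , ch] <- pmin(255, pmax(0, (background[ch] + 1) * 10^(-od[, , ch]) - 1))
  img
}

#' Estimate the dominant stain vectors of an OD image
#'
#' Deterministic plane fit: high-absorbance pixels are decomposed by SVD, the
#' two leading directions span the stain plane, and the stain vectors are
#' taken at the lower/upper angular percentiles of the pixel cloud within
#' that plane. The first returned vector is the hematoxylin-like one (largest
#' blue OD component; ties broken by larger red).
#'
#' If the pixel cloud is effectively one-dimensional the single stain
#' direction is returned first and the second vector (its in-plane
#' complement) is flagged via \code{attr(, "confidence") = 0}. A cloud that
#' is one-dimensional and achromatic (grey) carries no stain plane at all and
#' raises an error.
#'
#' @param od_map row x col x 3 OD array from \code{\link{rgb_to_od}}.
#' @param n_stains number of stains (only 2 supported).
#' @param od_threshold minimum OD vector norm for a pixel to count as
#'   foreground (default 0.15).
#' @param min_foreground minimum number of foreground pixels (default 1000).
#' @param angular_percentile robust extreme-angle quantile (default 0.01).
#' @return List of two \code{stain_vector}s with a \code{confidence}
#'   attribute vector (1 = supported by data, 0 = degenerate complement).
#' @export
estimate_stain_vectors <- function(od_map, n_stains = 2, od_threshold = 0.15,
                                   min_foreground = 1000,
                                   angular_percentile = 0.01) {
  if (n_stains != 2) stop("only two-stain estimation is supported")
  X <- cbind(as.vector(od_map[, , 1]), as.vector(od_map[, , 2]),
             as.vector(od_map[, , 3]))
  X <- X[sqrt(rowSums(X^2)) > od_threshold, , drop = FALSE]
  if (nrow(X) < min_foreground)
    stop("too few foreground pixels for stain estimation (",
         nrow(X), " < ", min_foreground, ")")
  sv <- svd(X, nu = 0, nv = 3)
  v1 <- sv$v[, 1]
  if (mean(X %*% v1) < 0) v1 <- -v1
  rank1 <- sv$d[2] < 1e-3 * sv$d[1]
  grey <- rep(1, 3) / sqrt(3)
  if (rank1) {
    if (abs(sum(v1 * grey)) > cos(10 * pi / 180))
      stop("no stain plane: image is achromatic")
    # single pure stain: return it first, plus an unsupported in-plane
    # complement flagged by zero confidence (no reordering applies)
    comp <- grey - sum(grey * v1) * v1
    comp <- comp / sqrt(sum(comp^2))
    vs <- lapply(list(pmax(v1, 0), pmax(comp, 0)),
                 function(u) u / sqrt(sum(u^2)))
    out <- list(stain_vector(vs[[1]], "hematoxylin-like"),
                stain_vector(vs[[2]], "counterstain"))
    attr(out, "confidence") <- c(1, 0)
    return(out)
  } else {
    v2 <- sv$v[, 2]
    proj <- X %*% cbind(v1, v2)
    phi <- atan2(proj[, 2], proj[, 1])
    qs <- stats::quantile(phi, c(angular_percentile, 1 - angular_percentile),
                          names = FALSE)
    mk <- function(a) {
      u <- cos(a) * v1 + sin(a) * v2
      if (sum(u) < 0) u <- -u
      pmax(u, 0)
    }
    vs <- list(mk(qs[1]), mk(qs[2]))
  }
  vs <- lapply(vs, function(u) u / sqrt(sum(u^2)))
  # hematoxylin-like first: larger blue OD (coarse 0.1 bins so estimation
  # noise cannot flip the order), ties broken by larger red
  key <- vapply(vs, function(u) round(u[3], 1) * 100 + u[1], numeric(1))
  ord <- order(key, decreasing = TRUE)
  vs <- vs[ord]
  out <- list(stain_vector(vs[[1]], "hematoxylin-like"),
              stain_vector(vs[[2]], "counterstain"))
  attr(out, "confidence") <- c(1, 1)
  out
}

#' Project an OD image onto a stain vector
#'
#' Per-pixel dot product with the unit stain vector, clipped at 0: higher
#' values mean more of that stain.
#'
#' @param od_map row x col x 3 OD array.
#' @param vector \code{stain_vector} (or unit-norm numeric length 3).
#' @return Numeric matrix, the grey-level stain map.
#' @export
project_stain <- function(od_map, vector) {
  v <- as.numeric(vector)
  if (abs(sqrt(sum(v^2)) - 1) > 1e-6) stop("stain vector must have unit norm")
  pmax(od_map[, , 1] * v[1] + od_map[, , 2] * v[2] + od_map[, , 3] * v[3], 0)
}

# angle between two direction vectors, in degrees
vector_angle_deg <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, abs(ca)))) * 180 / pi
}
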