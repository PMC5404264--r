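# Shared raster/polygon geometry helpers.

# Rasterize a closed polygon (n x 2 matrix of (row, col) vertices, implicitly
# closed) into a logical mask of dimension dm, by even-odd ray casting on
# pixel centers over the polygon's bounding box.
rasterize_polygon <- function(vertices, dm) {
  v <- as.matrix(vertices)
  out <- matrix(FALSE, dm[1], dm[2])
  if (nrow(v) < 3) return(out)
  r0 <- max(1L, floor(min(v[, 1])))
  r1 <- min(dm[1], ceiling(max(v[, 1])))
  c0 <- max(1L, floor(min(v[, 2])))
  c1 <- min(dm[2], ceiling(max(v[, 2])))
  if (r0 > r1 || c0 > c1) return(out)
  rr <- r0:r1
  cc <- c0:c1
  px <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  inside <- point_in_polygon(px[, 1], px[, 2], v)
  out[cbind(px[inside, 1], px[inside, 2])] <- TRUE
  out
}

# Even-odd point-in-polygon test, vectorized over query points.
point_in_polygon <- function(pr, pc, v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(pr))
  for (k in seq_len(n)) {
    ar <- v[k, 1]; ac <- v[k, 2]
    br <- v[j[k], 1]; bc <- v[j[k], 2]
    crosses <- ((ar > pr) != (br > pr))
    if (any(crosses)) {
      xc <- ac + (pr[crosses] - ar) / (br - ar) * (bc - ac)
      inside[crosses] <- xor(inside[crosses], pc[crosses] < xc)
    }
  }
  inside
}

# Rasterize an ellipse (center (row, col), full axis lengths major/minor,
# orientation theta of the major axis in radians, measured from the column
# axis toward the row axis) into mask indices of an existing matrix.
ellipse_pixels <- function(center, major, minor, theta, dm) {
  a <- major / 2
  b <- minor / 2
  ext <- ceiling(max(a, b)) + 1L
  rr <- max(1L, floor(center[1] - ext)):min(dm[1], ceiling(center[1] + ext))
  cc <- max(1L, floor(center[2] - ext)):min(dm[2], ceiling(center[2] + ext))
  if (!length(rr) || !length(cc)) return(cbind(row = integer(0), col = integer(0)))
  g <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  dr <- g[, 1] - center[1]
  dc <- g[, 2] - center[2]
  u <- dc * cos(theta) + dr * sin(theta)     # along major axis
  w <- -dc * sin(theta) + dr * cos(theta)    # along minor axis
  keep <- (u / a)^2 + (w / b)^2 <= 1
  cbind(row = g[keep, 1], col = g[keep, 2])
}

# Shoelace area of an (n x 2) polygon.
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Perimeter of an (n x 2) closed polygon.
polygon_perimeter <- function(v) {
  d <- diff(rbind(v, v[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# Centroid of mask pixels.
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}
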