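# HE nucleus segmentation: multi-scale center detection on the hematoxylin
# map, non-maxima suppression, polar sampling, dynamic-programming snake.

#' Default HE segmentation parameters
#'
#' DoG sigmas of 2.5 and 5 px and Hough radii of 8-20 px cover nucleus
#' diameters of roughly 5-15 um at 0.46 um/px; NMS separation 8 px; 72 polar
#' rays to 30 px.
#'
#' @return Named list of tunable parameters.
#' @export
he_params <- function() {
  list(sigma_small = 2.5, sigma_mid = 5, hough_radii = 8:20,
       response_floor = 0.3, min_separation_px = 8, n_rays = 72, r_max = 30,
       smoothness_lambda = 0.25, polar_blur_sigma = 1, min_area_px = 25,
       min_interior_od = 0.3, dedup_overlap = 0.3, refine_radius = 6)
}

#' Detect nucleus center candidates on a hematoxylin map
#'
#' Three peak-response maps are computed — difference-of-Gaussians at a small
#' and a mid scale for dense nuclei, and a circular Hough transform of the
#' gradient field for large nuclei — each rescaled to [0, 1] and aggregated
#' by pixelwise maximum. Local maxima of the aggregate above
#' \code{response_floor} become candidates.
#'
#' @param hem_map grey-level hematoxylin map (matrix).
#' @param params list as \code{\link{he_params}} (uses \code{sigma_small},
#'   \code{sigma_mid}, \code{hough_radii}, \code{response_floor}).
#' @return data.frame with columns \code{row}, \code{col},
#'   \code{scale_source} (\code{dog_small}, \code{dog_mid},
#'   \code{hough_large}) and \code{response}, ordered by descending response.
#' @export
detect_centers <- function(hem_map, params = he_params()) {
  stopifnot(params$sigma_small > 0, params$sigma_small < params$sigma_mid)
  if (!length(params$hough_radii)) stop("empty Hough radius list")
  maps <- list(
    dog_small = dog_response(hem_map, params$sigma_small),
    dog_mid = dog_response(hem_map, params$sigma_mid),
    hough_large = hough_response(hem_map, params$hough_radii))
  # only positive band-pass / accumulator response is center evidence
  maps <- lapply(maps, function(m) rescale01(pmax(m, 0)))
  agg <- pmax(maps[[1]], maps[[2]], maps[[3]])
  loc <- local_maxima(agg, params$response_floor)
  if (!nrow(loc))
    return(data.frame(row = integer(0), col = integer(0),
                      scale_source = character(0), response = numeric(0)))
  src <- names(maps)[max.col(cbind(maps[[1]][loc], maps[[2]][loc],
                                   maps[[3]][loc]), ties.method = "first")]
  out <- data.frame(row = loc[, 1], col = loc[, 2], scale_source = src,
                    response = agg[loc], stringsAsFactors = FALSE)
  out[order(-out$response, out$row, out$col), , drop = FALSE]
}

dog_response <- function(m, sigma) {
  as.matrix(EBImage::gblur(m, sigma)) - as.matrix(EBImage::gblur(m, 1.6 * sigma))
}

# circular Hough: strong-gradient pixels vote one radius step up-gradient
# (toward the darker-staining nucleus interior), accumulated over radii
hough_response <- function(m, radii) {
  sm <- as.matrix(EBImage::gblur(m, 1))
  nr <- nrow(sm); nc <- ncol(sm)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  thr <- stats::quantile(mag, 0.9, names = FALSE)
  if (thr <= 0) return(matrix(0, nr, nc))
  idx <- which(mag > thr)
  rr <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  ur <- gr[idx] / mag[idx]
  uc <- gc[idx] / mag[idx]
  acc <- matrix(0, nr, nc)
  for (r in radii) {
    vr <- round(rr + r * ur)
    vc <- round(cc + r * uc)
    ok <- vr >= 1 & vr <= nr & vc >= 1 & vc <= nc
    votes <- tabulate((vc[ok] - 1) * nr + vr[ok], nbins = nr * nc)
    acc <- acc + matrix(votes, nr, nc)
  }
  as.matrix(EBImage::gblur(acc, 2))
}

rescale01 <- function(m) {
  rng <- range(m)
  if (rng[2] <= rng[1]) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

# strict-ish local maxima (>= over 3x3 neighborhood) above a floor
local_maxima <- function(m, floor_val) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  ismax <- m >= floor_val
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & (m >= pad[2:(nr + 1) + dr, 2:(nc + 1) + dc])
  }
  which(ismax, arr.ind = TRUE)
}

#' Greedy non-maxima suppression of detection candidates
#'
#' Keeps the highest-response candidate first and drops any later candidate
#' within \code{min_separation_px} of a survivor.
#'
#' @param candidates data.frame from \code{\link{detect_centers}}.
#' @param min_separation_px minimum pairwise center distance (> 0).
#' @return The surviving candidates, ordered by descending response.
#' @export
nonmax_suppress <- function(candidates, min_separation_px = 8) {
  stopifnot(min_separation_px > 0)
  if (!nrow(candidates)) return(candidates)
  cand <- candidates[order(-candidates$response), , drop = FALSE]
  keep_r <- numeric(0); keep_c <- numeric(0); keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(keep) ||
        all((keep_r - cand$row[i])^2 + (keep_c - cand$col[i])^2 >=
            min_separation_px^2)) {
      keep <- c(keep, i)
      keep_r <- c(keep_r, cand$row[i])
      keep_c <- c(keep_c, cand$col[i])
    }
  }
  cand[keep, , drop = FALSE]
}

#' Extract a polar cross-section around a candidate center
#'
#' Bilinearly samples the map along \code{n_rays} equally spaced directions
#' at radii 1..\code{r_max}; samples falling outside the image take the
#' nearest edge value.
#'
#' @param hem_map grey-level map.
#' @param center (row, col) center.
#' @param n_rays number of rays (>= 16).
#' @param r_max maximum radius in px (>= 4).
#' @return Object of class \code{polar_sample}: list with \code{values}
#'   (n_rays x r_max matrix), \code{center}, \code{angles}.
#' @export
extract_polar <- function(hem_map, center, n_rays = 72, r_max = 30) {
  stopifnot(n_rays >= 16, r_max >= 4)
  ang <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  rr <- seq_len(r_max)
  pr <- outer(sin(ang), rr) + center[1]   # rows: rays, cols: radii
  pc <- outer(cos(ang), rr) + center[2]
  vals <- bilinear_sample(hem_map, pr, pc)
  structure(list(values = vals, center = center, angles = ang),
            class = "polar_sample")
}

# bilinear interpolation with edge clamping; pr/pc same shape
bilinear_sample <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  pr <- pmin(pmax(pr, 1), nr)
  pc <- pmin(pmax(pc, 1), nc)
  r0 <- pmin(floor(pr), nr - 1)
  c0 <- pmin(floor(pc), nc - 1)
  fr <- pr - r0
  fc <- pc - c0
  v00 <- m[cbind(as.vector(r0), as.vector(c0))]
  v10 <- m[cbind(as.vector(r0 + 1), as.vector(c0))]
  v01 <- m[cbind(as.vector(r0), as.vector(c0 + 1))]
  v11 <- m[cbind(as.vector(r0 + 1), as.vector(c0 + 1))]
  out <- (1 - as.vector(fr)) * (1 - as.vector(fc)) * v00 +
    as.vector(fr) * (1 - as.vector(fc)) * v10 +
    (1 - as.vector(fr)) * as.vector(fc) * v01 +
    as.vector(fr) * as.vector(fc) * v11
  matrix(out, nrow(pr), ncol(pr))
}

#' Trace a nucleus contour through a polar sample
#'
#' Snake-style boundary tracking as a circular minimum-cost path over rays:
#' the per-ray cost at radius r is the signed outward radial derivative of
#' the stain profile — the nucleus boundary is a falling edge going outward,
#' so strong negative derivatives attract the path while rising edges into a
#' neighboring nucleus repel it. Transitions are limited to |delta r| <= 2
#' px per ray with penalty \code{smoothness_lambda * |delta r|}, and the
#' path is closed (first and last radii agree) by dynamic programming over
#' all start radii. Radii are converted back to image coordinates.
#'
#' @param polar \code{polar_sample} from \code{\link{extract_polar}}.
#' @param smoothness_lambda smoothness penalty per px of radial step.
#' @return Object of class \code{nucleus_contour}: list with \code{vertices}
#'   (n_rays x 2 closed (row, col) polygon), \code{centroid}, \code{radii}.
#' @export
trace_contour <- function(polar, smoothness_lambda = 0.25) {
  v <- polar$values
  if (max(v) - min(v) < 1e-12) stop("no boundary evidence in polar sample")
  n_rays <- nrow(v)
  r_max <- ncol(v)
  grad <- t(apply(v, 1, function(p) {
    g <- numeric(length(p))
    g[2:(length(p) - 1)] <- (p[3:length(p)] - p[1:(length(p) - 2)]) / 2
    g[1] <- p[2] - p[1]
    g[length(p)] <- p[length(p)] - p[length(p) - 1]
    g
  }))
  cost <- grad   # negative (falling) outward derivative = boundary evidence
  # radius 1-2 is the candidate center itself; exclude from the boundary
  cost[, 1:2] <- abs(cost[, 1:2]) + max(abs(cost))
  radii <- dp_circular_path(cost, smoothness_lambda, max_step = 2)
  rows <- polar$center[1] + radii * sin(polar$angles)
  cols <- polar$center[2] + radii * cos(polar$angles)
  structure(list(vertices = cbind(row = rows, col = cols),
                 centroid = c(mean(rows), mean(cols)), radii = radii,
                 center = polar$center),
            class = "nucleus_contour")
}

# circular DP over all start radii at once: chains advance with |step| <=
# max_step per ray and must close on their start radius; the DP state is a
# (start radius x current radius) cost matrix
dp_circular_path <- function(cost, lambda, max_step = 2) {
  n <- nrow(cost)
  R <- ncol(cost)
  shifts <- -max_step:max_step
  D <- matrix(Inf, R, R)
  diag(D) <- cost[1, ]
  back <- array(0L, c(n, R, R))
  for (k in 2:n) {
    Dn <- matrix(Inf, R, R)
    bk <- matrix(0L, R, R)
    for (s in shifts) {
      dst <- which(seq_len(R) - s >= 1 & seq_len(R) - s <= R)
      cand <- D[, dst - s, drop = FALSE] + lambda * abs(s)
      cur <- Dn[, dst, drop = FALSE]
      upd <- cand < cur
      cur[upd] <- cand[upd]
      Dn[, dst] <- cur
      bcur <- bk[, dst, drop = FALSE]
      bcur[upd] <- matrix(dst - s, R, length(dst), byrow = TRUE)[upd]
      bk[, dst] <- bcur
    }
    D <- sweep(Dn, 2, cost[k, ], "+")
    back[k, , ] <- bk
  }
  pen <- lambda * abs(outer(seq_len(R), seq_len(R), "-"))
  pen[pen > lambda * max_step] <- Inf
  if (lambda == 0) pen[abs(outer(seq_len(R), seq_len(R), "-")) > max_step] <- Inf
  total <- D + pen
  idx <- which(total == min(total), arr.ind = TRUE)[1, ]
  r0 <- idx[1]
  path <- integer(n)
  path[n] <- idx[2]
  for (k in n:2) path[k - 1] <- back[k, r0, path[k]]
  path
}

# mean-shift style center refinement: move to the intensity-weighted
# centroid of a small window (background level subtracted) a few times
refine_center <- function(m, ctr, radius = 6, iters = 4) {
  for (it in seq_len(iters)) {
    rr <- max(1, round(ctr[1] - radius)):min(nrow(m), round(ctr[1] + radius))
    cc <- max(1, round(ctr[2] - radius)):min(ncol(m), round(ctr[2] + radius))
    w <- m[rr, cc, drop = FALSE]
    w <- pmax(w - stats::quantile(w, 0.25, names = FALSE), 0)
    if (sum(w) == 0) break
    new_ctr <- c(sum(rr * rowSums(w)), sum(cc * colSums(w))) / sum(w)
    done <- sqrt(sum((new_ctr - ctr)^2)) < 0.3
    ctr <- new_ctr
    if (done) break
  }
  clamp_center(ctr, dim(m))
}

clamp_center <- function(ctr, dm) {
  c(min(max(ctr[1], 2), dm[1] - 1), min(max(ctr[2], 2), dm[2] - 1))
}

#' Segment all nuclei in an HE-stained ROI
#'
#' Full HE chain: OD conversion, stain-vector estimation, hematoxylin
#' projection, multi-scale center detection, non-maxima suppression and a
#' polar snake per surviving candidate. Contours whose centroid falls in the
#' exclusion mask, whose area is below \code{min_area_px}, or whose interior
#' hematoxylin signal is below \code{min_interior_od} are dropped. The chain
#' contains no randomness.
#'
#' @param image RGB HE image (row x col x 3, [0, 255]).
#' @param exclusion_mask optional logical matrix of excluded tissue
#'   (fibroblasts, necrosis).
#' @param params list as \code{\link{he_params}}.
#' @return List of \code{nucleus_contour}s.
#' @export
segment_he_roi <- function(image, exclusion_mask = NULL, params = he_params()) {
  od <- rgb_to_od(image)
  vecs <- estimate_stain_vectors(od)
  hem <- project_stain(od, vecs[[1]])
  cand <- detect_centers(hem, params)
  cand <- nonmax_suppress(cand, params$min_separation_px)
  # speckle-suppressed map for boundary tracing
  hem_s <- as.matrix(EBImage::gblur(hem, params$polar_blur_sigma))
  claimed <- matrix(FALSE, nrow(hem), ncol(hem))
  out <- list()
  for (i in seq_len(nrow(cand))) {
    # detector peaks sit off-center on flat nuclei; pull the start point to
    # the local intensity centroid, then retrace from the contour centroid
    # until it stabilizes (at most twice)
    ctr <- refine_center(hem_s, c(cand$row[i], cand$col[i]),
                         params$refine_radius)
    con <- NULL
    for (it in 1:3) {
      con <- tryCatch(
        trace_contour(extract_polar(hem_s, ctr, params$n_rays, params$r_max),
                      params$smoothness_lambda),
        error = function(e) NULL)
      if (is.null(con)) break
      moved <- sqrt(sum((con$centroid - ctr)^2))
      if (moved < 1.5) break
      ctr <- clamp_center(con$centroid, dim(hem))
    }
    if (is.null(con)) next
    if (!is.null(exclusion_mask) &&
        exclusion_mask[round(con$centroid[1]), round(con$centroid[2])]) next
    mask <- rasterize_polygon(con$vertices, dim(hem))
    if (sum(mask) < params$min_area_px) next
    if (mean(hem[mask]) < params$min_interior_od) next
    # duplicate candidates on one nucleus trace near-identical contours;
    # keep the first (highest-response) claim on any image region
    if (sum(mask & claimed) / sum(mask) > params$dedup_overlap) next
    claimed <- claimed | mask
    con$area_px <- sum(mask)
    out[[length(out) + 1]] <- con
  }
  out
}
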