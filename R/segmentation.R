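#' Segmentation parameters
#'
#' @param dilate_radius,erode_radius disc structuring-element radii in
#'   pixels for the post-edge-detection morphology chain (0 disables the
#'   step). The default erosion radius exceeds the dilation radius to
#'   compensate for the half-width of the thresholded Sobel edge band,
#'   which otherwise inflates the mask outward (calibrated on noise-free
#'   synthetic cones against the ground-truth mask).
#' @param min_area smallest acceptable growth-cone area, um^2.
#' @param threshold optional fixed threshold on normalised gradient
#'   magnitude in (0, 1); default `NULL` uses Otsu's method.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(dilate_radius = 2, erode_radius = 4, min_area = 5,
                       threshold = NULL) {
  stopifnot(dilate_radius >= 0, erode_radius >= 0, min_area >= 0)
  structure(list(dilate_radius = dilate_radius, erode_radius = erode_radius,
                 min_area = min_area, threshold = threshold),
            class = "seg_params")
}

## standard Sobel kernels, written out with neighbour shifts
sobel_magnitude <- function(img) {
  gx <- (shift_mat_num(img, -1, -1) + 2 * shift_mat_num(img, 0, -1) +
           shift_mat_num(img, 1, -1)) -
        (shift_mat_num(img, -1, 1) + 2 * shift_mat_num(img, 0, 1) +
           shift_mat_num(img, 1, 1))
  gy <- (shift_mat_num(img, -1, -1) + 2 * shift_mat_num(img, -1, 0) +
           shift_mat_num(img, -1, 1)) -
        (shift_mat_num(img, 1, -1) + 2 * shift_mat_num(img, 1, 0) +
           shift_mat_num(img, 1, 1))
  sqrt(gx^2 + gy^2)
}

shift_mat_num <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## dilate -> fill holes -> erode; radii of 0 skip the respective step.
refine_mask <- function(binary, dilate_radius, erode_radius) {
  m <- matrix(as.numeric(binary != 0), nrow(binary))
  if (dilate_radius > 0)
    m <- EBImage::dilate(m, EBImage::makeBrush(2 * dilate_radius + 1, "disc"))
  m <- EBImage::fillHull(m)
  if (erode_radius > 0)
    m <- EBImage::erode(m, EBImage::makeBrush(2 * erode_radius + 1, "disc"))
  as.matrix(m) != 0
}

#' Segment the growth cone from cytoplasmic background fluorescence
#'
#' Edge-based segmentation: Sobel gradient magnitude, threshold (Otsu by
#' default), dilation, hole filling, erosion, and retention of the largest
#' connected component.
#'
#' @param frame single-channel image matrix (rows = y, columns = x).
#' @param pixel_size um per pixel.
#' @param params a [seg_params()].
#' @return Logical mask of the growth cone.
#' @export
segment_growth_cone <- function(frame, pixel_size, params = seg_params()) {
  if (!is.matrix(frame)) stop("frame must be a single-channel matrix")
  grad <- sobel_magnitude(frame)
  ## the outermost ring reflects zero padding, not image structure
  grad[c(1, nrow(grad)), ] <- 0
  grad[, c(1, ncol(grad))] <- 0
  if (max(grad) == 0) stop("no growth cone found: flat image")
  ## choose the threshold on the gradient of the median-filtered frame:
  ## the filter removes comet-scale spots, so a bright comet cannot drag
  ## the threshold above the cone-edge gradient. The threshold is then
  ## applied to the raw gradient (comet edges lie inside the cone and
  ## are absorbed by hole filling).
  mx <- max(frame)
  gradf <- sobel_magnitude(as.matrix(
    EBImage::medianFilter(frame / mx, 3)) * mx)
  gradf[c(1, nrow(gradf)), ] <- 0
  gradf[, c(1, ncol(gradf))] <- 0
  if (max(gradf) == 0) stop("no growth cone found: flat image")
  thr_abs <- if (is.null(params$threshold))
    EBImage::otsu(EBImage::Image(gradf / max(gradf)),
                  range = c(0, 1)) * max(gradf)
  else params$threshold * max(grad)
  edges <- grad > thr_abs
  ## seal the edge contour against the image border: where the object is
  ## cut by the frame (the neurite entry), the boundary ring is open and
  ## hole filling would leak out
  nr <- nrow(edges); nc <- ncol(edges)
  edges[, 1:2] <- edges[, 1:2] | edges[, c(3, 3)]
  edges[, (nc - 1):nc] <- edges[, (nc - 1):nc] | edges[, c(nc - 2, nc - 2)]
  edges[1:2, ] <- edges[1:2, ] | edges[c(3, 3), ]
  edges[(nr - 1):nr, ] <- edges[(nr - 1):nr, ] | edges[c(nr - 2, nr - 2), ]
  mask <- refine_mask(edges, params$dilate_radius, params$erode_radius)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  lab <- as.matrix(lab)
  if (max(lab) == 0) stop("no growth cone found")
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  if (sizes[best] * pixel_size^2 < params$min_area)
    stop("no growth cone found: largest component below min_area")
  lab == best
}

#' Boundary polygon of a binary mask
#'
#' Sub-pixel closed contour at level 0.5 (marching squares); the longest
#' contour is returned, in micrometres.
#'
#' @param mask logical matrix.
#' @param pixel_size um per pixel.
#' @return n x 2 matrix of (x, y) vertices, not repeating the first point.
#' @export
mask_boundary <- function(mask, pixel_size) {
  if (!any(mask)) stop("empty mask")
  z <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  z[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.numeric(mask)
  ## grid coordinates: row i of z sits at y = (i - 2) * px, col j at x = (j - 2) * px
  cl <- grDevices::contourLines(x = (seq_len(nrow(z)) - 2) * pixel_size,
                                y = (seq_len(ncol(z)) - 2) * pixel_size,
                                z = z, levels = 0.5)
  if (!length(cl)) stop("empty mask")
  len <- vapply(cl, function(p) sum(sqrt(diff(p$x)^2 + diff(p$y)^2)), 0)
  p <- cl[[which.max(len)]]
  out <- cbind(x = p$y, y = p$x)   # contourLines' x follows matrix rows (= our y)
  if (nrow(out) > 1 && all(out[1, ] == out[nrow(out), ]))
    out <- out[-nrow(out), , drop = FALSE]
  out
}

#' Morphological scalar features of a growth-cone mask
#'
#' Region properties in physical units: area, perimeter, centroid, and the
#' axes/eccentricity of the second-moment equivalent ellipse (length =
#' major axis, width = minor axis), as in the classical `regionprops`
#' convention.
#'
#' @param mask logical matrix.
#' @param pixel_size um per pixel.
#' @return Named list: `area` (um^2), `perimeter` (um), `length`, `width`
#'   (um), `eccentricity` in `[0, 1)`, `centroid` (x, y um).
#' @export
morphology_features <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  x <- (idx[, 2] - 1) * pixel_size
  y <- (idx[, 1] - 1) * pixel_size
  ctr <- c(mean(x), mean(y))
  ## second central moments of the pixel set, plus the 1/12 pixel term
  cxx <- mean((x - ctr[1])^2) + pixel_size^2 / 12
  cyy <- mean((y - ctr[2])^2) + pixel_size^2 / 12
  cxy <- mean((x - ctr[1]) * (y - ctr[2]))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  bnd <- mask_boundary(mask, pixel_size)
  per <- sum(sqrt(diff(c(bnd[, 1], bnd[1, 1]))^2 +
                  diff(c(bnd[, 2], bnd[1, 2]))^2))
  list(area = nrow(idx) * pixel_size^2,
       perimeter = per,
       length = 4 * sqrt(ev[1]),
       width = 4 * sqrt(ev[2]),
       eccentricity = sqrt(max(0, 1 - ev[2] / ev[1])),
       centroid = c(x = ctr[1], y = ctr[2]))
}

#' Growth-cone midline from the mask skeleton
#'
#' The midline follows the ridge of the interior distance transform,
#' realised as the maximum-arc-length endpoint-to-endpoint path through
#' the thinned mask, lightly smoothed, and ordered proximal to tip.
#'
#' @param mask logical matrix (single connected component).
#' @param pixel_size um per pixel.
#' @param entry_edge image edge through which the neurite enters
#'   (`"left"`, `"right"`, `"top"`, `"bottom"`); the midline endpoint
#'   farther from this edge is taken to be the tip.
#' @param smooth moving-average window (vertices) for smoothing.
#' @return n x 2 matrix of (x, y) vertices in um, first row = proximal
#'   end, last row = tip.
#' @export
compute_midline <- function(mask, pixel_size, entry_edge = "left",
                            smooth = 5) {
  if (sum(mask) < 8) stop("mask too small to skeletonize")
  skel <- skeletonize_mask(mask)
  path <- skeleton_longest_path(skel)
  ## near-isotropic masks (e.g. a disk) thin to a degenerate short path,
  ## in the limit a single centre pixel; that is a valid collapsed
  ## midline
  if (nrow(path) == 0) stop("mask too small to skeletonize")
  if (nrow(path) == 1) path <- path[c(1, 1), , drop = FALSE]
  ## snap each vertex to the perpendicular maximum of the interior
  ## distance transform: thinning approximates the medial axis but can
  ## run a pixel off the true ridge in wide regions
  if (nrow(path) > 2) {
    dt <- as.matrix(EBImage::distmap(matrix(as.numeric(mask), nrow(mask))))
    for (i in 2:(nrow(path) - 1)) {
      tg <- path[i + 1, ] - path[i - 1, ]
      nrm <- c(-tg[2], tg[1])
      L <- sqrt(sum(nrm^2))
      if (L == 0) next
      nrm <- nrm / L
      cand <- sapply(-2:2, function(k) {
        r <- path[i, 1] + round(k * nrm[1])
        c <- path[i, 2] + round(k * nrm[2])
        if (r < 1 || c < 1 || r > nrow(dt) || c > ncol(dt)) -Inf else dt[r, c]
      })
      k <- (-2:2)[which.max(cand)]
      path[i, ] <- path[i, ] + round(k * nrm)
    }
  }
  xy <- cbind(x = (path[, 2] - 1) * pixel_size,
              y = (path[, 1] - 1) * pixel_size)
  if (smooth > 1 && nrow(xy) > smooth) {
    k <- rep(1 / smooth, smooth)
    sm <- cbind(stats::filter(xy[, 1], k, sides = 2),
                stats::filter(xy[, 2], k, sides = 2))
    keep <- !is.na(sm[, 1])
    xy[keep, ] <- sm[keep, ]
  }
  ends <- xy[c(1, nrow(xy)), , drop = FALSE]
  edge_coord <- switch(entry_edge,
                       left = ends[, 1], right = -ends[, 1],
                       top = ends[, 2], bottom = -ends[, 2],
                       stop("unknown entry_edge"))
  ## tip = endpoint farther from the entry edge; ensure row 1 is proximal
  if (edge_coord[1] > edge_coord[2]) xy <- xy[nrow(xy):1, , drop = FALSE]
  xy
}

#' Leading-edge ("front") arc and tip point from midline and boundary
#'
#' A division point is placed on the midline at arc-length fraction
#' `fraction` from the tip end (default 1/2.7, i.e. a 1:1.7 front:rear
#' split of the midline). The front is the contiguous boundary arc lying
#' tip-ward of the line through the division point perpendicular to the
#' local midline direction.
#'
#' @param midline n x 2 matrix, proximal-to-tip order (um).
#' @param boundary closed polygon, m x 2 (um).
#' @param fraction arc-length fraction of the midline, measured from the
#'   tip, at which the front/rear division point is placed.
#' @return List: `front` (k x 2 polyline), `tip` (boundary point nearest
#'   the distal midline end), `division` (division point on the midline).
#' @export
compute_front <- function(midline, boundary, fraction = 1 / 2.7) {
  if (nrow(midline) < 3) stop("midline shorter than 3 points")
  seglen <- sqrt(diff(midline[, 1])^2 + diff(midline[, 2])^2)
  L <- sum(seglen)
  target <- (1 - fraction) * L          # arc length from the proximal end
  cs <- c(0, cumsum(seglen))
  i <- max(1, findInterval(min(target, L - 1e-12), cs))
  frac <- (target - cs[i]) / seglen[i]
  division <- midline[i, ] + frac * (midline[i + 1, ] - midline[i, ])
  ## local tip-ward tangent by central difference around the division point
  i0 <- max(1, i - 1); i1 <- min(nrow(midline), i + 2)
  tangent <- midline[i1, ] - midline[i0, ]
  tangent <- tangent / sqrt(sum(tangent^2))
  ## tip = boundary vertex farthest along the overall proximal-to-distal
  ## midline direction; more stable than projecting the skeleton
  ## endpoint, which can flip between boundary lobes frame to frame
  ax <- midline[nrow(midline), ] - midline[1, ]
  ax <- ax / sqrt(sum(ax^2))
  tip_i <- which.max(boundary[, 1] * ax[1] + boundary[, 2] * ax[2])
  tipward <- (boundary[, 1] - division[1]) * tangent[1] +
             (boundary[, 2] - division[2]) * tangent[2] > 0
  if (!tipward[tip_i]) tipward[tip_i] <- TRUE   # degenerate masks
  m <- length(tipward)
  ## contiguous circular run of tip-side vertices containing tip_i
  lo <- tip_i
  while (tipward[((lo - 2) %% m) + 1] && lo > tip_i - m + 1) lo <- lo - 1
  hi <- tip_i
  while (tipward[(hi %% m) + 1] && hi < tip_i + m - 1) hi <- hi + 1
  run <- ((lo:hi - 1) %% m) + 1
  list(front = boundary[run, , drop = FALSE],
       tip = c(x = unname(boundary[tip_i, 1]), y = unname(boundary[tip_i, 2])),
       division = c(x = unname(division[1]), y = unname(division[2])))
}

#' Full landmark geometry for one frame
#'
#' Convenience wrapper running [morphology_features()],
#' [compute_midline()] and [compute_front()] on a segmented mask.
#'
#' @inheritParams compute_midline
#' @param front_fraction see [compute_front()].
#' @return Object of class `gc_geometry` with the mask, boundary, midline,
#'   front arc, tip, division point and all morphology scalars.
#' @export
gc_geometry <- function(mask, pixel_size, entry_edge = "left",
                        front_fraction = 1 / 2.7) {
  feats <- morphology_features(mask, pixel_size)
  boundary <- mask_boundary(mask, pixel_size)
  midline <- compute_midline(mask, pixel_size, entry_edge)
  fr <- compute_front(midline, boundary, front_fraction)
  structure(c(list(mask = mask, pixel_size = pixel_size,
                   boundary = boundary, midline = midline,
                   front = fr$front, tip = fr$tip, division = fr$division),
              feats),
            class = "gc_geometry")
}

#' @export
print.gc_geometry <- function(x, ...) {
  cat(sprintf(
    "gc_geometry: area %.1f um^2, perimeter %.1f um, L %.1f x W %.1f um, ecc %.2f\n",
    x$area, x$perimeter, x$length, x$width, x$eccentricity))
  invisible(x)
}
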