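#' Minimal Euclidean distance from points to a polyline
#'
#' Exact point-to-segment distance minimised over all segments of the
#' curve.
#'
#' @param points n x 2 matrix (or length-2 vector) of (x, y).
#' @param curve m x 2 matrix of polyline vertices; a single vertex is
#'   treated as a point.
#' @return Numeric vector of distances, same units as the inputs.
#' @export
distance_to_curve <- function(points, curve) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  curve <- as.matrix(curve)
  if (nrow(curve) == 1)
    return(sqrt((points[, 1] - curve[1, 1])^2 +
                (points[, 2] - curve[1, 2])^2))
  a <- curve[-nrow(curve), , drop = FALSE]
  b <- curve[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    ap1 <- points[i, 1] - a[, 1]
    ap2 <- points[i, 2] - a[, 2]
    t <- ifelse(len2 > 0, (ap1 * ab[, 1] + ap2 * ab[, 2]) / len2, 0)
    t <- pmin(1, pmax(0, t))
    dx <- ap1 - t * ab[, 1]
    dy <- ap2 - t * ab[, 2]
    out[i] <- sqrt(min(dx^2 + dy^2))
  }
  out
}

#' Comet distances to growth-cone landmarks
#'
#' For every detection, the minimal distance to the front arc and to the
#' midline of that frame's geometry. Birth and death distances to the
#' front are reported only for complete-within-burst tracks, matching the
#' convention that only comets appearing and disappearing within the
#' burst enter birth/death analyses.
#'
#' @param tracks filtered detection data.frame (with `complete` column).
#' @param geometries list of `gc_geometry`, indexed by frame number.
#' @return List: `records` (one row per detection: `track`, `frame`,
#'   `dist_front`, `dist_midline`, `complete`) and `endpoints` (one row
#'   per complete track: `dist_front_birth`, `dist_front_death`).
#' @export
comet_landmark_distances <- function(tracks, geometries) {
  recs <- list()
  for (i in seq_len(nrow(tracks))) {
    f <- tracks$frame[i]
    g <- if (f <= length(geometries)) geometries[[f]] else NULL
    if (is.null(g)) {
      warning("no geometry for frame ", f, "; record skipped")
      next
    }
    p <- c(tracks$x[i], tracks$y[i])
    recs[[length(recs) + 1L]] <- data.frame(
      track = tracks$track[i], frame = f,
      dist_front = distance_to_curve(p, g$front),
      dist_midline = distance_to_curve(p, g$midline),
      complete = if ("complete" %in% names(tracks)) tracks$complete[i] else NA)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(track = integer(), frame = integer(),
               dist_front = numeric(), dist_midline = numeric(),
               complete = logical())
  endpoints <- do.call(rbind, lapply(split(records, records$track), function(r) {
    r <- r[order(r$frame), ]
    if (!isTRUE(r$complete[1])) return(NULL)
    data.frame(track = r$track[1],
               dist_front_birth = r$dist_front[1],
               dist_front_death = r$dist_front[nrow(r)])
  }))
  if (is.null(endpoints))
    endpoints <- data.frame(track = integer(), dist_front_birth = numeric(),
                            dist_front_death = numeric())
  rownames(records) <- rownames(endpoints) <- NULL
  list(records = records, endpoints = endpoints)
}

#' Classify comet net-path direction relative to the midline
#'
#' The angle between a track's net birth-to-death path and the tip-ward
#' midline tangent at the nearest midline vertex. Anterograde if the
#' absolute angle is at most `ant_max`, retrograde if at least `ret_min`,
#' lateral otherwise.
#'
#' @param summary per-track summary from [track_kinematics()] together
#'   with start coordinates: needs columns `track`, `net_dx`, `net_dy`,
#'   `net_len`, `x0`, `y0` (position at birth).
#' @param midline n x 2 midline matrix, proximal-to-tip order.
#' @param ant_max,ret_min classification thresholds, degrees.
#' @return data.frame `track`, `angle` (degrees, in `[-180, 180]`),
#'   `direction_class`; zero-length paths are dropped with a warning.
#' @export
path_angle_class <- function(summary, midline, ant_max = 45, ret_min = 135) {
  if (any(summary$net_len == 0)) {
    warning("dropping ", sum(summary$net_len == 0),
            " zero-net-path track(s): direction undefined")
    summary <- summary[summary$net_len > 0, , drop = FALSE]
  }
  n <- nrow(midline)
  ## tip-ward tangent at each vertex by central differences
  tang <- rbind(midline[2, ] - midline[1, ],
                midline[3:n, , drop = FALSE] -
                  midline[1:(n - 2), , drop = FALSE],
                midline[n, ] - midline[n - 1, ])
  out <- do.call(rbind, lapply(seq_len(nrow(summary)), function(i) {
    d2 <- (midline[, 1] - summary$x0[i])^2 + (midline[, 2] - summary$y0[i])^2
    tg <- tang[which.min(d2), ]
    v <- c(summary$net_dx[i], summary$net_dy[i])
    ang <- (atan2(v[2], v[1]) - atan2(tg[2], tg[1])) * 180 / pi
    ang <- ((ang + 180) %% 360) - 180
    cls <- if (abs(ang) <= ant_max) "anterograde"
           else if (abs(ang) >= ret_min) "retrograde" else "lateral"
    data.frame(track = summary$track[i], angle = ang, direction_class = cls)
  }))
  if (is.null(out))
    out <- data.frame(track = integer(), angle = numeric(),
                      direction_class = character())
  rownames(out) <- NULL
  out
}

#' Median comet speed profile by distance to the growth-cone front
#'
#' Instantaneous speeds are grouped into fixed-width distance-to-front
#' intervals (1 um by default: below 1 um, 1-2 um, ...), with the notch
#' median confidence interval per bin.
#'
#' @param records per-detection spatial records (needs `track`, `frame`,
#'   `dist_front`).
#' @param steps per-step speeds from [track_kinematics()] (`track`,
#'   `frame`, `speed`); each speed is attributed to the distance of the
#'   step's starting detection.
#' @param bin_width distance bin width, um.
#' @return data.frame per non-empty bin: `bin_lo`, `bin_hi`, `n`,
#'   `median`, `ci_lo`, `ci_hi`.
#' @export
front_zone_speed_profile <- function(records, steps, bin_width = 1) {
  m <- merge(steps, records[, c("track", "frame", "dist_front")],
             by = c("track", "frame"))
  if (nrow(m) == 0) stop("no speed records with matching distances")
  m$bin <- floor(m$dist_front / bin_width)
  out <- do.call(rbind, lapply(split(m, m$bin), function(d) {
    ci <- median_ci(d$speed)
    data.frame(bin_lo = d$bin[1] * bin_width,
               bin_hi = (d$bin[1] + 1) * bin_width,
               n = nrow(d), median = ci$median,
               ci_lo = ci$ci_lo, ci_hi = ci$ci_hi)
  }))
  out[order(out$bin_lo), ]
}
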