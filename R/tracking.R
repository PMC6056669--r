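#' Plus-end tracking parameters
#'
#' Defaults follow the published plus-end tracking settings for growth
#' cone EB3 comets: search radius range 1.5-6 px, minimum track length 3
#' frames, maximum gap 3 frames, maximum shrinkage factor 1.4, maximum
#' forward angle 35 degrees, maximum backward angle 15 degrees,
#' fluctuation radius 1.25 px.
#'
#' @param search_radius numeric length-2, min and max search radius (px).
#' @param min_track_length minimum number of detections per kept track.
#' @param max_gap maximum number of consecutive missed frames bridged by
#'   gap closing.
#' @param max_shrink maximum backward displacement as a multiple of the
#'   track's mean per-frame growth displacement.
#' @param max_fwd_angle maximum angle (deg) off the track direction for a
#'   forward continuation.
#' @param max_bwd_angle maximum angle (deg) off the reverse track
#'   direction for a backward continuation.
#' @param fluct_radius displacements below this radius (px) are exempt
#'   from the angle tests.
#' @return list of class `tracking_params`.
#' @export
tracking_params <- function(search_radius = c(1.5, 6), min_track_length = 3,
                            max_gap = 3, max_shrink = 1.4,
                            max_fwd_angle = 35, max_bwd_angle = 15,
                            fluct_radius = 1.25) {
  stopifnot(length(search_radius) == 2, search_radius[1] > 0,
            search_radius[1] <= search_radius[2],
            min_track_length >= 1, max_gap >= 0,
            max_fwd_angle > 0, max_fwd_angle <= 180,
            max_bwd_angle > 0, max_bwd_angle <= 180)
  structure(list(search_radius = search_radius,
                 min_track_length = as.integer(min_track_length),
                 max_gap = as.integer(max_gap), max_shrink = max_shrink,
                 max_fwd_angle = max_fwd_angle,
                 max_bwd_angle = max_bwd_angle,
                 fluct_radius = fluct_radius),
            class = "tracking_params")
}

#' Comet detection parameters
#'
#' @param median_radius radius (px) of the median filter used to estimate
#'   and subtract the cytoplasmic background when no segmentation mask is
#'   supplied; median filtering preserves the growth-cone edge step while
#'   removing spot-scale structure, so the residual isolates the comets.
#' @param sigma_small,sigma_large difference-of-Gaussians band-pass
#'   scales (px) applied to the background-subtracted residual.
#' @param n_sigma detection threshold in units of the expected local
#'   noise (Poisson shot noise of the estimated background plus
#'   `sigma0` read noise, propagated through the band-pass filter).
#' @param sigma0 assumed additive (read) noise SD, intensity units.
#' @param refine `"fit"` for neighbour-aware oriented Gaussian
#'   least-squares localisation (sub-pixel accuracy close to the photon
#'   limit), or `"parabolic"` for fast 3x3 quadratic peak interpolation.
#' @param spot_sigma assumed effective comet half-widths (px) along and
#'   across its axis, used as the fixed shape of the fitted model.
#' @param fit_halfwidth half-width (px) of the fitting window.
#' @param clean_pass logical; after fitting, subtract all fitted spots
#'   and run one more maxima pass on the residual to pick up comets
#'   merged with a brighter neighbour.
#' @return list of class `detect_params`.
#' @export
detect_params <- function(median_radius = 4, sigma_small = 1,
                          sigma_large = 3, n_sigma = 5, sigma0 = 3,
                          refine = c("fit", "parabolic"),
                          spot_sigma = c(2.2, 1.5), fit_halfwidth = 5,
                          clean_pass = TRUE) {
  structure(list(median_radius = median_radius, sigma_small = sigma_small,
                 sigma_large = sigma_large, n_sigma = n_sigma,
                 sigma0 = sigma0, refine = match.arg(refine),
                 spot_sigma = spot_sigma, fit_halfwidth = fit_halfwidth,
                 clean_pass = clean_pass),
            class = "detect_params")
}

## oriented fixed-shape Gaussian evaluated at (rv, cv) pixel coordinates
spot_model <- function(rv, cv, y, x, A, ang, sig) {
  ca <- cos(ang); sa <- sin(ang)
  u <- (cv - x) * ca + (rv - y) * sa
  v <- -(cv - x) * sa + (rv - y) * ca
  A * exp(-0.5 * (u^2 / sig[1]^2 + v^2 / sig[2]^2))
}

## two-pass sequential fitting with neighbour subtraction; est is a
## data.frame with columns r, c (integer peak), y, x, A, ang.
## Position and orientation are optimised while amplitude, a local
## constant offset and a linear baseline ramp are profiled out by
## linear least squares; the ramp absorbs background-model error near
## the growth-cone edge.
refine_spots_fit <- function(res, est, params, valid = NULL) {
  h <- params$fit_halfwidth
  sig <- params$spot_sigma
  for (pass in 1:2) {
    for (i in seq_len(nrow(est))) {
      rr <- max(1, est$r[i] - h):min(nrow(res), est$r[i] + h)
      cc <- max(1, est$c[i] - h):min(ncol(res), est$c[i] + h)
      Rw <- outer(rr, rep(1, length(cc)))
      Cw <- outer(rep(1, length(rr)), cc)
      z <- res[rr, cc]
      for (j in seq_len(nrow(est))) {
        if (j == i) next
        if ((est$y[j] - est$y[i])^2 + (est$x[j] - est$x[i])^2 < (4 * h)^2)
          z <- z - spot_model(Rw, Cw, est$y[j], est$x[j], est$A[j],
                              est$ang[j], sig)
      }
      keep_px <- if (is.null(valid)) rep(TRUE, length(z)) else
        as.vector(valid[rr, cc])
      if (sum(keep_px) < 20) keep_px <- rep(TRUE, length(z))
      rv <- as.vector(Rw)[keep_px]; cv <- as.vector(Cw)[keep_px]
      zv <- as.vector(z)[keep_px]
      lin_coef <- function(p) {
        g <- spot_model(rv, cv, p[1], p[2], 1, p[3], sig)
        X <- cbind(g, 1, rv - p[1], cv - p[2])
        tryCatch(stats::.lm.fit(X, zv), error = function(e) NULL)
      }
      obj <- function(p) {
        f <- lin_coef(p)
        if (is.null(f)) return(sum(zv^2))
        sum(f$residuals^2)
      }
      o <- try(stats::optim(c(est$y[i], est$x[i], est$ang[i]), obj,
                            method = "Nelder-Mead",
                            control = list(maxit = 300)), silent = TRUE)
      if (inherits(o, "try-error")) next
      ## reject fits that wander away from their peak (neighbour capture)
      if ((o$par[1] - est$r[i])^2 + (o$par[2] - est$c[i])^2 > h^2) next
      f <- lin_coef(o$par)
      if (is.null(f) || f$coefficients[1] <= 0) next
      est$y[i] <- o$par[1]; est$x[i] <- o$par[2]
      est$A[i] <- f$coefficients[1]; est$ang[i] <- o$par[3]
    }
  }
  est
}

#' Detect comet spots in one frame
#'
#' Background flattening (either a segmentation-mask background model or
#' median filtering), band-pass (difference-of-Gaussians) filtering of
#' the residual, local-maxima extraction above an adaptive
#' photon-statistics threshold, and sub-pixel localisation by
#' neighbour-aware least-squares fitting of an oriented Gaussian spot
#' model (or, optionally, fast parabolic peak interpolation). A final
#' CLEAN-style pass subtracts fitted spots and re-detects maxima, which
#' recovers comets partially merged with a brighter neighbour.
#'
#' @param frame image matrix.
#' @param pixel_size um per pixel.
#' @param params a [detect_params()].
#' @param mask optional growth-cone segmentation mask; when supplied the
#'   background is modelled as the in-mask median intensity over the
#'   blurred mask, which removes the cone edge from the residual exactly.
#' @return data.frame with columns `x`, `y` (um) and `intensity` (fitted
#'   or band-pass peak amplitude); zero rows if nothing is found.
#' @export
detect_comets <- function(frame, pixel_size, params = detect_params(),
                          mask = NULL) {
  if (!is.matrix(frame)) stop("frame must be a single-channel matrix")
  mx <- max(frame)
  if (mx <= 0)
    return(data.frame(x = numeric(), y = numeric(), intensity = numeric()))
  valid <- NULL
  if (!is.null(mask)) {
    ## model the cytoplasmic background as a constant plateau over its
    ## own intensity support: the median filter removes comet-scale
    ## structure and the half-level crossing marks the cone edge at
    ## sub-pixel fidelity, independent of the segmentation's morphology
    ## calibration (the mask only anchors the plateau level)
    lvl <- stats::median(frame[mask])
    med3 <- as.matrix(EBImage::medianFilter(frame / mx, 3)) * mx
    support <- matrix(as.numeric(med3 > lvl / 2), nrow(frame))
    bg <- lvl * as.matrix(EBImage::gblur(support,
                                         sigma = params$sigma_small))
    ## the model is unreliable in a +/- 2 px band around the support
    ## edge; exclude that band from the fitting support
    din <- as.matrix(EBImage::distmap(support))
    dout <- as.matrix(EBImage::distmap(1 - support))
    valid <- din > 2 | dout > 2
  } else {
    bg <- as.matrix(EBImage::medianFilter(frame / mx,
                                          params$median_radius)) * mx
  }
  res <- frame - bg
  find_peaks <- function(resid, n_sigma = params$n_sigma) {
    bp <- as.matrix(EBImage::gblur(resid, sigma = params$sigma_small)) -
          as.matrix(EBImage::gblur(resid, sigma = params$sigma_large))
    s1 <- params$sigma_small; s2 <- params$sigma_large
    atten <- sqrt(1 / (4 * pi * s1^2) + 1 / (4 * pi * s2^2) -
                  1 / (pi * (s1^2 + s2^2)))
    thr_map <- n_sigma * atten * sqrt(pmax(bg, 0) + params$sigma0^2)
    is_max <- bp > thr_map
    for (o in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1)))
      is_max <- is_max & bp >= shift_mat_num(bp, o[1], o[2])
    is_max[c(1, nrow(bp)), ] <- FALSE
    is_max[, c(1, ncol(bp))] <- FALSE
    list(pk = which(is_max, arr.ind = TRUE), bp = bp)
  }
  fp <- find_peaks(res)
  pk <- fp$pk
  if (nrow(pk) == 0)
    return(data.frame(x = numeric(), y = numeric(), intensity = numeric()))
  est <- data.frame(r = pk[, 1], c = pk[, 2],
                    y = as.numeric(pk[, 1]), x = as.numeric(pk[, 2]),
                    A = pmax(res[pk], 1), ang = 0)
  if (params$refine == "fit") {
    est <- refine_spots_fit(res, est, params, valid)
    if (params$clean_pass) {
      ## subtract the fitted spots, look for what is left
      rv <- outer(seq_len(nrow(res)), rep(1, ncol(res)))
      cv <- outer(rep(1, nrow(res)), seq_len(ncol(res)))
      res2 <- res
      for (i in seq_len(nrow(est)))
        res2 <- res2 - spot_model(rv, cv, est$y[i], est$x[i], est$A[i],
                                  est$ang[i], params$spot_sigma)
      ## a re-detection rides on subtraction residue, so ask for more
      ## evidence than a primary peak
      fp2 <- find_peaks(res2, n_sigma = 1.5 * params$n_sigma)
      pk2 <- fp2$pk
      if (nrow(pk2)) {
        ## ignore re-detections adjacent to an existing spot: closer than
        ## ~1.5 spot half-widths they are shape-mismatch residuals, not
        ## genuinely merged neighbours
        keep <- vapply(seq_len(nrow(pk2)), function(k)
          min((est$y - pk2[k, 1])^2 + (est$x - pk2[k, 2])^2) > 9, TRUE)
        if (any(keep)) {
          add <- data.frame(r = pk2[keep, 1], c = pk2[keep, 2],
                            y = as.numeric(pk2[keep, 1]),
                            x = as.numeric(pk2[keep, 2]),
                            A = pmax(res2[pk2[keep, , drop = FALSE]], 1),
                            ang = 0)
          est <- refine_spots_fit(res, rbind(est, add), params, valid)
        }
      }
    }
  } else {
    bp <- fp$bp
    for (i in seq_len(nrow(est))) {
      pr <- est$r[i]; pc <- est$c[i]
      den_r <- bp[pr - 1, pc] - 2 * bp[pr, pc] + bp[pr + 1, pc]
      den_c <- bp[pr, pc - 1] - 2 * bp[pr, pc] + bp[pr, pc + 1]
      if (den_r < 0 && den_c < 0) {
        dr <- (bp[pr - 1, pc] - bp[pr + 1, pc]) / (2 * den_r)
        dc <- (bp[pr, pc - 1] - bp[pr, pc + 1]) / (2 * den_c)
        est$y[i] <- pr + max(-0.5, min(0.5, dr))
        est$x[i] <- pc + max(-0.5, min(0.5, dc))
      }
    }
  }
  ## merge detections that converged onto the same spot: keep the
  ## brightest within a 2 px separation
  ord <- order(est$A, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        min((est$y[kept] - est$y[i])^2 + (est$x[kept] - est$x[i])^2) >= 4)
      kept <- c(kept, i)
  }
  est <- est[kept, , drop = FALSE]
  out <- data.frame(x = (est$x - 1) * pixel_size,
                    y = (est$y - 1) * pixel_size,
                    intensity = est$A)
  out <- out[order(out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

angle_between <- function(v, u) {
  ## unsigned angle in degrees between two 2-vectors
  cosv <- sum(v * u) / (sqrt(sum(v^2)) * sqrt(sum(u^2)))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Link per-frame spot detections into comet trajectories
#'
#' Frame-to-frame linking is a globally optimal one-to-one assignment
#' (Hungarian algorithm) minimising total displacement, with candidate
#' pairs restricted to a search radius that adapts to the median per-frame
#' displacement of current tracks (clamped to `search_radius`). Tracks
#' missing a detection stay open for up to `max_gap` frames and compete
#' for continuations; a gap-closing continuation must fall inside the
#' forward cone (`max_fwd_angle` off the track's recent mean direction)
#' or, for backward displacements, inside the backward cone
#' (`max_bwd_angle`) with magnitude at most `max_shrink` times the track's
#' mean growth step. Displacements below `fluct_radius` are exempt from
#' the angle tests.
#'
#' @param spots list with one data.frame (columns `x`, `y`, um) per frame
#'   of a single burst.
#' @param params a [tracking_params()].
#' @param frame_interval seconds between frames.
#' @param pixel_size um per pixel (converts the pixel-unit radii).
#' @return data.frame of detections: `track`, `frame` (1-based), `x`, `y`.
#' @export
link_tracks <- function(spots, params = tracking_params(),
                        frame_interval = 2, pixel_size = 0.211) {
  if (length(spots) < 2) stop("need detections for at least 2 frames")
  rmin <- params$search_radius[1] * pixel_size
  rmax <- params$search_radius[2] * pixel_size
  fluct <- params$fluct_radius * pixel_size
  BIG <- 1e8

  tracks <- list()   # each: frames, pos (n x 2), gap, closed
  for (f in seq_along(spots)) {
    S <- spots[[f]]
    S <- S[order(S$x, S$y), , drop = FALSE]   # canonical order
    open <- which(vapply(tracks, function(tr) !tr$closed, TRUE))
    ## age out tracks whose gap would exceed max_gap
    for (i in open) {
      gap_now <- f - 1L - tracks[[i]]$frames[length(tracks[[i]]$frames)]
      if (gap_now > params$max_gap) tracks[[i]]$closed <- TRUE
    }
    open <- which(vapply(tracks, function(tr) !tr$closed, TRUE))
    ns <- nrow(S)
    if (ns > 0 && length(open) > 0) {
      steps <- unlist(lapply(tracks[open], function(tr)
        if (nrow(tr$pos) > 1)
          sqrt(rowSums((tr$pos[-1, , drop = FALSE] -
                        tr$pos[-nrow(tr$pos), , drop = FALSE])^2)) /
            diff(tr$frames)))
      ## adapt only once the step sample is informative; early frames and
      ## sparse scenes fall back to the maximum of the search radius range
      radius <- if (length(steps) >= 20)
        min(max(3 * stats::median(steps), rmin), rmax) else rmax
      cost <- matrix(BIG, length(open), ns)
      for (ii in seq_along(open)) {
        tr <- tracks[[open[ii]]]
        last <- tr$pos[nrow(tr$pos), ]
        gap_span <- f - tr$frames[length(tr$frames)]   # >= 1
        d <- sqrt((S$x - last[1])^2 + (S$y - last[2])^2)
        ## a track with enough history carries its own motion scale; the
        ## scene-wide radius would otherwise split fast comets
        own <- if (nrow(tr$pos) > 3) {
          st <- sqrt(rowSums((tr$pos[-1, , drop = FALSE] -
                              tr$pos[-nrow(tr$pos), , drop = FALSE])^2)) /
            diff(tr$frames)
          min(max(3 * stats::median(st), rmin), rmax)
        } else radius
        ok <- d <= max(radius, own) * gap_span
        ## angle/shrinkage tests gate gap-closing continuations only;
        ## direct frame-to-frame links are restricted by the radius alone
        if (gap_span > 1 && nrow(tr$pos) > 1) {
          k <- min(3, nrow(tr$pos) - 1)
          mv <- tr$pos[nrow(tr$pos), ] - tr$pos[nrow(tr$pos) - k, ]
          stepmag <- sqrt(rowSums((tr$pos[-1, , drop = FALSE] -
                                   tr$pos[-nrow(tr$pos), , drop = FALSE])^2)) /
            diff(tr$frames)
          growth <- mean(stepmag)
          if (sum(mv^2) > 0) {
            for (jj in which(ok)) {
              disp <- c(S$x[jj], S$y[jj]) - last
              ## fluctuation exemption scales with the time the
              ## displacement accrued over
              if (sqrt(sum(disp^2)) <= fluct * gap_span) next
              afwd <- angle_between(disp, mv)
              if (afwd <= params$max_fwd_angle) next
              abwd <- angle_between(disp, -mv)
              if (abwd <= params$max_bwd_angle &&
                  sqrt(sum(disp^2)) <= params$max_shrink * growth * gap_span)
                next
              ok[jj] <- FALSE
            }
          }
        }
        cost[ii, ok] <- d[ok]
      }
      n <- max(length(open), ns)
      sq <- matrix(BIG, n, n)
      sq[seq_len(length(open)), seq_len(ns)] <- cost
      sol <- as.integer(clue::solve_LSAP(sq))
      taken <- rep(FALSE, ns)
      for (ii in seq_along(open)) {
        j <- sol[ii]
        if (j <= ns && cost[ii, j] < BIG) {
          tr <- tracks[[open[ii]]]
          tr$frames <- c(tr$frames, f)
          tr$pos <- rbind(tr$pos, c(S$x[j], S$y[j]))
          tracks[[open[ii]]] <- tr
          taken[j] <- TRUE
        }
      }
      new_j <- which(!taken)
    } else new_j <- seq_len(ns)
    for (j in new_j)
      tracks[[length(tracks) + 1L]] <-
        list(frames = f, pos = matrix(c(S$x[j], S$y[j]), 1), closed = FALSE)
  }
  if (!length(tracks))
    return(data.frame(track = integer(), frame = integer(),
                      x = numeric(), y = numeric()))
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track = i, frame = tr$frames, x = tr$pos[, 1], y = tr$pos[, 2])
  }))
}

#' Filter linked tracks and flag burst-complete ones
#'
#' Removes tracks with fewer than `min_track_length` detections and marks
#' a track complete-within-burst when it both appears after the first and
#' disappears before the last frame of the burst.
#'
#' @param tracks detection data.frame from [link_tracks()].
#' @param params a [tracking_params()].
#' @param frames_per_burst number of frames in the burst.
#' @return The filtered detection data.frame with a logical `complete`
#'   column (constant per track).
#' @export
filter_tracks <- function(tracks, params = tracking_params(),
                          frames_per_burst) {
  if (nrow(tracks) == 0) return(cbind(tracks, complete = logical()))
  n_det <- table(tracks$track)
  keep <- names(n_det)[n_det >= params$min_track_length]
  out <- tracks[tracks$track %in% as.integer(keep), , drop = FALSE]
  if (nrow(out) == 0) return(cbind(out, complete = logical()))
  rng <- do.call(rbind, lapply(split(out$frame, out$track), range))
  comp <- rng[, 1] > 1 & rng[, 2] < frames_per_burst
  out$complete <- comp[as.character(out$track)]
  rownames(out) <- NULL
  out
}

#' Per-track kinematics
#'
#' Instantaneous speed per contiguous step (a gap-spanning displacement is
#' divided by its total elapsed time and recorded as a single sample),
#' lifetime from first to last detection, and the net birth-to-death path
#' vector.
#'
#' @param tracks detection data.frame (`track`, `frame`, `x`, `y`).
#' @param frame_interval seconds between frames.
#' @return List with `steps` (one row per displacement: `track`, `frame`
#'   of the step start, `speed` um/s, `gap_span` frames) and `summary`
#'   (one row per track: detections, birth/death frame, `lifetime` s,
#'   `median_speed` um/s, net path components and length, `complete` if
#'   present in the input).
#' @export
track_kinematics <- function(tracks, frame_interval) {
  if (nrow(tracks) == 0)
    return(list(steps = data.frame(track = integer(), frame = integer(),
                                   speed = numeric(), gap_span = integer()),
                summary = data.frame()))
  sp <- split(tracks, tracks$track)
  steps <- do.call(rbind, lapply(sp, function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) return(NULL)
    df <- diff(tr$frame)
    disp <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    data.frame(track = tr$track[1], frame = tr$frame[-nrow(tr)],
               speed = disp / (df * frame_interval), gap_span = df)
  }))
  if (is.null(steps))
    steps <- data.frame(track = integer(), frame = integer(),
                        speed = numeric(), gap_span = integer())
  summary <- do.call(rbind, lapply(sp, function(tr) {
    tr <- tr[order(tr$frame), ]
    st <- steps$speed[steps$track == tr$track[1]]
    data.frame(track = tr$track[1], n_det = nrow(tr),
               birth_frame = tr$frame[1], death_frame = tr$frame[nrow(tr)],
               lifetime = (tr$frame[nrow(tr)] - tr$frame[1]) * frame_interval,
               median_speed = if (length(st)) stats::median(st) else NA_real_,
               net_dx = tr$x[nrow(tr)] - tr$x[1],
               net_dy = tr$y[nrow(tr)] - tr$y[1],
               net_len = sqrt((tr$x[nrow(tr)] - tr$x[1])^2 +
                              (tr$y[nrow(tr)] - tr$y[1])^2),
               complete = if ("complete" %in% names(tr)) tr$complete[1] else NA)
  }))
  rownames(steps) <- rownames(summary) <- NULL
  list(steps = steps, summary = summary)
}
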