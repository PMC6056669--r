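#' Configuration for the synthetic growth-cone time-lapse generator
#'
#' Builds the parameter set for [simulate_sequence()]. The generator
#' emulates a migrating growth cone seen through its cytoplasmic
#' fluorescence background, containing small anisotropic moving spots
#' (polymerizing microtubule plus-end "comets"). Every stochastic choice
#' is driven by `seed`, so a run is reproducible bit for bit.
#'
#' Defaults are calibrated to published wild-type DRG growth-cone values:
#' median comet speed 0.11 um/s, ~85% anterograde motion, a ~2 um
#' slow zone at the leading edge, and growth-cone migration of the order
#' of 0.25 um/min when a nonzero `migration_velocity` is requested.
#'
#' @param base_area cone area, um^2.
#' @param elongation ratio of the cone's long (proximal-distal) to short
#'   axis.
#' @param roughness amplitude of the low-order Fourier perturbation of the
#'   cone boundary (fraction of local radius).
#' @param migration_velocity signed whole-cone translation speed along the
#'   proximal-to-tip axis, um/min; positive = extension.
#' @param birth_rate comet nucleation rate, events per um^2 per second.
#' @param speed_median median comet speed, um/s (log-normal family).
#' @param speed_gsd geometric standard deviation of comet speed.
#' @param lifetime_mean mean comet lifetime, seconds (exponential,
#'   truncated at burst end).
#' @param anterograde_frac probability that a comet's base direction points
#'   toward the leading edge.
#' @param angular_noise per-step direction jitter SD, degrees.
#' @param damping_zone width of the near-front slow zone, um.
#' @param damping_factor speed multiplier applied inside the slow zone.
#' @param birth_exclusion_zone width (um) of a near-front band in which
#'   no comet may nucleate (0 disables); used to emulate genotypes with
#'   depleted microtubule polymerization at the leading edge.
#' @param background cytoplasmic background intensity (expected photons).
#' @param amplitude peak comet intensity above background.
#' @param sigma_along,sigma_across comet spot Gaussian widths along and
#'   across the direction of motion, um.
#' @param psf_sigma blur applied to the ideal image, um.
#' @param poisson_noise logical; apply Poisson shot noise.
#' @param read_noise additive Gaussian read noise SD (0 disables).
#' @param seed integer random seed.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(base_area = 50, elongation = 1.8, roughness = 0.06,
                       migration_velocity = 0,
                       birth_rate = 0.01, speed_median = 0.11,
                       speed_gsd = 1.4, lifetime_mean = 15,
                       anterograde_frac = 0.85, angular_noise = 15,
                       damping_zone = 2, damping_factor = 0.7,
                       birth_exclusion_zone = 0,
                       background = 40, amplitude = 120,
                       sigma_along = 0.45, sigma_across = 0.25,
                       psf_sigma = 0.2, poisson_noise = TRUE,
                       read_noise = 3, seed = 1) {
  nonneg <- c(base_area = base_area, roughness = roughness,
              birth_rate = birth_rate, speed_median = speed_median,
              lifetime_mean = lifetime_mean, angular_noise = angular_noise,
              damping_zone = damping_zone, damping_factor = damping_factor,
              birth_exclusion_zone = birth_exclusion_zone,
              background = background, amplitude = amplitude,
              sigma_along = sigma_along, sigma_across = sigma_across,
              psf_sigma = psf_sigma, read_noise = read_noise)
  if (any(!is.finite(nonneg)) || any(nonneg < 0))
    stop("rates, scales and noise levels must be finite and >= 0")
  if (base_area <= 0 || elongation <= 0 || speed_gsd < 1)
    stop("base_area and elongation must be > 0 and speed_gsd >= 1")
  if (anterograde_frac < 0 || anterograde_frac > 1)
    stop("anterograde_frac must lie in [0, 1]")
  structure(as.list(environment())[names(formals(sim_config))],
            class = "sim_config")
}

## Star-shaped cone boundary radius at polar angle theta (radians),
## measured from the cone centre; +x is the proximal-to-tip axis.
cone_radius <- function(theta, shape) {
  a <- shape$a; b <- shape$b
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  pert <- rep(1, length(theta))
  for (k in seq_along(shape$ak))
    pert <- pert + shape$ak[k] * cos((k + 1) * theta + shape$phik[k])
  r * pert
}

cone_centre <- function(shape, t_sec) {
  c(shape$cx0 + shape$v_mig * t_sec / 60, shape$cy)
}

## Analytic inside-test on micrometre coordinates (vectorised).
inside_cone <- function(x, y, shape, t_sec, with_stub = TRUE) {
  ctr <- cone_centre(shape, t_sec)
  dx <- x - ctr[1]; dy <- y - ctr[2]
  inside <- sqrt(dx^2 + dy^2) <= cone_radius(atan2(dy, dx), shape)
  if (with_stub)
    inside <- inside | (x >= 0 & x <= ctr[1] & abs(dy) <= shape$stub_w / 2)
  inside
}

#' Ground-truth binary mask for one simulated frame
#'
#' Recomputed analytically from the stored cone shape, so masks never need
#' to be kept in memory alongside the image stacks.
#'
#' @param sim a `gc_simulation` from [simulate_sequence()].
#' @param burst,frame zero-based burst and frame indices.
#' @return Logical matrix (rows = y, columns = x).
#' @export
true_mask <- function(sim, burst, frame) {
  t_sec <- frame_time(sim$schedule, burst, frame)
  px <- sim$schedule$pixel_size
  sh <- sim$shape
  xs <- (seq_len(sh$ncol) - 1) * px
  ys <- (seq_len(sh$nrow) - 1) * px
  g <- expand.grid(y = ys, x = xs)
  matrix(inside_cone(g$x, g$y, sh, t_sec), nrow = sh$nrow)
}

#' Ground-truth boundary polygon of the cone body for one frame
#'
#' @inheritParams true_mask
#' @param n number of vertices.
#' @return Closed polygon, n x 2 matrix of (x, y) in um.
#' @export
true_boundary <- function(sim, burst, frame, n = 240) {
  t_sec <- frame_time(sim$schedule, burst, frame)
  theta <- seq(-pi, pi, length.out = n)
  r <- cone_radius(theta, sim$shape)
  ctr <- cone_centre(sim$shape, t_sec)
  cbind(x = ctr[1] + r * cos(theta), y = ctr[2] + r * sin(theta))
}

#' Ground-truth front arc (leading-edge boundary) for one frame
#'
#' The true front is the boundary sub-arc facing the direction of
#' migration (within `half_angle` of the +x tip axis as seen from the
#' cone centre).
#'
#' @inheritParams true_mask
#' @param half_angle half-opening of the frontal sector, degrees.
#' @return Polyline, m x 2 matrix of (x, y) in um.
#' @export
true_front <- function(sim, burst, frame, half_angle = 70) {
  t_sec <- frame_time(sim$schedule, burst, frame)
  theta <- seq(-half_angle, half_angle, length.out = 80) * pi / 180
  r <- cone_radius(theta, sim$shape)
  ctr <- cone_centre(sim$shape, t_sec)
  cbind(x = ctr[1] + r * cos(theta), y = ctr[2] + r * sin(theta))
}

## Uniform rejection sampling of points inside the cone body at time t.
sample_in_cone <- function(n, shape, t_sec) {
  out <- matrix(NA_real_, 0, 2)
  ctr <- cone_centre(shape, t_sec)
  rmax <- max(shape$a, shape$b) * (1 + sum(abs(shape$ak)))
  while (nrow(out) < n) {
    m <- max(16, 3 * (n - nrow(out)))
    x <- runif(m, ctr[1] - rmax, ctr[1] + rmax)
    y <- runif(m, ctr[2] - rmax, ctr[2] + rmax)
    keep <- inside_cone(x, y, shape, t_sec, with_stub = FALSE)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a growth-cone time-lapse with exact ground truth
#'
#' Generates one image stack per burst plus complete ground-truth tables.
#' Comets nucleate uniformly in the cone body at rate
#' `birth_rate * area` per second, move with per-step displacement
#' `speed * frame_interval` along a direction that is anterograde (toward
#' the leading edge) with probability `anterograde_frac` and jittered by
#' `angular_noise`; inside the `damping_zone` of the front the speed is
#' multiplied by `damping_factor`. The cone mask translates rigidly at
#' `migration_velocity` along the proximal-to-tip axis. Comets leaving the
#' cone die. Rendering draws the cytoplasmic background over the mask,
#' adds anisotropic Gaussian spots elongated along the direction of
#' motion, blurs, then applies Poisson and Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param schedule an [make_schedule()].
#' @return A `gc_simulation`: list with `stacks` (one `nrow x ncol x
#'   frames` array per burst), `truth` (`comets` long table: one row per
#'   comet per frame; `comet_summary`: one row per comet;
#'   `behavior`: true extension/retraction label per burst pair),
#'   `shape`, `config`, `schedule`.
#' @export
simulate_sequence <- function(config, schedule) {
  stopifnot(inherits(config, "sim_config"), inherits(schedule, "acq_schedule"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  px <- schedule$pixel_size
  a <- sqrt(config$base_area * config$elongation / pi)
  b <- a / config$elongation
  n_harm <- 3L
  ak <- runif(n_harm, -config$roughness, config$roughness)
  phik <- runif(n_harm, 0, 2 * pi)
  total_t <- (schedule$n_bursts - 1) * schedule$burst_interval +
    (schedule$frames_per_burst - 1) * schedule$frame_interval
  drift <- config$migration_velocity * total_t / 60
  margin <- 3
  rmax <- max(a, b) * (1 + n_harm * config$roughness)
  cx0 <- margin + rmax + max(0, -drift)
  width_um <- cx0 + rmax + max(0, drift) + margin
  height_um <- 2 * rmax + 2 * margin
  shape <- list(a = a, b = b, ak = ak, phik = phik,
                stub_w = 1.5, cx0 = cx0, cy = height_um / 2,
                v_mig = config$migration_velocity,
                nrow = as.integer(ceiling(height_um / px)),
                ncol = as.integer(ceiling(width_um / px)))

  ## effective cone-body area under the perturbed boundary
  th <- seq(-pi, pi, length.out = 721)[-1]
  area_eff <- sum(cone_radius(th, shape)^2) * (2 * pi / 720) / 2

  FPB <- schedule$frames_per_burst
  FI <- schedule$frame_interval
  stacks <- vector("list", schedule$n_bursts)
  rows <- list(); summ <- list()
  next_id <- 1L

  for (bi in seq_len(schedule$n_bursts) - 1L) {
    ## --- comet bookkeeping for this burst -----------------------------
    n0 <- rpois(1, config$birth_rate * area_eff * config$lifetime_mean)
    births <- c(rep(0L, n0),
                rep(seq_len(FPB - 1L),
                    rpois(FPB - 1L, config$birth_rate * area_eff * FI)))
    nb <- length(births)
    if (nb == 0) warning("no comets nucleated in burst ", bi)
    com <- vector("list", nb)
    if (nb > 0) {
      lifes <- rexp(nb, 1 / config$lifetime_mean)
      speeds <- exp(rnorm(nb, log(config$speed_median), log(config$speed_gsd)))
      antero <- runif(nb) < config$anterograde_frac
      for (i in seq_len(nb)) {
        bf <- births[i]
        t_b <- frame_time(schedule, bi, bf)
        pos <- sample_in_cone(1, shape, t_b)
        if (config$birth_exclusion_zone > 0) {
          fr_poly <- true_front(list(schedule = schedule, shape = shape),
                                bi, bf)
          tries <- 0
          while (distance_to_curve(pos, fr_poly) <
                 config$birth_exclusion_zone && tries < 200) {
            pos <- sample_in_cone(1, shape, t_b)
            tries <- tries + 1
          }
        }
        df <- min(bf + floor(lifes[i] / FI), FPB - 1L)
        frames <- bf:df
        P <- matrix(NA_real_, length(frames), 2)
        P[1, ] <- pos
        dirs <- numeric(length(frames))          # step direction leaving frame j
        stspd <- rep(NA_real_, length(frames))   # true speed of that step
        base_ang <- if (antero[i]) 0 else pi
        front_now <- true_front(sim = list(schedule = schedule, shape = shape),
                                burst = bi, frame = bf)
        j <- 1L
        while (j < length(frames)) {
          t_now <- frame_time(schedule, bi, frames[j])
          ang <- base_ang + rnorm(1, 0, config$angular_noise * pi / 180)
          dfront <- distance_to_curve(P[j, , drop = FALSE],
                                      true_front(list(schedule = schedule,
                                                      shape = shape),
                                                 bi, frames[j]))
          s <- speeds[i] *
            if (dfront < config$damping_zone) config$damping_factor else 1
          newp <- P[j, ] + s * FI * c(cos(ang), sin(ang))
          t_next <- frame_time(schedule, bi, frames[j + 1L])
          if (!inside_cone(newp[1], newp[2], shape, t_next)) {
            frames <- frames[seq_len(j)]
            P <- P[seq_len(j), , drop = FALSE]
            dirs <- dirs[seq_len(j)]; stspd <- stspd[seq_len(j)]
            break
          }
          dirs[j] <- ang; stspd[j] <- s
          P[j + 1L, ] <- newp
          j <- j + 1L
        }
        if (length(frames) > 1) dirs[length(frames)] <- dirs[length(frames) - 1L]
        net <- P[nrow(P), ] - P[1, ]
        net_ang <- if (sum(net^2) == 0) NA_real_ else atan2(net[2], net[1]) * 180 / pi
        cls <- if (is.na(net_ang)) NA_character_
               else if (abs(net_ang) <= 45) "anterograde"
               else if (abs(net_ang) >= 135) "retrograde" else "lateral"
        com[[i]] <- list(id = next_id, burst = bi, frames = frames, P = P,
                         dirs = dirs, stspd = stspd, cls = cls, net = net)
        rows[[length(rows) + 1L]] <- data.frame(
          comet = next_id, burst = bi, frame = frames,
          time = frame_time(schedule, bi, frames),
          x = P[, 1], y = P[, 2], step_speed = stspd)
        summ[[length(summ) + 1L]] <- data.frame(
          comet = next_id, burst = bi,
          birth_frame = frames[1], death_frame = frames[length(frames)],
          n_frames = length(frames), base_speed = speeds[i],
          direction_class = cls, net_dx = net[1], net_dy = net[2])
        next_id <- next_id + 1L
      }
    }

    ## --- rendering ----------------------------------------------------
    stack <- array(0, dim = c(shape$nrow, shape$ncol, FPB))
    xs <- (seq_len(shape$ncol) - 1) * px
    ys <- (seq_len(shape$nrow) - 1) * px
    for (f in seq_len(FPB) - 1L) {
      t_sec <- frame_time(schedule, bi, f)
      g <- expand.grid(y = ys, x = xs)
      ideal <- matrix(config$background *
                        inside_cone(g$x, g$y, shape, t_sec), nrow = shape$nrow)
      for (cm in com) {
        k <- match(f, cm$frames)
        if (is.na(k)) next
        ideal <- add_spot(ideal, cm$P[k, ], cm$dirs[k], config, px)
      }
      if (config$psf_sigma > 0)
        ideal <- as.matrix(EBImage::gblur(ideal, sigma = config$psf_sigma / px))
      img <- if (config$poisson_noise)
        matrix(rpois(length(ideal), pmax(ideal, 0)), nrow = shape$nrow)
      else ideal
      if (config$read_noise > 0)
        img <- img + matrix(rnorm(length(img), 0, config$read_noise),
                            nrow = shape$nrow)
      stack[, , f + 1L] <- pmax(img, 0)
    }
    stacks[[bi + 1L]] <- stack
  }

  beh <- if (schedule$n_bursts > 1) {
    data.frame(burst_from = seq_len(schedule$n_bursts - 1L) - 1L,
               burst_to = seq_len(schedule$n_bursts - 1L),
               label = if (config$migration_velocity > 0) "extension"
                       else if (config$migration_velocity < 0) "retraction"
                       else "ambiguous")
  } else data.frame(burst_from = integer(), burst_to = integer(),
                    label = character())

  structure(list(stacks = stacks,
                 truth = list(
                   comets = if (length(rows)) do.call(rbind, rows) else
                     data.frame(comet = integer(), burst = integer(),
                                frame = integer(), time = numeric(),
                                x = numeric(), y = numeric(),
                                step_speed = numeric()),
                   comet_summary = if (length(summ)) do.call(rbind, summ) else
                     data.frame(comet = integer(), burst = integer(),
                                birth_frame = integer(), death_frame = integer(),
                                n_frames = integer(), base_speed = numeric(),
                                direction_class = character(),
                                net_dx = numeric(), net_dy = numeric()),
                   behavior = beh),
                 shape = shape, config = config, schedule = schedule),
            class = "gc_simulation")
}

## Add one anisotropic Gaussian spot (um position, radian orientation).
add_spot <- function(img, pos, ang, config, px) {
  sa <- config$sigma_along / px
  sc <- config$sigma_across / px
  r0 <- pos[2] / px + 1; c0 <- pos[1] / px + 1
  w <- ceiling(4 * max(sa, sc))
  rr <- max(1, floor(r0 - w)):min(nrow(img), ceiling(r0 + w))
  cc <- max(1, floor(c0 - w)):min(ncol(img), ceiling(c0 + w))
  if (!length(rr) || !length(cc)) return(img)
  dy <- outer(rr - r0, rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - c0)
  u <- dx * cos(ang) + dy * sin(ang)     # along motion
  v <- -dx * sin(ang) + dy * cos(ang)    # across motion
  img[rr, cc] <- img[rr, cc] +
    config$amplitude * exp(-0.5 * (u^2 / sa^2 + v^2 / sc^2))
  img
}

#' @export
print.gc_simulation <- function(x, ...) {
  cat(sprintf("gc_simulation: %d bursts, %d comets, canvas %d x %d px\n",
              x$schedule$n_bursts, nrow(x$truth$comet_summary),
              x$shape$nrow, x$shape$ncol))
  invisible(x)
}
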