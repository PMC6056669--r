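## Shared fixtures. Simulations are cached per parameter key so several
## test files can reuse them without re-rendering.

.sim_cache <- new.env(parent = emptyenv())

one_burst_schedule <- function(frames = 33)
  make_schedule(frames, 2, 600, 1, 0.211)

cached_sim <- function(key, config, schedule) {
  if (!exists(key, .sim_cache))
    assign(key, simulate_sequence(config, schedule), .sim_cache)
  get(key, .sim_cache)
}

## default-noise, default-density scene
default_sim <- function(seed = 1) {
  cached_sim(paste0("default", seed), sim_config(seed = seed),
             one_burst_schedule())
}

## noise-free sparse scene: comets optically resolvable, used for
## tracker-correctness checks
sparse_clean_sim <- function(seed = 1) {
  cached_sim(paste0("sparse", seed),
             sim_config(seed = seed, poisson_noise = FALSE, read_noise = 0,
                        base_area = 150, birth_rate = 1e-3),
             one_burst_schedule())
}

## detect every frame of a burst, using per-frame segmentation masks
detect_burst <- function(sim, burst = 1) {
  px <- sim$schedule$pixel_size
  lapply(seq_len(dim(sim$stacks[[burst]])[3]), function(f) {
    fr <- sim$stacks[[burst]][, , f]
    detect_comets(fr, px, mask = segment_growth_cone(fr, px))
  })
}

## single-track recovery bookkeeping: for each true comet with >= 3
## rendered frames, record whether one track covers it and the mean
## position error of the matched detections
recovery_table <- function(sim, tracks, match_radius_px = 2) {
  px <- sim$schedule$pixel_size
  tru <- sim$truth$comets
  summ <- sim$truth$comet_summary
  out <- NULL
  for (i in which(summ$n_frames >= 3)) {
    tc <- tru[tru$comet == summ$comet[i], ]
    ids <- c(); errs <- c()
    for (j in seq_len(nrow(tc))) {
      cand <- tracks[tracks$frame == tc$frame[j] + 1, ]
      if (!nrow(cand)) next
      d <- sqrt((cand$x - tc$x[j])^2 + (cand$y - tc$y[j])^2)
      if (min(d) < match_radius_px * px) {
        ids <- c(ids, cand$track[which.min(d)])
        errs <- c(errs, min(d))
      }
    }
    out <- rbind(out, data.frame(
      comet = summ$comet[i],
      single_track = length(unique(ids)) == 1 && length(ids) >= 3,
      mean_err_px = if (length(errs)) mean(errs) / px else NA_real_))
  }
  out
}

## one small end-to-end pipeline run, cached, for observation/pipeline tests
run_one_pipeline_fixture <- function() {
  if (!exists("pipe1", .sim_cache)) {
    schedule_args <- list(frames_per_burst = 10, frame_interval = 2,
                          burst_interval = 600, n_bursts = 2,
                          pixel_size = 0.211)
    out <- file.path(tempdir(), "conetrax-pipe1")
    res <- suppressWarnings(run_pipeline(list(
      out_dir = out, schedule = schedule_args,
      sim = list(seed = 5, migration_velocity = 0.25))))
    assign("pipe1", list(obs = res$default$obs,
                         behavior = res$default$behavior,
                         schedule_args = schedule_args, out_dir = out),
           .sim_cache)
  }
  get("pipe1", .sim_cache)
}

## brute-force point-to-polyline distance by dense sampling
brute_force_curve_distance <- function(p, curve, n = 10000) {
  seglen <- sqrt(diff(curve[, 1])^2 + diff(curve[, 2])^2)
  cs <- c(0, cumsum(seglen))
  s <- seq(0, cs[length(cs)], length.out = n)
  i <- pmin(findInterval(s, cs), length(seglen))
  t <- (s - cs[i]) / seglen[i]
  xs <- curve[i, 1] + t * (curve[i + 1, 1] - curve[i, 1])
  ys <- curve[i, 2] + t * (curve[i + 1, 2] - curve[i, 2])
  min(sqrt((xs - p[1])^2 + (ys - p[2])^2))
}

## rectangle mask fixture: nr x nc TRUE block inside a padded canvas
rect_mask <- function(nr = 10, nc = 40, pad = 6) {
  m <- matrix(FALSE, nr + 2 * pad, nc + 2 * pad)
  m[pad + seq_len(nr), pad + seq_len(nc)] <- TRUE
  m
}
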