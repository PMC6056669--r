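px <- 0.211

test_that("a single noise-free comet is detected once, within half a pixel", {
  sim <- sparse_clean_sim(2)
  tru <- sim$truth$comets
  ## frames containing exactly one true comet, away from the image border
  checked <- 0
  for (f in unique(tru$frame)) {
    tf <- tru[tru$frame == f, ]
    if (nrow(tf) != 1) next
    fr <- sim$stacks[[1]][, , f + 1]
    sp <- detect_comets(fr, px, mask = segment_growth_cone(fr, px))
    expect_equal(nrow(sp), 1)
    if (nrow(sp) == 1) {
      expect_lt(sqrt((sp$x - tf$x)^2 + (sp$y - tf$y)^2), 0.5 * px)
      checked <- checked + 1
    }
    if (checked >= 4) break
  }
  expect_gte(checked, 1)
})

test_that("a blank frame yields no detections", {
  expect_equal(nrow(detect_comets(matrix(0, 60, 60), px)), 0)
})

test_that("two comets ten pixels apart are both found and matched 1:1", {
  ## flat cytoplasmic disc with two rendered spots, no noise
  n <- 81
  mask <- outer(1:n, 1:n, function(r, c) (r - 41)^2 + (c - 41)^2 <= 35^2)
  img <- 40 * mask
  cfg <- sim_config(poisson_noise = FALSE, read_noise = 0)
  truth <- rbind(c(36, 41), c(46, 41))   # rows 10 px apart
  for (k in 1:2)
    img <- conetrax:::add_spot(img, (rev(truth[k, ]) - 1) * px, 0, cfg, px)
  img <- as.matrix(EBImage::gblur(img, 1))
  sp <- detect_comets(img, px, mask = mask)
  expect_equal(nrow(sp), 2)
  for (k in 1:2) {
    d <- sqrt((sp$x - (truth[k, 2] - 1) * px)^2 +
              (sp$y - (truth[k, 1] - 1) * px)^2)
    expect_lt(min(d), 0.5 * px)
  }
})

make_spot_list <- function(pos_list) {
  lapply(pos_list, function(p) {
    if (is.null(p)) data.frame(x = numeric(), y = numeric())
    else data.frame(x = p[, 1], y = p[, 2])
  })
}

test_that("a straight comet sampled every frame links into one gapless track", {
  pos <- lapply(0:9, function(i) cbind(1 + 0.2 * i, 2))
  tr <- link_tracks(make_spot_list(pos), tracking_params(), 2, px)
  expect_equal(length(unique(tr$track)), 1)
  expect_equal(tr$frame, 1:10)
  expect_equal(tr$x, 1 + 0.2 * (0:9))
})

test_that("a four-frame disappearance splits the trajectory", {
  ## present frames 1..5, absent 6..9 (4-frame gap > max gap 3), back 10..14
  pos <- c(lapply(0:4, function(i) cbind(1 + 0.2 * i, 2)),
           lapply(1:4, function(i) NULL),
           lapply(0:4, function(i) cbind(2.0 + 0.2 * i, 2)))
  tr <- link_tracks(make_spot_list(pos), tracking_params(), 2, px)
  tr <- filter_tracks(tr, tracking_params(), 14)
  expect_equal(length(unique(tr$track)), 2)
})

test_that("a three-frame gap is closed when the continuation is on-axis", {
  pos <- c(lapply(0:4, function(i) cbind(1 + 0.2 * i, 2)),
           lapply(1:3, function(i) NULL),
           lapply(0:2, function(i) cbind(1 + 0.2 * (8 + i), 2)))
  tr <- link_tracks(make_spot_list(pos), tracking_params(), 2, px)
  expect_equal(length(unique(tr$track)), 1)
  expect_equal(sort(tr$frame), c(1:5, 9:11))
})

test_that("an off-axis gap continuation beyond the fluctuation radius is rejected", {
  ## track moving +x at 1.04 px/frame; after a 1-frame gap the candidate
  ## sits 40 degrees off the track axis at a distance well beyond the
  ## fluctuation radius
  step <- 1.04 * px
  base <- lapply(0:4, function(i) cbind(1 + step * i, 2))
  ## well beyond the (gap-scaled) fluctuation radius
  d <- 4 * step
  ang <- 40 * pi / 180
  cand <- cbind(1 + step * 4 + d * cos(ang), 2 + d * sin(ang))
  pos40 <- c(base, list(NULL), list(cand))
  tr <- link_tracks(make_spot_list(pos40), tracking_params(), 2, px)
  expect_equal(length(unique(tr$track)), 2)
  ## the same candidate inside the forward cone is accepted
  ang2 <- 20 * pi / 180
  cand2 <- cbind(1 + step * 4 + d * cos(ang2), 2 + d * sin(ang2))
  pos20 <- c(base, list(NULL), list(cand2))
  tr2 <- link_tracks(make_spot_list(pos20), tracking_params(), 2, px)
  expect_equal(length(unique(tr2$track)), 1)
})

test_that("short tracks are removed and burst-complete tracks flagged", {
  params <- tracking_params()
  tr <- data.frame(track = c(1, 1, 2, 2, 2, 3, 3, 3),
                   frame = c(1, 2, 5, 6, 7, 31, 32, 33),
                   x = 0, y = 0)
  out <- filter_tracks(tr, params, frames_per_burst = 33)
  expect_false(1 %in% out$track)              # 2 detections < 3
  expect_true(all(out$complete[out$track == 2]))   # 5..7 inside the burst
  expect_false(any(out$complete[out$track == 3]))  # touches the last frame
  tr0 <- data.frame(track = c(4, 4, 4), frame = c(1, 2, 3), x = 0, y = 0)
  out0 <- filter_tracks(tr0, params, 33)
  expect_false(any(out0$complete))            # present at the first frame
})

test_that("kinematics arithmetic: displacement over time, gaps, net path", {
  ## 0.22 um per 2-s frame = 0.11 um/s
  tr <- data.frame(track = 1, frame = 1:5, x = 0.22 * (0:4), y = 0)
  k <- track_kinematics(tr, 2)
  expect_equal(k$steps$speed, rep(0.11, 4))
  expect_equal(k$summary$median_speed, 0.11)
  expect_equal(k$summary$lifetime, 8)
  expect_equal(k$summary$net_len, 0.88)

  ## stationary comet
  trs <- data.frame(track = 1, frame = 1:4, x = 1, y = 1)
  ks <- track_kinematics(trs, 2)
  expect_equal(unique(ks$steps$speed), 0)
  expect_equal(ks$summary$net_len, 0)

  ## a gap-spanning displacement is one sample over the elapsed time
  trg <- data.frame(track = 1, frame = c(1, 2, 5), x = c(0, 0.22, 1.54),
                    y = 0)
  kg <- track_kinematics(trg, 2)
  expect_equal(nrow(kg$steps), 2)
  expect_equal(kg$steps$speed[2], (1.54 - 0.22) / 6)
  expect_equal(kg$steps$gap_span[2], 3)
})

test_that("linking is invariant to spot ordering within a frame", {
  set.seed(5)
  pos <- lapply(0:7, function(i)
    cbind(c(1 + 0.2 * i, 4 - 0.15 * i, 2.5), c(2, 3, 1 + 0.18 * i)))
  sp1 <- make_spot_list(pos)
  sp2 <- lapply(sp1, function(d) d[sample(nrow(d)), , drop = FALSE])
  t1 <- link_tracks(sp1, tracking_params(), 2, px)
  t2 <- link_tracks(sp2, tracking_params(), 2, px)
  key <- function(d) paste(round(d$x, 9), round(d$y, 9), d$frame)
  s1 <- split(key(t1), t1$track)
  s2 <- split(key(t2), t2$track)
  norm <- function(s) sort(vapply(s, function(v) paste(sort(v), collapse = "|"), ""))
  expect_identical(norm(s1), norm(s2))
})

test_that("no emitted track violates the length or gap constraints", {
  for (s in 1:2) {
    sim <- default_sim(s)
    tr <- filter_tracks(link_tracks(detect_burst(sim), tracking_params(),
                                    2, px),
                        tracking_params(), 33)
    for (t in unique(tr$track)) {
      fr <- sort(tr$frame[tr$track == t])
      expect_gte(length(fr), 3)
      expect_lte(max(diff(fr)), 4)   # gap of at most 3 missing frames
    }
  }
})

test_that("noise-free comets are recovered as single accurate tracks", {
  rec <- NULL
  for (s in 1:6) {
    sim <- sparse_clean_sim(s)
    tr <- filter_tracks(link_tracks(detect_burst(sim), tracking_params(),
                                    2, px),
                        tracking_params(), 33)
    rec <- rbind(rec, recovery_table(sim, tr))
  }
  expect_gt(nrow(rec), 25)
  expect_gte(mean(rec$single_track), 0.95)
  good <- rec$mean_err_px[rec$single_track]
  expect_gte(mean(good < 0.5, na.rm = TRUE), 0.9)
})

test_that("median speed is recovered without material bias at default noise", {
  ## photon-limited localisation inflates sub-pixel steps; at 0.05 um/s a
  ## 2-s step is 0.36 px against a ~0.1 px localisation floor, so only a
  ## loose bound is attainable there (see the methods vignette)
  sched <- one_burst_schedule()
  for (med in c(0.11, 0.20)) {
    true_sp <- c(); meas_sp <- c()
    for (s in 1:2) {
      sim <- cached_sim(paste0("spd", med, s),
                        sim_config(seed = s, speed_median = med), sched)
      true_sp <- c(true_sp, sim$truth$comets$step_speed)
      tr <- filter_tracks(link_tracks(detect_burst(sim), tracking_params(),
                                      2, px),
                          tracking_params(), 33)
      meas_sp <- c(meas_sp, track_kinematics(tr, 2)$steps$speed)
    }
    expect_lt(abs(median(meas_sp) / median(true_sp, na.rm = TRUE) - 1),
              0.05)
  }
  true_sp <- c(); meas_sp <- c()
  for (s in 1:2) {
    sim <- cached_sim(paste0("spd005", s),
                      sim_config(seed = s, speed_median = 0.05), sched)
    true_sp <- c(true_sp, sim$truth$comets$step_speed)
    tr <- filter_tracks(link_tracks(detect_burst(sim), tracking_params(),
                                    2, px),
                        tracking_params(), 33)
    meas_sp <- c(meas_sp, track_kinematics(tr, 2)$steps$speed)
  }
  expect_lt(abs(median(meas_sp) / median(true_sp, na.rm = TRUE) - 1), 0.30)
})

test_that("tracking parameter validation catches bad settings", {
  expect_error(tracking_params(search_radius = c(6, 1.5)))
  expect_error(tracking_params(min_track_length = 0))
  expect_error(tracking_params(max_fwd_angle = 0))
  expect_error(detect_comets(1:5, px), "matrix")
})
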