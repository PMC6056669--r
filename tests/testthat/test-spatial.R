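px <- 0.211

test_that("point-to-polyline distance matches elementary cases", {
  seg <- rbind(c(-10, 0), c(10, 0))
  expect_equal(distance_to_curve(c(0, 5), seg), 5)
  expect_equal(distance_to_curve(c(3, 0), seg), 0)      # on the curve
  expect_equal(distance_to_curve(c(12, 0), seg), 2)     # beyond an endpoint
  ## single-vertex curve degenerates to point distance
  expect_equal(distance_to_curve(c(3, 4), rbind(c(0, 0))), 5)
})

test_that("distance to curve agrees with a dense brute-force oracle", {
  set.seed(31)
  worst <- 0
  for (rep in 1:1000) {
    nv <- sample(2:8, 1)
    curve <- cbind(cumsum(runif(nv, -2, 3)), cumsum(runif(nv, -2, 2)))
    p <- runif(2, -5, 10)
    worst <- max(worst, abs(distance_to_curve(p, curve) -
                              brute_force_curve_distance(p, curve)))
  }
  expect_lt(worst, 1e-3)
})

test_that("landmark distances: tip on the front, completeness rule, skips", {
  sim <- default_sim(1)
  g <- gc_geometry(segment_growth_cone(sim$stacks[[1]][, , 1], px), px)
  geoms <- rep(list(g), 6)
  tracks <- data.frame(
    track = c(1, 1, 1, 2, 2, 2),
    frame = c(2, 3, 4, 1, 2, 3),
    x = c(g$tip[1], g$tip[1], g$tip[1], 1, 1.2, 1.4),
    y = c(g$tip[2], g$tip[2], g$tip[2], 1, 1.0, 1.0),
    complete = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  res <- comet_landmark_distances(tracks, geoms)
  ## a comet sitting on the tip point has zero distance to the front
  expect_equal(max(res$records$dist_front[res$records$track == 1]), 0,
               tolerance = 1e-9)
  ## birth/death endpoint distances only for complete tracks
  expect_equal(res$endpoints$track, 1)
  ## missing geometry drops the record with a warning
  tracks2 <- rbind(tracks, data.frame(track = 3, frame = 9, x = 1, y = 1,
                                      complete = TRUE))
  expect_warning(res2 <- comet_landmark_distances(tracks2, geoms),
                 "no geometry")
  expect_false(9 %in% res2$records$frame)
})

test_that("a comet seeded behind the true front measures the seeded distance", {
  sim <- cached_sim("segclean", sim_config(seed = 7, poisson_noise = FALSE,
                                           read_noise = 0,
                                           birth_rate = 0.002),
                    one_burst_schedule(5))
  g <- gc_geometry(segment_growth_cone(sim$stacks[[1]][, , 1], px), px)
  fr_true <- true_front(sim, 0, 0)
  apex <- fr_true[which.max(fr_true[, 1]), ]
  p <- apex - c(3, 0)   # 3 um behind the frontmost point, along the axis
  expect_equal(distance_to_curve(p, g$front), 3, tolerance = 0.5)
})

test_that("net paths parallel and anti-parallel to the midline classify correctly", {
  mid <- cbind(x = seq(0, 20, by = 0.5), y = 0)
  summ <- data.frame(track = 1:4,
                     net_dx = c(1, -1, 0.1, 1), net_dy = c(0, 0, 1, 1),
                     net_len = c(1, 1, sqrt(1.01), sqrt(2)),
                     x0 = 10, y0 = 0)
  cls <- path_angle_class(summ, mid)
  ## exactly 45 degrees is anterograde (inclusive threshold)
  expect_equal(cls$direction_class,
               c("anterograde", "retrograde", "lateral", "anterograde"))
  expect_equal(cls$angle[1], 0, tolerance = 1e-9)
  expect_equal(abs(cls$angle[2]), 180, tolerance = 1e-9)
  ## zero net path dropped with a warning
  expect_warning(cls0 <- path_angle_class(
    data.frame(track = 9, net_dx = 0, net_dy = 0, net_len = 0,
               x0 = 1, y0 = 0), mid), "zero-net-path")
  expect_equal(nrow(cls0), 0)
})

test_that("direction classes partition all nonzero paths exhaustively", {
  mid <- cbind(x = seq(0, 20, by = 0.5), y = 0)
  set.seed(8)
  ang <- runif(400, -180, 180)
  summ <- data.frame(track = seq_along(ang),
                     net_dx = cos(ang * pi / 180),
                     net_dy = sin(ang * pi / 180),
                     net_len = 1, x0 = 10, y0 = 0)
  cls <- path_angle_class(summ, mid)
  expect_equal(nrow(cls), 400)
  expect_true(all(cls$direction_class %in%
                    c("anterograde", "retrograde", "lateral")))
  ## classes agree with the drawn angle
  expect_equal(cls$direction_class,
               ifelse(abs(ang) <= 45, "anterograde",
                      ifelse(abs(ang) >= 135, "retrograde", "lateral")))
})

test_that("a configured 85% anterograde cohort is recovered within binomial bounds", {
  cls <- c()
  for (s in 1:4) {
    sim <- cached_sim(paste0("dirclean", s),
                      sim_config(seed = s, poisson_noise = FALSE,
                                 read_noise = 0, base_area = 150,
                                 birth_rate = 1e-3, angular_noise = 5),
                      one_burst_schedule())
    res <- analyze_burst(sim$stacks[[1]], one_burst_schedule())
    cls <- c(cls, res$angles$direction_class)
  }
  n <- length(cls)
  half <- 1.96 * sqrt(0.85 * 0.15 / n)
  expect_gt(mean(cls == "anterograde"), 0.85 - half)
  expect_lt(mean(cls == "anterograde"), 0.85 + half)
})

test_that("near-front comets are slower by roughly the damping factor", {
  prof_all <- NULL
  for (s in 1:3) {
    sim <- default_sim(s)
    tr <- filter_tracks(link_tracks(detect_burst(sim), tracking_params(),
                                    2, px),
                        tracking_params(), 33)
    kin <- track_kinematics(tr, 2)
    geoms <- lapply(1:33, function(f)
      gc_geometry(segment_growth_cone(sim$stacks[[1]][, , f], px), px))
    rec <- comet_landmark_distances(tr, geoms)$records
    m <- merge(kin$steps, rec[, c("track", "frame", "dist_front")],
               by = c("track", "frame"))
    prof_all <- rbind(prof_all, m)
  }
  prof <- front_zone_speed_profile(
    prof_all[, c("track", "frame", "dist_front")],
    prof_all[, c("track", "frame", "speed")])
  expect_true(all(prof$n > 0))
  expect_true(all(prof$ci_lo <= prof$median & prof$median <= prof$ci_hi))
  near <- prof$median[prof$bin_lo < 2]
  far <- prof$median[prof$bin_lo >= 2 & prof$bin_lo < 4]
  expect_lt(max(near), min(far))   # slow zone below 2 um
  ratio <- median(prof_all$speed[prof_all$dist_front < 2]) /
    median(prof_all$speed[prof_all$dist_front >= 2])
  expect_equal(ratio, 0.7, tolerance = 0.15)
})

test_that("interior comet front-distances never exceed the cone length", {
  sim <- default_sim(1)
  g <- gc_geometry(segment_growth_cone(sim$stacks[[1]][, , 1], px), px)
  tru <- sim$truth$comets
  tf <- tru[tru$frame == 0, ]
  if (nrow(tf)) {
    d <- distance_to_curve(cbind(tf$x, tf$y), g$front)
    expect_true(all(d <= g$length + 1))
  }
})
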