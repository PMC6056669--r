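test_that("area and perimeter are recovered on a noise-free synthetic cone", {
  sched <- one_burst_schedule(5)
  sim <- cached_sim("segclean",
                    sim_config(seed = 7, poisson_noise = FALSE,
                               read_noise = 0, birth_rate = 0.002),
                    sched)
  px <- 0.211
  m <- segment_growth_cone(sim$stacks[[1]][, , 1], px)
  tm <- true_mask(sim, 0, 0)
  expect_lt(abs(sum(m) / sum(tm) - 1), 0.05)
  f_seg <- morphology_features(m, px)
  f_true <- morphology_features(tm, px)
  expect_lt(abs(f_seg$perimeter / f_true$perimeter - 1), 0.10)
})

test_that("segmentation of blank or flat input reports no growth cone", {
  expect_error(segment_growth_cone(matrix(0, 50, 50), 0.211),
               "no growth cone found")
  expect_error(segment_growth_cone(matrix(7, 50, 50), 0.211),
               "no growth cone found")
})

test_that("the morphology chain with zero-width elements is the identity on hole-free masks", {
  m <- rect_mask()
  expect_identical(conetrax:::refine_mask(m, 0, 0), m)
})

test_that("segmented and true masks agree at default noise (two-channel check)", {
  sim <- default_sim(1)
  px <- 0.211
  jac <- sapply(c(1, 17, 33), function(f) {
    m <- segment_growth_cone(sim$stacks[[1]][, , f], px)
    tm <- true_mask(sim, 0, f - 1)
    sum(m & tm) / sum(m | tm)
  })
  expect_true(all(jac >= 0.85))
})

test_that("region properties match closed forms on elementary shapes", {
  ## filled circle: eccentricity ~ 0, length ~ width
  n <- 41
  circ <- outer(1:n, 1:n, function(r, c) (r - 21)^2 + (c - 21)^2 <= 10^2)
  fc <- morphology_features(circ, 1)
  expect_lt(fc$eccentricity, 0.1)
  expect_equal(fc$length, fc$width, tolerance = 0.05)
  expect_equal(fc$area, sum(circ))

  ## axis-aligned 40 x 10 rectangle: equivalent-ellipse axes from the
  ## exact uniform-rectangle second moments (var = L^2/12)
  rm <- rect_mask(10, 40)
  fr <- morphology_features(rm, 1)
  expect_gt(fr$length, fr$width)
  expect_equal(fr$length, 4 * sqrt(40^2 / 12), tolerance = 0.02)
  expect_equal(fr$width, 4 * sqrt(10^2 / 12), tolerance = 0.02)
  expect_equal(fr$eccentricity, sqrt(1 - (10 / 40)^2), tolerance = 0.01)

  ## digitized ellipse a = 8, b = 4 um: e = sqrt(1 - (b/a)^2) = 0.866
  px <- 0.25
  nx <- 100
  ell <- outer(1:nx, 1:nx, function(r, c)
    ((c - 50) * px / 8)^2 + ((r - 50) * px / 4)^2 <= 1)
  fe <- morphology_features(ell, px)
  expect_equal(fe$eccentricity, sqrt(1 - (4 / 8)^2), tolerance = 0.01)

  expect_error(morphology_features(matrix(FALSE, 5, 5), 1), "empty mask")
})

test_that("rectangle midline follows the medial axis within half a pixel", {
  m <- rect_mask(10, 40, pad = 6)
  mid <- compute_midline(m, 1, entry_edge = "left")
  ## true medial axis: horizontal line at the vertical centre
  centre_y <- 6 + (1 + 10) / 2 - 1   # pixel-centre coordinates, 0-based
  L <- nrow(mid)
  core <- mid[ceiling(0.1 * L):floor(0.9 * L), , drop = FALSE]
  expect_true(all(abs(core[, 2] - centre_y) <= 0.5))
  ## ordered proximal (left) to tip (right)
  expect_lt(mid[1, 1], mid[L, 1])
})

test_that("the midline of a disk collapses toward its centre", {
  n <- 61
  disk <- outer(1:n, 1:n, function(r, c) (r - 31)^2 + (c - 31)^2 <= 20^2)
  mid <- compute_midline(disk, 1)
  arclen <- sum(sqrt(diff(mid[, 1])^2 + diff(mid[, 2])^2))
  expect_lt(arclen, 0.5 * 40)   # much shorter than the diameter
})

test_that("midline vertices sit on the ridge of the distance transform", {
  sim <- cached_sim("segclean", sim_config(seed = 7, poisson_noise = FALSE,
                                           read_noise = 0,
                                           birth_rate = 0.002),
                    one_burst_schedule(5))
  px <- 0.211
  m <- segment_growth_cone(sim$stacks[[1]][, , 1], px)
  ## unsmoothed midline: vertices are exact skeleton pixels
  mid <- compute_midline(m, px, smooth = 1)
  dt <- as.matrix(EBImage::distmap(matrix(as.numeric(m), nrow(m))))
  ok <- 0; tot <- 0
  for (i in 2:(nrow(mid) - 1)) {
    r <- round(mid[i, 2] / px) + 1
    c <- round(mid[i, 1] / px) + 1
    if (r < 2 || c < 2 || r > nrow(dt) - 1 || c > ncol(dt) - 1) next
    tg <- mid[i + 1, ] - mid[i - 1, ]
    nrm <- c(-tg[2], tg[1]) / sqrt(sum(tg^2))
    off <- round(nrm)
    if (all(off == 0)) next
    tot <- tot + 1
    if (dt[r, c] >= dt[r + off[2], c + off[1]] - 1e-9 &&
        dt[r, c] >= dt[r - off[2], c - off[1]] - 1e-9) ok <- ok + 1
  }
  expect_gt(tot, 10)
  expect_gte(ok / tot, 0.9)
})

test_that("mask too small to skeletonize raises an error", {
  m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE
  expect_error(compute_midline(m, 1), "too small")
})

test_that("front division point sits at the 1:1.7 split measured from the tip", {
  ## straight synthetic midline of arc length 27: division at 10 from tip
  mid <- cbind(x = seq(0, 27, by = 0.5), y = 0)
  boundary <- cbind(x = c(-1, 28, 28, -1), y = c(-3, -3, 3, 3))
  fr <- compute_front(mid, boundary)
  expect_equal(unname(27 - fr$division["x"]), 27 / 2.7, tolerance = 1e-6)
})

test_that("rectangle front arc covers the distal side and ~37% of the long sides", {
  ## rectangle boundary 40 x 10, dense vertices; horizontal midline
  xs <- seq(0, 40, by = 0.25); ys <- seq(0, 10, by = 0.25)
  boundary <- rbind(cbind(xs, 0), cbind(40, ys[-1]),
                    cbind(rev(xs)[-1], 10), cbind(0, rev(ys)[-c(1, length(ys))]))
  colnames(boundary) <- c("x", "y")
  mid <- cbind(x = seq(0, 40, by = 0.5), y = 5)
  fr <- compute_front(mid, boundary)
  ## division at 40/2.7 from the tip: long sides belong to the front for
  ## x > 40 - 14.81; the short distal side is included entirely
  xmin_front <- min(fr$front[, 1])
  expect_equal(xmin_front, 40 - 40 / 2.7, tolerance = 0.5)
  expect_true(any(fr$front[, 1] == 40))       # distal side present
  expect_equal(unname(fr$tip["x"]), 40, tolerance = 1e-6)
  ## front is a strict, non-empty subset of the boundary
  expect_gt(nrow(fr$front), 1)
  expect_lt(nrow(fr$front), nrow(boundary))
})

test_that("a zero division fraction collapses the front to the tip neighbourhood", {
  xs <- seq(0, 40, by = 0.25); ys <- seq(0, 10, by = 0.25)
  boundary <- rbind(cbind(xs, 0), cbind(40, ys[-1]),
                    cbind(rev(xs)[-1], 10), cbind(0, rev(ys)[-c(1, length(ys))]))
  colnames(boundary) <- c("x", "y")
  mid <- cbind(x = seq(0, 40, by = 0.5), y = 5)
  fr0 <- compute_front(mid, boundary, fraction = 0)
  fr <- compute_front(mid, boundary)
  expect_lt(nrow(fr0$front), nrow(fr$front))
  expect_true(all(fr0$front[, 1] >= 40 - 1e-6))
  expect_error(compute_front(mid[1:2, ], boundary), "shorter than 3")
})

test_that("gc_geometry composes all landmarks consistently", {
  sim <- default_sim(1)
  px <- 0.211
  g <- gc_geometry(segment_growth_cone(sim$stacks[[1]][, , 1], px), px)
  ## front arc length positive and below the full boundary length
  arclen <- function(p) sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
  expect_gt(arclen(g$front), 0)
  expect_lt(arclen(g$front), arclen(rbind(g$boundary, g$boundary[1, ])))
  expect_true(g$eccentricity >= 0 && g$eccentricity < 1)
  ## midline endpoints inside the mask
  for (i in c(1, nrow(g$midline))) {
    r <- round(g$midline[i, 2] / px) + 1
    c <- round(g$midline[i, 1] / px) + 1
    expect_true(g$mask[r, c])
  }
})
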