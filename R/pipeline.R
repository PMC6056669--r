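#' Analyze one burst stack: segmentation, tracking, spatial mapping
#'
#' Runs the per-frame stages on a single burst: growth-cone segmentation
#' and landmark geometry for every frame, comet detection, gap-closing
#' linking, track filtering, kinematics, landmark distances, and net-path
#' direction classification.
#'
#' @param stack rows x cols x frames array of one burst.
#' @param schedule an [make_schedule()].
#' @param seg a [seg_params()].
#' @param det a [detect_params()].
#' @param trk a [tracking_params()].
#' @param entry_edge neurite entry edge for midline orientation.
#' @param segment_frames which frames to segment: `"all"` or `"first"`
#'   (first-frame geometry reused for all frames, faster when the cone
#'   barely moves within a burst).
#' @return list: `geometries` (per frame), `tracks` (filtered
#'   detections), `kinematics`, `spatial` (records + endpoints),
#'   `angles`.
#' @export
analyze_burst <- function(stack, schedule, seg = seg_params(),
                          det = detect_params(), trk = tracking_params(),
                          entry_edge = "left", segment_frames = "all") {
  px <- schedule$pixel_size
  nf <- dim(stack)[3]
  frames_to_do <- if (segment_frames == "first") 1L else seq_len(nf)
  geoms <- vector("list", nf)
  for (f in frames_to_do) {
    mask <- segment_growth_cone(stack[, , f], px, seg)
    geoms[[f]] <- gc_geometry(mask, px, entry_edge)
  }
  if (segment_frames == "first")
    for (f in 2:nf) geoms[[f]] <- geoms[[1]]
  spots <- lapply(seq_len(nf), function(f)
    detect_comets(stack[, , f], px, det, mask = geoms[[f]]$mask))
  tracks <- link_tracks(spots, trk, schedule$frame_interval, px)
  tracks <- filter_tracks(tracks, trk, nf)
  kin <- track_kinematics(tracks, schedule$frame_interval)
  spat <- comet_landmark_distances(tracks, geoms)
  angles <- if (nrow(kin$summary)) {
    birth <- do.call(rbind, lapply(split(tracks, tracks$track), function(tr) {
      tr <- tr[order(tr$frame), ]
      data.frame(track = tr$track[1], x0 = tr$x[1], y0 = tr$y[1])
    }))
    path_angle_class(merge(kin$summary, birth, by = "track"),
                     geoms[[1]]$midline)
  } else data.frame(track = integer(), angle = numeric(),
                    direction_class = character())
  list(geometries = geoms, tracks = tracks, kinematics = kin,
       spatial = spat, angles = angles)
}

run_one_group <- function(sim_args, schedule, cfg, gc_id, log) {
  sim <- do.call(sim_config, sim_args)
  sim <- simulate_sequence(sim, schedule)
  geometry_rows <- list(); comet_rows <- list(); track_rows <- list()
  burst_geoms <- vector("list", schedule$n_bursts)
  for (b in seq_len(schedule$n_bursts)) {
    log(sprintf("  burst %d/%d", b, schedule$n_bursts))
    res <- tryCatch(
      analyze_burst(sim$stacks[[b]], schedule,
                    do.call(seg_params, cfg[["seg"]] %||% list()),
                    do.call(detect_params, cfg[["detect"]] %||% list()),
                    do.call(tracking_params, cfg[["track"]] %||% list()),
                    entry_edge = cfg[["entry_edge"]] %||% "left",
                    segment_frames = cfg[["segment_frames"]] %||% "all"),
      error = function(e) stop("stage analyze_burst failed for burst ",
                               b - 1L, ": ", conditionMessage(e),
                               call. = FALSE))
    burst_geoms[[b]] <- res$geometries[[1]]
    for (f in seq_along(res$geometries)) {
      g <- res$geometries[[f]]
      geometry_rows[[length(geometry_rows) + 1L]] <- data.frame(
        gc_id = gc_id, burst = b - 1L, frame = f - 1L,
        area = g$area, perimeter = g$perimeter, length = g$length,
        width = g$width, eccentricity = g$eccentricity,
        centroid_x = g$centroid[1], centroid_y = g$centroid[2])
    }
    tr <- res$tracks
    if (nrow(tr)) {
      tr$gc_id <- gc_id; tr$burst <- b - 1L
      track_rows[[length(track_rows) + 1L]] <- tr
      st <- res$kinematics$steps
      rec <- res$spatial$records
      d <- merge(rec, st[, c("track", "frame", "speed")],
                 by = c("track", "frame"), all.x = TRUE)
      d <- merge(d, res$angles, by = "track", all.x = TRUE)
      d <- merge(d, res$kinematics$summary[, c("track", "lifetime")],
                 by = "track")
      comet_rows[[length(comet_rows) + 1L]] <- data.frame(
        gc_id = gc_id, burst = b - 1L, frame = d$frame - 1L,
        track = d$track, speed = d$speed, dist_front = d$dist_front,
        dist_midline = d$dist_midline, angle = d$angle,
        direction_class = d$direction_class, lifetime = d$lifetime)
    }
  }
  behavior <- if (schedule$n_bursts > 1) {
    do.call(rbind, lapply(seq_len(schedule$n_bursts - 1L), function(b) {
      sc <- score_behavior(burst_geoms[[b]], burst_geoms[[b + 1L]],
                           dead_zone = cfg[["dead_zone"]] %||% 1, id = gc_id)
      data.frame(gc_id = gc_id, burst_from = b - 1L, burst_to = b,
                 label = sc$label, tip_displacement = sc$tip_displacement)
    }))
  } else data.frame(gc_id = integer(), burst_from = integer(),
                    burst_to = integer(), label = character(),
                    tip_displacement = numeric())
  geometry_df <- do.call(rbind, geometry_rows)
  comet_df <- if (length(comet_rows)) do.call(rbind, comet_rows) else
    data.frame(gc_id = integer(), burst = integer(), frame = integer(),
               track = integer(), speed = numeric(), dist_front = numeric(),
               dist_midline = numeric(), angle = numeric(),
               direction_class = character(), lifetime = numeric())
  obs <- assemble_observations(geometry_df, comet_df, behavior, schedule)
  list(sim = sim, obs = obs, behavior = behavior,
       tracks = if (length(track_rows)) do.call(rbind, track_rows) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-to-statistics pipeline
#'
#' Executes simulate, segment, detect/track, map, score and assemble for
#' one or two groups of synthetic growth cones, writes every stage's
#' tables as CSV plus a provenance JSON and a plain-text log, and (for
#' two groups) a per-area-bin comparison table with Holm-adjusted
#' rank-sum p-values.
#'
#' @param config nested list: `out_dir` (required); `schedule` (args for
#'   [make_schedule()]); `sim` (args for [sim_config()]) or `groups`
#'   (named list of two such arg lists); optional `seg`, `detect`,
#'   `track` parameter blocks, `dead_zone`, `entry_edge`,
#'   `segment_frames`, `compare_feature` (default `"speed"`),
#'   `write_stacks` (default FALSE).
#' @return Invisibly, a list with the observation tables per group and
#'   the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  log <- function(msg) cat(format(Sys.time(), "%H:%M:%S "), msg, "\n",
                           sep = "", file = log_path, append = TRUE)
  schedule <- do.call(make_schedule, config[["schedule"]] %||%
                        list(frames_per_burst = 33, frame_interval = 2,
                             burst_interval = 600, n_bursts = 4,
                             pixel_size = 0.211))
  groups <- config[["groups"]] %||% list(default = config[["sim"]] %||% list())
  results <- list()
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    log(sprintf("group %s: simulate + analyze", gname))
    res <- run_one_group(groups[[gi]], schedule, config, gc_id = gi, log)
    res$obs$growth_cones$group <- gname
    res$obs$comets$group <- gname
    results[[gname]] <- res
    prefix <- if (length(groups) > 1) paste0(gname, "_") else ""
    write_tables(stats::setNames(
      list(res$obs$growth_cones, res$obs$comets, res$behavior),
      paste0(prefix, c("growth_cones", "comets", "behavior"))),
      config$out_dir)
    if (!is.null(res$tracks))
      write_tables(stats::setNames(list(res$tracks),
                                   paste0(prefix, "tracks")),
                   config$out_dir)
    if (isTRUE(config$write_stacks))
      write_sequence(res$sim, file.path(config$out_dir,
                                        paste0(prefix, "stacks")))
  }
  if (length(groups) == 2) {
    log("two-group comparison")
    feat <- config[["compare_feature"]] %||% "speed"
    ga <- results[[1]]$obs; gb <- results[[2]]$obs
    area_of <- function(obs) {
      k <- paste(obs$comets$gc_id, obs$comets$burst, obs$comets$frame)
      gk <- paste(obs$growth_cones$gc_id, obs$growth_cones$burst,
                  obs$growth_cones$frame)
      obs$growth_cones$area[match(k, gk)]
    }
    va <- ga$comets[[feat]]; vb <- gb$comets[[feat]]
    aa <- area_of(ga); ab <- area_of(gb)
    ok_a <- !is.na(va); ok_b <- !is.na(vb)
    cmp <- compare_groups_by_area(va[ok_a], aa[ok_a], vb[ok_b], ab[ok_b],
                                  edges = config[["compare_edges"]] %||%
                                    seq(10, 170, by = 20))
    write_tables(list(comparison = cmp), config$out_dir)
    results$comparison <- cmp
  }
  prov <- list(package = "conetrax",
               version = as.character(utils::packageVersion("conetrax")),
               config = config)
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("done")
  invisible(c(results, list(out_dir = config$out_dir)))
}
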