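#' Assemble the two-level observation hierarchy
#'
#' Joins per-frame growth-cone geometry, per-detection comet records and
#' per-interval behavior labels into the two-level observation hierarchy:
#' a growth-cone table (one row per growth cone per frame, with that
#' frame's comet aggregates) and a comet table (one row per comet per
#' frame).
#'
#' @param geometry_df one row per (gc_id, burst, frame): columns `gc_id`,
#'   `burst`, `frame`, morphology scalars (`area`, `perimeter`, `length`,
#'   `width`, `eccentricity`, `centroid_x`, `centroid_y`) and optionally
#'   `group`.
#' @param comet_df one row per comet detection: `gc_id`, `burst`,
#'   `frame`, `track`, plus any of `speed` (instantaneous, um/s),
#'   `dist_front`, `dist_midline`, `angle`, `direction_class`,
#'   `lifetime`.
#' @param behavior_df one row per burst interval: `gc_id`, `burst_from`,
#'   `burst_to`, `label`.
#' @param schedule an [make_schedule()]; supplies absolute frame times.
#' @return list of class `observation_tables` with `growth_cones` and
#'   `comets` data.frames.
#' @export
assemble_observations <- function(geometry_df, comet_df, behavior_df,
                                  schedule) {
  key <- function(d) paste(d$gc_id, d$burst, d$frame)
  gkey <- key(geometry_df)
  orphans <- setdiff(unique(key(comet_df)), gkey)
  if (length(orphans))
    stop("comet rows reference missing growth-cone frames: ",
         paste(utils::head(orphans, 5), collapse = "; "))
  time <- frame_time(schedule, geometry_df$burst, geometry_df$frame)
  agg <- function(i) {
    d <- comet_df[key(comet_df) == gkey[i], , drop = FALSE]
    sp <- if ("speed" %in% names(d)) d$speed[!is.na(d$speed)] else numeric(0)
    data.frame(
      comet_number = nrow(d),
      comet_density = nrow(d) / geometry_df$area[i],
      median_speed = if (length(sp)) stats::median(sp) else NA_real_,
      median_dist_front = if (nrow(d) && "dist_front" %in% names(d))
        stats::median(d$dist_front) else NA_real_,
      median_dist_midline = if (nrow(d) && "dist_midline" %in% names(d))
        stats::median(d$dist_midline) else NA_real_)
  }
  gc <- cbind(geometry_df, time = time,
              do.call(rbind, lapply(seq_len(nrow(geometry_df)), agg)))
  ## behavior of the interval starting at this burst
  gc$behavior <- NA_character_
  if (nrow(behavior_df)) {
    bkey <- paste(behavior_df$gc_id, behavior_df$burst_from)
    m <- match(paste(gc$gc_id, gc$burst), bkey)
    gc$behavior <- behavior_df$label[m]
  }
  comets <- comet_df
  comets$time <- frame_time(schedule, comet_df$burst, comet_df$frame)
  structure(list(growth_cones = gc, comets = comets),
            class = "observation_tables")
}

#' Per-area-bin two-group comparison table
#'
#' Rank-sum p-values per growth-cone area bin for a feature, with
#' Holm-Bonferroni adjustment across bins, plus each group's median and
#' notch CI.
#'
#' @param values_a,values_b numeric feature values for the two groups.
#' @param area_a,area_b matching growth-cone areas (um^2).
#' @param edges area bin edges.
#' @return data.frame per bin present in both groups: medians, CIs, raw
#'   and Holm-adjusted p-values.
#' @export
compare_groups_by_area <- function(values_a, area_a, values_b, area_b,
                                   edges = seq(10, 170, by = 20)) {
  bin_a <- findInterval(area_a, edges)
  bin_b <- findInterval(area_b, edges)
  shared <- intersect(unique(bin_a), unique(bin_b))
  shared <- sort(shared[shared >= 1 & shared < length(edges)])
  if (!length(shared)) stop("no area bin contains both groups")
  rows <- lapply(shared, function(bn) {
    va <- values_a[bin_a == bn]; vb <- values_b[bin_b == bn]
    ca <- median_ci(va); cb <- median_ci(vb)
    data.frame(bin_lo = edges[bn], bin_hi = edges[bn + 1],
               n_a = ca$n, median_a = ca$median,
               n_b = cb$n, median_b = cb$median,
               p_raw = rank_sum_test(va, vb))
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_bonferroni(out$p_raw)
  out
}
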