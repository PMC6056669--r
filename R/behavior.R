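#' Score growth-cone behavior between consecutive bursts
#'
#' Net behavior (extension vs. retraction) over one long interval is
#' scored from the displacement of the growth-cone tip projected onto the
#' earlier burst's proximal-to-tip axis. Displacements inside the
#' `dead_zone` are labelled ambiguous; the paper-scale convention is a
#' 10-min interval over which a migrating cone typically moves ~2.5 um.
#'
#' @param geom_a,geom_b `gc_geometry` objects of the same growth cone at
#'   bursts b and b+1.
#' @param dead_zone unsigned displacement (um) below which the interval
#'   is labelled `"ambiguous"`.
#' @param id optional growth-cone identifier carried through (both
#'   geometries may carry a `gc_id` attribute; mismatching ids error).
#' @return data.frame with `tip_displacement` (signed um),
#'   `centroid_displacement` (signed um, same projection) and `label` in
#'   extension/retraction/ambiguous.
#' @export
score_behavior <- function(geom_a, geom_b, dead_zone = 1, id = NULL) {
  stopifnot(inherits(geom_a, "gc_geometry"), inherits(geom_b, "gc_geometry"))
  ida <- attr(geom_a, "gc_id"); idb <- attr(geom_b, "gc_id")
  if (!is.null(ida) && !is.null(idb) && !identical(ida, idb))
    stop("geometries belong to different growth cones: ", ida, " vs ", idb)
  axis <- geom_a$tip - c(geom_a$midline[1, 1], geom_a$midline[1, 2])
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("degenerate proximal-to-tip axis")
  axis <- axis / nrm
  tip_d <- sum((geom_b$tip - geom_a$tip) * axis)
  cen_d <- sum((geom_b$centroid - geom_a$centroid) * axis)
  label <- if (tip_d > dead_zone) "extension"
           else if (tip_d < -dead_zone) "retraction" else "ambiguous"
  data.frame(gc_id = if (is.null(id)) NA else id,
             tip_displacement = tip_d,
             centroid_displacement = cen_d,
             label = label)
}
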