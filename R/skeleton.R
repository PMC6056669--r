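## Morphological thinning and skeleton-path utilities.
## No installed package exposes 2-D binary thinning, so the classical
## Zhang-Suen algorithm is implemented here with vectorised neighbour
## shifts; the midline is then the maximum-arc-length endpoint-to-endpoint
## path through the skeleton's pixel adjacency graph.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' @param mask logical or 0/1 matrix.
#' @return Logical matrix of the same size marking skeleton pixels.
#' @export
skeletonize_mask <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask))
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      ## neighbours clockwise from north: P2..P9
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      cond <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L
      if (phase == 1)
        cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      else
        cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

## Longest endpoint-to-endpoint geodesic path through a skeleton.
## Returns an ordered matrix of (row, col) pixel indices.
skeleton_longest_path <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 2) return(idx)
  key <- paste(idx[, 1], idx[, 2])
  lookup <- seq_len(n); names(lookup) <- key
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    nb <- paste(idx[, 1] + offs$dr[k], idx[, 2] + offs$dc[k])
    hit <- !is.na(lookup[nb])
    j <- lookup[nb[hit]]
    i <- which(hit)
    keep <- i < j               # each undirected edge once
    from <- c(from, i[keep]); to <- c(to, j[keep])
    w <- c(w, rep(sqrt(offs$dr[k]^2 + offs$dc[k]^2), sum(keep)))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  deg <- igraph::degree(g)
  ends <- which(deg == 1)
  if (length(ends) < 2) {
    ## cyclic or blob-like skeleton: two-sweep farthest-pair heuristic
    d1 <- igraph::distances(g, v = 1)
    u <- which.max(replace(d1, !is.finite(d1), -1))
    du <- igraph::distances(g, v = u)
    v <- which.max(replace(du, !is.finite(du), -1))
    ends <- c(u, v)
  }
  dmat <- igraph::distances(g, v = ends, to = ends)
  dmat[!is.finite(dmat)] <- -1
  best <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  path <- igraph::shortest_paths(g, from = ends[best[1]],
                                 to = ends[best[2]])$vpath[[1]]
  idx[as.integer(path), , drop = FALSE]
}
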