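#' Detect trunk seeds in a height-normalized cloud
#'
#' First stage of shortest-path segmentation: points in the breast-height
#' slab are density-clustered in the x-y plane; clusters that are vertically
#' continuous through the slab and whose principal axis is near vertical
#' become trunk seeds. The seed base is the axis intersection with z = 0.
#'
#' @param cloud height-normalized point-cloud data.frame.
#' @param slab numeric length-2, the height slab (m) used for detection
#'   (default brackets breast height).
#' @param eps,min_pts DBSCAN parameters for planimetric clustering (m, count).
#' @param subbin vertical sub-bin size (m) for the continuity check.
#' @param min_occupancy minimum fraction of occupied sub-bins.
#' @param max_lean maximum principal-axis angle from vertical (degrees).
#' @return data.frame of seeds: `x, y` (base), `axis_x, axis_y, axis_z`
#'   (unit stem direction), `n_points`; zero rows when nothing qualifies.
#' @export
detect_trunks <- function(cloud, slab = c(0.5, 2.0), eps = 0.2, min_pts = 20,
                          subbin = 0.25, min_occupancy = 0.8, max_lean = 15) {
  sel <- cloud$z >= slab[1] & cloud$z <= slab[2]
  empty <- data.frame(x = numeric(0), y = numeric(0), axis_x = numeric(0),
                      axis_y = numeric(0), axis_z = numeric(0), n_points = integer(0))
  if (sum(sel) < min_pts) return(empty)
  full <- as.matrix(cloud[sel, c("x", "y", "z")])
  # cluster voxel representatives, not raw points: a dense trunk shell
  # projects onto one small circle and would make every pair a neighbour
  vs <- .voxel_subsample(full, voxel = 0.05)
  pts <- as.data.frame(vs$coords)
  names(pts) <- c("x", "y", "z")
  labs <- .dbscan(cbind(pts$x, pts$y), eps = eps,
                  min_pts = max(3L, min_pts %/% 2))
  seeds <- list()
  nbins <- ceiling((slab[2] - slab[1]) / subbin)
  for (cl in setdiff(unique(labs), 0L)) {
    vsel <- which(labs == cl)
    n_full <- sum(vs$voxel_of_full %in% vsel)   # full-resolution support
    if (n_full < min_pts) next
    p <- pts[vsel, , drop = FALSE]
    occ <- length(unique(pmin(floor((p$z - slab[1]) / subbin), nbins - 1L)))
    if (occ < min_occupancy * nbins) next
    ax <- .principal_axis(as.matrix(p))
    lean <- acos(abs(ax[3])) * 180 / pi
    if (lean > max_lean) next
    ctr <- colMeans(p)
    if (abs(ax[3]) < 1e-9) next
    base <- ctr[1:2] - (ctr[3] / ax[3]) * ax[1:2]
    seeds[[length(seeds) + 1L]] <- data.frame(
      x = base[1], y = base[2], axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
      n_points = n_full)
  }
  if (!length(seeds)) return(empty)
  out <- do.call(rbind, seeds)
  out[order(out$x, out$y), , drop = FALSE]
}

#' Segment individual trees by shortest path to the trunk bases
#'
#' Second stage: non-ground points are voxel-subsampled, linked into a
#' k-nearest-neighbour graph with Euclidean edge weights, and multi-source
#' shortest paths are run from the seed bases; every point joins the seed it
#' can reach with the least path length (plants minimize transport distance
#' to the roots, which is what makes this geodesic criterion work). Full-
#' resolution points inherit the label of their representative voxel.
#' Unreachable points fall back to the nearest seed by 3D distance (flagged).
#' Ties go to the lower seed index.
#'
#' @param cloud height-normalized point-cloud data.frame (non-ground points).
#' @param seeds data.frame from [detect_trunks()] (needs `x`, `y`).
#' @param voxel subsampling voxel size (m).
#' @param k neighbours in the point graph.
#' @param trunk_radius points within this planimetric distance of their seed
#'   axis are tagged `trunk` (the rest `crown`).
#' @return list of `segmented_tree` objects: each has `tree` (id), `points`
#'   (data.frame `x, y, z, part`), `base` (x, y), and `n_unreachable`.
#' @export
segment_trees <- function(cloud, seeds, voxel = 0.05, k = 5, trunk_radius = 0.3) {
  stopifnot(nrow(seeds) >= 1)
  pts <- as.matrix(cloud[, c("x", "y", "z")])
  vs <- .voxel_subsample(pts, voxel)
  sub <- vs$coords
  ns <- nrow(sub)
  kk <- min(k, ns - 1L)
  seed_xyz <- cbind(seeds$x, seeds$y, 0)

  if (ns < 2L || kk < 1L) {
    lab_sub <- rep(1L, ns); unreach <- 0L
  } else {
    nn <- .knn_grid(sub, sub, kk + 1L, cell = 3 * voxel)
    from <- rep(seq_len(ns), kk)
    to <- as.vector(nn$idx[, -1, drop = FALSE])
    w <- as.vector(nn$dist[, -1, drop = FALSE])
    # seed vertices ns+1..ns+n_seeds, wired to their nearest voxels near the base
    n_seed <- nrow(seeds)
    snn <- .knn_grid(seed_xyz, sub, min(5L, ns))
    sfrom <- rep(ns + seq_len(n_seed), ncol(snn$idx))
    sto <- as.vector(snn$idx)
    sw <- as.vector(snn$dist)
    g <- igraph::make_empty_graph(n = ns + n_seed, directed = FALSE)
    g <- igraph::add_edges(g, rbind(c(from, sfrom), c(to, sto)),
                           weight = c(w, sw))
    dmat <- igraph::distances(g, v = ns + seq_len(n_seed), to = seq_len(ns))
    unreach_mask <- !is.finite(apply(dmat, 2, min))
    lab_sub <- apply(dmat, 2, which.min)       # ties -> lower seed index
    if (any(unreach_mask)) {
      d3 <- .knn_grid(sub[unreach_mask, , drop = FALSE], seed_xyz, 1L)$idx[, 1]
      lab_sub[unreach_mask] <- d3
      warning(sum(unreach_mask), " subsampled points unreachable in the graph; ",
              "assigned to the nearest seed by 3D distance")
    }
    unreach <- sum(unreach_mask)
  }
  lab_full <- lab_sub[vs$voxel_of_full]

  out <- vector("list", nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    p <- cloud[lab_full == s, , drop = FALSE]   # extra label columns ride along
    rr <- sqrt((p$x - seeds$x[s])^2 + (p$y - seeds$y[s])^2)
    p$part <- ifelse(rr <= trunk_radius, "trunk", "crown")
    rownames(p) <- NULL
    out[[s]] <- structure(list(tree = s, points = p,
                               base = c(x = seeds$x[s], y = seeds$y[s]),
                               n_unreachable = unreach),
                          class = "segmented_tree")
  }
  out
}

#' @export
print.segmented_tree <- function(x, ...) {
  cat(sprintf("segmented_tree #%d: %d points (%d trunk-tagged), base (%.2f, %.2f)\n",
              x$tree, nrow(x$points), sum(x$points$part == "trunk"),
              x$base[1], x$base[2]))
  invisible(x)
}
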