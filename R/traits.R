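#' Structural trait extraction from a segmented tree
#'
#' Extractors for the seven directly measured growth structural
#' characteristics of one height-normalized, segmented tree: height (H, m),
#' diameter at breast height (DBH, cm), crown width (CW, m), crown projection
#' area (CA, m^2), cut-and-fill crown volume (CV, m^3), height to living
#' crown (HLC, m) and cylinder-model trunk volume (TV, m^3).
#' [extract_traits()] composes them into one record.
#'
#' @param tree a `segmented_tree` from [segment_trees()], or any list with
#'   `points` (data.frame `x, y, z`, optionally `part`) and `base` (x, y).
#' @name traits
NULL

.tree_pts <- function(tree) {
  p <- tree$points
  stopifnot(is.data.frame(p), all(c("x", "y", "z") %in% names(p)))
  p
}

#' @rdname traits
#' @param percentile robust-maximum percentile for the treetop (the raw
#'   maximum is sensitive to isolated returns).
#' @return `tree_height()`: H in metres.
#' @export
tree_height <- function(tree, percentile = 0.9995) {
  p <- .tree_pts(tree)
  if (nrow(p) < 10L) stop("too few points (< 10) for a height estimate")
  unname(stats::quantile(p$z, percentile, names = FALSE, type = 7))
}

#' @rdname traits
#' @param window height window (m) of the breast-height slice.
#' @param eps,min_pts DBSCAN parameters for the slice clustering (m, count).
#' @return `dbh_from_slice()`: DBH in centimetres.
#' @export
dbh_from_slice <- function(tree, window = c(1.25, 1.35), eps = 0.03, min_pts = 10) {
  p <- .tree_pts(tree)
  sl <- p[p$z >= window[1] & p$z <= window[2], , drop = FALSE]
  if (nrow(sl) < min_pts) stop("occluded breast height: too few points in the slice")
  labs <- .dbscan(cbind(sl$x, sl$y), eps = eps, min_pts = min_pts)
  if (all(labs == 0L)) stop("occluded breast height: no DBSCAN cluster in the slice")
  base <- tree$base
  # cluster nearest the stem axis (planimetric distance of the cluster centre)
  cl_ids <- setdiff(unique(labs), 0L)
  dctr <- vapply(cl_ids, function(cl) {
    ctr <- colMeans(sl[labs == cl, c("x", "y")])
    sqrt((ctr[1] - base[1])^2 + (ctr[2] - base[2])^2)
  }, 0)
  keep <- cl_ids[which.min(dctr)]
  fit <- .fit_circle(as.matrix(sl[labs == keep, c("x", "y")]))
  2 * fit$r * 100
}

#' @rdname traits
#' @param dbh DBH in cm (used to carve out the trunk); estimated from the
#'   slice when `NULL`.
#' @param bin height bin (m) of the vertical occupancy profile.
#' @param min_frac a bin is "occupied" when it holds at least this fraction of
#'   the tree's points.
#' @param min_run occupied-bin run length required to accept the crown base
#'   (rejects isolated noise blobs below the true base).
#' @param floor_z bins below this height are never accepted as crown base.
#' @return `height_to_crown()`: HLC in metres.
#' @export
height_to_crown <- function(tree, dbh = NULL, bin = 0.1, min_frac = 5e-4,
                            min_run = 3L, floor_z = 0.3) {
  p <- .tree_pts(tree)
  if (is.null(dbh)) dbh <- dbh_from_slice(tree)
  r_excl <- 1.5 * (dbh / 200)
  rr <- sqrt((p$x - tree$base[1])^2 + (p$y - tree$base[2])^2)
  q <- p[rr > r_excl, , drop = FALSE]
  if (nrow(q) == 0L) stop("no crown points outside the trunk radius")
  brk <- floor(q$z / bin)
  cnt <- table(brk)
  occupied <- as.integer(names(cnt))[cnt >= min_frac * nrow(p)]
  occupied <- sort(occupied[occupied * bin >= floor_z])
  if (!length(occupied)) stop("no crown points: vertical profile empty above the floor")
  # first bin starting a run of >= min_run consecutive occupied bins
  runs <- split(occupied, cumsum(c(1L, diff(occupied) != 1L)))
  for (r in runs) if (length(r) >= min_run) return(r[1] * bin)
  stop("no crown points: no occupied run of the required length")
}

#' @rdname traits
#' @param hlc crown base height (m); crown points are those with z >= hlc.
#' @return `crown_width()`: CW in metres (mean of the E-W and N-S extents);
#'   `crown_area()`: CA in m^2 (2D convex hull of the crown projection).
#' @export
crown_width <- function(tree, hlc) {
  p <- .tree_pts(tree)
  cr <- p[p$z >= hlc, , drop = FALSE]
  if (nrow(cr) < 2L) stop("no crown points above hlc")
  mean(c(diff(range(cr$x)), diff(range(cr$y))))
}

#' @rdname traits
#' @export
crown_area <- function(tree, hlc) {
  p <- .tree_pts(tree)
  cr <- p[p$z >= hlc, , drop = FALSE]
  if (nrow(cr) < 3L) stop("fewer than 3 crown points: no projection area")
  .hull_area(cbind(cr$x, cr$y))
}

#' @rdname traits
#' @param cell raster cell size (m) for the cut-and-fill integration.
#' @return `crown_volume()`: CV in m^3, the volume between the upper and lower
#'   crown surfaces (sum over occupied cells of (max z - min z) * cell^2).
#' @export
crown_volume <- function(tree, hlc, cell = 0.25) {
  p <- .tree_pts(tree)
  cr <- p[p$z >= hlc, , drop = FALSE]
  if (nrow(cr) == 0L) stop("no crown points above hlc")
  ci <- floor((cr$x - min(cr$x)) / cell)
  cj <- floor((cr$y - min(cr$y)) / cell)
  idx <- paste(ci, cj)
  top <- tapply(cr$z, idx, max)
  bot <- tapply(cr$z, idx, min)
  sum(top - bot) * cell^2
}

#' @rdname traits
#' @param seg_len geodesic segment length (m) of the cylinder decomposition.
#' @param voxel subsampling voxel (m) for the woody connectivity graph.
#' @param k graph neighbours.
#' @param stem_only use only `part == "trunk"` points (default); with
#'   `FALSE` the whole woody graph is decomposed.
#' @param return_cylinders also return the fitted cylinder list (start, end,
#'   radius per cylinder) as the `"cylinders"` attribute, for inspection or
#'   CSV export.
#' @return `trunk_volume_qsm()`: TV in m^3, the sum of fitted cylinder
#'   volumes over geodesic segments, radii clamped non-increasing from the
#'   base (taper monotonicity).
#' @export
trunk_volume_qsm <- function(tree, seg_len = 0.5, voxel = 0.05, k = 5,
                             stem_only = TRUE, return_cylinders = FALSE) {
  p <- .tree_pts(tree)
  wood <- if (stem_only && "part" %in% names(p)) p[p$part == "trunk", , drop = FALSE] else p
  if (nrow(wood) < 10L) stop("too few woody points for a cylinder model")
  if (diff(range(wood$z)) < 1e-6) stop("zero-length tree: no vertical extent in woody points")
  pts <- as.matrix(wood[, c("x", "y", "z")])
  vs <- .voxel_subsample(pts, voxel)
  sub <- vs$coords
  ns <- nrow(sub)
  kk <- min(k, ns - 1L)
  nn <- .knn_grid(sub, sub, kk + 1L, cell = 3 * voxel)
  g <- igraph::make_empty_graph(n = ns, directed = FALSE)
  g <- igraph::add_edges(g, rbind(rep(seq_len(ns), kk), as.vector(nn$idx[, -1])),
                         weight = as.vector(nn$dist[, -1]))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("disconnected woody cloud: using the largest connected component")
    keep <- comp$membership == which.max(comp$csize)
  } else keep <- rep(TRUE, ns)
  # multi-source geodesic distance from the base points (lowest 20 cm)
  zmin <- min(sub[keep, 3])
  src <- which(keep & sub[, 3] <= zmin + 0.2)
  dvec <- suppressWarnings(apply(igraph::distances(g, v = src, to = seq_len(ns)), 2, min))
  segs <- floor(dvec / seg_len)

  total <- 0
  last_r <- Inf
  cyls <- list()
  for (s in sort(unique(segs[keep & is.finite(segs)]))) {
    vsel <- which(keep & is.finite(segs) & segs == s)
    if (length(vsel) < 3L) next
    sg <- igraph::induced_subgraph(g, vsel)
    cm <- igraph::components(sg)$membership
    seg_max_r <- 0
    for (cc in seq_len(max(cm))) {
      # cylinder from the full-resolution points mapped to these voxels
      fsel <- vs$voxel_of_full %in% vsel[cm == cc]
      q <- pts[fsel, , drop = FALSE]
      if (nrow(q) < 5L) next
      ax <- .principal_axis(q)
      ctr <- colMeans(q)
      t_par <- as.vector((q - matrix(ctr, nrow(q), 3, byrow = TRUE)) %*% ax)
      radial <- sqrt(rowSums((q - matrix(ctr, nrow(q), 3, byrow = TRUE) -
                                outer(t_par, ax))^2))
      r <- stats::median(radial)
      r <- min(r, last_r)     # taper monotonicity along the path from the base
      # geodesic smear around the stem surface stretches the axial extent of a
      # bin beyond its geodesic width; a cylinder cannot outgrow its segment
      len <- min(diff(range(t_par)), seg_len)
      total <- total + pi * r^2 * len
      if (return_cylinders) {
        p0 <- ctr + min(t_par) * ax; p1 <- ctr + max(t_par) * ax
        cyls[[length(cyls) + 1L]] <- data.frame(
          x0 = p0[1], y0 = p0[2], z0 = p0[3],
          x1 = p1[1], y1 = p1[2], z1 = p1[3], radius = r, length = len)
      }
      seg_max_r <- max(seg_max_r, r)
    }
    if (seg_max_r > 0) last_r <- seg_max_r
  }
  if (total <= 0) stop("cylinder decomposition produced no volume")
  if (return_cylinders) attr(total, "cylinders") <- do.call(rbind, cyls)
  total
}

#' @rdname traits
#' @param cv_cell cell size forwarded to [crown_volume()].
#' @return `extract_traits()`: one-row data.frame with columns
#'   `H, DBH, CW, CA, CV, TV, HLC` (units as above). Fails atomically: if any
#'   extractor fails, the error names every trait that failed.
#' @export
extract_traits <- function(tree, cv_cell = 0.25) {
  res <- list(); errs <- character(0)
  grab <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      errs[[length(errs) + 1L]] <<- paste0(name, " (", conditionMessage(e), ")")
      NA_real_
    })
    res[[name]] <<- v
  }
  grab("H", tree_height(tree))
  grab("DBH", dbh_from_slice(tree))
  hlc <- tryCatch(height_to_crown(tree, dbh = if (is.na(res$DBH)) NULL else res$DBH),
                  error = function(e) {
                    errs[[length(errs) + 1L]] <<- paste0("HLC (", conditionMessage(e), ")")
                    NA_real_
                  })
  res$HLC <- hlc
  if (!is.na(hlc)) {
    grab("CW", crown_width(tree, hlc))
    grab("CA", crown_area(tree, hlc))
    grab("CV", crown_volume(tree, hlc, cell = cv_cell))
  } else {
    errs <- c(errs, "CW (no crown base)", "CA (no crown base)", "CV (no crown base)")
    res$CW <- res$CA <- res$CV <- NA_real_
  }
  grab("TV", trunk_volume_qsm(tree))
  if (length(errs))
    stop("trait extraction failed for: ", paste(errs, collapse = "; "))
  data.frame(H = res$H, DBH = res$DBH, CW = res$CW, CA = res$CA,
             CV = res$CV, TV = res$TV, HLC = res$HLC)
}
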