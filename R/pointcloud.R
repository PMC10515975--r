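#' Point cloud IO
#'
#' Plot clouds are plain data.frames with numeric columns `x, y, z` (metres,
#' z-up) and optional label columns (`class`, `tree`). Supported on disk:
#' whitespace/comma-separated XYZ tables and ASCII PLY. Binary LAS/LAZ is a
#' non-goal (register and convert upstream).
#'
#' @param path file path; format chosen by extension (`.ply` vs anything else
#'   treated as a delimited XYZ table with a header).
#' @param cloud a point-cloud data.frame.
#' @name pointcloud_io
NULL

#' @rdname pointcloud_io
#' @export
read_cloud <- function(path) {
  if (!file.exists(path)) stop("point cloud file not found: ", path)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return(.read_ply(path))
  df <- utils::read.table(path, header = TRUE, sep = "", check.names = FALSE)
  if (ncol(df) == 1L)  # comma-separated fallback
    df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  df
}

#' @rdname pointcloud_io
#' @export
write_cloud <- function(cloud, path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return(.write_ply(cloud, path))
  utils::write.table(cloud, path, row.names = FALSE, quote = FALSE, sep = " ")
  invisible(path)
}

# minimal ASCII PLY: vertex element with float x/y/z plus extra properties
.read_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply")) stop("not a PLY file: ", path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("PLY header not terminated")
  hdr <- lines[seq_len(endh)]
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
  vline <- grep("^element vertex ", hdr, value = TRUE)
  nvert <- as.integer(sub("^element vertex ", "", vline[1]))
  props <- sub("^property \\S+ ", "", grep("^property ", hdr, value = TRUE))
  body <- lines[endh + seq_len(nvert)]
  m <- utils::read.table(text = body, col.names = props, check.names = FALSE)
  m
}

.write_ply <- function(cloud, path) {
  num <- vapply(cloud, is.numeric, logical(1))
  cols <- names(cloud)[num]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(cloud)),
               paste("property float", cols),
               "end_header"), con)
  utils::write.table(cloud[cols], con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Clip a cloud to a height range
#'
#' Simple denoising used ahead of ground filtering: drops points outside
#' `[zmin, zmax]` (absolute elevation).
#' @param cloud point-cloud data.frame.
#' @param zmin,zmax elevation bounds (m).
#' @export
clip_z <- function(cloud, zmin = -Inf, zmax = Inf) {
  cloud[cloud$z >= zmin & cloud$z <= zmax, , drop = FALSE]
}

#' Progressive densification ground filtering
#'
#' Classifies ground points by progressive densification: the lowest point in
#' each coarse grid cell seeds the ground set; remaining points are added
#' iteratively when the perpendicular distance to the local ground facet (the
#' plane through the 3 nearest accepted ground points) and the iteration
#' angle to the nearest of those points fall below thresholds.
#'
#' @param cloud point-cloud data.frame (`x, y, z`).
#' @param seed_grid coarse seeding cell size (m).
#' @param angle maximum iteration angle (degrees).
#' @param dist maximum perpendicular distance to the facet (m).
#' @param max_iter densification iteration cap.
#' @param candidate_slack only points within this height above the coarse seed
#'   surface are considered (speed; ground never sits above it by more).
#' @param clean_cell,clean_tol after each pass, accepted points more than
#'   `clean_tol` above the lowest accepted point of their `clean_cell` grid
#'   cell are demoted again; this stops near-vertical structures (trunk
#'   bases) from climbing into the ground class.
#' @return logical ground mask over the rows of `cloud`.
#' @export
filter_ground <- function(cloud, seed_grid = 5, angle = 6, dist = 0.3,
                          max_iter = 20L, candidate_slack = 1.0,
                          clean_cell = 0.5, clean_tol = 0.1) {
  n <- nrow(cloud)
  if (n == 0L) stop("empty point cloud")
  xy <- cbind(cloud$x, cloud$y)
  if (n >= 3L) {
    cc <- sweep(xy, 2, colMeans(xy), "-")
    if (min(eigen(crossprod(cc), symmetric = TRUE, only.values = TRUE)$values) < 1e-12)
      stop("degenerate scene: points are collinear in x-y, cannot filter ground")
  } else stop("need at least 3 points to filter ground")

  key <- .cell_key(xy, seed_grid)
  seed_idx <- vapply(split(seq_len(n), key), function(ii) ii[which.min(cloud$z[ii])], 1L)
  ground <- rep(FALSE, n)
  ground[seed_idx] <- TRUE

  # candidate pre-filter: height above the nearest seed's elevation
  near_seed <- .knn_grid(xy, xy[seed_idx, , drop = FALSE], 1L)$idx[, 1]
  cand <- which(!ground & (cloud$z - cloud$z[seed_idx][near_seed]) <= candidate_slack)

  tan_a <- tan(angle * pi / 180)
  for (it in seq_len(max_iter)) {
    if (!length(cand)) break
    gi <- which(ground)
    nn <- .knn_grid(xy[cand, , drop = FALSE], xy[gi, , drop = FALSE], 3L)
    p1 <- gi[nn$idx[, 1]]; p2 <- gi[nn$idx[, 2]]; p3 <- gi[nn$idx[, 3]]
    # facet normal through the 3 nearest ground points
    v1 <- cbind(cloud$x[p2] - cloud$x[p1], cloud$y[p2] - cloud$y[p1], cloud$z[p2] - cloud$z[p1])
    v2 <- cbind(cloud$x[p3] - cloud$x[p1], cloud$y[p3] - cloud$y[p1], cloud$z[p3] - cloud$z[p1])
    nx <- v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]
    ny <- v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3]
    nz <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
    nl <- sqrt(nx^2 + ny^2 + nz^2)
    degen <- nl < 1e-12
    w <- cbind(cloud$x[cand] - cloud$x[p1], cloud$y[cand] - cloud$y[p1], cloud$z[cand] - cloud$z[p1])
    dperp <- abs(w[, 1] * nx + w[, 2] * ny + w[, 3] * nz) / pmax(nl, 1e-12)
    # degenerate facet: fall back to vertical offset from the nearest ground point
    dperp[degen] <- abs(cloud$z[cand] - cloud$z[p1])[degen]
    dh <- nn$dist[, 1]
    ang_ok <- dperp <= pmax(dh, 1e-9) * tan_a | (dh < 1e-9 & dperp <= dist)
    add <- dperp <= dist & ang_ok
    if (!any(add)) break
    ground[cand[add]] <- TRUE
    cand <- cand[!add]
    # demote accepted points sitting well above the local ground minimum
    gi2 <- which(ground)
    ck <- .cell_key(xy[gi2, , drop = FALSE], clean_cell)
    zmin <- stats::ave(cloud$z[gi2], ck, FUN = min)
    bad <- cloud$z[gi2] - zmin > clean_tol
    if (any(bad)) {
      keep_seed <- gi2[bad] %in% seed_idx   # never demote the coarse seeds
      demote <- gi2[bad][!keep_seed]
      ground[demote] <- FALSE               # demoted for good (not re-candidates)
    }
  }
  ground
}

#' Raster surfaces: DEM and CHM
#'
#' `build_dem()` rasterizes ground elevations (per-cell mean) and fills empty
#' cells from their nearest filled neighbours (inverse-distance over the 3
#' nearest). `build_chm()` rasterizes the maximum normalized height per cell.
#' `query_surface()` bilinearly interpolates inside the raster extent and
#' falls back to the nearest cell outside it (with a warning).
#'
#' @param ground point-cloud data.frame of ground points.
#' @param cell_size raster cell size (m).
#' @return a `grid_surface`: list with `origin`, `cell`, `z` (matrix, rows =
#'   x cells, cols = y cells).
#' @export
build_dem <- function(ground, cell_size = 0.1) {
  stopifnot(nrow(ground) > 0, cell_size > 0)
  .rasterize(ground, cell_size, fun = "mean", fill = TRUE)
}

#' @rdname build_dem
#' @param cloud a height-normalized cloud (from [normalize_heights()]).
#' @export
build_chm <- function(cloud, cell_size = 0.1) {
  stopifnot(nrow(cloud) > 0, cell_size > 0)
  .rasterize(cloud, cell_size, fun = "max", fill = FALSE)
}

.rasterize <- function(pts, cell, fun, fill) {
  ox <- min(pts$x); oy <- min(pts$y)
  ci <- pmin(floor((pts$x - ox) / cell), floor((max(pts$x) - ox) / cell)) + 1L
  cj <- pmin(floor((pts$y - oy) / cell), floor((max(pts$y) - oy) / cell)) + 1L
  nx <- max(ci); ny <- max(cj)
  z <- matrix(NA_real_, nx, ny)
  idx <- (cj - 1L) * nx + ci
  agg <- if (fun == "mean") tapply(pts$z, idx, mean) else tapply(pts$z, idx, max)
  z[as.integer(names(agg))] <- agg
  if (fill && anyNA(z)) {
    filled <- which(!is.na(z), arr.ind = TRUE)
    empty <- which(is.na(z), arr.ind = TRUE)
    nn <- .knn_grid(empty, filled, min(3L, nrow(filled)))
    w <- 1 / pmax(nn$dist, 1e-9)
    vals <- matrix(z[!is.na(z)][nn$idx], nrow = nrow(empty))
    z[is.na(z)] <- rowSums(vals * w) / rowSums(w)
  }
  structure(list(origin = c(ox, oy), cell = cell, z = z), class = "grid_surface")
}

#' @rdname build_dem
#' @param surface a `grid_surface`.
#' @param x,y query coordinates (vectors).
#' @export
query_surface <- function(surface, x, y) {
  z <- surface$z; cell <- surface$cell
  nx <- nrow(z); ny <- ncol(z)
  # cell-center coordinates; bilinear between centers, clamped to the edge
  gx <- (x - surface$origin[1]) / cell - 0.5
  gy <- (y - surface$origin[2]) / cell - 0.5
  outside <- gx < -0.5 | gy < -0.5 | gx > nx - 0.5 | gy > ny - 0.5
  if (any(outside)) warning("query outside DEM extent: nearest-cell extrapolation used")
  i0 <- pmin(pmax(floor(gx), 0), nx - 1L); j0 <- pmin(pmax(floor(gy), 0), ny - 1L)
  i1 <- pmin(i0 + 1L, nx - 1L); j1 <- pmin(j0 + 1L, ny - 1L)
  fx <- pmin(pmax(gx - i0, 0), 1); fy <- pmin(pmax(gy - j0, 0), 1)
  v00 <- z[cbind(i0 + 1L, j0 + 1L)]; v10 <- z[cbind(i1 + 1L, j0 + 1L)]
  v01 <- z[cbind(i0 + 1L, j1 + 1L)]; v11 <- z[cbind(i1 + 1L, j1 + 1L)]
  # any NA corner (unfilled CHM cell): fall back to the nearest non-NA corner
  out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  bad <- is.na(out)
  if (any(bad)) {
    cand <- cbind(v00, v10, v01, v11)[bad, , drop = FALSE]
    out[bad] <- apply(cand, 1, function(r) if (all(is.na(r))) NA_real_ else r[which(!is.na(r))[1]])
  }
  out
}

#' Normalize point heights against a DEM
#'
#' Subtracts the interpolated ground elevation from every point's z, turning
#' elevations into heights above ground. The inverse (`denormalize = TRUE`)
#' restores elevations.
#' @param cloud point-cloud data.frame.
#' @param dem `grid_surface` from [build_dem()].
#' @param denormalize add the DEM back instead of subtracting.
#' @export
normalize_heights <- function(cloud, dem, denormalize = FALSE) {
  g <- query_surface(dem, cloud$x, cloud$y)
  cloud$z <- if (denormalize) cloud$z + g else cloud$z - g
  cloud
}
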