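# Internal geometry helpers shared by the point-cloud, segmentation and trait
# modules. All neighbour searches use a uniform-grid bucket index so nothing
# here is worse than O(n * candidates); inputs are plain numeric matrices with
# columns x, y(, z).

#' @importFrom data.table data.table setkey setorder := .N .SD
NULL

# integer cell key for 2- or 3-column coordinate matrices
.cell_key <- function(xy, cell, origin = NULL) {
  if (is.null(origin)) origin <- apply(xy, 2, min)
  idx <- sweep(xy, 2, origin, "-") %/% cell
  storage.mode(idx) <- "integer"
  # collapse to a single character key (dimension-agnostic, exact)
  do.call(paste, c(as.data.frame(idx), sep = ","))
}

# k nearest neighbours of `query` among `ref` (matrices, same ncol).
# Returns list(idx = n_query x k matrix of ref row indices, dist = matrix).
# Grid-bucket search (numeric cell keys + keyed data.table joins) with
# progressive radius doubling for sparse regions.
.knn_grid <- function(query, ref, k, cell = NULL) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  d <- ncol(ref)
  nr <- nrow(ref)
  if (nr == 0L) stop("no reference points for neighbour search")
  k <- min(k, nr)
  if (nr <= 600L || as.double(nrow(query)) * as.double(nr) <= 4e6) {
    # small problem: exact brute force
    idx <- matrix(0L, nrow(query), k); dst <- matrix(NA_real_, nrow(query), k)
    for (i in seq_len(nrow(query))) {
      dd <- sqrt(colSums((t(ref) - query[i, ])^2))
      o <- order(dd)[seq_len(k)]
      idx[i, ] <- o; dst[i, ] <- dd[o]
    }
    return(list(idx = idx, dist = dst))
  }
  rng <- apply(rbind(ref, query), 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-9)
  if (is.null(cell)) {
    # aim for a handful of points per bucket
    cell <- max((prod(span) * k / nr)^(1 / d), 1e-6)
  }
  origin <- rng[1, ]
  # numeric linear cell keys with strides wide enough for the largest ring
  dims <- floor(span / cell) + 130
  strides <- cumprod(c(1, dims[-d]))
  lin_key <- function(m) {
    ii <- floor(sweep(m, 2, origin, "-") / cell) + 64
    as.vector(ii %*% strides)
  }
  ref_dt <- data.table(ck = lin_key(ref), ridx = seq_len(nr))
  setkey(ref_dt, ck)
  qkey <- lin_key(query)

  qn <- nrow(query)
  out_idx <- matrix(0L, qn, k)
  out_dst <- matrix(Inf, qn, k)
  pending <- seq_len(qn)
  ring <- 1L
  while (length(pending) > 0L && ring <= 16L) {
    if (as.double(length(pending)) * nr <= 2e6) break  # brute force cheaper now
    offs <- as.matrix(expand.grid(rep(list(seq(-ring, ring)), d)))
    off_key <- as.vector(offs %*% strides)
    probe <- data.table(ck = rep(qkey[pending], times = length(off_key)) +
                          rep(off_key, each = length(pending)),
                        qid = rep(pending, times = length(off_key)))
    cand <- ref_dt[probe, on = "ck", nomatch = 0L, allow.cartesian = TRUE]
    if (nrow(cand)) {
      cand[, dd := sqrt(rowSums((query[cand$qid, , drop = FALSE] -
                                   ref[cand$ridx, , drop = FALSE])^2))]
      setorder(cand, qid, dd)
      cand <- cand[cand[, list(V1 = .I[seq_len(min(.N, k))]), by = "qid"]$V1]
      st <- cand[, list(n = .N, kd = max(dd)), by = "qid"]
      # done when k neighbours found, all within the guaranteed radius
      ok <- st$qid[st$n >= k & st$kd <= ring * cell]
      if (length(ok)) {
        sub <- cand[cand$qid %in% ok, ]
        pos <- sub[, seq_len(.N), by = "qid"]$V1
        out_idx[cbind(sub$qid, pos)] <- sub$ridx
        out_dst[cbind(sub$qid, pos)] <- sub$dd
        pending <- setdiff(pending, ok)
      }
    }
    ring <- ring * 2L
  }
  if (length(pending)) { # brute force for stragglers
    for (i in pending) {
      dd <- sqrt(colSums((t(ref) - query[i, ])^2))
      o <- order(dd)[seq_len(k)]
      out_idx[i, ] <- o; out_dst[i, ] <- dd[o]
    }
  }
  list(idx = out_idx, dist = out_dst)
}

# all pairs within eps (fixed radius), returned as a two-column index matrix
# (i < j). Used by DBSCAN and graph construction.
.radius_pairs <- function(pts, eps) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  d <- ncol(pts)
  origin <- apply(pts, 2, min)
  key <- .cell_key(pts, eps, origin)
  cellidx <- floor(sweep(pts, 2, origin, "-") / eps)
  storage.mode(cellidx) <- "integer"
  buckets <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(rep(list(-1:1), d)))
  from <- integer(0); to <- integer(0)
  for (j in seq_len(nrow(offs))) {
    nk <- do.call(paste, c(as.data.frame(sweep(cellidx, 2, offs[j, ], "+")), sep = ","))
    hit <- buckets[nk]
    len <- lengths(hit, use.names = FALSE)
    keep <- len > 0L
    if (!any(keep)) next
    from <- c(from, rep.int(seq_len(n)[keep], len[keep]))
    to <- c(to, unlist(hit[keep], use.names = FALSE))
  }
  sel <- from < to
  from <- from[sel]; to <- to[sel]
  if (!length(from)) return(matrix(integer(0), 0, 2))
  dd <- sqrt(rowSums((pts[from, , drop = FALSE] - pts[to, , drop = FALSE])^2))
  ok <- dd <= eps
  pr <- cbind(from[ok], to[ok])
  pr[!duplicated(pr), , drop = FALSE]
}

# DBSCAN on a coordinate matrix. Core points have >= min_pts neighbours
# (self included) within eps; clusters are connected components of the
# core-core eps graph; border points join the cluster of a core neighbour;
# the rest are noise (cluster 0).
.dbscan <- function(pts, eps, min_pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  pr <- .radius_pairs(pts, eps)
  deg <- tabulate(c(pr[, 1], pr[, 2]), nbins = n) + 1L
  core <- deg >= min_pts
  labs <- integer(n)
  if (!any(core)) return(labs)
  cc <- pr[core[pr[, 1]] & core[pr[, 2]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(matrix(as.character(cc), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(as.character(which(core)), igraph::V(g)$name)),
                            name = setdiff(as.character(which(core)), igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  labs[as.integer(names(comp))] <- as.integer(comp)
  # border points: attach to any core neighbour's cluster
  border_edges <- rbind(pr, pr[, 2:1, drop = FALSE])
  sel <- core[border_edges[, 2]] & !core[border_edges[, 1]]
  if (any(sel)) {
    be <- border_edges[sel, , drop = FALSE]
    labs[be[, 1]] <- labs[be[, 2]]   # last write wins; any core cluster is valid
  }
  # renumber clusters 1..m by decreasing size for stability
  if (any(labs > 0L)) {
    sz <- sort(table(labs[labs > 0L]), decreasing = TRUE)
    remap <- stats::setNames(seq_along(sz), names(sz))
    labs[labs > 0L] <- remap[as.character(labs[labs > 0L])]
  }
  labs
}

# voxel subsampling: one representative point (centroid) per occupied voxel.
# Returns list(coords, voxel_of_full) where voxel_of_full maps every input
# point to its representative row.
.voxel_subsample <- function(pts, voxel) {
  pts <- as.matrix(pts)
  key <- .cell_key(pts, voxel)
  f <- factor(key, levels = unique(key))
  id <- as.integer(f)
  cx <- rowsum(pts, id, reorder = TRUE) / as.vector(table(id))
  list(coords = cx, voxel_of_full = id)
}

# Circle fit: Kasa algebraic fit then Gauss-Newton geometric refinement.
# Returns list(cx, cy, r).
.fit_circle <- function(xy, iters = 20L) {
  x <- xy[, 1]; y <- xy[, 2]
  if (length(x) < 3L) stop("need >= 3 points for a circle fit")
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) stop("degenerate circle fit"))
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(max(sol[3] + cx^2 + cy^2, .Machine$double.eps))
  for (it in seq_len(iters)) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    di[di < 1e-12] <- 1e-12
    res <- di - r
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.solve(crossprod(J), crossprod(J, res)), error = function(e) NULL)
    if (is.null(step)) break
    cx <- cx - step[1]; cy <- cy - step[2]; r <- r - step[3]
    if (max(abs(step)) < 1e-12) break
  }
  list(cx = cx, cy = cy, r = abs(r))
}

# area of the 2D convex hull (shoelace over grDevices::chull)
.hull_area <- function(xy) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 3L) stop("need >= 3 non-collinear points for a hull area")
  h <- grDevices::chull(xy)
  px <- xy[h, 1]; py <- xy[h, 2]
  ar <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
  if (ar <= 0) stop("collinear points: hull area is zero")
  ar
}

# principal axis (unit vector) of a point set via the leading eigenvector
.principal_axis <- function(pts) {
  pts <- as.matrix(pts)
  cc <- sweep(pts, 2, colMeans(pts), "-")
  ev <- eigen(crossprod(cc) / max(nrow(pts) - 1, 1), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[length(v)] < 0) v <- -v
  v
}
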