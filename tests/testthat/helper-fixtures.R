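# Programmatic fixtures shared across tests. Everything is generated in code;
# no data files.

# A segmented_tree built directly from sampled surfaces, bypassing the
# segmentation pipeline: vertical tapered cylinder trunk (optionally with an
# ellipsoid crown of volumetric points), already height-normalized.
make_cylinder_tree <- function(r = 0.10, h = 8, taper = 0, base = c(0, 0),
                               crown = NULL, n_trunk = 4000, seed = 1) {
  set.seed(seed)
  z <- stats::runif(n_trunk, 0, h)
  th <- stats::runif(n_trunk, 0, 2 * pi)
  rr <- pmax(r * (1 - taper * z / h), 0)   # taper as total fractional loss over h
  pts <- data.frame(x = base[1] + rr * cos(th), y = base[2] + rr * sin(th),
                    z = z, part = "trunk")
  if (!is.null(crown)) {
    # crown: list(a, b, base, top, n)
    a <- crown$a; b <- crown$b; cb <- crown$base; ct <- crown$top
    cz <- (cb + ct) / 2; cc <- (ct - cb) / 2
    got <- 0; acc <- list()
    while (got < crown$n) {
      m <- (crown$n - got) * 3
      px <- stats::runif(m, -a, a); py <- stats::runif(m, -b, b)
      pz <- stats::runif(m, cb, ct)
      keep <- (px / a)^2 + (py / b)^2 + ((pz - cz) / cc)^2 <= 1
      acc[[length(acc) + 1L]] <- data.frame(x = base[1] + px, y = base[2] + py,
                                            z = pz, part = "crown")[keep, ]
      got <- got + sum(keep)
    }
    pts <- rbind(pts, do.call(rbind, acc)[seq_len(crown$n), ])
  }
  structure(list(tree = 1L, points = pts, base = c(x = base[1], y = base[2]),
                 n_unreachable = 0L),
            class = "segmented_tree")
}

# A small noise-free 2-tree stand with reduced densities for fast tests.
small_stand <- function(n_trees = 2, seed = 3, noise_sd = 0, relief = 0.3, ...) {
  stand_spec(n_trees = n_trees, spacing = 6, noise_sd = noise_sd,
             ground_relief_amplitude = relief,
             point_density = list(ground = 40, trunk = 1500, crown = 80),
             seed = seed, ...)
}

# run a stand through ground filtering + normalization + segmentation
segment_stand <- function(st) {
  gm <- filter_ground(st$cloud)
  dem <- build_dem(st$cloud[gm, ])
  nrm <- normalize_heights(st$cloud, dem)
  veg <- nrm[!gm & nrm$z > 0.1, , drop = FALSE]
  seeds <- detect_trunks(veg)
  list(mask = gm, dem = dem, veg = veg, seeds = seeds,
       trees = if (nrow(seeds)) segment_trees(veg, seeds) else list())
}

# brute-force diversity oracle: enumerate all ordered allele pairs
oracle_diversity <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-12)
  A <- length(p)
  he <- 0; pic_pair <- 0
  for (i in seq_len(A)) for (j in seq_len(A)) if (i != j) he <- he + p[i] * p[j]
  ne <- 1 / sum(sapply(seq_len(A), function(i) p[i]^2))
  if (A >= 2) for (i in seq_len(A - 1)) for (j in (i + 1):A)
    pic_pair <- pic_pair + 2 * p[i]^2 * p[j]^2
  list(He = he, Ne = ne, PIC = 1 - sum(p^2) - pic_pair)
}

# least-squares additive-tree oracle: enumerate unrooted 4-taxon topologies,
# fit branch lengths by non-negative least squares, return best topology id
best_quartet_topology <- function(D) {
  taxa <- rownames(D)
  tops <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  sse <- sapply(tops, function(tp) {
    # unrooted quartet ((a,b),(c,d)): 5 edges -> path matrix over 6 pairs
    a <- tp[1]; b <- tp[2]; c <- tp[3]; d <- tp[4]
    pairs <- rbind(c(a, b), c(a, c), c(a, d), c(b, c), c(b, d), c(c, d))
    X <- matrix(0, 6, 5)  # columns: ea, eb, ec, ed, internal
    for (r in seq_len(6)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      X[r, match(i, tp)] <- 1; X[r, match(j, tp)] <- 1
      same_side <- (match(i, tp) <= 2) == (match(j, tp) <= 2)
      if (!same_side) X[r, 5] <- 1
    }
    y <- apply(pairs, 1, function(pr) D[pr[1], pr[2]])
    beta <- nnls_fit(X, y)$coefficients
    sum((X %*% beta - y)^2)
  })
  which.min(sse)
}

# tiny non-negative least squares via constrained optim (used by the oracle)
nnls_fit <- function(X, y) {
  f <- function(b) sum((X %*% b - y)^2)
  res <- stats::optim(rep(0.5, ncol(X)), f, lower = rep(0, ncol(X)),
                      method = "L-BFGS-B")
  list(coefficients = res$par)
}
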