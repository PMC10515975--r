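#' Specify a synthetic plantation stand
#'
#' Builds the parameter set for [generate_stand()]: a rectangular plantation
#' plot with trees on a regular grid, each tree a linearly tapered trunk plus
#' a crown envelope (ellipsoid or cone), standing on a smooth sinusoidal
#' ground relief. Defaults reproduce a 30 m x 30 m ginkgo timber plot with
#' stand-average structure (tree height 7.757 m, DBH 13.233 cm, crown base
#' 2.094 m, crown width 4.254 m).
#'
#' Per-tree fields (`trunk_height`, `trunk_dbh`, `crown_base`, `crown_radii`)
#' are recycled to `n_trees`. `taper_rate` is the fractional decrease of trunk
#' radius per metre of height; the quoted `trunk_dbh` is the diameter at
#' exactly 1.30 m, so DBH ground truth is exact by construction.
#'
#' @param n_trees number of trees in the plot.
#' @param spacing grid spacing between trunk bases (m).
#' @param trunk_height total tree height(s) (m).
#' @param trunk_dbh diameter(s) at breast height (cm).
#' @param taper_rate fractional radius decrease per metre of height.
#' @param crown_base height(s) to the living crown (m); must be < trunk_height.
#' @param crown_radii crown semi-axes (m): E-W and N-S; a length-2 vector or an
#'   `n_trees` x 2 matrix.
#' @param crown_shape `"ellipsoid"` or `"cone"` (apex at the tree top).
#' @param ground_relief_amplitude amplitude of the sinusoidal ground relief (m).
#' @param relief_period wavelength of the relief field (m).
#' @param point_density named list: `ground` (points per m^2), `trunk` (points
#'   per m^2 of trunk surface), `crown` (points per m^3 of crown volume).
#' @param noise_sd isotropic Gaussian noise added to every coordinate (m).
#' @param seed integer seed; the whole generation is deterministic given it.
#' @return an object of class `stand_spec`.
#' @export
stand_spec <- function(n_trees = 23, spacing = 6,
                       trunk_height = 7.757, trunk_dbh = 13.233,
                       taper_rate = 0.05, crown_base = 2.094,
                       crown_radii = c(2.127, 2.127),
                       crown_shape = c("ellipsoid", "cone"),
                       ground_relief_amplitude = 0.3, relief_period = 15,
                       point_density = list(ground = 50, trunk = 2000, crown = 150),
                       noise_sd = 0.005, seed = 1L) {
  crown_shape <- match.arg(crown_shape)
  stopifnot(n_trees >= 1, spacing > 0, all(trunk_dbh > 0), all(trunk_height > 0),
            taper_rate >= 0, ground_relief_amplitude >= 0, noise_sd >= 0,
            point_density$ground > 0, point_density$trunk > 0, point_density$crown >= 0)
  trunk_height <- rep_len(trunk_height, n_trees)
  trunk_dbh <- rep_len(trunk_dbh, n_trees)
  crown_base <- rep_len(crown_base, n_trees)
  if (is.matrix(crown_radii)) {
    stopifnot(ncol(crown_radii) == 2)
    crown_radii <- crown_radii[rep_len(seq_len(nrow(crown_radii)), n_trees), , drop = FALSE]
  } else {
    stopifnot(length(crown_radii) == 2)
    crown_radii <- matrix(crown_radii, n_trees, 2, byrow = TRUE)
  }
  has_crown <- point_density$crown > 0 & crown_radii[, 1] > 0
  if (any(crown_base[has_crown] >= trunk_height[has_crown]))
    stop("crown_base must be below trunk_height")
  structure(list(
    n_trees = as.integer(n_trees), spacing = spacing,
    trunk_height = trunk_height, trunk_dbh = trunk_dbh,
    taper_rate = taper_rate, crown_base = crown_base,
    crown_radii = crown_radii, crown_shape = crown_shape,
    ground_relief_amplitude = ground_relief_amplitude,
    relief_period = relief_period, point_density = point_density,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "stand_spec")
}

# trunk radius profile: radius at breast height fixed by trunk_dbh
.trunk_radius <- function(z, r_bh, taper) pmax(r_bh * (1 - taper * (z - 1.3)), 0)

# exact trunk volume: integral of pi r(z)^2 dz over [0, h], r linear in z
.trunk_volume_true <- function(h, r_bh, taper) {
  if (taper == 0) return(pi * r_bh^2 * h)
  # r(z) = r_bh * (1 - taper (z - 1.3)); zero crossing at z0
  z0 <- 1.3 + 1 / taper
  zmax <- min(h, z0)
  f <- function(z) {
    u <- 1 - taper * (z - 1.3)
    -pi * r_bh^2 * u^3 / (3 * taper)
  }
  f(zmax) - f(0)
}

# ground relief field
.relief <- function(x, y, amp, period) {
  if (amp == 0) return(rep(0, length(x)))
  amp * sin(2 * pi * x / period) * sin(2 * pi * y / period)
}

#' Generate a synthetic stand point cloud with analytic ground truth
#'
#' Samples a plot-level point cloud from a [stand_spec()]: ground points
#' uniform over the plot on the relief surface, trunk points on the tapered
#' trunk surface, crown points uniformly *inside* the crown envelope
#' (volumetric, so cut-and-fill crown volume and crown-base detection are
#' exercised realistically). Every point carries its true class
#' (`ground`/`trunk`/`crown`) and tree id, and the returned truth table holds
#' the exact structural characteristics of every tree.
#'
#' @param spec a [stand_spec()].
#' @return list with elements `cloud` (data.frame `x,y,z,class,tree`) and
#'   `truth` (data.frame: `tree, x, y, H, DBH, HLC, CW, CA, CV, TV`; heights m,
#'   DBH cm, areas m^2, volumes m^3). With `noise_sd = 0`, `cloud` points lie
#'   exactly on (ground/trunk) or inside (crown) the generating surfaces and
#'   `truth` is exact.
#' @export
generate_stand <- function(spec) {
  stopifnot(inherits(spec, "stand_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_trees
    ncols <- ceiling(sqrt(n))
    nrows <- ceiling(n / ncols)
    ix <- (seq_len(n) - 1L) %% ncols
    iy <- (seq_len(n) - 1L) %/% ncols
    bx <- (ix + 0.5) * spec$spacing
    by <- (iy + 0.5) * spec$spacing
    side_x <- ncols * spec$spacing
    side_y <- nrows * spec$spacing

    r_bh <- spec$trunk_dbh / 200            # cm diameter -> m radius
    r_base <- .trunk_radius(0, r_bh, spec$taper_rate)
    if (n > 1) {
      dmat <- as.matrix(stats::dist(cbind(bx, by)))
      diag(dmat) <- Inf
      lim <- outer(r_base, r_base, "+")
      if (any(dmat < lim)) stop("overlapping trunks: base distance below the sum of trunk radii")
    }

    amp <- spec$ground_relief_amplitude
    per <- spec$relief_period

    # ground
    ng <- max(4L, round(spec$point_density$ground * side_x * side_y))
    gx <- stats::runif(ng, 0, side_x)
    gy <- stats::runif(ng, 0, side_y)
    gz <- .relief(gx, gy, amp, per)
    cloud <- list(data.frame(x = gx, y = gy, z = gz,
                             class = "ground", tree = NA_integer_))

    truth <- data.frame(tree = seq_len(n), x = bx, y = by,
                        H = spec$trunk_height, DBH = spec$trunk_dbh,
                        HLC = spec$crown_base, CW = NA_real_, CA = NA_real_,
                        CV = NA_real_, TV = NA_real_)

    for (i in seq_len(n)) {
      h <- spec$trunk_height[i]
      zrel <- .relief(bx[i], by[i], amp, per)
      # trunk surface
      surf <- 2 * pi * mean(.trunk_radius(seq(0, h, length.out = 200), r_bh[i], spec$taper_rate)) * h
      nt <- max(50L, round(spec$point_density$trunk * surf))
      tz <- stats::runif(nt, 0, h)
      th <- stats::runif(nt, 0, 2 * pi)
      tr <- .trunk_radius(tz, r_bh[i], spec$taper_rate)
      cloud[[length(cloud) + 1L]] <- data.frame(
        x = bx[i] + tr * cos(th), y = by[i] + tr * sin(th), z = zrel + tz,
        class = "trunk", tree = i)
      truth$TV[i] <- .trunk_volume_true(h, r_bh[i], spec$taper_rate)

      # crown
      a <- spec$crown_radii[i, 1]; b <- spec$crown_radii[i, 2]
      hc <- h - spec$crown_base[i]
      if (a > 0 && b > 0 && spec$point_density$crown > 0) {
        vol <- if (spec$crown_shape == "ellipsoid") (4 / 3) * pi * a * b * (hc / 2)
               else pi * a * b * hc / 3
        nc <- max(20L, round(spec$point_density$crown * vol))
        # rejection sampling inside the envelope
        pts <- matrix(numeric(0), 0, 3)
        while (nrow(pts) < nc) {
          m <- ceiling((nc - nrow(pts)) * 2.2)
          px <- stats::runif(m, -a, a); py <- stats::runif(m, -b, b)
          pz <- stats::runif(m, 0, hc)
          inside <- if (spec$crown_shape == "ellipsoid") {
            cz <- hc / 2
            (px / a)^2 + (py / b)^2 + ((pz - cz) / cz)^2 <= 1
          } else {
            s <- 1 - pz / hc   # radius shrinks linearly to the apex
            (px / (a * s))^2 + (py / (b * s))^2 <= 1
          }
          pts <- rbind(pts, cbind(px, py, pz)[inside, , drop = FALSE])
        }
        pts <- pts[seq_len(nc), , drop = FALSE]
        cloud[[length(cloud) + 1L]] <- data.frame(
          x = bx[i] + pts[, 1], y = by[i] + pts[, 2],
          z = zrel + spec$crown_base[i] + pts[, 3],
          class = "crown", tree = i)
        truth$CW[i] <- (2 * a + 2 * b) / 2
        truth$CA[i] <- pi * a * b
        truth$CV[i] <- vol
      }
    }
    cloud <- do.call(rbind, cloud)
    if (spec$noise_sd > 0) {
      m <- nrow(cloud)
      cloud$x <- cloud$x + stats::rnorm(m, 0, spec$noise_sd)
      cloud$y <- cloud$y + stats::rnorm(m, 0, spec$noise_sd)
      cloud$z <- cloud$z + stats::rnorm(m, 0, spec$noise_sd)
    }
    rownames(cloud) <- NULL
    list(cloud = cloud, truth = truth)
  })
}
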