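test_that("tree height is a robust maximum", {
  col <- structure(list(points = data.frame(x = 0, y = 0,
                                            z = seq(0, 5, length.out = 2000)),
                        base = c(x = 0, y = 0)), class = "segmented_tree")
  expect_equal(tree_height(col), 5, tolerance = 0.01)
  few <- structure(list(points = data.frame(x = 0, y = 0, z = 1:5),
                        base = c(x = 0, y = 0)), class = "segmented_tree")
  expect_error(tree_height(few), "too few")
  # an isolated high outlier barely moves the robust percentile
  out <- col; out$points$z[1] <- 50
  expect_lt(tree_height(out), 5.1)
})

test_that("DBH from the 1.3 m slice matches the generating radius", {
  tr <- make_cylinder_tree(r = 0.066165, h = 8, n_trunk = 6000, seed = 2)
  expect_equal(dbh_from_slice(tr), 13.233, tolerance = 0.05)
  # 12 exact points on a circle of r = 0.10 (plus slice filler to pass min_pts)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- data.frame(x = 0.10 * cos(th), y = 0.10 * sin(th), z = 1.3)
  tree <- structure(list(points = pts, base = c(x = 0, y = 0)),
                    class = "segmented_tree")
  # eps must reach the next point on the circle (arc spacing 2*pi*0.1/12)
  expect_equal(dbh_from_slice(tree, eps = 0.06, min_pts = 3), 20, tolerance = 1e-6)
})

test_that("a detached noise clump near the slice is rejected", {
  tr <- make_cylinder_tree(r = 0.08, h = 8, n_trunk = 6000, seed = 3)
  clump <- data.frame(x = 1 + runif(30, 0, 0.04), y = runif(30, 0, 0.04),
                      z = runif(30, 1.25, 1.35), part = "trunk")
  tr$points <- rbind(tr$points, clump)
  expect_equal(dbh_from_slice(tr), 16, tolerance = 0.1)
  empty <- make_cylinder_tree(r = 0.08, h = 1, n_trunk = 20, seed = 4)
  expect_error(dbh_from_slice(empty), "occluded")
})

test_that("crown base detection follows the occupancy-run rule", {
  tr <- make_cylinder_tree(r = 0.0662, h = 7.76, n_trunk = 5000,
                           crown = list(a = 2.1, b = 2.1, base = 2.094,
                                        top = 7.76, n = 6000), seed = 5)
  expect_equal(height_to_crown(tr), 2.094, tolerance = 0.15)
  # branchless cylinder: no crown at all
  bare <- make_cylinder_tree(r = 0.08, h = 8, n_trunk = 5000, seed = 6)
  expect_error(height_to_crown(bare, dbh = 16), "no crown")
  # a 1-bin noise blob 1 m under the true 3 m base is skipped by the run rule
  tr2 <- make_cylinder_tree(r = 0.0662, h = 8, n_trunk = 5000,
                            crown = list(a = 2, b = 2, base = 3, top = 8,
                                         n = 6000), seed = 7)
  blob <- data.frame(x = 1.2 + runif(40, 0, 0.05), y = runif(40, 0, 0.05),
                     z = runif(40, 2.0, 2.1), part = "crown")
  tr2$points <- rbind(tr2$points, blob)
  expect_equal(height_to_crown(tr2), 3, tolerance = 0.15)
})

test_that("crown width and area match closed forms and simple fixtures", {
  tr <- make_cylinder_tree(r = 0.05, h = 8, n_trunk = 1000,
                           crown = list(a = 2, b = 1.5, base = 2, top = 8,
                                        n = 30000), seed = 8)
  expect_equal(crown_width(tr, 2), 3.5, tolerance = 0.05)
  expect_equal(crown_area(tr, 2), pi * 2 * 1.5, tolerance = 0.02 * pi * 3)
  # four corners of a 2 x 2 square
  sq <- structure(list(points = data.frame(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2),
                                           z = 5), base = c(x = 1, y = 1)),
                  class = "segmented_tree")
  expect_equal(crown_width(sq, 4), 2)
  expect_equal(crown_area(sq, 4), 4)
  # rotation about z by 90 degrees swaps extents, CW unchanged
  rot <- tr
  rot$points <- transform(rot$points, x = -tr$points$y, y = tr$points$x)
  rot$base <- c(x = 0, y = 0)
  expect_equal(crown_width(rot, 2), crown_width(tr, 2), tolerance = 1e-9)
  expect_equal(crown_area(rot, 2), crown_area(tr, 2), tolerance = 1e-9)
})

test_that("cut-and-fill crown volume approaches closed forms", {
  # solid box 2 x 2 x 1, dense
  set.seed(9)
  n <- 60000
  box <- structure(list(points = data.frame(x = runif(n, 0, 2),
                                            y = runif(n, 0, 2),
                                            z = runif(n, 3, 4)),
                        base = c(x = 1, y = 1)), class = "segmented_tree")
  expect_equal(crown_volume(box, 3, cell = 0.1), 4, tolerance = 0.05 * 4)
  # coplanar crown: zero volume
  flat <- structure(list(points = data.frame(x = runif(500), y = runif(500),
                                             z = 5), base = c(x = 0, y = 0)),
                    class = "segmented_tree")
  expect_equal(crown_volume(flat, 4), 0)
  # uniform ellipsoid a = b = 2, c = 1.5
  tr <- make_cylinder_tree(r = 0.05, h = 6, n_trunk = 500,
                           crown = list(a = 2, b = 2, base = 3, top = 6,
                                        n = 50000), seed = 10)
  expect_equal(crown_volume(tr, 3), (4 / 3) * pi * 2 * 2 * 1.5,
               tolerance = 0.08 * 25.13)
})

test_that("cylinder-model trunk volume matches closed forms", {
  cyl <- make_cylinder_tree(r = 0.10, h = 8, n_trunk = 12000, seed = 11)
  expect_equal(trunk_volume_qsm(cyl), pi * 0.01 * 8, tolerance = 0.05)
  cone <- make_cylinder_tree(r = 0.12, h = 8, taper = 1, n_trunk = 12000, seed = 12)
  expect_equal(trunk_volume_qsm(cone), (pi / 3) * 0.12^2 * 8, tolerance = 0.10)
  zerol <- make_cylinder_tree(r = 0.1, h = 1e-9, n_trunk = 200, seed = 13)
  expect_error(trunk_volume_qsm(zerol), "zero-length|too few")
})

test_that("the cylinder list export covers the stem", {
  cyl <- make_cylinder_tree(r = 0.10, h = 6, n_trunk = 8000, seed = 18)
  tv <- trunk_volume_qsm(cyl, return_cylinders = TRUE)
  tab <- attr(tv, "cylinders")
  expect_true(is.data.frame(tab))
  expect_named(tab, c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "length"))
  expect_equal(sum(pi * tab$radius^2 * tab$length), as.numeric(tv))
  expect_equal(sum(tab$length), 6, tolerance = 0.1)
})

test_that("trunk volume grows when branch wood is added", {
  cyl <- make_cylinder_tree(r = 0.10, h = 6, n_trunk = 8000, seed = 14)
  tv1 <- trunk_volume_qsm(cyl)
  # graft a side branch (kept as trunk-tagged wood)
  t <- runif(2500, 0, 2); th <- runif(2500, 0, 2 * pi)
  branch <- data.frame(x = t * 0.707 + 0.04 * cos(th),
                       y = 0.04 * sin(th),
                       z = 3 + t * 0.707, part = "trunk")
  cyl2 <- cyl; cyl2$points <- rbind(cyl$points, branch)
  tv2 <- trunk_volume_qsm(cyl2)
  expect_gt(tv2, tv1)
})

test_that("extractors are invariant under rigid motion", {
  tr <- make_cylinder_tree(r = 0.08, h = 8, n_trunk = 6000,
                           crown = list(a = 1.8, b = 1.4, base = 2.5, top = 8,
                                        n = 8000), seed = 15)
  sh <- tr
  sh$points$x <- sh$points$x + 12.3; sh$points$y <- sh$points$y - 4.5
  sh$base <- c(x = 12.3, y = -4.5)
  expect_equal(tree_height(sh), tree_height(tr), tolerance = 1e-12)
  expect_equal(dbh_from_slice(sh), dbh_from_slice(tr), tolerance = 1e-9)
  expect_equal(crown_area(sh, 2.5), crown_area(tr, 2.5), tolerance = 1e-9)
  expect_equal(crown_volume(sh, 2.5), crown_volume(tr, 2.5), tolerance = 1e-9)
})

test_that("extract_traits composes atomically and deterministically", {
  tr <- make_cylinder_tree(r = 0.0662, h = 7.76, n_trunk = 6000,
                           crown = list(a = 2.1, b = 2.1, base = 2.094,
                                        top = 7.76, n = 8000), seed = 16)
  rec <- extract_traits(tr)
  expect_named(rec, c("H", "DBH", "CW", "CA", "CV", "TV", "HLC"))
  expect_true(all(rec > 0))
  expect_lt(rec$HLC, rec$H)
  expect_identical(extract_traits(tr), rec)
  bare <- make_cylinder_tree(r = 0.08, h = 8, n_trunk = 6000, seed = 17)
  err <- tryCatch(extract_traits(bare), error = conditionMessage)
  expect_match(err, "HLC"); expect_match(err, "CW")
  expect_match(err, "CA"); expect_match(err, "CV")
})
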