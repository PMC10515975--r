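test_that("a flat plane plus an elevated blob filters to exactly the plane", {
  set.seed(41)
  n <- 2000
  plane <- data.frame(x = runif(n, 0, 20), y = runif(n, 0, 20), z = 0)
  blob <- data.frame(x = runif(300, 8, 12), y = runif(300, 8, 12),
                     z = runif(300, 4.5, 5.5))
  cloud <- rbind(plane, blob)
  gm <- filter_ground(cloud)
  expect_true(all(gm[1:n]))
  expect_false(any(gm[(n + 1):(n + 300)]))
  expect_error(filter_ground(plane[0, ]), "empty")
  line <- data.frame(x = 1:50, y = 1:50, z = 0)
  expect_error(filter_ground(line), "collinear")
})

test_that("ground recovery on relief exceeds 98% with few canopy intrusions", {
  st <- generate_stand(small_stand(seed = 19, relief = 0.3))
  gm <- filter_ground(st$cloud)
  truth <- st$cloud$class == "ground"
  expect_gte(sum(gm & truth) / sum(truth), 0.98)
  # whatever sneaks in must be near the ground (trunk feet), never canopy
  fp <- st$cloud[gm & !truth, ]
  expect_true(all(fp$z - plustree:::.relief(fp$x, fp$y, 0.3, 15) < 0.35))
})

test_that("DEM interpolation tracks the generating relief field", {
  st <- generate_stand(small_stand(seed = 23, relief = 0.3))
  gm <- filter_ground(st$cloud)
  dem <- build_dem(st$cloud[gm, ], cell_size = 0.1)
  qx <- runif(300, 1, 11); qy <- runif(300, 1, 5)  # inside the 12 x 6 m plot
  est <- query_surface(dem, qx, qy)
  expect_lt(max(abs(est - plustree:::.relief(qx, qy, 0.3, 15))), 0.08)
})

test_that("normalization is exact on flat ground and invertible", {
  set.seed(47)
  flat <- data.frame(x = runif(500, 0, 10), y = runif(500, 0, 10), z = 2)
  tree <- data.frame(x = 5, y = 5, z = 10)
  cloud <- rbind(flat, tree)
  gm <- c(rep(TRUE, 500), FALSE)
  dem <- build_dem(cloud[gm, ])
  nrm <- normalize_heights(cloud, dem)
  expect_equal(nrm$z[501], 8, tolerance = 1e-9)
  back <- normalize_heights(nrm, dem, denormalize = TRUE)
  expect_equal(back$z, cloud$z, tolerance = 1e-12)
  # single ground cell -> constant DEM
  one <- build_dem(data.frame(x = 0.5, y = 0.5, z = 3), cell_size = 1)
  expect_equal(query_surface(one, 0.5, 0.5), 3)
})

test_that("the CHM holds the maximum normalized height per cell", {
  nrm <- data.frame(x = c(0.2, 0.25, 3.1), y = c(0.2, 0.22, 3.0),
                    z = c(5, 7, 2))
  chm <- build_chm(nrm, cell_size = 0.5)
  expect_equal(max(chm$z, na.rm = TRUE), 7)
})

test_that("trunk detection finds exactly the true bases", {
  st <- generate_stand(small_stand(seed = 29, relief = 0))
  gm <- st$cloud$class == "ground"
  seeds <- detect_trunks(st$cloud[!gm, ])
  expect_equal(nrow(seeds), 2)
  ord <- order(seeds$x)
  expect_lt(max(abs(seeds$x[ord] - sort(st$truth$x))), 0.02)
  expect_lt(max(abs(seeds$y - st$truth$y[1])), 0.02)
})

test_that("an empty slab or a leaning stem yields no seeds", {
  set.seed(53)
  shrubless <- data.frame(x = runif(400, 0, 10), y = runif(400, 0, 10),
                          z = runif(400, 0, 0.3))
  expect_equal(nrow(detect_trunks(shrubless)), 0)
  # 20 degree lean exceeds the 15 degree default verticality threshold
  h <- runif(3000, 0, 4)
  th <- runif(3000, 0, 2 * pi)
  lean <- data.frame(x = 5 + h * tan(20 * pi / 180) + 0.07 * cos(th),
                     y = 5 + 0.07 * sin(th), z = h)
  ax <- plustree:::.principal_axis(as.matrix(lean))
  expect_gt(acos(abs(ax[3])) * 180 / pi, 15)   # the axis really leans > 15 deg
  expect_equal(nrow(detect_trunks(lean)), 0)
})

test_that("two separated trees segment at >= 99% accuracy", {
  st <- generate_stand(small_stand(seed = 31, relief = 0))
  veg <- st$cloud[st$cloud$class != "ground", ]
  seeds <- detect_trunks(veg)
  trees <- segment_trees(veg, seeds)
  expect_length(trees, 2)
  hits <- 0; tot <- 0
  for (tr in trees) {
    truthid <- which.min((tr$base[1] - st$truth$x)^2 + (tr$base[2] - st$truth$y)^2)
    hits <- hits + sum(tr$points$tree == truthid)
    tot <- tot + nrow(tr$points)
  }
  expect_equal(tot, nrow(veg))        # labels partition the non-ground cloud
  expect_gte(hits / tot, 0.99)
})

test_that("a single seed claims every point; labels survive translation", {
  st <- generate_stand(stand_spec(n_trees = 1, noise_sd = 0,
                                  ground_relief_amplitude = 0,
                                  point_density = list(ground = 20, trunk = 800,
                                                       crown = 50), seed = 37))
  veg <- st$cloud[st$cloud$class != "ground", ]
  seeds <- detect_trunks(veg)
  trees <- segment_trees(veg, seeds)
  expect_length(trees, 1)
  expect_equal(nrow(trees[[1]]$points), nrow(veg))
  # rigid x-y translation leaves the partition unchanged
  veg2 <- veg; veg2$x <- veg2$x + 100; veg2$y <- veg2$y - 50
  seeds2 <- seeds; seeds2$x <- seeds2$x + 100; seeds2$y <- seeds2$y - 50
  trees2 <- segment_trees(veg2, seeds2)
  expect_equal(nrow(trees2[[1]]$points), nrow(trees[[1]]$points))
  expect_equal(trees2[[1]]$points$z, trees[[1]]$points$z)
})

test_that("interlocking crowns stay above 90% accuracy", {
  sp <- stand_spec(n_trees = 2, spacing = 2.5, crown_radii = c(2, 2),
                   noise_sd = 0, ground_relief_amplitude = 0,
                   point_density = list(ground = 30, trunk = 1500, crown = 80),
                   seed = 41)
  st <- generate_stand(sp)
  veg <- st$cloud[st$cloud$class != "ground", ]
  seeds <- detect_trunks(veg)
  expect_equal(nrow(seeds), 2)
  trees <- segment_trees(veg, seeds)
  hits <- 0; tot <- 0
  for (tr in trees) {
    truthid <- which.min((tr$base[1] - st$truth$x)^2 + (tr$base[2] - st$truth$y)^2)
    hits <- hits + sum(tr$points$tree == truthid)
    tot <- tot + nrow(tr$points)
  }
  expect_gte(hits / tot, 0.90)
})

test_that("cloud IO round-trips XYZ and ASCII PLY", {
  df <- data.frame(x = runif(50), y = runif(50), z = runif(50))
  p1 <- withr::local_tempfile(fileext = ".xyz")
  p2 <- withr::local_tempfile(fileext = ".ply")
  write_cloud(df, p1); write_cloud(df, p2)
  r1 <- read_cloud(p1); r2 <- read_cloud(p2)
  expect_equal(r1$z, df$z, tolerance = 1e-6)
  expect_equal(r2$x, df$x, tolerance = 1e-6)
  expect_error(read_cloud("no/such/file.xyz"), "not found")
  expect_equal(nrow(clip_z(df, zmin = 0.5)), sum(df$z >= 0.5))
})
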