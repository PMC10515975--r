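test_that("group standardization yields zero mean, unit variance", {
  set.seed(5)
  tab <- data.frame(a = rnorm(40, 10, 3), b = runif(40, 0, 7))
  groups <- rep(c("g1", "g2"), each = 20)
  std <- standardize_traits(tab, groups)
  for (g in c("g1", "g2")) {
    z <- std[[g]]$z
    expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
    expect_equal(unname(vapply(z, stats::sd, 0)), c(1, 1), tolerance = 1e-12)
  }
  # documented convention: sample SD -> {1,3} maps to +/- 0.707
  z2 <- standardize_traits(data.frame(v = c(1, 3)), c(1, 1))[["1"]]$z$v
  expect_equal(z2, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  zp <- standardize_traits(data.frame(v = c(1, 3)), c(1, 1),
                           sd_type = "population")[["1"]]$z$v
  expect_equal(zp, c(-1, 1), tolerance = 1e-12)
  expect_warning(standardize_traits(data.frame(v = rep(2, 5), w = 1:5),
                                    rep(1, 5)), "constant")
})

test_that("PCA bookkeeping matches the correlation-matrix identities", {
  # eigenvalue 12.454 on 13 traits -> contribution 95.800 %
  expect_equal(12.454 / 13 * 100, 95.8, tolerance = 1e-3)
  # two perfectly correlated traits: lambda = {2, 0}
  toy <- data.frame(a = 1:10, b = 2 * (1:10))
  f <- pca_fit(toy)
  expect_equal(f$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(f$contribution[1], 100, tolerance = 1e-9)
  expect_equal(sum(f$contribution), 100, tolerance = 1e-9)
  # near-independent traits: eigenvalues near 1
  set.seed(9)
  big <- as.data.frame(matrix(rnorm(4000 * 4), ncol = 4))
  fb <- pca_fit(big)
  expect_true(all(abs(fb$eigenvalues - 1) < 0.1))
  expect_true(all(diff(fb$ccr) > 0))
  expect_error(pca_fit(data.frame(a = 1)), "at least 2")
})

test_that("component retention follows the printed contribution sequences", {
  expect_equal(select_components(c(95.800, 2, 1)), 1L)
  expect_equal(select_components(c(79.051, 8.394, 5, 4)), 2L)
  expect_equal(select_components(c(68.504, 9.771, 7.356, 5)), 3L)
  expect_equal(select_components(rep(100 / 13, 13)), 12L)  # ceiling(0.85 * 13)
})

test_that("PC scores are hand-checkable projections, orthogonal over the group", {
  set.seed(7)
  z <- scale(matrix(rnorm(60), ncol = 2))
  f <- pca_fit(z)
  s <- pc_scores(z, f, 2)
  expect_equal(unname(s[, 1]), unname(as.vector(z %*% f$vectors[, 1])))
  expect_equal(stats::cov(s)[1, 2], 0, tolerance = 1e-9)
  expect_equal(attr(s, "convention"), "eigenvector")
  zero <- pc_scores(matrix(0, 4, 2), f, 2)
  expect_true(all(zero == 0))
  sl <- pc_scores(z, f, 1, coef = "loading")
  expect_equal(unname(sl[, 1]),
               unname(as.vector(z %*% f$vectors[, 1])) * sqrt(f$eigenvalues[1]))
})

test_that("composite scores reproduce the published worked examples", {
  expect_equal(composite_score(653.207, 0.958), 625.772, tolerance = 0.005)
  expect_equal(composite_score(c(478.100, -59.841, 21.507),
                               c(0.68504, 0.09771, 0.07356)),
               323.253, tolerance = 0.005)
  expect_equal(composite_score(c(486.499, 42.763), c(0.79051, 0.08394)),
               388.172, tolerance = 0.005)
  expect_equal(composite_score(c(392.492, -14.432, -0.074),
                               c(0.68504, 0.09771, 0.07356)),
               267.457, tolerance = 0.005)
  expect_equal(composite_score(c(0, 0), c(0.7, 0.1)), 0)
  expect_error(composite_score(c(1, 2), c(0.5)), "mismatch")
})

test_that("composite score is linear and selection is rank-invariant", {
  set.seed(13)
  s <- matrix(rnorm(30), ncol = 3)
  w <- c(0.6, 0.3, 0.1)
  expect_equal(composite_score(3 * s, w), 3 * composite_score(s, w))
  f <- composite_score(s, w)
  names(f) <- sprintf("T%02d", 1:10)
  sel1 <- rank_and_select(f, rep(1, 10), 0.2)
  sel2 <- rank_and_select(exp(f), rep(1, 10), 0.2)  # monotone transform
  expect_identical(sel1$id[sel1$selected], sel2$id[sel2$selected])
})

test_that("the inclusion rule keeps at least one tree per group", {
  f <- stats::setNames(seq_len(102), sprintf("G%03d", 1:102))
  groups <- rep(c("g1", "g2", "g3"), c(3, 30, 69))
  sel <- rank_and_select(f, groups, 0.10)
  picked <- table(sel$group[sel$selected])
  expect_equal(unname(c(picked[["g1"]], picked[["g2"]], picked[["g3"]])),
               c(1, 3, 7))
  expect_equal(unname(table(sel$group[sel$selected])[["g1"]]), 1)  # floor of one
  # ranks are a permutation within each group
  for (g in unique(groups))
    expect_setequal(sel$rank[sel$group == g], seq_len(sum(groups == g)))
  expect_equal(rank_and_select(stats::setNames(1:10, letters[1:10]),
                               rep(1, 10), 0.10)$id[1], "j")
})

test_that("a tree dominating every trait is always rank 1", {
  # size-structured traits (shared growth factor), as in real stands
  for (s in 1:5) {
    set.seed(s)
    size <- rnorm(20)
    tab <- as.data.frame(sapply(1:13, function(j) size + rnorm(20, sd = 0.4)))
    tab[7, ] <- apply(tab, 2, max) + 0.5    # dominate all 13 traits
    rownames(tab) <- sprintf("T%02d", 1:20)
    ev <- evaluate_groups(tab, rep("g", 20))
    expect_equal(ev$selection$id[ev$selection$rank == 1], "T07")
  }
})
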