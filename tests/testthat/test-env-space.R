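test_that("the pooled PCA centres, orders and orients its axes", {
  set.seed(1)
  t1 <- data.frame(a = rnorm(600), b = rnorm(600), c = rnorm(600, sd = 2))
  t2 <- data.frame(a = rnorm(400, 1), b = rnorm(400), c = rnorm(400))
  pca <- fit_pca_env(list(t1, t2))
  pooled_mean <- colMeans(rbind(t1, t2))
  expect_equal(as.numeric(project_env(pca, rbind(pooled_mean))), c(0, 0))
  expect_equal(crossprod(pca$loadings), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gte(pca$variance_explained[1], pca$variance_explained[2])
  # sign convention: dominant loading of each axis is positive
  for (ax in 1:2)
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, ax])), ax], 0)
  # isotropic 2-variable cloud splits the variance evenly
  iso <- data.frame(a = rnorm(10000), b = rnorm(10000))
  expect_equal(fit_pca_env(iso)$variance_explained, c(0.5, 0.5),
               tolerance = 0.02, ignore_attr = TRUE)
  # duplicated variable collapses onto one axis
  dup <- data.frame(a = rnorm(500))
  dup$b <- dup$a
  expect_equal(fit_pca_env(dup)$variance_explained[1], 1, tolerance = 1e-12)
  expect_error(fit_pca_env(data.frame(a = rnorm(50), b = rep(2, 50))), "constant")
  expect_error(fit_pca_env(data.frame(a = rnorm(3), b = rnorm(3), c = rnorm(3))),
               "k \\+ 2")
})

test_that("projection is the standardized loading product", {
  set.seed(2)
  tab <- data.frame(a = rnorm(100, 5, 2), b = runif(100), c = rnorm(100))
  pca <- fit_pca_env(tab)
  hand <- sweep(sweep(as.matrix(tab), 2, pca$means), 2, pca$scales, "/") %*%
    pca$loadings
  expect_equal(unname(project_env(pca, tab)), unname(hand))
  expect_error(project_env(pca, tab[, 1:2]), "columns")
})

test_that("density grids satisfy the occupancy invariants", {
  set.seed(3)
  bg <- cbind(rnorm(2000), rnorm(2000))
  occ <- cbind(rnorm(200, 0.5, 0.4), rnorm(200, -0.3, 0.4))
  g <- env_grid(bg, R = 60)
  dg <- build_density_grid(occ, bg, g)
  expect_true(all(dg$z >= 0) && all(dg$z <= 1))
  expect_equal(max(dg$z), 1)
  expect_true(all(dg$z[dg$e == 0] == 0))
  expect_gt(sum(dg$o), 0); expect_gt(sum(dg$e), 0)
  # point mass at a cell centre with a cell-scale bandwidth: z peaks there
  # and collapses to ~0 within a couple of cells
  pt <- cbind(g$x[30], g$y[40])
  h <- (g$x[2] - g$x[1]) / 3
  pm <- build_density_grid(pt, bg, g, bandwidth = c(h, h))
  expect_equal(which(pm$z == 1, arr.ind = TRUE), cbind(row = 30L, col = 40L))
  expect_lt(sum(pm$z > 0.01), 10)
  # occurrences identical to the background: z constant over the support
  dg2 <- build_density_grid(bg, bg, g)
  zpos <- dg2$z[dg2$e > 0]
  expect_lt(max(zpos) / min(zpos), 1.5)
  expect_error(env_grid(cbind(rep(1, 5), rep(2, 5))), "degenerate")
})

test_that("the vectorized KDE equals direct kernel summation", {
  for (seed in 1:5) {
    set.seed(seed)
    sc <- cbind(rnorm(30), rnorm(30, 1))
    g <- env_grid(cbind(rnorm(50), rnorm(50, 1)), R = 25)
    got <- nicheshift:::kde_grid(sc, g, bandwidth = c(0.4, 0.3))$density
    expect_lt(max(abs(got - oracle_kde(sc, g, 0.4, 0.3))), 1e-10)
  }
})

test_that("analogue masks follow the availability quantiles", {
  set.seed(4)
  bg1 <- cbind(rnorm(800, -3), rnorm(800))
  bg2 <- cbind(rnorm(800, 3), rnorm(800))
  g <- env_grid(list(bg1, bg2), R = 50)
  occ1 <- bg1[1:50, ]; occ2 <- bg2[1:50, ]
  g1 <- build_density_grid(occ1, bg1, g)
  g2 <- build_density_grid(occ2, bg2, g)
  # widely separated availabilities: nearly (here exactly) disjoint supports
  m_dis <- analogue_mask(g1, g2, 0)
  expect_equal(sum(m_dis$mask), sum(g1$e > 0 & g2$e > 0))
  # identical availability: the mask at q = 0 is the whole support
  g2b <- build_density_grid(occ1, bg1, g)
  m_id <- analogue_mask(g1, g2b, 0)
  expect_equal(m_id$mask, g1$e > 0)
  # q = 0.1 removes exactly the cells at or below each 10th positive percentile
  m_q <- analogue_mask(g1, g2b, 0.1)
  thr <- quantile(g1$e[g1$e > 0], 0.1, names = FALSE)
  expect_equal(m_q$mask, g1$e > thr & g2b$e > thr)
  expect_error(analogue_mask(g1, g2, 1), "quantile")
})

test_that("MESS flags novel climates and is non-negative on itself", {
  set.seed(5)
  ref <- data.frame(a = rnorm(100), b = runif(100))  # even n: exact medians
  at_median <- data.frame(a = median(ref$a), b = median(ref$b))
  expect_equal(mess(ref, at_median)$mess, 100)
  below <- data.frame(a = min(ref$a) - 1, b = median(ref$b))
  expect_lt(mess(ref, below)$mess, 0)
  self <- mess(ref, ref)
  expect_true(all(self$mess >= 0))
  expect_equal(self$fraction_nonnegative, 1.0)
  expect_error(mess(data.frame(a = rep(1, 10)), data.frame(a = 2)), "constant")
})
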