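test_that("Schoener's D satisfies its identities and formula", {
  z <- matrix(runif(25), 5, 5)
  expect_equal(schoener_d(z, z), 1)
  expect_equal(schoener_d(z, 3.7 * z), 1)  # scale invariance
  a <- matrix(0, 2, 2); a[1, 1] <- 1
  b <- matrix(0, 2, 2); b[2, 2] <- 1
  expect_equal(schoener_d(a, b), 0)
  # p1 = (1, 0), p2 = (0.5, 0.5)
  expect_equal(schoener_d(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)), 0.5)
  # symmetry and oracle agreement on random surfaces
  for (seed in 1:20) {
    set.seed(seed)
    z1 <- matrix(rexp(36), 6, 6); z2 <- matrix(rexp(36), 6, 6)
    d <- schoener_d(z1, z2)
    expect_equal(d, schoener_d(z2, z1))
    expect_equal(d, oracle_schoener_d(z1, z2), tolerance = 1e-12)
    expect_true(d >= 0 && d <= 1)
  }
  expect_error(schoener_d(matrix(0, 2, 2), z[1:2, 1:2]), "all zero")
})

test_that("the expansion/stability/unfilling decomposition is exact on toys", {
  m <- matrix(TRUE, 1, 3)
  z_nat <- matrix(c(0.5, 1, 0), 1)
  z_inv <- matrix(c(0, 1, 0.25), 1)
  esu <- esu_indices(z_nat, z_inv, m)
  expect_equal(esu$expansion, 0.25 / 1.25)
  expect_equal(esu$max_niche_stability, 0.8)
  expect_equal(esu$unfilling, 0.5 / 1.5)
  # identical niches: full stability
  same <- esu_indices(z_nat, z_nat, m)
  expect_equal(unlist(same[1:3]), c(expansion = 0, max_niche_stability = 1,
                                    unfilling = 0))
  # disjoint niches inside the mask: complete expansion and unfilling
  dis <- esu_indices(matrix(c(1, 0), 1), matrix(c(0, 1), 1), matrix(TRUE, 1, 2))
  expect_equal(unlist(dis[1:3]), c(expansion = 1, max_niche_stability = 0,
                                   unfilling = 1))
  # invasive occupancy entirely outside the mask: the 1/0/1 convention
  expect_warning(
    conv <- esu_indices(matrix(c(1, 0), 1), matrix(c(0, 1), 1),
                        matrix(c(TRUE, FALSE), 1)),
    "no occupancy")
  expect_equal(unlist(conv[1:3]), c(expansion = 1, max_niche_stability = 0,
                                    unfilling = 1))
  expect_error(esu_indices(matrix(c(0, 1), 1), matrix(c(1, 0), 1),
                           matrix(c(TRUE, FALSE), 1)), "native niche")
})

test_that("expansion + stability = 1 across random surfaces", {
  for (seed in 1:15) {
    set.seed(seed)
    z1 <- matrix(rexp(100) * rbinom(100, 1, 0.6), 10, 10)
    z2 <- matrix(rexp(100) * rbinom(100, 1, 0.6), 10, 10)
    m <- matrix(rbinom(100, 1, 0.8) == 1, 10, 10)
    esu <- tryCatch(suppressWarnings(esu_indices(z1, z2, m)),
                    error = function(e) NULL)
    if (!is.null(esu)) {
      expect_equal(esu$expansion + esu$max_niche_stability, 1)
      expect_true(all(unlist(esu[1:3]) >= 0 & unlist(esu[1:3]) <= 1))
    }
  }
})

test_that("the equivalency test matches exhaustive enumeration for tiny samples", {
  set.seed(7)
  bg <- cbind(rnorm(200), rnorm(200))
  s1 <- cbind(c(-1.2, -0.8), c(0.3, -0.2))
  s2 <- cbind(c(1.1, 0.7), c(0.1, 0.4))
  res <- equivalency_test(s1, s2, bg, exhaustive = TRUE, R = 25)
  expect_equal(res$n_perm, choose(4, 2))
  # independent enumeration of all 6 reallocations through the same estimator
  pooled <- rbind(s1, s2)
  grid <- env_grid(bg, R = 25)
  avail <- build_density_grid(pooled, bg, grid)
  ds <- sapply(combn(4, 2, simplify = FALSE), function(pick) {
    g1 <- nicheshift:::rebuild_z(pooled[pick, , drop = FALSE], avail)
    g2 <- nicheshift:::rebuild_z(pooled[-pick, , drop = FALSE], avail)
    schoener_d(g1$z, g2$z)
  })
  expect_equal(sort(res$null_Ds), sort(ds))
  expect_equal(res$p_value, (1 + sum(ds <= res$observed_D)) / (length(ds) + 1))
  # two identical singleton sets: every reallocation reproduces the data, p = 1
  one <- cbind(0.5, -0.5)
  deg <- equivalency_test(one, one, bg, exhaustive = TRUE, R = 25)
  expect_equal(deg$p_value, 1)
  expect_true(all(abs(deg$null_Ds - deg$observed_D) < 1e-12))
})

test_that("the similarity test detects overlap and degenerates gracefully", {
  set.seed(8)
  bg <- cbind(rnorm(1500), rnorm(1500))
  grid <- env_grid(bg, R = 50)
  # strongly overlapping niches inside a broad shared space
  hits <- 0
  for (seed in 1:10) {
    set.seed(100 + seed)
    occ1 <- cbind(rnorm(60, 0.4, 0.3), rnorm(60, 0.2, 0.3))
    occ2 <- cbind(rnorm(60, 0.5, 0.3), rnorm(60, 0.1, 0.3))
    g1 <- build_density_grid(occ1, bg, grid)
    g2 <- build_density_grid(occ2, bg, grid)
    p <- similarity_test(g1, g2, n_perm = 99, seed = seed)$p_value
    expect_true(p > 0 && p <= 1)
    if (p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
  # single-cell available space: all null values equal the observation
  g1 <- build_density_grid(cbind(0, 0), bg, grid)
  tiny <- g1
  tiny$e[, ] <- 0
  keep <- which(g1$e > 0, arr.ind = TRUE)[1, ]
  tiny$e[keep[1], keep[2]] <- 1
  expect_warning(res <- similarity_test(g1, tiny, n_perm = 19, seed = 1),
                 "smaller than 2")
  expect_equal(res$p_value, 1)
})

test_that("temporal series accumulate records and repeat empty years", {
  sc <- spread_scenario(3)
  es <- scenario_env_space(sc)
  ser <- temporal_dynamics(es$native_grid, es$scores$inv_occ, es$inv_years,
                           es$scores$inv_bg)
  expect_equal(ser$year, 2014:2017)
  expect_true(!is.unsorted(ser$n_records_cumulative))
  expect_equal(ser$n_records_cumulative[4], nrow(es$scores$inv_occ))
  # a requested year with no new records duplicates the previous row
  ser2 <- temporal_dynamics(es$native_grid, es$scores$inv_occ, es$inv_years,
                           es$scores$inv_bg, eval_years = c(2014:2017, 2018))
  expect_equal(unlist(ser2[5, -1]), unlist(ser2[4, -1]))
  # all records in one year: a single-row series
  ser3 <- temporal_dynamics(es$native_grid, es$scores$inv_occ,
                            rep(2015L, length(es$inv_years)), es$scores$inv_bg)
  expect_equal(nrow(ser3), 1)
  expect_error(temporal_dynamics(es$native_grid, es$scores$inv_occ,
                                 es$inv_years, es$scores$inv_bg,
                                 eval_years = 2010), "first year")
})

test_that("the marginality sweep distinguishes modal from fringe niches", {
  set.seed(9)
  bg <- cbind(rnorm(3000), rnorm(3000))
  grid <- env_grid(bg, R = 60)
  g_nat <- build_density_grid(cbind(rnorm(150, 0, 0.4), rnorm(150, 0, 0.4)),
                              bg, grid)
  # invasive niche concentrated at the modal environment: metrics barely move
  g_modal <- build_density_grid(cbind(rnorm(150, 0.2, 0.3), rnorm(150, 0, 0.3)),
                                bg, grid)
  sw_modal <- marginality_sweep(g_nat, g_modal)
  expect_lt(max(sw_modal$expansion) - min(sw_modal$expansion), 0.05)
  # a niche holding half its occupancy in the 5% availability fringe, outside
  # the native support: excluding 10% of marginal climates removes exactly
  # that mass from the mask, so expansion collapses from 0.5 to 0
  g_fringe <- build_density_grid(cbind(rnorm(60, 0, 0.2), rnorm(60, 0, 0.2)),
                                 bg, grid)
  e <- g_nat$e
  fr <- e > 0 & e <= quantile(e[e > 0], 0.05) & g_nat$z == 0
  g_fringe$z[fr] <- sum(g_fringe$z) / sum(fr)
  g_fringe$z <- g_fringe$z / max(g_fringe$z)
  sw_fringe <- suppressWarnings(marginality_sweep(g_nat, g_fringe,
                                                  quantiles = c(0, 0.1)))
  expect_gt(abs(sw_fringe$expansion[2] - sw_fringe$expansion[1]), 0.2)
  expect_equal(sw_fringe$expansion[1], 0.5)
  # a single zero quantile reproduces the plain index computation
  sw0 <- marginality_sweep(g_nat, g_modal, quantiles = 0)
  esu0 <- esu_indices(g_nat, g_modal, analogue_mask(g_nat, g_modal, 0))
  expect_equal(sw0$expansion, esu0$expansion)
  expect_equal(sw0$unfilling, esu0$unfilling)
})
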