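test_that("pseudo-absence sampling avoids presences and respects the ratio", {
  st <- make_env_stack(15, 15, 2, seed = 11)
  ctr <- nicheshift:::cell_centre(st, c(3, 5, 7, 9), c(3, 5, 7, 9))
  pres <- occurrence_set(data.frame(x = ctr[, "x"], y = ctr[, "y"],
                                    population = "native"))
  pa <- sample_pseudo_absences(st, pres, ratio = 5, seed = 2)
  expect_equal(nrow(pa), 20)
  # no pseudo-absence may fall in a presence cell, and all cells are valid
  pres_key <- paste(c(3, 5, 7, 9), c(3, 5, 7, 9))
  expect_false(any(paste(pa$row, pa$col) %in% pres_key))
  expect_true(all(st$valid_mask[cbind(pa$row, pa$col)]))
  expect_equal(anyDuplicated(paste(pa$row, pa$col)), 0)  # without replacement
  expect_identical(pa, sample_pseudo_absences(st, pres, ratio = 5, seed = 2))
  expect_false(identical(pa, sample_pseudo_absences(st, pres, ratio = 5, seed = 3)))
  expect_error(sample_pseudo_absences(st, pres, ratio = 0), ">= 1")
  expect_error(sample_pseudo_absences(st, pres, ratio = 100), "not enough")
})

test_that("every learner separates an easy problem and not a null one", {
  set.seed(12)
  mk <- function(n) {
    pres <- data.frame(a = rnorm(n, 2, 0.3), b = rnorm(n), presence = 1)
    abs_ <- data.frame(a = rnorm(n, -2, 0.3), b = rnorm(n), presence = 0)
    rbind(pres, abs_)
  }
  train <- mk(60); test <- mk(40)
  null_train <- train; null_train$presence <- sample(null_train$presence)
  for (alg in c("boosted_trees", "random_forest", "maxent_like")) {
    fit <- fit_sdm(alg, train, seed = 5)
    s <- predict(fit, test[c("a", "b")])
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(roc_auc(s, test$presence), 1)
    # permuted labels carry no signal: held-out AUC stays near one half
    null_fit <- fit_sdm(alg, null_train, seed = 5)
    expect_lt(abs(roc_auc(predict(null_fit, test[c("a", "b")]),
                          test$presence) - 0.5), 0.15)
    # refitting with the same seed reproduces the scores exactly
    expect_identical(predict(fit_sdm(alg, train, seed = 5), test[c("a", "b")]), s)
  }
  expect_error(fit_sdm("random_forest", transform(train, presence = 1)),
               "both classes")
  expect_error(fit_sdm("nonsense", train))
})

test_that("the rank AUC matches hand counts and the pairwise oracle", {
  # 4 points: presence/absence pairs won 3 of 4 times
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)  # tie counts one half
  for (seed in 1:20) {
    set.seed(seed)
    scores <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # many ties
    labels <- rbinom(30, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("the max-SSS threshold is optimal over the full scan", {
  scores <- c(0.2, 0.35, 0.4, 0.9); labels <- c(0, 0, 1, 1)
  thr <- max_sss_threshold(scores, labels)
  expect_gt(thr, 0.35); expect_lte(thr, 0.4)
  expect_equal(sss_at(scores, labels, thr), 2)  # perfect separation
  # property: no candidate midpoint beats the returned threshold
  for (seed in 1:15) {
    set.seed(seed)
    s <- round(runif(40), 2); l <- rbinom(40, 1, 0.5)
    if (length(unique(l)) < 2 || length(unique(s)) < 2) next
    t0 <- max_sss_threshold(s, l)
    expect_equal(t0, oracle_max_sss(s, l)$threshold)
    u <- sort(unique(s))
    cand <- (u[-1] + u[-length(u)]) / 2
    expect_true(all(sss_at(s, l, t0) >= sapply(cand, sss_at, scores = s,
                                               labels = l) - 1e-12))
  }
  expect_warning(t1 <- max_sss_threshold(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)),
                 "identical")
  expect_equal(t1, 0.4)
  expect_error(max_sss_threshold(1:4, rep(1, 4)), "both classes")
})

test_that("the consensus rule is a strict majority", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  c3 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2)
  cons <- nicheshift:::consensus_map(list(a, b, c3))
  expect_equal(cons$agreement, matrix(c(3L, 2L, 2L, 0L), 2))
  expect_equal(cons$consensus, matrix(c(TRUE, TRUE, TRUE, FALSE), 2))
  # an exact half is not a majority
  half <- nicheshift:::consensus_map(list(a, b))
  expect_equal(half$consensus, a & b)
  # NA predictions never vote for presence
  a_na <- a; a_na[1, 1] <- NA
  expect_equal(nicheshift:::consensus_map(list(a_na))$consensus[1, 1], FALSE)
})

test_that("a small ensemble trains, projects and overlays coherently", {
  sc <- sdm_scenario(21)
  ens <- run_ensemble(sc$native_stack, sc$native_occ,
                      algorithms = c("random_forest", "maxent_like"),
                      reps = 2, seed = 3, dataset = "native")
  expect_s3_class(ens, "ensemble_result")
  expect_equal(nrow(ens$run_table), 4)
  expect_equal(ens$failed_runs, 0)
  expect_true(all(ens$run_table$auc >= 0 & ens$run_table$auc <= 1))
  expect_gt(mean(ens$run_table$auc), 0.8)  # a learnable specialist niche
  expect_true(all(ens$agreement_count >= 0 & ens$agreement_count <= 4))
  expect_equal(ens$consensus_binary, ens$agreement_count > 2)
  # projecting onto the training stack reproduces the consensus exactly
  self_proj <- project_ensemble(ens, sc$native_stack)
  expect_equal(self_proj$consensus_binary, ens$consensus_binary)
  expect_equal(self_proj$agreement_count, ens$agreement_count)
  # shuffled layers must be refused, not silently mis-scored
  shuffled <- sc$invaded_stack
  shuffled$layer_names <- rev(shuffled$layer_names)
  expect_error(project_ensemble(ens, shuffled), "layer names")
  # deterministic end to end
  ens2 <- run_ensemble(sc$native_stack, sc$native_occ,
                       algorithms = c("random_forest", "maxent_like"),
                       reps = 2, seed = 3, dataset = "native")
  expect_equal(ens2$run_table, ens$run_table)
  expect_equal(ens2$consensus_binary, ens$consensus_binary)
  expect_error(run_ensemble(sc$native_stack, sc$native_occ[1:5, ]),
               "at least 8")
})

test_that("the risk overlay partitions cells into the four categories", {
  n <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE), 3)
  i <- matrix(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE), 3)
  rm_ <- risk_overlay(n, i)
  expect_equal(rm_$category, n * 2L + i * 1L, ignore_attr = TRUE)
  expect_equal(sum(rm_$shares), 1)
  expect_equal(rm_$high_risk_share, unname(1 - rm_$shares["neither"]))
  # identical maps: only "both" and "neither" occur
  same <- risk_overlay(n, n)
  expect_equal(unname(same$shares[c("invasive_only", "native_only")]), c(0, 0))
  expect_equal(unname(same$shares["both"]), mean(n))
  # disjoint maps: no "both" cells
  expect_equal(unname(risk_overlay(n, !n)$shares["both"]), 0)
  # the valid mask restricts the denominators
  mask <- matrix(FALSE, 3, 3); mask[1, ] <- TRUE
  masked <- risk_overlay(n, i, mask)
  expect_true(all(is.na(masked$category[!mask])))
  expect_equal(sum(masked$shares), 1)
  expect_error(risk_overlay(n, i[1:2, 1:2]), "shape")
})
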