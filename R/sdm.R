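#' Sample pseudo-absences from a range
#'
#' Uniform sample, without replacement, of valid cells that contain no
#' presence; the conventional background for presence-only modelling is five
#' pseudo-absences per presence.
#'
#' @param stack an [env_stack()].
#' @param presences an [occurrence_set()].
#' @param ratio pseudo-absences per presence (default 5, must be >= 1).
#' @param seed integer seed.
#' @return Data frame of pseudo-absence cell centres (`x`, `y`, `row`, `col`).
#' @export
sample_pseudo_absences <- function(stack, presences, ratio = 5, seed = 1) {
  if (ratio < 1) stop("ratio must be >= 1")
  pres_cells <- point_cell(stack, presences$x, presences$y)
  occupied <- matrix(FALSE, n_rows(stack), n_cols(stack))
  occupied[pres_cells] <- TRUE
  candidates <- which(stack$valid_mask & !occupied, arr.ind = TRUE)
  n_pa <- ratio * nrow(presences)
  if (nrow(candidates) < n_pa)
    stop("not enough non-presence cells for ", n_pa, " pseudo-absences")
  rng <- local_rng(seed)
  pick <- candidates[rng$sample(nrow(candidates), n_pa), , drop = FALSE]
  xy <- cell_centre(stack, pick[, 1], pick[, 2])
  data.frame(x = xy[, "x"], y = xy[, "y"], row = pick[, 1], col = pick[, 2])
}

sdm_algorithms <- c("boosted_trees", "random_forest", "maxent_like")

# linear + quadratic feature expansion used by the maxent-like learner
quad_features <- function(m) {
  cbind(m, m^2)
}

#' Fit one species distribution model
#'
#' Three pluggable presence/background learners mapping an environmental
#' vector to a suitability score in `[0, 1]`:
#' * `boosted_trees` — gradient-boosted trees (xgboost, logistic objective);
#' * `random_forest` — probability random forest (randomForest);
#' * `maxent_like` — an L1-regularized presence-vs-background logistic model
#'   over linear + quadratic features. This is a declared surrogate for
#'   maximum-entropy modelling (to whose solution it is closely related); the
#'   learner interface is pluggable so a true MaxEnt engine can be swapped in.
#'
#' @param algorithm `"boosted_trees"`, `"random_forest"` or `"maxent_like"`.
#' @param train_table data frame of environmental columns plus a 0/1 column
#'   `presence`.
#' @param seed integer seed (fits are deterministic per seed).
#' @return An object of class `sdm_scorer`; use [predict()] to score new
#'   environments.
#' @export
fit_sdm <- function(algorithm, train_table, seed = 1) {
  algorithm <- match.arg(algorithm, sdm_algorithms)
  y <- train_table$presence
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  x <- as.matrix(train_table[setdiff(names(train_table), "presence")])
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (is.null(old))
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv()))
  model <- switch(algorithm,
    boosted_trees = xgboost::xgboost(
      x = x, y = factor(y, levels = c(0, 1)), nrounds = 60,
      max_depth = 3, learning_rate = 0.2, subsample = 0.8, nthreads = 1,
      verbosity = 0),
    random_forest = randomForest::randomForest(
      x = x, y = factor(y, levels = c(0, 1)), ntree = 300),
    maxent_like = {
      cv <- glmnet::cv.glmnet(quad_features(x), y, family = "binomial",
                              alpha = 1, nfolds = 5, standardize = TRUE)
      cv
    })
  structure(list(algorithm = algorithm, model = model,
                 layer_names = colnames(x), seed = seed),
            class = "sdm_scorer")
}

#' Predict suitability scores from a fitted SDM
#'
#' @param object an `sdm_scorer`.
#' @param newdata matrix or data frame of environmental values with the
#'   training columns, in order.
#' @param ... unused.
#' @return Numeric vector of suitabilities in `[0, 1]`.
#' @export
predict.sdm_scorer <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$layer_names, drop = FALSE])
  switch(object$algorithm,
    boosted_trees = as.numeric(stats::predict(object$model, x)),
    random_forest = as.numeric(
      stats::predict(object$model, x, type = "prob")[, "1"]),
    maxent_like = as.numeric(stats::predict(
      object$model, quad_features(x), s = "lambda.min", type = "response")))
}

#' Rank-based area under the ROC curve
#'
#' The Mann–Whitney statistic: the probability that a random presence scores
#' above a random absence, with ties contributing one half.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 vector (1 = presence).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximizing sensitivity plus specificity
#'
#' Scans the midpoints of consecutive sorted unique scores and returns the
#' cut-off (scores at or above it are predicted present) with the highest
#' sensitivity + specificity; ties resolve to the lowest such threshold,
#' favouring sensitivity. Equivalent to the TSS-maximizing threshold.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 vector.
#' @return The threshold; if all scores are equal the single score value is
#'   returned with a warning (degenerate classifier).
#' @export
max_sss_threshold <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("both classes required")
  u <- sort(unique(scores))
  if (length(u) == 1) {
    warning("all scores identical; degenerate threshold")
    return(u)
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  sss <- vapply(cand, function(t) {
    pred <- scores >= t
    mean(pred[labels == 1]) + mean(!pred[labels == 0])
  }, 0)
  cand[which.max(sss)]  # which.max: first (lowest) of tied maxima
}

score_stack <- function(scorer, stack) {
  tbl <- stack_values_table(stack)
  s <- predict(scorer, tbl[stack$layer_names])
  out <- matrix(NA_real_, n_rows(stack), n_cols(stack))
  out[cbind(tbl$row, tbl$col)] <- s
  out
}

consensus_map <- function(binary_maps) {
  agreement <- Reduce(`+`, lapply(binary_maps, function(m) {
    m[is.na(m)] <- FALSE; m * 1L
  }))
  list(agreement = agreement,
       consensus = agreement > length(binary_maps) / 2)  # strict majority
}

#' Repeated-split ensemble of distribution models
#'
#' For each repetition: fresh pseudo-absences (`ratio` per presence), a
#' stratified train/test split preserving the class ratio, and one fit per
#' algorithm. Each of the `reps x length(algorithms)` runs records its
#' held-out AUC, derives its own max-sensitivity+specificity threshold on the
#' training scores, and binarizes its prediction over the whole stack. The
#' ensemble presence map keeps a cell only when strictly more than half of
#' the runs predict presence.
#'
#' @param stack an [env_stack()].
#' @param presences an [occurrence_set()] (>= 8 records).
#' @param algorithms algorithms to include (default all three).
#' @param reps repetitions per algorithm (default 10, giving 30 runs).
#' @param train_fraction fraction of data used for fitting (default 0.75).
#' @param ratio pseudo-absences per presence (default 5).
#' @param seed integer seed.
#' @param dataset label carried on the result.
#' @return An object of class `ensemble_result`: `runs` (list of per-run
#'   records with scorer, AUC, threshold, binary map), `run_table`,
#'   `agreement_count`, `consensus_binary`, `failed_runs`.
#' @export
run_ensemble <- function(stack, presences, algorithms = sdm_algorithms,
                         reps = 10, train_fraction = 0.75, ratio = 5,
                         seed = 1, dataset = "entity") {
  if (nrow(presences) < 8) stop("need at least 8 presences")
  pres_env <- extract_env_at_points(stack, presences)
  pres_kept <- attr(pres_env, "occurrences")
  rng <- local_rng(seed)
  runs <- list(); failed <- 0L
  for (rep in seq_len(reps)) {
    pa <- sample_pseudo_absences(stack, pres_kept, ratio = ratio,
                                 seed = seed + 1000L * rep)
    pa_env <- as.data.frame(vapply(seq_len(n_layers(stack)), function(l)
      stack$values[, , l][cbind(pa$row, pa$col)], numeric(nrow(pa))))
    names(pa_env) <- stack$layer_names
    tbl <- rbind(cbind(pres_env, presence = 1),
                 cbind(pa_env, presence = 0))
    # stratified split preserving the presence : pseudo-absence ratio
    idx_p <- which(tbl$presence == 1); idx_a <- which(tbl$presence == 0)
    tr <- c(idx_p[rng$sample(length(idx_p), round(train_fraction * length(idx_p)))],
            idx_a[rng$sample(length(idx_a), round(train_fraction * length(idx_a)))])
    train <- tbl[tr, ]; test <- tbl[-tr, ]
    for (alg in algorithms) {
      run <- tryCatch({
        scorer <- fit_sdm(alg, train, seed = seed + 1000L * rep + match(alg, sdm_algorithms))
        train_scores <- predict(scorer, train[stack$layer_names])
        thr <- max_sss_threshold(train_scores, train$presence)
        test_scores <- predict(scorer, test[stack$layer_names])
        suit <- score_stack(scorer, stack)
        list(algorithm = alg, repetition = rep, scorer = scorer,
             auc = roc_auc(test_scores, test$presence), threshold = thr,
             binary_map = suit >= thr, seed = scorer$seed)
      }, error = function(e) e)
      if (inherits(run, "error")) {
        failed <- failed + 1L
        warning("run failed (", alg, ", rep ", rep, "): ", conditionMessage(run))
      } else runs[[length(runs) + 1L]] <- run
    }
  }
  n_total <- reps * length(algorithms)
  if (failed > 0.1 * n_total)
    stop("ensemble failed: ", failed, " of ", n_total, " runs errored")
  cons <- consensus_map(lapply(runs, `[[`, "binary_map"))
  structure(list(
    runs = runs,
    run_table = data.frame(
      algorithm = vapply(runs, `[[`, "", "algorithm"),
      repetition = vapply(runs, `[[`, 0, "repetition"),
      auc = vapply(runs, `[[`, 0, "auc"),
      threshold = vapply(runs, `[[`, 0, "threshold")),
    agreement_count = cons$agreement, consensus_binary = cons$consensus,
    failed_runs = failed, dataset = dataset, stack_layers = stack$layer_names),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> '%s': %d runs, mean test AUC %.3f, %d consensus-presence cells\n",
              x$dataset, length(x$runs), mean(x$run_table$auc),
              sum(x$consensus_binary)))
  invisible(x)
}

#' Project an ensemble onto another range
#'
#' Applies every run's scorer, with its own training threshold, to the other
#' range's stack (reciprocal distribution modelling), and returns the
#' strict-majority consensus there.
#'
#' @param ensemble an [run_ensemble()] result.
#' @param other_stack an [env_stack()] with identical layer names and order.
#' @return List with `consensus_binary` and `agreement_count` on the other
#'   range's grid.
#' @export
project_ensemble <- function(ensemble, other_stack) {
  if (!identical(other_stack$layer_names, ensemble$stack_layers))
    stop("layer names/order differ from the training stack")
  maps <- lapply(ensemble$runs, function(run)
    score_stack(run$scorer, other_stack) >= run$threshold)
  cons <- consensus_map(maps)
  list(consensus_binary = cons$consensus, agreement_count = cons$agreement)
}

#' Invasion-risk overlay of two consensus maps
#'
#' Combines the native-trained and invasive-trained consensus predictions on
#' one grid into four categories: `both` (predicted suitable by both models),
#' `native_only`, `invasive_only`, and `neither`. Under reciprocal
#' distribution modelling every cell predicted by at least one model is a
#' high-risk area; `neither` is low risk.
#'
#' @param native_consensus,invasive_consensus logical matrices on one grid.
#' @param valid_mask optional logical matrix of cells to include.
#' @return Object of class `risk_map`: integer `category` matrix (codes 0
#'   neither, 1 invasive_only, 2 native_only, 3 both), `shares` (fractions
#'   over valid cells, summing to 1) and `high_risk_share`.
#' @export
risk_overlay <- function(native_consensus, invasive_consensus,
                         valid_mask = NULL) {
  if (!identical(dim(native_consensus), dim(invasive_consensus)))
    stop("consensus maps differ in shape")
  if (is.null(valid_mask))
    valid_mask <- matrix(TRUE, nrow(native_consensus), ncol(native_consensus))
  cat_m <- matrix(NA_integer_, nrow(native_consensus), ncol(native_consensus))
  cat_m[valid_mask] <- native_consensus[valid_mask] * 2L +
    invasive_consensus[valid_mask] * 1L
  counts <- vapply(0:3, function(code) sum(cat_m[valid_mask] == code), 0L)
  shares <- counts / sum(counts)
  names(shares) <- c("neither", "invasive_only", "native_only", "both")
  structure(list(category = cat_m, shares = shares,
                 high_risk_share = unname(sum(shares[c("invasive_only",
                                                       "native_only", "both")]))),
            class = "risk_map")
}
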