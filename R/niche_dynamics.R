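mask_matrix <- function(mask, z) {
  if (is.null(mask)) return(matrix(TRUE, nrow(z), ncol(z)))
  m <- if (inherits(mask, "analogue_mask")) mask$mask else mask
  if (!identical(dim(m), dim(z))) stop("mask and surface dimensions differ")
  m
}

#' Schoener's D niche overlap
#'
#' Both occupancy surfaces are normalized to sum to one over the comparison
#' cells, then `D = 1 - 0.5 * sum(|p1 - p2|)`: 0 means no overlap, 1 identical
#' niches. Symmetric, and invariant to rescaling either surface by a positive
#' constant.
#'
#' @param z1,z2 occupancy surfaces (matrices, or [build_density_grid()]
#'   results whose `z` is used) on one shared grid.
#' @param mask optional [analogue_mask()] or logical matrix restricting the
#'   comparison to analogue climates.
#' @return D in `[0, 1]`.
#' @export
schoener_d <- function(z1, z2, mask = NULL) {
  if (inherits(z1, "density_grid") && inherits(z2, "density_grid"))
    assert_shared_grid(z1, z2)
  if (inherits(z1, "density_grid")) z1 <- z1$z
  if (inherits(z2, "density_grid")) z2 <- z2$z
  if (!identical(dim(z1), dim(z2))) stop("surfaces differ in shape")
  m <- mask_matrix(mask, z1)
  s1 <- sum(z1[m]); s2 <- sum(z2[m])
  if (s1 <= 0 || s2 <= 0) stop("a surface is all zero within the mask")
  1 - 0.5 * sum(abs(z1[m] / s1 - z2[m] / s2))
}

#' Expansion, maximum niche stability and unfilling
#'
#' The COUE decomposition of the invasive niche, restricted to analogue
#' climates. Within the mask the two niches are binarized on their occupancy
#' support (`z` above `threshold`, default 0). Expansion is the share of
#' invasive occupancy in conditions unused by the native population;
#' maximum niche stability is its complement (the share inside the native
#' niche — the most the invader could stabilize at without occupying novel
#' conditions); unfilling is the share of native occupancy in analogue
#' conditions the invader has not (yet) reached. If the invasive niche has no
#' analogue-space occupancy at all, expansion and unfilling are 1 by
#' convention (with a warning): the entire invaded niche lies outside the
#' native's analogue conditions.
#'
#' @param z_native,z_invasive [build_density_grid()] results (or z matrices)
#'   on one shared grid.
#' @param mask an [analogue_mask()] or logical matrix.
#' @param threshold occupancy value above which a cell counts as part of the
#'   niche; 0 uses the full kernel support.
#' @return Named list `expansion`, `max_niche_stability`, `unfilling`,
#'   `n_analogue_cells`.
#' @export
esu_indices <- function(z_native, z_invasive, mask, threshold = 0) {
  if (inherits(z_native, "density_grid") && inherits(z_invasive, "density_grid"))
    assert_shared_grid(z_native, z_invasive)
  if (inherits(z_native, "density_grid")) z_native <- z_native$z
  if (inherits(z_invasive, "density_grid")) z_invasive <- z_invasive$z
  m <- mask_matrix(mask, z_native)
  if (!any(m)) stop("empty analogue mask")
  N <- z_native > threshold
  I <- z_invasive > threshold
  if (!any(N & m)) stop("native niche has no occupancy in analogue space")
  if (!any(I & m)) {
    warning("invasive niche has no occupancy in analogue space; ",
            "expansion and unfilling set to 1")
    return(list(expansion = 1, max_niche_stability = 0, unfilling = 1,
                n_analogue_cells = sum(m)))
  }
  expansion <- sum(z_invasive[I & !N & m]) / sum(z_invasive[I & m])
  unfilling <- sum(z_native[N & !I & m]) / sum(z_native[N & m])
  list(expansion = expansion, max_niche_stability = 1 - expansion,
       unfilling = unfilling, n_analogue_cells = sum(m))
}

perm_p_value <- function(observed, null_values, direction) {
  b <- switch(direction,
    lower = sum(null_values <= observed),
    higher = sum(null_values >= observed),
    `two-sided` = 2 * min(sum(null_values <= observed),
                          sum(null_values >= observed)))
  min(1, (1 + b) / (length(null_values) + 1))
}

perm_result <- function(observed, null_values, kind, direction, n_perm, seed) {
  structure(list(observed_D = observed, null_Ds = null_values,
                 p_value = perm_p_value(observed, null_values, direction),
                 n_perm = n_perm, kind = kind, direction = direction,
                 seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Niche %s test: observed D = %.3f, p = %.4f (%s, %d permutations)\n",
              x$kind, x$observed_D, x$p_value, x$direction, x$n_perm))
  invisible(x)
}

#' Niche equivalency permutation test
#'
#' Tests whether the two niches are interchangeable: the pooled occurrence
#' scores are randomly reallocated between the two entities (preserving sample
#' sizes), the occupancy surfaces rebuilt against the fixed shared
#' availability, and Schoener's D recomputed for each permutation. With
#' direction `"lower"` (the default) equivalency is rejected when the observed
#' overlap is lower than expected under random reallocation — the signature of
#' a niche shift.
#'
#' @param occ_scores_1,occ_scores_2 occurrence score matrices (n x 2).
#' @param shared_bg_scores pooled background scores defining availability.
#' @param n_perm number of permutations, >= 19.
#' @param seed integer seed.
#' @param direction `"lower"`, `"higher"` or `"two-sided"`.
#' @param grid optional [env_grid()]; defaults to one built from
#'   `shared_bg_scores`.
#' @param R grid resolution when `grid` is not supplied.
#' @param bandwidth optional fixed kernel bandwidth (length 2).
#' @param exhaustive enumerate every reallocation instead of sampling
#'   (feasible only for tiny samples; `n_perm` is then ignored).
#' @return A `perm_test` object; `p_value = (1 + b) / (n_perm + 1)`.
#' @export
equivalency_test <- function(occ_scores_1, occ_scores_2, shared_bg_scores,
                             n_perm = 99, seed = 1, direction = "lower",
                             grid = NULL, R = 100, bandwidth = NULL,
                             exhaustive = FALSE) {
  if (!exhaustive && n_perm < 19) stop("n_perm must be >= 19")
  s1 <- rbind(occ_scores_1); s2 <- rbind(occ_scores_2)
  n1 <- nrow(s1); n2 <- nrow(s2)
  if (n1 + n2 < 2) stop("pooled occurrence set too small")
  if (is.null(grid)) grid <- env_grid(shared_bg_scores, R = R)
  avail <- build_density_grid(rbind(s1, s2), shared_bg_scores, grid,
                              bandwidth = bandwidth)
  d_of <- function(a, b) {
    g1 <- rebuild_z(a, avail, bandwidth)
    g2 <- rebuild_z(b, avail, bandwidth)
    schoener_d(g1$z, g2$z)
  }
  observed <- d_of(s1, s2)
  pooled <- rbind(s1, s2)
  if (exhaustive) {
    if (choose(n1 + n2, n1) > 5000) stop("too many splits for exhaustive mode")
    splits <- utils::combn(n1 + n2, n1, simplify = FALSE)
    null_ds <- vapply(splits, function(pick)
      d_of(pooled[pick, , drop = FALSE], pooled[-pick, , drop = FALSE]), 0)
    n_perm <- length(null_ds)
  } else {
    rng <- local_rng(seed)
    null_ds <- vapply(seq_len(n_perm), function(p) {
      pick <- rng$sample(n1 + n2, n1)
      d_of(pooled[pick, , drop = FALSE], pooled[-pick, , drop = FALSE])
    }, 0)
  }
  perm_result(observed, null_ds, "equivalency", direction, n_perm, seed)
}

# integer-offset translation of a surface with zero fill
shift_surface <- function(z, dr, dc) {
  R <- nrow(z); C <- ncol(z)
  out <- matrix(0, R, C)
  sr <- seq_len(R) - dr; sc <- seq_len(C) - dc
  okr <- sr >= 1 & sr <= R; okc <- sc >= 1 & sc <= C
  out[okr, okc] <- z[sr[okr], sc[okc]]
  out
}

#' Niche similarity permutation test
#'
#' Tests whether the niche occupied in one range is more similar to the niche
#' in the other range than expected by chance, given what environments each
#' range offers. Each permutation relocates entity 2's occupancy surface to a
#' random centre within entity 2's own available environmental space (cells
#' with positive availability), zeroing any mass translated outside that
#' support, and recomputes D against entity 1. One-tailed by default:
#' similarity is supported when the observed D exceeds most null values.
#'
#' @param grid_1,grid_2 [build_density_grid()] results on one shared grid.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param direction `"higher"` (more similar than chance) by default.
#' @return A `perm_test` object.
#' @export
similarity_test <- function(grid_1, grid_2, n_perm = 99, seed = 1,
                            direction = "higher") {
  assert_shared_grid(grid_1, grid_2)
  avail2 <- which(grid_2$e > 0, arr.ind = TRUE)
  if (nrow(avail2) < 2) {
    warning("entity 2's available space is smaller than 2 cells; p = 1")
    obs <- schoener_d(grid_1$z, grid_2$z)
    return(perm_result(obs, rep(obs, n_perm), "similarity", direction,
                       n_perm, seed))
  }
  observed <- schoener_d(grid_1$z, grid_2$z)
  w <- grid_2$z
  tot <- sum(w)
  cr <- sum(row(w) * w) / tot
  cc <- sum(col(w) * w) / tot
  rng <- local_rng(seed)
  null_ds <- vapply(seq_len(n_perm), function(p) {
    repeat {
      target <- avail2[rng$sample(nrow(avail2), 1), ]
      zs <- shift_surface(w, round(target[1] - cr), round(target[2] - cc))
      zs[grid_2$e == 0] <- 0
      if (sum(zs) > 0) break
    }
    schoener_d(grid_1$z, zs)
  }, 0)
  perm_result(observed, null_ds, "similarity", direction, n_perm, seed)
}

#' Yearly niche dynamics of an invasion
#'
#' For each year, the invasive entity is the cumulative set of records dated
#' up to and including that year; its occupancy surface is rebuilt against the
#' fixed invaded-range availability and compared with the fixed native niche
#' (overlap D and the expansion / stability / unfilling decomposition within
#' the analogue mask). One kernel bandwidth, computed once from the full dated
#' set, is reused for every year so the series reflects the accumulation of
#' records only. Undated records must be excluded upstream.
#'
#' @param native_grid the native [build_density_grid()].
#' @param occ_scores invasive occurrence scores (n x 2).
#' @param years integer year per score row (no NAs).
#' @param inv_bg_scores invaded-range background scores (availability).
#' @param intersect_quantile marginality quantile for the analogue mask.
#' @param mode `"cumulative"` (each year's cumulative set vs the native
#'   niche) or `"stepwise"` (each year's new records vs the cumulative set of
#'   all previous years, D only).
#' @param eval_years optional years at which to evaluate the series (default:
#'   the record years); a year adding no new records repeats the previous row.
#' @return Data frame with one row per year: `year`, `expansion`,
#'   `max_niche_stability`, `unfilling`, `D`, `n_records_cumulative`.
#' @export
temporal_dynamics <- function(native_grid, occ_scores, years, inv_bg_scores,
                              intersect_quantile = 0, mode = "cumulative",
                              eval_years = NULL) {
  occ_scores <- rbind(occ_scores)
  if (length(years) != nrow(occ_scores)) stop("one year per score row required")
  if (anyNA(years)) stop("undated records must be excluded upstream")
  yrs <- if (is.null(eval_years)) sort(unique(years)) else sort(eval_years)
  if (!any(years <= yrs[1])) stop("no records at or before the first year")
  grid <- native_grid$grid
  bw <- c(silverman_bw(occ_scores[, 1], diff(grid$xlim)),
          silverman_bw(occ_scores[, 2], diff(grid$ylim)))
  inv_avail <- build_density_grid(occ_scores, inv_bg_scores, grid)
  rows <- lapply(yrs, function(y) {
    cum <- occ_scores[years <= y, , drop = FALSE]
    g <- rebuild_z(cum, inv_avail, bandwidth = bw)
    msk <- analogue_mask(native_grid, g, intersect_quantile)
    if (mode == "cumulative") {
      d <- schoener_d(native_grid$z, g$z, msk)
      esu <- suppressWarnings(esu_indices(native_grid$z, g$z, msk))
    } else {
      prev <- occ_scores[years < y, , drop = FALSE]
      if (nrow(prev) == 0) {
        d <- NA_real_
        esu <- list(expansion = NA_real_, max_niche_stability = NA_real_,
                    unfilling = NA_real_)
      } else {
        gp <- rebuild_z(prev, inv_avail, bandwidth = bw)
        d <- schoener_d(gp$z, g$z, msk)
        esu <- suppressWarnings(esu_indices(gp$z, g$z, msk))
      }
    }
    data.frame(year = y, expansion = esu$expansion,
               max_niche_stability = esu$max_niche_stability,
               unfilling = esu$unfilling, D = d,
               n_records_cumulative = nrow(cum))
  })
  do.call(rbind, rows)
}

#' Niche metrics under increasing marginality exclusion
#'
#' Recomputes overlap and the expansion / stability / unfilling indices while
#' successively discarding a growing proportion of the most marginal (least
#' frequent) available environments from the analogue mask. Little variation
#' across quantiles indicates the species occupies the common environments of
#' both ranges; large variation indicates reliance on rare, marginal
#' conditions.
#'
#' @param native_grid,invasive_grid [build_density_grid()] results on one grid.
#' @param quantiles ascending marginality quantiles in `[0, 1)`.
#' @param threshold occupancy binarization threshold for [esu_indices()].
#' @return Data frame with one row per quantile: `intersect_quantile`,
#'   `expansion`, `max_niche_stability`, `unfilling`, `D`,
#'   `n_analogue_cells`, `empty_mask` flag.
#' @export
marginality_sweep <- function(native_grid, invasive_grid,
                              quantiles = c(0, 0.1, 0.2), threshold = 0) {
  if (is.unsorted(quantiles)) stop("quantiles must be ascending")
  rows <- lapply(quantiles, function(q) {
    msk <- analogue_mask(native_grid, invasive_grid, q)
    if (!any(msk$mask))
      return(data.frame(intersect_quantile = q, expansion = NA_real_,
                        max_niche_stability = NA_real_, unfilling = NA_real_,
                        D = NA_real_, n_analogue_cells = 0L, empty_mask = TRUE))
    esu <- suppressWarnings(
      esu_indices(native_grid$z, invasive_grid$z, msk, threshold))
    d <- tryCatch(schoener_d(native_grid$z, invasive_grid$z, msk),
                  error = function(e) NA_real_)
    data.frame(intersect_quantile = q, expansion = esu$expansion,
               max_niche_stability = esu$max_niche_stability,
               unfilling = esu$unfilling, D = d,
               n_analogue_cells = esu$n_analogue_cells, empty_mask = FALSE)
  })
  do.call(rbind, rows)
}
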