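#' Fit the shared environmental ordination (PCA-env)
#'
#' A PCA on the standardized, pooled background environments of all ranges:
#' using every valid pixel of both study areas maximises the ecological
#' variance represented by the first two axes, which then define the common
#' environmental space in which all niches are compared. The sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' making results reproducible across platforms.
#'
#' @param background_tables a list of records-x-k tables (one per range) with
#'   identical column names, or a single table.
#' @return An object of class `pca_env` with elements `means`, `scales`,
#'   `loadings` (k x 2), `variance_explained` (fractions, first two axes) and
#'   `layer_names`.
#' @export
fit_pca_env <- function(background_tables) {
  if (is.data.frame(background_tables) || is.matrix(background_tables))
    background_tables <- list(background_tables)
  pooled <- do.call(rbind, lapply(background_tables, function(t)
    as.matrix(as.data.frame(t))))
  k <- ncol(pooled)
  if (nrow(pooled) < k + 2) stop("need at least k + 2 pooled records")
  sds <- apply(pooled, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(pooled)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(pooled, center = TRUE, scale. = TRUE)
  load2 <- pc$rotation[, 1:2, drop = FALSE]
  for (a in 1:2) {
    i <- which.max(abs(load2[, a]))
    if (load2[i, a] < 0) load2[, a] <- -load2[, a]
  }
  structure(list(
    means = pc$center, scales = pc$scale, loadings = load2,
    variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[1:2],
    layer_names = colnames(pooled)),
    class = "pca_env")
}

#' @export
print.pca_env <- function(x, ...) {
  cat(sprintf("<pca_env> %d variables; axis 1: %.1f%%, axis 2: %.1f%% variance\n",
              length(x$means), 100 * x$variance_explained[1],
              100 * x$variance_explained[2]))
  invisible(x)
}

#' Project environmental records into the ordination space
#'
#' @param pca a [fit_pca_env()] model.
#' @param table records x k table with the model's columns (in model order).
#' @return Numeric matrix of scores, records x 2.
#' @export
project_env <- function(pca, table) {
  m <- as.matrix(as.data.frame(table))
  if (ncol(m) != length(pca$means))
    stop("table has ", ncol(m), " columns; model expects ", length(pca$means))
  if (!is.null(colnames(m)) && !identical(colnames(m), pca$layer_names))
    stop("column names/order do not match the fitted model")
  scores <- sweep(sweep(m, 2, pca$means), 2, pca$scales, "/") %*% pca$loadings
  colnames(scores) <- c("axis1", "axis2")
  scores
}

#' Define the shared environmental-space grid
#'
#' All entities compared in one analysis must share one grid: its bounds are
#' the min/max of the pooled background scores of both ranges, padded by a
#' fraction of each axis range so kernels are not truncated at the extremes.
#'
#' @param bg_scores_list list of score matrices (one per range), or one matrix.
#' @param R grid resolution per axis (R x R cells).
#' @param pad fractional padding of each axis range (default 5%).
#' @return An object of class `niche_grid` (axis bounds, R, cell centres).
#' @export
env_grid <- function(bg_scores_list, R = 100, pad = 0.05) {
  if (!is.list(bg_scores_list)) bg_scores_list <- list(bg_scores_list)
  pooled <- do.call(rbind, bg_scores_list)
  rngs <- apply(pooled, 2, range)
  if (any(rngs[1, ] == rngs[2, ])) stop("degenerate bounds: all scores identical")
  span <- rngs[2, ] - rngs[1, ]
  lo <- rngs[1, ] - pad * span
  hi <- rngs[2, ] + pad * span
  structure(list(
    xlim = c(lo[1], hi[1]), ylim = c(lo[2], hi[2]), R = as.integer(R),
    x = seq(lo[1] + (hi[1] - lo[1]) / (2 * R), hi[1], length.out = R),
    y = seq(lo[2] + (hi[2] - lo[2]) / (2 * R), hi[2], length.out = R)),
    class = "niche_grid")
}

# Silverman's rule-of-thumb bandwidth per axis (stats::bw.nrd0); degenerate
# samples fall back to a small fraction of the axis span.
silverman_bw <- function(v, span) {
  if (length(v) >= 2 && stats::sd(v) > 0) {
    bw <- stats::bw.nrd0(v)
    if (is.finite(bw) && bw > 0) return(bw)
  }
  span / 50
}

# Product-Gaussian KDE on the grid, kernel truncated at 3 bandwidths per axis
# (gives occupancy surfaces a genuine finite support). Vectorized as two
# n x R kernel matrices combined by a crossproduct.
kde_grid <- function(scores, grid, bandwidth = NULL) {
  n <- nrow(scores)
  hx <- if (is.null(bandwidth)) silverman_bw(scores[, 1], diff(grid$xlim)) else bandwidth[1]
  hy <- if (is.null(bandwidth)) silverman_bw(scores[, 2], diff(grid$ylim)) else bandwidth[2]
  ux <- outer(scores[, 1], grid$x, function(s, g) (g - s) / hx)
  uy <- outer(scores[, 2], grid$y, function(s, g) (g - s) / hy)
  kx <- ifelse(abs(ux) <= 3, exp(-ux^2 / 2), 0)
  ky <- ifelse(abs(uy) <= 3, exp(-uy^2 / 2), 0)
  d <- crossprod(kx, ky) / (n * hx * hy * 2 * pi)
  list(density = d, bandwidth = c(hx, hy))
}

#' Kernel-density occupancy surfaces for one entity
#'
#' Estimates, on the shared grid, the occurrence density `o` (Gaussian product
#' kernel over the entity's occurrence scores), the availability density `e`
#' (same kernel over the entity's background scores), and the corrected
#' occupancy `z = o / e`, zeroed wherever availability falls below a floor
#' (1e-12 of its maximum) and rescaled to maximum 1. `z` expresses how
#' intensely the species occupies each environment relative to how common that
#' environment is in its range, the surface on which overlap and the niche
#' dynamic indices are computed.
#'
#' @param occ_scores entity occurrence scores (n x 2), at least 1 row.
#' @param bg_scores entity background scores (m x 2), at least 2 rows.
#' @param grid the shared [env_grid()].
#' @param bandwidth `NULL` for Silverman's rule per axis (computed separately
#'   for occurrences and background), or a fixed numeric length-2 bandwidth.
#' @param entity label carried on the result.
#' @return An object of class `density_grid` with `o`, `e`, `z` (R x R
#'   matrices), the grid, bandwidths and entity label.
#' @export
build_density_grid <- function(occ_scores, bg_scores, grid,
                               bandwidth = NULL, entity = "entity") {
  occ_scores <- rbind(occ_scores)
  if (nrow(occ_scores) < 1) stop("need at least one occurrence score")
  if (nrow(bg_scores) < 2) stop("need at least two background scores")
  ok <- kde_grid(occ_scores, grid, bandwidth)
  ek <- kde_grid(bg_scores, grid, bandwidth)
  e <- ek$density
  e[e < 1e-12 * max(e)] <- 0
  z <- ok$density
  z[e == 0] <- 0
  z[e > 0] <- z[e > 0] / e[e > 0]
  if (max(z) > 0) z <- z / max(z)
  structure(list(o = ok$density, e = e, z = z, grid = grid,
                 bandwidth_occ = ok$bandwidth, bandwidth_bg = ek$bandwidth,
                 n_occ = nrow(occ_scores), entity = entity),
            class = "density_grid")
}

# rebuild only the occupancy surface against a fixed availability surface
rebuild_z <- function(occ_scores, ref_grid, bandwidth = NULL) {
  ok <- kde_grid(rbind(occ_scores), ref_grid$grid, bandwidth)
  z <- ok$density
  e <- ref_grid$e
  z[e == 0] <- 0
  z[e > 0] <- z[e > 0] / e[e > 0]
  if (max(z) > 0) z <- z / max(z)
  out <- ref_grid
  out$o <- ok$density; out$z <- z
  out$bandwidth_occ <- ok$bandwidth; out$n_occ <- nrow(rbind(occ_scores))
  out
}

assert_shared_grid <- function(g1, g2) {
  if (!isTRUE(all.equal(g1$grid[c("xlim", "ylim", "R")],
                        g2$grid[c("xlim", "ylim", "R")])))
    stop("density grids do not share bounds and resolution")
}

#' Analogue-climate mask in environmental space
#'
#' The cells where both ranges offer the environment: with
#' `intersect_quantile = 0` every cell with positive availability in both
#' ranges is analogue; with a quantile q > 0, each range's marginal
#' environments — cells whose availability falls at or below its own q-th
#' quantile over positive cells — are excluded, so increasing q strips
#' progressively rarer climates from the comparison.
#'
#' @param native_grid,invaded_grid [build_density_grid()] results on one grid.
#' @param intersect_quantile marginality quantile in `[0, 1)`.
#' @return An object of class `analogue_mask` (logical R x R matrix plus the
#'   quantile used).
#' @export
analogue_mask <- function(native_grid, invaded_grid, intersect_quantile = 0) {
  assert_shared_grid(native_grid, invaded_grid)
  if (intersect_quantile < 0 || intersect_quantile >= 1)
    stop("intersect_quantile must be in [0, 1)")
  e1 <- native_grid$e; e2 <- invaded_grid$e
  if (intersect_quantile == 0) {
    m <- e1 > 0 & e2 > 0
  } else {
    t1 <- stats::quantile(e1[e1 > 0], intersect_quantile, names = FALSE)
    t2 <- stats::quantile(e2[e2 > 0], intersect_quantile, names = FALSE)
    m <- e1 > t1 & e2 > t2
  }
  structure(list(mask = m, intersect_quantile = intersect_quantile),
            class = "analogue_mask")
}

#' Multivariate environmental similarity surface (MESS)
#'
#' For every projection record and each variable, the similarity s depends on
#' f, the percentage of reference values strictly below the projection value:
#' `f = 0` gives `100 (p - min) / (max - min)` (negative below the reference
#' minimum), `0 < f <= 50` gives `2 f`, `50 < f < 100` gives `2 (100 - f)`,
#' and `f = 100` gives `100 (max - p) / (max - min)`. The MESS value is the
#' minimum over variables; negative values flag environments outside the
#' reference range (novel climates), where model projections are
#' extrapolations.
#'
#' @param reference_table records x k reference environments (e.g. the
#'   training range's background).
#' @param projection_table records x k environments to screen.
#' @return List with `mess` (per projection record) and `fraction_nonnegative`
#'   (share of records with MESS >= 0, i.e. inside the reference envelope).
#' @export
mess <- function(reference_table, projection_table) {
  ref <- as.matrix(as.data.frame(reference_table))
  prj <- as.matrix(as.data.frame(projection_table))
  if (ncol(ref) != ncol(prj)) stop("reference and projection differ in variables")
  n <- nrow(ref)
  s <- matrix(NA_real_, nrow(prj), ncol(ref))
  for (v in seq_len(ncol(ref))) {
    rv <- ref[, v]
    mn <- min(rv); mx <- max(rv)
    if (mn == mx) stop("constant reference variable: column ", v)
    p <- prj[, v]
    f <- 100 * vapply(p, function(x) sum(rv < x), 0) / n
    s[, v] <- ifelse(f == 0, 100 * (p - mn) / (mx - mn),
              ifelse(f <= 50, 2 * f,
              ifelse(f < 100, 2 * (100 - f),
                     100 * (mx - p) / (mx - mn))))
  }
  m <- apply(s, 1, min)
  list(mess = m, fraction_nonnegative = mean(m >= 0))
}
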