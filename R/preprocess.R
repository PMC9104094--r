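#' Spatially rarefy occurrences to one record per grid cell
#'
#' Reduces spatial autocorrelation and sampling bias by keeping at most one
#' record per rarefaction cell of side `cell_size` (half-open cell membership,
#' anchored at the stack origin). When several records share a cell, the one
#' whose environmental vector (per-layer standardized over all input records)
#' lies farthest from the centroid of the records already kept is retained —
#' i.e. the most environmentally distinct point survives — with ties broken by
#' input order. Cells are visited in order of first appearance, which makes
#' the procedure deterministic and idempotent.
#'
#' @param occ an [occurrence_set()].
#' @param stack the [env_stack()] supplying environmental values.
#' @param cell_size rarefaction cell side; defaults to the stack's cell size.
#' @return The rarefied [occurrence_set()] (a subset of the input rows).
#' @export
rarefy_occurrences <- function(occ, stack, cell_size = stack$cell_size) {
  if (nrow(occ) == 0) stop("empty occurrence set")
  if (cell_size <= 0) stop("cell_size must be > 0")
  env <- extract_env_at_points(stack, occ)
  occ <- attr(env, "occurrences")
  em <- scale(as.matrix(env))
  em[, apply(em, 2, function(c) any(!is.finite(c)))] <- 0  # constant layers
  ci <- floor((occ$x - stack$origin[1]) / cell_size)
  cj <- floor((occ$y - stack$origin[2]) / cell_size)
  cell_id <- paste(ci, cj)
  keep <- integer(0)
  for (id in unique(cell_id)) {
    members <- which(cell_id == id)
    if (length(members) == 1L) { keep <- c(keep, members); next }
    centroid <- if (length(keep)) colMeans(em[keep, , drop = FALSE]) else
      colMeans(em)
    d <- sqrt(colSums((t(em[members, , drop = FALSE]) - centroid)^2))
    keep <- c(keep, members[which.max(d)])  # which.max: first of tied maxima
  }
  occ[sort(keep), , drop = FALSE]
}

#' Drop collinear environmental variables
#'
#' Pairwise Pearson correlations are computed on the pooled table of
#' environmental values (conventionally background cells from both ranges).
#' While any surviving pair has `|r| >= threshold`, the lowest-priority layer
#' involved in an offending pair is removed, so the retained set never
#' contains a pair at or above the threshold and always favours the layers
#' listed first in `priority`.
#'
#' @param env_table data frame or matrix, records x layers.
#' @param threshold correlation cut-off in `(0, 1]`; 0.70 is the conventional
#'   collinearity screen for distribution modelling.
#' @param priority layer names in decreasing order of (biological) importance;
#'   defaults to the table's column order.
#' @return Character vector of retained layer names, in priority order.
#' @export
filter_correlated <- function(env_table, threshold = 0.70,
                              priority = colnames(env_table)) {
  env_table <- as.data.frame(env_table)
  if (ncol(env_table) < 2) stop("need at least 2 layers")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (!setequal(priority, names(env_table)))
    stop("priority must list exactly the table's layers")
  constant <- vapply(env_table, function(v) stats::sd(v) == 0, TRUE)
  if (any(constant))
    warning("constant layer(s) treated as uncorrelated: ",
            paste(names(env_table)[constant], collapse = ", "))
  kept <- priority
  repeat {
    live <- kept[!constant[kept]]
    if (length(live) < 2) break
    cm <- abs(stats::cor(env_table[live]))
    diag(cm) <- 0
    offending <- which(cm >= threshold, arr.ind = TRUE)
    if (nrow(offending) == 0) break
    involved <- unique(live[c(offending)])
    drop <- involved[which.max(match(involved, priority))]
    kept <- setdiff(kept, drop)
  }
  kept
}
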