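#' Environmental layer stack
#'
#' A gridded multi-layer environmental raster for one range. Values are stored
#' as a `n_rows x n_cols x k` array; all layers share one validity mask. The
#' grid is an abstract planar raster: rows run top to bottom (y decreases with
#' row), columns left to right (x increases with column), with square cells of
#' side `cell_size` (nominally km) and `origin` at the lower-left corner.
#'
#' @param values numeric array `n_rows x n_cols x k`, or a list of matrices.
#' @param layer_names character vector of k unique layer names.
#' @param cell_size positive cell side length.
#' @param origin numeric length-2 `(x0, y0)`, lower-left corner.
#' @param valid_mask logical `n_rows x n_cols` matrix; `NULL` means all valid.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(values, layer_names = NULL, cell_size = 1,
                      origin = c(0, 0), valid_mask = NULL) {
  if (is.list(values) && !is.array(values)) {
    dims <- unique(lapply(values, dim))
    if (length(dims) != 1L) stop("all layers must share the same shape")
    values <- array(unlist(values, use.names = FALSE),
                    dim = c(dims[[1]], length(values)))
  }
  stopifnot(is.array(values), length(dim(values)) == 3L)
  k <- dim(values)[3]
  if (is.null(layer_names)) layer_names <- paste0("env", seq_len(k))
  if (length(layer_names) != k) stop("layer_names must have one entry per layer")
  if (anyDuplicated(layer_names)) stop("layer_names must be unique")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, dim(values)[1], dim(values)[2])
  }
  stopifnot(identical(dim(valid_mask), dim(values)[1:2]))
  # a cell with a non-finite value in any layer is invalid everywhere
  finite <- apply(is.finite(values), c(1, 2), all)
  valid_mask <- valid_mask & finite
  structure(
    list(values = values, layer_names = layer_names,
         cell_size = cell_size, origin = as.numeric(origin),
         valid_mask = valid_mask),
    class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<env_stack> %d x %d cells, %d layers (%s), cell size %g\n",
              d[1], d[2], d[3], paste(x$layer_names, collapse = ", "),
              x$cell_size))
  cat(sprintf("  valid cells: %d / %d\n", sum(x$valid_mask), d[1] * d[2]))
  invisible(x)
}

n_rows <- function(stack) dim(stack$values)[1]
n_cols <- function(stack) dim(stack$values)[2]
n_layers <- function(stack) dim(stack$values)[3]

#' Table of environmental values at all valid cells
#'
#' @param stack an `env_stack`.
#' @return A data frame with one row per valid cell and one column per layer,
#'   plus `row` and `col` indices.
#' @export
stack_values_table <- function(stack) {
  idx <- which(stack$valid_mask, arr.ind = TRUE)
  out <- as.data.frame(
    vapply(seq_len(n_layers(stack)),
           function(l) stack$values[, , l][stack$valid_mask],
           numeric(sum(stack$valid_mask))))
  names(out) <- stack$layer_names
  out$row <- idx[, 1]
  out$col <- idx[, 2]
  out
}

# centre coordinates of cell (row i, col j); row 1 is the top row
cell_centre <- function(stack, i, j) {
  cs <- stack$cell_size
  cbind(x = stack$origin[1] + (j - 0.5) * cs,
        y = stack$origin[2] + (n_rows(stack) - i + 0.5) * cs)
}

# cell indices containing points; half-open membership [edge, edge + cs)
point_cell <- function(stack, x, y) {
  cs <- stack$cell_size
  j <- floor((x - stack$origin[1]) / cs) + 1L
  i <- n_rows(stack) - floor((y - stack$origin[2]) / cs)
  cbind(row = as.integer(i), col = as.integer(j))
}
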