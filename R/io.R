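#' Occurrence records
#'
#' A labelled, optionally dated point data set: one row per presence record
#' with planar coordinates, an optional observation year, and a population
#' label (e.g. `native`, `P1`, `P2`).
#'
#' @param df data frame with columns `x`, `y`, optional `year`, `population`.
#' @return The validated data frame with class `occurrence_set` prepended.
#' @export
occurrence_set <- function(df) {
  if (!all(c("x", "y") %in% names(df))) stop("occurrences need x and y columns")
  if (is.null(df$population)) stop("occurrences need a population label")
  if (is.null(df$year)) df$year <- NA_integer_
  df <- df[, c("x", "y", "year", "population")]
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  df$year <- suppressWarnings(as.integer(df$year))
  df$population <- as.character(df$population)
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("coordinates must be finite")
  if (any(!nzchar(df$population))) stop("population labels must be non-empty")
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Read / write occurrence CSV files
#'
#' The dialect is a UTF-8 CSV with header `x,y,year,population` (`year` may be
#' absent or blank; `.` decimal separator). Rows whose coordinates do not parse
#' are dropped with a message giving the count; a file yielding no valid row is
#' an error.
#'
#' @param path CSV file path.
#' @return For `read_occurrences`, an [occurrence_set()].
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty occurrence file: ", path)
  missing <- setdiff(c("x", "y", "population"), names(df))
  if (length(missing))
    stop("occurrence file lacks mandatory column(s): ", paste(missing, collapse = ", "))
  xs <- suppressWarnings(as.numeric(df$x))
  ys <- suppressWarnings(as.numeric(df$y))
  bad <- !is.finite(xs) | !is.finite(ys)
  if (any(bad))
    message(sum(bad), " row(s) with unparseable coordinates dropped")
  df <- df[!bad, , drop = FALSE]
  df$x <- xs[!bad]; df$y <- ys[!bad]
  if (nrow(df) == 0) stop("no valid rows in occurrence file: ", path)
  occurrence_set(df)
}

#' @rdname read_occurrences
#' @param occ an [occurrence_set()].
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- ESRI ASCII grid rasters -------------------------------------------------

read_ascii_grid <- function(path) {
  head <- readLines(path, n = 6)
  kv <- strsplit(trimws(head), "\\s+")
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                         tolower(vapply(kv, `[`, "", 1)))
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.na(hdr[key])) stop("malformed ASCII grid header in ", path)
  vals <- scan(path, skip = 6, quiet = TRUE)
  if (length(vals) != hdr["ncols"] * hdr["nrows"])
    stop("ASCII grid ", path, " has wrong number of cells")
  m <- matrix(vals, nrow = hdr["nrows"], ncol = hdr["ncols"], byrow = TRUE)
  nodata <- if (!is.na(hdr["nodata_value"])) hdr["nodata_value"] else NA_real_
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  xll <- if (!is.na(hdr["xllcorner"])) hdr["xllcorner"] else 0
  yll <- if (!is.na(hdr["yllcorner"])) hdr["yllcorner"] else 0
  list(values = m, cell_size = unname(hdr["cellsize"]), origin = c(xll, yll))
}

write_ascii_grid <- function(m, path, cell_size, origin, nodata = -9999) {
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", origin[1]),
           sprintf("yllcorner %.10g", origin[2]),
           sprintf("cellsize %.10g", cell_size),
           sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1, function(r) paste(format(r, digits = 10, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write an environmental stack as ESRI ASCII grids
#'
#' One single-band `.asc` file per layer, all sharing shape, cell size and
#' origin; the stack's validity mask is the conjunction of the per-layer
#' NODATA masks (a cell missing in any layer is invalid in all).
#'
#' @param paths character vector of `.asc` files, or a single directory whose
#'   `.asc` files (sorted) are the layers.
#' @return For `read_env_stack`, an [env_stack()] with layers named from the
#'   file names.
#' @export
read_env_stack <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- sort(list.files(paths, "\\.asc$", full.names = TRUE))
  if (length(paths) == 0) stop("no raster layers found")
  grids <- lapply(paths, read_ascii_grid)
  shapes <- unique(lapply(grids, function(g) dim(g$values)))
  if (length(shapes) != 1) stop("raster layers differ in shape")
  cs <- unique(vapply(grids, `[[`, 0, "cell_size"))
  if (length(cs) != 1) stop("raster layers differ in cell size")
  vals <- array(unlist(lapply(grids, `[[`, "values")),
                dim = c(shapes[[1]], length(grids)))
  env_stack(vals, sub("\\.asc$", "", basename(paths)),
            cell_size = cs, origin = grids[[1]]$origin)
}

#' @rdname read_env_stack
#' @param stack an [env_stack()].
#' @param dir output directory (created if needed).
#' @export
write_env_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_len(n_layers(stack))) {
    m <- stack$values[, , l]
    m[!stack$valid_mask] <- NA_real_
    write_ascii_grid(m, file.path(dir, paste0(stack$layer_names[l], ".asc")),
                     stack$cell_size, stack$origin)
  }
  invisible(dir)
}

#' Extract environmental values at occurrence points
#'
#' Nearest-cell lookup on the stack's grid; records falling on invalid cells
#' (or outside the extent) are dropped and counted.
#'
#' @param stack an [env_stack()].
#' @param occ an [occurrence_set()].
#' @return Data frame of layer values, one row per retained record, with the
#'   retained records attached as attribute `occurrences` and the number of
#'   dropped records as attribute `n_dropped`.
#' @export
extract_env_at_points <- function(stack, occ) {
  ij <- point_cell(stack, occ$x, occ$y)
  inside <- ij[, 1] >= 1 & ij[, 1] <= n_rows(stack) &
            ij[, 2] >= 1 & ij[, 2] <= n_cols(stack)
  valid <- inside
  valid[inside] <- stack$valid_mask[ij[inside, , drop = FALSE]]
  if (!any(valid)) stop("no occurrence falls on a valid cell")
  ij <- ij[valid, , drop = FALSE]
  out <- as.data.frame(vapply(
    seq_len(n_layers(stack)),
    function(l) stack$values[, , l][ij],
    numeric(nrow(ij))))
  names(out) <- stack$layer_names
  attr(out, "occurrences") <- occ[valid, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!valid)
  out
}
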