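#' Gaussian niche definition in environmental space
#'
#' Describes a species' realized niche as an axis-aligned Gaussian in raw
#' environmental units: suitability falls off independently along each layer.
#'
#' @param centre numeric k-vector of optimal environmental values.
#' @param breadth numeric k-vector of strictly positive niche breadths
#'   (standard deviations, layer units).
#' @param label entity name (e.g. "native", "P1").
#' @return An object of class `niche_def`.
#' @export
niche_def <- function(centre, breadth, label = "entity") {
  centre <- as.numeric(centre); breadth <- as.numeric(breadth)
  if (length(centre) != length(breadth))
    stop("centre and breadth must have the same length")
  if (any(!is.finite(breadth)) || any(breadth <= 0))
    stop("breadth must be strictly positive and finite")
  structure(list(centre = centre, breadth = breadth, label = label),
            class = "niche_def")
}

# 3x3 mean filter with edge replication, applied once
mean_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    out <- out + pad[di + seq_len(nr), dj + seq_len(nc)]
  out / 9
}

#' Generate a synthetic environmental stack
#'
#' Each layer is a deterministic planar gradient (direction rotating with the
#' layer index) scaled by its weight, plus seeded white noise smoothed twice by
#' a 3x3 mean filter to give mild spatial autocorrelation. Optional layer pairs
#' can be forced to be strongly collinear (Pearson |r| >= 0.9), to exercise the
#' correlation filter downstream.
#'
#' @param n_rows,n_cols grid dimensions, each >= 8.
#' @param k_layers number of layers, >= 2.
#' @param gradient_weights numeric k-vector scaling each layer's gradient.
#' @param noise_scale standard deviation of the (pre-smoothing) noise field.
#' @param correlation_pairs optional list of integer pairs `(i, j)`; layer j is
#'   rebuilt as layer i plus a small perturbation so that |r| >= 0.9.
#' @param seed integer seed; identical arguments give bitwise-identical stacks.
#' @param cell_size,origin passed to [env_stack()].
#' @return An [env_stack()].
#' @export
make_env_stack <- function(n_rows, n_cols, k_layers,
                           gradient_weights = rep(1, k_layers),
                           noise_scale = 1, correlation_pairs = NULL,
                           seed = 1, cell_size = 5, origin = c(0, 0)) {
  if (n_rows < 8 || n_cols < 8) stop("n_rows and n_cols must be >= 8")
  if (k_layers < 2) stop("k_layers must be >= 2")
  if (length(gradient_weights) != k_layers)
    stop("gradient_weights must have length k_layers")
  if (noise_scale < 0) stop("noise_scale must be non-negative")
  u <- matrix(seq(0, 1, length.out = n_rows), n_rows, n_cols)
  v <- matrix(seq(0, 1, length.out = n_cols), n_rows, n_cols, byrow = TRUE)
  vals <- array(0, c(n_rows, n_cols, k_layers))
  rng <- local_rng(seed)
  for (l in seq_len(k_layers)) {
    theta <- pi * (l - 1) / k_layers
    grad <- cos(theta) * v + sin(theta) * u
    noise <- matrix(rng$rnorm(n_rows * n_cols, sd = noise_scale), n_rows, n_cols)
    if (noise_scale > 0) noise <- mean_filter3(mean_filter3(noise))
    vals[, , l] <- gradient_weights[l] * grad + noise
  }
  for (p in correlation_pairs) {
    i <- p[[1]] + 1L; j <- p[[2]] + 1L  # pairs use 0-based layer indices
    if (i < 1 || j < 1 || i > k_layers || j > k_layers || i == j)
      stop("invalid correlation pair")
    s <- stats::sd(vals[, , i])
    if (s == 0) s <- 1
    eps <- matrix(rng$rnorm(n_rows * n_cols, sd = 0.1 * s), n_rows, n_cols)
    vals[, , j] <- vals[, , i] + mean_filter3(eps)
  }
  env_stack(vals, paste0("env", seq_len(k_layers)), cell_size, origin)
}

#' Ground-truth suitability of every cell under a Gaussian niche
#'
#' Per cell, the product over layers of `exp(-(v - centre)^2 / (2 breadth^2))`;
#' exactly 1 iff the cell sits at the niche centre in every layer.
#'
#' @param stack an [env_stack()] with k layers.
#' @param niche a [niche_def()] of matching length.
#' @return Matrix of suitabilities in `[0, 1]`; `NA` on invalid cells.
#' @export
true_suitability <- function(stack, niche) {
  if (n_layers(stack) != length(niche$centre))
    stop("stack and niche dimensionality differ")
  s <- matrix(1, n_rows(stack), n_cols(stack))
  for (l in seq_len(n_layers(stack))) {
    d <- (stack$values[, , l] - niche$centre[l]) / niche$breadth[l]
    s <- s * exp(-d^2 / 2)
  }
  s[!stack$valid_mask] <- NA_real_
  s
}

#' Sample dated occurrence records from a suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to
#' suitability; coordinates are snapped to cell centres. When an introduction
#' cell, a spread rate and years are given, a cell is eligible in year t only
#' if its Euclidean grid distance from the introduction is at most
#' `spread_rate * (t - years[1])`, emulating radial spread from a point of
#' introduction; records are spread as evenly as possible across years.
#'
#' @param stack the [env_stack()] the suitability refers to.
#' @param suitability matrix as from [true_suitability()].
#' @param n number of records, >= 1.
#' @param seed integer seed.
#' @param introduction_cell optional `c(row, col)` of the introduction point.
#' @param spread_rate radial spread in cells per year (used with years).
#' @param years optional strictly increasing integer years.
#' @param population population label stored on each record.
#' @return An occurrence data frame (columns `x`, `y`, `year`, `population`).
#' @export
sample_occurrences <- function(stack, suitability, n, seed = 1,
                               introduction_cell = NULL, spread_rate = NULL,
                               years = NULL, population = "entity") {
  if (n < 1) stop("n must be >= 1")
  w <- suitability
  w[!stack$valid_mask | !is.finite(w)] <- 0
  if (all(w == 0)) stop("suitability is zero on every valid cell")
  rng <- local_rng(seed)
  idx <- which(stack$valid_mask, arr.ind = TRUE)
  wv <- w[idx]
  dist_intro <- NULL
  if (!is.null(introduction_cell)) {
    dist_intro <- sqrt((idx[, 1] - introduction_cell[1])^2 +
                       (idx[, 2] - introduction_cell[2])^2)
  }
  if (is.null(years)) {
    draw <- rng$sample(nrow(idx), n, replace = TRUE, prob = wv)
    rec_year <- rep(NA_integer_, n)
  } else {
    if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
    per <- diff(round(seq(0, n, length.out = length(years) + 1)))
    draw <- integer(0); rec_year <- integer(0)
    for (t in seq_along(years)) {
      if (per[t] == 0) next
      wy <- wv
      if (!is.null(dist_intro)) {
        elapsed <- years[t] - years[1]
        wy[dist_intro > spread_rate * elapsed] <- 0
      }
      if (all(wy == 0))
        stop(sprintf("no eligible cell with positive suitability in year %d", years[t]))
      draw <- c(draw, rng$sample(nrow(idx), per[t], replace = TRUE, prob = wy))
      rec_year <- c(rec_year, rep(years[t], per[t]))
    }
  }
  xy <- cell_centre(stack, idx[draw, 1], idx[draw, 2])
  occurrence_set(data.frame(x = xy[, "x"], y = xy[, "y"], year = rec_year,
                            population = population))
}

#' Assemble a full invasion scenario with known ground truth
#'
#' Builds a native and an invaded environmental stack, places a Gaussian niche
#' in each (the invaded centre offset from the native one by `shift_delta`),
#' and samples occurrence sets — the invaded one optionally spreading radially
#' from an introduction cell over a sequence of years. With `shift_delta = 0`
#' and saturated sampling the downstream expectation is Expansion near 0 and
#' high overlap; with a shift large enough to separate the occupied envelopes,
#' Expansion = 1, Unfilling = 1 and D near 0.
#'
#' @param config a list; see Details.
#' @details Recognised keys (with defaults): `n_rows` (40), `n_cols` (40),
#'   `k_layers` (5), `gradient_weights`, `noise_scale` (0.3),
#'   `correlation_pairs`, `native_centre`, `native_breadth`, `shift_delta`
#'   (zero vector), `shift_delta_sd` and `native_breadth_sd` (alternatives in
#'   units of each layer's realised standard deviation),
#'   `breadth_factor` (1, scales the invaded breadth),
#'   `n_native` (150), `n_invasive` (400), `introduction_cell`, `spread_rate`,
#'   `years`, `identical_stacks` (FALSE; TRUE gives both ranges the very same
#'   environmental layers), `seed` (1), `cell_size` (5). Niche centres default to the middle
#'   of each layer's realised value range; breadths default to 15% of it.
#' @return A list of class `invasion_scenario` with the stacks, niches,
#'   suitabilities and occurrence sets.
#' @export
make_invasion_scenario <- function(config = list()) {
  cfg <- utils::modifyList(list(
    n_rows = 40, n_cols = 40, k_layers = 5, noise_scale = 1,
    gradient_weights = NULL, correlation_pairs = NULL,
    native_centre = NULL, native_breadth = NULL, shift_delta = NULL,
    shift_delta_sd = NULL, native_breadth_sd = NULL,
    breadth_factor = 1, n_native = 150, n_invasive = 400,
    introduction_cell = NULL, spread_rate = NULL, years = NULL,
    identical_stacks = FALSE, seed = 1, cell_size = 5), config)
  if (is.null(cfg$gradient_weights)) cfg$gradient_weights <- rep(1, cfg$k_layers)
  seed <- as.integer(cfg$seed)
  native_stack <- make_env_stack(cfg$n_rows, cfg$n_cols, cfg$k_layers,
                                 cfg$gradient_weights, cfg$noise_scale,
                                 cfg$correlation_pairs, seed = seed,
                                 cell_size = cfg$cell_size)
  invaded_stack <- make_env_stack(cfg$n_rows, cfg$n_cols, cfg$k_layers,
                                  cfg$gradient_weights, cfg$noise_scale,
                                  cfg$correlation_pairs,
                                  seed = if (cfg$identical_stacks) seed else seed + 1L,
                                  cell_size = cfg$cell_size)
  rng_means <- apply(native_stack$values, 3, mean)
  rng_sds <- apply(native_stack$values, 3, stats::sd)
  centre <- if (is.null(cfg$native_centre)) rng_means else as.numeric(cfg$native_centre)
  breadth <- if (!is.null(cfg$native_breadth)) as.numeric(cfg$native_breadth)
             else if (!is.null(cfg$native_breadth_sd))
               pmax(rep_len(cfg$native_breadth_sd, cfg$k_layers) * rng_sds, 1e-8)
             else pmax(0.6 * rng_sds, 1e-8)
  delta <- if (!is.null(cfg$shift_delta)) as.numeric(cfg$shift_delta)
           else if (!is.null(cfg$shift_delta_sd))
             rep_len(cfg$shift_delta_sd, cfg$k_layers) * rng_sds
           else rep(0, cfg$k_layers)
  if (length(delta) != cfg$k_layers) stop("shift_delta must have one entry per layer")
  native_niche <- niche_def(centre, breadth, "native")
  invaded_niche <- niche_def(centre + delta, breadth * cfg$breadth_factor, "invasive")
  nat_suit <- true_suitability(native_stack, native_niche)
  inv_suit <- true_suitability(invaded_stack, invaded_niche)
  if (!is.null(cfg$years) && is.null(cfg$introduction_cell)) {
    # default introduction point: the most suitable invaded cell
    cfg$introduction_cell <- as.integer(
      which(inv_suit == max(inv_suit, na.rm = TRUE), arr.ind = TRUE)[1, ])
  }
  native_occ <- sample_occurrences(native_stack, nat_suit, cfg$n_native,
                                   seed = seed + 2L, population = "native")
  invasive_occ <- sample_occurrences(invaded_stack, inv_suit, cfg$n_invasive,
                                     seed = seed + 3L,
                                     introduction_cell = cfg$introduction_cell,
                                     spread_rate = cfg$spread_rate,
                                     years = cfg$years, population = "invasive")
  structure(list(
    native_stack = native_stack, invaded_stack = invaded_stack,
    native_niche = native_niche, invaded_niche = invaded_niche,
    shift_delta = delta, native_suitability = nat_suit,
    invaded_suitability = inv_suit, native_occ = native_occ,
    invasive_occ = invasive_occ, introduction_cell = cfg$introduction_cell,
    spread_rate = cfg$spread_rate, years = cfg$years, seed = seed,
    config = cfg), class = "invasion_scenario")
}
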