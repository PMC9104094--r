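pipeline_stages <- c("synth", "preprocess", "envspace", "niche", "sdm", "report")

default_config <- function() list(
  scenario = NULL, inputs = NULL,
  preprocess = list(cell_size = NULL, corr_threshold = 0.70, priority = NULL),
  envspace = list(grid_resolution = 100L, bandwidth = NULL, pad = 0.05),
  niche = list(n_perm = 99L, quantiles = c(0, 0.1, 0.2), esu_threshold = 0,
               intersect_quantile = 0),
  sdm = list(enabled = TRUE, reps = 10L, ratio = 5L, train_fraction = 0.75,
             algorithms = sdm_algorithms),
  seed = 1L, outdir = NULL)

merge_config <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults) && !identical(path, "scenario") &&
        !identical(path, "inputs"))
      stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]))
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]], full)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' @param config a YAML file path or a named list. Keys outside the documented
#'   schema are rejected rather than silently ignored. Exactly one of
#'   `scenario` (a synthetic-scenario block, see [make_invasion_scenario()])
#'   or `inputs` (paths `native_stack`, `invaded_stack`, `native_occ`,
#'   `invasive_occ`) must be present.
#' @return The validated, fully-defaulted config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- default_config()
  # scenario / inputs blocks have open schemas; validate their presence only
  cfg <- merge_config(config, defaults)
  has_scen <- !is.null(cfg$scenario); has_inp <- !is.null(cfg$inputs)
  if (has_scen == has_inp)
    stop("config must contain exactly one of 'scenario' or 'inputs'")
  if (has_inp) {
    missing <- setdiff(c("native_stack", "invaded_stack", "native_occ",
                         "invasive_occ"), names(cfg$inputs))
    if (length(missing))
      stop("inputs block lacks: ", paste(missing, collapse = ", "))
  }
  if (is.null(cfg$outdir)) stop("config must set an output directory (outdir)")
  stopifnot(cfg$preprocess$corr_threshold > 0, cfg$preprocess$corr_threshold <= 1,
            cfg$envspace$grid_resolution >= 10, cfg$niche$n_perm >= 19,
            cfg$sdm$train_fraction > 0, cfg$sdm$train_fraction < 1,
            cfg$sdm$ratio >= 1)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

out_path <- function(cfg, ...) {
  p <- file.path(cfg$outdir, ...)
  dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
  p
}

log_msg <- function(cfg, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  message(line)
  cat(line, "\n", file = out_path(cfg, "pipeline.log"), append = TRUE)
}

# ---- stages -----------------------------------------------------------------

stage_synth <- function(cfg) {
  if (is.null(cfg$scenario)) {
    log_msg(cfg, "synth: using user-supplied inputs, nothing to generate")
    return(invisible(NULL))
  }
  scen <- cfg$scenario
  scen$seed <- child_seed(cfg$seed, "synth")
  sc <- make_invasion_scenario(scen)
  write_env_stack(sc$native_stack, out_path(cfg, "data", "native_stack"))
  write_env_stack(sc$invaded_stack, out_path(cfg, "data", "invaded_stack"))
  write_occurrences(sc$native_occ, out_path(cfg, "data", "native_occ.csv"))
  write_occurrences(sc$invasive_occ, out_path(cfg, "data", "invasive_occ.csv"))
  log_msg(cfg, "synth: scenario seed %d, %d native / %d invasive records",
          sc$seed, nrow(sc$native_occ), nrow(sc$invasive_occ))
  invisible(sc)
}

load_inputs <- function(cfg) {
  p <- if (!is.null(cfg$inputs)) cfg$inputs else list(
    native_stack = out_path(cfg, "data", "native_stack"),
    invaded_stack = out_path(cfg, "data", "invaded_stack"),
    native_occ = out_path(cfg, "data", "native_occ.csv"),
    invasive_occ = out_path(cfg, "data", "invasive_occ.csv"))
  list(native_stack = read_env_stack(p$native_stack),
       invaded_stack = read_env_stack(p$invaded_stack),
       native_occ = read_occurrences(p$native_occ),
       invasive_occ = read_occurrences(p$invasive_occ))
}

stage_preprocess <- function(cfg) {
  inp <- load_inputs(cfg)
  cs <- cfg$preprocess$cell_size
  if (is.null(cs)) cs <- inp$native_stack$cell_size
  nat <- rarefy_occurrences(inp$native_occ, inp$native_stack, cs)
  inv <- rarefy_occurrences(inp$invasive_occ, inp$invaded_stack, cs)
  bg <- rbind(stack_values_table(inp$native_stack)[inp$native_stack$layer_names],
              stack_values_table(inp$invaded_stack)[inp$invaded_stack$layer_names])
  priority <- cfg$preprocess$priority
  if (is.null(priority)) priority <- inp$native_stack$layer_names
  kept <- filter_correlated(bg, cfg$preprocess$corr_threshold, priority)
  write_occurrences(nat, out_path(cfg, "preprocess", "native_occ_rarefied.csv"))
  write_occurrences(inv, out_path(cfg, "preprocess", "invasive_occ_rarefied.csv"))
  writeLines(kept, out_path(cfg, "preprocess", "kept_layers.txt"))
  log_msg(cfg,
    "preprocess: rarefied to %d native / %d invasive records (cell %g); kept %d/%d layers (r < %g)",
    nrow(nat), nrow(inv), cs, length(kept), ncol(bg), cfg$preprocess$corr_threshold)
  invisible(list(native = nat, invasive = inv, kept_layers = kept))
}

subset_layers <- function(stack, layers) {
  idx <- match(layers, stack$layer_names)
  env_stack(stack$values[, , idx, drop = FALSE], layers,
            stack$cell_size, stack$origin, stack$valid_mask)
}

load_preprocessed <- function(cfg) {
  inp <- load_inputs(cfg)
  kept <- readLines(out_path(cfg, "preprocess", "kept_layers.txt"))
  list(native_stack = subset_layers(inp$native_stack, kept),
       invaded_stack = subset_layers(inp$invaded_stack, kept),
       native_occ = read_occurrences(out_path(cfg, "preprocess",
                                              "native_occ_rarefied.csv")),
       invasive_occ = read_occurrences(out_path(cfg, "preprocess",
                                                "invasive_occ_rarefied.csv")))
}

env_space_objects <- function(cfg) {
  pre <- load_preprocessed(cfg)
  nat_bg <- stack_values_table(pre$native_stack)[pre$native_stack$layer_names]
  inv_bg <- stack_values_table(pre$invaded_stack)[pre$invaded_stack$layer_names]
  pca <- fit_pca_env(list(nat_bg, inv_bg))
  sc <- list(nat_bg = project_env(pca, nat_bg),
             inv_bg = project_env(pca, inv_bg),
             nat_occ = project_env(pca, extract_env_at_points(pre$native_stack,
                                                              pre$native_occ)),
             inv_occ = project_env(pca, extract_env_at_points(pre$invaded_stack,
                                                              pre$invasive_occ)))
  grid <- env_grid(list(sc$nat_bg, sc$inv_bg),
                   R = cfg$envspace$grid_resolution, pad = cfg$envspace$pad)
  bw <- cfg$envspace$bandwidth
  if (!is.null(bw)) bw <- as.numeric(bw)
  list(pre = pre, pca = pca, scores = sc, grid = grid,
       native_grid = build_density_grid(sc$nat_occ, sc$nat_bg, grid, bw, "native"),
       invasive_grid = build_density_grid(sc$inv_occ, sc$inv_bg, grid, bw, "invasive"),
       mess = mess(nat_bg, inv_bg), bandwidth = bw)
}

stage_envspace <- function(cfg) {
  es <- env_space_objects(cfg)
  for (nm in names(es$scores))
    utils::write.csv(es$scores[[nm]],
                     out_path(cfg, "envspace", paste0("scores_", nm, ".csv")),
                     row.names = FALSE)
  grid_meta <- list(
    xlim = es$grid$xlim, ylim = es$grid$ylim, R = es$grid$R,
    variance_explained = as.numeric(es$pca$variance_explained),
    mess_fraction_nonnegative = es$mess$fraction_nonnegative,
    bandwidth_occ_native = as.numeric(es$native_grid$bandwidth_occ),
    bandwidth_occ_invasive = as.numeric(es$invasive_grid$bandwidth_occ))
  yaml::write_yaml(grid_meta, out_path(cfg, "envspace", "envspace.yml"))
  for (ent in c("native", "invasive")) {
    g <- es[[paste0(ent, "_grid")]]
    for (surf in c("o", "e", "z"))
      utils::write.csv(g[[surf]],
                       out_path(cfg, "envspace", sprintf("%s_%s.csv", ent, surf)),
                       row.names = FALSE)
  }
  log_msg(cfg,
    "envspace: PCA axes explain %.1f%% + %.1f%%; MESS non-negative fraction %.4f; occurrence bandwidths logged",
    100 * es$pca$variance_explained[1], 100 * es$pca$variance_explained[2],
    es$mess$fraction_nonnegative)
  invisible(es)
}

stage_niche <- function(cfg) {
  es <- env_space_objects(cfg)
  seed <- child_seed(cfg$seed, "niche")
  q0 <- cfg$niche$intersect_quantile
  sweep_tbl <- marginality_sweep(es$native_grid, es$invasive_grid,
                                 cfg$niche$quantiles, cfg$niche$esu_threshold)
  sweep_tbl$population <- "invasive"
  eq <- equivalency_test(es$scores$nat_occ, es$scores$inv_occ,
                         rbind(es$scores$nat_bg, es$scores$inv_bg),
                         n_perm = cfg$niche$n_perm, seed = seed,
                         grid = es$grid, bandwidth = es$bandwidth)
  sim <- similarity_test(es$native_grid, es$invasive_grid,
                         n_perm = cfg$niche$n_perm, seed = seed + 1L)
  sim_rev <- similarity_test(es$invasive_grid, es$native_grid,
                             n_perm = cfg$niche$n_perm, seed = seed + 2L)
  perm_tbl <- data.frame(
    kind = c("equivalency", "similarity_inv_vs_nat", "similarity_nat_vs_inv"),
    observed_D = c(eq$observed_D, sim$observed_D, sim_rev$observed_D),
    p_value = c(eq$p_value, sim$p_value, sim_rev$p_value),
    n_perm = cfg$niche$n_perm, seed = c(seed, seed + 1L, seed + 2L))
  occ <- attr(extract_env_at_points(es$pre$invaded_stack, es$pre$invasive_occ),
              "occurrences")
  temporal <- NULL
  if (any(!is.na(occ$year))) {
    dated <- !is.na(occ$year)
    log_msg(cfg, "niche: %d undated invasive record(s) excluded from the temporal series",
            sum(!dated))
    temporal <- temporal_dynamics(es$native_grid, es$scores$inv_occ[dated, , drop = FALSE],
                                  occ$year[dated], es$scores$inv_bg, q0)
    temporal$population <- "invasive"
    utils::write.csv(temporal, out_path(cfg, "niche", "temporal_dynamics.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(sweep_tbl, out_path(cfg, "niche", "niche_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(perm_tbl, out_path(cfg, "niche", "permutation_tests.csv"),
                   row.names = FALSE)
  log_msg(cfg,
    "niche: D = %.3f at q = %g; equivalency p = %.3f, similarity p = %.3f (n_perm %d, seed %d)",
    sweep_tbl$D[1], sweep_tbl$intersect_quantile[1], eq$p_value, sim$p_value,
    cfg$niche$n_perm, seed)
  invisible(list(sweep = sweep_tbl, permutations = perm_tbl, temporal = temporal))
}

stage_sdm <- function(cfg) {
  if (!isTRUE(cfg$sdm$enabled)) {
    log_msg(cfg, "sdm: stage disabled in config")
    return(invisible(NULL))
  }
  pre <- load_preprocessed(cfg)
  seed <- child_seed(cfg$seed, "sdm")
  ens_nat <- run_ensemble(pre$native_stack, pre$native_occ,
                          cfg$sdm$algorithms, cfg$sdm$reps,
                          cfg$sdm$train_fraction, cfg$sdm$ratio,
                          seed = seed, dataset = "native")
  ens_inv <- run_ensemble(pre$invaded_stack, pre$invasive_occ,
                          cfg$sdm$algorithms, cfg$sdm$reps,
                          cfg$sdm$train_fraction, cfg$sdm$ratio,
                          seed = seed + 7L, dataset = "invasive")
  nat_on_inv <- project_ensemble(ens_nat, pre$invaded_stack)
  inv_on_nat <- project_ensemble(ens_inv, pre$native_stack)
  risk <- risk_overlay(nat_on_inv$consensus_binary, ens_inv$consensus_binary,
                       pre$invaded_stack$valid_mask)
  runs <- rbind(cbind(dataset = "native", ens_nat$run_table),
                cbind(dataset = "invasive", ens_inv$run_table))
  utils::write.csv(runs, out_path(cfg, "sdm", "sdm_runs.csv"), row.names = FALSE)
  utils::write.csv(data.frame(category = names(risk$shares),
                              share = as.numeric(risk$shares)),
                   out_path(cfg, "sdm", "risk_shares.csv"), row.names = FALSE)
  st <- pre$invaded_stack
  write_ascii_grid(risk$category + 0, out_path(cfg, "sdm", "risk_categories.asc"),
                   st$cell_size, st$origin)
  write_ascii_grid(ens_inv$consensus_binary + 0,
                   out_path(cfg, "sdm", "consensus_invasive.asc"),
                   st$cell_size, st$origin)
  write_ascii_grid(nat_on_inv$consensus_binary + 0,
                   out_path(cfg, "sdm", "consensus_native_projected.asc"),
                   st$cell_size, st$origin)
  log_msg(cfg, "sdm: mean AUC native %.3f / invasive %.3f; high-risk share %.3f",
          mean(ens_nat$run_table$auc), mean(ens_inv$run_table$auc),
          risk$high_risk_share)
  invisible(list(native = ens_nat, invasive = ens_inv, risk = risk,
                 native_on_invaded = nat_on_inv, invasive_on_native = inv_on_nat))
}

stage_report <- function(cfg) {
  read_if <- function(...) {
    p <- out_path(cfg, ...)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  report <- list(
    provenance = list(
      seed = cfg$seed,
      config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))) %% 1e9,
      package_version = as.character(utils::packageVersion("nicheshift")),
      r_version = R.version.string),
    niche_metrics = read_if("niche", "niche_metrics.csv"),
    temporal_dynamics = read_if("niche", "temporal_dynamics.csv"),
    permutation_tests = read_if("niche", "permutation_tests.csv"),
    sdm_runs = read_if("sdm", "sdm_runs.csv"),
    risk_shares = read_if("sdm", "risk_shares.csv"))
  yaml::write_yaml(report, out_path(cfg, "report.yml"))
  log_msg(cfg, "report: written to %s", out_path(cfg, "report.yml"))
  class(report) <- "analysis_report"
  report
}

#' Run the full niche-dynamics pipeline
#'
#' Executes the requested stages in order: synthesize (or ingest) the ranges,
#' rarefy occurrences and filter collinear layers, build the shared
#' environmental space and occupancy surfaces, compute overlap / permutation
#' tests / niche dynamics, fit the reciprocal SDM ensembles and risk overlay,
#' and assemble the report. All intermediate artifacts are persisted as plain
#' CSV / YAML / ASCII-grid files under the configured output directory; a
#' failure in the SDM stage does not discard completed niche-dynamics
#' outputs. Deterministic per config seed (stages derive child seeds by fixed
#' offsets, so single stages can be rerun reproducibly).
#'
#' @param config a YAML path or config list; see [read_pipeline_config()].
#' @param stages subset of stages to run, in pipeline order.
#' @return The `analysis_report` (invisibly, unless the report stage is
#'   excluded, in which case `NULL`).
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  cfg <- read_pipeline_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  report <- NULL
  for (st in pipeline_stages[pipeline_stages %in% stages]) {
    res <- switch(st,
      synth = stage_synth(cfg),
      preprocess = stage_preprocess(cfg),
      envspace = stage_envspace(cfg),
      niche = stage_niche(cfg),
      sdm = tryCatch(stage_sdm(cfg), error = function(e) {
        log_msg(cfg, "sdm: stage failed (%s); niche outputs retained",
                conditionMessage(e))
        NULL
      }),
      report = stage_report(cfg))
    if (st == "report") report <- res
  }
  invisible(report)
}
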