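# Shared scenario -> environmental-space plumbing for the niche tests.

# project a scenario into its shared PCA space and build both density grids
scenario_env_space <- function(sc, R = 100) {
  nat_bg <- stack_values_table(sc$native_stack)[sc$native_stack$layer_names]
  inv_bg <- stack_values_table(sc$invaded_stack)[sc$invaded_stack$layer_names]
  pca <- fit_pca_env(list(nat_bg, inv_bg))
  env_i <- extract_env_at_points(sc$invaded_stack, sc$invasive_occ)
  sc_list <- list(
    nat_occ = project_env(pca, extract_env_at_points(sc$native_stack, sc$native_occ)),
    inv_occ = project_env(pca, env_i),
    nat_bg = project_env(pca, nat_bg),
    inv_bg = project_env(pca, inv_bg))
  grid <- env_grid(list(sc_list$nat_bg, sc_list$inv_bg), R = R)
  list(pca = pca, scores = sc_list, grid = grid,
       inv_years = attr(env_i, "occurrences")$year,
       native_grid = build_density_grid(sc_list$nat_occ, sc_list$nat_bg, grid,
                                        entity = "native"),
       invasive_grid = build_density_grid(sc_list$inv_occ, sc_list$inv_bg, grid,
                                          entity = "invasive"))
}

no_shift_scenario <- function(seed, n = 1000)
  make_invasion_scenario(list(seed = seed, identical_stacks = TRUE,
                              n_native = n, n_invasive = n))

shift_scenario <- function(seed)
  make_invasion_scenario(list(seed = seed, identical_stacks = TRUE,
                              shift_delta_sd = -1.5, native_breadth_sd = 0.35))

spread_scenario <- function(seed)
  make_invasion_scenario(list(seed = seed, identical_stacks = TRUE,
                              years = 2014:2017, spread_rate = 6,
                              n_invasive = 300))

# specialist niche for the SDM ground-truth checks
sdm_scenario <- function(seed)
  make_invasion_scenario(list(seed = seed, identical_stacks = TRUE,
                              native_breadth_sd = 0.3,
                              n_native = 150, n_invasive = 200))

presence_coverage <- function(consensus, stack, occ) {
  ij <- nicheshift:::point_cell(stack, occ$x, occ$y)
  mean(consensus[ij])
}
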