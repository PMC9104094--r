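# Private seeded RNG stream: draws are reproducible per seed and do not
# disturb (or depend on) the caller's global RNG state.
local_rng <- function(seed) {
  state <- NULL
  run <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(as.integer(seed)) else
      assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    rnorm  = function(...) run(function() stats::rnorm(...)),
    runif  = function(...) run(function() stats::runif(...)),
    sample = function(n, size = n, replace = FALSE, prob = NULL)
      run(function() sample.int(n, size, replace = replace, prob = prob))
  )
}

# per-stage child seeds derived from one pipeline seed by fixed offsets,
# kept well inside 32-bit integer range
child_seed <- function(seed, stage) {
  offsets <- c(synth = 0L, preprocess = 101L, envspace = 211L,
               niche = 307L, sdm = 401L, report = 503L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) + offsets[[stage]]) %% 2147483647)
}
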