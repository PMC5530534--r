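# Shared fixtures, built in code. The cached experiment is small enough
# for quick model fits but keeps the full alpha-lattice structure.

fixture_env <- new.env()

small_experiment <- function() {
  if (is.null(fixture_env$exp)) {
    cfg <- sim_config(n_trials = 3L, n_bands = 25L, seed = 42L)
    fixture_env$exp <- simulate_experiment(cfg)
  }
  fixture_env$exp
}

small_second_stage <- function() {
  if (is.null(fixture_env$ss)) {
    exp <- small_experiment()
    s1 <- stage_one(exp$plot_table, band_varcomps = "share_yield")
    fixture_env$ss <- assemble_second_stage(s1)
  }
  fixture_env$ss
}

# direct cell-level data with a known functional signal
cell_level_sim <- function() {
  if (is.null(fixture_env$cell)) {
    cfg <- sim_config(n_trials = 4L, n_bands = 30L, seed = 7L)
    fixture_env$cell <- simulate_second_stage(cfg)
  }
  fixture_env$cell
}

quick_control <- function(iterations = 1500L, burn_in = 500L, seed = 1L) {
  sampler_control(iterations, burn_in, thin = 1L, seed = seed)
}
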