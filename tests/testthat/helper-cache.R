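# shared fixtures: the baseline model and memoised long simulations, so the
# expensive control runs and phase sweeps are computed once per test session
.sw_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sw_cache))
    assign(key, force(expr), envir = .sw_cache)
  get(key, envir = .sw_cache)
}

sw_model <- function() cached("model", build_model(baseline_config()))

control_run <- function(mode, t = 25000) {
  cached(paste0("control_", mode, "_", t),
         simulate_scenario(sw_model(), t_span = t, mode = mode))
}

control_gait <- function(mode) {
  cached(paste0("gait_", mode),
         summarize_gait(control_run(mode), window = c(10000, 25000)))
}

# sweep of the front-leg drive decoupling; n chooses the onset grid
fl_drive_sweep <- function(mode, n) {
  cached(paste0("sweep_", mode, "_", n),
         sweep_command_phase(sw_model(), decouple_cpg_drive("FL", "lift"),
                             n_phases = n, mode = mode))
}
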