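# Presets, batteries and magnitude sweeps are reused across test files;
# compute them once per session on first use.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

get_preset <- function(name) cached(paste0("preset_", name), load_preset(name))

get_battery <- function(name) cached(paste0("battery_", name),
                                     run_battery(get_preset(name)))

get_sweep <- function(name, mags = c(2, 3, 4)) {
  cached(paste0("sweep_", name), {
    p <- get_preset(name)
    lapply(mags, function(m) {
      simulate_condition(
        p, apply_scenario(p$reflex,
                          scenario_spec("imbalanced_sensitivity", "force", m)),
        label = sprintf("imbalanced_force_x%g", m))
    })
  })
}

# mean of a column over [t0, t1]
wmean <- function(sim, t0, t1, col = "theta") {
  d <- sim$data
  mean(d[[col]][d$t >= t0 & d$t <= t1])
}
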