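# Simulated runs are the expensive shared resource of this suite; cache them
# per (site, scenario) so test files can reuse the same trajectories.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(site_name, kind, n_years, seed, delta = 0,
                       ramp_rate = 0.6, precip = 1, co2 = 1) {
  key <- paste(site_name, kind, n_years, seed, delta, ramp_rate, precip, co2,
               sep = "|")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  s <- site_preset(site_name)
  sc <- switch(kind,
    control = scenario_spec("control", n_years = n_years, seed = seed),
    step = scenario_spec("step", n_years = n_years, step_delta_air = delta,
                         seed = seed),
    ramp = scenario_spec("ramp", n_years = n_years, ramp_rate = ramp_rate,
                         precip_multiplier_end = precip,
                         co2_fertilization_end = co2, seed = seed)
  )
  .run_cache[[key]] <- simulate_ecosystem(s, sc)
  .run_cache[[key]]
}

# the paired step/control and ramp/control ensembles used by several files
step_pair <- function(site_name, seed = 11, n_years = 10) {
  s <- site_preset(site_name)
  list(control = cached_run(site_name, "control", n_years, seed),
       step = cached_run(site_name, "step", n_years, seed,
                         delta = s$default_step_delta))
}

ramp_pair <- function(site_name, seed = 12, ff = TRUE) {
  list(control = cached_run(site_name, "control", 100, seed),
       ramp = if (ff)
         cached_run(site_name, "ramp", 100, seed, precip = 1.25, co2 = 1.35)
       else cached_run(site_name, "ramp", 100, seed))
}
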