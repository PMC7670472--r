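#' Forcing scenario specification
#'
#' Declares the perturbation design applied to a site archetype. Three kinds
#' are supported:
#'
#' * `control` — no perturbation; the baseline every analysis compares to.
#' * `step` — chamber-style step warming: `step_delta_air` degC added to air
#'   temperature uniformly from the scenario start (default 10-year design).
#' * `ramp` — monotonic warming at `ramp_rate` degC per decade (default
#'   0.6 degC/decade, the observed high-latitude rate of roughly twice the
#'   global average), optionally with end-of-run precipitation and CO2
#'   fertilization multipliers (the fully-forced variant of the
#'   high-emissions pathway; with both at 1 the ramp is temperature-only).
#'
#' @param kind One of `"control"`, `"step"`, `"ramp"`.
#' @param start_year Calendar year of the first simulated day.
#' @param n_years Simulation length in years (365-day years).
#' @param step_delta_air Step magnitude in degC (step only), in `[0, 5]`.
#' @param ramp_rate Warming rate in degC per decade (ramp only), in `[0, 2]`.
#' @param precip_multiplier_end Multiplier on the precipitation index reached
#'   at the end of a ramp run (linearly interpolated from 1).
#' @param co2_fertilization_end Multiplier on potential photosynthesis reached
#'   at the end of a ramp run (linearly interpolated from 1).
#' @param seed Integer seed for the weather-noise stream.
#'
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("ramp", n_years = 100, ramp_rate = 0.6, seed = 1)
scenario_spec <- function(kind = c("control", "step", "ramp"),
                          start_year = 2001,
                          n_years = 10,
                          step_delta_air = 0,
                          ramp_rate = 0,
                          precip_multiplier_end = 1,
                          co2_fertilization_end = 1,
                          seed = 1L) {
  kind <- match.arg(kind)
  if (n_years < 1) stop("scenario_spec: n_years must be >= 1", call. = FALSE)
  if (step_delta_air < 0 || step_delta_air > 5)
    stop("scenario_spec: step_delta_air must lie in [0, 5] degC", call. = FALSE)
  if (ramp_rate < 0 || ramp_rate > 2)
    stop("scenario_spec: ramp_rate must lie in [0, 2] degC/decade", call. = FALSE)
  if (kind == "control" &&
      (step_delta_air != 0 || ramp_rate != 0 ||
       precip_multiplier_end != 1 || co2_fertilization_end != 1))
    stop("scenario_spec: control scenarios must keep all perturbation fields ",
         "at identity values", call. = FALSE)
  if (kind == "step" && (ramp_rate != 0 || precip_multiplier_end != 1 ||
                         co2_fertilization_end != 1))
    stop("scenario_spec: step scenarios perturb air temperature only",
         call. = FALSE)
  if (kind == "ramp" && step_delta_air != 0)
    stop("scenario_spec: ramp scenarios do not take step_delta_air",
         call. = FALSE)
  structure(
    list(kind = kind, start_year = as.integer(start_year),
         n_years = as.integer(n_years),
         step_delta_air = step_delta_air, ramp_rate = ramp_rate,
         precip_multiplier_end = precip_multiplier_end,
         co2_fertilization_end = co2_fertilization_end,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$kind, ": ", x$n_years, " yr from ", x$start_year,
      ", seed ", x$seed, "\n", sep = "")
  if (x$kind == "step") cat("  step_delta_air ", x$step_delta_air, " degC\n", sep = "")
  if (x$kind == "ramp")
    cat("  ramp_rate ", x$ramp_rate, " degC/decade; precip x",
        x$precip_multiplier_end, ", CO2 x", x$co2_fertilization_end,
        " at end\n", sep = "")
  invisible(x)
}
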