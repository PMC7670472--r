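#' Generate daily atmospheric forcing for a site and scenario
#'
#' Builds the daily air-temperature, precipitation-index, and CO2-multiplier
#' series that drive the simulator: a sinusoidal annual cycle around the site
#' mean, the scenario trend (step offset or linear ramp), and seeded AR(1)
#' weather noise. Deterministic given `scenario$seed`.
#'
#' @param site A [site_preset()].
#' @param scenario A [scenario_spec()].
#' @param noise_sd Standard deviation (degC) of the AR(1) daily noise;
#'   defaults to the preset value. Set to 0 for a noise-free sinusoid.
#'
#' @return A tibble with columns `day` (1-based index), `year` (calendar),
#'   `doy`, `air_temp` (degC), `precip_index` (dimensionless multiplier), and
#'   `co2_mult` (multiplier on potential photosynthesis).
#' @export
#' @examples
#' f <- make_forcing(site_preset("foothills-tundra"),
#'                   scenario_spec("control", n_years = 2, seed = 3))
#' mean(f$air_temp)
make_forcing <- function(site, scenario, noise_sd = site$noise_sd) {
  stopifnot(inherits(site, "site_preset"), inherits(scenario, "scenario_spec"))
  nd <- scenario$n_years * 365L
  day <- seq_len(nd)
  doy <- ((day - 1L) %% 365L) + 1L
  yr_frac <- (day - 0.5) / 365
  year <- scenario$start_year + (day - 1L) %/% 365L

  seasonal <- site$mean_annual_air_temp -
    site$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365)

  trend <- switch(scenario$kind,
    control = rep(0, nd),
    step = rep(scenario$step_delta_air, nd),
    ramp = scenario$ramp_rate * yr_frac / 10,
    stop("make_forcing: unknown scenario kind '", scenario$kind, "'",
         call. = FALSE)
  )

  noise <- if (noise_sd > 0) {
    phi <- site$noise_phi
    with_seed(scenario$seed, {
      z <- rnorm(nd, sd = noise_sd * sqrt(1 - phi^2))
      as.numeric(stats::filter(z, phi, method = "recursive"))
    })
  } else {
    rep(0, nd)
  }

  frac_through <- if (nd > 1) (day - 1) / (nd - 1) else rep(0, nd)
  precip_index <- if (scenario$kind == "ramp") {
    1 + (scenario$precip_multiplier_end - 1) * frac_through
  } else rep(1, nd)
  co2_mult <- if (scenario$kind == "ramp") {
    1 + (scenario$co2_fertilization_end - 1) * frac_through
  } else rep(1, nd)

  out <- tibble::tibble(day = day, year = year, doy = doy,
                        air_temp = seasonal + trend + noise,
                        precip_index = precip_index, co2_mult = co2_mult)
  attr(out, "scenario_seed") <- scenario$seed
  out
}
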