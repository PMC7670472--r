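#' Site archetype presets
#'
#' Four site archetypes spanning the Alaskan permafrost-to-boreal gradient
#' ship with the package. Each preset bundles the climate, soil-column, and
#' ecophysiological parameters of the reduced-complexity simulator:
#'
#' * `cold-coastal-tundra` — very cold coastal plain over continuous
#'   permafrost; short cool growing season; shallow active layer that deepens
#'   but never clears 0.6 m. The sink-transition archetype: a carbon source
#'   under decade-scale step warming (fast heterotroph response), a carbon
#'   sink under the century ramp (large vegetation headroom).
#' * `foothills-tundra` — continuous permafrost with warmer summers. The
#'   source archetype: loses carbon under both step and ramp warming, but the
#'   long-term loss per degree-year is far smaller than the short-term one
#'   because vegetation partly compensates while deep thaw keeps the column
#'   losing.
#' * `discontinuous-permafrost-tundra` — moist acidic tundra over
#'   discontinuous permafrost with a thaw front near 1 m; short-term source,
#'   near neutral-to-sink under the fully forced century ramp, with strong
#'   thaw-driven deep turnover.
#' * `boreal-forest` — upland boreal forest, little/no near-surface
#'   permafrost; temperature-saturated vegetation and high decomposition
#'   sensitivity make it a persistent, monotonic source.
#'
#' The soil column resolves four depths (0.1, 0.6, 1.0 and 1.7 m), the depths
#' at which the depth-resolved temperature-sensitivity metric is evaluated.
#'
#' @param name One of the four archetype names (see above).
#'
#' @return An object of class `site_preset`: a named list with fields
#'   `name`, `mean_annual_air_temp` (degC), `seasonal_amplitude` (degC),
#'   `initial_soc_per_layer` (g C m-2), `layer_depths` (m), `q10`,
#'   `base_decomp_rate` (yr-1 per layer), `litter_fraction`,
#'   `veg_response_timescale` (yr), `nutrient_halfsat` (g N m-2),
#'   `stefan_coeff` (m per sqrt(degC day)), `moisture_baseline` (saturation
#'   fraction) plus internal ecophysiological constants.
#' @export
#' @examples
#' site_preset("cold-coastal-tundra")$layer_depths
site_preset <- function(name = site_preset_names()) {
  name <- match.arg(name)
  base <- list(
    name = name,
    layer_depths = c(0.1, 0.6, 1.0, 1.7),
    # soil thermal coupling: first-order filter time constants (days) and
    # air-coupling gains per layer; deeper layers are slower and more damped
    soil_tau = c(3, 20, 45, 90),
    soil_gain = c(1.0, 0.8, 0.6, 0.4),
    deep_offset = 1.5,           # degC added to MAAT for the deep boundary
    q10 = 2.0,
    tref = 10,                   # degC reference for the Q10 law
    litter_fraction = 0.55,      # of NPP, routed to surface SOC
    root_fraction = 0.05,        # of NPP, routed to the deepest thawed layer
    npp_fraction = 0.5,          # NPP:GPP ratio
    veg_response_timescale = 15, # yr, vegetation turnover/response
    nutrient_halfsat = 1.0,      # g N m-2, Michaelis-Menten half-saturation
    n_min_frac = 0.012,          # g N mineralized per g C respired
    n_uptake_frac = 0.012,       # g N taken up per g C of NPP
    photo_t_half = 8,            # degC half-saturation of photosynthesis
    clim_memory_yr = 6,          # yr, canopy climate-memory timescale
    photo_pmax = 12,             # g C m-2 d-1 canopy-max GPP (times gpp_scale)
    veg_halfsat = 200,           # g C m-2 half-saturation of canopy closure
    n_dep = 0.12,                # g N m-2 yr-1 fixed input (deposition/fixation)
    n_leach = 0.08,              # yr-1 first-order mineral-N loss
    moisture_baseline = 0.6,
    moisture_opt = 0.6,
    stefan_coeff = 0.026,
    noise_sd = 2.5,              # degC daily AR(1) weather noise
    noise_phi = 0.8,
    snow_accum = 0.004,          # m snow depth per cold day
    snow_melt = 0.003,           # m per degC-day above freezing
    initial_veg_c = 250,         # g C m-2
    initial_n = 1.0,             # g N m-2
    default_step_delta = 0.9     # degC, site-typical chamber warming
  )
  tweaks <- switch(name,
    "cold-coastal-tundra" = list(
      mean_annual_air_temp = -12, seasonal_amplitude = 18,
      initial_soc_per_layer = c(9000, 14000, 12000, 10000),
      q10 = 2.2, photo_t_half = 14, nutrient_halfsat = 1.6, stefan_coeff = 0.016,
      clim_memory_yr = 10,
      gpp_scale = 1.0, default_step_delta = 0.85,
      photo_pmax = 117.46, base_decomp_rate = c(0.0445381, 0.004, 0.002, 0.001),
      initial_veg_c = 360, veg_halfsat = 360, initial_n = 1.6, n_dep = 0.128
    ),
    "foothills-tundra" = list(
      mean_annual_air_temp = -8, seasonal_amplitude = 17,
      initial_soc_per_layer = c(10000, 15000, 13000, 11000),
      q10 = 2.2, photo_t_half = 16, nutrient_halfsat = 0.8, stefan_coeff = 0.027,
      gpp_scale = 1.0, default_step_delta = 1.1,
      photo_pmax = 81.137, base_decomp_rate = c(0.0351687, 0.00121494, 0.012, 0.005),
      initial_veg_c = 540, veg_halfsat = 540, initial_n = 0.8, n_dep = 0.064
    ),
    "discontinuous-permafrost-tundra" = list(
      mean_annual_air_temp = -4, seasonal_amplitude = 16,
      initial_soc_per_layer = c(11000, 16000, 14000, 9000),
      q10 = 1.8, photo_t_half = 15, nutrient_halfsat = 1.4, stefan_coeff = 0.030,
      gpp_scale = 1.1, default_step_delta = 0.35,
      photo_pmax = 58.5912, base_decomp_rate = c(0.0329924, 0.000892501, 0.000911138, 0.005),
      initial_veg_c = 840, veg_halfsat = 840, initial_n = 1.4, n_dep = 0.112
    ),
    "boreal-forest" = list(
      mean_annual_air_temp = -2, seasonal_amplitude = 19,
      initial_soc_per_layer = c(7000, 10000, 8000, 6000),
      q10 = 2.8, photo_t_half = 4, nutrient_halfsat = 0.6, stefan_coeff = 0.050,
      gpp_scale = 1.6, default_step_delta = 0.9,
      photo_pmax = 26.6106, base_decomp_rate = c(0.0577388, 0.00040248, 0.00174687, 0.00605445),
      initial_veg_c = 1500, veg_halfsat = 1500, initial_n = 0.6, n_dep = 0.048
    )
  )
  preset <- utils::modifyList(base, tweaks)
  validate_site_preset(preset)
  structure(preset, class = "site_preset")
}

#' @rdname site_preset
#' @export
site_preset_names <- function() {
  c("cold-coastal-tundra", "foothills-tundra",
    "discontinuous-permafrost-tundra", "boreal-forest")
}

#' @rdname site_preset
#' @export
site_presets <- function() {
  setNames(lapply(site_preset_names(), site_preset), site_preset_names())
}

validate_site_preset <- function(p) {
  stopifnot(
    all(diff(p$layer_depths) > 0), all(p$layer_depths > 0),
    all(p$initial_soc_per_layer >= 0),
    p$q10 >= 1,
    p$litter_fraction >= 0, p$litter_fraction <= 1,
    p$litter_fraction + p$root_fraction <= 1,
    length(p$base_decomp_rate) == length(p$layer_depths),
    all(p$base_decomp_rate >= 0),
    p$veg_response_timescale > 0, p$nutrient_halfsat > 0,
    p$stefan_coeff > 0,
    p$moisture_baseline > 0, p$moisture_baseline < 1
  )
  invisible(p)
}

#' @export
print.site_preset <- function(x, ...) {
  cat("<site_preset> ", x$name, "\n", sep = "")
  cat("  MAAT ", x$mean_annual_air_temp, " degC, amplitude ",
      x$seasonal_amplitude, " degC, Q10 ", x$q10, "\n", sep = "")
  cat("  SOC per layer (g C m-2): ",
      paste(x$initial_soc_per_layer, collapse = ", "), "\n", sep = "")
  invisible(x)
}
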