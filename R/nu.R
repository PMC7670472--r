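#' Emergent temperature sensitivity of SOC from paired runs
#'
#' Computes the depth-resolved emergent temperature sensitivity of soil
#' organic carbon between a perturbed and a baseline run:
#'
#' \deqn{\nu = \frac{(C_p - C_b)/\Delta T}{\Delta t}}
#'
#' where `C_p` and `C_b` are the end-of-window SOC stocks (g C m-2) at the
#' requested depth in the perturbed and baseline runs (both started from the
#' same initial condition), `delta_t_soil` is the window-mean soil-temperature
#' difference (perturbed minus baseline, degC) at that depth, and
#' `delta_years` is the window length. A negative value means the layer is
#' losing carbon per degree of soil warming per year; a positive value means
#' it is gaining.
#'
#' Windows are given as year boundaries `c(start, end)`: the window covers
#' calendar years `start + 1` through `end`, so `c(2090, 2100)` is the final
#' decade of a run ending in 2100 and `delta_years = end - start`.
#'
#' A layer that is permafrost (never biogeochemically active) in both runs
#' throughout the window cannot change its stock; such cells are reported
#' with `frozen = TRUE` and `nu = 0` rather than as a 0/0 artefact. A
#' non-frozen cell whose temperature contrast is below `eps_t` is flagged
#' `valid = FALSE` (dividing by noise is meaningless) and `nu` is `NA`.
#'
#' @param perturbed,baseline `ecosystem_run` objects sharing site, calendar,
#'   and depth grid.
#' @param depth Soil depth in metres; must match a layer of the site preset.
#' @param window Length-2 numeric, year boundaries `c(start, end)`.
#' @param eps_t Minimum absolute window-mean temperature difference (degC)
#'   for a valid ratio. Default 0.01.
#'
#' @return A one-row tibble with columns `nu` (g C m-2 degC-1 yr-1), `c_p`,
#'   `c_b` (g C m-2), `delta_t_soil` (degC), `delta_years` (yr), `depth` (m),
#'   `window_start`, `window_end`, `frozen`, `valid`, `reason`.
#' @export
#' @examples
#' # arithmetic helper: a 10-yr loss of 90 g C m-2 under +1.1 degC soil warming
#' nu_from_stocks(c_p = -90, c_b = 0, delta_t = 1.1, delta_years = 10)
compute_nu <- function(perturbed, baseline, depth, window, eps_t = 0.01) {
  stopifnot(inherits(perturbed, "ecosystem_run"),
            inherits(baseline, "ecosystem_run"),
            length(window) == 2, window[2] > window[1])
  check_run_compat(perturbed, baseline)
  l <- layer_index(perturbed, depth)
  days_p <- perturbed$year > window[1] & perturbed$year <= window[2]
  days_b <- baseline$year > window[1] & baseline$year <= window[2]
  if (!any(days_p) || !any(days_b))
    stop("compute_nu: window (", window[1], ", ", window[2],
         "] lies outside the simulated years", call. = FALSE)

  end_p <- max(which(days_p))
  end_b <- max(which(days_b))
  c_p <- perturbed$soc[end_p, l]
  c_b <- baseline$soc[end_b, l]
  delta_t <- mean(perturbed$soil_temp[days_p, l]) -
    mean(baseline$soil_temp[days_b, l])
  delta_years <- window[2] - window[1]

  frozen <- !any(layer_active(perturbed, l)[days_p]) &&
    !any(layer_active(baseline, l)[days_b])

  if (frozen) {
    nu <- 0
    valid <- TRUE
    reason <- NA_character_
  } else if (abs(delta_t) < eps_t) {
    nu <- NA_real_
    valid <- FALSE
    reason <- "temperature change below tolerance"
  } else {
    nu <- ((c_p - c_b) / delta_t) / delta_years
    valid <- TRUE
    reason <- NA_character_
  }

  tibble::tibble(nu = nu, c_p = c_p, c_b = c_b, delta_t_soil = delta_t,
                 delta_years = delta_years, depth = depth,
                 window_start = window[1], window_end = window[2],
                 frozen = frozen, valid = valid, reason = reason)
}

#' @rdname compute_nu
#' @param windows A list of year-boundary windows.
#' @return For `nu_profile()`: a tibble with one row per depth x window, the
#'   full grid over the site's layer depths (cells that cannot be computed
#'   carry their validity flags rather than aborting the grid).
#' @export
nu_profile <- function(perturbed, baseline, windows, eps_t = 0.01) {
  if (!is.list(windows)) windows <- list(windows)
  depths <- perturbed$site$layer_depths
  grid <- expand.grid(d = seq_along(depths), w = seq_along(windows))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    compute_nu(perturbed, baseline, depths[grid$d[i]],
               windows[[grid$w[i]]], eps_t = eps_t)
  })
  out <- do.call(rbind, rows)
  out$scenario <- perturbed$scenario$kind
  out
}

#' @rdname compute_nu
#' @param c_p,c_b Perturbed and baseline stocks; `delta_t` soil temperature
#'   difference (degC); `delta_years` window length (yr).
#' @param units `"g"` (default) or `"kg"`; stocks in kg C m-2 are converted
#'   to g C m-2 so that `nu` is always in g C m-2 degC-1 yr-1.
#' @export
nu_from_stocks <- function(c_p, c_b, delta_t, delta_years,
                           units = c("g", "kg")) {
  units <- match.arg(units)
  scale <- if (units == "kg") 1000 else 1
  ((c_p - c_b) * scale / delta_t) / delta_years
}

layer_index <- function(run, depth) {
  l <- which(abs(run$site$layer_depths - depth) < 1e-9)
  if (length(l) != 1)
    stop("compute_nu: depth ", depth, " m is not on the layer grid (",
         paste(run$site$layer_depths, collapse = ", "), ")", call. = FALSE)
  l
}

layer_active <- function(run, l) {
  (run$ald >= run$site$layer_depths[l]) & (run$soil_temp[, l] > 0)
}

check_run_compat <- function(a, b) {
  if (!identical(a$site$layer_depths, b$site$layer_depths))
    stop("runs have mismatched depth grids", call. = FALSE)
  if (!identical(a$site$name, b$site$name))
    stop("runs come from different site presets", call. = FALSE)
  if (!identical(a$year[1], b$year[1]))
    stop("runs have mismatched calendars", call. = FALSE)
  invisible(TRUE)
}
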