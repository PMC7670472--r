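#' Write and read simulated runs as tidy CSV + JSON sidecar
#'
#' A run is serialized as one tidy CSV with columns `date`, `variable`,
#' `depth_m` (`NA` for column-integrated variables), `value`, `units`, plus a
#' JSON sidecar of the same base name holding the site preset and scenario.
#' `resolution = "daily"` writes the full daily state (large but lossless and
#' round-trippable via [read_run_csv()]); `"annual"` writes the one-row-per
#' -year aggregate table from [annual_table()] in the same long format.
#'
#' @param run An `ecosystem_run`.
#' @param path Output CSV path; the sidecar replaces `.csv` with `.json`.
#' @param resolution `"daily"` or `"annual"`.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path, resolution = c("daily", "annual")) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(run, "ecosystem_run"))
  long <- if (resolution == "daily") run_to_long(run) else run_to_long_annual(run)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(long, path, row.names = FALSE, na = "")
  sidecar <- sub("\\.csv$", ".json", path)
  meta <- list(
    site = unclass(run$site),
    scenario = unclass(run$scenario),
    resolution = resolution,
    format = "permasens-run-v1"
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

run_to_long <- function(run) {
  nd <- length(run$day)
  dates <- as.Date(paste0(run$year, "-01-01")) + (run$doy - 1)
  depths <- run$site$layer_depths
  scalar_vars <- list(
    air_temp = c("degC"), ald = c("m"), snow_depth = c("m"),
    gpp = c("gC m-2 d-1"), npp = c("gC m-2 d-1"), rh = c("gC m-2 d-1"),
    reco = c("gC m-2 d-1"), veg_c = c("gC m-2"), nutrient_n = c("gN m-2")
  )
  blocks <- lapply(names(scalar_vars), function(v) {
    data.frame(date = dates, variable = v, depth_m = NA_real_,
               value = run[[v]], units = scalar_vars[[v]])
  })
  layer_vars <- list(soil_temp = "degC", soil_moisture = "fraction",
                     soc = "gC m-2")
  for (v in names(layer_vars)) {
    for (l in seq_along(depths)) {
      blocks[[length(blocks) + 1L]] <-
        data.frame(date = dates, variable = v, depth_m = depths[l],
                   value = run[[v]][, l], units = layer_vars[[v]])
    }
  }
  do.call(rbind, blocks)
}

run_to_long_annual <- function(run) {
  at <- annual_table(run)
  dates <- as.Date(paste0(at$year, "-12-31"))
  units <- c(gpp = "gC m-2 yr-1", npp = "gC m-2 yr-1", rh = "gC m-2 yr-1",
             reco = "gC m-2 yr-1", ald_max = "m", snow_max = "m",
             air_temp_mean = "degC", soil_temp_mean_0.1m = "degC",
             veg_c = "gC m-2", soc_total = "gC m-2")
  blocks <- lapply(names(units), function(v) {
    data.frame(date = dates, variable = v, depth_m = NA_real_,
               value = at[[v]], units = unname(units[v]))
  })
  for (d in run$site$layer_depths) {
    col <- paste0("soc_", d, "m")
    blocks[[length(blocks) + 1L]] <-
      data.frame(date = dates, variable = "soc", depth_m = d,
                 value = at[[col]], units = "gC m-2")
  }
  do.call(rbind, blocks)
}

#' @rdname write_run_csv
#' @return `read_run_csv()` reconstructs the `ecosystem_run` from a
#'   daily-resolution CSV and its sidecar (annual files cannot be inverted to
#'   daily state and raise an error).
#' @export
read_run_csv <- function(path) {
  sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar))
    stop("read_run_csv: sidecar ", sidecar, " not found", call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$resolution, "daily"))
    stop("read_run_csv: only daily-resolution files round-trip to a run ",
         "object", call. = FALSE)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  site <- structure(meta$site, class = "site_preset")
  scenario <- structure(meta$scenario, class = "scenario_spec")

  nd <- scenario$n_years * 365L
  day <- seq_len(nd)
  grab <- function(v) {
    x <- long$value[long$variable == v & is.na(long$depth_m)]
    stopifnot(length(x) == nd)
    x
  }
  grab_mat <- function(v) {
    m <- vapply(site$layer_depths, function(d)
      long$value[long$variable == v & !is.na(long$depth_m) &
                   abs(long$depth_m - d) < 1e-9],
      numeric(nd))
    m
  }
  run <- structure(
    list(site = site, scenario = scenario,
         day = day,
         year = scenario$start_year + (day - 1L) %/% 365L,
         doy = ((day - 1L) %% 365L) + 1L,
         air_temp = grab("air_temp"),
         soil_temp = grab_mat("soil_temp"),
         soil_moisture = grab_mat("soil_moisture"),
         ald = grab("ald"), snow_depth = grab("snow_depth"),
         gpp = grab("gpp"), npp = grab("npp"), rh = grab("rh"),
         reco = grab("reco"), soc = grab_mat("soc"),
         veg_c = grab("veg_c"), nutrient_n = grab("nutrient_n")),
    class = "ecosystem_run"
  )
  run
}

#' Write study summaries or forest tables as CSV
#'
#' Thin wrappers fixing the column contract of the meta-analysis interchange
#' files: studies CSVs carry exactly `variable, source, mean_treat, sd_treat,
#' n_treat, mean_ambient, sd_ambient, n_ambient`.
#'
#' @param studies A study-summary tibble.
#' @param path Output path.
#' @export
write_studies_csv <- function(studies, path) {
  cols <- c("variable", "source", "mean_treat", "sd_treat", "n_treat",
            "mean_ambient", "sd_ambient", "n_ambient")
  stopifnot(all(cols %in% names(studies)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(studies)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_studies_csv
#' @export
read_studies_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
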