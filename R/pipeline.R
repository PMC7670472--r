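#' Configuration for the full step-versus-ramp experiment
#'
#' Declares the whole experiment the package exists to run: which site
#' archetypes to simulate, the short-term (10-year step warming, replicated
#' chamber analogue) and long-term (100-year ramp; temperature-only and
#' fully-forced variants) designs, which analysis stages to run, and a single
#' master seed from which every stochastic stream is derived.
#'
#' @param sites Character vector of [site_preset_names()].
#' @param short_years,short_reps Step-warming design: duration and replicate
#'   count per arm. The step magnitude is the site-typical chamber soil
#'   warming stored in each preset (`default_step_delta`) unless
#'   `short_delta` overrides it for all sites.
#' @param short_delta Optional single step magnitude (degC) applied to all
#'   sites.
#' @param long_years,ramp_rate Ramp design: duration and warming rate
#'   (degC/decade; default 0.6, the observed high-latitude rate).
#' @param ff_precip,ff_co2 End-of-run precipitation and CO2 multipliers of
#'   the fully-forced ramp variant (the temperature-only variant keeps both
#'   at 1).
#' @param nu_windows_long List of year-boundary windows for the long-run
#'   sensitivity profile (default: final decade).
#' @param analyses Named logical vector toggling stages: `nu`, `meta`,
#'   `procnet`.
#' @param procnet_vars,procnet_max_lag,procnet_bins,procnet_shuffles,procnet_last_years
#'   Process-network settings (applied to the fully-forced ramp run, daily
#'   resolution over the final `procnet_last_years` years).
#' @param master_seed Integer master seed.
#' @param output_dir Directory for the output bundle.
#' @param start_year Calendar year of the first simulated day.
#'
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sites = site_preset_names(),
                              short_years = 10, short_reps = 3,
                              short_delta = NULL,
                              long_years = 100, ramp_rate = 0.6,
                              ff_precip = 1.25, ff_co2 = 1.35,
                              nu_windows_long = NULL,
                              analyses = c(nu = TRUE, meta = TRUE,
                                           procnet = TRUE),
                              procnet_vars = c("gpp", "rh", "soil_temp",
                                               "soil_moisture", "ald", "soc"),
                              procnet_max_lag = 5, procnet_bins = 6,
                              procnet_shuffles = 100,
                              procnet_last_years = 20,
                              master_seed = 42L,
                              output_dir = tempfile("permasens-"),
                              start_year = 2001) {
  bad <- setdiff(sites, site_preset_names())
  if (length(bad) > 0)
    stop("experiment_config: unknown site(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  stopifnot(short_years >= 1, long_years >= 1, short_reps >= 2,
            all(c("nu", "meta", "procnet") %in% names(analyses)))
  if (is.null(nu_windows_long))
    nu_windows_long <- list(c(start_year - 1 + long_years - 10,
                              start_year - 1 + long_years))
  structure(
    list(sites = sites, short_years = as.integer(short_years),
         short_reps = as.integer(short_reps), short_delta = short_delta,
         long_years = as.integer(long_years), ramp_rate = ramp_rate,
         ff_precip = ff_precip, ff_co2 = ff_co2,
         nu_windows_long = nu_windows_long,
         analyses = as.logical(analyses[c("nu", "meta", "procnet")]),
         procnet_vars = procnet_vars,
         procnet_max_lag = as.integer(procnet_max_lag),
         procnet_bins = as.integer(procnet_bins),
         procnet_shuffles = as.integer(procnet_shuffles),
         procnet_last_years = as.integer(procnet_last_years),
         master_seed = as.integer(master_seed),
         output_dir = output_dir, start_year = as.integer(start_year)),
    class = "experiment_config"
  )
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @param path JSON file path.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$analyses <- as.list(setNames(x$analyses, c("nu", "meta", "procnet")))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_config(
    sites = x$sites, short_years = x$short_years, short_reps = x$short_reps,
    short_delta = x$short_delta, long_years = x$long_years,
    ramp_rate = x$ramp_rate, ff_precip = x$ff_precip, ff_co2 = x$ff_co2,
    nu_windows_long = if (is.matrix(x$nu_windows_long))
      lapply(seq_len(nrow(x$nu_windows_long)),
             function(i) as.numeric(x$nu_windows_long[i, ])) else
      lapply(x$nu_windows_long, as.numeric),
    analyses = unlist(x$analyses),
    procnet_vars = x$procnet_vars, procnet_max_lag = x$procnet_max_lag,
    procnet_bins = x$procnet_bins, procnet_shuffles = x$procnet_shuffles,
    procnet_last_years = x$procnet_last_years,
    master_seed = x$master_seed, output_dir = x$output_dir,
    start_year = x$start_year
  )
}

#' Run the full step-versus-ramp experiment
#'
#' Orchestrates the step-versus-ramp experiment end to end for every configured
#' site archetype: simulates the baseline, step-warming, temperature-only
#' ramp and fully-forced ramp runs; computes the depth-resolved emergent
#' temperature-sensitivity grid; runs the replicated warming pairs and the
#' meta-analysis forest table; builds the transfer-entropy process network;
#' and writes every artifact (annual run CSVs with JSON sidecars, analysis
#' tables, GraphML networks) plus a checksum manifest and a structured log
#' under `config$output_dir`. Deterministic given `config$master_seed`: the
#' same configuration produces byte-identical artifacts and manifest.
#'
#' Stage failures abort with the stage name; artifacts already written are
#' preserved and the manifest flags the bundle as partial.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_bundle`: list with `config`,
#'   `runs` (nested per site), `nu_table`, `forest_table`, `studies`,
#'   `networks`, `manifest`, and `output_dir`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(master_seed = config$master_seed, stages = list())
  t_all <- Sys.time()
  bundle <- list(config = config, runs = list(), nu_table = NULL,
                 forest_table = NULL, studies = NULL, networks = list(),
                 output_dir = config$output_dir)

  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(code, error = function(e) {
      write_manifest(config$output_dir, partial = TRUE)
      stop("run_experiment: stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
    log$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  ana <- setNames(config$analyses, c("nu", "meta", "procnet"))

  bundle$runs <- stage("simulate", {
    out <- list()
    for (i in seq_along(config$sites)) {
      s <- site_preset(config$sites[i])
      delta <- config$short_delta %||% s$default_step_delta
      seed_long <- child_seed(config$master_seed, i * 100 + 1)
      seed_short <- child_seed(config$master_seed, i * 100 + 2)
      sims <- list(
        control_long = simulate_ecosystem(s, scenario_spec(
          "control", start_year = config$start_year,
          n_years = config$long_years, seed = seed_long)),
        ramp_t = simulate_ecosystem(s, scenario_spec(
          "ramp", start_year = config$start_year,
          n_years = config$long_years, ramp_rate = config$ramp_rate,
          seed = seed_long)),
        ramp_ff = simulate_ecosystem(s, scenario_spec(
          "ramp", start_year = config$start_year,
          n_years = config$long_years, ramp_rate = config$ramp_rate,
          precip_multiplier_end = config$ff_precip,
          co2_fertilization_end = config$ff_co2, seed = seed_long)),
        control_short = simulate_ecosystem(s, scenario_spec(
          "control", start_year = config$start_year,
          n_years = config$short_years, seed = seed_short)),
        step = simulate_ecosystem(s, scenario_spec(
          "step", start_year = config$start_year,
          n_years = config$short_years, step_delta_air = delta,
          seed = seed_short))
      )
      for (nm in names(sims)) {
        write_run_csv(sims[[nm]],
                      file.path(config$output_dir, "runs",
                                paste0(config$sites[i], "-", nm, ".csv")),
                      resolution = "annual")
      }
      out[[config$sites[i]]] <- sims
    }
    out
  })

  if (ana[["nu"]]) {
    bundle$nu_table <- stage("nu", {
      rows <- lapply(config$sites, function(sn) {
        r <- bundle$runs[[sn]]
        w_short <- c(config$start_year - 1,
                     config$start_year - 1 + config$short_years)
        tabs <- list(
          cbind(site = sn,
                nu_profile(r$step, r$control_short, list(w_short))),
          cbind(site = sn,
                nu_profile(r$ramp_t, r$control_long, config$nu_windows_long)),
          cbind(site = sn,
                nu_profile(r$ramp_ff, r$control_long, config$nu_windows_long))
        )
        tabs[[2]]$scenario <- "ramp_t"
        tabs[[3]]$scenario <- "ramp_ff"
        do.call(rbind, tabs)
      })
      tab <- tibble::as_tibble(do.call(rbind, rows))
      utils::write.csv(as.data.frame(tab),
                       file.path(config$output_dir, "nu_table.csv"),
                       row.names = FALSE, na = "")
      tab
    })
  }

  if (ana[["meta"]]) {
    bundle$studies <- stage("meta", {
      rows <- lapply(seq_along(config$sites), function(i) {
        s <- site_preset(config$sites[i])
        delta <- config$short_delta %||% s$default_step_delta
        pe_model <- gen_warming_pair(
          s, delta, n_years = config$short_years, n_reps = config$short_reps,
          seed = child_seed(config$master_seed, i * 100 + 3))
        # synthetic stand-in for the empirical studies: an independent
        # replicate batch of the same design (different seeds), labelled so
        pe_emp <- gen_warming_pair(
          s, delta, n_years = config$short_years, n_reps = config$short_reps,
          seed = child_seed(config$master_seed, i * 100 + 4))
        st_m <- pe_model$studies
        st_m$source <- "model"
        st_e <- pe_emp$studies
        st_e$source <- "empirical"
        cbind(site = config$sites[i], rbind(st_m, st_e))
      })
      studies <- tibble::as_tibble(do.call(rbind, rows))
      write_studies_csv(studies, file.path(config$output_dir, "studies.csv"))
      studies
    })
    bundle$forest_table <- stage("forest", {
      ft <- model_vs_empirical_table(
        bundle$studies[bundle$studies$source == "model", ],
        bundle$studies[bundle$studies$source == "empirical", ])
      utils::write.csv(as.data.frame(ft),
                       file.path(config$output_dir, "forest.csv"),
                       row.names = FALSE, na = "")
      ft
    })
  }

  if (ana[["procnet"]]) {
    bundle$networks <- stage("procnet", {
      dir.create(file.path(config$output_dir, "procnet"),
                 recursive = TRUE, showWarnings = FALSE)
      nets <- list()
      for (i in seq_along(config$sites)) {
        sn <- config$sites[i]
        net <- build_network(
          bundle$runs[[sn]]$ramp_ff, config$procnet_vars,
          max_lag = config$procnet_max_lag, n_bins = config$procnet_bins,
          n_shuffles = config$procnet_shuffles,
          seed = child_seed(config$master_seed, i * 100 + 5),
          resolution = "daily", last_years = config$procnet_last_years)
        utils::write.csv(
          as.data.frame(net$all_pairs),
          file.path(config$output_dir, "procnet",
                    paste0(sn, "-edges.csv")), row.names = FALSE)
        write_network_graphml(net, file.path(config$output_dir, "procnet",
                                             paste0(sn, ".graphml")))
        nets[[sn]] <- net
      }
      nets
    })
  }

  summary_tab <- summarize_experiment(bundle)
  utils::write.csv(as.data.frame(summary_tab),
                   file.path(config$output_dir, "summary.csv"),
                   row.names = FALSE, na = "")
  bundle$manifest <- write_manifest(config$output_dir, partial = FALSE)

  log$total_seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  jsonlite::write_json(log, file.path(config$output_dir, "log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 3)
  structure(bundle, class = "experiment_bundle")
}

# checksum manifest of every artifact in the bundle (the log is excluded:
# it records wall-clock timings and is not part of the reproducible surface)
write_manifest <- function(output_dir, partial = FALSE) {
  files <- sort(setdiff(
    list.files(output_dir, recursive = TRUE),
    c("manifest.csv", "log.json")))
  man <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(output_dir, files))),
    partial = partial
  )
  utils::write.csv(man, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  tibble::as_tibble(man)
}

#' Summarize an experiment bundle
#'
#' One row per site: net 10-year and 100-year SOC changes relative to the
#' paired baseline (g C m-2), the top-layer emergent temperature sensitivity
#' per scenario, and the number of significant causal edges into the SOC
#' node. Stages that were disabled in the configuration yield `NA` columns.
#'
#' @param bundle An `experiment_bundle` (see [run_experiment()]).
#' @return A tibble with one row per site.
#' @export
summarize_experiment <- function(bundle) {
  cfg <- bundle$config
  rows <- lapply(cfg$sites, function(sn) {
    r <- bundle$runs[[sn]]
    soc_end <- function(run) sum(run$soc[nrow(run$soc), ])
    nu_top <- function(scen) {
      if (is.null(bundle$nu_table)) return(NA_real_)
      t <- bundle$nu_table
      sel <- t$site == sn & t$scenario == scen &
        t$depth == min(t$depth) & t$window_end == max(t$window_end[t$scenario == scen])
      if (!any(sel)) NA_real_ else t$nu[sel][1]
    }
    edges_into_soc <- if (length(bundle$networks) == 0) NA_integer_ else
      sum(bundle$networks[[sn]]$edges$target == "soc")
    tibble::tibble(
      site = sn,
      soc_change_step = soc_end(r$step) - soc_end(r$control_short),
      soc_change_ramp_t = soc_end(r$ramp_t) - soc_end(r$control_long),
      soc_change_ramp_ff = soc_end(r$ramp_ff) - soc_end(r$control_long),
      nu_top_step = nu_top("step"),
      nu_top_ramp_t = nu_top("ramp_t"),
      nu_top_ramp_ff = nu_top("ramp_ff"),
      n_edges_into_soc = edges_into_soc
    )
  })
  do.call(rbind, rows)
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("<experiment_bundle> ", length(x$config$sites), " sites -> ",
      x$output_dir, "\n", sep = "")
  print(summarize_experiment(x))
  invisible(x)
}

#' Write the small seeded fixture files used in examples and tests
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(dir, seed = 7L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  run <- simulate_ecosystem(
    site_preset("foothills-tundra"),
    scenario_spec("control", n_years = 2, seed = seed))
  write_run_csv(run, file.path(dir, "demo-run.csv"), resolution = "daily")
  st_m <- simulate_ratio_studies(1.2, n_reps = 5, k_studies = 4, seed = seed)
  st_m$source <- "model"
  st_e <- simulate_ratio_studies(1.2, n_reps = 5, k_studies = 4,
                                 seed = seed + 1L)
  st_e$source <- "empirical"
  write_studies_csv(rbind(st_m, st_e), file.path(dir, "demo-studies.csv"))
  utils::write.csv(as.data.frame(simulate_causal_chain(500, seed = seed)),
                   file.path(dir, "demo-chain.csv"), row.names = FALSE)
  invisible(dir)
}
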