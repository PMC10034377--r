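#' Write a study to a directory
#'
#' Directory-per-field layout: each field directory holds `weather.csv`,
#' `soil.yaml`, `mgmt.yaml` and `obs.csv`; the true generating parameters
#' (when present) go to `truth.json` at the top level.
#'
#' @param study list with `fields` (and optionally `truth`) as returned by
#'   [generate_study()].
#' @param dir output directory (created if needed).
#' @return `invisible(dir)`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in study$fields) {
    fd <- file.path(dir, f$id)
    dir.create(fd, showWarnings = FALSE)
    wx <- f$weather
    wx$date <- format(wx$date)
    write.csv(wx, file.path(fd, "weather.csv"), row.names = FALSE)
    write.csv(f$obs, file.path(fd, "obs.csv"), row.names = FALSE)
    yaml::write_yaml(list(texture = f$soil$texture,
                          layers = as.list(f$soil$layers),
                          theta_init = f$soil$theta_init),
                     file.path(fd, "soil.yaml"))
    yaml::write_yaml(list(crop = f$crop, cultivar = f$cultivar,
                          start_date = format(f$mgmt$start_date),
                          establishment = f$mgmt$establishment,
                          density = f$mgmt$density,
                          horizon = f$mgmt$horizon,
                          irrigation = as.list(f$mgmt$irrigation)),
                     file.path(fd, "mgmt.yaml"))
  }
  if (!is.null(study$truth))
    jsonlite::write_json(lapply(study$truth, function(p) p[PARAM_ORDER]),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study directory
#'
#' Reads a directory in the layout produced by [write_study()] (or
#' hand-assembled real data in the same layout) into validated
#' [field_dataset()] objects. Malformed inputs (missing columns,
#' non-contiguous weather dates, out-of-bounds observations, unknown
#' variable labels) are rejected with informative errors.
#'
#' @param dir study directory.
#' @return list with `fields` and, when `truth.json` is present, `truth`.
#' @export
read_study <- function(dir) {
  if (!dir.exists(dir)) stop("no such study directory: ", dir)
  sub <- list.dirs(dir, recursive = FALSE)
  if (!length(sub)) stop("study directory has no field subdirectories")
  fields <- lapply(sub, function(fd) {
    wx <- validate_weather(read.csv(file.path(fd, "weather.csv")))
    obs <- read.csv(file.path(fd, "obs.csv"))
    sy <- yaml::read_yaml(file.path(fd, "soil.yaml"))
    my <- yaml::read_yaml(file.path(fd, "mgmt.yaml"))
    soil <- soil_profile(texture = sy$texture,
                         layers = as.data.frame(sy$layers),
                         theta_init = unlist(sy$theta_init))
    irr <- if (length(my$irrigation$day))
      data.frame(day = unlist(my$irrigation$day),
                 depth = unlist(my$irrigation$depth))
    else data.frame(day = integer(), depth = numeric())
    mg <- management(my$start_date, my$establishment, my$density,
                     my$horizon, irr)
    field_dataset(basename(fd), my$crop, my$cultivar, obs, wx, soil, mg)
  })
  out <- list(fields = fields)
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tr <- jsonlite::read_json(tf, simplifyVector = TRUE)
    crop <- fields[[1]]$crop
    out$truth <- lapply(tr, function(p)
      do.call(crop_parameters, c(list(crop = crop), p)))
  }
  out
}

#' Run the full calibration experiment
#'
#' The end-to-end chain on one synthetic study: generate (or load) the
#' fields, screen the parameters with the Morris method on a
#' representative field, calibrate the influential subset per stratum of
#' each requested stratification scheme with DRAM, propagate each
#' posterior over the year x soil scenario grid, and compare the
#' stratified against the pooled summaries. All stage artifacts, the
#' comparison table and a run manifest (every numeric setting and seed)
#' are written under `out_dir`.
#'
#' @param config a [study_config()] (or a study list with `fields`).
#' @param out_dir output directory.
#' @param schemes stratification schemes to run besides the pooled
#'   calibration.
#' @param seed master seed for every stage.
#' @param morris_r Morris replicate count (study value 100; the reduced
#'   demo uses 20).
#' @param n_iter,burn_in DRAM settings (study values 30,000 / 3,000).
#' @param n_draws posterior draws propagated per stratum (study value
#'   5000).
#' @param n_years,soils scenario grid: number of synthetic weather years
#'   and soil texture classes.
#' @param max_params cap on the number of calibrated parameters (the most
#'   influential are kept).
#' @return invisibly, a list with `sensitivity`, `chains`, `summaries`,
#'   `comparison`, `manifest`.
#' @export
run_experiment <- function(config, out_dir, schemes = c("cultivar"),
                           seed = 1, morris_r = 20, n_iter = 5000,
                           burn_in = 1000, n_draws = 500, n_years = 10,
                           soils = c("loam", "loamy_sand"),
                           max_params = 4) {
  ok <- c("all", "cultivar", "period", "cultivar_x_period")
  bad <- setdiff(schemes, ok)
  if (length(bad))
    stop("unknown stratification scheme(s): ", paste(bad, collapse = ", "),
         " (schemes must be of: ", paste(ok, collapse = ", "), ")")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- if (inherits(config, "study_config")) generate_study(config)
           else config
  fields <- study$fields
  crop <- fields[[1]]$crop
  base <- crop_parameters(crop)
  write_study(study, file.path(out_dir, "study"))

  # screening on the first field's scenario over the default +/-25% ranges
  space_all <- default_screening_space(base)
  f1 <- fields[[1]]
  sens <- morris_screen(space_all, base, f1$weather, f1$soil, f1$mgmt,
                        days = sort(unique(f1$obs$day[f1$obs$day > 0])),
                        levels = 8, r = morris_r, seed = seed)
  sel <- head(sens$selected, max_params)
  space <- space_all[match(sel, space_all$name), ]
  class(space) <- c("param_space", "data.frame")
  write.csv(sens$table, file.path(out_dir, "morris.csv"), row.names = FALSE)

  # calibration per stratum: pooled plus each requested scheme
  strata <- stratify(fields, "all")
  for (sc in setdiff(schemes, "all"))
    strata <- c(strata, stratify(fields, sc))
  chains <- list()
  summaries <- list()
  for (i in seq_along(strata)) {
    lab <- names(strata)[i]
    ch <- calibrate_fields(strata[[i]], space, base, n_iter = n_iter,
                           burn_in = burn_in, seed = seed + i, label = lab)
    chains[[lab]] <- ch
    write.csv(as.data.frame(ch$samples),
              file.path(out_dir, paste0("chain_", lab, ".csv")),
              row.names = FALSE)
  }

  # propagation over the year x soil grid
  years <- lapply(seq_len(n_years), function(y)
    generate_weather(year_seed = seed * 100L + y,
                     ndays = fields[[1]]$mgmt$horizon + 10,
                     start = fields[[1]]$mgmt$start_date))
  names(years) <- paste0("y", seq_len(n_years))
  soil_list <- lapply(seq_along(soils), function(i)
    generate_soil(soils[i], seed = seed + 7L * i))
  names(soil_list) <- soils
  eval_day <- if (crop == "spinach") 38L else 84L
  eval_var <- if (crop == "spinach") "biomass" else "yield"
  # reference management: field 1's start/density with a fixed calendar
  # irrigation schedule so every scenario year sees the same practice
  mg1 <- fields[[1]]$mgmt
  horizon <- mg1$horizon
  ref_mgmt <- management(mg1$start_date, mg1$establishment, mg1$density,
                         horizon,
                         irrigation = data.frame(
                           day = seq(10, horizon, by = 10), depth = 20))
  grid <- scenario_grid(years, soil_list, ref_mgmt,
                        eval_day = eval_day, eval_var = eval_var)
  for (lab in names(chains)) {
    vec <- sample_posterior(chains[[lab]], n = n_draws, seed = seed + 99L)
    summaries[[lab]] <- propagate(vec, grid, base, label = lab)
  }
  comparison <- compare_stratifications(summaries[["all"]],
                                        summaries[names(summaries) != "all"])
  write.csv(comparison, file.path(out_dir, "comparison.csv"),
            row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("aquacal")),
    crop = crop, n_fields = length(fields), schemes = schemes,
    seed = seed, morris = list(levels = 8, r = morris_r),
    dram = list(n_iter = n_iter, burn_in = burn_in, jump_frac = 0.1,
                dr_shrink = 5, adapt_start = 10 * nrow(space),
                sigma2_prior = c(0.01, 0.01)),
    propagation = list(n_draws = n_draws, n_years = n_years, soils = soils,
                       eval_day = eval_day, eval_var = eval_var,
                       ke_soil = KE_SOIL),
    calibrated_parameters = space$name,
    acceptance_rates = lapply(chains, function(ch) ch$acceptance_rate),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sensitivity = sens, chains = chains, summaries = summaries,
                 comparison = comparison, manifest = manifest))
}

#' Default screening ranges around a parameter set
#'
#' A +/-25% range (respecting hard physical bounds for fractions and
#' thresholds) around every screenable parameter of `base` — the ranges a
#' practitioner would take from literature and expert knowledge when no
#' crop-specific table is available.
#'
#' @param base a [crop_parameters()] set.
#' @param rel half-width of the relative range (default 0.25).
#' @return a [parameter_space()] over the screenable fields.
#' @export
default_screening_space <- function(base, rel = 0.25) {
  nm <- c("plan", "ccs", "ccx", "cgc", "cdc", "kc", "wp", "baseT", "stbio",
          "sen", "yld", "hilen", "hi", "mat", "root", "rtn", "rtx",
          "pexup", "pexlw", "pexhp", "psto", "psen", "psenshp", "anaer",
          "evardc")
  lo <- vapply(nm, function(f) base[[f]] * (1 - rel), numeric(1))
  hi <- vapply(nm, function(f) base[[f]] * (1 + rel), numeric(1))
  frac <- c("ccx", "hi", "pexup", "pexlw", "psto", "psen")
  hi[frac] <- pmin(hi[frac], 1)
  # keep phenology orderings intact across the whole box
  lo["sen"] <- max(lo["sen"], hi["plan"] * 1.05)
  lo["mat"] <- max(lo["mat"], hi["sen"] * 1.02, hi["yld"] + hi["hilen"])
  parameter_space(nm, lo, hi)
}
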