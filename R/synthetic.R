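# default observation noise standard deviations (study conditions):
# canopy cover 5 percentage points; biomass/yield 8% relative with a
# 0.05 t/ha floor; soil water 2 vol%
default_noise <- function() {
  list(canopy_cover = 5, biomass_rel = 0.08, biomass_floor = 0.05,
       swc = 2)
}

#' Generate a synthetic daily weather series
#'
#' Belgian-type weather for one growing period: daily mean temperature
#' from a sinusoidal annual cycle (annual mean 10.5 deg C, amplitude
#' 7.5 deg C, peak in late July) plus AR(1) anomalies; rain occurrence from
#' a two-state Markov chain with gamma depths; reference
#' evapotranspiration from the Hargreaves temperature formula with
#' extraterrestrial radiation for 51 deg N, floored at 0.1 mm.
#'
#' @param period `"first"` (season starting mid-April) or `"second"`
#'   (mid-July), or an explicit start `Date` via `start`.
#' @param year_seed RNG seed; doubles as the "year" index of a scenario.
#' @param ndays series length in days (default 120).
#' @param start optional explicit start date overriding `period`.
#' @return weather data.frame (`date`, `tmin`, `tmax`, `precip`, `et0`).
#' @export
generate_weather <- function(period = c("first", "second"), year_seed = 1,
                             ndays = 120, start = NULL) {
  if (is.null(start)) {
    period <- match.arg(period)
    start <- as.Date(if (period == "first") "2019-04-15" else "2019-07-20")
  } else start <- as.Date(start)
  dates <- seq(start, by = "day", length.out = ndays)
  doy <- as.integer(format(dates, "%j"))
  with_seed(year_seed, {
    anom <- numeric(ndays)
    anom[1] <- rnorm(1, 0, 2)
    for (t in 2:ndays) anom[t] <- 0.7 * anom[t - 1] + rnorm(1, 0, 2 * sqrt(1 - 0.49))
    # warmest around day 210 (late July): the seasonal cycle lags the
    # solar peak, which is what makes the second growing period the warmer
    tmean <- 10.5 + 7.5 * cos(2 * pi * (doy - 210) / 365.25) + anom
    dtr <- pmax(2, rnorm(ndays, 9, 1.5)) # diurnal temperature range
    tmax <- tmean + dtr / 2
    tmin <- tmean - dtr / 2
    wet <- logical(ndays)
    wet[1] <- runif(1) < 0.4
    for (t in 2:ndays)
      wet[t] <- runif(1) < if (wet[t - 1]) 0.55 else 0.30
    precip <- ifelse(wet, rgamma(ndays, shape = 0.7, scale = 6), 0)
    et0 <- pmax(0.1, hargreaves_et0(doy, tmean, tmax, tmin))
    data.frame(date = dates, tmin = tmin, tmax = tmax,
               precip = precip, et0 = et0)
  })
}

#' Rain-responsive irrigation schedule
#'
#' Emulates commercial irrigation practice on the monitored fields: every
#' `check_every` days, if the rainfall of the preceding window fell short
#' of `rain_min` mm, one irrigation event of `depth` mm is scheduled.
#' Deterministic given the weather.
#'
#' @param weather a weather series (row 1 = day 0).
#' @param horizon season length in days.
#' @param check_every evaluation interval in days (default 7).
#' @param rain_min rainfall threshold per window (mm, default 15).
#' @param depth irrigation gift per event (mm, default 20).
#' @return data.frame (`day`, `depth`) suitable for [management()].
#' @export
irrigation_schedule <- function(weather, horizon, check_every = 7,
                                rain_min = 15, depth = 20) {
  days <- seq(check_every, horizon, by = check_every)
  ev <- days[vapply(days, function(d) {
    sum(weather$precip[(d - check_every + 2):(d + 1)]) < rain_min
  }, logical(1))]
  data.frame(day = ev, depth = rep(depth, length(ev)))
}

# Hargreaves-Samani reference evapotranspiration (mm/day) with FAO
# extraterrestrial radiation for latitude `lat` degrees north
hargreaves_et0 <- function(doy, tmean, tmax, tmin, lat = 51) {
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(clamp(-tan(phi) * tan(dec), -1, 1))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws)) # MJ/m2/day
  0.0023 * (ra / 2.45) * (tmean + 17.8) * sqrt(pmax(0, tmax - tmin))
}

#' Generate a soil profile for a texture class
#'
#' Two 0.3 m layers from the texture lookup ([soil_texture_table()]) with
#' multiplicative +/-`jitter` relative perturbation of each hydraulic
#' value (seeded), initial water content at field capacity.
#'
#' @param texture one of the four texture classes.
#' @param seed RNG seed.
#' @param jitter relative jitter half-width (default 0.05; 0 = exact
#'   lookup values).
#' @return a [soil_profile()].
#' @export
generate_soil <- function(texture, seed = 1, jitter = 0.05) {
  tab <- soil_texture_table()
  if (!texture %in% tab$texture) stop("unknown texture class: ", texture)
  row <- tab[tab$texture == texture, ]
  with_seed(seed, {
    jit <- function(x) x * runif(length(x) * 2, 1 - jitter, 1 + jitter)
    layers <- data.frame(
      thickness = c(0.3, 0.3),
      theta_sat = jit(row$theta_sat),
      theta_fc = jit(row$theta_fc),
      theta_wp = jit(row$theta_wp),
      tau = clamp(jit(row$tau), 0, 1)
    )
    soil_profile(texture = texture, layers = layers)
  })
}

#' Generate a noisy observation campaign for one field
#'
#' Simulates the field with the true parameter set and samples it on the
#' cadence schedule (with an optional +/-1 day seeded stagger): canopy
#' cover at day 0 and every sampling date, biomass and soil water at every
#' sampling date (both layers for cauliflower, top layer only for
#' spinach), yield at the final harvest date. Independent Gaussian noise
#' is added per variable and truncated at the physical bounds (cover in
#' `[0, 100]`, non-negatives floored at 0).
#'
#' @param truth the true [crop_parameters()] set.
#' @param weather,soil,mgmt the field scenario.
#' @param crop `"cauliflower"` or `"spinach"` (controls soil-water depths).
#' @param cadence sampling interval in days (>= 1).
#' @param noise list with elements `canopy_cover`, `biomass_rel`, `biomass_floor`, `swc`; sds of 0 give exact
#'   observations.
#' @param seed RNG seed.
#' @param stagger apply the +/-1 day sampling-date stagger (default TRUE).
#' @return obs data.frame (`day`, `variable`, `value`).
#' @export
generate_field_campaign <- function(truth, weather, soil, mgmt, crop,
                                    cadence = 14, noise = default_noise(),
                                    seed = 1, stagger = TRUE) {
  if (cadence < 1) stop("cadence must be >= 1 day")
  traj <- simulate_crop(truth, weather, soil, mgmt)
  horizon <- min(mgmt$horizon, max(traj$day))
  with_seed(seed, {
    days <- seq(cadence, horizon, by = cadence)
    if (stagger && length(days))
      days <- clamp(days + sample(-1:1, length(days), replace = TRUE),
                    1, horizon)
    days <- sort(unique(days))
    noisy <- function(x, sd_abs, lo = 0, hi = Inf) {
      clamp(x + rnorm(length(x), 0, sd_abs), lo, hi)
    }
    rows <- list(
      data.frame(day = c(0, days),
                 variable = "canopy_cover",
                 value = noisy(sim_observable(traj, "canopy_cover", c(0, days)),
                               noise$canopy_cover, 0, 100)),
      data.frame(day = days, variable = "biomass",
                 value = {
                   b <- sim_observable(traj, "biomass", days)
                   noisy(b, pmax(noise$biomass_rel * b, noise$biomass_floor))
                 }),
      data.frame(day = max(days), variable = "yield",
                 value = {
                   y <- sim_observable(traj, "yield", max(days))
                   noisy(y, max(noise$biomass_rel * y, noise$biomass_floor))
                 }),
      data.frame(day = days, variable = "swc_0_30",
                 value = noisy(sim_observable(traj, "swc_0_30", days),
                               noise$swc))
    )
    if (crop == "cauliflower")
      rows[[length(rows) + 1]] <- data.frame(
        day = days, variable = "swc_30_60",
        value = noisy(sim_observable(traj, "swc_30_60", days), noise$swc))
    obs <- do.call(rbind, rows)
    rownames(obs) <- NULL
    obs
  })
}

#' Synthetic study configuration
#'
#' Defines a multi-field campaign emulating the monitored commercial
#' fields: cauliflower (transplanted, two cultivars, biweekly destructive
#' sampling, 90-day horizon, 16 fields by default) or spinach (sown, two
#' cultivars, weekly sampling, 45-day horizon, 12 fields by default),
#' spread over two growing periods and the four texture classes.
#'
#' @param crop `"cauliflower"` or `"spinach"`.
#' @param fields_per_cell integer vector of field counts per
#'   cultivar x period cell, in the order (cv1-first, cv1-second,
#'   cv2-first, cv2-second); recycled over cells.
#' @param cultivars named list of parameter-override lists defining each
#'   cultivar's true deviations from the crop default.
#' @param cadence sampling interval in days.
#' @param horizon season length in days.
#' @param noise observation noise levels (see
#'   [generate_field_campaign()]).
#' @param seed master seed; all field-level seeds derive from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(crop = c("cauliflower", "spinach"),
                         fields_per_cell = NULL, cultivars = NULL,
                         cadence = NULL, horizon = NULL,
                         noise = default_noise(), seed = 1) {
  crop <- match.arg(crop)
  if (is.null(cultivars))
    cultivars <- if (crop == "cauliflower")
      list(David = list(cgc = 0.0125, hi = 0.48),
           Giewont = list(cgc = 0.0115, hi = 0.42))
    else
      list(Eagle = list(cgc = 0.0185, wp = 0.155),
           Whale = list(cgc = 0.0175, wp = 0.145))
  if (is.null(fields_per_cell))
    fields_per_cell <- if (crop == "cauliflower") 4L else 3L
  if (is.null(cadence)) cadence <- if (crop == "cauliflower") 14 else 7
  if (is.null(horizon)) horizon <- if (crop == "cauliflower") 90 else 45
  ncell <- 2 * length(cultivars)
  fields_per_cell <- rep_len(as.integer(fields_per_cell), ncell)
  if (sum(fields_per_cell) < 1) stop("need at least one field")
  if (any(unlist(noise)[c("canopy_cover", "biomass_rel", "swc")] < 0))
    stop("noise sds must be >= 0")
  structure(list(crop = crop, fields_per_cell = fields_per_cell,
                 cultivars = cultivars, cadence = cadence,
                 horizon = as.integer(horizon), noise = noise,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a synthetic multi-field study
#'
#' Composes weather, soil, management and a noisy observation campaign for
#' every field across the cultivar x period cells of the configuration,
#' and returns the exact true parameter set used to generate each field.
#' Spinach sowing density is drawn per field from the commercial range
#' 1,190,000-2,500,000 plants/ha; cauliflower transplant density is fixed
#' at 33,000 plants/ha. Soil textures cycle through the four classes.
#'
#' @param config a [study_config()].
#' @return list with elements `fields` (list of [field_dataset()]) and
#'   `truth` (named list: field id -> true `crop_params`).
#' @export
generate_study <- function(config) {
  crop <- config$crop
  base <- crop_parameters(crop)
  textures <- soil_texture_table()$texture
  cells <- expand.grid(period = c("first", "second"),
                       cultivar = names(config$cultivars),
                       stringsAsFactors = FALSE)[, 2:1]
  fields <- list()
  truth <- list()
  fid <- 0L
  for (ci in seq_len(nrow(cells))) {
    cv <- cells$cultivar[ci]
    pd <- cells$period[ci]
    n <- config$fields_per_cell[ci]
    for (j in seq_len(n)) {
      fid <- fid + 1L
      fseed <- config$seed * 10000L + fid
      id <- sprintf("%s_%s_%s_%02d", crop, cv, pd, j)
      pars <- do.call(crop_parameters,
                      c(list(crop = crop), config$cultivars[[cv]]))
      start0 <- as.Date(if (pd == "first") "2019-04-15" else "2019-07-20")
      dens <- with_seed(fseed, {
        shift <- sample(-5:5, 1)
        d <- if (crop == "spinach") runif(1, 1.19e6, 2.5e6) else 33000
        list(shift = shift, d = d)
      })
      start <- start0 + dens$shift
      pars$density <- dens$d
      wx <- generate_weather(year_seed = fseed + 500L,
                             ndays = config$horizon + 10, start = start)
      so <- generate_soil(textures[(fid - 1L) %% 4L + 1L],
                          seed = fseed + 1000L)
      mg <- management(start,
                       establishment = if (crop == "cauliflower")
                         "transplanted" else "sown",
                       density = dens$d, horizon = config$horizon,
                       irrigation = irrigation_schedule(wx, config$horizon))
      obs <- generate_field_campaign(pars, wx, so, mg, crop,
                                     cadence = config$cadence,
                                     noise = config$noise,
                                     seed = fseed + 2000L)
      fields[[fid]] <- field_dataset(id, crop, cv, obs, wx, so, mg)
      truth[[id]] <- pars
    }
  }
  list(fields = fields, truth = truth)
}
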