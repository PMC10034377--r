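# shared fixtures and independent oracles for the test suite

# constant benign weather, row 1 = day 0
constant_weather <- function(ndays, tmin = 12, tmax = 22, precip = 0,
                             et0 = 4, start = "2019-06-01") {
  data.frame(date = seq(as.Date(start), by = "day", length.out = ndays + 1),
             tmin = tmin, tmax = tmax, precip = precip, et0 = et0)
}

# a parameter set engineered so every stress coefficient is 1, the canopy
# jumps to full adjusted cover (CC* = 1) on day 1, and the harvest index
# never engages: daily biomass is exactly wp * kc
stress_free_params <- function(wp = 0.17, kc = 1.05) {
  crop_parameters("cauliflower",
    ccx = 1, ccs = 3000, density = 33000,       # cc0 = 0.99
    cgc = 1, plan = 0.5, sen = 5000, mat = 6000, root = 600,
    yld = 4000, hilen = 500, stbio = 1e-6,
    pexup = 1, pexlw = 1, psto = 1, psen = 1, anaer = 0,
    wp = wp, kc = kc)
}

# management with daily irrigation so soil water never limits
well_watered_mgmt <- function(ndays, depth = 12, start = "2019-06-01") {
  management(start, "transplanted", horizon = ndays,
             irrigation = data.frame(day = seq_len(ndays), depth = depth))
}

# a randomized but valid simulation scenario, for property tests
random_scenario <- function(seed) {
  set.seed(seed)
  base <- crop_parameters(sample(c("cauliflower", "spinach"), 1))
  sp <- default_screening_space(base)
  x <- runif(nrow(sp), sp$lower, sp$upper)
  p <- set_parameters(base, stats::setNames(x, sp$name))
  hz <- sample(40:90, 1)
  wx <- generate_weather(sample(c("first", "second"), 1),
                         year_seed = seed, ndays = hz + 5)
  soil <- generate_soil(sample(soil_texture_table()$texture, 1), seed = seed)
  irr <- if (runif(1) < 0.5) irrigation_schedule(wx, hz)
         else data.frame(day = integer(), depth = numeric())
  mg <- management(wx$date[1], attr(base, "establishment"), horizon = hz,
                   irrigation = irr)
  list(params = p, weather = wx, soil = soil, mgmt = mg)
}

# check the daily water balance of a trajectory against its inputs;
# returns the largest absolute closure error in mm
water_balance_error <- function(traj, scn) {
  thcols <- grep("^theta_", names(traj))
  thick <- scn$soil$layers$thickness
  storage <- as.matrix(traj[, thcols]) %*% (thick * 10)
  irr <- numeric(nrow(traj))
  if (nrow(scn$mgmt$irrigation))
    irr[scn$mgmt$irrigation$day + 1] <- scn$mgmt$irrigation$depth
  days <- traj$day[-1] + 1 # weather rows for simulated days
  influx <- scn$weather$precip[days] + irr[days]
  outflux <- traj$tr[-1] + traj$evap[-1] + traj$drainage[-1] + traj$excess[-1]
  max(abs(diff(storage) - (influx - outflux)))
}

# independent elementary-effects oracle: direct enumeration over the
# trajectory points, kept deliberately separate from the package's
# implementation
reference_ee <- function(design, y) {
  pts <- design$points
  k <- ncol(pts)
  out <- matrix(NA_real_, design$r, k)
  for (tr in seq_len(design$r)) {
    rows <- ((tr - 1) * (k + 1) + 1):(tr * (k + 1))
    for (j in seq_len(k)) {
      d <- pts[rows[j + 1], ] - pts[rows[j], ]
      i <- which(d != 0)
      out[tr, i] <- (y[rows[j + 1]] - y[rows[j]]) / d[i]
    }
  }
  out
}

# crude effective sample size (initial positive sequence)
ess <- function(x) {
  a <- stats::acf(x, lag.max = min(length(x) - 1, 400), plot = FALSE)$acf[-1]
  neg <- which(a < 0)[1]
  if (!is.na(neg)) a <- a[seq_len(neg - 1)]
  length(x) / (1 + 2 * sum(a))
}
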