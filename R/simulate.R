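# soil evaporation coefficient for bare soil (fixed convention)
KE_SOIL <- 1.10

#' Daily growing degree days
#'
#' Average-temperature GDD with both temperatures clamped to
#' `[baseT, uppT]`: `max(0, (clamp(tmax) + clamp(tmin))/2 - baseT)`.
#'
#' @param tmin,tmax daily minimum / maximum temperature (deg C).
#' @param baseT,uppT base and upper cutoff temperatures (deg C).
#' @return thermal time for the day (deg C d); vectorized.
#' @examples
#' gdd_day(10, 20, baseT = 15, uppT = 30) # 2.5
#' @export
gdd_day <- function(tmin, tmax, baseT, uppT) {
  stopifnot(all(tmin <= tmax))
  pmax(0, (clamp(tmax, baseT, uppT) + clamp(tmin, baseT, uppT)) / 2 - baseT)
}

#' Water-stress coefficient
#'
#' Convex stress response on the depletion fraction of total available
#' water: Ks = 1 below `p_up`, 0 above `p_lo`, and in between
#' `1 - (exp(s*x) - 1)/(exp(s) - 1)` with
#' `x = (depletion - p_up)/(p_lo - p_up)`; the limit `shape -> 0` is the
#' linear ramp `1 - x`.
#'
#' @param depletion root-zone depletion as a fraction of TAW (>= 0).
#' @param p_up,p_lo upper (stress onset) and lower (full stress) thresholds.
#' @param shape curvature; 0 gives the linear response.
#' @return Ks in `[0, 1]`; vectorized over `depletion`.
#' @examples
#' stress_coefficient(0.5, 0.2, 0.8, 3)
#' @export
stress_coefficient <- function(depletion, p_up, p_lo, shape = 0) {
  if (p_up > p_lo) stop("invalid thresholds: p_up > p_lo")
  if (p_up == p_lo) return(ifelse(depletion <= p_up, 1, 0))
  x <- clamp((depletion - p_up) / (p_lo - p_up), 0, 1)
  if (abs(shape) < 1e-12) 1 - x
  else clamp(1 - (exp(shape * x) - 1) / (exp(shape) - 1), 0, 1)
}

#' One canopy-cover step
#'
#' Advances green canopy cover over a thermal-time step. In the growth
#' phase cover follows exponential growth `CC = CC0 * exp(cgc_eff * t)` up
#' to `ccx/2` and the decaying approach
#' `CC = ccx - 0.25 * (ccx^2/CC0) * exp(-cgc_eff * t)` above, with
#' `cgc_eff = ks_exp * cgc`; both are applied incrementally so a varying
#' stress path is supported. In the senescence phase cover declines as
#' `CC = cc_onset * (1 - 0.05 * (exp((cdc/ccx) * t_sen) - 1))`, floored at
#' zero, with `t_sen` the cumulative thermal time since senescence onset.
#'
#' @param cc_prev cover at the start of the step (fraction).
#' @param gdd_step thermal time of the step (deg C d).
#' @param params [crop_parameters()] set (uses ccx, cgc, cdc, ccs, density).
#' @param ks_exp expansion stress coefficient in `[0, 1]`.
#' @param phase `"growth"` or `"senescence"`.
#' @param cc_onset,sen_tt for the senescence phase: cover at onset and the
#'   cumulative thermal time since onset *including* this step.
#' @return the new canopy cover (fraction).
#' @export
canopy_cover_step <- function(cc_prev, gdd_step, params, ks_exp = 1,
                              phase = c("growth", "senescence"),
                              cc_onset = NULL, sen_tt = NULL) {
  phase <- match.arg(phase)
  ccx <- params$ccx
  if (cc_prev > ccx + 1e-12) stop("invalid state: cc_prev > ccx")
  if (phase == "growth") {
    cge <- ks_exp * params$cgc
    cc <- if (cc_prev <= ccx / 2) cc_prev * exp(cge * gdd_step)
          else ccx - (ccx - cc_prev) * exp(-cge * gdd_step)
    clamp(cc, 0, ccx)
  } else {
    if (is.null(cc_onset) || is.null(sen_tt))
      stop("senescence phase needs cc_onset and sen_tt")
    max(0, cc_onset * (1 - 0.05 * (exp((params$cdc / ccx) * sen_tt) - 1)))
  }
}

#' Partition reference evapotranspiration into transpiration and evaporation
#'
#' Uses the adjusted cover `CC* = 1.72*cc - cc^2 + 0.30*cc^3` (clamped to
#' `[0, 1]`) to split ET0: potential transpiration
#' `Tr = ks_sto * ks_aer * kc * CC* * ET0` and potential soil evaporation
#' `E = ke * (1 - CC*) * ET0 * late_season_factor` with `ke = 1.10`.
#'
#' @param cc canopy cover (fraction).
#' @param et0 reference evapotranspiration (mm).
#' @param kc crop transpiration coefficient at full canopy.
#' @param ks_sto,ks_aer stomatal and aeration stress coefficients.
#' @param late_season_factor multiplier on soil evaporation after
#'   senescence onset (`1 - evardc/100`); 1 before.
#' @return list(tr, e_pot) in mm (potential values, before soil limitation).
#' @export
partition_et <- function(cc, et0, kc, ks_sto = 1, ks_aer = 1,
                         late_season_factor = 1) {
  if (et0 <= 0) stop("et0 must be > 0")
  ccstar <- clamp(1.72 * cc - cc^2 + 0.30 * cc^3, 0, 1)
  list(tr = ks_sto * ks_aer * kc * ccstar * et0,
       e_pot = KE_SOIL * (1 - ccstar) * et0 * late_season_factor)
}

#' Daily biomass increment
#'
#' Water-driven production: `dB = ks_bio * wp * (tr / et0)`, where `wp` is
#' the normalized water productivity and `ks_bio` the cold-stress
#' coefficient `clamp(gdd_day / stbio, 0, 1)` computed by the caller.
#'
#' @param tr actual transpiration (mm).
#' @param et0 reference evapotranspiration (mm), > 0.
#' @param wp normalized water productivity (t/ha).
#' @param ks_bio biomass (cold) stress coefficient in `[0, 1]`.
#' @return biomass increment (t/ha).
#' @export
biomass_increment <- function(tr, et0, wp, ks_bio = 1) {
  if (et0 <= 0) stop("et0 must be > 0")
  stopifnot(tr >= 0)
  ks_bio * wp * (tr / et0)
}

#' Harvest-index build-up fraction
#'
#' Zero before yield formation starts (`yld`), a linear ramp of thermal
#' duration `hilen`, one thereafter.
#'
#' @param gdd_cum cumulative thermal time since start (deg C d).
#' @param yld thermal time to start of yield formation (deg C d).
#' @param hilen thermal duration of harvest-index build-up (deg C d), > 0.
#' @return fraction in `[0, 1]`; vectorized over `gdd_cum`.
#' @export
harvest_index_fraction <- function(gdd_cum, yld, hilen) {
  if (hilen <= 0) stop("hilen must be > 0")
  clamp((gdd_cum - yld) / hilen, 0, 1)
}

#' One day of the layered soil water bucket
#'
#' Order of fluxes: infiltration (precip + irrigation) fills layers
#' top-down to saturation, the remainder leaving as `excess`; water above
#' field capacity percolates at `tau * (theta - theta_fc)` per day, each
#' layer draining into the next (bottom layer out of the profile);
#' evaporation is extracted from the top layer down to `0.5 * theta_wp`,
#' reduced below field capacity by the linear drying coefficient
#' `Kr = (theta - 0.5 theta_wp) / (theta_fc - 0.5 theta_wp)` (stage-2
#' evaporation); transpiration from the root zone proportionally to each
#' layer's available water, floored at `theta_wp`. The daily mass balance
#' is checked to 1e-6 mm and a violation raises an error.
#'
#' @param theta per-layer volumetric water content (vol%).
#' @param precip,irrigation,e_pot,tr_pot daily fluxes (mm, >= 0).
#' @param soil a [soil_profile()].
#' @param root_depth effective rooting depth (m) for transpiration
#'   extraction; defaults to the full profile.
#' @return list(theta, drainage, excess, e_act, tr_act).
#' @export
soil_water_step <- function(theta, precip, irrigation, e_pot, tr_pot, soil,
                            root_depth = NULL) {
  L <- soil$layers
  nl <- nrow(L)
  stopifnot(length(theta) == nl, precip >= 0, irrigation >= 0,
            e_pot >= 0, tr_pot >= 0)
  if (any(theta < 0 | theta > L$theta_sat + 1e-9))
    stop("soil state outside [0, theta_sat]")
  if (is.null(root_depth)) root_depth <- sum(L$thickness)
  storage <- function(th) sum(th / 100 * L$thickness * 1000) # vol% -> mm
  w0 <- storage(theta)

  # infiltration, top-down
  inflow <- precip + irrigation
  for (l in seq_len(nl)) {
    cap <- (L$theta_sat[l] - theta[l]) / 100 * L$thickness[l] * 1000
    add <- min(inflow, max(0, cap))
    theta[l] <- theta[l] + add / (L$thickness[l] * 10)
    inflow <- inflow - add
  }
  excess <- inflow

  # drainage cascade, top-down; receiver capped at saturation
  drainage <- 0
  for (l in seq_len(nl)) {
    d <- L$tau[l] * max(0, theta[l] - L$theta_fc[l]) / 100 * L$thickness[l] * 1000
    if (l < nl) {
      cap <- (L$theta_sat[l + 1] - theta[l + 1]) / 100 * L$thickness[l + 1] * 1000
      d <- min(d, max(0, cap))
      theta[l + 1] <- theta[l + 1] + d / (L$thickness[l + 1] * 10)
    } else {
      drainage <- d
    }
    theta[l] <- theta[l] - d / (L$thickness[l] * 10)
  }

  # evaporation from the top layer, reduced as the surface dries
  floor_e <- 0.5 * L$theta_wp[1]
  avail_e <- max(0, theta[1] - floor_e) / 100 * L$thickness[1] * 1000
  kr <- clamp((theta[1] - floor_e) / (L$theta_fc[1] - floor_e), 0, 1)
  e_act <- min(e_pot * kr, avail_e)
  theta[1] <- theta[1] - e_act / (L$thickness[1] * 10)

  # transpiration from the root zone, proportional to available water
  top <- cumsum(c(0, L$thickness))[seq_len(nl)]
  dz <- pmax(0, pmin(top + L$thickness, root_depth) - top)
  avail <- pmax(0, theta - L$theta_wp) / 100 * dz * 1000
  tot <- sum(avail)
  tr_act <- min(tr_pot, tot)
  if (tot > 0 && tr_act > 0) {
    ext <- tr_act * avail / tot
    theta <- theta - ext / (L$thickness * 10)
  }

  bal <- (storage(theta) - w0) - (precip + irrigation - e_act - tr_act -
                                    drainage - excess)
  if (abs(bal) > 1e-6)
    stop("soil water mass balance violated by ", format(bal), " mm")
  list(theta = theta, drainage = drainage, excess = excess,
       e_act = e_act, tr_act = tr_act)
}

#' Simulate a crop season
#'
#' Chains the daily operations: thermal time, rooting-depth growth (linear
#' in thermal time from `rtn` to `rtx`, reached at `root`), root-zone
#' depletion and TAW, the four water-stress coefficients (expansion,
#' stomatal, senescence, aeration) plus cold stress on biomass, canopy
#' development, the transpiration/evaporation split, the soil water bucket,
#' water-driven biomass accumulation and harvest-index yield build-up. The
#' simulation stops at maturity (`mat` deg C d) or at the management
#' horizon, whichever comes first.
#'
#' @param params a [crop_parameters()] set.
#' @param weather daily weather (see [validate_weather()]); row 1 is day 0
#'   and at least `horizon + 1` rows are required.
#' @param soil a [soil_profile()].
#' @param mgmt a [management()] plan.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); both produce identical trajectories.
#' @return data.frame of class `daily_trajectory`, one row per day from
#'   day 0: `day`, `gdd_day`, `gdd_cum`, `cc`, `root_depth`,
#'   `theta_1..theta_L` (vol%), `dr`, `taw` (mm), `tr`, `evap`,
#'   `drainage`, `excess` (mm), `ks_exp`, `ks_sto`, `ks_sen`, `ks_aer`,
#'   `ks_bio`, `biomass`, `yield` (t/ha).
#' @examples
#' wx <- generate_weather("first", year_seed = 1, ndays = 100)
#' mg <- management(wx$date[1], "transplanted", horizon = 90)
#' tr <- simulate_crop(crop_parameters("cauliflower"), wx,
#'                     soil_profile("loam"), mg)
#' tail(tr[, c("day", "cc", "biomass", "yield")], 3)
#' @export
simulate_crop <- function(params, weather, soil, mgmt, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  validate_crop_parameters(params)
  weather <- validate_weather(weather)
  if (!is.null(mgmt$density)) params$density <- mgmt$density
  validate_crop_parameters(params)
  horizon <- mgmt$horizon
  if (nrow(weather) < horizon + 1)
    stop("horizon too short: weather has ", nrow(weather),
         " days, need ", horizon + 1)
  irr <- numeric(horizon + 1)
  if (nrow(mgmt$irrigation))
    irr[mgmt$irrigation$day + 1] <- irr[mgmt$irrigation$day + 1] +
      mgmt$irrigation$depth
  transplanted <- identical(mgmt$establishment, "transplanted")

  if (engine == "cpp") {
    L <- soil$layers
    out <- simulate_core_cpp(
      param_vector(params), as.integer(transplanted),
      weather$tmin[seq_len(horizon + 1)], weather$tmax[seq_len(horizon + 1)],
      weather$precip[seq_len(horizon + 1)], weather$et0[seq_len(horizon + 1)],
      irr, L$thickness, L$theta_sat, L$theta_fc, L$theta_wp, L$tau,
      soil$theta_init, as.integer(horizon), KE_SOIL
    )
    traj <- as.data.frame(out)
    names(traj) <- trajectory_columns(nrow(soil$layers))
  } else {
    traj <- simulate_crop_r(params, weather, soil, irr, horizon, transplanted)
  }
  class(traj) <- c("daily_trajectory", "data.frame")
  attr(traj, "start_date") <- mgmt$start_date
  traj
}

trajectory_columns <- function(nl) {
  c("day", "gdd_day", "gdd_cum", "cc", "root_depth",
    paste0("theta_", seq_len(nl)), "dr", "taw", "tr", "evap",
    "drainage", "excess", "ks_exp", "ks_sto", "ks_sen", "ks_aer", "ks_bio",
    "biomass", "yield")
}

# Precompiled scenario for repeated simulation of one field under many
# parameter vectors (calibration, screening, propagation): all validation
# and data marshalling happens once, after which fast_sim() is a direct
# call into the compiled core.
compile_scenario <- function(params, weather, soil, mgmt) {
  validate_crop_parameters(params)
  weather <- validate_weather(weather)
  if (!is.null(mgmt$density)) params$density <- mgmt$density
  horizon <- mgmt$horizon
  if (nrow(weather) < horizon + 1)
    stop("horizon too short: weather has ", nrow(weather), " days, need ",
         horizon + 1)
  irr <- numeric(horizon + 1)
  if (nrow(mgmt$irrigation))
    irr[mgmt$irrigation$day + 1] <- irr[mgmt$irrigation$day + 1] +
      mgmt$irrigation$depth
  L <- soil$layers
  nm <- trajectory_columns(nrow(L))
  keep <- seq_len(horizon + 1)
  list(par0 = param_vector(params),
       transplanted = as.integer(identical(mgmt$establishment, "transplanted")),
       tmin = weather$tmin[keep], tmax = weather$tmax[keep],
       precip = weather$precip[keep], et0 = weather$et0[keep], irr = irr,
       thick = L$thickness, th_s = L$theta_sat, th_fc = L$theta_fc,
       th_wp = L$theta_wp, tau = L$tau, init = soil$theta_init,
       horizon = as.integer(horizon),
       cols = setNames(seq_along(nm), nm))
}

# raw trajectory matrix for a compiled scenario; idx/values overwrite
# entries of the PARAM_ORDER vector
fast_sim <- function(scn, idx = NULL, values = NULL) {
  par <- scn$par0
  if (length(idx)) par[idx] <- values
  simulate_core_cpp(par, scn$transplanted, scn$tmin, scn$tmax, scn$precip,
                    scn$et0, scn$irr, scn$thick, scn$th_s, scn$th_fc,
                    scn$th_wp, scn$tau, scn$init, scn$horizon, KE_SOIL)
}

# pure-R reference engine; mirrors src/simulate_core.cpp step for step
simulate_crop_r <- function(p, weather, soil, irr, horizon, transplanted) {
  L <- soil$layers
  nl <- nrow(L)
  theta <- soil$theta_init
  cc0 <- p$ccs * p$density / 1e8
  cc <- if (transplanted) cc0 else 0
  gdd_cum <- 0
  biomass <- 0
  senescent <- FALSE
  cc_onset <- NA_real_
  sen_tt <- 0
  rows <- vector("list", horizon + 1)
  rows[[1]] <- c(0, 0, 0, cc, p$rtn, theta, 0, 0, 0, 0, 0, 0,
                 1, 1, 1, 1, 1, 0, 0)
  last <- 1

  for (t in seq_len(horizon)) {
    g <- gdd_day(weather$tmin[t + 1], weather$tmax[t + 1], p$baseT, p$uppT)
    gdd_cum <- gdd_cum + g
    zr <- min(p$rtn + (p$rtx - p$rtn) * min(1, gdd_cum / p$root),
              sum(L$thickness))
    top <- cumsum(c(0, L$thickness))[seq_len(nl)]
    dz <- pmax(0, pmin(top + L$thickness, zr) - top)
    taw <- sum((L$theta_fc - L$theta_wp) / 100 * dz * 1000)
    dr <- sum(pmax(0, L$theta_fc - theta) / 100 * dz * 1000)
    pfrac <- if (taw > 0) dr / taw else 0
    ks_exp <- stress_coefficient(pfrac, p$pexup, p$pexlw, p$pexhp)
    ks_sto <- stress_coefficient(pfrac, p$psto, 1, 0)
    ks_sen <- stress_coefficient(pfrac, p$psen, 1, p$psenshp)
    th_rz <- if (sum(dz) > 0) sum(theta * dz) / sum(dz) else theta[1]
    ts_rz <- if (sum(dz) > 0) sum(L$theta_sat * dz) / sum(dz) else L$theta_sat[1]
    ks_aer <- if (p$anaer <= 0) 1 else clamp((ts_rz - th_rz) / p$anaer, 0, 1)
    ks_bio <- if (p$stbio > 0) clamp(g / p$stbio, 0, 1) else 1

    if (!senescent && gdd_cum >= p$sen) {
      senescent <- TRUE
      cc_onset <- cc
      sen_tt <- 0
    }
    if (senescent) {
      sen_tt <- sen_tt + g
      cc <- canopy_cover_step(cc, g, p, phase = "senescence",
                              cc_onset = cc_onset, sen_tt = sen_tt)
    } else if (gdd_cum >= p$plan) {
      if (cc <= 0) cc <- cc0
      if (ks_sen < 1) {
        dt <- g * (1 - ks_sen)
        cc <- max(0, cc * (1 - 0.05 * (exp((p$cdc / p$ccx) * dt) - 1)))
      } else {
        cc <- canopy_cover_step(cc, g, p, ks_exp = ks_exp, phase = "growth")
      }
    }

    et0 <- weather$et0[t + 1]
    late <- if (senescent) 1 - p$evardc / 100 else 1
    pe <- partition_et(cc, et0, p$kc, ks_sto, ks_aer, late)
    sw <- soil_water_step(theta, weather$precip[t + 1], irr[t + 1],
                          pe$e_pot, pe$tr, soil, root_depth = zr)
    theta <- sw$theta
    biomass <- biomass + biomass_increment(sw$tr_act, et0, p$wp, ks_bio)
    yield <- harvest_index_fraction(gdd_cum, p$yld, p$hilen) * p$hi * biomass

    rows[[t + 1]] <- c(t, g, gdd_cum, cc, zr, theta, dr, taw, sw$tr_act,
                       sw$e_act, sw$drainage, sw$excess, ks_exp, ks_sto,
                       ks_sen, ks_aer, ks_bio, biomass, yield)
    last <- t + 1
    if (gdd_cum >= p$mat) break
  }
  traj <- as.data.frame(do.call(rbind, rows[seq_len(last)]))
  names(traj) <- trajectory_columns(nl)
  traj
}
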