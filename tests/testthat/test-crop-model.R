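test_that("daily thermal time follows the clamped-average formula", {
  expect_equal(gdd_day(10, 20, baseT = 15, uppT = 30), 2.5)
  expect_equal(gdd_day(2, 14, baseT = 15, uppT = 30), 0) # tmax below base
  expect_equal(gdd_day(15, 30, baseT = 15, uppT = 30), (30 - 15) / 2)
  expect_equal(gdd_day(10, 45, baseT = 15, uppT = 30), (30 + 15) / 2 - 15)
})

test_that("stress coefficient has the right plateaus and exponential body", {
  expect_equal(stress_coefficient(0, 0.2, 0.8, 3), 1)
  expect_equal(stress_coefficient(0.9, 0.2, 0.8, 3), 0)
  expect_equal(stress_coefficient(0.5, 0.2, 0.8, 0), 0.5) # linear midpoint
  expect_equal(stress_coefficient(0.5, 0, 1, 3),
               1 - (exp(1.5) - 1) / (exp(3) - 1))
  # shape -> 0 converges to the linear ramp
  expect_equal(stress_coefficient(0.3, 0, 1, 1e-9), 0.7, tolerance = 1e-6)
  expect_error(stress_coefficient(0.5, 0.8, 0.2), "invalid thresholds")
})

test_that("canopy growth follows the exponential and decay branches", {
  p <- crop_parameters("cauliflower", ccx = 0.95, cgc = 0.01)
  # zero effective growth leaves cover unchanged
  expect_equal(canopy_cover_step(0.2, 50, p, ks_exp = 0), 0.2)
  # below ccx/2: cc0 * exp(cgc * t); 0.05 doubles after 69.3 deg C d
  expect_equal(canopy_cover_step(0.05, 69.3, p), 0.05 * exp(0.693))
  expect_equal(canopy_cover_step(0.05, 69.3, p), 0.10, tolerance = 1e-3)
  # above ccx/2: decaying approach never exceeds ccx
  cc <- canopy_cover_step(0.6, 500, p)
  expect_lt(cc, p$ccx)
  expect_gt(cc, 0.6)
  # senescence decline floors at zero for large cdc
  psen <- crop_parameters("cauliflower", cdc = 2)
  expect_equal(canopy_cover_step(0.9, 10, psen, phase = "senescence",
                                 cc_onset = 0.9, sen_tt = 40), 0)
  expect_error(canopy_cover_step(0.99, 10, p), "invalid state")
})

test_that("ET partitioning and biomass increment follow their products", {
  pe <- partition_et(0, 4, kc = 1.1)
  expect_equal(pe$tr, 0)
  expect_equal(pe$e_pot, 1.10 * 4) # bare soil evaporates at ke * et0
  # full adjusted cover: CC*(1) clamps to 1
  pe2 <- partition_et(1, 4, kc = 1.1)
  expect_equal(pe2$tr, 4.4)
  expect_equal(partition_et(0.8, 4, 1.1, ks_sto = 0)$tr, 0)
  expect_equal(biomass_increment(0, 4, 0.15), 0)
  expect_equal(biomass_increment(4, 4, 0.15), 0.15)
  expect_equal(biomass_increment(3, 4, 0.15, ks_bio = 0.5), 0.05625)
})

test_that("harvest index ramps linearly between yld and yld + hilen", {
  expect_equal(harvest_index_fraction(399, 400, 500), 0)
  expect_equal(harvest_index_fraction(650, 400, 500), 0.5)
  expect_equal(harvest_index_fraction(900, 400, 500), 1)
  expect_equal(harvest_index_fraction(2000, 400, 500), 1)
})

test_that("soil bucket conserves mass and drains above field capacity", {
  soil <- soil_profile("loam")
  th <- soil$layers$theta_fc
  # no fluxes: identity, no drainage
  out <- soil_water_step(th, 0, 0, 0, 0, soil)
  expect_equal(out$theta, th)
  expect_equal(out$drainage, 0)
  # a saturated 0.3 m layer with tau = 0.5 drains 22.5 mm on day one
  s1 <- soil_profile(layers = data.frame(thickness = 0.3, theta_sat = 45,
                                         theta_fc = 30, theta_wp = 10,
                                         tau = 0.5),
                     theta_init = 45)
  out1 <- soil_water_step(45, 0, 0, 0, 0, s1)
  expect_equal(out1$drainage, 0.5 * (45 - 30) / 100 * 300)
  # infiltration beyond saturation leaves as excess
  out2 <- soil_water_step(th, 500, 0, 0, 0, soil)
  expect_gt(out2$excess, 0)
  cap <- sum((soil$layers$theta_sat - th) / 100 * soil$layers$thickness * 1000)
  expect_equal(out2$excess, 500 - cap)
})

test_that("compiled and reference engines produce identical trajectories", {
  for (seed in 1:8) {
    scn <- random_scenario(seed)
    t_cpp <- simulate_crop(scn$params, scn$weather, scn$soil, scn$mgmt)
    t_r <- simulate_crop(scn$params, scn$weather, scn$soil, scn$mgmt,
                         engine = "r")
    expect_lt(max(abs(as.matrix(t_cpp) - as.matrix(t_r))), 1e-9)
  }
})

test_that("trajectory invariants hold on randomized scenarios", {
  for (seed in 11:30) {
    scn <- random_scenario(seed)
    tr <- simulate_crop(scn$params, scn$weather, scn$soil, scn$mgmt)
    expect_true(all(tr$cc >= 0 & tr$cc <= scn$params$ccx + 1e-12))
    expect_true(all(diff(tr$biomass) >= -1e-12))
    expect_true(all(tr$yield <= scn$params$hi * tr$biomass + 1e-12))
    ks <- as.matrix(tr[, c("ks_exp", "ks_sto", "ks_sen", "ks_aer", "ks_bio")])
    expect_true(all(ks >= 0 & ks <= 1))
    expect_lt(water_balance_error(tr, scn), 1e-6)
  }
})

test_that("a well-watered season never triggers water stress", {
  p <- crop_parameters("cauliflower")
  wx <- constant_weather(60)
  tr <- simulate_crop(p, wx, soil_profile("loam"), well_watered_mgmt(60))
  expect_true(all(tr$ks_exp == 1))
  expect_true(all(tr$ks_sto == 1))
  expect_true(all(tr$ks_sen == 1))
})

test_that("with unlimited water biomass is invariant to rain timing", {
  p <- stress_free_params()
  soil <- soil_profile("loam")
  mg <- well_watered_mgmt(30)
  wx1 <- constant_weather(30)
  wx2 <- wx1
  wx2$precip[10:14] <- c(30, 0, 0, 20, 0) # same water, different days
  b1 <- simulate_crop(p, wx1, soil, mg)$biomass
  b2 <- simulate_crop(p, wx2, soil, mg)$biomass
  expect_equal(tail(b1, 1), tail(b2, 1), tolerance = 1e-12)
})

test_that("less mid-season rain cannot increase biomass", {
  p <- crop_parameters("cauliflower")
  soil <- generate_soil("loamy_sand", seed = 3)
  wx_wet <- generate_weather("first", year_seed = 8, ndays = 95)
  wx_dry <- wx_wet
  mid <- 40:60
  wet_days <- mid[wx_wet$precip[mid] > 0]
  wx_dry$precip[wet_days] <- pmax(0, wx_wet$precip[wet_days] - 40 / length(wet_days))
  mg <- management(wx_wet$date[1], "transplanted", horizon = 90)
  b_wet <- tail(simulate_crop(p, wx_wet, soil, mg)$biomass, 1)
  b_dry <- tail(simulate_crop(p, wx_dry, soil, mg)$biomass, 1)
  expect_lte(b_dry, b_wet + 1e-12)
})

test_that("scaling wp scales final biomass exactly when stress is unchanged", {
  scn <- random_scenario(99)
  p2 <- scn$params
  p2$wp <- 3 * scn$params$wp
  b1 <- tail(simulate_crop(scn$params, scn$weather, scn$soil, scn$mgmt)$biomass, 1)
  b2 <- tail(simulate_crop(p2, scn$weather, scn$soil, scn$mgmt)$biomass, 1)
  expect_equal(b2, 3 * b1, tolerance = 1e-12)
})

test_that("input validation rejects broken scenarios", {
  p <- crop_parameters("cauliflower")
  expect_error(simulate_crop(p, constant_weather(10), soil_profile("loam"),
                             management("2019-06-01", "transplanted",
                                        horizon = 90)),
               "horizon too short")
  expect_error(crop_parameters("cauliflower", mat = 100), NA) # build ok
  expect_error(validate_crop_parameters(crop_parameters("cauliflower",
                                                        mat = 100)),
               "plan < sen < mat")
  expect_error(soil_profile("peat"), "unknown texture")
})
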