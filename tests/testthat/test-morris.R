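test_that("trajectory designs respect the grid geometry", {
  sp <- parameter_space(letters[1:4], rep(0, 4), rep(1, 4))
  d <- build_trajectories(sp, levels = 8, r = 10, seed = 3)
  expect_equal(d$delta, 8 / 14) # levels / (2 * (levels - 1))
  expect_equal(nrow(d$points), 10 * (4 + 1))
  # each consecutive pair differs in exactly one coordinate by +/- delta
  for (tr in 1:10) {
    rows <- ((tr - 1) * 5 + 1):(tr * 5)
    for (j in 1:4) {
      dx <- d$points[rows[j + 1], ] - d$points[rows[j], ]
      expect_equal(sum(dx != 0), 1)
      expect_equal(abs(dx[dx != 0]), d$delta)
    }
  }
  expect_true(all(d$points >= 0 & d$points <= 1))
  # grid membership: coordinates are multiples of 1/(levels-1)
  expect_true(all(abs(d$points * 7 - round(d$points * 7)) < 1e-12))
  # determinism
  d2 <- build_trajectories(sp, levels = 8, r = 10, seed = 3)
  expect_identical(d$points, d2$points)
  expect_error(build_trajectories(sp, levels = 7, r = 10, seed = 1),
               "invalid design")
})

test_that("affine models give exact range-scaled mu* and zero sigma", {
  sp <- parameter_space(c("a", "b"), c(0, 0), c(2, 5))
  d <- build_trajectories(sp, levels = 8, r = 20, seed = 5)
  phys <- sweep(sweep(d$points, 2, c(2, 5), "*"), 2, c(0, 0), "+")
  y <- 3 * phys[, 1] + 2 * phys[, 2] + 1
  ee <- elementary_effects(d, y)
  mu <- apply(abs(ee[, , 1]), 2, mean)
  sg <- apply(ee[, , 1], 2, sd)
  # normalized-coordinate effects carry the range scaling
  expect_equal(mu, c(3 * 2, 2 * 5), tolerance = 1e-10)
  expect_lt(max(sg), 1e-10)
  # constant model: all effects zero
  ee0 <- elementary_effects(d, rep(4, nrow(phys)))
  expect_true(all(ee0 == 0))
})

test_that("interaction terms force positive sigma on both factors", {
  sp <- parameter_space(c("a", "b"), c(0, 0), c(1, 1))
  d <- build_trajectories(sp, levels = 8, r = 30, seed = 7)
  y <- d$points[, 1] * d$points[, 2]
  ee <- elementary_effects(d, y)
  expect_gt(sd(ee[, 1, 1]), 0)
  expect_gt(sd(ee[, 2, 1]), 0)
})

test_that("package effects agree with the direct-enumeration reference", {
  sp <- parameter_space(letters[1:5], rep(0, 5), rep(1, 5))
  d <- build_trajectories(sp, levels = 8, r = 25, seed = 11)
  x <- d$points
  y <- sin(3 * x[, 1]) + x[, 2]^2 * x[, 3] + exp(x[, 4]) + 0.5 * x[, 5]
  ee <- elementary_effects(d, y)
  ref <- reference_ee(d, y)
  expect_lt(max(abs(ee[, , 1] - ref) / pmax(abs(ref), 1e-12)), 1e-8)
})

test_that("rescaling makes mu* invariant to output scale", {
  sp <- parameter_space(c("a", "b"), c(0.5, 0.5), c(1.5, 1.5))
  d <- build_trajectories(sp, levels = 8, r = 20, seed = 13)
  x <- d$points
  y <- 2 + x[, 1] + 0.5 * x[, 2]
  r1 <- rescale_and_aggregate(elementary_effects(d, y), y,
                              variables = "v", days = 1)
  r2 <- rescale_and_aggregate(elementary_effects(d, 2 * y), 2 * y,
                              variables = "v", days = 1)
  expect_equal(r1$mu_star_agg, r2$mu_star_agg, tolerance = 1e-12)
})

test_that("aggregation averages days then variables", {
  sp <- parameter_space(c("a", "b"), c(0, 0), c(1, 1))
  d <- build_trajectories(sp, levels = 8, r = 15, seed = 17)
  x <- d$points
  # two variables with identical rescaled profiles aggregate to either
  y1 <- 1 + x[, 1] + 2 * x[, 2]
  Y <- cbind(y1, y1, 2 * y1) # var v1 on two days, var v2 once (scaled)
  ee <- elementary_effects(d, Y)
  res <- rescale_and_aggregate(ee, Y, variables = c("v1", "v1", "v2"),
                               days = c(1, 2, 1))
  single <- rescale_and_aggregate(elementary_effects(d, y1), y1,
                                  variables = "v1", days = 1)
  expect_equal(res$mu_star_agg, single$mu_star_agg, tolerance = 1e-12)
  # hand-computed linear two-output aggregate via the reference oracle
  y2 <- 3 + 0.2 * x[, 1] + 0.9 * x[, 2]
  Y2 <- cbind(y1, y2)
  res2 <- rescale_and_aggregate(elementary_effects(d, Y2), Y2,
                                variables = c("v1", "v2"), days = c(1, 1))
  ref <- (colMeans(abs(reference_ee(d, y1))) / mean(y1) +
          colMeans(abs(reference_ee(d, y2))) / mean(y2)) / 2
  expect_equal(unname(res2$mu_star_agg), unname(ref), tolerance = 1e-12)
  # degenerate variable: identically zero output
  expect_error(rescale_and_aggregate(ee, cbind(y1, y1, 0 * y1),
                                     variables = c("v1", "v1", "dead"),
                                     days = c(1, 2, 1)),
               "degenerate")
})

test_that("influential-subset selection takes the minimal prefix", {
  mu <- c(p1 = 0.5, p2 = 0.3, p3 = 0.15, p4 = 0.05)
  expect_equal(select_influential(mu, 0.95), c("p1", "p2", "p3"))
  expect_equal(select_influential(c(a = 0.96, b = 0.04), 0.95), "a")
  # idempotent on its own output; prefix length non-increasing in threshold
  lens <- vapply(c(0.5, 0.7, 0.9, 0.99),
                 function(th) length(select_influential(mu, th)), numeric(1))
  expect_true(all(diff(lens) >= 0))
  expect_error(select_influential(c(a = 0, b = 0)), "all-zero")
})

test_that("crop-model screening ranks canopy growth among the leaders", {
  base <- crop_parameters("cauliflower")
  sp <- default_screening_space(base)
  wx <- generate_weather("first", year_seed = 2, ndays = 100)
  mg <- management(wx$date[1], "transplanted", horizon = 90,
                   irrigation = irrigation_schedule(wx, 90))
  res <- morris_screen(sp, base, wx, soil_profile("loam"), mg,
                       r = 12, seed = 4)
  expect_true(all(res$mu_star_agg >= 0))
  expect_equal(sum(res$share), 1)
  expect_true("cgc" %in% res$selected[1:5])
  # selection is the minimal prefix reaching 95% cumulative share
  ord <- order(-res$mu_star_agg, seq_along(res$mu_star_agg))
  cum <- cumsum(res$mu_star_agg[ord]) / sum(res$mu_star_agg)
  expect_gte(cum[length(res$selected)], 0.95 - 1e-12)
  if (length(res$selected) > 1)
    expect_lt(cum[length(res$selected) - 1], 0.95)
})
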