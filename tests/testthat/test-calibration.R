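make_labelled_fields <- function(counts) {
  # counts: named list cultivar -> c(first, second)
  fields <- list()
  i <- 0
  for (cv in names(counts)) {
    for (pd in c("first", "second")) {
      n <- counts[[cv]][if (pd == "first") 1 else 2]
      for (j in seq_len(n)) {
        i <- i + 1
        start <- if (pd == "first") "2019-04-20" else "2019-07-25"
        wx <- constant_weather(30, start = start)
        mg <- management(start, "transplanted", horizon = 30)
        obs <- data.frame(day = c(10, 20), variable = "biomass",
                          value = c(0.5, 1.0))
        fields[[i]] <- field_dataset(paste0("f", i), "cauliflower", cv,
                                     obs, wx, soil_profile("loam"), mg)
      }
    }
  }
  fields
}

test_that("stratification partitions fields by label", {
  fields <- make_labelled_fields(list(David = c(7, 4), Giewont = c(2, 3)))
  s_all <- stratify(fields, "all")
  expect_length(s_all, 1)
  expect_length(s_all[[1]], 16)
  s_cvp <- stratify(fields, "cultivar_x_period")
  expect_equal(sort(vapply(s_cvp, length, numeric(1))),
               sort(c(David_first = 7, Giewont_first = 2,
                      David_second = 4, Giewont_second = 3)),
               ignore_attr = TRUE)
  # a partition: disjoint with union equal to the input
  ids <- unlist(lapply(s_cvp, function(g) vapply(g, `[[`, "", "id")))
  expect_setequal(ids, vapply(fields, `[[`, "", "id"))
  expect_length(ids, length(fields))
  # single cultivar collapses to one stratum
  solo <- make_labelled_fields(list(David = c(2, 1)))
  expect_length(stratify(solo, "cultivar"), 1)
  # period labels derive from the start month
  expect_equal(vapply(stratify(fields, "period"), length, numeric(1)),
               c(first = 9, second = 7))
})

test_that("log-likelihood matches the Gaussian closed forms", {
  p <- crop_parameters("cauliflower")
  wx <- generate_weather("first", year_seed = 6, ndays = 95)
  mg <- management(wx$date[1], "transplanted", horizon = 90,
                   irrigation = irrigation_schedule(wx, 90))
  soil <- generate_soil("loam", seed = 6)
  noise0 <- list(canopy_cover = 0, biomass_rel = 0, biomass_floor = 0, swc = 0)
  obs <- generate_field_campaign(p, wx, soil, mg, "cauliflower",
                                 noise = noise0, seed = 1)
  f <- field_dataset("f1", "cauliflower", "X", obs, wx, soil, mg)
  th <- c(wp = p$wp)
  vars <- unique(obs$variable)
  s2 <- stats::setNames(rep(1, length(vars)), vars)
  # zero residuals: -n/2 log(2 pi) at unit variances
  expect_equal(log_likelihood(th, list(f), s2, p),
               -nrow(obs) / 2 * log(2 * pi), tolerance = 1e-8)
  # single observation with residual = sigma
  one <- obs[obs$variable == "biomass", ][1, ]
  one$value <- one$value + 0.5
  f1 <- field_dataset("f1", "cauliflower", "X", one, wx, soil, mg)
  expect_equal(log_likelihood(th, list(f1), c(biomass = 0.25), p),
               -0.5 * log(2 * pi * 0.25) - 0.5, tolerance = 1e-8)
})

test_that("the likelihood prefers the generating parameters", {
  p <- crop_parameters("cauliflower")
  wins <- 0
  for (rep in 1:50) {
    wx <- generate_weather("first", year_seed = 200 + rep, ndays = 95)
    mg <- management(wx$date[1], "transplanted", horizon = 90,
                     irrigation = irrigation_schedule(wx, 90))
    soil <- generate_soil("loam", seed = 300 + rep)
    obs <- generate_field_campaign(p, wx, soil, mg, "cauliflower",
                                   seed = 400 + rep)
    f <- field_dataset("f", "cauliflower", "X", obs, wx, soil, mg)
    vars <- unique(obs$variable)
    s2 <- stats::setNames(c(biomass = 0.1, canopy_cover = 25, swc_0_30 = 4,
                            swc_30_60 = 4, yield = 0.1)[vars], vars)
    l_true <- log_likelihood(c(wp = p$wp), list(f), s2, p)
    l_pert <- log_likelihood(c(wp = 1.2 * p$wp), list(f), s2, p)
    if (l_true >= l_pert) wins <- wins + 1
  }
  expect_gte(wins, 48) # >= 95% of 50 seeded replicates
})

test_that("DRAM samples the uniform prior when the likelihood is flat", {
  sp <- parameter_space(c("a", "b"), c(0, 10), c(1, 30))
  ch <- suppressWarnings(run_dram(function(th) 0, sp, n_iter = 20000,
                                  burn_in = 2000, seed = 4))
  po <- posterior_samples(ch)
  for (j in 1:2) {
    rng <- sp$upper[j] - sp$lower[j]
    se <- rng / sqrt(12 * ess(po[, j]))
    expect_lt(abs(mean(po[, j]) - (sp$lower[j] + sp$upper[j]) / 2), 3 * se)
  }
  expect_true(all(po[, 1] >= 0 & po[, 1] <= 1))
  expect_gt(ch$acceptance_rate, 0)
  expect_lt(ch$acceptance_rate, 1)
})

test_that("DRAM recovers a conjugate linear-Gaussian posterior", {
  set.seed(9)
  x <- runif(40, 0, 2)
  s2 <- 0.25
  y <- 1.3 * x + rnorm(40, 0, sqrt(s2))
  prec <- sum(x^2) / s2
  an_mean <- sum(x * y) / s2 / prec
  an_sd <- 1 / sqrt(prec)
  lp <- function(th) -sum((y - th[1] * x)^2) / (2 * s2)
  ch <- suppressWarnings(run_dram(lp, parameter_space("a", -10, 10),
                                  n_iter = 20000, burn_in = 2000, seed = 5))
  po <- posterior_samples(ch)[, 1]
  ne <- ess(po)
  expect_lt(abs(mean(po) - an_mean), 3 * an_sd / sqrt(ne))
  expect_lt(abs(sd(po) - an_sd), 3 * an_sd / sqrt(2 * (ne - 1)))
})

test_that("DRAM passes a goodness-of-fit check on a 2-D Gaussian target", {
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  Si <- solve(S)
  lp <- function(th) -0.5 * drop(t(th) %*% Si %*% th)
  sp <- parameter_space(c("u", "v"), c(-8, -8), c(8, 8))
  ch <- suppressWarnings(run_dram(lp, sp, n_iter = 30000, burn_in = 3000,
                                  seed = 6))
  po <- posterior_samples(ch)
  r2 <- rowSums((po %*% Si) * po) # Mahalanobis radii ~ chisq(2)
  thin <- po[seq(1, nrow(po), by = 27), , drop = FALSE]
  r2t <- r2[seq(1, length(r2), by = 27)]
  counts <- table(cut(r2t, qchisq(seq(0, 1, 0.1), df = 2),
                      include.lowest = TRUE))
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("DRAM defaults echo the study settings", {
  fm <- formals(run_dram)
  expect_equal(fm$n_iter, 30000)
  expect_equal(fm$burn_in, 3000)
  expect_equal(fm$jump_frac, 0.1)
})

test_that("calibrated chains stay inside the prior and estimate variances", {
  st <- generate_study(study_config("cauliflower", fields_per_cell = c(1, 1, 0, 0),
                                    seed = 77))
  sp <- parameter_space(c("cgc", "wp"), c(0.008, 0.10), c(0.016, 0.25))
  ch <- suppressWarnings(calibrate_fields(st$fields, sp,
                                          crop_parameters("cauliflower"),
                                          n_iter = 1500, burn_in = 300,
                                          seed = 2))
  po <- posterior_samples(ch)
  expect_true(all(po[, "cgc"] >= 0.008 & po[, "cgc"] <= 0.016))
  expect_true(all(po[, "wp"] >= 0.10 & po[, "wp"] <= 0.25))
  expect_true(all(ch$sigma2 > 0))
  expect_equal(nrow(po), 1200)
  expect_error(run_dram(function(th) -Inf,
                        parameter_space("a", 0, 1), n_iter = 100,
                        burn_in = 10, seed = 1),
               "non-finite")
})

test_that("error-model diagnostics flag what they should", {
  # identical residual vectors correlate perfectly
  r <- rnorm(30)
  res <- data.frame(variable = rep(c("a", "b"), each = 30),
                    residual = c(r, r))
  d <- check_error_assumptions(res)
  expect_equal(d$pearson$r[1], 1)
  expect_true(d$pearson$flagged[1])
  # variance inflation by 10x is caught by the Levene test
  set.seed(3)
  res2 <- data.frame(variable = rep(c("a", "b"), each = 100),
                     residual = c(rnorm(100, 0, 1), rnorm(100, 0, 10)))
  expect_true(check_error_assumptions(res2)$levene$flagged)
  # type-I error rate of the homogeneity flag is near alpha
  set.seed(11)
  flags <- vapply(1:100, function(i) {
    rr <- data.frame(variable = rep(c("a", "b"), each = 40),
                     residual = rnorm(80))
    check_error_assumptions(rr)$levene$flagged
  }, logical(1))
  expect_lte(mean(flags), 0.12)
  expect_error(check_error_assumptions(data.frame(variable = "a",
                                                  residual = 1:5)),
               "insufficient")
})

test_that("posterior summaries report moments, intervals and densities", {
  # fabricated constant chain: sd 0, interval collapses
  sp <- parameter_space("a", 0, 1)
  ch <- structure(list(samples = matrix(0.4, 500, 1,
                                        dimnames = list(NULL, "a")),
                       burn_in = 100L, n_iter = 500L, space = sp),
                  class = "posterior_chain")
  s <- posterior_summaries(ch)
  expect_equal(s$sd, 0)
  expect_equal(s$q5, 0.4)
  expect_equal(s$q95, 0.4)
  # uniform chain: mean ~ 0.5, 90% interval ~ [0.05, 0.95]
  ch2 <- suppressWarnings(run_dram(function(th) 0, sp, n_iter = 10000,
                                   burn_in = 1000, seed = 8))
  s2 <- posterior_summaries(ch2)
  expect_equal(s2$mean, 0.5, tolerance = 0.05)
  expect_equal(s2$q5, 0.05, tolerance = 0.04)
  expect_equal(s2$q95, 0.95, tolerance = 0.04)
  expect_error(posterior_summaries(structure(list(
    samples = matrix(1, 50, 1), burn_in = 0L, n_iter = 50L, space = sp),
    class = "posterior_chain")), "too short")
})
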