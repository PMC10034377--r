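#' Assemble a field dataset
#'
#' Bundles one field's observations with its weather, soil and management
#' and the cultivar / growing-period labels used for stratification. The
#' period label is derived from the start month (April-June = `first`,
#' July-October = `second`).
#'
#' @param id field identifier.
#' @param crop `"cauliflower"` or `"spinach"`.
#' @param cultivar cultivar label.
#' @param obs data.frame with columns `day`, `variable`
#'   (`canopy_cover`, `biomass`, `yield`, `swc_0_30`, `swc_30_60`), `value`.
#' @param weather,soil,mgmt as for [simulate_crop()].
#' @return list of class `field_dataset`.
#' @export
field_dataset <- function(id, crop, cultivar, obs, weather, soil, mgmt) {
  need <- c("day", "variable", "value")
  if (!all(need %in% names(obs))) stop("obs needs columns day, variable, value")
  vocab <- c("canopy_cover", "biomass", "yield", "swc_0_30", "swc_30_60")
  bad <- setdiff(unique(obs$variable), vocab)
  if (length(bad)) stop("unknown observation variable(s): ",
                        paste(bad, collapse = ", "))
  if (any(obs$value < 0)) stop("negative observation values")
  cv <- obs$value[obs$variable == "canopy_cover"]
  if (length(cv) && any(cv > 100)) stop("canopy cover above 100%")
  if (any(obs$day < 0 | obs$day > mgmt$horizon))
    stop("observation days outside the season")
  if (crop == "spinach" && any(obs$variable == "swc_30_60"))
    stop("spinach fields carry no 30-60 cm soil water observations")
  structure(list(id = id, crop = crop, cultivar = cultivar,
                 period = growing_period(mgmt$start_date),
                 obs = obs, weather = weather, soil = soil, mgmt = mgmt),
            class = "field_dataset")
}

#' Stratify fields for calibration
#'
#' Partitions a multi-field study into the calibration strata compared in
#' the pipeline: all fields pooled, by cultivar, by growing period
#' (first: April-July starts in April-June; second: July-October), or by
#' the cultivar x period cross.
#'
#' @param fields list of [field_dataset()] objects.
#' @param scheme `"all"`, `"cultivar"`, `"period"` or `"cultivar_x_period"`.
#' @return named list of field subsets (a partition of `fields`).
#' @export
stratify <- function(fields, scheme = c("all", "cultivar", "period",
                                        "cultivar_x_period")) {
  scheme <- match.arg(scheme)
  lab <- vapply(fields, function(f) {
    if (is.null(f$cultivar) || is.null(f$period)) stop("unlabeled field: ", f$id)
    switch(scheme,
      all = "all",
      cultivar = f$cultivar,
      period = f$period,
      cultivar_x_period = paste(f$cultivar, f$period, sep = "_")
    )
  }, character(1))
  split(fields, factor(lab, levels = unique(lab)))
}

# trajectory column holding each observed variable; canopy cover is
# observed in percent while the simulator state is a fraction
sim_observable <- function(traj, variable, day) {
  idx <- match(day, traj$day)
  if (anyNA(idx)) stop("observation day beyond simulated trajectory")
  switch(variable,
    canopy_cover = traj$cc[idx] * 100,
    biomass = traj$biomass[idx],
    yield = traj$yield[idx],
    swc_0_30 = traj$theta_1[idx],
    swc_30_60 = traj$theta_2[idx],
    stop("unknown variable: ", variable)
  )
}

#' Residuals of a parameter vector against a field subset
#'
#' Simulates every field with the shared crop parameters `theta` (merged
#' into `base_params`; weather/soil/management stay field-specific) and
#' returns observed minus simulated values at the exact observation days,
#' grouped by variable.
#'
#' @param theta named numeric vector over the calibrated subset.
#' @param fields list of [field_dataset()] objects.
#' @param base_params full [crop_parameters()] set for the fixed entries.
#' @return data.frame with columns `field`, `day`, `variable`, `residual`.
#' @export
residuals_by_variable <- function(theta, fields, base_params) {
  out <- lapply(fields, function(f) {
    p <- set_parameters(base_params, theta)
    traj <- simulate_crop(p, f$weather, f$soil, f$mgmt)
    sim <- vapply(seq_len(nrow(f$obs)), function(i) {
      sim_observable(traj, f$obs$variable[i], f$obs$day[i])
    }, numeric(1))
    data.frame(field = f$id, day = f$obs$day, variable = f$obs$variable,
               residual = f$obs$value - sim)
  })
  do.call(rbind, out)
}

#' Gaussian log-likelihood of a parameter vector
#'
#' Independent Gaussian errors per observation with one error variance per
#' observed variable, summed over fields, variables and observation times:
#' `sum_v [ -n_v/2 log(2 pi sigma2_v) - SS_v / (2 sigma2_v) ]`.
#'
#' @inheritParams residuals_by_variable
#' @param sigma2 named numeric vector of error variances per variable
#'   (names matching the observation variables), all > 0.
#' @return the log-likelihood (scalar).
#' @export
log_likelihood <- function(theta, fields, sigma2, base_params) {
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  res <- residuals_by_variable(theta, fields, base_params)
  ll <- 0
  for (v in unique(res$variable)) {
    r <- res$residual[res$variable == v]
    s2 <- sigma2[[v]]
    if (is.null(s2)) stop("sigma2 missing for variable ", v)
    ll <- ll - length(r) / 2 * log(2 * pi * s2) - sum(r^2) / (2 * s2)
  }
  ll
}

mvn_logd <- function(x, mean, chol_cov) {
  z <- backsolve(chol_cov, x - mean, transpose = TRUE)
  -sum(log(diag(chol_cov))) - 0.5 * sum(z^2) - length(x) / 2 * log(2 * pi)
}

#' Delayed-rejection adaptive Metropolis sampling
#'
#' Single-chain DRAM under independent uniform priors on the bounds of
#' `space`. The proposal starts as an independent Gaussian with standard
#' deviation `jump_frac` times the prior range per parameter; after
#' `10 * k` iterations the proposal covariance adapts to
#' `2.38^2 / k` times the running sample covariance (plus a 1e-10 jitter).
#' A rejected proposal triggers one delayed-rejection stage with the
#' proposal scale shrunk by a factor 5 and the two-stage acceptance ratio.
#' Proposals outside the prior support are rejected outright. The study
#' default is 30,000 iterations with a burn-in of 3,000.
#'
#' Two likelihood interfaces are supported: a plain `log_post(theta)`
#' callable (error variances fixed or irrelevant), or a `residual_fn`
#' returning per-variable residual vectors, in which case per-variable
#' error variances are resampled each iteration from their conjugate
#' inverse-gamma conditional (prior IG(0.01, 0.01)) and the Gaussian
#' log-likelihood is assembled internally.
#'
#' @param log_post function(theta) -> log posterior density (up to a
#'   constant); ignored when `residual_fn` is given.
#' @param space a [parameter_space()]; bounds define the uniform prior.
#' @param n_iter,burn_in chain length and burn-in (defaults 30,000 / 3,000).
#' @param jump_frac initial proposal sd as a fraction of the range (0.1).
#' @param seed RNG seed.
#' @param residual_fn optional function(theta) -> named list of residual
#'   vectors per variable (see [residuals_by_variable()]).
#' @param sigma2_fixed optional named vector: use these error variances
#'   with `residual_fn` instead of sampling them.
#' @param init initial point (default: prior midpoint).
#' @param dr_shrink delayed-rejection proposal shrink factor (5).
#' @param adapt_start iteration at which covariance adaptation begins
#'   (default `10 * k`).
#' @param label stratum label stored on the chain.
#' @return list of class `posterior_chain`: `samples` (n_iter x k),
#'   `log_post`, `sigma2` (n_iter x n_var or NULL), `acceptance_rate`,
#'   `burn_in`, `space`, `seed`, `label`, `settings`.
#' @export
run_dram <- function(log_post = NULL, space, n_iter = 30000, burn_in = 3000,
                     jump_frac = 0.1, seed = 1, residual_fn = NULL,
                     sigma2_fixed = NULL, init = NULL, dr_shrink = 5,
                     adapt_start = NULL, label = "all") {
  k <- nrow(space)
  lower <- space$lower; upper <- space$upper
  rng <- upper - lower
  if (is.null(adapt_start)) adapt_start <- 10L * k
  if (is.null(init)) init <- (lower + upper) / 2
  in_bounds <- function(th) all(th >= lower & th <= upper)
  a0 <- 0.01; b0 <- 0.01 # inverse-gamma prior on error variances

  estimate_sigma2 <- !is.null(residual_fn) && is.null(sigma2_fixed)
  use_resid <- !is.null(residual_fn)
  if (!use_resid && is.null(log_post)) stop("need log_post or residual_fn")

  gauss_ll <- function(ss, n, s2) {
    sum(-n / 2 * log(2 * pi * s2) - ss / (2 * s2))
  }
  # returns list(lp = log posterior given s2, ss, n) for in-bounds theta
  evaluate <- function(th, s2) {
    if (use_resid) {
      res <- tryCatch(residual_fn(th), error = function(e) NULL)
      if (is.null(res)) return(NULL) # simulation failure -> reject
      ss <- vapply(res, function(r) sum(r^2), numeric(1))
      n <- vapply(res, length, numeric(1))
      list(lp = gauss_ll(ss, n, s2[names(res)]), ss = ss, n = n)
    } else {
      lp <- log_post(th)
      if (!is.finite(lp)) return(NULL)
      list(lp = lp, ss = NULL, n = NULL)
    }
  }

  with_seed(seed, {
    # error-variance state
    s2 <- sigma2_fixed
    cur <- NULL
    if (use_resid && is.null(s2)) {
      res0 <- residual_fn(init)
      s2 <- vapply(res0, function(r) max(mean(r^2), 1e-4), numeric(1))
    }
    cur <- evaluate(init, s2)
    if (is.null(cur) || !is.finite(cur$lp))
      stop("non-finite log posterior at the initial point")
    theta <- init

    samples <- matrix(NA_real_, n_iter, k,
                      dimnames = list(NULL, space$name))
    lps <- numeric(n_iter)
    s2mat <- if (estimate_sigma2)
      matrix(NA_real_, n_iter, length(s2),
             dimnames = list(NULL, names(s2))) else NULL
    accepted <- 0L
    # running moments for adaptation
    run_mean <- theta
    run_m2 <- matrix(0, k, k)
    n_run <- 1L
    chol0 <- diag(jump_frac * rng, k)
    chol_cur <- chol0
    sd_fac <- 2.38^2 / k

    for (it in seq_len(n_iter)) {
      if (estimate_sigma2) {
        # conjugate inverse-gamma update given current residuals
        s2 <- vapply(seq_along(cur$ss), function(j) {
          1 / rgamma(1, shape = a0 + cur$n[j] / 2, rate = b0 + cur$ss[j] / 2)
        }, numeric(1))
        names(s2) <- names(cur$ss)
        cur$lp <- gauss_ll(cur$ss, cur$n, s2)
      }

      if (it > adapt_start) {
        cov_run <- run_m2 / (n_run - 1)
        ch <- tryCatch(chol(sd_fac * cov_run + diag(1e-10, k)),
                       error = function(e) NULL)
        if (!is.null(ch)) chol_cur <- ch
      }

      y1 <- theta + drop(crossprod(chol_cur, rnorm(k)))
      cand1 <- if (in_bounds(y1)) evaluate(y1, s2) else NULL
      lp1 <- if (is.null(cand1)) -Inf else cand1$lp
      a1 <- min(1, exp(lp1 - cur$lp))
      if (is.finite(lp1) && runif(1) < a1) {
        theta <- y1; cur <- cand1; accepted <- accepted + 1L
      } else {
        # delayed rejection: shrunk proposal, two-stage acceptance ratio
        chol2 <- chol_cur / dr_shrink
        y2 <- theta + drop(crossprod(chol2, rnorm(k)))
        cand2 <- if (in_bounds(y2)) evaluate(y2, s2) else NULL
        if (!is.null(cand2)) {
          lp2 <- cand2$lp
          a_y2_y1 <- min(1, exp(lp1 - lp2)) # alpha1 from y2 toward y1
          if (a_y2_y1 < 1) {
            q_num <- mvn_logd(y1, y2, chol_cur)
            q_den <- mvn_logd(y1, theta, chol_cur)
            log_a2 <- (lp2 + q_num + log1p(-a_y2_y1)) -
                      (cur$lp + q_den + log1p(-a1))
            if (is.finite(log_a2) && log(runif(1)) < log_a2) {
              theta <- y2; cur <- cand2; accepted <- accepted + 1L
            }
          }
        }
      }

      # rank-1 running covariance update
      n_run <- n_run + 1L
      d <- theta - run_mean
      run_mean <- run_mean + d / n_run
      run_m2 <- run_m2 + tcrossprod(d, theta - run_mean)

      samples[it, ] <- theta
      lps[it] <- cur$lp
      if (estimate_sigma2) s2mat[it, ] <- s2
    }

    acc <- accepted / n_iter
    if (acc < 0.1 || acc > 0.5)
      warning("DRAM acceptance rate ", round(acc, 3),
              " outside the usual [0.1, 0.5] window", call. = FALSE)
    structure(list(samples = samples, log_post = lps, sigma2 = s2mat,
                   acceptance_rate = acc, burn_in = as.integer(burn_in),
                   n_iter = as.integer(n_iter), space = space, seed = seed,
                   label = label,
                   settings = list(jump_frac = jump_frac,
                                   dr_shrink = dr_shrink,
                                   adapt_start = adapt_start,
                                   sd_scale = sd_fac,
                                   sigma2_prior = c(a = a0, b = b0),
                                   estimate_sigma2 = estimate_sigma2)),
              class = "posterior_chain")
  })
}

#' Post-burn-in samples of a chain
#' @param chain a [run_dram()] result.
#' @return matrix of post-burn-in samples.
#' @export
posterior_samples <- function(chain) {
  chain$samples[(chain$burn_in + 1):chain$n_iter, , drop = FALSE]
}

#' Calibrate a field subset
#'
#' Convenience wrapper binding [residuals_by_variable()] to [run_dram()]
#' for one calibration stratum: uniform priors on `space`, per-variable
#' error variances estimated by conjugate updates.
#'
#' @param fields list of [field_dataset()] objects (one stratum).
#' @param space [parameter_space()] over the calibrated subset.
#' @param base_params full [crop_parameters()] set for fixed entries.
#' @param label stratum label.
#' @inheritParams run_dram
#' @param ... passed on to [run_dram()].
#' @return a `posterior_chain`.
#' @export
calibrate_fields <- function(fields, space, base_params, n_iter = 30000,
                             burn_in = 3000, seed = 1, label = "all", ...) {
  run_dram(space = space, n_iter = n_iter, burn_in = burn_in, seed = seed,
           residual_fn = make_residual_fn(fields, space, base_params),
           label = label, ...)
}

# fast residual closure over precompiled field scenarios; observed values,
# trajectory row/column indices and the cover %-scale are resolved once
make_residual_fn <- function(fields, space, base_params) {
  idx <- match(space$name, PARAM_ORDER)
  if (anyNA(idx)) stop("space names must be crop parameters")
  pre <- lapply(fields, function(f) {
    scn <- compile_scenario(base_params, f$weather, f$soil, f$mgmt)
    colv <- c(canopy_cover = unname(scn$cols["cc"]),
              biomass = unname(scn$cols["biomass"]),
              yield = unname(scn$cols["yield"]),
              swc_0_30 = unname(scn$cols["theta_1"]),
              swc_30_60 = unname(scn$cols["theta_2"]))
    list(scn = scn,
         row = f$obs$day + 1L,
         col = unname(colv[f$obs$variable]),
         scale = ifelse(f$obs$variable == "canopy_cover", 100, 1),
         value = f$obs$value, variable = f$obs$variable)
  })
  vars <- sort(unique(unlist(lapply(pre, `[[`, "variable"))))
  function(theta) {
    res <- lapply(pre, function(fp) {
      m <- fast_sim(fp$scn, idx, as.numeric(theta))
      if (nrow(m) < max(fp$row))
        stop("observation day beyond simulated trajectory")
      fp$value - m[cbind(fp$row, fp$col)] * fp$scale
    })
    lab <- unlist(lapply(pre, `[[`, "variable"))
    split(unlist(res), factor(lab, levels = vars))
  }
}

#' Check the error-model assumptions
#'
#' Tests the two calibration assumptions on a residual set: equal error
#' variance across output variables (Levene's test in its median-centred
#' Brown-Forsythe form, via `car::leveneTest`) and uncorrelated errors
#' between variables (pairwise Pearson `cor.test` on residual pairs
#' aligned by field and day where those columns are present, by index
#' otherwise).
#'
#' @param residuals data.frame with columns `variable`, `residual` and
#'   optionally `field`, `day` for alignment.
#' @param alpha significance level for flagging violations (0.05).
#' @return list of class `error_diagnostics`: `levene` (statistic, p,
#'   flagged), `pearson` (pairwise data.frame), `alpha`.
#' @export
check_error_assumptions <- function(residuals, alpha = 0.05) {
  if (!all(c("variable", "residual") %in% names(residuals)))
    stop("residuals needs columns variable, residual")
  vars <- unique(residuals$variable)
  cnt <- table(residuals$variable)
  if (length(vars) < 2 || any(cnt < 3))
    stop("insufficient data: need >= 2 variables with >= 3 residuals each")
  lev <- car::leveneTest(residual ~ factor(variable), data = residuals,
                         center = stats::median)
  lev_stat <- lev$`F value`[1]
  lev_p <- lev$`Pr(>F)`[1]
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  pear <- do.call(rbind, lapply(pairs, function(pr) {
    a <- residuals[residuals$variable == pr[1], , drop = FALSE]
    b <- residuals[residuals$variable == pr[2], , drop = FALSE]
    if (all(c("field", "day") %in% names(residuals))) {
      m <- merge(a, b, by = c("field", "day"))
      x <- m$residual.x; y <- m$residual.y
    } else {
      n <- min(nrow(a), nrow(b))
      x <- a$residual[seq_len(n)]; y <- b$residual[seq_len(n)]
    }
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
      return(data.frame(var1 = pr[1], var2 = pr[2], n = length(x),
                        r = NA_real_, p = NA_real_, flagged = FALSE))
    ct <- cor.test(x, y)
    data.frame(var1 = pr[1], var2 = pr[2], n = length(x),
               r = unname(ct$estimate), p = ct$p.value,
               flagged = ct$p.value < alpha)
  }))
  structure(list(levene = list(statistic = lev_stat, p = lev_p,
                               flagged = lev_p < alpha),
                 pearson = pear, alpha = alpha),
            class = "error_diagnostics")
}

#' Posterior summaries per parameter
#'
#' Mean, standard deviation, equal-tailed 90% credible interval and a
#' kernel density estimate over the prior range for every calibrated
#' parameter.
#'
#' @param chain a [run_dram()] chain with at least 100 post-burn-in draws.
#' @return data.frame (mean, sd, q5, q95 per parameter) with the density
#'   estimates in attribute `density`.
#' @export
posterior_summaries <- function(chain) {
  post <- posterior_samples(chain)
  if (nrow(post) < 100) stop("chain too short: need >= 100 post-burn-in draws")
  sp <- chain$space
  out <- data.frame(
    parameter = colnames(post),
    mean = colMeans(post),
    sd = apply(post, 2, sd),
    q5 = apply(post, 2, quantile, 0.05),
    q95 = apply(post, 2, quantile, 0.95),
    row.names = NULL
  )
  dens <- lapply(seq_len(ncol(post)), function(j) {
    if (sd(post[, j]) == 0) NULL
    else density(post[, j], from = sp$lower[j], to = sp$upper[j])
  })
  names(dens) <- colnames(post)
  attr(out, "density") <- dens
  out
}
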