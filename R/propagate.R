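#' Mean absolute deviation about the mean
#'
#' `(1/n) * sum(|x_i - mean(x)|)` — the spread summary used for propagated
#' output distributions (mean-centred, not the median-centred variant).
#'
#' @param x numeric vector, length >= 1.
#' @return scalar MAD.
#' @examples
#' mean_abs_dev(c(0, 1, 2)) # 2/3
#' @export
mean_abs_dev <- function(x) {
  if (length(x) < 1) stop("empty input")
  mean(abs(x - mean(x)))
}

#' Draw parameter vectors from a posterior chain
#'
#' `n` rows drawn uniformly with replacement from the post-burn-in
#' samples; the study default is 5000 draws.
#'
#' @param chain a [run_dram()] chain.
#' @param n number of draws (default 5000).
#' @param seed RNG seed.
#' @return n x k matrix of parameter vectors.
#' @export
sample_posterior <- function(chain, n = 5000, seed = 1) {
  post <- posterior_samples(chain)
  if (nrow(post) < 1) stop("empty chain")
  idx <- with_seed(seed, sample.int(nrow(post), n, replace = TRUE))
  post[idx, , drop = FALSE]
}

#' Year x soil scenario grid
#'
#' The propagation scenario set: a list of weather years crossed with a
#' list of soil profiles under one fixed management, evaluated for one
#' output variable at one day after start. The study layout is ten
#' weather years by two soils (loam and loamy sand), with spinach biomass
#' read at day 38 after sowing and cauliflower yield at day 84 after
#' planting.
#'
#' @param years named list of weather series.
#' @param soils named list of [soil_profile()] objects.
#' @param mgmt a [management()] plan shared by all cells.
#' @param eval_day day index after start at which the output is read.
#' @param eval_var `"biomass"` or `"yield"`.
#' @return list of class `scenario_grid`.
#' @export
scenario_grid <- function(years, soils, mgmt, eval_day, eval_var = c("yield", "biomass")) {
  eval_var <- match.arg(eval_var)
  if (!length(years) || !length(soils)) stop("empty scenario grid")
  if (eval_day < 1 || eval_day > mgmt$horizon)
    stop("evaluation day outside the simulation horizon")
  if (is.null(names(years))) names(years) <- paste0("year", seq_along(years))
  if (is.null(names(soils))) names(soils) <- paste0("soil", seq_along(soils))
  structure(list(years = years, soils = soils, mgmt = mgmt,
                 eval_day = as.integer(eval_day), eval_var = eval_var),
            class = "scenario_grid")
}

#' Propagate posterior parameter uncertainty through the simulator
#'
#' For every scenario cell (year x soil) each parameter vector is run
#' through [simulate_crop()] and the evaluation variable is read at the
#' evaluation day; the resulting output distribution is summarized by its
#' mean and mean absolute deviation. Failed simulations (degenerate
#' parameter draws) are excluded; more than 1% failures aborts.
#'
#' @param vectors matrix of parameter vectors (named columns) as from
#'   [sample_posterior()].
#' @param grid a [scenario_grid()].
#' @param base_params full [crop_parameters()] set for fixed entries.
#' @param label stratum label recorded in the summary.
#' @return data.frame of class `propagation_summary`: `stratum`, `year`,
#'   `soil`, `n`, `mean`, `mad`, `n_failed` per cell.
#' @export
propagate <- function(vectors, grid, base_params, label = "all") {
  if (!nrow(vectors)) stop("no parameter vectors supplied")
  cells <- expand.grid(year = names(grid$years), soil = names(grid$soils),
                       stringsAsFactors = FALSE)
  idx <- match(colnames(vectors), PARAM_ORDER)
  if (anyNA(idx)) stop("vector columns must be named crop parameters")
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    wx <- grid$years[[cells$year[ci]]]
    so <- grid$soils[[cells$soil[ci]]]
    scn <- compile_scenario(base_params, wx, so, grid$mgmt)
    vcol <- scn$cols[[grid$eval_var]]
    vals <- rep(NA_real_, nrow(vectors))
    for (i in seq_len(nrow(vectors))) {
      vals[i] <- tryCatch({
        m <- fast_sim(scn, idx, vectors[i, ])
        if (nrow(m) < grid$eval_day + 1)
          stop("evaluation day beyond simulated trajectory")
        m[grid$eval_day + 1, vcol]
      }, error = function(e) NA_real_)
    }
    ok <- vals[!is.na(vals)]
    nf <- sum(is.na(vals))
    if (nf > 0.01 * nrow(vectors))
      stop("propagation failed for ", nf, " of ", nrow(vectors),
           " parameter vectors in cell ", cells$year[ci], "/", cells$soil[ci])
    out[[ci]] <- data.frame(stratum = label, year = cells$year[ci],
                            soil = cells$soil[ci], n = length(ok),
                            mean = mean(ok), mad = mean_abs_dev(ok),
                            n_failed = nf)
  }
  structure(do.call(rbind, out),
            class = c("propagation_summary", "data.frame"))
}

sim_observable_raw <- function(traj, variable, day) {
  idx <- match(day, traj$day)
  if (is.na(idx)) stop("evaluation day beyond simulated trajectory")
  traj[[variable]][idx]
}

#' Compare stratified against pooled propagation
#'
#' Joins the pooled summary with each subset summary on the scenario grid
#' and reports, per cell, the two means and MADs, the deviation of the
#' subset mean from the pooled mean, and the MAD ratio (subset / pooled) —
#' the paired records behind the pooled-vs-subset cross plots.
#'
#' @param pooled a [propagate()] summary for the pooled calibration.
#' @param subsets list of [propagate()] summaries for the strata.
#' @return data.frame with one row per cell x subset.
#' @export
compare_stratifications <- function(pooled, subsets) {
  if (inherits(subsets, "propagation_summary")) subsets <- list(subsets)
  key <- function(d) paste(d$year, d$soil)
  out <- lapply(subsets, function(s) {
    if (!setequal(key(pooled), key(s)))
      stop("grid mismatch between pooled and subset summaries")
    m <- merge(pooled, s, by = c("year", "soil"),
               suffixes = c("_pooled", "_subset"))
    data.frame(stratum = m$stratum_subset, year = m$year, soil = m$soil,
               pooled_mean = m$mean_pooled, pooled_mad = m$mad_pooled,
               subset_mean = m$mean_subset, subset_mad = m$mad_subset,
               dev_mean = m$mean_subset - m$mean_pooled,
               mad_ratio = m$mad_subset / m$mad_pooled)
  })
  do.call(rbind, out)
}
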