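#' Parameter space for screening and calibration
#'
#' An ordered table of parameter names with lower/upper bounds, resolvable
#' to [crop_parameters()] fields. Bounds double as the uniform prior in
#' the Bayesian calibration.
#'
#' @param name character vector of parameter names (unique).
#' @param lower,upper numeric bounds, `lower < upper` elementwise.
#' @return data.frame of class `param_space`.
#' @examples
#' parameter_space(c("cgc", "wp"), c(0.008, 0.10), c(0.016, 0.25))
#' @export
parameter_space <- function(name, lower, upper) {
  stopifnot(length(name) == length(lower), length(lower) == length(upper))
  if (anyDuplicated(name)) stop("parameter names must be unique")
  if (any(lower >= upper)) stop("need lower < upper for every parameter")
  structure(data.frame(name = as.character(name), lower = as.numeric(lower),
                       upper = as.numeric(upper), stringsAsFactors = FALSE),
            class = c("param_space", "data.frame"))
}

# map points in the unit hypercube (rows) to physical units
space_denorm <- function(space, x) {
  sweep(sweep(x, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
}

#' Build Morris one-at-a-time trajectories
#'
#' Classic winding trajectories on an `levels`-level grid of the unit
#' hypercube with step `delta = levels / (2 * (levels - 1))`: each of the
#' `r` trajectories visits `k + 1` points, consecutive points differing in
#' exactly one coordinate by +/- delta.
#'
#' @param space a [parameter_space()] (defines `k` and the physical bounds).
#' @param levels number of grid levels, even and >= 2.
#' @param r number of trajectories (replicates).
#' @param seed RNG seed; identical seeds give identical designs.
#' @return list of class `morris_design`: `points` (r*(k+1) x k matrix in
#'   unit coordinates, trajectories stacked), `delta`, `levels`, `r`,
#'   `space`, `seed`.
#' @export
build_trajectories <- function(space, levels = 8, r = 100, seed = 1) {
  k <- nrow(space)
  if (levels < 2 || levels %% 2 != 0)
    stop("invalid design: levels must be even and >= 2")
  if (r < 1) stop("r must be >= 1")
  delta <- levels / (2 * (levels - 1))
  grid <- seq(0, 1 - delta, by = 1 / (levels - 1))
  points <- with_seed(seed, {
    B <- matrix(0, k + 1, k)
    B[lower.tri(B)] <- 1 # row i+1 has ones in the first i columns
    J <- matrix(1, k + 1, k)
    do.call(rbind, lapply(seq_len(r), function(i) {
      xstar <- matrix(sample(grid, k, replace = TRUE), k + 1, k, byrow = TRUE)
      D <- diag(sample(c(-1, 1), k, replace = TRUE), k)
      P <- diag(k)[, sample(k), drop = FALSE]
      (xstar + (delta / 2) * ((2 * B - J) %*% D + J)) %*% P
    }))
  })
  structure(list(points = points, delta = delta, levels = levels, r = r,
                 space = space, seed = seed),
            class = "morris_design")
}

#' Elementary effects from evaluated trajectories
#'
#' For every consecutive pair of trajectory points (differing in one
#' coordinate by a signed step `s = +/- delta`), the elementary effect of
#' that coordinate is `(f(x + s e_i) - f(x)) / s`, computed in normalized
#' (unit-hypercube) coordinates so that effects carry the parameter-range
#' scaling.
#'
#' @param design a [build_trajectories()] design.
#' @param outputs numeric vector (one output) or matrix (rows = design
#'   points in design order, columns = output components).
#' @return array of elementary-effect samples with dimensions (replicates, parameters, outputs).
#' @export
elementary_effects <- function(design, outputs) {
  pts <- design$points
  if (is.vector(outputs)) outputs <- matrix(outputs, ncol = 1)
  if (nrow(outputs) != nrow(pts))
    stop("missing output: expected ", nrow(pts), " evaluations, got ",
         nrow(outputs))
  if (anyNA(outputs)) stop("missing output: NA model evaluations")
  k <- ncol(pts)
  r <- design$r
  ee <- array(NA_real_, c(r, k, ncol(outputs)))
  for (tr in seq_len(r)) {
    base <- (tr - 1) * (k + 1)
    for (j in seq_len(k)) {
      dx <- pts[base + j + 1, ] - pts[base + j, ]
      i <- which(abs(dx) > 1e-12)
      if (length(i) != 1) stop("trajectory step changes != 1 coordinate")
      ee[tr, i, ] <- (outputs[base + j + 1, ] - outputs[base + j, ]) / dx[i]
    }
  }
  ee
}

#' Rescale elementary effects and aggregate to a sensitivity ranking
#'
#' Elementary effects of each (variable, day) output component are divided
#' by the mean simulated output of that component over all design points
#' before computing mu* (mean absolute effect) and sigma (standard
#' deviation). The aggregate ranking statistic is the mean of rescaled mu*
#' over days within each variable, then over variables. Components with a
#' near-zero mean output (e.g. yield before yield formation) are skipped.
#'
#' @param ee elementary-effect array from [elementary_effects()].
#' @param outputs the matrix of model outputs used for the effects.
#' @param variables character vector, variable label per output column.
#' @param days numeric vector, observation day per output column.
#' @param rescale divide by per-component output means (default TRUE).
#' @param zero_tol components with `|mean| <= zero_tol` are dropped.
#' @return list of class `sensitivity_result`: `table` (parameter x
#'   component mu*/sigma, long data.frame), `mu_star_agg` (named vector in
#'   space order), `share`, `space`.
#' @export
rescale_and_aggregate <- function(ee, outputs, variables, days,
                                  rescale = TRUE, zero_tol = 1e-12) {
  if (is.vector(outputs)) outputs <- matrix(outputs, ncol = 1)
  stopifnot(length(variables) == ncol(outputs), length(days) == ncol(outputs))
  k <- dim(ee)[2]
  mus <- colMeans(outputs)
  keep <- if (rescale) abs(mus) > zero_tol else rep(TRUE, ncol(outputs))
  if (!any(keep)) stop("degenerate output: all components have zero mean")
  tab <- list()
  mu_mat <- matrix(NA_real_, k, ncol(outputs)) # rescaled mu* per component
  for (j in which(keep)) {
    eej <- ee[, , j, drop = FALSE]
    dim(eej) <- dim(ee)[1:2]
    if (rescale) eej <- eej / mus[j]
    mu_mat[, j] <- colMeans(abs(eej))
    tab[[length(tab) + 1]] <- data.frame(
      parameter = pnames(ee, j, k), variable = variables[j], day = days[j],
      mu_star = colMeans(abs(eej)), sigma = apply(eej, 2, sd)
    )
  }
  dead <- setdiff(unique(variables), unique(variables[keep]))
  if (length(dead))
    stop("degenerate variable(s) with zero output all season: ",
         paste(dead, collapse = ", "))
  # day-mean within variable, then variable-mean
  byvar <- lapply(split(which(keep), variables[keep]), function(cols) {
    rowMeans(mu_mat[, cols, drop = FALSE])
  })
  mu_agg <- rowMeans(do.call(cbind, byvar))
  names(mu_agg) <- attr(ee, "pnames") %||% paste0("x", seq_len(k))
  structure(list(table = do.call(rbind, tab), mu_star_agg = mu_agg,
                 share = mu_agg / sum(mu_agg)),
            class = "sensitivity_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pnames <- function(ee, j, k) attr(ee, "pnames") %||% paste0("x", seq_len(k))

#' Select the influential parameter subset
#'
#' Parameters are ranked by descending aggregated mu* (ties broken by
#' declaration order) and the shortest prefix whose cumulative share of
#' total sensitivity reaches `threshold` is returned.
#'
#' @param result a [rescale_and_aggregate()] result (or named mu* vector).
#' @param threshold cumulative-share cutoff, default 0.95.
#' @return character vector of selected parameter names, most influential
#'   first.
#' @export
select_influential <- function(result, threshold = 0.95) {
  mu <- if (inherits(result, "sensitivity_result")) result$mu_star_agg
        else result
  if (any(mu < 0)) stop("mu* must be non-negative")
  if (all(mu == 0)) stop("all-zero sensitivity: nothing to select")
  ord <- order(-mu, seq_along(mu)) # stable: ties by declaration order
  cum <- cumsum(mu[ord]) / sum(mu)
  n <- which(cum >= threshold - 1e-12)[1]
  names(mu)[ord][seq_len(n)]
}

#' Morris screening of the crop simulator
#'
#' Runs the full screening on one representative field scenario: builds
#' trajectories over `space`, simulates every design point (parameters not
#' in `space` stay at `base_params`), extracts the output variables on the
#' observation schedule, and aggregates rescaled elementary effects into a
#' parameter ranking with the influential subset at 95% cumulative
#' sensitivity.
#'
#' @param space a [parameter_space()].
#' @param base_params full [crop_parameters()] set supplying the
#'   non-screened parameters.
#' @param weather,soil,mgmt the scenario, as for [simulate_crop()].
#' @param days observation days on which sensitivity is evaluated
#'   (defaults to a weekly schedule over the horizon).
#' @param variables trajectory columns to screen (canopy cover, biomass,
#'   yield, soil water by default).
#' @param levels,r,seed Morris design settings; the study default is
#'   8 levels and 100 replicates.
#' @param threshold cumulative-share cutoff for [select_influential()].
#' @return a `sensitivity_result` with an additional `selected` element.
#' @export
morris_screen <- function(space, base_params, weather, soil, mgmt,
                          days = NULL, variables = c("cc", "biomass",
                                                     "yield", "theta_1"),
                          levels = 8, r = 100, seed = 1, threshold = 0.95) {
  if (is.null(days)) days <- seq(7, mgmt$horizon, by = 7)
  design <- build_trajectories(space, levels = levels, r = r, seed = seed)
  phys <- space_denorm(space, design$points)
  ncomp <- length(days) * length(variables)
  outputs <- matrix(NA_real_, nrow(phys), ncomp)
  varlab <- rep(variables, each = length(days))
  daylab <- rep(days, times = length(variables))
  scn <- compile_scenario(base_params, weather, soil, mgmt)
  pidx <- match(space$name, PARAM_ORDER)
  if (anyNA(pidx)) stop("space names must be crop parameters")
  vcol <- unname(unlist(scn$cols[variables]))
  for (i in seq_len(nrow(phys))) {
    m <- fast_sim(scn, pidx, phys[i, ])
    if (nrow(m) < max(days) + 1)
      stop("observation day beyond simulated trajectory")
    outputs[i, ] <- as.vector(m[days + 1, vcol])
  }
  ee <- elementary_effects(design, outputs)
  attr(ee, "pnames") <- space$name
  res <- rescale_and_aggregate(ee, outputs, varlab, daylab)
  res$selected <- select_influential(res, threshold)
  res$design <- design[c("levels", "r", "delta", "seed")]
  res
}
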