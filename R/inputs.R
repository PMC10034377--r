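#' Soil hydraulic lookup for the four Belgian texture classes
#'
#' Representative saturation / field-capacity / wilting-point contents
#' (vol%) and daily drainage coefficients tau for the texture classes of
#' the study region. Values are overridable by constructing a
#' [soil_profile()] with explicit layers.
#'
#' @return data.frame with one row per texture class.
#' @export
soil_texture_table <- function() {
  data.frame(
    texture = c("sand", "loamy_sand", "sandy_loam", "loam"),
    theta_sat = c(36, 38, 41, 46),
    theta_fc = c(13, 16, 22, 31),
    theta_wp = c(5, 7, 10, 15),
    tau = c(0.9, 0.8, 0.6, 0.4),
    stringsAsFactors = FALSE
  )
}

#' Soil profile
#'
#' A layered bucket soil. Either give a `texture` class (layers are built
#' from [soil_texture_table()], two layers of 0.3 m) or an explicit
#' `layers` data.frame with columns `thickness` (m), `theta_sat`,
#' `theta_fc`, `theta_wp` (vol%), `tau` (0-1).
#'
#' @param texture one of `"sand"`, `"loamy_sand"`, `"sandy_loam"`, `"loam"`.
#' @param layers optional explicit layer table (overrides `texture`).
#' @param theta_init initial volumetric water content per layer (vol%);
#'   defaults to field capacity.
#' @return object of class `soil_profile`: list(texture, layers, theta_init).
#' @examples
#' s <- soil_profile("loam")
#' s$layers
#' @export
soil_profile <- function(texture = NULL, layers = NULL, theta_init = NULL) {
  if (is.null(layers)) {
    tab <- soil_texture_table()
    if (is.null(texture) || !texture %in% tab$texture)
      stop("unknown texture class: ", if (is.null(texture)) "NULL" else texture)
    row <- tab[tab$texture == texture, ]
    layers <- data.frame(
      thickness = c(0.3, 0.3),
      theta_sat = row$theta_sat, theta_fc = row$theta_fc,
      theta_wp = row$theta_wp, tau = row$tau
    )
  }
  need <- c("thickness", "theta_sat", "theta_fc", "theta_wp", "tau")
  if (!all(need %in% names(layers))) stop("layers must have columns: ",
                                          paste(need, collapse = ", "))
  if (any(layers$thickness <= 0)) stop("layer thicknesses must be > 0")
  if (any(!(layers$theta_wp < layers$theta_fc & layers$theta_fc < layers$theta_sat)))
    stop("each layer needs theta_wp < theta_fc < theta_sat")
  if (any(layers$tau < 0 | layers$tau > 1)) stop("tau must be in [0, 1]")
  if (is.null(theta_init)) theta_init <- layers$theta_fc
  theta_init <- rep_len(theta_init, nrow(layers))
  if (any(theta_init < 0.5 * layers$theta_wp) || any(theta_init > layers$theta_sat))
    stop("initial water content must lie in [0.5*theta_wp, theta_sat]")
  structure(list(texture = texture, layers = layers, theta_init = theta_init),
            class = "soil_profile")
}

#' Validate a daily weather series
#'
#' Weather is a data.frame with columns `date` (Date or ISO string),
#' `tmin`, `tmax` (deg C), `precip`, `et0` (mm). Dates must be contiguous,
#' `tmin <= tmax`, `precip >= 0`, `et0 > 0`.
#'
#' @param weather weather data.frame.
#' @return the weather data.frame with `date` coerced to `Date`.
#' @export
validate_weather <- function(weather) {
  need <- c("date", "tmin", "tmax", "precip", "et0")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather is missing column(s): ", paste(miss, collapse = ", "))
  weather$date <- as.Date(weather$date)
  if (nrow(weather) > 1) {
    gaps <- diff(as.integer(weather$date))
    if (any(gaps != 1)) {
      at <- weather$date[which(gaps != 1)[1]]
      stop("weather dates not contiguous after ", format(at))
    }
  }
  if (any(weather$tmin > weather$tmax)) stop("weather has tmin > tmax")
  if (any(weather$precip < 0)) stop("weather has negative precipitation")
  if (any(weather$et0 <= 0)) stop("weather has non-positive et0")
  weather
}

#' Management plan
#'
#' @param start_date sowing (spinach) or planting (cauliflower) date; day 0
#'   of the simulation.
#' @param establishment `"sown"` or `"transplanted"`.
#' @param density plant density (plants per ha); overrides the crop
#'   parameter set when supplied to [simulate_crop()].
#' @param horizon simulation horizon in days after `start_date`.
#' @param irrigation data.frame with columns `day` (index after start) and
#'   `depth` (mm); may be empty.
#' @return object of class `management`.
#' @export
management <- function(start_date, establishment = c("sown", "transplanted"),
                       density = NULL, horizon = 90,
                       irrigation = data.frame(day = integer(), depth = numeric())) {
  establishment <- match.arg(establishment)
  start_date <- as.Date(start_date)
  if (!all(c("day", "depth") %in% names(irrigation)))
    stop("irrigation needs columns day, depth")
  if (any(irrigation$depth < 0)) stop("irrigation depths must be >= 0")
  if (any(irrigation$day < 0 | irrigation$day > horizon))
    stop("irrigation days must lie within [0, horizon]")
  structure(list(start_date = start_date, establishment = establishment,
                 density = density, horizon = as.integer(horizon),
                 irrigation = irrigation),
            class = "management")
}

# growing-period label from the start month: April-June -> first,
# July-October -> second (a July start belongs to the late cycle)
growing_period <- function(start_date) {
  m <- as.integer(format(as.Date(start_date), "%m"))
  if (m >= 4 && m <= 6) "first"
  else if (m >= 7 && m <= 10) "second"
  else stop("start month ", m, " outside the April-October season")
}
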