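#' Crop parameter sets
#'
#' Construct the full parameter set of the water-driven simulator, starting
#' from a built-in crop default (transplanted cauliflower or sown spinach)
#' and overriding individual entries. All phenology is expressed in thermal
#' time (growing degree days, deg C d) above `baseT`.
#'
#' Fields (units):
#' \describe{
#'   \item{plan}{thermal time from sowing/planting to 90 percent emergence or
#'     transplant recovery (°C d)}
#'   \item{ccs}{canopy size of an average seedling/transplant (cm2 per plant)}
#'   \item{density}{plant density (plants per ha)}
#'   \item{ccx}{maximum canopy cover (fraction)}
#'   \item{cgc, cdc}{canopy growth / decline coefficients (fraction per °C d)}
#'   \item{kc}{crop transpiration coefficient at full canopy (-)}
#'   \item{wp}{normalized water productivity (t/ha per unit Tr/ET0)}
#'   \item{baseT, uppT}{base and cutoff temperatures for thermal time (°C)}
#'   \item{stbio}{minimum daily degrees for unreduced biomass production (°C d)}
#'   \item{sen, yld, mat}{thermal time to senescence onset, start of yield
#'     formation, and maturity (°C d)}
#'   \item{hilen}{thermal duration of harvest-index build-up (°C d)}
#'   \item{hi}{reference harvest index (fraction)}
#'   \item{root, rtn, rtx}{thermal time to maximum rooting depth (°C d);
#'     minimum and maximum effective rooting depth (m)}
#'   \item{pexup, pexlw, pexhp}{canopy-expansion depletion thresholds
#'     (fraction of TAW) and stress-curve shape}
#'   \item{psto}{stomatal-closure depletion threshold (fraction of TAW)}
#'   \item{psen, psenshp}{early-senescence threshold and shape}
#'   \item{anaer}{anaerobiotic point: vol% below saturation where aeration
#'     stress starts (0 disables aeration stress)}
#'   \item{evardc}{late-season reduction of soil evaporation by the senesced
#'     canopy (percent)}
#'   \item{hinc, hingsto, hipsflo}{harvest-index adjustment parameters,
#'     carried but inert in this implementation}
#' }
#'
#' @param crop `"cauliflower"` (transplanted) or `"spinach"` (sown).
#' @param ... named overrides of individual fields.
#' @return A named list of class `crop_params` with an `establishment`
#'   attribute (`"transplanted"` or `"sown"`).
#' @examples
#' p <- crop_parameters("cauliflower", wp = 0.18)
#' p$wp
#' @export
crop_parameters <- function(crop = c("cauliflower", "spinach"), ...) {
  crop <- match.arg(crop)
  p <- crop_defaults(crop)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown crop parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  structure(p,
    class = "crop_params", crop = crop,
    establishment = if (crop == "cauliflower") "transplanted" else "sown"
  )
}

crop_defaults <- function(crop) {
  switch(crop,
    cauliflower = list(
      plan = 60, ccs = 20, density = 33000, ccx = 0.95,
      cgc = 0.012, cdc = 0.008, kc = 1.05, wp = 0.17,
      baseT = 4, uppT = 30, stbio = 8,
      sen = 900, yld = 400, hilen = 500, hi = 0.45, mat = 1150,
      root = 600, rtn = 0.20, rtx = 0.50,
      pexup = 0.20, pexlw = 0.60, pexhp = 3,
      psto = 0.50, psen = 0.70, psenshp = 3,
      anaer = 5, evardc = 60, hinc = 0, hingsto = 0, hipsflo = 0
    ),
    spinach = list(
      plan = 80, ccs = 3, density = 1.8e6, ccx = 0.90,
      cgc = 0.018, cdc = 0.008, kc = 1.00, wp = 0.15,
      baseT = 3, uppT = 28, stbio = 6,
      sen = 550, yld = 100, hilen = 200, hi = 0.85, mat = 650,
      root = 300, rtn = 0.10, rtx = 0.30,
      pexup = 0.25, pexlw = 0.60, pexhp = 3,
      psto = 0.50, psen = 0.70, psenshp = 3,
      anaer = 5, evardc = 60, hinc = 0, hingsto = 0, hipsflo = 0
    ),
    stop("unknown crop: ", crop)
  )
}

#' Validate a crop parameter set
#'
#' Checks the internal consistency constraints of a [crop_parameters()] set:
#' positive thermal-time fields with `plan < sen < mat` and
#' `yld + hilen <= mat`, fractions in (0, 1], ordered depletion thresholds,
#' `rtn <= rtx`, and initial cover `ccs * density / 1e8 < ccx`.
#'
#' @param params a `crop_params` object (or plain named list).
#' @return `invisible(TRUE)`; stops with an informative message otherwise.
#' @export
validate_crop_parameters <- function(params) {
  p <- params
  tt <- c("plan", "stbio", "sen", "yld", "hilen", "mat", "root")
  for (f in tt) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop("thermal-time field '", f, "' must be > 0")
  }
  if (!(p$plan < p$sen && p$sen < p$mat)) stop("need plan < sen < mat")
  if (p$yld + p$hilen > p$mat) stop("need yld + hilen <= mat")
  if (!(p$ccx > 0 && p$ccx <= 1)) stop("ccx must be in (0, 1]")
  if (!(p$hi > 0 && p$hi <= 1)) stop("hi must be in (0, 1]")
  if (!(p$pexup >= 0 && p$pexup <= p$pexlw && p$pexlw <= 1))
    stop("need 0 <= pexup <= pexlw <= 1")
  if (p$psto < 0 || p$psto > 1 || p$psen < 0 || p$psen > 1)
    stop("psto and psen must be in [0, 1]")
  if (p$rtn > p$rtx) stop("need rtn <= rtx")
  if (p$density <= 0) stop("density must be > 0")
  if (p$baseT >= p$uppT) stop("need baseT < uppT")
  cc0 <- p$ccs * p$density / 1e8
  if (cc0 >= p$ccx)
    stop("initial cover ccs*density/1e8 = ", signif(cc0, 3),
         " must be below ccx = ", p$ccx)
  invisible(TRUE)
}

# fixed ordering used to pass parameters to the compiled simulator core
PARAM_ORDER <- c(
  "plan", "ccs", "density", "ccx", "cgc", "cdc", "kc", "wp",
  "baseT", "uppT", "stbio", "sen", "yld", "hilen", "hi", "mat",
  "root", "rtn", "rtx", "pexup", "pexlw", "pexhp",
  "psto", "psen", "psenshp", "anaer", "evardc",
  "hinc", "hingsto", "hipsflo"
)

param_vector <- function(params) {
  vapply(PARAM_ORDER, function(f) as.numeric(params[[f]]), numeric(1))
}

#' Replace a subset of parameters by name
#'
#' Utility used by the screening and calibration layers: returns `params`
#' with the entries named in `theta` replaced by its values.
#'
#' @param params a `crop_params` object.
#' @param theta named numeric vector of replacement values.
#' @return the modified `crop_params` object.
#' @export
set_parameters <- function(params, theta) {
  stopifnot(!is.null(names(theta)), all(names(theta) %in% names(params)))
  params[names(theta)] <- as.numeric(theta)
  params
}
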