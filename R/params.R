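#' Kinetic and physical parameters of the well model
#'
#' Bundles every rate constant, Michaelis constant, diffusivity and
#' promoter-curve parameter used by the simulation. Invertase kinetics
#' (`km_sucrose` = 11 mM, `vmax_hydrolysis` = 3.6e8 glucose molecules per
#' second per fully induced cell) are enzyme-assay measurements on intact
#' cells; the promoter peak window (0.25-1 mM glucose) reflects induction
#' of the invertase gene by low glucose and its repression above ~1 mM.
#' The remaining defaults are documented model choices (see the methods
#' vignette): small-sugar diffusivities in water at 30 C, a hexose
#' transporter tuned to the measured intake of slowly growing cells
#' (~1-2e6 glucose molecules/s at low micromolar-range glucose), random
#' close packing for the clump interior, and a growth threshold of 1.5e6
#' glucose molecules/s.
#'
#' @param km_sucrose Michaelis constant of sucrose hydrolysis (mM).
#' @param vmax_hydrolysis maximal hydrolysis rate at full induction
#'   (glucose molecules s^-1 cell^-1).
#' @param km_hexose Michaelis constant of hexose import (mM).
#' @param vmax_import maximal hexose import rate
#'   (molecules s^-1 cell^-1).
#' @param d_sucrose,d_glucose diffusivities (um^2 s^-1).
#' @param promoter_peak_lo,promoter_peak_hi bounds (mM glucose) of the
#'   window in which promoter activity peaks.
#' @param promoter_basal promoter activity at zero glucose, in `[0,1]`.
#' @param invertase_tau first-order time constant of induction (s).
#' @param cell_radius cell radius (um).
#' @param packing_fraction volume fraction of cells inside a clump.
#' @param min_growth_intake minimum glucose intake supporting
#'   proliferation (molecules s^-1 cell^-1).
#' @return an object of class `kinetic_params` (a validated named list).
#' @examples
#' p <- kinetic_params()
#' hydrolysis_rate(11, induction = 1, params = p)  # Vmax/2 = 1.8e8
#' @export
kinetic_params <- function(km_sucrose = 11,
                           vmax_hydrolysis = 3.6e8,
                           km_hexose = 5,
                           vmax_import = 1.5e8,
                           d_sucrose = 520,
                           d_glucose = 600,
                           promoter_peak_lo = 0.25,
                           promoter_peak_hi = 1,
                           promoter_basal = 0.1,
                           invertase_tau = 3600,
                           cell_radius = 2.5,
                           packing_fraction = 0.64,
                           min_growth_intake = 1.5e6) {
  p <- list(km_sucrose = km_sucrose, vmax_hydrolysis = vmax_hydrolysis,
            km_hexose = km_hexose, vmax_import = vmax_import,
            d_sucrose = d_sucrose, d_glucose = d_glucose,
            promoter_peak_lo = promoter_peak_lo,
            promoter_peak_hi = promoter_peak_hi,
            promoter_basal = promoter_basal,
            invertase_tau = invertase_tau, cell_radius = cell_radius,
            packing_fraction = packing_fraction,
            min_growth_intake = min_growth_intake)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("%s must be a single finite number", field),
           call. = FALSE)
    v
  }
  positive <- c("km_sucrose", "km_hexose", "vmax_import",
                "d_sucrose", "d_glucose", "promoter_peak_lo",
                "promoter_peak_hi", "invertase_tau", "cell_radius",
                "min_growth_intake")
  for (f in positive)
    if (num1(f) <= 0)
      stop(sprintf("%s must be strictly positive", f), call. = FALSE)
  # zero allowed: an invertase deletion has no hydrolysis activity
  if (num1("vmax_hydrolysis") < 0)
    stop("vmax_hydrolysis must be nonnegative", call. = FALSE)
  b <- num1("promoter_basal")
  if (b < 0 || b > 1)
    stop("promoter_basal must lie in [0, 1]", call. = FALSE)
  phi <- num1("packing_fraction")
  if (phi <= 0 || phi > 1)
    stop("packing_fraction must lie in (0, 1]", call. = FALSE)
  if (p$promoter_peak_lo >= p$promoter_peak_hi)
    stop("promoter_peak_lo must be smaller than promoter_peak_hi",
         call. = FALSE)
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters of the well model\n")
  cat(sprintf("  hydrolysis : Km = %g mM sucrose, Vmax = %.3g molecules/s/cell\n",
              x$km_sucrose, x$vmax_hydrolysis))
  cat(sprintf("  import     : Km = %g mM hexose,  Vmax = %.3g molecules/s/cell\n",
              x$km_hexose, x$vmax_import))
  cat(sprintf("  diffusion  : D_sucrose = %g, D_glucose = %g um^2/s\n",
              x$d_sucrose, x$d_glucose))
  cat(sprintf("  promoter   : basal %g, peak in [%g, %g] mM, tau = %g s\n",
              x$promoter_basal, x$promoter_peak_lo, x$promoter_peak_hi,
              x$invertase_tau))
  cat(sprintf("  geometry   : cell radius %g um, packing fraction %g\n",
              x$cell_radius, x$packing_fraction))
  cat(sprintf("  growth     : threshold %.3g molecules/s\n",
              x$min_growth_intake))
  invisible(x)
}

# Internal promoter-curve shape constants derived from the peak window.
# The curve is a product of a saturating induction branch (half-max K_i
# far below the window: induction saturates at micromolar glucose) and a
# sharp Hill repression branch (coefficient 4, midpoint K_r above the
# window). The raw product is normalised by its maximum, which lies
# inside the peak window.
promoter_shape <- function(p) {
  g_mid <- sqrt(p$promoter_peak_lo * p$promoter_peak_hi)
  ki <- 1e-3 * g_mid
  kr <- 4 * g_mid
  f <- function(g) (g / (g + ki)) * (kr^4 / (kr^4 + g^4))
  opt <- optimize(f, c(0, 10 * p$promoter_peak_hi), maximum = TRUE)
  list(ki = ki, kr = kr, fstar = opt$objective, g_peak = opt$maximum)
}
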