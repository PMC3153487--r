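#' Promoter activity of the invertase gene
#'
#' Low glucose induces invertase expression and glucose above roughly
#' 0.25-1 mM represses it, so the activity of the regulated promoter is a
#' unimodal function of extracellular glucose: basal at 0 mM, maximal
#' (activity 1) inside the window `[promoter_peak_lo, promoter_peak_hi]`,
#' and monotonically decreasing above it. In `"constitutive"` mode the
#' promoter is decoupled from glucose and the function returns 1, the
#' scenario used to test that the clump advantage survives breaking the
#' glucose-invertase positive feedback loop.
#'
#' @param glucose_mM nonnegative glucose concentration(s), mM.
#' @param params a [kinetic_params()] object.
#' @param mode `"regulated"` or `"constitutive"`.
#' @return promoter activity in `[0, 1]`, same length as `glucose_mM`.
#' @examples
#' promoter_activity(0.5)                        # near 1, in the peak window
#' promoter_activity(16) < promoter_activity(0.5)  # repression
#' promoter_activity(7, mode = "constitutive")   # exactly 1
#' @export
promoter_activity <- function(glucose_mM, params = kinetic_params(),
                              mode = c("regulated", "constitutive")) {
  mode <- match.arg(mode)
  check_nonneg(glucose_mM, "glucose_mM")
  if (mode == "constitutive") return(rep(1, length(glucose_mM)))
  sh <- promoter_shape(params)
  f <- (glucose_mM / (glucose_mM + sh$ki)) *
    (sh$kr^4 / (sh$kr^4 + glucose_mM^4))
  params$promoter_basal + (1 - params$promoter_basal) * f / sh$fstar
}

#' Sucrose hydrolysis rate of one cell
#'
#' Michaelis-Menten kinetics of cell-wall invertase, scaled by the cell's
#' induction level: `induction * Vmax * S / (Km + S)`. One sucrose yields
#' one glucose and one fructose; the returned rate counts glucose. The
#' fructose produced alongside is not tracked separately because import
#' treats both hexoses identically.
#'
#' @param sucrose_mM nonnegative sucrose concentration(s), mM.
#' @param induction invertase induction level(s), >= 0 (1 = fully induced).
#' @param params a [kinetic_params()] object.
#' @return hydrolysis rate, glucose molecules s^-1 cell^-1.
#' @examples
#' hydrolysis_rate(11)   # half saturation: 1.8e8
#' @export
hydrolysis_rate <- function(sucrose_mM, induction = 1,
                            params = kinetic_params()) {
  check_nonneg(sucrose_mM, "sucrose_mM")
  check_nonneg(induction, "induction")
  induction * params$vmax_hydrolysis * sucrose_mM /
    (params$km_sucrose + sucrose_mM)
}

#' Hexose import rate of one cell
#'
#' Saturable transporter kinetics `Vmax * G / (Km + G)`. Glucose and
#' fructose are imported at the same rate, so only the glucose field is
#' simulated and reported; total monosaccharide intake is twice the
#' glucose intake.
#'
#' @param glucose_mM nonnegative glucose concentration(s), mM.
#' @param params a [kinetic_params()] object.
#' @return import rate, glucose molecules s^-1 cell^-1.
#' @examples
#' p <- kinetic_params()
#' import_rate(p$km_hexose, p)  # Vmax/2
#' @export
import_rate <- function(glucose_mM, params = kinetic_params()) {
  check_nonneg(glucose_mM, "glucose_mM")
  params$vmax_import * glucose_mM / (params$km_hexose + glucose_mM)
}

#' State of a single tracked cell
#'
#' @param induction invertase induction level in `[0, 1]`.
#' @param intake_rate instantaneous glucose import (molecules/s).
#' @param cumulative_intake total glucose imported so far (molecules).
#' @return an object of class `cell_state`.
#' @export
cell_state <- function(induction = 1, intake_rate = 0,
                       cumulative_intake = 0) {
  check_nonneg(induction, "induction")
  check_nonneg(intake_rate, "intake_rate")
  check_nonneg(cumulative_intake, "cumulative_intake")
  structure(list(induction = induction, intake_rate = intake_rate,
                 cumulative_intake = cumulative_intake),
            class = "cell_state")
}

#' Relax invertase induction toward the promoter set point
#'
#' First-order relaxation of the induction level toward
#' `promoter_activity(glucose_mM)` with time constant `invertase_tau`:
#' `e <- e + dt * (a - e) / tau`. By default the relaxation is
#' symmetric, so enzyme capacity also tracks the set point downward
#' (deactivation/turnover of wall invertase on the tau timescale), which
#' lets glucose repression act; `decay = FALSE` gives a ratcheting
#' variant in which wall-retained invertase never declines.
#'
#' @param state a [cell_state()] object, or a bare numeric induction
#'   level (in which case a numeric is returned).
#' @param glucose_mM local glucose concentration (mM).
#' @param dt time step (s), > 0.
#' @param params a [kinetic_params()] object.
#' @param mode promoter mode, see [promoter_activity()].
#' @param decay if `FALSE`, induction only moves upward.
#' @return updated `state` of the same type as the input.
#' @examples
#' invertase_update(0, glucose_mM = 0.5, dt = 36)  # ~ dt/tau
#' @export
invertase_update <- function(state, glucose_mM, dt,
                             params = kinetic_params(),
                             mode = c("regulated", "constitutive"),
                             decay = TRUE) {
  mode <- match.arg(mode)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  bare <- is.numeric(state)
  e <- if (bare) state else state$induction
  check_nonneg(e, "induction")
  a <- promoter_activity(glucose_mM, params, mode)
  e_new <- ifelse(decay | a > e, e + dt * (a - e) / params$invertase_tau, e)
  e_new <- pmin(pmax(e_new, 0), 1)
  if (bare) return(e_new)
  state$induction <- e_new
  state
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("%s must be finite and nonnegative", name), call. = FALSE)
  invisible(x)
}
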