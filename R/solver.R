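#' One implicit diffusion step on the radial grid
#'
#' Advances `d C/dt = D r^-2 d/dr (r^2 dC/dr)` by one time step on the
#' finite-volume grid of a [well_geometry][build_geometry()], with
#' zero-flux conditions at the cell surface and the outer wall. The
#' default `theta = 0.5` is the Crank-Nicolson weighting (second-order in
#' time); `theta = 1` is backward Euler (first-order, L-stable), which
#' the coupled simulation driver uses. Either weighting conserves total
#' solute exactly. Reactions are handled separately (see
#' [reaction_step()] and [run_simulation()]).
#'
#' @param field concentrations per node (mM), nonnegative.
#' @param D diffusivity (um^2/s).
#' @param dt time step (s), > 0.
#' @param geometry a [well_geometry][build_geometry()].
#' @param theta implicitness weight in `[0.5, 1]`.
#' @return the updated concentration field.
#' @examples
#' g <- build_geometry("isolated", grid_nodes = 50)
#' f <- diffusion_step(rep(2, 50), D = 600, dt = 1, geometry = g)
#' all.equal(f, rep(2, 50))  # uniform fields are stationary
#' @export
diffusion_step <- function(field, D, dt, geometry, theta = 0.5) {
  stopifnot(inherits(geometry, "well_geometry"))
  if (length(field) != geometry$grid_nodes)
    stop("field length does not match the geometry's grid", call. = FALSE)
  if (!is.numeric(field) || any(!is.finite(field)))
    stop("field must be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  if (!is.numeric(D) || length(D) != 1 || D < 0)
    stop("D must be a single nonnegative number", call. = FALSE)
  if (theta < 0.5 || theta > 1)
    stop("theta must lie in [0.5, 1]", call. = FALSE)
  diffusion_step_cpp(field, geometry$vol, geometry$gface, D, dt, theta)
}

#' Radial simulation state
#'
#' Holds the sucrose and glucose fields (mM per node), the per-node
#' invertase induction of reactive nodes, elapsed time, and cumulative
#' molecule tallies.
#'
#' @param geometry a [well_geometry][build_geometry()].
#' @param sucrose_mM initial uniform sucrose concentration (mM).
#' @param glucose_mM initial uniform glucose concentration (mM).
#' @param induction0 initial induction of all cells (default 1: cells
#'   pregrown in low glucose are fully induced).
#' @return an object of class `sim_state`.
#' @export
sim_state <- function(geometry, sucrose_mM, glucose_mM = 0,
                      induction0 = 1) {
  stopifnot(inherits(geometry, "well_geometry"))
  check_nonneg(sucrose_mM, "sucrose_mM")
  check_nonneg(glucose_mM, "glucose_mM")
  n <- geometry$grid_nodes
  structure(list(time = 0,
                 sucrose_field = rep(sucrose_mM[1], n),
                 glucose_field = rep(glucose_mM[1], n),
                 induction = rep(induction0, n),
                 hydrolyzed_molecules = 0,
                 imported_molecules = 0,
                 imported_central_molecules = 0,
                 central_intake_rate = 0),
            class = "sim_state")
}

#' One reaction step (no diffusion)
#'
#' Applies, over one time step, the local reaction terms at every node
#' holding cells: induction update, Michaelis-Menten sucrose hydrolysis
#' (sink on sucrose, equal source on glucose) and hexose import (sink on
#' glucose). Sinks are treated linearised-implicitly, which keeps fields
#' nonnegative without clamping and makes the molecule bookkeeping exact:
#' sucrose consumed equals glucose produced in every step.
#'
#' @param state a [sim_state()].
#' @param dt time step (s), > 0.
#' @param geometry the [well_geometry][build_geometry()] the state lives
#'   on.
#' @param params a [kinetic_params()] object.
#' @param mode promoter mode, see [promoter_activity()].
#' @param decay passed to the induction update, see [invertase_update()].
#' @return the updated `sim_state`.
#' @export
reaction_step <- function(state, dt, geometry, params = kinetic_params(),
                          mode = c("regulated", "constitutive"),
                          decay = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "sim_state"), inherits(geometry, "well_geometry"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  conv <- .molecules_per_um3_per_mM
  S <- state$sucrose_field
  G <- state$glucose_field
  e <- state$induction
  cells <- geometry$cells
  vol <- geometry$vol
  rx <- which(cells > 0)

  # (1)-(2): induction responds to local glucose
  e[rx] <- invertase_update(e[rx], G[rx], dt, params, mode, decay)

  # import coefficient linearised at the measured (start-of-step) glucose
  km <- numeric(length(G))
  km[rx] <- cells[rx] * params$vmax_import /
    ((params$km_hexose + G[rx]) * vol[rx] * conv)

  # (3): hydrolysis, linearised-implicit sink on sucrose
  kh <- numeric(length(S))
  kh[rx] <- cells[rx] * e[rx] * params$vmax_hydrolysis /
    ((params$km_sucrose + S[rx]) * vol[rx] * conv)
  S_new <- S / (1 + dt * kh)
  hyd <- kh * S_new * dt * vol * conv         # molecules per node
  G <- G + kh * S_new * dt                    # 1:1 source, mM

  # (4): import, linearised-implicit sink on glucose
  G_new <- G / (1 + dt * km)
  imp <- km * G_new * dt * vol * conv

  state$sucrose_field <- S_new
  state$glucose_field <- G_new
  state$induction <- e
  state$time <- state$time + dt
  state$hydrolyzed_molecules <- state$hydrolyzed_molecules + sum(hyd)
  state$imported_molecules <- state$imported_molecules + sum(imp)
  central <- imp[1] / cells[1]
  state$imported_central_molecules <-
    state$imported_central_molecules + central
  state$central_intake_rate <- central / dt
  state
}
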