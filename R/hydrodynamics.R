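#' Rectangular simulation chamber
#'
#' Defines the closed 2-D chamber `[0,L] x [0,H]` on a uniform grid of square
#' cells, with the reagent inlet on the left wall and a catalytic region A on
#' the floor. Grid nodes sit at cell centres `((i-1/2) dx, (j-1/2) dx)`.
#'
#' @param L Chamber length (m).
#' @param H Chamber height (m).
#' @param Ny Number of grid cells across the height (>= 8); `dx = H/Ny` and
#'   `Nx = L/dx` must be an integer (square cells).
#' @param catalytic_interval Extent `c(x_start, x_end)` of the catalytic
#'   region A on the floor (m).
#' @param dz Nominal out-of-plane thickness (m); defaults to one grid spacing.
#'   It cancels in all `n/n0` observables and only scales absolute amounts.
#'
#' @return An object of class `cc_domain`.
#' @export
domain <- function(L = 3e-3, H = 1.3e-3, Ny = 26,
                   catalytic_interval = c(1.5e-4, L), dz = NULL) {
  if (L <= 0 || H <= 0) stop("domain dimensions must be positive")
  if (Ny < 8) stop("Ny must be at least 8")
  dx <- H / Ny
  Nx <- as.integer(round(L / dx))
  Ny <- as.integer(Ny)
  if (Nx < 8) stop("Nx must be at least 8; increase L or Ny")
  if (abs(Nx * dx - L) > 1e-9 * L)
    stop("grid cells must be square: L must be an integer multiple of H/Ny")
  ci <- catalytic_interval
  if (length(ci) != 2 || ci[1] < 0 || ci[2] > L + 1e-12 || ci[1] >= ci[2])
    stop("catalytic_interval must satisfy 0 <= x_start < x_end <= L")
  if (is.null(dz)) dz <- dx
  structure(list(L = L, H = H, dx = dx, Nx = Nx, Ny = Ny, dz = dz,
                 catalytic_interval = c(ci[1], min(ci[2], L)),
                 inlet_wall = "left"),
            class = "cc_domain")
}

# 0-based column range of catalytic region A (cells whose centre lies in it)
catalytic_cols <- function(dom) {
  centers <- (seq_len(dom$Nx) - 0.5) * dom$dx
  idx <- which(centers >= dom$catalytic_interval[1] &
               centers <= dom$catalytic_interval[2])
  if (length(idx) == 0) c(0L, -1L) else c(min(idx) - 1L, max(idx) - 1L)
}

#' Quiescent fluid state on the lattice
#'
#' Initializes the D2Q9 lattice Boltzmann state at rest. The physical-to-
#' lattice mapping is fixed by the grid spacing and the relaxation time:
#' `dt = (tau - 1/2)/3 * dx^2 / nu`, so that the lattice viscosity matches
#' the physical one.
#'
#' @param dom A [domain()] object.
#' @param consts A [physical_constants()] object.
#' @param tau BGK relaxation time in lattice units; must lie in (0.55, 1.5).
#' @param periodic_x Use periodic boundaries in x instead of side walls
#'   (the plane-channel benchmark mode).
#' @return An object of class `cc_fluid` with velocity (m s^-1) and pressure
#'   (Pa, gauge-fixed to zero mean) on the grid.
#' @export
fluid_field <- function(dom, consts, tau = 1.35, periodic_x = FALSE) {
  if (tau <= 0.55 || tau >= 1.5)
    stop("relaxation time tau must lie in (0.55, 1.5)")
  dt_lbm <- (tau - 0.5) / 3 * dom$dx^2 / consts$nu
  z <- matrix(0, dom$Nx, dom$Ny)
  structure(list(f = cc_lbm_equilibrium(dom$Nx, dom$Ny),
                 ux = z, uy = z, p = z, rho = z + 1,
                 t = 0, tau = tau, dt_lbm = dt_lbm,
                 dx = dom$dx, Nx = dom$Nx, Ny = dom$Ny,
                 rho0 = consts$rho0, periodic_x = periodic_x,
                 umax_lb = 0),
            class = "cc_fluid")
}

#' Solutal buoyancy body force
#'
#' Boussinesq buoyancy of the reagent-laden fluid relative to pure solvent:
#' a vertical body force `f_y = -rho0 g beta_C C` (N m^-3). Zero where the
#' reagent is absent; the hydrostatic part of the pure-solvent weight is
#' absorbed into the pressure.
#'
#' @param C A [concentration_field()] object (or a plain concentration
#'   matrix in M).
#' @param consts A [physical_constants()] object.
#' @param reagent A [reagent_model()] object.
#' @return A list with force components `fx`, `fy` (N m^-3) on the grid,
#'   class `cc_force`.
#' @export
make_buoyancy_force <- function(C, consts, reagent) {
  Cm <- if (inherits(C, "cc_concentration")) C$C else C
  if (!is.matrix(Cm)) stop("C must be a concentration field or matrix")
  structure(list(fx = matrix(0, nrow(Cm), ncol(Cm)),
                 fy = -consts$rho0 * consts$g * reagent$beta_C * Cm),
            class = "cc_force")
}

#' Advance the fluid by one (or more) coupling steps
#'
#' Runs the lattice Boltzmann scheme for `dt` seconds (which must be an
#' integer multiple of the lattice step `state$dt_lbm`) under a frozen body
#' force, then refreshes the macroscopic fields. No-slip is enforced on all
#' walls by half-way bounce-back (periodic in x in channel-benchmark mode).
#'
#' @param state A [fluid_field()] object.
#' @param force A `cc_force` body-force field (N m^-3) on the same grid, or
#'   `NULL` for unforced relaxation.
#' @param dt Time to advance (s); must be `>= state$dt_lbm`.
#' @return The advanced `cc_fluid` state.
#' @export
step_fluid <- function(state, force, dt) {
  nrep <- round(dt / state$dt_lbm)
  if (nrep < 1 || abs(nrep * state$dt_lbm - dt) > 1e-9 * dt)
    stop("dt must be a positive integer multiple of the lattice step dt_lbm = ",
         format(state$dt_lbm))
  nn <- state$Nx * state$Ny
  if (is.null(force)) {
    ax <- ay <- numeric(nn)
  } else {
    if (!all(dim(force$fy) == c(state$Nx, state$Ny)))
      stop("force grid does not match the fluid grid")
    conv <- state$dt_lbm^2 / state$dx / state$rho0  # N/m^3 -> lattice accel
    ax <- as.numeric(force$fx) * conv
    ay <- as.numeric(force$fy) * conv
  }
  res <- cc_lbm_steps(state$f, ax, ay, state$Nx, state$Ny, state$tau,
                      nrep, state$periodic_x)
  conv_u <- state$dx / state$dt_lbm
  state$f <- res$f
  state$ux <- matrix(res$ux * conv_u, state$Nx, state$Ny)
  state$uy <- matrix(res$uy * conv_u, state$Nx, state$Ny)
  rho <- matrix(res$rho, state$Nx, state$Ny)
  state$rho <- rho
  p <- state$rho0 * conv_u^2 * (rho - 1) / 3
  state$p <- p - mean(p)
  state$umax_lb <- res$umax_lb
  state$t <- state$t + nrep * state$dt_lbm
  state
}

#' Interpolate the fluid velocity at a point
#'
#' Bilinear interpolation of the grid velocity, honouring the no-slip walls
#' (the velocity is zero on all four walls, which form the outermost
#' interpolation nodes). Exact at grid nodes and for fields linear between
#' them.
#'
#' @param state A [fluid_field()] object.
#' @param position Numeric `c(x, y)` in metres, inside the domain.
#' @return Velocity `c(ux, uy)` (m s^-1).
#' @export
interpolate_velocity <- function(state, position) {
  L <- state$Nx * state$dx
  H <- state$Ny * state$dx
  if (position[1] < 0 || position[1] > L || position[2] < 0 || position[2] > H)
    stop("position lies outside the domain")
  cc_interp_velocity(state$ux, state$uy, state$dx, position[1], position[2])
}

#' Discrete divergence of the velocity field
#'
#' Central-difference divergence with the no-slip wall values as boundary
#' neighbours; used by the incompressibility diagnostics.
#'
#' @param state A [fluid_field()] object.
#' @return Matrix of `du_x/dx + du_y/dy` (s^-1) on the grid.
#' @export
divergence <- function(state) {
  ux <- state$ux; uy <- state$uy
  dx <- state$dx
  nx <- nrow(ux); ny <- ncol(ux)
  # pad with wall values (0) half a cell outside; one-sided spacing at walls
  xw <- rbind(0, ux, 0)   # (nx+2) x ny
  yw <- cbind(0, uy, 0)   # nx x (ny+2)
  ddx <- (xw[3:(nx + 2), ] - xw[1:nx, ])
  ddx[1, ] <- ddx[1, ] / (1.5 * dx); ddx[nx, ] <- ddx[nx, ] / (1.5 * dx)
  ddx[2:(nx - 1), ] <- ddx[2:(nx - 1), ] / (2 * dx)
  ddy <- (yw[, 3:(ny + 2)] - yw[, 1:ny])
  ddy[, 1] <- ddy[, 1] / (1.5 * dx); ddy[, ny] <- ddy[, ny] / (1.5 * dx)
  ddy[, 2:(ny - 1)] <- ddy[, 2:(ny - 1)] / (2 * dx)
  ddx + ddy
}
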