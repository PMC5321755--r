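#' Closed-form validation oracles
#'
#' Independent references for the solvers: literal-arithmetic Stokes
#' sedimentation, the semi-infinite diffusion profile, the plane-channel
#' (Poiseuille) parabola, and the 2-D Brownian mean-squared displacement.
#' Each is a few lines of closed-form arithmetic with no dependence on the
#' solver code paths, so agreement is a genuine cross-check.
#'
#' @name oracles
NULL

# scale: elementwise |reference| by default; pass a scalar (e.g. 1 for a
# normalized profile) when the reference legitimately crosses zero
oracle_report <- function(name, computed, reference, tolerance, scale = NULL) {
  if (is.null(scale)) scale <- ifelse(abs(reference) > 0, abs(reference), 1)
  err <- max(abs(computed - reference) / scale)
  structure(list(name = name, computed = computed, reference = reference,
                 tolerance = tolerance, max_rel_err = err,
                 passed = err <= tolerance),
            class = "cc_oracle_report")
}

#' @export
print.cc_oracle_report <- function(x, ...) {
  cat(sprintf("oracle %-10s %s (tol %.3g, max rel err %.3g)\n", x$name,
              if (x$passed) "PASS" else "FAIL", x$tolerance, x$max_rel_err))
  invisible(x)
}

#' Stokes sedimentation oracle
#'
#' Evaluates `2 (rho_t - rho0) g R^2 / (9 eta)` by literal arithmetic and
#' compares it with [sedimentation_speed()]; also reports the full-height
#' settling time `H/V`. A neutrally buoyant tracer settles at zero speed
#' (infinite settling time, flagged).
#'
#' @param consts A [physical_constants()] object.
#' @param tracer A [tracer_model()] object.
#' @param H Chamber height for the settling time (m).
#' @return A `cc_oracle_report` with the settling time (s) and an
#'   `infinite_settling` flag as attributes.
#' @export
stokes_oracle <- function(consts, tracer, H = 1.3e-3) {
  ref <- 2 * (tracer$rho_t - consts$rho0) * consts$g * tracer$R^2 /
    (9 * consts$rho0 * consts$nu)
  rep <- oracle_report("stokes", sedimentation_speed(tracer, consts), ref,
                       tolerance = 0.01)
  attr(rep, "settling_time") <- if (ref > 0) H / ref else Inf
  attr(rep, "infinite_settling") <- !(ref > 0)
  rep
}

#' Semi-infinite diffusion profile
#'
#' `C(x, t) = C0 erfc(x / (2 sqrt(D t)))`: the concentration ahead of a wall
#' held at `C0` from `t = 0` in a quiescent half-space.
#'
#' @param D Diffusivity (m^2 s^-1).
#' @param C0 Wall concentration (M).
#' @param x Positions (m).
#' @param t Time (s), positive.
#' @return Concentrations (M).
#' @export
diffusion_oracle <- function(D, C0, x, t) {
  if (t <= 0) stop("t must be positive")
  C0 * erfc(x / (2 * sqrt(D * t)))
}

#' Complementary error function
#' @param z Numeric.
#' @return `erfc(z)`.
#' @export
erfc <- function(z) 2 * stats::pnorm(-z * sqrt(2))

#' Plane-channel (Poiseuille) velocity profile
#'
#' Steady profile `u(y) = f y (H - y) / (2 rho0 nu)` of a channel of height
#' `H` driven by a uniform horizontal body force `f` with no-slip top and
#' bottom; the mid-channel maximum is `f H^2 / (8 rho0 nu)`.
#'
#' @param force Body force (N m^-3).
#' @param consts A [physical_constants()] object.
#' @param H Channel height (m).
#' @param y Heights at which to evaluate (m).
#' @return Velocities (m s^-1).
#' @export
poiseuille_oracle <- function(force, consts, H, y) {
  force * y * (H - y) / (2 * consts$rho0 * consts$nu)
}

#' Brownian mean-squared displacement
#'
#' `MSD(t) = 4 D_t t` for free 2-D diffusion.
#'
#' @param D_t Tracer diffusivity (m^2 s^-1).
#' @param times Times (s).
#' @return Mean-squared displacements (m^2).
#' @export
msd_oracle <- function(D_t, times) 4 * D_t * times

#' Run the oracle validation suite against the solvers
#'
#' Four benchmarks, each comparing a solver to its closed-form reference:
#' `stokes` (arithmetic, tolerance 1%), `diffusion` (quiescent reagent
#' stepper vs erfc profile, 1%), `poiseuille` (forced channel flow vs the
#' parabola at the default grid, 2%), `msd` (Brownian tracer ensemble vs
#' `4 D_t t`, 5% at 1e4 tracers).
#'
#' @param suite Which oracles to run.
#' @param seed RNG seed for the stochastic benchmark.
#' @return A list of `cc_oracle_report`s; attribute `passed` is the
#'   conjunction.
#' @export
validate_suite <- function(suite = c("stokes", "diffusion", "poiseuille",
                                     "msd"), seed = 1L) {
  suite <- match.arg(suite, several.ok = TRUE)
  con <- physical_constants()
  tra <- tracer_model(consts = con)
  reports <- list()

  if ("stokes" %in% suite) reports$stokes <- stokes_oracle(con, tra)

  if ("diffusion" %in% suite) {
    dom <- domain(L = 1.28e-3, H = 8e-5, Ny = 8,
                  catalytic_interval = c(0, 1.28e-3))
    rea <- reagent_model(rmax = 0)
    flow <- fluid_field(dom, con)
    conc <- concentration_field(dom)
    bc <- inlet_bc("A", C0 = 0.1, lam = 0)
    t_end <- 50
    conc <- step_concentration(conc, flow, bc, rea, dom, t_end)
    x <- (seq_len(dom$Nx) - 0.5) * dom$dx
    ref <- diffusion_oracle(rea$D, bc$C0, x, t_end)
    reports$diffusion <- oracle_report("diffusion", conc$C[, 1] / bc$C0,
                                       ref / bc$C0, tolerance = 0.01,
                                       scale = 1)
  }

  if ("poiseuille" %in% suite) {
    dom <- domain(L = 6.5e-4, H = 1.3e-3, Ny = 32,
                  catalytic_interval = c(0, 6.5e-4))
    flow <- fluid_field(dom, con, periodic_x = TRUE)
    f <- 4
    force <- structure(list(fx = matrix(f, dom$Nx, dom$Ny),
                            fy = matrix(0, dom$Nx, dom$Ny)),
                       class = "cc_force")
    flow <- step_fluid(flow, force, 8000 * flow$dt_lbm)
    y <- (seq_len(dom$Ny) - 0.5) * dom$dx
    ref <- poiseuille_oracle(f, con, dom$H, y)
    reports$poiseuille <- oracle_report("poiseuille",
                                        flow$ux[1, ] / max(ref),
                                        ref / max(ref), tolerance = 0.02,
                                        scale = 1)
  }

  if ("msd" %in% suite) {
    set.seed(seed)
    dom <- domain(L = 1, H = 1, Ny = 8, catalytic_interval = c(0, 1))
    flow <- fluid_field(dom, con)
    tra0 <- tracer_model(rho_t = con$rho0, consts = con)  # neutral: V = 0
    N <- 10000L
    ens <- structure(list(x = rep(0.5, N), y = rep(0.5, N),
                          settled = logical(N), N = N, seed = seed),
                     class = "cc_tracers")
    x0 <- ens$x; y0 <- ens$y
    dt <- 2
    nstep <- 100L
    for (k in seq_len(nstep)) ens <- step_tracers(ens, flow, dt, tra0)
    msd <- mean((ens$x - x0)^2 + (ens$y - y0)^2)
    reports$msd <- oracle_report("msd", msd,
                                 msd_oracle(tra0$D_t, nstep * dt),
                                 tolerance = 0.05)
  }

  attr(reports, "passed") <- all(vapply(reports, `[[`, TRUE, "passed"))
  reports
}
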