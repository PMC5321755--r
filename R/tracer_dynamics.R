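#' Initialize a tracer ensemble
#'
#' Places `N` tracers i.i.d. uniformly over the chamber, reproducibly for a
#' given seed (the seed also fixes the Brownian noise stream of the run).
#'
#' @param N Number of tracers (>= 1).
#' @param dom A [domain()] object.
#' @param seed Integer RNG seed.
#' @return An object of class `cc_tracers` with positions, sticky
#'   settled flags and the seed.
#' @export
initialize_tracers <- function(N, dom, seed = 1L) {
  if (N < 1) stop("N must be at least 1")
  set.seed(seed)
  structure(list(x = runif(N, 0, dom$L), y = runif(N, 0, dom$H),
                 settled = logical(N), N = as.integer(N),
                 seed = as.integer(seed)),
            class = "cc_tracers")
}

# repulsive branch of the Morse wall force as a function of wall distance
morse_wall_force <- function(d, eps, omega, d0) {
  s <- exp(pmin(omega * (d0 - d), 60))
  ifelse(d < d0, 2 * eps * omega * s * (s - 1), 0)
}

#' Repulsive wall force on a tracer
#'
#' Sum over the four walls of the repulsive branch of a Morse potential
#' `U(d) = eps (1 - exp(-omega (d - d0)))^2` with minimum at `d0 = R`; the
#' force acts along the inward normal of each wall, is zero beyond `d0` and
#' grows on the scale `1/omega` as the tracer approaches contact.
#'
#' @param position Numeric `c(x, y)` (m), inside the domain.
#' @param dom A [domain()] object.
#' @param tracer A [tracer_model()] object.
#' @return Force vector `c(Fx, Fy)` (N).
#' @export
wall_force <- function(position, dom, tracer) {
  x <- position[1]; y <- position[2]
  d0 <- tracer$R
  fx <- morse_wall_force(x, tracer$eps, tracer$omega, d0) -
        morse_wall_force(dom$L - x, tracer$eps, tracer$omega, d0)
  fy <- morse_wall_force(y, tracer$eps, tracer$omega, d0) -
        morse_wall_force(dom$H - y, tracer$eps, tracer$omega, d0)
  c(fx, fy)
}

#' Brownian displacement increments
#'
#' Independent zero-mean Gaussian displacements with variance `2 D_t dt`
#' per component, drawn from R's global RNG stream.
#'
#' @param dt Time step (s), positive.
#' @param D_t Tracer diffusivity (m^2 s^-1).
#' @param n Number of displacement pairs.
#' @return An `n x 2` matrix of displacements (m).
#' @export
draw_noise <- function(dt, D_t, n = 1) {
  if (dt <= 0) stop("dt must be positive")
  matrix(rnorm(2 * n, sd = sqrt(2 * D_t * dt)), n, 2)
}

# floor band within which a tracer counts as settled
settle_height <- function(tracer) tracer$R + 3 / tracer$omega

#' Advance the tracer ensemble by one step
#'
#' First-order overdamped Langevin update: advection with the interpolated
#' flow, Stokes sedimentation, Brownian noise, and the repulsive Morse wall
#' forces. The stiff wall-normal force term is treated implicitly (its fixed
#' point is the exact hover height where `mu F = V_sed`), everything else
#' explicitly. Positions are clamped to the domain only as a last-resort
#' safeguard; clamp events are counted on the returned ensemble.
#'
#' @param ens A [initialize_tracers()] ensemble.
#' @param flow A [fluid_field()] object.
#' @param dt Time step (s), equal to or an integer divisor of the fluid step.
#' @param tracer A [tracer_model()] object.
#' @param noise Draw Brownian displacements (disable for deterministic
#'   oracle tests).
#' @return The advanced `cc_tracers`; settled flags are updated by the
#'   floor-band counting rule and are sticky.
#' @export
step_tracers <- function(ens, flow, dt, tracer, noise = TRUE) {
  res <- cc_tracer_step(ens$x, ens$y, ens$settled, flow$ux, flow$uy,
                        flow$dx, dt, tracer$V_sed, tracer$D_t, tracer$mu,
                        tracer$eps, tracer$omega, tracer$R,
                        settle_height(tracer), noise)
  if (res$clamped > 0) {
    ens$clamped <- (ens$clamped %||% 0L) + res$clamped
    if (ens$clamped > 0.001 * ens$N * max(1, (ens$steps %||% 0L)))
      stop("excessive tracer clamping (", ens$clamped,
           " events): wall forces or step size are misconfigured")
  }
  ens$x <- res$x
  ens$y <- res$y
  ens$settled <- res$settled
  ens$steps <- (ens$steps %||% 0L) + 1L
  ens
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the settled-tracer counting rule
#'
#' A tracer is counted as settled once its height drops into the floor band
#' `y < R + 3/omega` (the hover-height scale of the wall potential). Settled
#' tracers keep moving horizontally with the local flow (no wall friction)
#' and are never un-counted.
#'
#' @param ens A [initialize_tracers()] ensemble.
#' @param tracer A [tracer_model()] object.
#' @return The ensemble with updated sticky `settled` flags.
#' @export
settled_rule <- function(ens, tracer) {
  ens$settled <- ens$settled | (ens$y < settle_height(tracer))
  ens
}
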