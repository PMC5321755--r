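#' Full parameterization of a simulation run
#'
#' Collects every parameter of a run — chamber geometry, fluid constants,
#' reagent and reaction model, tracer model, inlet family, numerics and run
#' control — validating all module-level invariants. Unknown keys in any
#' section are rejected.
#'
#' The `time_scale` run parameter compresses time by a factor `s`: every
#' rate process (gravity, reagent diffusivity, inlet decay, reaction rate,
#' inlet flux, tracer diffusivity) is multiplied by `s`, which reproduces
#' the `s = 1` dynamics exactly with `t -> t/s` while inertia stays
#' negligible. Positions, concentrations and `n/n0` are unaffected; only
#' reported times are in compressed seconds. The desk preset uses `s = 20`.
#'
#' @param domain,consts,reagent,tracer,bc,numerics,run Named lists of
#'   overrides for the corresponding parameter groups; see
#'   [physical_constants()], [reagent_model()], [tracer_model()], [domain()]
#'   and [inlet_bc()] for the fields and defaults. `numerics` holds `tau`
#'   (LBM relaxation time), `n_couple` (lattice steps per coupling step) and
#'   `out_every` (coupling steps per output record). `run` holds `seed`,
#'   `N` (tracers), `time_scale`, `noise`, and optionally `horizon`
#'   (simulated seconds; default `4/lam_eff`).
#' @return An object of class `cc_config`.
#' @export
simulation_config <- function(domain = list(), consts = list(),
                              reagent = list(), tracer = list(),
                              bc = list(), numerics = list(), run = list()) {
  take <- function(given, defaults, section) {
    bad <- setdiff(names(given), names(defaults))
    if (length(bad))
      stop("unknown key(s) in ", section, ": ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, given, keep.null = TRUE)
  }
  dom_p <- take(domain, list(L = 13e-3, H = 1.3e-3, Ny = 20,
                             catalytic_interval = NULL, dz = NULL), "domain")
  con_p <- take(consts, list(rho0 = 1000, nu = 1e-6, g = 9.8,
                             T_amb = 298, kB = 1.380649e-23), "consts")
  rea_p <- take(reagent, list(D = 1e-9, beta_C = 1e-2, C0 = 0.1,
                              lam = 1 / 4200, KM = 0.093, M_sites = 4,
                              kcat = 2.12e5, E_areal = 2e-8, rmax = NULL),
                "reagent")
  tra_p <- take(tracer, list(R = 2e-6, rho_t = 1050, eps = 1.2e-14,
                             omega = 6e4), "tracer")
  bc_p <- take(bc, list(family = "A", q0 = NULL), "bc")
  num_p <- take(numerics, list(tau = 1.35, n_couple = 100L, out_every = 20L),
                "numerics")
  run_p <- take(run, list(seed = 1L, N = 500L, time_scale = 1,
                          horizon = NULL, noise = TRUE), "run")

  if (is.null(dom_p$catalytic_interval))
    dom_p$catalytic_interval <- c(0.05 * dom_p$L, dom_p$L)
  dom <- domain(dom_p$L, dom_p$H, dom_p$Ny, dom_p$catalytic_interval,
                dom_p$dz)
  con <- do.call(physical_constants, con_p)
  rea <- do.call(reagent_model, rea_p)
  tra <- tracer_model(tra_p$R, tra_p$rho_t, tra_p$eps, tra_p$omega, con)
  bcc <- inlet_bc(bc_p$family, rea$C0, rea$lam, bc_p$q0, rea$D)
  if (num_p$tau <= 0.55 || num_p$tau >= 1.5)
    stop("numerics$tau must lie in (0.55, 1.5)")
  if (num_p$n_couple < 1 || num_p$out_every < 1)
    stop("numerics$n_couple and numerics$out_every must be positive")
  if (run_p$N < 1) stop("run$N must be at least 1")
  if (run_p$time_scale <= 0) stop("run$time_scale must be positive")
  structure(list(domain = dom, consts = con, reagent = rea, tracer = tra,
                 bc = bcc, numerics = num_p, run = run_p,
                 params = list(domain = dom_p, consts = con_p,
                               reagent = rea_p, tracer = tra_p, bc = bc_p,
                               numerics = num_p, run = run_p)),
            class = "cc_config")
}

#' Desk-scale preset of the reference chamber
#'
#' A 13 mm x 1.3 mm chamber at the reference parameters with time compressed
#' twentyfold (`time_scale = 20`, so the nominal 70 min fuel-depletion time
#' passes in 3.5 simulated minutes); finishes in about a minute of
#' computation while integrating the same dimensionless problem as the
#' full-scale run (the Reynolds number stays well below one).
#'
#' @param rmax Maximal areal reaction rate (mol m^-2 s^-1), nominal scale.
#' @param C0 Gel reagent concentration (M).
#' @param seed Integer RNG seed.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `cc_config`.
#' @export
desk_config <- function(rmax = 1.7e-5, C0 = 0.1, seed = 1L, ...) {
  over <- list(...)
  args <- utils::modifyList(
    list(domain = list(L = 13e-3, H = 1.3e-3, Ny = 20),
         reagent = list(rmax = rmax, C0 = C0),
         run = list(seed = seed, N = 500L, time_scale = 20)),
    over)
  do.call(simulation_config, args)
}

#' Full-geometry preset
#'
#' The unscaled 20 mm x 1.3 mm chamber with the nominal 70 min depletion
#' time; mirrors the reference set-up and is correspondingly expensive.
#'
#' @inheritParams desk_config
#' @return A `cc_config`.
#' @export
full_config <- function(rmax = 1.7e-5, C0 = 0.1, seed = 1L, ...) {
  over <- list(...)
  args <- utils::modifyList(
    list(domain = list(L = 20e-3, H = 1.3e-3, Ny = 26),
         reagent = list(rmax = rmax, C0 = C0),
         run = list(seed = seed, N = 500L, time_scale = 1)),
    over)
  do.call(simulation_config, args)
}

#' Read a configuration from a YAML file
#'
#' The file holds the seven parameter sections of [simulation_config()];
#' every value is validated on load and schema violations name the offending
#' key. Writing and re-loading a configuration reproduces it exactly.
#'
#' @param path Path to a YAML configuration file.
#' @return A `cc_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("domain", "consts", "reagent", "tracer", "bc", "numerics", "run")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  raw <- lapply(raw, function(sec) lapply(sec, function(v)
    if (identical(v, "NULL")) NULL else v))
  do.call(simulation_config, raw)
}

#' Write a configuration to a YAML file
#'
#' @param cfg A `cc_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(lapply(cfg$params, function(sec)
    lapply(sec, function(v) if (is.null(v)) "NULL" else v)), path,
    precision = 15L)
  invisible(path)
}

#' @export
print.cc_config <- function(x, ...) {
  cat("<chemoconvect configuration>\n")
  cat(sprintf("  chamber: %.3g mm x %.3g mm (grid %d x %d, dx = %.3g um)\n",
              1e3 * x$domain$L, 1e3 * x$domain$H, x$domain$Nx, x$domain$Ny,
              1e6 * x$domain$dx))
  cat(sprintf("  reagent: C0 = %g M, 1/lam = %.3g min, rmax = %.3g mol/m2/s, inlet family %s\n",
              x$reagent$C0, 1 / x$reagent$lam / 60, x$reagent$rmax,
              x$bc$family))
  cat(sprintf("  tracers: N = %d, R = %g um, V_sed = %.3g um/s\n",
              x$run$N, 1e6 * x$tracer$R, 1e6 * x$tracer$V_sed))
  cat(sprintf("  run: seed %d, time_scale %g, tau %g\n",
              x$run$seed, x$run$time_scale, x$numerics$tau))
  invisible(x)
}
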