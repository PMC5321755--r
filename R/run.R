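#' Run a full chemoconvection simulation
#'
#' Executes the coupled operator sequence per coupling step: (1) the fluid
#' advances under the buoyancy force of the current reagent field; (2) the
#' reagent advances by advection-diffusion with the updated flow, the inlet
#' condition and the catalytic floor sink; (3) the tracers advance with the
#' updated flow. The run ends when the reagent inventory has fallen below
#' 0.1% of the total injected and every tracer has settled, or at the time
#' horizon (default `4/lam`).
#'
#' Identical configuration and seed give bit-identical results.
#'
#' @param cfg A [simulation_config()] object.
#' @param outdir Optional directory; when given, the configuration echo,
#'   mass-balance ledger, histogram, velocity profile, field snapshot and
#'   summary are written there as delimited text.
#' @param verbose Print the physical-to-lattice unit mapping and progress.
#' @return An object of class `cc_run` with elements `summary` (peak
#'   position, settled fraction, mass-balance residual, termination reason,
#'   ...), `ledger` (per-record mass balance table), `histogram`,
#'   `profile_transport` (per-column maximal horizontal velocity at the
#'   median-deposition time, from which the vortex edge is read),
#'   `profile_peakflow` (the same at the instant of strongest flow),
#'   `fields` (final C, ux, uy, p), and `tracers`.
#' @export
run_simulation <- function(cfg, outdir = NULL, verbose = FALSE) {
  dom <- cfg$domain; con <- cfg$consts; rea <- cfg$reagent; tra <- cfg$tracer
  s <- cfg$run$time_scale
  tau <- cfg$numerics$tau
  dt_lbm <- (tau - 0.5) / 3 * dom$dx^2 / con$nu
  dt <- cfg$numerics$n_couple * dt_lbm
  lam_eff <- rea$lam * s
  horizon <- cfg$run$horizon
  if (is.null(horizon)) horizon <- 4 / lam_eff
  ia <- catalytic_cols(dom)
  fam <- match(cfg$bc$family, c("A", "B", "C"))
  if (verbose)
    message(sprintf(
      "lattice mapping: dx = %.3g um, dt_lbm = %.3g s, tau = %g, coupling dt = %.3g s, horizon = %.5g s (time_scale %g)",
      1e6 * dom$dx, dt_lbm, tau, dt, horizon, s))

  set.seed(cfg$run$seed)
  ens <- list(x = runif(cfg$run$N, 0, dom$L), y = runif(cfg$run$N, 0, dom$H))
  res <- cc_run(dom$Nx, dom$Ny, dom$dx,
                tau, dt_lbm, cfg$numerics$n_couple,
                con$g * s, rea$beta_C,
                rea$D * s, rea$KM, rea$rmax * s,
                ia[1], ia[2],
                fam, rea$C0, lam_eff, cfg$bc$q0 * s,
                ens$x, ens$y,
                tra$V_sed * s, tra$D_t * s, tra$mu,
                tra$eps, tra$omega, tra$R, settle_height(tra),
                horizon, cfg$numerics$out_every, cfg$run$noise)

  ledger <- res$ledger
  ledger$inventory <- ledger$inventory * 1000 * dom$dz
  ledger$injected <- ledger$injected * 1000 * dom$dz
  ledger$consumed <- ledger$consumed * 1000 * dom$dz
  resid <- abs(ledger$inventory - (ledger$injected - ledger$consumed))
  mass_residual <- max(resid) / max(ledger$injected[nrow(ledger)], 1e-300)

  tracers <- structure(list(x = res$tracer_x, y = res$tracer_y,
                            settled = res$settled, N = cfg$run$N,
                            seed = cfg$run$seed),
                       class = "cc_tracers")
  hist <- areal_concentration(tracers, dom, t = res$t)
  peak <- if (any(hist$counts > 0)) find_peak(hist) else NA_real_
  xs <- (seq_len(dom$Nx) - 0.5) * dom$dx
  prof <- as.numeric(res$profiles$peakflow)
  attr(prof, "x") <- xs
  # the vortex edge is read from the flow at median deposition time: the
  # state representative of the transport, not the brief start-up transient
  prof_tr <- as.numeric(res$profiles$transport)
  if (res$profiles$t_transport < 0) prof_tr <- as.numeric(res$profiles$final)
  attr(prof_tr, "x") <- xs
  vthresh <- 0.05 * max(prof_tr, 0)
  vedge <- if (vthresh > 0) vortex_extent(prof_tr, vthresh) else NA_real_

  conv_u <- dom$dx / dt_lbm
  p <- con$rho0 * conv_u^2 * (res$rho - 1) / 3
  p <- p - mean(p)
  out <- structure(list(
    config = cfg,
    summary = list(peak_position = peak,
                   settled_fraction = mean(res$settled),
                   mass_residual = mass_residual,
                   termination = if (res$termination == 1) "depleted" else "horizon",
                   t_end = res$t,
                   vortex_edge = vedge,
                   t_transport = res$profiles$t_transport,
                   t_peakflow = res$profiles$t_peakflow,
                   umax = max(ledger$umax),
                   total_injected_mol = ledger$injected[nrow(ledger)],
                   total_consumed_mol = ledger$consumed[nrow(ledger)],
                   clamped = res$clamped,
                   clipped_mol = res$clipped * 1000 * dom$dz,
                   max_conc_substeps = res$max_conc_substeps,
                   histogram = list(centers = hist$centers,
                                    counts = hist$counts,
                                    n_over_n0 = hist$n_over_n0)),
    ledger = ledger,
    histogram = hist,
    profile_peakflow = prof,
    profile_transport = prof_tr,
    profile_final = as.numeric(res$profiles$final),
    fields = list(C = res$C, ux = res$ux, uy = res$uy, p = p),
    tracers = tracers),
    class = "cc_run")
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

#' @export
print.cc_run <- function(x, ...) {
  s <- x$summary
  cat("<chemoconvect run>\n")
  cat(sprintf("  ended at t = %.4g s (%s); settled %.1f%%\n",
              s$t_end, s$termination, 100 * s$settled_fraction))
  cat(sprintf("  pile peak at x = %.3g mm; vortex edge %.3g mm; max |u| = %.3g um/s\n",
              1e3 * s$peak_position, 1e3 * s$vortex_edge, 1e6 * s$umax))
  cat(sprintf("  mass balance residual %.2g; injected %.3g mol, consumed %.3g mol\n",
              s$mass_residual, s$total_injected_mol, s$total_consumed_mol))
  invisible(x)
}

# full-precision delimited text (lossless numeric round trip)
write_tsv17 <- function(df, path) {
  df2 <- as.data.frame(lapply(df, function(v)
    if (is.double(v)) sprintf("%.17g", v) else v), check.names = FALSE)
  names(df2) <- names(df)
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the artifacts of a run to a directory
#'
#' Emits `config.yaml`, `ledger.tsv` (t, inventory, injected, consumed,
#' ...), `histogram.tsv` (x_bin_center_m, count, n_over_n0), `profile.tsv`
#' (x_m, max_ux_m_per_s), `fields.tsv` (x, y, ux, uy, p, C per grid node,
#' full precision, lossless round trip), `tracers.tsv` and `summary.yaml`.
#'
#' @param run A `cc_run` object.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_config(run$config, file.path(outdir, "config.yaml"))
  write_tsv17(run$ledger, file.path(outdir, "ledger.tsv"))
  h <- run$histogram
  write_tsv17(data.frame(x_bin_center_m = h$centers, count = h$counts,
                         n_over_n0 = h$n_over_n0),
              file.path(outdir, "histogram.tsv"))
  write_tsv17(data.frame(x_m = attr(run$profile_peakflow, "x"),
                         max_ux_transport_m_per_s =
                           as.numeric(run$profile_transport),
                         max_ux_peakflow_m_per_s =
                           as.numeric(run$profile_peakflow)),
              file.path(outdir, "profile.tsv"))
  dom <- run$config$domain
  g <- expand.grid(i = seq_len(dom$Nx), j = seq_len(dom$Ny))
  write_tsv17(data.frame(x = (g$i - 0.5) * dom$dx, y = (g$j - 0.5) * dom$dx,
                         ux = as.numeric(run$fields$ux),
                         uy = as.numeric(run$fields$uy),
                         p = as.numeric(run$fields$p),
                         C = as.numeric(run$fields$C)),
              file.path(outdir, "fields.tsv"))
  tr <- run$tracers
  write_tsv17(data.frame(id = seq_len(tr$N), x = tr$x, y = tr$y,
                         settled = tr$settled),
              file.path(outdir, "tracers.tsv"))
  write_summary(run, file.path(outdir, "summary.yaml"))
  invisible(outdir)
}

#' Write the run summary to a YAML file
#'
#' @param run A `cc_run` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(run, path) {
  yaml::write_yaml(run$summary, path)
  invisible(path)
}

#' Read back a field snapshot written by [write_run()]
#'
#' @param path Path to a `fields.tsv` file.
#' @return A data frame with columns x, y, ux, uy, p, C.
#' @export
read_fields <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Sweep reaction rate and reagent amount
#'
#' Reruns a base configuration over lists of `rmax` and `C0` values and
#' tabulates the pile position — the study design behind the two control
#' laws (pile moves away from the inlet as the rate decreases or the fuel
#' amount increases).
#'
#' @param cfg Base [simulation_config()].
#' @param rmax_values Maximal reaction rates to sweep (mol m^-2 s^-1).
#' @param C0_values Gel concentrations to sweep (M).
#' @param verbose Print one line per run.
#' @return A data frame with columns rmax, C0, peak_position, vortex_edge,
#'   settled_fraction, t_end.
#' @export
sweep_peaks <- function(cfg, rmax_values = NULL, C0_values = NULL,
                        verbose = FALSE) {
  if (is.null(rmax_values)) rmax_values <- cfg$reagent$rmax
  if (is.null(C0_values)) C0_values <- cfg$reagent$C0
  grid <- expand.grid(rmax = rmax_values, C0 = C0_values)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    p <- cfg$params
    p$reagent$rmax <- grid$rmax[k]
    p$reagent$C0 <- grid$C0[k]
    r <- run_simulation(do.call(simulation_config, p))
    if (verbose)
      message(sprintf("rmax = %.2g, C0 = %.2g -> peak %.3g mm (%s)",
                      grid$rmax[k], grid$C0[k],
                      1e3 * r$summary$peak_position, r$summary$termination))
    data.frame(rmax = grid$rmax[k], C0 = grid$C0[k],
               peak_position = r$summary$peak_position,
               vortex_edge = r$summary$vortex_edge,
               settled_fraction = r$summary$settled_fraction,
               t_end = r$summary$t_end)
  })
  do.call(rbind, rows)
}
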