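test_that("configurations validate, reject bad input and round-trip", {
  cfg <- desk_config(rmax = 1.7e-4, C0 = 0.2, seed = 3)
  expect_s3_class(cfg, "cc_config")
  expect_equal(cfg$reagent$C0, 0.2)
  expect_equal(cfg$bc$C0, 0.2)  # the inlet inherits the gel concentration
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$params, cfg$params)
  expect_equal(cfg2$domain, cfg$domain)
  # write -> load -> write is byte-stable
  path2 <- tempfile(fileext = ".yaml")
  write_config(cfg2, path2)
  expect_identical(readLines(path), readLines(path2))

  expect_error(simulation_config(tracer = list(rho_t = 990)), "buoyant")
  expect_error(simulation_config(reagent = list(bogus = 1)), "unknown key")
  expect_error(simulation_config(numerics = list(tau = 2)), "tau")
  expect_error(simulation_config(domain = list(L = 3.14e-3, H = 1.3e-3,
                                               Ny = 26)), "square")
})

coarse <- list(L = 13e-3, H = 1.3e-3, Ny = 16)  # cheap grid for driver checks

test_that("identical configuration and seed give bit-identical runs", {
  cfg <- desk_config(rmax = 1.7e-4, C0 = 0.1, seed = 11,
                     domain = coarse, run = list(horizon = 30))
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$tracers$x, r2$tracers$x)
  expect_identical(r1$fields$C, r2$fields$C)
})

test_that("null-physics run settles uniformly with zero flow", {
  cfg <- desk_config(seed = 21,
                     domain = coarse,
                     reagent = list(beta_C = 0, rmax = 0, C0 = 0),
                     bc = list(family = "C", q0 = 0),
                     run = list(horizon = 250))
  r <- run_simulation(cfg)
  expect_identical(r$summary$umax, 0)  # exactly quiescent
  expect_equal(r$summary$settled_fraction, 1)
  expect_identical(r$summary$total_injected_mol, 0)
  # settled positions stay uniform: chi-square on the histogram counts
  p <- stats::chisq.test(r$histogram$counts)$p.value
  expect_gt(p, 0.01)
})

test_that("the three inlet families give the same qualitative outcome", {
  base <- list(rmax = 1.7e-2, C0 = 0.1, seed = 5, domain = coarse,
               run = list(horizon = 420))
  ra <- run_simulation(do.call(desk_config, c(base, list(bc = list(family = "A")))))
  rb <- run_simulation(do.call(desk_config, c(base, list(bc = list(family = "B")))))
  # family C with its flux amplitude matched to family A's realized injection
  cfgc <- do.call(desk_config, c(base, list(bc = list(family = "C"))))
  bc_matched <- match_injection(cfgc$bc, ra$summary$total_injected_mol,
                                cfgc$domain)
  cfgc$bc <- bc_matched
  rc <- run_simulation(cfgc)
  peaks <- c(ra$summary$peak_position, rb$summary$peak_position,
             rc$summary$peak_position)
  L <- ra$config$domain$L
  # an interior pile for every family, at nearby positions
  expect_true(all(peaks > 0 & peaks < L))
  expect_lt(max(peaks) - min(peaks), 0.15 * L)
  injected <- c(ra$summary$total_injected_mol, rc$summary$total_injected_mol)
  expect_equal(injected[2], injected[1], tolerance = 0.2)
})

test_that("run artifacts are written and the field snapshot round-trips", {
  r <- desk_run_short()
  outdir <- tempfile()
  write_run(r, outdir)
  expect_true(all(file.exists(file.path(outdir,
    c("config.yaml", "ledger.tsv", "histogram.tsv", "profile.tsv",
      "fields.tsv", "tracers.tsv", "summary.yaml")))))
  snap <- read_fields(file.path(outdir, "fields.tsv"))
  expect_identical(snap$C, as.numeric(r$fields$C))   # lossless round trip
  expect_identical(snap$ux, as.numeric(r$fields$ux))
  cfg2 <- load_config(file.path(outdir, "config.yaml"))
  expect_equal(cfg2$params, r$config$params)
})
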