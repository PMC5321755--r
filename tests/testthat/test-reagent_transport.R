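test_that("inlet families evaluate correctly and decay in time", {
  a <- inlet_bc("A", C0 = 0.1, lam = 1 / 4200)
  expect_equal(inlet_value(a, 0), 0.1)
  expect_equal(inlet_value(a, 4200), 0.1 / exp(1))  # one depletion time
  b <- inlet_bc("B", C0 = 0.1, lam = 1 / 4200)
  expect_equal(inlet_value(b, 4200), 0)
  expect_equal(inlet_value(b, 2 * 4200), 0)  # clamped after hitting zero
  cc <- inlet_bc("C", C0 = 0.1, lam = 1 / 4200)
  expect_gt(inlet_value(cc, 0), 0)
  ts <- seq(0, 3 * 4200, length.out = 30)
  for (bc in list(a, b, cc))
    expect_true(all(diff(inlet_value(bc, ts)) <= 0))
  expect_error(inlet_value(a, -1), "nonnegative")
})

test_that("closed box conserves the reagent inventory to machine precision", {
  dom <- small_domain(Ny = 10)
  rea <- reagent_model(rmax = 0)
  flow <- quiet_flow(dom)
  conc <- concentration_field(dom)
  set.seed(2)
  conc$C <- matrix(runif(dom$Nx * dom$Ny, 0, 0.1), dom$Nx, dom$Ny)
  m0 <- total_reagent(conc, dom)
  for (k in 1:50) {
    conc <- step_concentration(conc, flow, sealed_inlet(), rea, dom, 0.5)
    expect_lt(abs(total_reagent(conc, dom) - m0) / m0, 1e-6)
  }
  expect_true(all(conc$C >= 0))
  expect_equal(conc$total_injected, 0)
  expect_equal(conc$total_consumed, 0)
})

test_that("quiescent diffusion from a held inlet matches the erfc profile", {
  dom <- domain(L = 1.28e-3, H = 8e-5, Ny = 8,
                catalytic_interval = c(0, 1.28e-3))
  rea <- reagent_model(rmax = 0)
  conc <- concentration_field(dom)
  bc <- inlet_bc("A", C0 = 0.1, lam = 0)  # held at C0
  t_end <- 50
  conc <- step_concentration(conc, quiet_flow(dom), bc, rea, dom, t_end)
  x <- (seq_len(dom$Nx) - 0.5) * dom$dx
  ref <- diffusion_oracle(rea$D, bc$C0, x, t_end)
  expect_lt(max(abs(conc$C[, 1] - ref)) / bc$C0, 0.01)
  # uniform across the transverse direction
  expect_lt(max(abs(conc$C - conc$C[, 1])), 1e-12)
  # injected bookkeeping equals the inventory (no sink)
  expect_equal(conc$total_injected, total_reagent(conc, dom),
               tolerance = 1e-10)
})

test_that("floor sink removes reagent at the Michaelis-Menten rate", {
  dom <- small_domain(Ny = 10)  # catalyst covers the whole floor
  rea <- reagent_model(rmax = 1.7e-2)
  conc <- concentration_field(dom)
  conc$C[] <- rea$KM  # half-saturation everywhere
  dt <- 1e-3
  conc <- step_concentration(conc, quiet_flow(dom), sealed_inlet(), rea,
                             dom, dt)
  areaA <- diff(dom$catalytic_interval) * dom$dz
  expect_equal(conc$total_consumed, rea$rmax / 2 * areaA * dt,
               tolerance = 0.01)
  # mass balance: inventory drop equals the consumed bookkeeping
  m <- total_reagent(conc, dom)
  m0 <- rea$KM * 1000 * dom$L * dom$H * dom$dz
  expect_equal(m0 - m, conc$total_consumed, tolerance = 1e-9)
})

test_that("total reagent integrates the field with unit conversion", {
  dom <- small_domain()
  conc <- concentration_field(dom)
  expect_identical(total_reagent(conc, dom), 0)
  conc$C[] <- 0.1
  expect_equal(total_reagent(conc, dom),
               0.1 * 1000 * dom$L * dom$H * dom$dz)
})

test_that("advection by a driven flow keeps mass bookkeeping exact", {
  dom <- small_domain(Ny = 12)
  rea <- reagent_model(rmax = 1.7e-4)
  bc <- inlet_bc("A", C0 = 0.1, lam = 1 / 100)
  # a gentle convective roll from a buoyancy kick
  conc <- concentration_field(dom)
  conc$C[seq_len(dom$Nx / 2), ] <- 0.05
  flow <- quiet_flow(dom)
  force <- make_buoyancy_force(conc, cc_consts, rea)
  flow <- step_fluid(flow, force, 2000 * flow$dt_lbm)
  expect_gt(max(abs(flow$ux)), 0)
  for (k in 1:20)
    conc <- step_concentration(conc, flow, bc, rea, dom, 0.05)
  inv0 <- 0.05 * 1000 * dom$L / 2 * dom$H * dom$dz
  inv <- total_reagent(conc, dom)
  resid <- abs(inv - inv0 - (conc$total_injected - conc$total_consumed))
  expect_lt(resid / max(inv, conc$total_injected), 1e-9)
  expect_true(all(conc$C >= 0))
})
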