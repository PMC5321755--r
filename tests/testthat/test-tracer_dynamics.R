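test_that("tracer initialization is uniform, in-domain and reproducible", {
  dom <- small_domain()
  e1 <- initialize_tracers(500, dom, seed = 42)
  expect_length(e1$x, 500)
  expect_true(all(e1$x > 0 & e1$x < dom$L & e1$y > 0 & e1$y < dom$H))
  expect_false(any(e1$settled))
  e2 <- initialize_tracers(500, dom, seed = 42)
  expect_identical(e1, e2)
  big <- initialize_tracers(1e5, dom, seed = 1)
  suppressWarnings({  # runif's 2^-32 grid yields a few ties at this n
    expect_gt(stats::ks.test(big$x / dom$L, "punif")$p.value, 0.01)
    expect_gt(stats::ks.test(big$y / dom$H, "punif")$p.value, 0.01)
  })
})

test_that("wall force is repulsive, short-ranged and symmetric", {
  dom <- small_domain()
  tra <- tracer_model(consts = cc_consts)
  centre <- wall_force(c(dom$L / 2, dom$H / 2), dom, tra)
  expect_identical(centre, c(0, 0))  # walls are far beyond the cutoff R
  # equal distances from floor and left wall: force along the diagonal
  d <- 1e-6
  f <- wall_force(c(d, d), dom, tra)
  expect_gt(f[1], 0)
  expect_equal(f[1], f[2])
  # closer to the wall means a stronger push
  f2 <- wall_force(c(d / 2, d), dom, tra)
  expect_gt(f2[1], f[1])
  # ceiling pushes down
  expect_lt(wall_force(c(dom$L / 2, dom$H - d), dom, tra)[2], 0)
})

test_that("Brownian displacements have the prescribed statistics", {
  expect_identical(draw_noise(1, 0, n = 10), matrix(0, 10, 2))
  set.seed(8)
  dt <- 0.2; Dt <- 1.09e-13
  z <- draw_noise(dt, Dt, n = 1e5)
  expect_equal(stats::var(z[, 1]), 2 * Dt * dt, tolerance = 0.03)
  expect_equal(stats::var(z[, 2]), 2 * Dt * dt, tolerance = 0.03)
  expect_lt(abs(stats::cor(z[, 1], z[, 2])), 0.02)
  expect_lt(abs(mean(z)), 3 * sqrt(2 * Dt * dt / 2e5))
  expect_error(draw_noise(0, Dt), "positive")
})

test_that("a lone tracer sediments at V and hovers where mu F = V", {
  dom <- small_domain()
  tra <- tracer_model(consts = cc_consts)
  flow <- quiet_flow(dom)
  ens <- place_tracers(dom$L / 2, dom$H / 2)
  n <- 40L; dt <- 5
  for (k in seq_len(n)) ens <- step_tracers(ens, flow, dt, tra, noise = FALSE)
  expect_equal(ens$y, dom$H / 2 - tra$V_sed * n * dt, tolerance = 1e-9)
  expect_equal(ens$x, dom$L / 2)  # no horizontal drift
  # independent oracle: root of mu*F(d) - V on the force law
  hover <- uniroot(function(d)
    tra$mu * chemoconvect:::morse_wall_force(d, tra$eps, tra$omega, tra$R) - tra$V_sed,
    c(1e-9, tra$R), tol = 1e-15)$root
  ens2 <- place_tracers(dom$L / 2, 3e-6)
  for (k in 1:300) ens2 <- step_tracers(ens2, flow, 0.05, tra, noise = FALSE)
  expect_lt(abs(ens2$y - hover), 1e-9)
  expect_true(ens2$settled)
})

test_that("free Brownian motion reproduces the 2-D diffusion law", {
  dom <- domain(L = 1, H = 1, Ny = 8, catalytic_interval = c(0, 1))
  tra <- tracer_model(rho_t = cc_consts$rho0, consts = cc_consts)  # V = 0
  flow <- quiet_flow(dom)
  N <- 10000L
  set.seed(99)
  ens <- place_tracers(rep(0.5, N), rep(0.5, N))
  nstep <- 50L; dt <- 1
  for (k in seq_len(nstep)) ens <- step_tracers(ens, flow, dt, tra)
  msd <- mean((ens$x - 0.5)^2 + (ens$y - 0.5)^2)
  expect_equal(msd, 4 * tra$D_t * nstep * dt, tolerance = 0.05)
  # increments stay Gaussian: squared displacements are exponential-like
  expect_equal(stats::var((ens$x - 0.5)), 2 * tra$D_t * nstep * dt,
               tolerance = 0.05)
  expect_identical(ens$N, N)
})

test_that("advection follows streamlines exactly in a linear shear", {
  dom <- small_domain(Ny = 10)
  tra <- tracer_model(rho_t = cc_consts$rho0, consts = cc_consts)  # V = 0
  flow <- quiet_flow(dom)
  gam <- 0.02
  ys <- (seq_len(dom$Ny) - 0.5) * dom$dx
  flow$ux <- matrix(rep(gam * ys, each = dom$Nx), dom$Nx, dom$Ny)
  y0 <- dom$H / 2
  ens <- place_tracers(1e-4, y0)
  n <- 20L; dt <- 0.005
  for (k in seq_len(n)) ens <- step_tracers(ens, flow, dt, tra, noise = FALSE)
  expect_equal(ens$x, 1e-4 + gam * y0 * n * dt, tolerance = 1e-12)
  expect_equal(ens$y, y0)
  # one-way coupling: the fluid state is untouched by tracer stepping
  expect_identical(flow$ux[3, 3], gam * ys[3])
})

test_that("settling of a uniform ensemble is linear in time and completes", {
  dom <- domain(L = 1.3e-3, H = 1.3e-3, Ny = 26,
                catalytic_interval = c(0, 1.3e-3))
  con20 <- physical_constants(g = 20 * 9.8)  # time-compressed settling
  tra <- tracer_model(consts = con20)
  flow <- fluid_field(dom, con20)
  N <- 2000L
  set.seed(4)
  ens <- place_tracers(runif(N, 0, dom$L), runif(N, 0, dom$H))
  dt <- 1
  tmax <- ceiling(dom$H / tra$V_sed)
  fr <- c()
  for (k in seq_len(tmax)) {
    ens <- step_tracers(ens, flow, dt, tra, noise = FALSE)
    fr <- c(fr, mean(ens$settled))
  }
  expect_equal(fr[length(fr)], 1)  # all settled within H/V
  ts <- seq_len(tmax) * dt
  pred <- pmin(1, (chemoconvect:::settle_height(tra) + tra$V_sed * ts) / dom$H)
  expect_lt(max(abs(fr - pred)), 0.05)
  # settled flags are sticky
  expect_true(all(settled_rule(ens, tra)$settled))
})
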