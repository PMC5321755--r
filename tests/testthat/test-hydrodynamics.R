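test_that("buoyancy force is vertical, proportional to C, zero without reagent", {
  dom <- small_domain()
  rea <- reagent_model()
  C <- concentration_field(dom)
  f0 <- make_buoyancy_force(C, cc_consts, rea)
  expect_true(all(f0$fx == 0) && all(f0$fy == 0))
  C$C[] <- 0.1
  f1 <- make_buoyancy_force(C, cc_consts, rea)
  # rho0 g beta_C C = 1000 * 9.8 * 1e-3 per unit volume, downward
  expect_equal(unique(as.numeric(f1$fy)), -9.8)
  expect_true(all(f1$fy <= 0))
  C$C[] <- 0.2
  f2 <- make_buoyancy_force(C, cc_consts, rea)
  expect_equal(f2$fy, 2 * f1$fy)
})

test_that("quiescent state is a fixed point and grid mismatch is rejected", {
  dom <- small_domain()
  flow <- quiet_flow(dom)
  zero <- make_buoyancy_force(concentration_field(dom), cc_consts,
                              reagent_model())
  flow <- step_fluid(flow, zero, 50 * flow$dt_lbm)
  expect_identical(max(abs(flow$ux)), 0)
  expect_identical(max(abs(flow$uy)), 0)
  bad <- make_buoyancy_force(matrix(0.1, 3, 3), cc_consts, reagent_model())
  expect_error(step_fluid(flow, bad, flow$dt_lbm), "grid")
  expect_error(step_fluid(flow, zero, 0.1 * flow$dt_lbm), "multiple")
})

test_that("forced channel flow converges to the Poiseuille parabola", {
  for (Ny in c(16, 32)) {
    dom <- domain(L = 1.3e-3 / Ny * 8, H = 1.3e-3, Ny = Ny,
                  catalytic_interval = c(0, 1e-4))
    flow <- fluid_field(dom, cc_consts, periodic_x = TRUE)
    f <- 4  # N m^-3, horizontal
    force <- structure(list(fx = matrix(f, dom$Nx, dom$Ny),
                            fy = matrix(0, dom$Nx, dom$Ny)),
                       class = "cc_force")
    flow <- step_fluid(flow, force, 8000 * flow$dt_lbm)
    y <- (seq_len(dom$Ny) - 0.5) * dom$dx
    ref <- poiseuille_oracle(f, cc_consts, dom$H, y)
    err <- max(abs(flow$ux[1, ] - ref)) / max(ref)
    expect_lt(err, 0.02)
    if (Ny == 16) err16 <- err else expect_lt(err, err16)  # grid convergence
    # profile is uniform along the channel
    expect_lt(max(abs(sweep(flow$ux, 2, flow$ux[1, ]))), 1e-12 * max(ref))
    # mid-channel maximum matches the closed form f H^2 / (8 rho0 nu)
    expect_equal(max(max_ux_profile(flow)), f * dom$H^2 / (8 * 1000 * 1e-6),
                 tolerance = 0.02)
  }
})

test_that("stable stratification stays hydrostatic and divergence is small", {
  dom <- small_domain(Ny = 16)
  rea <- reagent_model()
  C <- concentration_field(dom)
  # heavier fluid below: C decreasing with height, uniform in x
  C$C <- matrix(rep(seq(0.2, 0, length.out = dom$Ny), each = dom$Nx),
                dom$Nx, dom$Ny)
  flow <- quiet_flow(dom)
  force <- make_buoyancy_force(C, cc_consts, rea)
  flow <- step_fluid(flow, force, 4000 * flow$dt_lbm)
  # pressure absorbs the stratified weight; residual spurious currents sit
  # orders of magnitude below the buoyancy velocity scale g beta_C C H^2/nu
  u_scale <- cc_consts$g * rea$beta_C * max(C$C) * dom$H^2 / cc_consts$nu
  expect_lt(max(abs(flow$ux), abs(flow$uy)), 1e-4 * u_scale)
})

test_that("an active convective flow is discretely divergence-free", {
  r <- desk_run_short()
  flow <- structure(list(ux = r$fields$ux, uy = r$fields$uy,
                         dx = r$config$domain$dx,
                         Nx = r$config$domain$Nx, Ny = r$config$domain$Ny),
                    class = "cc_fluid")
  umax <- max(abs(flow$ux), abs(flow$uy))
  expect_gt(umax, 1e-5)  # the pump is running
  # central-difference divergence: zero up to the O(dx^2) operator mismatch
  expect_lt(max(abs(divergence(flow))) * flow$dx / umax, 0.05)
})

test_that("velocity interpolation is exact at nodes and on linear fields", {
  dom <- small_domain(Ny = 10)
  flow <- quiet_flow(dom)
  gam <- 2.5
  ys <- (seq_len(dom$Ny) - 0.5) * dom$dx
  flow$ux <- matrix(rep(gam * ys, each = dom$Nx), dom$Nx, dom$Ny)
  flow$uy <- flow$ux * 0.3
  # nodal exactness
  i <- 4; j <- 7
  pos <- c((i - 0.5) * dom$dx, (j - 0.5) * dom$dx)
  expect_equal(interpolate_velocity(flow, pos),
               c(flow$ux[i, j], flow$uy[i, j]), tolerance = 1e-12)
  # exact reproduction of a linear field anywhere between interior nodes
  set.seed(5)
  for (k in 1:25) {
    p <- c(runif(1, dom$dx, dom$L - dom$dx), runif(1, dom$dx, dom$H - dom$dx))
    v <- interpolate_velocity(flow, p)
    expect_equal(v[1], gam * p[2], tolerance = 1e-12)
    expect_equal(v[2], 0.3 * gam * p[2], tolerance = 1e-12)
  }
  expect_error(interpolate_velocity(flow, c(-1e-6, 1e-4)), "outside")
})
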