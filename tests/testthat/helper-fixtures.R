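# shared tiny fixtures; everything is built in code at test time

cc_consts <- physical_constants()

# a small square-cell box with the catalyst covering the whole floor
small_domain <- function(L = 5e-4, H = 5e-4, Ny = 10)
  domain(L = L, H = H, Ny = Ny, catalytic_interval = c(0, L))

# quiescent flow on a given domain
quiet_flow <- function(dom, consts = cc_consts) fluid_field(dom, consts)

# an ensemble at prescribed positions (bypasses the random initializer)
place_tracers <- function(x, y) {
  structure(list(x = x, y = y, settled = logical(length(x)),
                 N = length(x), seed = NA_integer_),
            class = "cc_tracers")
}

# a sealed inlet: family C with zero flux amplitude
sealed_inlet <- function() inlet_bc("C", C0 = 0, lam = 0, q0 = 0)

# short-horizon desk run shared by several cheap checks
desk_run_short <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_simulation(desk_config(rmax = 1.7e-4, C0 = 0.1, seed = 7,
                                           run = list(horizon = 60)))
    cache
  }
})
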