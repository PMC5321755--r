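Package: chemoconvect
Title: Chemoconvective Transport of Microparticle Cargo by Catalytic Micropumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional simulator of solutal chemoconvection in a closed
    microchamber: a reagent diffuses in from a gel reservoir at one wall,
    is decomposed by a Michaelis-Menten surface reaction on a catalytic
    region of the floor, and the resulting solutal density gradients drive
    a buoyant convective roll (Boussinesq approximation) that transports
    suspended micron-scale tracer particles. The incompressible flow is
    solved with a D2Q9 lattice Boltzmann scheme, reagent transport with a
    flux-limited finite-volume advection-diffusion scheme, and tracers with
    overdamped Langevin dynamics (advection, Stokes sedimentation, Brownian
    noise, repulsive Morse wall potentials). Includes observables for the
    settled-particle areal concentration n/n0, pile (peak) position and
    convective-vortex extent, closed-form validation oracles, a run driver
    with sweep utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
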