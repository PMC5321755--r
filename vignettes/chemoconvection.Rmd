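---
title: "Chemoconvective cargo transport: model, numerics and design choices"
author: "chemoconvect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemoconvective cargo transport: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

A closed rectangular microchamber $\{(x,y): 0 \le x \le L,\ 0 \le y \le H\}$
is filled with water (density $\rho_0 = 10^3\,$kg m$^{-3}$, kinematic
viscosity $\nu = 10^{-6}\,$m$^2$s$^{-1}$). A reagent — hydrogen peroxide in
the reference system — enters through the left wall from a depleting gel
reservoir and diffuses with $D = 10^{-9}\,$m$^2$s$^{-1}$. A catalyst-coated
region $A$ of the floor decomposes it at the Michaelis–Menten areal rate

$$ r(C) \;=\; r_{\max}\,\frac{C}{K_M + C}, \qquad
   r_{\max} = M\,k_{\mathrm{cat}}\,[E], $$

with $M = 4$ active sites per catalase molecule,
$k_{\mathrm{cat}} = 2.12\times10^{5}\,$s$^{-1}$,
$[E] = 2\times10^{-8}\,$mol m$^{-2}$ (so
$r_{\max} = 1.7\times10^{-2}$ mol m$^{-2}$s$^{-1}$) and $K_M = 0.093\,$M,
the concentration at half-maximal rate.

The dissolved reagent makes the solution heavier. Because the products
(oxygen, water) and the reaction heat contribute an order of magnitude less,
the density law keeps exactly one solute,

$$ \rho = \rho_0\,(1 + \beta_C\,C), $$

and buoyancy enters the incompressible Navier–Stokes equations only through
the Boussinesq body force $-\rho_0\,g\,\beta_C\,C\,\hat e_y$. The lateral
concentration gradient — fresh reagent at the inlet, consumed reagent
downstream — drives a single convective roll: dense fluid sinks at the
inlet, flows along the floor toward the far wall, and returns along the
ceiling.

Suspended cargo is modelled as $N$ passive spherical polystyrene tracers
(radius $R = 2\,\mu$m, density $\rho_t = 1.05\,$g cm$^{-3}$) obeying an
overdamped Langevin equation: advection with the local flow $\mathbf u$,
Stokes sedimentation at

$$ V \;=\; \frac{2(\rho_t-\rho_0)\,g\,R^2}{9\eta} \;\approx\; 0.44\ \mu\mathrm{m\,s^{-1}}, $$

Brownian noise with diffusivity $D_t = k_BT/(6\pi\eta R)$, and repulsive
wall forces. Tracers do not act back on the fluid and do not interact with
each other; friction with the walls is neglected, so settled tracers keep
drifting with the local near-floor flow. Sedimentation is the key asymmetry:
the forward (lower) branch of the roll carries more tracers than the return
(upper) branch, so cargo drifts away from the inlet and piles up where the
forward flow dies — the edge of the convective vortex. The pile position is
controlled by the reaction rate ($r_{\max}$, via how fast the fuel is
consumed) and by the amount of fuel supplied ($C_0$).

### Inlet families

The gel reservoir is represented by a boundary condition on the left wall;
all three families decay with time and model fuel depletion:

* **A** (default): wall concentration $C(0,y,t) = C_0 e^{-\lambda t}$, with
  $C_0 = 0.1\,$M and depletion time $\lambda^{-1} = 70\,$min;
* **B**: linearly decreasing wall concentration $C_0\max(0, 1-\lambda t)$;
* **C**: prescribed influx $q_0 e^{-\lambda t}$.

The amplitude $q_0$ of family C is a free convention because the injection
realized by families A/B is emergent (diffusion- and convection-limited).
The default is the quasi-steady diffusive flux scale
$q_0 = 10^3 C_0\sqrt{D\lambda}$ mol m$^{-2}$s$^{-1}$;
`match_injection()` rescales it to the realized total injection of a
family-A run when a matched comparison is wanted. The three families give
the same qualitative outcome (an interior pile at nearby positions), which
is why the package defaults to the simplest one.

### Wall potential

Tracers are kept inside the chamber by the repulsive branch of a Morse
potential, $U(d) = \varepsilon\,(1 - e^{-\omega (d - d_0)})^2$ for wall
distance $d < d_0$ and zero beyond, with $\varepsilon = 1.2\times10^{-14}\,$J
and $\omega = 6\times10^{4}\,$m$^{-1}$. The minimum distance is set to the
tracer radius, $d_0 = R$: contact at one particle radius, force range
$\sim\omega^{-1} \approx 17\,\mu$m. A sedimenting tracer comes to rest at
the hover height where $\mu F(d^*) = V$; with the default parameters $d^*$
sits a few nanometres below $d_0$. A tracer is *counted* as settled once
$y < R + 3/\omega$ (the floor band: hover height plus three force e-folding
lengths); the flag is sticky, matching the convention that settled cargo is
never un-counted even though it still slides horizontally.

## Numerics

**Flow.** D2Q9 BGK lattice Boltzmann with Guo forcing and half-way
bounce-back walls (periodic in $x$ for the plane-channel benchmark). The
physical-to-lattice mapping fixes the time step from the relaxation time
$\tau$: $\Delta t = \tfrac{\tau - 1/2}{3}\,\Delta x^2/\nu$, so lattice and
physical viscosities agree. $\tau = 1.35$ by default, and configurations are
validated to keep $\tau \in (0.55, 1.5)$ and the lattice velocity below
$0.3$ (runs abort on violation; typical runs sit near $10^{-3}$). Pressure
is reported gauge-fixed to zero mean.

**Reagent.** Finite-volume flux-form advection (second-order with minmod
limiting) plus central diffusion, stepped explicitly with automatic
substepping to honour the advective (CFL $\le 0.4$) and diffusive
($D\Delta t/\Delta x^2 \le 0.2$) bounds. The Michaelis–Menten sink is a
flux condition on the floor cells of region $A$, linearized implicitly
within each substep — unconditionally stable even at the highest
$r_{\max}$, where the floor cell is depleted in milliseconds. Inlet and
sink fluxes are bookkept exactly as applied, so the global balance
*inventory = injected − consumed* holds to round-off; runs report the
residual. Negative excursions from advection are clipped and logged; a
clipped mass above $10^{-6}$ of the inventory aborts the step.

**Tracers.** First-order (Euler–Maruyama) integration of the overdamped
Langevin equation at the coupling step, with one refinement: the
wall-normal Morse force is stiff ($\mu\,\partial F/\partial d\,\Delta t \gg 1$
near contact), so that term is treated implicitly per axis (a few
safeguarded Newton iterations on a monotone scalar equation). Implicit
Euler here is still first-order, is unconditionally stable, and its fixed
point is the *exact* hover height $\mu F(d^*) = V$ — which the test suite
verifies against an independent root-find on the force law. Positions are
clamped to the domain only as a last-resort safeguard; clamp events are
counted and a rate above 0.1% aborts the run as a misconfiguration.

**Coupling.** Per coupling step (default 100 lattice steps): (1) the fluid
advances under the buoyancy force of the current concentration field;
(2) the concentration advances with the updated flow; (3) the tracers
advance with the updated flow. The buoyancy force is frozen within a
coupling step; the fluid's viscous relaxation time ($H^2/\nu \approx 1.7$ s)
is far shorter than the time scale on which the concentration field evolves,
so the flow tracks the forcing adiabatically.

## The desk preset: an exact time compression

The reference chamber evolves over hours ($\lambda^{-1} = 70$ min, full
settling within 50 min), while the lattice step is sub-millisecond. The
desk preset makes the study tractable by applying a uniform time
compression $s$ (default 20) to *every rate process*: $g$, $D$, $\lambda$,
$r_{\max}$, the family-C influx and the tracer diffusivity are all
multiplied by $s$. Because each term of the governing equations is a rate,
this reproduces the $s{=}1$ dynamics exactly with $t \to t/s$: every
dimensionless group (solutal Rayleigh number, Damköhler number, Péclet
numbers, the sedimentation-to-convection balance) is preserved. The one
exception is the Reynolds number, which grows by $s$ but stays well below
one (order 0.3 at $s = 20$), so the flow remains in the quasi-steady
viscous regime the model assumes. Pile positions, concentrations and
$n/n_0$ are unaffected; only reported times are in compressed seconds.

The desk chamber is $13\,\mathrm{mm} \times 1.3\,\mathrm{mm}$ on a
$200\times20$ grid of square cells ($\Delta x = 65\,\mu$m). The length
matters: the high-rate convective roll spans several millimetres
(experimentally, flow dies off 4–10 mm from the gel), so a chamber much
shorter than that cannot contain the vortex and every condition would pile
cargo at the far wall. The catalytic region starts at $0.05\,L$
(0.65 mm), mirroring the gap between gel and catalyst pattern in the
reference set-up, and extends to the far wall. The full-geometry preset
(`full_config()`) is the unscaled $20\,\mathrm{mm}$ chamber at
$\lambda^{-1} = 70$ min on a $400\times26$ grid; it integrates roughly
$400\times$ more lattice work than a desk run and is provided for
completeness rather than routine use.

## What a desk run emulates — and what it does not

The simulated study reproduces the reference *in silico* experiment: $N =
500$ tracers scattered uniformly in a reagent-free chamber, fuel arriving
through the left wall with a decaying amplitude, a single catalytic floor
region, and the settled-cargo histogram $n/n_0$ in bins of
$\Delta x = 2.5\times10^{-4}\,$m (a coarser 500 µm display binning is also
available via the `dx` argument). It does **not** model: oxygen bubbles or
the oxygen/thermal contributions to buoyancy (dropped from the density law
by construction), the gel's internal porosity (the inlet condition *is* the
gel model), tracer–tracer and tracer–wall friction, 3-D effects (the
reference system is uniform in the third dimension; discrete catalyst
stripes behave like uniform coverage), or image-analysis observables used
for the laboratory density measurements — the settled-count histogram is
the model-side equivalent. Passing tests therefore validate the transport
mechanism and its control laws, not those excluded effects.

## Numerical and design choices, in brief

* $\beta_C = 10^{-2}\,$M$^{-1}$: chosen to reproduce the stated order of
  the peroxide density excess, $\beta_C C \sim 10^{-3}$ at $C \sim 0.1$ M.
  Exposed in the configuration.
* Ambient temperature 298 K for the Brownian noise.
* Morse form and cutoff as above ($d_0 = R$, repulsive branch only).
* Settled band $y < R + 3/\omega$.
* Vortex edge: smallest $x$ beyond which the per-column maximum of $u_x$
  stays below 5% of its global maximum — the profile decays smoothly, so a
  small threshold marks where forward transport effectively stops; the
  choice is validated by the peak–vortex co-location property rather than
  by any external number. The profile is evaluated at the
  median-deposition time (the first output with half the tracers settled):
  the roll is strongest during the brief start-up transient and contracts
  as the fuel depletes, and the mid-deposition snapshot is the flow state
  representative of the transport that builds the pile.
* Ties in the histogram peak break toward the inlet (leftmost bin).
* Stopping rule: a run ends when the reagent inventory falls below 0.1% of
  the total injected *and* all tracers have settled, or at the horizon
  $4/\lambda$.
* Oracle tolerances: 1% for analytic arithmetic and the diffusion
  benchmark, 2% for the channel-flow benchmark at the default grid, 5% for
  the stochastic MSD benchmark at $10^4$ tracers.

## Reproducibility

A configuration plus a seed determines a run bit-for-bit: the seed fixes
the initial tracer positions and the Brownian stream, and all solvers are
deterministic. Run-level reproducibility is promised; per-tracer streams
are not independent of $N$.

```{r example}
library(chemoconvect)
cfg <- desk_config(rmax = 1.7e-2, C0 = 0.1, seed = 1)
r <- run_simulation(cfg, verbose = TRUE)
r$summary$peak_position   # pile position (m)
r$summary$vortex_edge     # where the forward flow dies (m)
plot(r$histogram$centers * 1e3, r$histogram$n_over_n0, type = "h",
     xlab = "x (mm)", ylab = "n / n0")
```

## Known limitations

The concentration boundary layer above the catalytic floor is thinner than
a grid cell at the highest reaction rates; the sink then acts on the
floor-cell average, which preserves the saturated-consumption physics but
not the layer's internal profile. The desk grid ($16$ cells across the
height) resolves the single-roll structure, not fine secondary vortices.
The histogram peak is reported at bin-centre resolution
($\pm\,\Delta x/2 = 125\,\mu$m), and its position jitters by about one bin
between seeds at $N = 500$; at the highest reaction rates the final pile is
broad (the roll's deposition footprint spans a couple of millimetres), so
the arg-max bin can wander by a further bin or two there. Buoyant
(lighter-than-water) tracers are rejected by validation rather than
supported.
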