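---
title: "Modelling transverse acoustophoretic focusing in a BAW resonator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transverse acoustophoretic focusing in a BAW resonator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acoustofocus)
```

## The physical model

A bulk acoustic wave (BAW) transversal resonator drives an ultrasonic
standing wave across the width $w_{ch}$ of a rectangular microchannel. At
the half-wave resonance the side walls are pressure anti-nodes and a single
pressure node runs along the channel centre; suspended particles with a
positive acoustic contrast factor collect there. `acoustofocus` models the
transverse transport of such particles, the estimation of the acoustic
energy density from tracked trajectories, and the boundary-driven acoustic
streaming that sets the lower size limit of the method.

Throughout, the transverse coordinate $y \in [0, w_{ch}]$ is measured from
the left wall; the node sits at $w_{ch}/2$ and the half-wave mode has
wavenumber $k = \pi/w_{ch}$.

**Radiation force.** The primary radiation force on a small compressible
sphere of volume $V_p$ in the standing field of energy density $E_{ac}$ is

$$F_R(y) = V_p\,k\,E_{ac}\,\phi\,\sin(2ky), \qquad
\phi = \frac{5\rho_p - 2\rho_m}{2\rho_p + \rho_m} -
\frac{\beta_p}{\beta_m},$$

where $\rho$, $\beta$ are densities and compressibilities of particle and
medium. The prefactor is written with the *medium* compressibility
$\beta_m$ (through $E_{ac} = p_0^2\beta_m/4$); versions of this formula
that carry $\beta_p$ in the prefactor are dimensionally identical but are
not consistent with the closed-form path below, so the package uses
$\beta_m$ everywhere.

**Transverse path.** Balancing $F_R$ against Stokes drag
$F_D = -6\pi\eta_m a_0 v$ gives an overdamped drift whose closed form is

$$y(t) = \frac{1}{k}\arctan\!\Big\{\tan\big(k y_0\big)\,
e^{A t}\Big\},\qquad
A = \frac{4\phi}{9\eta_m}\,(k a_0)^2\,E_{ac},$$

valid on the lower half channel and extended to the upper half by
reflection about the node. $A$ is the focusing rate (1/s): $\ln\tan(ky)$
grows linearly in time with slope $A$. Inverting for $E_{ac}$ given two
positions and the elapsed time is the energy-density measurement principle:

$$E_{ac} = \frac{9\eta_m}{4\phi (k a_0)^2 t}
\ln\frac{\tan(k y_t)}{\tan(k y_0)}.$$

The pressure amplitude follows from
$p_a = 2 c_m \sqrt{E_{ac}\rho_m}$, and the design rule for the channel
width is $w_{ch} = c_m/(2f)$.

```{r}
medium <- water_medium()
geometry <- device_geometry()
bead <- polystyrene_species(4e-6)
contrast_factor(bead, medium)
pressure_amplitude(7.25, medium) / 1e6   # MPa
```

## Coordinate and mode conventions

The fabricated reference channel is 190 µm wide but the measured drive
resonance (4.623 MHz) does not coincide with the ideal half-wave frequency
of that width in water (3.897 MHz) — real devices resonate where the full
coupled structure resonates, not where the idealised fluid column does. The
package therefore separates two notions:

* `drive_field(frequency, medium)` carries the medium wavelength
  $\lambda = c_m/f$ and is what the design calculators use;
* `resonant_drive(geometry, medium)` builds the *mode-consistent* field
  with $\lambda = 2 w_{ch}$, $k = \pi/w_{ch}$, which every path, force and
  simulation routine requires (they check it).

The trajectory estimator likewise derives $k = \pi/w_{ch}$ from the
geometry: it is the only reading under which $\tan(k y)$ is single-branch
across a half channel, which the closed-form inversion needs.

## Energy-density estimation from tracks

The input is the $(t, y)$ track of each particle, as exported by video
tracking at a known pixel size. Three estimators are provided:

* **`path_fit` (default)** — nonlinear least squares of the closed-form
  path on the raw track. Localization noise is additive on the fitted
  coordinate, so the fit is essentially unbiased even when the transient
  spans only a few frames.
* **`regression`** — the least-squares slope of $\ln|\tan(k y)|$ versus
  $t$ over the pre-arrival window, excluding samples within 2 pixels of
  the node or a wall (where the tangent degenerates and noise is
  amplified).
* **`endpoints`** — the literal two-point inversion.

The default deserves a note. At the reference operating point
($E_{ac} \approx 7$ J/m³, 4 µm beads) the focusing e-fold time is about
0.5 s while frames arrive every 0.5 s, so a track contributes only ~4–7
usable pre-arrival samples. The `regression` window necessarily ends with
a sample *conditioned on still being outside the node band*, which drags
the fitted slope down by several percent; in synthetic recovery
experiments (3000 paths at the acquisition defaults) the log-tangent
regression showed a mean bias near −7 %, while the direct path fit stayed
within −1 %. Per-particle estimates are averaged across particles and
reported as mean ± sample standard deviation, with the derived pressure
amplitude attached; averaging the raw coordinates across particles
instead would discard the per-particle spread that the ± figure reports.

```{r}
acq <- acquisition_spec()        # 500 ms frames, 120 s, 1.63 um/px, 1 px noise
df <- generate_trajectories(7.25, bead, medium, geometry, acq, seed = 1)
trajs <- lapply(split(df, df$particle_id),
                function(d) list(id = d$particle_id[1], t = d$t, y = d$y))
estimate_energy_density(trajs, bead, medium, geometry)
```

## The synthetic-data generator

`generate_trajectories()` emulates the time-lapse experiment: 20 particles
tracked for 2 minutes at 500 ms frame interval through a 4× objective
(1.63 µm/pixel), with initial positions drawn uniformly outside the
extreme 5 % near the walls and outside the node band (tracked beads start
near the walls and move inward), positions following the closed-form path,
Gaussian localization noise of 1 pixel, and quantization to the pixel
grid. The noise default is a choice — tracking software reports positions
to the pixel scale but not its error — and is exposed in
`acquisition_spec()`. Quantization can be disabled; exact (1e-9) recovery
round trips are only meaningful without it.

What the generator does *not* emulate: particle detection/linking errors,
out-of-focus loss, particle–particle interactions, axial drift through
the field of view, and non-Gaussian localization tails. Passing recovery
tests therefore validate the estimator against its own forward model, not
against raw video.

## Acoustic streaming

Boundary layers on the channel walls rectify the first-order field into a
steady (Rayleigh) streaming flow, computed here by the limiting-velocity
method: the analytic half-wave mode
($p_1 = p_a\cos ky$, $v_1 = i (p_a/\rho_m c_m)\sin ky$) yields a
tangential slip velocity on the horizontal walls,

$$v_L(y) = -\tfrac{3}{8}\,\frac{U^2}{c_m}\,\sin(2ky), \qquad
U = \frac{p_a}{\rho_m c_m},$$

directed from the node toward the anti-nodes, with vanishing slip on the
side walls. The printed component formulas of the limiting-velocity method
pair each velocity component with the *other* component's conjugate in
some transcriptions; the package pairs each component with its own
conjugate, which is the combination that reproduces the classical Rayleigh
slip above (verified to 1 % in the tests).

The bulk flow is then a Stokes problem on the cross-section with that slip
as the tangential wall condition. It is solved in
streamfunction–vorticity form as a single sparse linear system
(interior: $\nabla^2\psi + \omega = 0$, $\nabla^2\omega = 0$; walls:
$\psi = 0$ plus a Thom-type vorticity closure carrying the slip), after
nondimensionalising lengths by the width and velocities by the peak slip
so both unknown fields are O(1). The velocity derived from $\psi$ is
discretely divergence-free by construction; the solution shows the
classical four counter-rotating rolls per half wavelength. A direct solve
was preferred over SOR iteration because the problem is linear and small
(the default 128×64 grid solves in well under a second). The second-order
pressure is reconstructed by line integration of $\mu\nabla^2 v_2$ and is
diagnostic only.

## Trajectory simulation and focusing metrics

`simulate_population()` advances non-interacting particles through the
channel with a vectorised RK4 integrator: transverse acoustophoretic
drift, optional streaming advection (bilinear interpolation of the solved
cross-section flow), and axial advection by the rectangular-duct
Poiseuille profile (Fourier series, 11 odd terms, scaled to the
volumetric flow rate). The default step satisfies a transverse
displacement bound of $w_{ch}/100$ per step, with automatic halving on
overshoot. Particle centres are kept one radius off the walls: a point
particle advected onto the no-slip plane by streaming would acquire
exactly zero axial velocity and never leave the channel, which is an
artifact of the point approximation, not physics.

Two focusing metrics mirror the two experimental readouts: the fraction
of particles inside the central band of width $w_{ch}/3$ (image-analysis
style) and the fraction exiting through the central outlet (collection
style, with `generate_outlet_readout()` adding a UV-Vis-like noisy signal
proxy). Entry positions are uniform over the inlet cross-section — the
device runs with a single inlet and no sheath flow — and injection rates
derive from concentration × flow rate with a ceiling
(5.68×10⁵ /mL at 3 µL/min → 28.4 → 29 /s).

Study sizes in the shipped tests are 200 particles per condition with
fixed seeds; this keeps each scenario's binomial standard error near 3 %
while the qualitative contrasts under test (trends with flow rate, drive
voltage and particle size) are an order of magnitude larger.

## Critical particle diameter

Below a critical size, streaming drag outweighs the radiation force.
Equating the maximum acoustophoretic velocity $(2\phi/9\eta_m) k a^2
E_{ac}$ with the maximum Rayleigh slip $(3/2)E_{ac}/(\rho_m c_m)$ — the
energy density cancels — gives

$$2a_c = \sqrt{\frac{27\,\eta_m}{2\pi\,\phi\,\rho_m\,f}}
\approx 1.3\ \mu m$$

for polystyrene in water at 4.623 MHz. Published closed forms for this
quantity vary in their O(1) constant depending on which streaming velocity
scale is balanced; the package's reading is verified internally against a
numerical balance on its own slip field rather than against any single
printed constant, and the device-scale conclusion (a cutoff between 0.5
and 2 µm, so 1 µm particles and 500 nm nanoparticles do not focus)
is robust to that choice.

```{r}
fld <- drive_field(4.623e6, medium, Eac = 7.25)
critical_diameter(contrast_factor(bead, medium), medium, fld) * 1e6  # um
```

## Known limitations

* Single-particle physics only: no secondary (particle–particle)
  radiation forces, no aggregation. The experimentally observed decline
  of focusing at high concentration is *not* reproduced by this model;
  the simulator's per-second injection rates affect ensemble size, not
  per-particle dynamics.
* With streaming enabled, sub-critical particles are advected by the roll
  return flow, which feeds the channel centre at mid-height; combined
  with exit sampling that favours fast (mid-height) particles, the
  simulated central-outlet fraction of 0.5 µm particles can sit
  noticeably *above* the uniform 1/3 baseline at low flow rates, much as
  the experimental nanoparticle readouts do (≈ 50 %).
* The first-order field is the ideal analytic mode; wall actuation,
  acoustic losses and the resonance shift of the real device are not
  modelled. The voltage-to-energy-density map is a quadratic calibration
  anchored at one measured point (52.92 V ↦ 7.25 J/m³), not a transducer
  model.
* The streaming solve is 2D (cross-section); axial streaming and
  boundary-layer-resolving corrections are out of scope.
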