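---
title: "Modelling dipolar chain formation and hyperthermia heating of magnetite nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dipolar chain formation and hyperthermia heating of magnetite nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainheat)
```

## The problem

Magnetic particle hyperthermia (MPH) heats tissue-embedded magnetite
nanoparticles (MNPs) with an AC magnetic field in the 100–1000 kHz range;
the figure of merit is the specific loss power (SLP), the dissipated power
per gram of magnetic material. When MNPs are immobilised in a gel after
alignment in a static field, they assemble into linear chains whose shape
anisotropy changes the hysteresis loop and hence the heating efficiency.
`chainheat` models this pipeline end to end:

1. **chain formation** — an on-the-fly coarse-grained Brownian dynamics
   simulator of field-driven dipolar chaining;
2. **hysteresis losses** — a finite-temperature Stoner–Wohlfarth loss model
   for random versus aligned configurations;
3. **heat transfer** — lumped and 1D radial conduction models producing
   heating/cooling temperature traces;
4. **calorimetry** — initial-slope SLP extraction from those traces.

A synthetic-data module generates every input the pipeline needs, so all
stages are testable without laboratory data.

## Dipolar energetics and the coupling parameter

Each particle of diameter $d_0$, mass density $\rho_p$ and mass
magnetization $M_s$ carries a saturation moment
$\mu_s = M_s \rho_p \frac{\pi}{6} d_0^3$. Two co-axial moments in contact
have interaction energy $-\mu_0\mu_s^2 / (2\pi d_0^3)$, and we define the
dimensionless coupling parameter as this contact energy over the thermal
energy:

$$\Gamma = \frac{\mu_0 \mu_s^2}{2\pi d_0^3 k_B T}.$$

With the default 40 nm magnetite parameters
($\rho_p = 5180$ kg/m³, $M_s = 92$ A·m²/kg, water at 300 K)
$\Gamma \approx 192$: dipolar attraction overwhelms thermal motion and
chains form. The 10 nm preset ($M_s = 30$ A·m²/kg, an assumed value — no
measured moment is available for the small population) gives
$\Gamma \approx 0.32$: thermal energy dominates and the simulator treats
the system as non-aggregating. $\Gamma^{1/3} d_0$ is also the exact
attraction radius of a single particle (below), which ties the energy and
geometry conventions together.

A chain of $s$ co-aligned dipoles attracts a test particle on its axis at
distance $r$ beyond the tip with energy
$E(s, r) = -\frac{\mu_0\mu_s^2}{2\pi}\sum_{j=0}^{s-1}(r + j d_0)^{-3}$.
The **attraction radius** $r_a(s)$ solves $E(s, r_a) = -k_B T$; it is found
by bracketed root-finding (tolerance $10^{-12} d_0$), grows with $s$ and
saturates for long chains (from $5.8\,d_0$ at $s = 1$ to about $10\,d_0$
at $s = 30$ for the 40 nm preset).

## The chain-formation simulator

Simulation objects are single particles or rigid chains pinned to the
field ($z$) axis; a chain of $s$ beads spans $s\,d_0$ physically. Chains do
not rotate — the applied field saturates and aligns the moments, and the
model inherits that assumption. Per step of length $\Delta t$ each object
receives independent Gaussian displacements with per-axis variance
$2 D \Delta t$, with the Stokes–Einstein coefficient
$D = k_B T / (3\pi\eta d_0)$ for singletons and end-corrected slender-body
rod coefficients for chains:

$$D_\parallel = \frac{k_B T (\ln s - 0.207)}{2\pi\eta\, s d_0}, \qquad
  D_\perp = \frac{k_B T (\ln s + 0.839)}{4\pi\eta\, s d_0}.$$

The axial/lateral ratio approaches the slender-body limit of 2 for long
chains. The end corrections are asymptotic: for $s \in \{2, 3\}$ they place
$D_\parallel$ slightly below $D_\perp$ and below the $s = 3$ value — a
known small-aspect-ratio artifact of these canonical constants that we
keep rather than patch, since no displayed alternative is available and the
affected chains exist only transiently.

**Merging.** After every displacement step, any pair whose tip-to-tip
distance falls below $r_a$ of the longer partner aggregates instantly: the
two objects are replaced by one of length $s_1 + s_2$ at their
length-weighted centre of mass. Qualifying pairs are processed
closest-first, re-scanning after every merge, until none qualify. Merging
is irreversible (no fragmentation), so the mean chain length is
nondecreasing and the object count shrinks — the "on-the-fly"
coarse-graining that lets the simulation accelerate as it proceeds. With
the field off, or when $\Gamma \le 1$, no merging ever occurs.

**Numerical choices.**

* The time step is auto-clamped so the RMS singleton step
  $\sqrt{2 D_1 \Delta t}$ is at most $0.1\,d_0$ ($\Delta t \approx 0.73$ µs
  for 40 nm in water), so an object cannot tunnel through an attraction
  zone ($r_a \ge d_0$) in one move.
* Boundaries are periodic (minimum-image distances) by default; reflecting
  walls are available. Periodic boundaries avoid wall artifacts in the
  spacing statistics.
* Volume exclusion: a move that would push two objects into overlap
  (segment distance below $d_0$ and shrinking) without satisfying the
  attraction-zone test is rejected for both partners that step. Allowing
  separation-increasing moves from an overlapped configuration lets the
  rare post-merge overlap relax instead of deadlocking.
* Determinism: one seeded generator; Gaussian draws are consumed in stable
  object-id order, so a (configuration, seed) pair reproduces a trajectory
  bit-identically.
* Initial configurations place $N$ singletons uniformly with minimum
  pairwise distance $d_0$ by rejection sampling; packing fractions above
  0.3 are refused.

**Statistics.** Per snapshot the package reports the mean chain length
$\langle s\rangle(t)$, object count, bond-alignment order parameter
$\langle\cos^2\theta\rangle$ (identically 1 whenever chains exist, because
bonds lie on the field axis by construction) and the mean lateral
(x–y, minimum-image) nearest-neighbour spacing between chains with
$s \ge 2$.

## What the simulator reproduces — and one thing it does not

The presets carry the published geometry verbatim: a cubic box of side
$80\,d_0$ with $N = 380/760/1520$ particles for 1/2/4 mg/mL, a 40 mT
alignment field, and the two particle sizes. (Converting concentration to
count from bulk magnetite density gives $N \approx 189$ per mg/mL — about
half the published counts; `concentration_to_count()` documents the
discrepancy and an override reproduces the published numbers, which the
presets use.) Tests and the acceptance script run scaled versions
(box $40\,d_0$, $N$ scaled to the same concentrations, a few thousand
steps, i.e. a few milliseconds of physical time) to stay desk-sized;
durations were fixed by the growth-plateau criterion — increments below 5%
of $\langle s\rangle$ over the final 10% of the run.

At $\Gamma \approx 192$ the attraction radius ($5.8\,d_0$) is comparable
to the mean inter-particle spacing at 4 mg/mL ($\approx 7\,d_0$), so the
initial configuration is super-critical: much of the chaining happens in a
rapid early cascade. Two expected orderings follow robustly: the 40 nm
system chains while the 10 nm system never does, and the stabilized mean
chain length increases with concentration. A third does **not**: the mean
lateral spacing between stabilized chains *increases* with concentration
in this model, because denser systems cascade into fewer, longer,
laterally depleted chains (each chain has consumed its laterally-near
neighbours, a Matérn-like thinning). The decrease of chain spacing with
concentration seen in gel micrographs holds here only during the brief
early transient. This is an honest limitation of the tip-zone merge rule
at full saturation moment: lateral bundling and chain-width growth, which
real gels show, are out of scope.

## Hysteresis losses and predicted SLP

Single-domain particles with anisotropy constant $K$ have anisotropy field
$H_K = 2K/(\mu_0 M_{s,v})$. The finite-temperature, finite-frequency
coercivity is modelled by the standard sweep-rate law

$$H_c(T, f) = \kappa H_K\left[1 -
  \left(\frac{k_B T \ln(f_0/f)}{K V}\right)^{3/4}\right]_+,$$

with attempt frequency $f_0 = 10^{10}$ Hz (configurable),
$\kappa = 0.48$ for randomly oriented easy axes and $1.0$ for aligned
ones. The bracket clips to zero in the superparamagnetic regime — the
10 nm particles at either operating frequency. The exponent, $\kappa$
values and $f_0$ are interpretable defaults of the classical
thermal-activation treatment; they are assumptions, not fitted values.

The loop area per cycle is the squareness-corrected rectangular estimate
$A_v = 4\alpha\,\mu_0 H_c M_{s,v}$ (J/m³), with $\alpha = 0.5$ for random
and $0.75$ for aligned configurations, evaluated with the 30 mT minor-loop
magnetizations (18 A·m²/kg chain, 8 A·m²/kg random) rather than the
intrinsic $M_s$, because 30 mT is the operating amplitude. A minor-loop
rule sets $A_v = 0$ when the drive amplitude $H_\text{max}$ does not
exceed $H_c$ — no switching, no loss. Volumetric heating is
$Q = A_v f \omega$ with volume fraction $\omega = c/\rho_p$, and the
predicted SLP is $A_m f$ (mass-normalized area times frequency, reported
in W/g).

**Which $H_c$ enters the chain/random comparison?** No coercivity values
are printed for the two textures, and with the magnetite defaults the
aligned $\kappa = 1$ value ($\mu_0 H_c \approx 37$ mT) would exceed the
30 mT drive and zero the aligned loop under the minor-loop rule.
`compare_configurations()` therefore defaults to a *shared* coercive field
(the random-orientation value, $\mu_0 H_c \approx 18$ mT at 300 K and
765 kHz) for both rows, isolating the texture effect carried by $\alpha$
and the minor-loop magnetization:

```{r}
rep <- compare_configurations(particle_spec(40e-9, 5180, 92, 1.1e4),
                              environment_spec(), field_spec())
rep
attr(rep, "slp_ratio")
```

The ratio $(0.75 \times 18)/(0.5 \times 8) = 3.375$ is scale-free in
$H_c$ and $f$; per-orientation coercivities remain available via
`hc_mode = "per_orientation"` for sensitivity work. The dipolar
shape-anisotropy field of a chain (`chain_anisotropy_field()`, a
point-dipole lattice sum saturating at the $\zeta(3)$ infinite-chain
limit) is provided for such studies but never feeds the coercivity law
unless wired in explicitly.

## Heat transfer

The published validation used a 3D finite-element model of the vial; we
replace it with two analytically checkable reductions:

* **Lumped energy balance**
  $\dot T = Q V_s/(m_f c) - \lambda (T - T_\text{amb})/(m_f c)$, solved
  with an adaptive-step integrator at relative tolerance $10^{-8}$ and
  checked in tests against the exponential closed form to below
  $10^{-6}$ K. The loss coefficient $\lambda$ (W/K) is either user-set or
  fitted from a cooling phase by a log-linear fit.
* **1D spherical conduction**
  $\rho C_p \partial_t T = k r^{-2}\partial_r(r^2\partial_r T) + Q$ on a
  uniform radial grid (default 50 intervals), explicit stepping with the
  internal step auto-set to $0.25\,\Delta r^2 \rho C_p / k$; a larger
  requested step is refused with the required bound. The convective
  boundary uses film coefficient $h = \lambda/(4\pi R^2)$, so the
  fast-conduction limit reproduces the lumped model (verified at
  $k$ scaled ×100); the fixed-boundary steady state matches the parabolic
  profile $T_b + Q(R^2 - r^2)/(6k)$ to better than 0.1%.

Default sample parameters mirror the measurement geometry: 1 mL / 1 g of
water-like fluid, $c = 4186$ J/(kg·K), 0.4 s sampling.

## Calorimetry

SLP is extracted by the initial-slope method,
$\mathrm{SLP} = c\,(m_f/m_\text{MNPs})\,\Delta T/\Delta t$, with the slope
from an OLS line over the start of the heating phase. The default window
is 30 s — "initial" is not quantified in the source, and 30 s keeps the
exponential-curvature bias below $w/2\tau \approx 3\%$ for thermal time
constants $\tau \gtrsim 500$ s; recovery studies in the tests use a 10 s
window, for which the bias is ~1%. `slope_window_sensitivity()` reports
the fitted slope across windows so users can audit this choice. Plain OLS
is used rather than Box–Lucas or corrected-slope estimators because the
measured quantity is defined as a fitted initial gradient; the batch
driver (`slp_batch()`) processes trace sets with per-row error capture and
reports chain/random SLP ratios per condition.

Monte-Carlo checks: with 0.05 K Gaussian noise (the synthetic-trace noise
model) and $\tau = 500$ s, the mean recovered SLP over 100 replicates is
within ~1% of truth; noise leaves the fitted slope unbiased within three
standard errors.

## What the synthetic data do and do not show

The generators emulate: the two particle populations, the published box /
count / field conditions, and lumped-model temperature traces with i.i.d.
Gaussian noise. They do not emulate: particle-size dispersity, lateral
chain bundling or chain width, gel viscoelasticity (only a scalar
viscosity enters; the gelation-stage value is user-supplied, with water at
300 K as default and a hot-water 0.355 mPa·s variant), field-dependent
moments below saturation, Brownian-relaxation heating, or probe-position
effects in the vial. Passing tests therefore demonstrate internal
consistency of the model chain on inputs with this structure, not
quantitative agreement with any particular measured sample.

## Problem sizes

The test-suite and acceptance-script simulations use a $40\,d_0$ box with
48–190 particles (matching the 1 and 4 mg/mL concentrations), runs of
500–2500 steps (0.4–1.8 ms of physical time, past the growth plateau at
these densities), 10 seeds for stochastic orderings, and 100-replicate
Monte-Carlo recovery studies — sizes chosen so the whole pipeline
reproduces on a laptop in about a minute while keeping every stochastic
acceptance margin at three standard errors or better.
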