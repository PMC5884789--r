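---
title: "Simulating partial gravity on a Random Positioning Machine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating partial gravity on a Random Positioning Machine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(rpmsim)
```

## The problem

Organisms on a Random Positioning Machine (RPM) are rotated by two
independently driven perpendicular gimbals so that the gravity vector,
expressed in the sample's own frame, points in ever-changing directions.
When the orientation distribution is uniform over the sphere, the
time-averaged gravity approaches zero — simulated microgravity. Many
questions in gravitational biology, however, concern *fractional* gravity
(Moon ≈ 0.17 g, Mars ≈ 0.38 g): somewhere between weightlessness and
Earth gravity, where thresholds of gravity sensing are expected to lie.
`rpmsim` implements and cross-checks the two strategies for generating
such levels on RPM hardware, as a simulator and experiment-design tool.

## The software paradigm: a spheroid instead of a sphere

### Model

Let the gravity direction in the sample frame spend equal time per unit
*area* on the surface of a prolate spheroid with semi-major axis 1,
eccentricity $e$, and one focal point at the rotation centre.
Parametrising the surface by the axial coordinate $z \in [-1, 1]$:

* area element: $dA \propto \sqrt{1 - e^2 z^2}\, dz$;
* distance from the focus to the surface point: $d(z) = 1 - e z$;
* direction from the focus, axial component: $a(z) = (z - e)/(1 - e z)$,
  transverse component $\sqrt{1-e^2}\sqrt{1-z^2}/(1 - e z)$, with
  $a^2 + t^2 = 1$ identically (the direction is always a unit vector).

Because residence is uniform in *area* but the map from area to solid
angle is distorted by the off-centre viewpoint, directions towards the
near vertex are over-represented, and the mean gravity vector is

$$
p(e) \;=\; \frac{\left|\int_{-1}^{1} (e - z)\,
  \sqrt{\tfrac{1+ez}{1-ez}}\; dz\right|}
  {\int_{-1}^{1} \sqrt{1 - e^2 z^2}\; dz},
$$

a strictly increasing function with $p(0)=0$ and $p \to 1$ as
$e \to 1$. `mean_g_from_eccentricity()` evaluates both integrals by
adaptive quadrature (absolute tolerance $10^{-8}$ each; the integrands
are finite at the endpoints, so no special treatment is needed), and
`eccentricity_for_mean_g()` inverts the map by bracketed bisection on
$[0, 1-10^{-9}]$ to $10^{-6}$, unique by monotonicity.

```{r map}
mean_g_from_eccentricity(c(0, 0.25, 0.53, 0.66, 0.87))
plot_eccentricity_map()
```

The four standard settings (Moon 0.25, Mars 0.53, half-g 0.66,
three-quarter-g 0.87) fall out of the quadrature to within printed
rounding. The suite also cross-checks the quadrature against an
independent Monte-Carlo surface-sampling oracle (up to $10^7$ draws,
agreement within 3 standard errors) — two routes to the same number.

### Orientation convention

The mean of $a(z)$ over the area measure is *negative* (towards the near
vertex), so the spheroid's axis is oriented such that this mean direction
coincides with `symmetry_axis` — by default $(0,0,-1)$, the sample's
"down". A biology experiment needs a defined net-g direction relative to
the specimen; delivering it along the sample's down makes the partial-g
condition directly comparable to a static control. $p$ is reported as the
magnitude of the mean vector.

### Trajectory driver

The concrete path the machine takes over the spheroid is not part of the
model (any surface-uniform traversal yields the same stationary
distribution, differing only in convergence speed). The driver here
draws i.i.d. waypoint directions from the target distribution — axial
coordinate by rejection sampling under the area density, azimuth uniform
— and slews between them along shortest great-circle arcs at the maximum
frame rate (default 60°/s, the standard RPM maximum; the "maximum
acceleration" of machine settings panels is dimensionally this angular
speed). Arc motion continues seamlessly through waypoints within a time
step, so the commanded rate is exactly respected. Alternatives (random
walks, space-filling curves) would converge at different speeds; the
waypoint scheme was chosen because it provably targets the stated
stationary distribution without inventing further dynamics.

Two consequences worth noting when interpreting results:

* convergence-error magnitudes after a fixed time are driver-specific.
  The package therefore checks *decay* of the running error
  $\bigl|\,\lVert\bar g(t)\rVert - p\,\bigr|$ (monotone trend on a
  log-spaced grid) and order of magnitude, not specific printed values;
  a seeded 4 h Mars-level run here ends near $10^{-4}$ g.
* i.i.d. waypoints mix faster than a physical machine with inertia
  might; real hardware may need longer runs for the same error.

```{r run}
cfg <- load_config(overrides = list(mode = "sw", target_g = 0.38,
                                    duration = 3600, seed = 11))
sim <- run_simulation(cfg)
glance(sim)
autoplot(sim$convergence)
```

### The two-state baseline

The simplest partial-g scheme points the sample down for a fraction
$q = (p+1)/2$ of the time and up for the rest, giving mean $p$ exactly.
`two_state_trajectory()` provides it as a deterministic baseline: same
mean, radically different orientation distribution (two atoms instead of
a smooth spheroid density) — exactly the property the density diagnostics
are meant to expose.

## The hardware paradigm: centrifuge on an RPM

With the RPM providing a near-weightless baseline, a mounted centrifuge
adds $g = \omega^2 r / g_0$. The package uses $g_0 = 9.81$ m/s²
throughout, matching the convention of the reference settings it
reproduces. `solve_rpm()` rounds to integer rpm (ties to even), the
controller's granularity; note that at 75 rpm and 16 cm the realised
level is 1.006 g — integer-rpm quantisation means round-tripping a target
through the solver can land within, but not exactly on, 0.01 g of the
target.

Design artefacts quantified:

* **Residual g** (`residual_g()`): the frame rotation itself imposes
  $\omega_f^2 r$ on samples displaced from the rotation centre — 0.022 g
  at 60°/s and 0.20 m, ~5–6 % of a Mars-level run. The planner reports it
  alongside every setting.
* **Combination rule** (`combined_g()`): how the residual superimposes on
  the centrifuge vector depends on their time-varying relative direction,
  which the model does not resolve; the default is therefore the
  conservative interval $[g - r_{es}, g + r_{es}]$, with `rss` (if the
  residual direction averages out) and `scalar_add` available.
* **g-gradient** (`g_gradient()`): linear in the sample's radial extent
  at fixed $\omega$ — the argument for large-platter centrifuges.
* **Equi-gravity placement** (`equigravity_positions()`): seeds or
  specimens are placed along an arc of constant radius (constant g),
  clipped to the Petri dish (default 9 cm); positions are kept 2 % inside
  the rim so none touch the dish wall.

```{r hw}
plan_hw(0.38, 0.12)
equigravity_positions(0.12, 0.09, 0.12, n = 25) |> head(3)
```

## Density diagnostics

`equal_area_partition()` builds a band-and-sector partition of the
sphere: band boundaries equally spaced in $\cos\theta$ and an equal
number of sectors per band, so every cell has identical solid angle
(default 10 × 10 = 100 cells; equal areas make densities directly
comparable and keep the chi-square expectation flat). Densities are
residence-*time*-weighted (trapezoidal share per sample), so non-uniform
sampling steps are handled, and normalised so 1 = uniform.
`expected_spheroid_density()` gives the analytic cell masses of the
target distribution in closed form (antiderivative of the area density
mapped through the focus projection), which the suite compares with
empirical sampler maps by chi-square.

```{r density}
part <- equal_area_partition(10)
u <- sample_spheroid_directions(spheroid_spec(0.53), 2e5, seed = 1)
autoplot(sample_density(u, part))
uniformity_metrics(expected_spheroid_density(spheroid_spec(0.53), part))
```

## Numerical choices and degenerate inputs

* Quadrature: `stats::integrate`, absolute tolerance $10^{-8}$;
  inversion by `stats::uniroot` to $10^{-6}$.
* Trajectory integration: fixed step (default $dt = 0.1$ s), exact for
  the piecewise-constant rate drivers used; internal gimbal angles are
  unwrapped for continuity and wrapped to $[0, 2\pi)$ only for
  reporting. Rates beyond `max_rate` are clipped and flagged in the
  trace metadata.
* Antipodal waypoints (undefined great circle) are broken
  deterministically towards a fixed perpendicular direction.
* Time averaging uses trapezoidal weights, making means exactly additive
  over concatenated traces.
* Eccentricity 1, negative durations, empty traces, a zero `max_rate`,
  infeasible equi-gravity radii and contradictory configurations
  (both `target_g` and `eccentricity`) all raise informative errors.
* One seeded generator drives each run (`seed` in the config, recorded
  in every trace and report); identical configurations reproduce traces
  and reports bit-identically apart from timestamps.

## What the simulations do and do not show

Test problem sizes were chosen to exercise the asymptotics at desk
scale: $10^6$–$10^7$ draws for sampler-vs-quadrature checks, 2–4 h
simulated runs at $dt = 0.1$ s for convergence properties. The generator
emulates the *kinematic* content of the paradigms — orientation
distributions, time averages, centrifuge algebra. It does not model
motor dynamics (torque, inertia, backlash), Coriolis forces, fluid shear
in culture vessels, or vibration; agreement of a simulated run with its
target therefore validates the algorithmic design, not the biological
equivalence of the stimulus. Whether a given organism reads a
spheroid-averaged 0.38 g like a centrifuged 0.38 g is an experimental
question the two paradigms are designed to let one ask.
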