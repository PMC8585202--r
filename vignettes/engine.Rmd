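---
title: "The dipscreen engine: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dipscreen engine: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipscreen)
```

## The screening question

Cationic surfactants (octenidine, chlorhexidine, Gemini detergents) act on
bacterial membranes, and a first-order screening question is how expensive
it is, in free energy, for such a molecule to move from bulk water to the
core of a given lipid bilayer. Atomistic free-energy methods answer this
accurately but at a cost of CPU-months per molecule. `dipscreen` implements
a deliberately minimal implicit model that answers the same question in
seconds to minutes: good enough to rank candidate molecules and membranes,
not a replacement for a statistical-mechanics-grade potential of mean
force.

## The model

**Membrane.** The bilayer is a set of point dipoles. Each leaflet is a
regular lateral grid (spacing $\sqrt{\mathrm{APL}}$) on a plane at
$z = \pm h$, where $h$ is the half-thickness (default 20 Å, a typical
phosphate-plane distance for POPC/POPG bilayers) and the number of sites
per leaflet is $\lfloor l_x l_y / \mathrm{APL} \rfloor$. Every site's
dipole vector is drawn once, per axis, from a normal law with the lipid's
per-axis mean and standard deviation; these statistics were derived from
long MD trajectories and are shipped as the `PC` and `PG` presets.
Phosphatidylglycerol's large mean $z$ component ($-35.08$ D, against
$+1.65$ D for phosphatidylcholine) is what makes "anionic" membranes
behave differently in this model.

**Agent.** The surfactant is a point dipole $\boldsymbol\mu$ attached to a
sphere of mass $m$ and Stokes radius $R$, with an octanol–water partition
coefficient $\log_{10} P$.

**Field.** The interaction of the agent with site $i$ is
$$E_i = \frac{\boldsymbol\mu_i \cdot \boldsymbol\mu}
             {4\pi\varepsilon_0\,\varepsilon_r\, r_i^3},$$
summed over all sites of both leaflets with no cutoff. Only the scalar
product of the moments enters; the orientational term of the full dipole
tensor is omitted by design (the agent is a point mass, not a rotor). The
force is the analytic gradient, $3E_i/r_i$ along the site-to-agent unit
vector. $\varepsilon_r$ is resolved from the *agent's* $z$: 88.0 in water,
4.0 inside $|z| < h$, with the boundary itself assigned to water. A smooth
logistic switch (~2 Å wide) is available in `dielectric_at()` for
sensitivity checks but the engine always uses the sharp rule, because the
free-energy bookkeeping needs an unambiguous crossing event.

**Propagation.** The agent obeys the damped two-step recurrence
$$r_{n+1} = r_{n-1} + 2\Delta t\, v_n, \qquad
  v_{n+1} = v_{n-1}\Bigl(1 - \tfrac{2\Delta t\, b}{m}\Bigr)
            + \tfrac{2\Delta t}{m} F(r_n),$$
with Stokes drag $b = 6\pi\eta R$ ($\eta$ region-resolved like
$\varepsilon_r$) and the kinetic energy capped at $k_BT$ after every
velocity update: whenever $m|v|^2/2 > k_BT$ the speed is rescaled to
$\sqrt{2k_BT/m}$, preserving direction. The recurrence is implemented
exactly as written — position paired with the velocity one level back —
which decomposes into two interleaved leapfrog chains of effective step
$2\Delta t$; with the cap and drag off it conserves energy to well under
1% over $10^4$ steps (asserted in the test suite). It is bootstrapped with
$r_0 = r_{-1}$ and $v_0 = v_{-1}$.

**Free energy.** Along the trajectory the engine records the Hamiltonian
$H = E_p + \min(mv^2/2,\, k_BT)$ and accumulates
$\Delta G \mathrel{+}= H_n - H_{n-1}$, plus a transfer term
$\pm\,\Delta H_\mathrm{transfer} = \pm\ln(10)\,R\,T\log_{10}P$ (per
molecule) whenever the agent crosses the water/membrane boundary (positive
on entry under the default sign convention, negative on exit, so an
enter-then-exit round trip cancels exactly). The cumulative $\Delta G$ is
binned by $z$ (bin width 0.2 Å, the convention of reference
adaptive-biasing-force profiles), each bin holding the mean of its
samples, and re-zeroed at the bulk bin containing the starting height.
`find_extrema()` smooths with a 3-bin moving average before locating
barriers and minima; `trans_free_energy()` reports
$\Delta G_\mathrm{core} - \Delta G_\mathrm{bulk}$ and an explicit
"not reached" (`NA`) when the agent never came near $z = 0$.

## What the bookkeeping can and cannot show

Two properties of this construction are worth stating plainly, because
they shape every profile the engine produces.

First, the dipole field is conservative, so the per-step Hamiltonian
differences telescope: in the water phase, where the cap rarely binds and
drag is weak, the profile is close to flat (and monotone non-increasing,
since the cap can only remove energy). Structure in the profile comes from
the *non-conservative* ingredients — kinetic-energy trimming where the
field accelerates the agent beyond $k_BT$, drag dissipation, the
$\varepsilon_r$ jump at the boundary (the same configuration is 22 times
more energetic inside), and the transfer term. In particular, the net
bulk-to-core value is dominated by $\Delta H_\mathrm{transfer}$ (12.70
kcal/mol for octenidine at 300 K, 7.52 kcal/mol for chlorhexidine —
values the test suite verifies to four significant digits) plus the
dielectric jump at the entry crossing. Screening comparisons with this
engine are therefore most meaningful *between* systems — the same agent
against differently charged membranes, or two agents against the same
membrane — where the orderings are driven by the dipole statistics; the
acceptance tests assert exactly those orderings (PG entry barriers exceed
PC ones, and PG translocation costs exceed PC ones, for both reference
agents).

Second, the dynamics is deterministic — there is no thermostat and no
random force; all run-to-run variation comes from the membrane seeds. With
kinetic energy capped at $k_BT$, the agent cannot climb free-energy
structure much larger than $k_BT \approx 0.6$ kcal/mol. Inside the
membrane, where $\varepsilon_r = 4$ amplifies the random site couplings,
the landscape is rough on a multi-$k_BT$ scale, so runs can end trapped in
the first interior well (typically a few Å below the leaflet plane) rather
than at the bilayer center. That is expected behaviour, not an error:
the trajectory contract is "starts in bulk water, ends at or below the
interface region". Anionic PG membranes, whose coherent $-35$ D
$z$-dipoles push the agent toward the core once it is past the upper
plane, are crossed far more often than neutral PC ones. When the core is
not reached, `trans_free_energy()` says so rather than returning a number.

## The starting state

The agent starts at the lateral box center, 45 Å above the bilayer
center. Its default initial velocity points at the membrane with speed
$\sqrt{2k_BT/m}$, i.e. its kinetic energy starts exactly at the thermal
cap (~89 m/s for octenidine at 300 K). This is the package's own choice
where the scheme needed one: water-phase dipole forces at 45 Å are of
order $10^{-4}$ kcal/mol/Å, so an agent released *from rest* either takes
orders of magnitude more than the default step budget to arrive
(femtosecond steps, ballistic in a nearly flat field) or — against
membranes whose mean coupling to the agent is repulsive, as PG's is for
both reference agents — never arrives at all. A thermal approach velocity
is also the premise behind the default step budget: at ~90 m/s the agent
needs about $5 \times 10^4$ steps to traverse 45 Å, and the default
$5 \times 10^5$ steps leave a wide margin for drag and interior
slowdowns. `v_start = "rest"` restores the from-rest behaviour.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `dt` | 1e-15 | s | femtosecond steps resolve the capped motion (0.9 mÅ per step at cap speed) |
| `n_steps` | 5e5 | — | ~10x the thermal-speed traversal time of 45 Å |
| `z_start` | 45 | Å | reference starting height in bulk water |
| `half_thickness` | 20 | Å | phosphate-plane distance; also the dielectric/viscosity switch |
| `apl` | 64 | Å² | area per lipid; 80 x 80 Å box gives 100 sites per leaflet |
| `bin_width` | 0.2 | Å | reaction-coordinate bin convention of the reference profiles |
| `temperature` | 300 | K | sets the cap $k_BT$ and the transfer enthalpy |
| `drag_radius` | 1e-14 | m | reference engine value; only scales $b$ (it is far below molecular size, which we keep as-is and document) |
| `transfer_sign` | +1 | — | entry costs $+\Delta H_\mathrm{transfer}$; set $-1$ for the lipophilic reading where entering the membrane is favourable |
| `r_min` | 1 | Å | clamp on site distances guarding the $1/r^3$ singularity |

## Numerical choices and degenerate inputs

* **Minimum-distance clamp.** The pair energy diverges as the agent passes
  a lattice site; distances below `r_min` (1 Å) are clamped (energy and
  force evaluated at 1 Å along the true direction) and counted. Interactive
  field evaluations warn; trajectories record the count as an attribute.
* **Bootstrap.** The two-step recurrence needs two prior states; both are
  initialised to the starting state, making the first velocity update a
  forward-Euler-like half start.
* **Units.** Positions in Å and dipoles in Debye at every interface;
  joules per molecule internally (masses converted from g/mol via
  Avogadro's number); kcal/mol in every report. A single constants table
  (`physical_constants()`) is the only source of conversion factors.
* **Ties and boundaries.** $|z| = h$ exactly is water; the profile
  reference is the bin containing `z_start` (falling back to the nearest
  populated bin); empty interior bins are `NA`, never zero; extrema
  detection requires at least 5 populated bins and returns empty feature
  tables for flat profiles.
* **Divergence.** Non-finite state or excursion beyond a 10x box envelope
  aborts the run with the offending step index; the CLI maps this to exit
  code 3.
* **Determinism.** One integer seed fully determines a membrane (positions
  are seed-independent; only dipole draws vary); trajectories are pure
  functions of their inputs; replicate screens use `seed, seed + 1, ...`.
  The global RNG state is restored after membrane generation.

## Replicates and the screening workflow

Because each membrane realisation is random and trajectories respond to
individual wells, single runs are noisy by construction. `screen_agent()`
runs 10 seeds by default, aligns the per-seed profiles on their common
grid (same bin width and origin enforced), and reports the per-bin mean
and standard deviation together with features of the mean profile. The
acceptance workflow (`scripts/acceptance.R`) uses exactly this path:
10 replicates per lipid/agent system at the defaults above.

## What the generator does not emulate

The membrane is two static planes of point dipoles: no lipid mixtures, no
curvature or undulations, no explicit ions or water, no lateral lipid
motion, no agent rotation, no periodic images (the 80 x 80 Å default box
keeps edge effects small at the center). Passing tests show that the
engine reproduces its own model's mechanics exactly and that its
between-system orderings follow the dipole statistics; they do not show
that the absolute profile values match experiment or atomistic free-energy
calculations.

## Known limitations

* The net bulk-to-core value is transfer-term dominated (see above), so
  absolute $\Delta G_\mathrm{trans}$ values should be read as
  logP-calibrated offsets plus dipole corrections, not as potentials of
  mean force.
* Deterministic capped dynamics cannot hop multi-$k_BT$ interior wells;
  neutral-membrane runs often end trapped near the interface, and the
  core value is then reported as not reached.
* The printed two-step recurrence updates positions without a direct
  force term; it is implemented as printed (the interleaved-leapfrog
  structure keeps it stable), and `verlet_step()` exposes the literal
  update for inspection.
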