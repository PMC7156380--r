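---
title: "Coupled Mo-U mass balance and euxinia inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled Mo-U mass balance and euxinia inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoredox)
```

This vignette documents the scientific models implemented in `paleoredox`,
the assumptions behind them, the tunable parameters and their defaults, and
the numerical and design choices made where the method left room for choice.

## 1. From bulk shale measurements to authigenic signals

Bulk shale Mo and U are a mixture of a lithogenic (detrital) component
inherited from eroded crust and an authigenic component scavenged from
seawater; only the latter records global seawater isotope values. The
detrital component is estimated by standardizing to an element of
crust-like, conservative behavior — Al for Mo and Th for U —

$$[\mathrm{Mo}]_{detr} = \left(\tfrac{Mo}{Al}\right)_{crust}[\mathrm{Al}]_{bulk},
\qquad
[\mathrm{U}]_{detr} = \left(\tfrac{U}{Th}\right)_{crust}[\mathrm{Th}]_{bulk},$$

and the authigenic concentration and isotope value follow by two-component
unmixing:

$$[\mathrm{Me}]_{auth} = [\mathrm{Me}]_{bulk} - [\mathrm{Me}]_{detr}, \qquad
\delta_{auth} = \frac{\delta_{bulk}[\mathrm{Me}]_{bulk} -
\delta_{detr}[\mathrm{Me}]_{detr}}{[\mathrm{Me}]_{auth}}.$$

The crustal ratios, their 2SD uncertainties, and the detrital end-member
isotope values are *inputs*, shipped as a plain-text reference table
(`inst/extdata/crustal_reference.csv`) with provenance notes, never
hard-coded: the correction remains auditable and any laboratory's preferred
crustal model can be substituted. Samples whose correction yields
$[\mathrm{Me}]_{auth} \le 0$ ("over-corrected") are flagged invalid and
excluded from downstream isotope statistics but retained in the table.

Uncertainty on the authigenic estimates combines the analytical 2SE with the
crustal-ratio 2SD by *seeded parametric resampling* (default $10^4$ draws):
both quantities are redrawn from normal distributions at their stated
half-widths and the correction re-run. Resampling was chosen over linearized
error formulas because it is assumption-light, exact for this nonlinear
ratio, and directly testable against a brute-force Monte Carlo oracle (the
test suite checks agreement within 5% on randomized cases).

Local depositional redox is screened by iron speciation. Highly reactive
iron is the sum of the four sequential-extraction fractions
($\mathrm{Fe_{HR}} = \mathrm{Fe_{carb}+Fe_{ox}+Fe_{mag}+Fe_{py}}$, the
standard Poulton–Canfield scheme). Samples with
$\mathrm{Fe_{HR}/Fe_T} \le 0.38$ classify oxic; anoxic samples subdivide on
$\mathrm{Fe_{Py}/Fe_{HR}}$ into ferruginous ($\le 0.7$), possibly euxinic
($0.7$–$0.8$] and euxinic ($> 0.8$). All thresholds are arguments. Only
euxinic / possibly euxinic samples feed the global inference, because only
under sulfidic bottom waters are both metals captured with small, consistent
fractionations from seawater.

The record statistics are computed on *both* bulk and detritally corrected
values (both are reported by `augment_samples()`); for Mo the difference is
small because detrital Mo is a minor fraction of these strongly enriched
shales.

## 2. The coupled Mo-U box model

Each metal is modeled with one seawater reservoir, a riverine source and
three redox-sensitive sinks (oxic, broadly reducing, euxinic). The state
variables are the dissolved inventory $N$ (mol) and the isotope-weighted
inventory $N\delta$ (mol ‰) — exactly the quantities differentiated in the
governing equations, which avoids chain-rule rearrangement; seawater
$\delta_{sw}$ is the derived ratio. Sink fluxes are first order in seawater
concentration,

$$F_i = b_i A_i \alpha_i \frac{[\mathrm{Me}]_{sw}}{[\mathrm{Me}]_{M.sw}},
\qquad A_i = A f_i, \qquad
f_{oxic} = f_{ox.lim} - f_{eux} - f_{red},$$

so the system is linear with a unique, globally attracting steady state:

$$N_{ss} = \frac{F_{riv}}{\sum_i k_i}, \qquad
\delta_{sw,ss} = \delta_{riv} - \frac{\sum_i k_i \Delta_i}{\sum_i k_i},
\qquad k_i = \frac{b_i A_i \alpha_i}{[\mathrm{Me}]_{M.sw} M}.$$

Both solution paths are implemented. The time-dependent path integrates the
four-component system with a variable-coefficient stiff-capable solver
(`deSolve::vode`) from modern initial conditions, declaring convergence when
every component changes by less than a relative $10^{-8}$ over a 1 Myr
window (50 Myr cap, with a failure flag). The closed form is the default in
ensembles because the two agree to better than $10^{-6}$ relative (a
property the acceptance suite re-verifies on 100 random draws) and it is
orders of magnitude faster. The convergence criterion and cap are the
package's own choices; residence times under the default parameter ranges
are well below 1 Myr, so the windows comfortably resolve equilibration.

Fixed constants (total seafloor area $3.6\times10^{14}$ m², seawater mass
$1.41\times10^{21}$ kg, modern seawater Mo and U of 150 and 14 nmol/kg,
modern $\delta^{98}$Mo$_{sw}$ = +2.34‰ and $\delta^{238}$U$_{sw}$ = −0.39‰)
live in `mb_constants()`. The modern concentrations are interpreted on the
nmol/kg scale; this is corroborated by the resulting modern residence times
($N/F_{riv} \approx$ 0.7–0.9 Myr, comfortably above 400 kyr), consistent
with both metals being well-mixed tracers.

Sediment archives project from steady seawater with *local* fractionations
drawn independently of the global sink means:

$$\delta^{98}\mathrm{Mo}_{eux} = \delta^{98}\mathrm{Mo}_{sw} + \Delta^{98}\mathrm{Mo}_{eux.loc},\quad
\delta^{238}\mathrm{U}_{eux} = \delta^{238}\mathrm{U}_{sw} + \Delta^{238}\mathrm{U}_{eux.loc},\quad
\delta^{238}\mathrm{U}_{carb} = \delta^{238}\mathrm{U}_{sw} + \Delta^{238}\mathrm{U}_{carb.loc}.$$

This separation lets a local depositional environment deviate from the
global mean sink behavior, which is exactly the scatter observed among
modern euxinic basins. The locally scaled burial rates
($b_{U.eux.loc}$, $b_{Mo.eux.loc}$) are drawn and stored for completeness
but feed no quantity in the global balance.

## 3. Pseudospatial burial scaling over hypsometry

As euxinia expands beyond the shelf, authigenic burial necessarily moves
into deeper water, where sinking metal–organic complexes are increasingly
remineralized before reaching the sediment. The scaling coefficient

$$\alpha_{eux} = \frac{\overline{1.58 - 0.16\ln z}\;\big|_{z \in Z_{eux}}}
{1.58 - 0.16\ln \min(Z_{eux})}$$

averages an empirical organic-carbon remineralization depth law over the
depth window the euxinic sink occupies on the global depth–area curve,
normalized to the shallowest euxinic depth ($\alpha_{oxic} \equiv 1$). The
broadly reducing sink occupies the window *directly below* the euxinic one;
its depths are absolute water depths from the same curve (the incremental
depth beyond $\max(z_{eux})$ plus $\max(z_{eux})$ — the only reading under
which the reducing window's shallow limit equals the euxinic window's deep
limit), normalized by the same $\alpha_{eux.min}$ denominator. The
shallowest 5% of seafloor is held authigenically neutral unless total
euxinia exceeds 95%, in which case the window slides to the deepest
$f_{eux}$ of the seafloor; the reducing window applies the same encroachment
rule at its lower end. When $f_{eux} = 0$ the $\alpha_{eux.min}$ reference
depth is taken at the neutral-zone base (area fraction 0.05) — a limit
convention, flagged as such.

Numerical choices: windows are discretized into $N$ = 100 equal-area
increments represented at their area midpoints (an area-weighted midpoint
rule, quadratically convergent), while the $\alpha_{eux.min}$ denominator is
pinned at the window's shallow-edge depth so it does not drift with $N$;
doubling $N$ changes $\alpha$ by well under 0.5%. Depths are floored at 1 m
before taking logarithms so the fully euxinic window ($f_{eux}=1$, which
reaches area fraction 0) stays defined. A genuinely single-depth window has
$\alpha = 1$ exactly.

The depth–area curve itself is a LOESS smoother of a bundled hypsometric
table (cumulative seafloor area fraction vs depth, reconstructed from the
classic 1000-m binned global ocean depth-zone area fractions), with the span
selected by leave-one-out cross-validation over a span grid and a
monotonization post-step (running maximum on a fine grid). Any user table
with the same two columns may be substituted. Whether to monotonize, the
span grid and $N$ are all exposed as arguments.

## 4. Monte Carlo global sensitivity analysis

$f_{eux}$ is swept over 31 logarithmically equispaced scenarios. The grid
bounds (0.1%–100%, i.e. a 0.1 dex step) follow from the percentile values
the workflow is designed to resolve, all of which lie exactly on a 0.1 dex
grid; both bounds and count are configuration. For each scenario, every
varied parameter is drawn independently from a *uniform* distribution
between its observed modern minimum and maximum (`mb_param_ranges()`), a
deliberate choice to avoid privileging a most-likely modern analog;
$f_{red} \sim U(0, 1-f_{eux})$. Draws where $f_{ox.lim} < f_{eux} + f_{red}$
clamp $f_{oxic}$ at zero and are flagged rather than rejected, preserving
the prior over the remaining parameters. An elevated-weathering variant
scales both riverine flux ranges by a configurable multiplier, and any
individual range (for example the reducing-sink fractionations) can be
overridden in configuration.

Reproducibility: per-scenario seeds derive from the master seed by a fixed
counter scheme (`master %% 1e5 * 1000 + scenario`), and parameters are drawn
in a fixed documented column order, so an ensemble is bit-identical given
(configuration, master seed).

## 5. Compatibility filtering and the time-dependent reconstruction

The time-independent estimate retains ensemble runs whose projected values
for *every* supplied proxy lie within that record's inclusive min–max range.
Filtering is joint and per-run — a single steady seawater state must satisfy
all archives simultaneously — rather than an intersection of marginal
$f_{eux}$ sets, because each run projects one ocean onto all three archives.
Measured 2σ uncertainties can optionally widen the ranges (off by default:
the criterion is the measured *range*). A binned mode (10 uniform bins
between the measured extremes, half-open with the top bin closed; a constant
record degenerates to one narrow bin) is also provided; range mode is the
default for the time-independent estimate. Summaries use nearest-rank
percentiles so that medians and percentile bounds land on actual scenario
grid values.

The time-dependent reconstruction proceeds at 20 kyr timesteps over
444.7–440.8 Ma (all configurable): each record is smoothed against age by
cross-validated LOESS (degree 1, span by leave-one-out CV over a documented
grid); at each timestep covered by a record, the smoothed "measured" value
is assigned to one of that proxy's 10 bins and ensemble runs in the same bin
are retained; retained sets intersect across covering proxies. Timesteps
covered by no record are gaps, not errors. Finally, cross-validated LOESS
curves through the per-timestep median, 5th and 95th percentiles give the
envelope, clamped to [0, 1]. The shale core's age model is linear between
the stage boundaries (443.8 Ma at the base, 440.8 Ma at the top of the
sampled interval); the carbonate record carries its own ages.

## 6. The synthetic-data generator

The generator emulates the study conditions end-to-end so the whole workflow
is testable without any external data: 59 core samples whose *authigenic*
$\delta^{98}$Mo is drawn N(0.69‰, 0.13‰) and $\delta^{238}$U N(−0.02‰,
0.07‰); a carbonate $\delta^{238}$U series around −0.45‰ (SD 0.10‰, the
scale of typical reported analytical 2SD, chosen here because the record
level only reports a mean) spanning the 444.7–443.5 Ma onset window;
lognormal TOC around 4 wt%; authigenic metal loadings proportional to TOC
(7 and 2 ppm per wt% for Mo and U — organic-carbon-loaded enrichments with
no stratigraphic isotope trend); detrital components from generated Al and
Th via the crustal ratios; and iron-speciation ratios drawn in the locally
euxinic field ($\mathrm{Fe_{HR}/Fe_T} \in [0.4, 1]$,
$\mathrm{Fe_{Py}/Fe_{HR}} \in [0.7, 1]$). Bulk concentrations and isotope
values are assembled by the *exact inverse* of the detrital correction, so
preprocessing recovers the injected truth to machine precision — a designed
round trip that pins the correction algebra.

What the generator does *not* emulate: diagenetic overprints, particulate
shuttle enrichments, basin restriction, age-model error, or any correlation
structure between samples beyond the TOC–metal coupling. Passing tests on
synthetic data therefore demonstrate the correctness of the algorithms and
the internal consistency of the workflow under the stated statistical
conditions — not the fidelity of any particular natural record.

`forward_truth_dataset()` additionally generates records from a *known*
$f_{eux}$ by running the mass balance itself and adding observation noise
(SD 0.05‰, half the 2SE scale), enabling parameter-recovery experiments: the
5th–95th percentile interval of the filtered ensemble brackets injected
truths of 1%, 10% and 50% in ≥ 90% of seeded trials (the suite runs 50 per
truth). At the grid extremes (0.1%, 100%) the retained set is one-sided and
its median sits measurably inside the boundary — an expected property of
compatibility filtering with broad priors, worth remembering when reading
reconstructed medians near the edges of the scenario grid.

## 7. Problem sizes and limitations

The shipped defaults run the full protocol: 31 scenarios × 1000 runs
(closed-form path, ~1 s), 196 timesteps in the reconstruction, $10^4$
resampling draws per sample for uncertainty propagation. The test suite
exercises reduced sizes where a property does not need the full ensemble
(e.g. 5 scenarios × 4 runs for the ODE/analytic row-wise comparison) and
the full ensemble where the scientific claim depends on it.

Known limitations: the ocean is a single well-mixed box (no circulation or
spatially explicit redox); inference is compatibility filtering, not a
Bayesian posterior — retained distributions inherit the scenario grid's
logarithmic prior; the steady-state assumption means rapid transients are
interpreted only through their binned record values; and the pseudospatial
scaling is a first-order remineralization correction, not a sediment-flux
model.
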