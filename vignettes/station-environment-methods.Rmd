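---
title: "Characterizing the environment of reef and ocean sampling stations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing the environment of reef and ocean sampling stations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefcontext)
```

## Scope

`reefcontext` characterizes the environment of coral-reef and open-ocean
sampling stations along four axes: the thermal history a reef site
experienced before sampling, the transport and mixing properties of the
water mass sampled at a station, the consolidation of heterogeneous
environmental measurements (in-situ samples, underway sensors, satellite
match-ups, model output) onto samples and sites, and the validation of
plankton-net sampling through normalized biovolume size spectra. Every
stage can be exercised end-to-end on synthetic inputs with known ground
truth, so the whole pipeline is testable offline.

## Thermal history of a reef site

The input is a daily SST series per site, built by pooling the values of the
9 satellite pixels nearest the site across platforms
(`daily_average_pixels()`). From it the package derives the CoRTAD family of
thermal-stress indices.

**Seasonal climatology.** SST is averaged per day-of-year on a 366-bin
calendar (Feb 29 is bin 60; in non-leap years the bin is skipped so Mar 1 is
always bin 61 — calendar alignment without resampling). The raw cycle is
triplicated and concatenated, filtered with a zero-phase (forward–backward)
low-pass, and the middle year extracted; triplication removes edge
transients. The filter is a Chebyshev type-I IIR of order 3 with 0.1 dB
passband ripple — the ripple specification is what distinguishes this family
— and a cutoff period of 36 days, i.e. a normalized cutoff of
(1/36)/(1/2) of the Nyquist frequency at daily sampling. The annual
harmonic sits deep inside the passband: the two-pass gain there is ~0.998,
so a pure annual sinusoid is preserved to ~0.2 % of its amplitude.
Because the passband gain is slightly below unity except at DC, repeated
application of the climatology builder is idempotent to numerical precision
only for constant cycles; a smooth non-constant cycle moves by one further
passband factor (~0.5 % of amplitude) per application. The test suite
asserts exactly these two statements rather than a stricter idempotence no
Chebyshev filter can deliver.

**Weekly climatologies.** The filtered cycle is reduced to 52 means over
contiguous 7-day blocks of day-of-year (block 52 absorbs days 358–366).
The maximum and minimum weekly climatology anchor the heat- and cold-stress
anomalies. Contiguous blocks were chosen because the source products name
weekly climatologies without a binning rule; this is the CoRTAD-style
convention.

**Indices.** With `sst_interp` the gap-filled daily SST:

* anomaly = SST − seasonal cycle(day-of-year);
* `TSA_heat` = `sst_interp` − max weekly climatology;
  `TSA_cold` = `sst_interp` − min weekly climatology;
* degree heating weeks `TSA_DHW` = (1/7) × Σ over the trailing 84 days of
  `TSA_heat` on days with `TSA_heat ≥ 1 °C` (so units are °C-weeks, the
  CoRTAD convention; the source tables do not print units). `TSA_DCW` is
  the cold-side analogue over days with `TSA_cold ≤ −1 °C` and is ≤ 0;
* every frequency index counts days in the trailing 52 weeks (364 days,
  inclusive of the current day) where the underlying series crosses its
  ±1 °C (or ±1 °C-week) threshold. `TSA_DCW_freq` counts days with
  `TSA_DCW ≤ −1 °C-weeks`: the cold-side threshold is applied with a
  negative sign, by symmetry with the heat side.

Interior gaps are linearly interpolated before the rolling windows are
applied; leading/trailing missing days are excluded, and the 95th percentile
of consecutive-missing run lengths is carried as a data-quality summary.
Days whose windows are not yet fully covered by data are flagged `burn_in`
— the first 364 + 84 − 1 observed days, since the DHW frequency looks back
52 weeks at a quantity that itself accumulates over 12 weeks — and excluded
from site summaries. All rolling indices are implemented with cumulative
sums but tested against O(n·w) brute-force recomputation, exactly, on
20-year series.

**Parameter recovery.** A square heatwave of amplitude A °C and duration D
days should yield max DHW = A·D/7 °C-weeks. An event injected into the same
series that builds the climatology contaminates the baseline (≈ A·D / span
per day-of-year bin, ~0.13 °C here), biasing DHW low by several tenths of a
°C-week. Whether the climatology should exclude the sampling year is an
open design choice; the recovery checks therefore build the climatology from
the pre-event years and inject the event into the sampling year, which
isolates the accumulation machinery from climatology estimation (each is
tested separately). By default `assemble_indices()` builds the climatology
from the full series, matching the production convention of using all data
up to the sampling date.

**Site summaries.** `summarize_site()` reduces each index to
min/max/sum/mean/sd over the non-burn-in span up to the sampling date plus
the value at the sampling day, and reports the most recent heat and cold
stress events (maximal runs with `TSA_heat ≥ 1` / `TSA_cold ≤ −1`: end
date, peak, duration) and the recovery time since each (0 when the event is
ongoing; capped at the observed span when no event ever occurred). Reef
Check surveys are matched within a 10 km haversine radius
(`match_reefcheck()`).

## Flow diagnostics over stadium regions

The sampled water mass is modelled as a stadium: all points within 0.1° of
the segment joining the transect endpoints, filled with virtual particles
every 0.01° (`stadium_spec()`, `seed_stadium()`). Membership is evaluated
in degree space — radius and pitch are specified in degrees — with boundary
ties included; the lattice is anchored at the starting endpoint so seeding
is deterministic.

**Eulerian diagnostics** (`eulerian_fields()`): absolute velocity, kinetic
energy, divergence, vorticity, the shear/strain term s², and Okubo–Weiss
OW = s² − ζ² (an exact identity at every node, asserted in tests).
Derivatives are centered finite differences with one-sided stencils at the
edges, on a spherical metric (R = 6 371 000 m, longitude scaled by
cos(lat)); rates are converted to d⁻¹/d⁻² (× 86 400). The synthetic
generator supplies closed-form truth: solid-body rotation at ω d⁻¹ has
ζ = 2ω and OW = −4ω²; a linear strain at σ d⁻¹ has OW = +4σ² and
FTLE = σ; a uniform divergent flow has divergence δ.

**Advection** (`advect()`): 4th-order Runge–Kutta with a fixed 0.125-day
step — far below the grid-crossing time for ≤ 2 m s⁻¹ surface currents —
with bilinear spatial and linear temporal velocity interpolation, storing
daily positions. Particles interpolating into missing-velocity cells are
frozen and flagged `beached`; particles whose stage evaluations leave the
grid are flagged `left_domain`. Backward advection is the default, as the
Lagrangian diagnostics ask where the sampled water came from; forward
advection is available for the betweenness legs and reversibility tests
(forward-then-backward error < 10⁻³° in steady fields).

**FTLE** (`ftle()`): each particle carries an auxiliary cross at ±0.01°;
after advection over τ the flow-map gradient is formed by central
differences in meters and FTLE = ln λ_max(FᵀF) / (2τ), in d⁻¹. One caveat
the tests make explicit: off the equator the cos(lat) metric gives a uniform
zonal flow a real (tiny, ~10⁻⁶–10⁻⁵ d⁻¹) angular shear, so the "uniform
flow has zero FTLE" statement is exact only on the equator.

**Lagrangian divergence** (`lagrangian_divergence()`): the Eulerian
divergence interpolated along the backward trajectory, integrated by the
trapezoidal rule over the daily positions and divided by τ — a time average,
so the printed unit (d⁻¹) is preserved; a raw time integral would be
dimensionless.

**Retention time** (`retention_time()`): membership in an eddy at each
daily backward step uses the common Okubo–Weiss convention
OW < −0.2 σ_OW, with σ_OW the spatial standard deviation of OW over the
domain at that day; retention is the count of consecutive in-eddy days
backward from the sampling day, 0 if currently outside, capped at the
60-day window, and computed only at the largest advective time.

**Betweenness** (`flow_network_betweenness()`): the domain is binned into
boxes (default: the grid resolution); one particle per box is advected
forward over each of two legs centered on the sampling day
(t₀ − τ/2 → t₀ and t₀ → t₀ + τ/2), giving transition indicators P1(a→m)
and P2(m→b). A node's betweenness is Σ_{a,b} P1(a→m)·P2(m→b), normalized
to sum 1: it is high where many origins funnel through a box that still
passes water onward — the bottleneck semantics — and is exactly
brute-forceable, which the tests exploit with an explicit double sum. This
two-leg path-probability formulation is a deliberate, stated approximation
of network betweenness; it is not a reimplementation of any published
network-construction pipeline.

**Station statistics** (`station_diagnostics()`): each diagnostic is
reduced to exactly four values — mean, 25th, 50th, 75th percentiles — over
surviving particles, per advective time τ ∈ {5, 10, 15, 20, 30, 60} days
for the Lagrangian diagnostics (Eulerian diagnostics are evaluated once, at
the sampling day). Statistics are withheld when fewer than 4 particles
survive or more than half are lost, since percentiles of a decimated,
spatially biased ensemble are not meaningful.

## Environmental context: aggregation, correction, merging

**Provenance.** Sampling-design labels are composed/parsed as
`OA###-I##-S##-C###` with strict range checks (`compose_design_label()` is
exactly invertible by `parse_design_label()`). Events are grouped into
stations greedily in time order: an event joins the open station if within
75 km and 0.25 days of the station's running centroid, otherwise it opens
the next one; isolated non-systematic events get station 0. Greedy centroid
linkage was chosen because a "group of events" rule without a linkage
convention is not deterministic; greedy-in-time is, and matches how a
cruise actually accretes stations. Stations within 370 km (200 nautical
miles) of an island inherit its label, nearest island first, ties to the
lower code.

**Match-up buffers.** Level-3-style mapped grids (4 km, 8-day composites)
are sampled with a pixel buffer: the (2b+1)×(2b+1) window centered on the
containing pixel, statistics over valid pixels only, with n = 0 and the
token `nav` when fully masked. The standard 2-pixel buffer yields the
5×5-pixel (20 km) window; the 12-pixel cloud-fallback buffer yields
25×25 pixels (100 km). Both are emitted side by side rather than merged, so
downstream users can see when the small window was cloud-limited.

**Sample-level aggregation** (`match_context()`): records within the time
(dt), horizontal (dxy) and vertical (dz) tolerances are aggregated to n,
mean, sd, and 5/25/50/75/95 percentiles; the reported lags are those of the
nearest contributing record (nearest in time, ties by distance). Sign
conventions, which the source material leaves open: dt = sample − context
in fractional days, dz positive when the sample is deeper.

**Bias correction** (`bias_correct_source()`): satellite/model values are
regressed on their in-situ counterparts (OLS); bias is a slope ≠ 1 and/or
intercept ≠ 0, inverted as (source − intercept)/slope. The phrase
"dividing by the slope and subtracting the intercept" is ambiguous about
order; both inversions are implemented (`order = "divide_first"` gives
source/slope − intercept) and the algebraically exact inverse of the fitted
line is the default. A correction is accepted only when r ≥ 0.5, slope in
[1/3, 3] and n ≥ 10 — repository thresholds standing in for the qualitative
"large bias persisted" exclusion; rejected sources are never merged.
`merge_sources()` then takes the first available value in priority order
(in-situ first), records the provenance of every value, never overwrites a
present in-situ value, and emits `nav` where every source is missing.
Afternoon-sampled variables that missed their morning station are filled by
time-weighted linear interpolation between the adjacent stations
(`interpolate_station_gap()`), boundary gaps left missing.

All modules share one percentile convention: linear interpolation between
closest order statistics (R's type 7).

## Plankton-net validation (NBSS)

Theoretical tow volume is π r² × speed × duration — used because at low
tow speeds flowmeters under-rotate (readings ~60× too low render them
unusable). The normalized biovolume size spectrum divides the total living
biovolume per size class by the class width (mm³) and the sampled volume
(m³). Classes are log₂-spaced and anchored at 2⁰ mm³ — standard NBSS
practice, since the method reference leaves binning open. The spectrum
conserves total biovolume exactly and is linear in the sample, both asserted
as properties. Relative sampling efficiency between two nets is the mean ±
sd of per-class spectrum ratios over classes where both spectra are
positive. Slope recovery: an abundance density ∝ s^β yields a biovolume
density ∝ s^(β+1), so the log–log NBSS slope estimates β + 1; the fit
excludes classes with fewer than 5 objects because the sparse tail is
dominated by sampling noise.

## Synthetic data: what it emulates, and what it does not

* **SST series**: sinusoidal seasonal cycle + linear trend + stationary
  AR(1) noise (initialized from its stationary distribution — no burn-in
  artifact) + square/triangular events + geometric-length missing runs
  placed uniformly without overlap. Defaults emulate a tropical Pacific
  reef: 27 °C mean, 2 °C amplitude, 0.2 °C/decade trend, 0.25 °C noise with
  lag-1 autocorrelation 0.8, 5 % missing days in runs of mean length 5.
  Triangular events ramp linearly and symmetrically, giving non-trivial DHW
  accumulation profiles.
* **Velocity fields**: analytic uniform/solid-body/strain/divergent flows
  on a small equatorial 0.25° grid (local tangent-plane construction with
  pointwise cos(lat) scaling keeps the closed-form truth exact to well
  under the 10⁻³ test tolerances); the time-periodic double gyre is
  provided for qualitative Lagrangian structure only, with no closed-form
  truth claimed. An optional Rankine core on the solid-body flow gives a
  compact vortex in a strain-dominated far field for retention tests.
* **Multi-source tables**: satellite/model = slope·truth + intercept +
  noise with missingness. The default truth variable is centered near the
  origin (mean 2, sd 2): the intercept of a match-up regression is only
  statistically identifiable near the data's support — with an SST-like
  regressor centered at 27 °C the intercept standard error at n = 200 is
  ≈ 0.1, which would make intercept recovery at that tolerance a coin flip
  rather than a test.
* **Plankton samples**: truncated power-law biovolumes by inverse-CDF
  sampling (log-uniform at slope −1 exactly).

None of this emulates cloud masks, orbital sampling geometry, land masks,
mesoscale turbulence spectra, or plankton patchiness. Passing tests
demonstrate that the algorithms are correct against known truth and their
own stated conventions — not that the conventions are optimal for any
particular real-world product.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately modest
problems: 15–20-year daily SST series, 21×21-node velocity grids, stadium
seedings of a few hundred to ~700 particles, advective times up to 60 days,
n = 200 regression pairs, and 10⁴-object plankton samples. These sizes are
the package's own choice of the smallest problems on which every stated
tolerance is meaningful. Ties in percentiles follow type-7 interpolation;
all randomness is seeded, and the pipeline orchestrator derives one seed
per stage from a single master seed so reruns are byte-identical.

## Known limitations

* Climatology bins with no data in any year abort with a pre-interpolation
  instruction rather than being filled silently (Feb 29 alone is special:
  it is interpolated from its neighbors when the span contains no leap
  year).
* The advection grid is regular in lon/lat; near-polar domains would need a
  different metric treatment than the cos(lat) scaling used here.
* The betweenness network uses one particle per box (transition indicators,
  not densities); finer transport estimates would seed multiple particles
  per box.
* Station statistics assume the stadium fits inside the velocity-field
  domain; particles advected out of it reduce n rather than wrapping.
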