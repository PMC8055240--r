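---
title: "GammaBED: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GammaBED: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GammaBED)
```

## The biological problem

Gamma Knife radiosurgery delivers a single-session prescription as an
ordered sequence of iso-centres, each a focal dose distribution with
its own beam-on time, with short beam-off repositioning gaps in
between. The prescription is stated in physical dose, but sublethal
radiation damage repairs on the timescale of the delivery itself (the
fast repair half-time is on the order of ten minutes, comparable to a
multi-shot treatment), so the biological effect of a fixed physical
dose depends on *when* each voxel receives its dose. GammaBED makes
this dependence computable: per-voxel biologically effective dose
(BED), the cost of unscheduled interruptions, and the spread of BED
achievable purely by re-ordering the shots.

## The BED model

Each voxel `v` experiences an exposure protocol: one
constant-dose-rate segment per iso-centre, rate
`R_k(v) = d_k(v) / t_k` for the shot's dose contribution `d_k(v)` and
beam-on time `t_k`, separated by the plan's beam-off intervals. Under
the linear-quadratic model with incomplete repair,

$$\mathrm{BED}(v) \;=\; D_T(v) \;+\;
  \frac{c\,\Phi(\Xi,\mu_1) + (1-c)\,\Phi(\Xi,\mu_2)}{\alpha/\beta},$$

with the dose-protraction function

$$\Phi(\Xi,\mu) \;=\; 2\iint_{s<s'} R(s)\,R(s')\,
  e^{-\mu(s'-s)}\,ds\,ds'.$$

For piecewise-constant rates this expands in closed form into one
self term per segment,
$\phi_{self} = (2R^2/\mu^2)(\mu t - 1 + e^{-\mu t})$, plus one cross
term per segment pair,
$\phi_{cross} = (2R_jR_k/\mu^2)(1-e^{-\mu t_j})(1-e^{-\mu t_k})
e^{-\mu\tau_{jk}}$, where $\tau_{jk}$ is the beam-off time from the
end of segment *j* to the start of segment *k* on the absolute
timeline — so the interval between non-adjacent shots automatically
accumulates all intermediate beam-on and beam-off periods. The
published form of the model states the double-integral shell rather
than the expansion (and in particular leaves the placement of the
factor 2 implicit); we therefore treat the expansion as a claim to be
verified, not transcribed: `phiNumericOracle()` evaluates the double
integral by adaptive 2D quadrature over the piecewise-constant rate
function, and the test suite requires closed-form agreement to a
relative error below 1e-6 on randomized protocols under both repair
rates. The oracle shares no code with the closed forms and is never
used in the pipeline.

Two analytic limits bound every voxel: with all repair suppressed
(durations and intervals → 0) BED → $D(1 + D/(\alpha/\beta))$, the
acute value; with complete repair between shots BED →
$\sum_k d_k(1 + d_k/(\alpha/\beta))$; and as $\mu \to \infty$, BED
collapses to the physical dose. These limits, time-reversal
invariance of $\Phi$, strict monotone decrease of BED in any spanned
interval, and the bracketing of the bi-exponential BED by the two
mono-exponential ones are all asserted as properties in the tests.

### Parameters

`repairParams()` carries the four radiobiological constants:

| parameter | default | units | meaning |
|---|---|---|---|
| `alphaBeta` | 2.47 | Gy | tissue dose-squared sensitivity |
| `halfTimeFast` | 11.4 | min | fast repair half-time (0.19 h) |
| `halfTimeSlow` | 129.6 | min | slow repair half-time (2.16 h) |
| `partitionFast` | 0.98 | — | fraction of repair on the fast component |

The defaults are the collective two-component fit to rat spinal-cord
iso-effect data that radiosurgery BED analyses conventionally use; the
α/β of 2.47 Gy comes from the same fit (its 95% CI, 1.50–3.95 Gy,
spans the clinically conventional 2 Gy). `partitionFast = 1` recovers
the mono-exponential model. BED values are labelled with the α/β used
(Gy_2.47 by default). Units are fixed throughout: minutes, Gy,
Gy/min.

### Numerical choices

For $\mu t < 10^{-4}$ the factor $(\mu t - 1 + e^{-\mu t})$ is
evaluated by its Taylor series and $(1 - e^{-\mu t})$ via `expm1`, so
near-acute segments do not suffer catastrophic cancellation; the
acute-limit tests exercise durations down to $10^{-9}$ min. Voxels
with zero total dose are assigned BED 0. Zero-dose shots at a voxel
are kept as rate-0 segments (the timeline stays legible); a test
proves dropping them leaves $\Phi$ unchanged. Grid evaluation
(`bedGrid()`) is vectorised over voxels and is proven elementwise
equal to the per-voxel `bedVoxel()` loop.

## The prescription shell

Summaries are computed on the prescription isodose shell: all voxels
whose total dose lies within an absolute, inclusive ±0.02 Gy window of
the prescription (`extractShell()`), i.e. dose deviations below 0.17%
at 12 Gy and 0.16% at 13 Gy. The window is absolute because that is
how the comparison set is conventionally defined; it is configurable.
The shell depends only on the summed dose grid, so it is invariant
under re-ordering and gap edits and is extracted once per case. "Mean
BED on the shell" is the mean of per-voxel BED values, not the BED of
the mean dose — consistent with the per-voxel evaluation mandate. An
empty shell raises a warning at extraction and an error in any
summary, never a silent NaN.

## Gap analysis

`insertGap()` lengthens one inter-iso-centre beam-off period
*additively* (the interruption happens on top of the scheduled
repositioning gap), so the total treatment time grows by exactly the
gap duration and dose grids are untouched. `gapSweep()` simulates a
single 15-minute gap — roughly one fast repair half-time, a nominal
unscheduled-interruption duration — at each of the N−1 positions and
reports the relative change of shell-mean BED against the original
plan (the original plan is the reference; the alternative reading,
relative to the gapped plan, was rejected as inconsistent with "change
due to the gap"). Only single gaps are swept, matching the scenario
studied; `insertGap()` composes additively if multi-gap scenarios are
ever needed, but that territory is untested.

## Sequence search

`applySequence()` re-orders shots; beam-on times travel with their
shot while beam-off durations stay attached to schedule slots. The
slot-versus-shot attachment of gaps is genuinely underdetermined for
re-ordered deliveries; slot-attachment was chosen, and at the uniform
0.06 min default the choice is inert.

`exhaustiveSearch()` evaluates all n! orderings. The objective — mean
BED over the shell — makes this cheap: per-voxel pair magnitudes
$(2R_jR_k/\mu^2)(1-e^{-\mu t_j})(1-e^{-\mu t_k})$ are
permutation-independent, so their shell means are cached once per
case ($O(n^2)$ numbers per repair component) and each permutation
costs only the $e^{-\mu\tau}$ attenuation products: the 8! = 40,320
sweep takes well under a second on one CPU. Plans beyond the
configurable limit of 8 shots are refused with the sequence count they
would need (13 shots ≈ 6.2270e9), unless overridden. Ties are broken
to the lexicographically smallest permutation, and exhaustive results
are proven against a naive full-grid loop for 3 and 4 shots. Because
$\Phi$ is time-reversal invariant and slot gaps are uniform, every
ordering's BED equals its reversal's — extremes are always attained at
least twice.

The heuristics order shots by their mean shell dose-rate
(`shotMeanDoseRate()`): `heuristicMaxSequence()` fills schedule
positions outside-in with ascending rates so the strongest shots sit
contiguously mid-schedule (a pyramidal rate profile that preserves
their mutual incomplete-repair interaction); `heuristicMinSequence()`
alternates strongest-remaining and weakest-remaining so strong shots
are maximally separated. The published description of these rules is
verbal ("pyramidal", "spread out"); the concrete constructions here
are our determinizations — ties resolve to the original order, and
with no rate variation the original order is returned — validated by
the property that they always land within the exhaustive extremes,
rather than asserted to be the original authors' exact rule.

Cohort statistics (`cohortSummary()`) aggregate per-case rows: group
means, the min-to-max spread of achievable BED relative to the group
mean original BED, mean heuristic increase and decrease, the
between-group ratio of mean original BEDs, and two-sided paired
t-tests of the min-vs-max sequences (sidedness is not stated in the
source material; two-sided is the conservative choice). Identical
`x` and `y` give zero-variance differences and raise a degenerate-case
error from `pairedTTest()` rather than returning t = 0; the cohort
summary tolerates this by omitting the test. A "table ingest" mode
(`readCohortTable()`) accepts printed per-case values so the cohort
statistics are testable independently of the BED engine; a 15-case
vestibular schwannoma results table ships in `inst/extdata/`.

## The synthetic plan generator

Real inputs would be planning-system research exports (per-iso-centre
dose matrices and beam-on times), which are not distributable. The
generator (`makePlan()`, `makeCohort()`) reproduces the *statistical
structure* those exports feed into the analysis:

- 31×31×31 dose grids (0.5 mm spacing — a region of interest around
  the target), 4–19 iso-centres, total times 20.8–73.7 min, 6 cases
  at 12 Gy and 9 at 13 Gy per cohort, stratified so each cohort covers
  the time span and ordered by time within group;
- shots packed inside an ellipsoidal target with a minimum mutual
  distance d0 derived from target volume and shot count, Gaussian
  kernels of width ≈ 0.38–0.48 · d0 (clamped to the 4–16 mm collimator
  span) and near-equal amplitudes. This makes each margin voxel
  dose-dominated by its nearest shot — the feature of real plans that
  keeps per-voxel BED near its acute value and caps the damage a
  single gap can do. Width fractions well above ~0.5 were found to
  produce margins fed diffusely by many shots, with repair deficits
  and gap sensitivities far larger than clinical plans exhibit;
- the summed dose is rescaled so the prescription level sits on the
  flank level with the fattest ±0.02 Gy shell (at least 30 voxels);
- beam-on times are loosely tied to shot strength with a several-fold
  random spread, which carries the required ≥3× heterogeneity of
  per-shot mean shell dose-rates;
- infeasible draws (thin shell, failed packing, flat rate profile) are
  regenerated with fresh geometry — bounded retries, with the packing
  distance shrunk only after placement failures and kernel widths
  widened only after shell failures — and a clear error if the budget
  is exhausted. Everything is deterministic under the seed.

What the generator does *not* emulate: source-decay and collimator
physics (collapsed into amplitude/width heterogeneity — the BED
mathematics only sees rates and times), skull attenuation, plug
patterns, and the actual per-shot dose-rate profiles of any real case
(only their qualitative shape: a few dominant shots over a flatter
background). Passing the synthetic-cohort tests therefore shows the
pipeline reproduces the *kind* of gap and sequencing behaviour
clinical cohorts show — reductions of roughly 0.1–10%, pyramidal
re-sequencing helping in most cases, significant min-vs-max
separation — not the numbers of any specific patient series. An
`elongated` target preset (single long axis) exercises the geometry on
which rate-based heuristics are expected to underperform.

## Problem sizes and runtime

The test suite runs in seconds: quadrature-oracle comparison on 100
random protocols (≤5 segments), exhaustive searches to 8 shots,
heuristic-versus-exhaustive bracketing on 20 generated plans (4–7
shots), and two full 15-case cohorts with complete gap sweeps and
sequencing. A full 31³ BED grid for a 19-shot plan evaluates in well
under a second, so interactive use during planning review is
realistic.

## Known limitations

- Analyses are shell-based; whole-volume BED grids are computed
  (`bedGrid()`, `runBED()`) but the optimisation objective is the
  shell mean only.
- Gaps are modelled only between iso-centres, not within a shot's
  beam-on period.
- The heuristics use the mean shell dose-rate, which has no direct
  radiobiological meaning at the single-voxel level; they are search
  devices, bounded by the exhaustive extremes where those are
  computable.
- Repair parameters are treatment-wide constants; no tissue
  heterogeneity or parameter fitting.
- The bundle format deliberately avoids proprietary planning-system
  formats; DICOM-RT import is out of scope.
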