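# GammaBED

Biologically effective dose (BED) modelling for multi-iso-centre Gamma
Knife radiosurgery.

A Gamma Knife treatment delivers its prescription as a sequence of
iso-centres ("shots"), each with its own 3D dose distribution and
beam-on time, separated by short beam-off repositioning gaps. Clinical
prescriptions are stated as total physical dose only, yet sublethal
radiation damage repairs during the tens of minutes a multi-shot
delivery takes — so two plans with identical physical dose but
different timing, shot ordering, or unscheduled interruptions are not
biologically equivalent. GammaBED quantifies this for treatment
planners and medical physicists: it computes the per-voxel BED of a
plan, measures how much biological effect an unscheduled gap costs at
every possible position, and searches the space of shot delivery
orders for the BED-minimising and BED-maximising sequences.

## The model

Each voxel v sees an exposure protocol Ξ: one constant-dose-rate
segment per iso-centre (rate d_k(v)/t_k, duration t_k), separated by
beam-off intervals. Under the linear-quadratic model with
bi-exponential incomplete repair,

    BED(v) = D_T(v) + [ c·Φ(Ξ, µ1) + (1 − c)·Φ(Ξ, µ2) ] / (α/β)

where D_T is the voxel's total dose, µ1 = ln2/T½,fast and
µ2 = ln2/T½,slow are the fast and slow repair rates, and c is the
partition coefficient. The dose-protraction function

    Φ(Ξ, µ) = 2 ∬_{s<s'} R(s) R(s') e^{−µ(s'−s)} ds ds'

expands in closed form into per-segment self terms
(2R²/µ²)(µt − 1 + e^{−µt}) and pairwise cross terms
(2R_jR_k/µ²)(1 − e^{−µt_j})(1 − e^{−µt_k}) e^{−µτ}, with τ the beam-off
time between segments on the absolute timeline. The closed forms are
validated in the test suite against an independent adaptive-quadrature
oracle. Defaults (α/β = 2.47 Gy, half-times 11.4 and 129.6 min,
c = 0.98) are the rat spinal-cord collective fit commonly used for
radiosurgery BED work; all four are configurable.

BED summaries are taken on the prescription isodose shell — all voxels
within ±0.02 Gy of the prescription — so voxels receiving the same
physical dose are compared.

## Worked example

```r
library(GammaBED)

params <- repairParams()
#> RepairParams: alpha/beta = 2.47 Gy; repair half-times 11.4 / 129.6 min
#> (fast/slow); partition c = 0.98

plan <- makePlan(seed = 7, nShots = 8, prescription = 13, totalTime = 24)
shell <- extractShell(plan)
#> Shell: 33 voxels within +/- 0.02 Gy of 13 Gy

bed <- bedGrid(plan, params)
round(shellStats(bed, shell), 2)
#>    n  mean median   q25   q75   min   max
#> 1 33 69.81  73.42 63.73 75.91 56.23 78.37
```

Although every shell voxel receives 13 Gy physically, the BED spans
56–78 Gy_2.47: voxels whose dose arrives in one brief, high-dose-rate
shot approach the acute value 13(1 + 13/2.47) ≈ 81.4, while voxels fed
slowly by several temporally distant shots lose effect to repair.

```r
gapSweep(plan, params, duration = 15, shell = shell)
#>   position meanBED relChangePct
#> 1        1  67.405       -3.449
#> ...
#> 5        5  65.624       -6.001
#> 7        7  68.689       -1.610
```

A 15-minute interruption costs between 1.6% and 6.0% of the mean shell
BED depending on where it falls — the same gap is almost four times as
damaging between positions 5 and 6 (which separates the strongest
shots) as at the end of the delivery.

```r
ex <- exhaustiveSearch(plan, params, shell = shell)   # 8! = 40,320 orders
c(min = ex$min$meanBED, orig = ex$meanBEDOrig, max = ex$max$meanBED)
#>   min  orig   max
#> 68.31 69.81 72.18
deltaRel(ex$meanBEDOrig, ex$min$meanBED, ex$max$meanBED)
#> [1] 5.55
```

Re-ordering the same eight shots moves the mean shell BED across a
5.6% range with no change to the physical dose. `heuristicMaxSequence()`
(group high-dose-rate shots mid-schedule, "pyramidal") and
`heuristicMinSequence()` (spread them out) approximate these extremes
without enumeration, and `runSequence()`/`cohortSummary()` assemble
per-case tables and paired min-vs-max t-tests for whole cohorts.

`makeCohort()` generates a 15-case synthetic cohort (6 cases at 12 Gy,
9 at 13 Gy, 4–19 shots, 20.8–73.7 min) emulating the structure of
clinical plan exports, and `writePlanBundle()`/`readPlanBundle()`
persist plans as a JSON manifest plus one NIfTI dose volume per shot.
A thin CLI over these functions ships at `inst/scripts/gammabed`
(subcommands `simulate`, `bed`, `gaps`, `sequence`).

## Not in scope

Dose calculation physics (dose grids are inputs), DICOM-RT/planning
system connectivity, BED-optimised inverse planning, and clinical
outcome interpretation.
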