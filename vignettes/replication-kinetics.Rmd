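---
title: "Stochastic fork speeds and the dynamics of DNA replication"
author: "replifork"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic fork speeds and the dynamics of DNA replication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replifork)
```

## The model

Budding-yeast DNA replication initiates at ~400 origins with known genomic
coordinates. In G1, origins are *licensed* with a probability called the
competence $c^i$; during S phase a licensed origin *fires* at a stochastic
time and launches two divergent replication forks. Forks elongate until they
meet an oncoming fork, reach a chromosome end, or run into DNA that is
already replicated; origins overrun by a fork before their own firing time
are *passively replicated* and never fire.

`replifork` implements this mechanism as a per-cell Monte-Carlo draw
followed by deterministic kinetic propagation:

* the firing time of origin $i$ is
  $t_0^i \sim \mathcal{N}(\mu_t^i, \sigma_t^2)$, with a per-origin mean
  $\mu_t^i$ and one global firing-time variance $\sigma_t^2$, truncated to
  $t_0^i \ge 0$ by resampling;
* every fork -- including the two forks of the same origin -- gets its own
  constant speed $v \sim \mathcal{N}(\mu_v, \sigma_v^2)$, truncated to
  $v > 0$ by resampling;
* licensing is Bernoulli($c^i$), where $c^i$ is drawn once per condition,
  uniformly between the origin's measured efficiency and 1, and shared by
  all cells of that condition.

The distinguishing assumption is $\sigma_v^2 > 0$: fork speed varies
*between* forks while each individual fork is constant. Setting
`varV = 0` recovers the classical constant-speed model as a special case.

The observable the model targets is the *DNA track*: a maximal continuous
stretch of replicated DNA at the observation time $t_{exp}$, the quantity
measured (without genomic coordinates) by DNA combing.

## Closed-form track moments

For a single unobstructed fork of an origin with mean firing time $\mu_t$,
the replicated distance is $\Delta x = v \, \Delta t$ with
$\Delta t = t_{exp} - t_0$. When
$\sigma_t \sigma_v \ll \mu_{\Delta t}\mu_v$, the product of the two
Gaussians is itself approximately Gaussian with

$$\mu_{\Delta x} = \mu_v \, \mu_{\Delta t}, \qquad
  \sigma_{\Delta x}^2 = \mu_v^2\sigma_t^2 + \mu_{\Delta t}^2\sigma_v^2 .$$

`trackMoments()` returns these predictions and `sampleForkDistances()`
draws from the exact truncated sampling scheme for cross-checking. Two
consequences drive the package's analyses:

* with $\sigma_v = 0$ the second term vanishes, so a constant-speed model
  fitted to stochastic-speed data must inflate $\sigma_t^2$ to reproduce the
  observed track spread -- the compensation the fitting suite demonstrates;
* the *mean* track length is unaffected by $\sigma_v^2$, so speed
  stochasticity is invisible in averaged (population-wide) data and only
  shows up in single-molecule track distributions, increasingly so at later
  observation times.

Two track semantics coexist deliberately. The moment formulas describe a
*single fork's* distance; DNA combing sees the *full* two-fork (possibly
fused) track. `extractTracks()` returns the latter; inference that relies
on the former (the moment checks, the firing-time pipeline) halves full
widths under a left/right symmetry assumption or works directly with
per-fork records.

Exactness caveats, verified numerically in the tests: the product-normal
approximation ignores a $\sigma_v^2\sigma_t^2$ cross term (sub-percent in
the regimes used), and positivity truncation of the speed distribution
raises the realized mean speed by a few percent once
$\sigma_v \gtrsim \mu_v/2$ -- which is why "equal means" assertions use a
10% band at $\sigma_v^2 = 0.9$.

## The kinetic engine

Propagation uses a fixed time step (default `dt = 0.1` min, i.e. 0.15 kb at
1.5 kb/min -- far below the 1-kb analysis bin), but all events inside a step
are resolved by exact linear back-solution: fork--fork meeting points are
placed at the exact weighted collision point
(simultaneous multi-fork ties resolved leftmost first), chromosome-end
absorption times are exact, and firing-time coverage checks extrapolate
edge positions to the exact firing instant. Segment boundaries therefore
carry no systematic discretisation error; the test suite holds the engine
to an independent continuous-time event-driven oracle within one spatial
step and typically observes agreement at floating-point resolution.

Coordinates are 0-based kilobases with half-open `[a, b)` segments;
chromosome ends absorb forks. An optional per-minute fork termination
probability `pEnd` (used for hydroxyurea-like conditions) is implemented as
a pre-drawn exponential fork lifetime with rate $-\log(1-p_{end})$ per
minute, i.e. the continuous-time limit of a per-minute Bernoulli trial;
`pEnd = 0` (the default) disables it.

Each cell consumes its own counter-based RNG stream derived from the master
seed, so `simulatePopulation()` is bit-reproducible given
`(seed, nCells, params)`, cell $i$ is independent of how many cells were
requested, and results do not depend on R's global RNG state.

## The distance-dependent speed modifier

Stochastic firing occasionally leaves large origin-free gaps whose closure
dominates total replication time (the "random replication gap problem").
The package's empirical remedy accelerates an emerging fork according to
the distance $D$ to the nearest approaching fork:

$$v_{\mathrm{eff}} = \min\!\big(v \cdot f(D),\; 1.9\,\mu_v\big), \qquad
  f(D) = \min\!\Big(1.9,\; 1 + 0.9 \min(1, D/D_0)\Big),$$

with cap factor 1.9 and a ramp scale $D_0$ (default 100 kb, the scale of
the larger inter-origin gaps) at which the factor saturates. The factor is
evaluated once at fork birth against the nearest currently approaching
fork (falling back to the chromosome end when none approaches); a per-step
re-evaluation mode exists behind `reevalPerStep`. Only the monotone
dependence and the 1.9 cap are constrained by the data the modifier is
modeled after; the linear saturating ramp is this package's choice of the
simplest such form.

By default the modifier is a pure on-top acceleration: the base-speed
distribution keeps its configured mean $\mu_v$ (the global speed parameter
stays at the experimentally observed value) and only gap-facing forks are
boosted. An alternative `calibrateMean = TRUE` mode rescales the
base-speed distribution via a short pilot run (three fixed-point
iterations -- the cap makes a single-pass rescale insufficient) so that
the *realized* mean effective speed equals $\mu_v$. The default matters:
rescaling the whole distribution downward also slows the slow tail of the
truncated speed distribution, which is precisely what limits completion,
and in paired simulations the recalibrated modifier loses most of its
completion advantage while the acceleration-only form reaches 98%
completion about 10 minutes earlier on a yeast-scale genome. The absolute
$1.9\,\mu_v$ cap binds even at $D = 0$ for rare fast base-speed draws; we
accept this reading because the cap is stated as a property of the
resulting speed.

## Fitting and model selection

`fitReplicationParams()` minimizes the residual sum of squares (RSS)
between normalized 1-kb track-length histograms of simulated and target
samples with a real-coded genetic algorithm: tournament selection (size 3),
uniform crossover ($p = 0.5$ per gene), Gaussian mutation (sd 10% of each
bound range, per-gene probability 0.2) and 1% elitism. These operator
settings are this package's defaults, chosen for robustness; the search
problem itself only fixes the RSS objective, 1-kb binning and the
population-of-parameter-sets design (default 5000, scaled down in tests).
Every candidate is evaluated with one common derived seed
(common random numbers), making fitness deterministic within a run so the
GA does not churn on Monte-Carlo noise. RSS is computed on *normalized*
frequencies: raw counts would scale with sample size and make thresholds
meaningless. `selectModel()` applies the two-stage rule: admissible
candidates have RSS below a threshold, and among them the model whose mean
per-cell active-origin count is closest to the experimental target is
chosen (per-cell mean, with ties broken by RSS; a population-total
alternative can be computed from the same outputs).

The recovery experiment in the acceptance suite fits a synthetic combing
sample (one 600-kb chromosome, 20 origins, truth
$\mu_v = 1.5$, $\sigma_v^2 = 0.9$, $\sigma_t^2 = 9.7$) observed at 20 min,
mid-S for this fixture. The observation time matters for identifiability:
late in S phase most tracks are fusions of many origins and the histogram
flattens toward a near-degenerate shape that barely constrains the
parameters; mid-S tracks still carry the per-origin speed and firing-time
signal. $t_{exp}$ is held at its true value during the fit because a free
$t_{exp}$ trades off against $\mu_v$ through
$\mu_{\Delta x} = \mu_v(t_{exp} - \mu_t)$.

## Firing-time inference from copy-number profiles

For BrdU-type copy-number data the per-origin mean firing time is obtained
by the pipeline in `inferFiringTimes()`:

1. **Normalize**: one global scale factor anchors the signal at a
   calibration origin to its independently (qPCR-) known efficiency.
2. **Smooth**: Savitzky--Golay filtering (default window 11 grid points,
   polynomial order 3 -- wide enough to suppress noise, short enough to
   leave a ~10-bin peak undistorted); the smoothed argmax refines the
   origin position.
3. **Transform**: around an isolated origin the efficiency-scaled coverage
   at distance $d$ is the survival function
   $P(\Delta x \ge d)$ of the per-fork distance, so minus its derivative in
   $d$ -- computed on each flank and pooled -- is the per-fork distance
   density. The unreplicated baseline (0 for BrdU signal, 1 for absolute
   copy number) is subtracted first.
4. **Fit**: a least-squares Gaussian (Levenberg--Marquardt) whose mean
   estimates $\mu_{\Delta x}$; non-positive widths or flat segments are
   flagged and excluded rather than propagated.
5. **Invert**: $\mu_t = t_{exp} - \mu_{\Delta x}/\mu_v$, clamping negative
   results to 0 with a warning.

The transformation step assumes origins are far enough apart that flanks
do not overlap within the fitted window (the window is capped at half the
distance to the neighboring origin). The synthetic validation fixture
therefore uses ~100-kb spacing and an observation time at which mean
per-fork distances stay below half that spacing; under those conditions
the pipeline recovers generating firing times with Pearson $r > 0.95$.
Densely packed early-firing origin clusters violate the assumption and are
flagged by failed fits rather than silently mis-estimated.

## Population analytics

`timingProfile()` reports $t_{50}$, the median across cells of each
position's replication time (1-kb grid by default), computed from per-fork
records; local minima mark origins. `copyNumberAt()` converts the same
records into $1 +$ the replicated cell fraction, and its 1.5-crossing at a
position coincides with that position's $t_{50}$ by construction.
`completionCurve()`/`timeToFraction()` summarize whole-genome completion.

`slopeVsDistance()` quantifies the relation between local profile slope
and the distance to the inter-fork meeting zone: for each profile minimum
it regresses $t_{50}$ on position over the origin-proximal 35% of the
monotone run toward the adjacent maximum (least squares rather than a
two-point difference, for noise robustness) and reports apparent speed
against $D$, the min-to-max distance. The origin-proximal restriction is
deliberate: near the maximum the profile shape is dominated by the meeting
zone and by cell-to-cell heterogeneity, not by the emerging fork whose
speed the slope is supposed to reflect; using the full run dilutes and can
even invert the correlation. Two properties are exercised in the tests:
slopes vary substantially (CV > 0.1) even though speeds are drawn
independently of genomic location -- so profile slope is *not* a clean
local speed readout -- and the distance-dependent modifier raises the
slope-vs-$D$ correlation above the unmodified model's.

## The synthetic-data generator

`syntheticSpec()`/`makeOriginMap()`/`makeCombingSample()`/
`makeCopyNumberData()` emulate the three experimental inputs (origin
tables, combing track lists, BrdU copy-number profiles) at yeast scale:
16 chromosomes totalling 12 Mb, 400 origins at ~30 kb jittered spacing,
mean firing times uniform over 5--35 min, efficiencies Beta(5, 1.5)
(skewed high, mean ~0.77), fork speed 1.5 kb/min with variance 0.9
(kb/min)$^2$, firing-time variance 9.7 min$^2$, observation at 42 min.
Wild-type-like runs under these defaults complete ~50--80 min, and the
fitted-parameter scales match the wild-type regime. Tracks receive 1-kb
Gaussian measurement noise and a 1-kb detection limit emulating combing
resolution; profiles receive additive Gaussian noise and carry a
designated calibration origin whose true signal level is emitted as ground
truth. All generators are deterministic given the spec seed and always
return their ground truth.

What the generator does *not* emulate -- and what green tests therefore do
not establish about real data: location-dependent fork impediments
(replication fork barriers, non-B DNA), correlated origin firing, chromatin
context, finite fiber lengths in combing (tracks are never split by fiber
ends), and microarray-specific noise structure. Passing recovery tests
show the pipeline is self-consistent at realistic scales, not that real
data satisfy its assumptions.

## Numerical choices and degenerate inputs

* `dt = 0.1` min; halving it changes segment boundaries only at
  floating-point scale because within-step events are solved exactly.
* Truncation by resampling, never clipping: clipping would put point mass
  at 0 and distort exactly the variances the model fits.
* Histogram bins are half-open `[k, k+1)` kb; tracks below the detection
  limit (default 1 kb) are dropped *before* normalization.
* `rssDistance()` aligns histograms on the union of occupied bins;
  mismatched bin widths are an error, not a silent rebin.
* Degenerate Gaussians (`varV = 0` or `varT = 0`) short-circuit to their
  means; `tExp <= muT` is an error in `trackMoments()` (the origin has not
  fired on average); empty track samples and flat profile segments raise
  errors or flags rather than NaNs.
* GA bounds are hard: mutations are clamped, so boundary optima (e.g. a
  true `varV = 0`) remain reachable.

## Scales used in the shipped checks

The bundled verification runs are sized for a laptop-class machine: 10^6
draws for the moment checks, 1000 cells for tiling/monotonicity, a
population of 200 parameter sets for 30 generations at 500 cells per
evaluation on a 600-kb/20-origin fixture for the recovery experiment
(plus a 200 x 15 constrained run), 200 paired cells on the full 12-Mb
genome for the completion contrast, and 400 cells for the inference round
trip. The config default of 5000 parameter sets per generation matches the
scale the method is designed for and remains available unchanged.

## Known limitations

* Fork speed is constant per fork; within-fork speed changes (stalling,
  barrier pausing) are out of scope by design.
* The modifier's ramp shape is an ansatz constrained only by monotonicity,
  the 1.9 cap and mean preservation.
* `pEnd` is a phenomenological termination channel; broken forks are not
  restarted.
* The flank-derivative density transformation assumes isolated origins;
  the package flags rather than resolves overlapping-origin clusters.
* Active-origin counts are per-cell means; a population-total definition
  would differ in conditions with strong cell-to-cell licensing variation.
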