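---
title: "Quantifying representational drift in longitudinal calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying representational drift in longitudinal calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

One-photon calcium imaging can follow the same cortical neurons for weeks
while an animal performs a learned task. The scientific question the
package addresses is whether the neurons' task tuning is *stable* over
such periods or *drifts* — gradually re-mapping while behavior stays
constant. The concrete setting is a two-choice M-maze task: a mouse
samples an odor at a central port and runs to the left or right reward
arm. Every analysis operates on the linearized outward trajectory
(sampling port to reward, normalized to [0, 1]) and treats left-choice
and right-choice runs separately, because prefrontal cells are often
trajectory-specific.

`driftframe` implements the full analysis battery — trace preprocessing,
trajectory-specific tuning functions, drift metrics with shuffle nulls, a
drift surrogate model, population-vector geometry, cross-day decoders, an
encoding model with variance partitioning, and probabilistic longitudinal
cell registration — together with a synthetic-data generator whose ground
truth makes every stage testable by parameter recovery.

## The synthetic experiment

`generate_experiment()` draws a population of model neurons
(`ground_truth_cells()`) and simulates daily sessions
(`simulate_maze_trajectories()` + `synthesize_session()`):

```{r}
library(driftframe)
ex <- generate_experiment(n_cells = 100, n_sessions = 13, n_trials = 40,
                          drift = drift_config(p_drift = 0.1,
                                               noise_sd = 0.1,
                                               n_sessions = 13),
                          seed = 1)
```

Each cell has a place-field-like tuning bump (circular Gaussian on the
linearized position, width 0.08 by default), a left/right gain pair that
encodes side preference, an optionally direction-specific field center
(half the cells by default, giving genuinely trajectory-specific maps),
multiplicative speed-quartile and goal gains, and a per-day detection
probability. Per frame, the event rate is the product of amplitude, bump
and gains; events are drawn as Bernoulli thinning, convolved with a
single-exponential indicator kernel (tau = 0.7 s, GCaMP6f-like, with a
2-frame rise so transients have a resolvable rising phase), and the raw
trace receives a baseline offset, a slow sinusoidal baseline drift and
white noise, so that the preprocessing stages have genuine work to do.

Cross-day drift is a 1-bin circular shift of the field (on the 20-bin
outward grid) applied per session with probability `p_drift`; each cell
drifts in a fixed direction until its cumulative shift exceeds 10 bins,
after which steps are random -1/+1 so the field cannot wrap back onto its
origin. Drift can alternatively be parameterized per elapsed calendar day
(`per_day = TRUE`), which lets a schedule with a one-week pause express
the same expected drift as seven consecutive daily sessions — the
time-versus-experience contrast as a synthetic property. Activity dropout
is i.i.d. per day: the data cannot distinguish biology from focus drift,
so the simplest null is the honest one.

Defaults mirror the acquisition the analyses were designed for: 20 Hz
frames, ~40 trials per session, 40 cm arm length, 13 sessions over 24
nominal days. Footprints for registration are anisotropic Gaussian blobs
with a minimum 15 px centroid separation (somata are spatially
exclusive), sd 4–6 px, jittered per day.

What the generator does **not** emulate: raw movies (no pixel data —
footprints are generated directly), correlated noise across cells,
non-stationary behavior within a session, error-trial strategies, or any
specific biophysical indicator model. Passing parameter-recovery tests
therefore shows that the analysis code measures what it claims on data
obeying its assumptions, not that real cortical data obey them.

## Preprocessing

Raw traces are baseline-corrected with a running 10th-percentile filter
(30 s centered window; edges use the truncated window to avoid padding
artifacts) and standardized by *iterative z-scoring*: the mean (baseline)
and sd (sigma) are re-estimated after excluding samples above baseline +
3 sigma, until sigma changes by less than 0.1% ((sigma0 - sigma1)/sigma1
< 0.001; iteration cap 100). *Significant transients* are maximal runs of
z strictly above 3 lasting at least 0.2 s ("exceeding" is read as a
strict inequality; a run grazing 3.0 exactly is excluded). The *rising
phase* keeps each transient from threshold crossing to its first local
maximum; plateau peaks resolve to the plateau's first frame.

Numerical choice: the percentile filter is evaluated on a 1 s grid and
linearly interpolated in `preprocess_session()` (`stride` argument;
`baseline_correct()` itself defaults to exact per-frame evaluation). The
baseline is band-limited by the 30 s window, so the grid changes the
estimate by well under 1% of a noise sd while cutting an order of
magnitude of cost. Whether the 30 s window should be centered or causal
is not determined by the analysis definition; centered is used.

## Tuning, side index, spatial information

Tuning functions bin activity on 20 half-open bins of the linearized
outward trajectory (last bin closed), divide the binned signal by the
occupation probability and normalize to the peak bin. Unvisited bins get
occupancy 0 and are excluded pairwise from correlations; an all-zero map
is flagged and left unnormalized. Tuning correlations use the z-scored
traces; side index and spatial information use transient-masked signal —
the two conventions are kept distinct on purpose, following the analyses
they feed.

The side index is S = (a_l - a_r)/(a_l + a_r) with a_l, a_r the mean
transient signals on left and right runs; S is undefined (NA) for silent
cells. Spatial information is SI = sum_i lambda_i ln(lambda_i/lambda)
p_i, with lambda the occupancy-weighted mean rate (sum_i p_i lambda_i):
that convention makes SI exactly 0 for a uniform map, and 0 ln 0 := 0.

The divergence point of left and right trajectories interpolates each
run's linear position and x-coordinate by a factor of 10, bins x into 50
linear-position bins, and runs an equal-variance two-sample t-test per
bin with Bonferroni correction for 50 comparisons; the first significant
bin is the divergence point.

## Drift metrics and geometry

Cross-day stability is the Pearson correlation of each registered
neuron's tuning function between day 1 and a later day, computed per
direction, then averaged over directions and neurons. Its chance
reference permutes the neuron identities of day 1 (100 permutations by
default). The drift surrogate (`simulate_tuning_drift()`) applies the
same shift-with-probability model directly to observed tuning functions,
with additive per-bin Gaussian noise (sd 0 to 0.5) that accumulates
across sessions.

The population-geometry analysis takes the population activity vectors at
the start, midpoint and endpoint of the outward trajectory (bins 1, 10
and 20 of the same grid — the extremes plus the middle; the bins are a
`geometry_report()` argument) for each direction: 6 corner points in
neuron-dimensional space. At each corner, the 10 pairwise angles between
edges to the other 5 corners form a 6 x 10 edge-angle matrix (radians;
pair order is lexicographic in the far-corner indices — any fixed order
cancels in the differences). Dissimilarity between days is the Frobenius
norm of the matrix difference; it is normalized between the within-day
level (odd vs even runs, averaged over days) and the level of row- and
column-shuffled tuning, so 0 means "no more change than within a day"
and 1 means "as different as shuffled data". Angles are scale- and
rotation-invariant, which the test suite asserts with random orthogonal
maps.

## Decoders

Position: a linear epsilon-insensitive support-vector regression (cost
C = 1, epsilon = 0) maps single-frame population activity to linear
position, trained separately per direction on day 1 and evaluated as the
mean absolute error on the target day. Training frames are subsampled
evenly to at most 400 per direction: the quadratic-programming cost of
the SVR grows superlinearly with sample count while accuracy saturates
well below a full 20 Hz session. The chance reference retrains on
permuted training positions. Features are single frames (no smoothing
window) with no standardization beyond the pipeline's z-scoring.

Outcome: L2-regularized logistic regression (inverse regularization
C = 5) on per-trial per-cell mean center-epoch activity, trained on day 1
and tested on all trials of the target day; the null permutes target-day
labels (100 iterations). Variants implemented: leave-one-out decoding
within a day (with an option to restrict features to frames before the
divergence point), exhaustive single-cell leave-one-out decoding with a
0.5 z activity cut-off, and accuracy as a function of random subset size.

## Encoding model

The encoding model is a linear-link GLM — ordinary least squares on
one-hot categorical predictors, since the explained-variance criterion
(squared Pearson correlation between prediction and held-out data)
presupposes a continuous response. Predictors over the concatenated
correct outward-trial frames: position (50 bins; first and last kept,
the middle 48 merged into 6 contiguous groups of 8, for 8 levels — the
only equal partition consistent with that construction), per-animal
speed quartiles (4 levels) and goal (2 levels). Cross-validation chunks
the data in 5 s bins randomly assigned to 10 folds so training and test
frames are never adjacent; aliased (empty) factor levels are dropped per
fold with a log message.

Variance is partitioned three ways: single-predictor models; "shifted"
models in which one predictor is circularly shifted in time by a random
offset (offsets under 5 s are excluded to prevent near-identity shifts);
and "without" models with one predictor removed. A cell is significantly
modulated by a predictor when its delta-r2 (full minus without) exceeds
99% of a null distribution built from shifted-minus-without differences
(1000 draws by default; the test suite uses 200).

## Registration

Candidate cell pairs across sessions are gated by a centroid distance
below 31 px (a single fixed default for what is, in real data, a
per-dataset calibration) and scored by the Pearson correlation of their
footprint images on the union of supports. The correlation distribution
is fitted by a weighted sum of a lognormal component for same-cell pairs
— parameterized in (1 - r), since same-cell correlations crowd the upper
boundary — and a beta component for different-cell pairs, minimizing the
mean squared error against a 100-bin empirical density. P_same is the
posterior weight of the same component, with two safeguards: pairs in
the density gap where the mixture assigns essentially no probability get
P_same = 0 (the raw posterior there is a ratio of two vanishing tails),
and P_same is made non-decreasing in the correlation by a left-to-right
envelope, so a pair more similar than a typical same-cell pair can never
score below the component mode. Clustering is iterative: sessions in
chronological order, cells by descending mean footprint correlation;
each cell joins the cluster with the highest P_same above 0.95 (one cell
per session per cluster; ties broken by footprint correlation), or
founds a new cluster. "Repeatedly active" cells are clusters spanning
every session with the cell detected as active each day.

Image alignment (cross-correlation or optical flow on real movies) is out
of scope; synthetic footprints are generated pre-aligned with residual
jitter.

## Problem sizes and what the tests show

The unit tests run on small experiments (tens of cells, 2–4 sessions,
~20–40 trials) with oracle-verified expectations; the acceptance tests
use the sizes the properties are stated at — notably drift recovery on
200 cells x 13 sessions for p_drift in {0, 0.2, 0.5}, GLM calibration on
200 noise cells at 200 permutations, and registration on 100-cell
two-session data at 2 px jitter. `scripts/acceptance.R` runs the
end-to-end pipeline at 60 cells x 13 sessions with p_drift = 0.1,
noise 0.1 and per-day activity 0.95 (so about half the population is
active on all 13 days, matching the regime the analyses target).

Three measured behaviors deserve a note. First, the chance reference of
the position decoder: a converged linear SVR trained on permuted
positions predicts nearly a constant, so its MAE approaches the
best-constant error (~0.25 for uniform positions) when the training set
is much larger than the neuron count, and approaches the
independent-uniform error (~1/3) when the fit has enough freedom to
spread its predictions; at the package's operating point the measured
value is ~0.30. Second, the normalized edge-angle dissimilarity of
drift-free synthetic data converges to ~0 only once maps are estimated
from enough trials (40-trial sessions with >= 60 cells); at very small
sizes the within-day odd/even reference is itself noisy. Third, the
shuffled-identity null of the cross-day tuning correlation is not exactly
zero but ~0.05: the indicator kernel gives every z-based map a rightward
bleed tail and a shared edge structure, so maps of *different* neurons
correlate slightly in expectation. The shuffle permutation is
fixed-point-free (a derangement), so this residual reflects genuine
common map structure, not self-matches.

## Known limitations

- The forward model is a stand-in: no claim is made that synthetic traces
  match any particular indicator's noise spectrum or kinetics, and
  synthetic traces are never compared to recorded ones.
- The registration module assumes pre-aligned footprints; it measures the
  matching model, not image registration.
- The parametric P_same posterior is only meaningful where the mixture
  has density; the safeguards above make the gap behavior conservative
  (pairs there are treated as different).
- Single-frame decoding features ignore temporal correlations introduced
  by the indicator kernel; decoder accuracies are therefore specific to
  this feature convention.
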