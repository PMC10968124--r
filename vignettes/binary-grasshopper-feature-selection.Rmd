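---
title: "Binary grasshopper optimization for wrapper feature selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary grasshopper optimization for wrapper feature selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgoafs)
```

## The problem

Wrapper feature selection searches the $2^D - 1$ non-empty subsets of $D$
features for one that minimizes the out-of-sample error of a classifier
trained on it, traded off against subset size.  `bgoafs` scores a 0/1 mask
$S$ by

$$\mathrm{fitness}(S) \;=\; \alpha \,\mathrm{Err}(S) \;+\; \beta\,\frac{|S|}{D},
\qquad \alpha = 1 - \beta,$$

where $\mathrm{Err}(S)$ is the hold-out misclassification rate of a
$k$-nearest-neighbour classifier restricted to the columns in $S$.  The
defaults $\alpha = 0.99$, $\beta = 0.01$ are the de-facto standard in the
binary feature-selection literature: the size term only breaks ties between
subsets of (nearly) equal error.  Because the weights are never dominated by
the size term, `weight_beta` matters mostly through the error quantization
of the evaluation split — with $m$ evaluation samples, errors move in steps
of $1/m$, so $\beta/D < \alpha/m$ keeps error strictly prioritized.

## Continuous grasshopper dynamics

The swarm of $N$ grasshoppers carries continuous positions
$X_i \in [lb, ub]^D$.  Pairs interact through the social-force kernel

$$S(r) = f\,e^{-r/l} - e^{-r},$$

repulsive at short range, attractive at long range, with a zero crossing
(the *comfort zone boundary*) at $r = 3\ln 2 \approx 2.079$ for the default
$f = 0.5$, $l = 1.5$.  Each iteration the pairwise Euclidean distances are
affinely normalized into $[1, 4]$ — an interval that straddles the comfort
boundary, so the swarm always contains both attracting and repelling pairs —
and every grasshopper takes the step

$$\Delta X_{id} = c \sum_{j \ne i} c\,\frac{ub - lb}{2}\,
  S(\hat d_{ij})\,\frac{x_{jd} - x_{id}}{\hat d_{ij}},
\qquad X_{id} \leftarrow \Delta X_{id} + T_d,$$

where $T$ is the incumbent best solution and $c$ shrinks linearly from
$c_{\max} = 1$ to $c_{\min} = 10^{-5}$ over the $L$ iterations, collapsing
the swarm onto $T$ as the run ends.  Both multiplicative coefficients are
the same $c$; the kernel argument and the unit-vector denominator both use
the *normalized* scalar distance $\hat d_{ij}$, so the kernel is always
evaluated where it is well-behaved and the degenerate case
$d_{ij} = 0$ cannot reach a division.  When all pairwise distances are
equal (e.g. a fully collapsed swarm) the affine map is undefined and every
pair is assigned the interval midpoint 2.5; a swarm of one has no pairs and
takes a zero social step.  Proposed positions are clipped to the box — the
positions feed periodic (sine) and odd (arctan) transfer functions, and
clipping keeps their arguments in a fixed range.

## From continuous positions to bit masks

A transfer function maps a coordinate to a probability in $[0, 1]$ used to
set or flip the corresponding bit.  The package ships ten variants behind
one name vocabulary (`transfer_variants()`):

* **S-shaped baselines** `s1`–`s4`: sigmoids $1/(1+e^{-x})$,
  $1/(1+e^{-2x})$, $1/(1+e^{-x/2})$, $1/(1+e^{-x/3})$ under the *set-rule*
  (bit $\leftarrow 1$ with probability $T(x)$).
* **V-shaped baselines** `v1`–`v4`: $|\mathrm{erf}(\tfrac{\sqrt\pi}{2}x)|$,
  $|\tanh x|$, $|x/\sqrt{1+x^2}|$, $|\tfrac{2}{\pi}\arctan(\tfrac{\pi}{2}x)|$
  under the *flip-rule* (bit complemented with probability $T(x)$).
* **`tvg`** (default): a two-stage time-varying binarization.  First the
  sine transfer $|\sin(x/\alpha)|$ sets bits by the set-rule; then the
  V-shaped-plus-Gaussian transfer
  $\min\{1, \max\{0, |\tfrac{2}{\pi}\arctan(\tfrac{\pi}{2}x/\beta)| +
  \mathcal N(0, \sigma)\}\}$ complements bits by the flip-rule.

Three linear schedules steer the time-varying stage from exploration to
exploitation: $\alpha$ *increases* over $[\alpha_{\min}, \alpha_{\max}] =
[0.05, 5]$, while $\beta$ and $\sigma$ *decrease* over $[0.05, 10]$ and
$[0.01, 10]$ respectively.  Early on, a tiny $\alpha$ makes the sine stage
oscillate rapidly (near-random bits) and a large $\sigma$ randomizes the
flip probabilities; late in the run the sine stage is nearly flat, the
V-shape is steep and the Gaussian mutation has faded to $\sigma = 0.01$.

Three choices here were genuinely open and are resolved as follows:

* $\sin(x/\alpha)$ can be negative; a signed value is not a probability, so
  the absolute value is taken (transfer functions must map into $[0, 1]$).
* The Gaussian term can push the TVG value outside $[0, 1]$; it is clipped
  rather than wrapped or resampled, the least surprising bounded map.
* An $\alpha$ range printed as $[0, 5]$ would divide by zero at the start
  of the schedule, so $\alpha_{\min}$ uses a small positive floor (0.05),
  configurable in `transfer_schedule()`.
* $\mathcal N(0, \sigma)$ is parameterized by standard deviation, with one
  independent draw per individual, per dimension, per iteration.

Transfers are applied to the updated continuous *position* (not the raw
step vector) for all ten variants, so every variant shares a single
binarization input.

## The search loop

`bgoa_optimize()` initializes positions uniformly in the box, thresholds
them at the box midpoint into initial masks, evaluates everyone, and keeps
the best mask as the target $T$.  Each of the $L$ iterations then updates
$c$ and the schedules, moves the swarm, binarizes, repairs any empty mask
(the bit with the largest absolute coordinate is forced on; first index on
ties), re-evaluates, and replaces $T$ only on *strict* improvement — ties
keep the incumbent, which makes the best-fitness trace well-defined and
nonincreasing.  Evaluation is synchronous: all positions move before any
mask is rescored.  Fitness is called exactly $N(L + 1)$ times.

All randomness flows from R's generator seeded once per run; draws are
consumed in a fixed documented order (initial positions, then per iteration
the sine uniforms, flip uniforms, and Gaussians, individual-major and
dimension-minor), so a run is bit-for-bit reproducible from its seed, and
`run_experiment()` derives run $i$'s seed as `seed + i - 1`.

## The wrapper objective

`fs_problem()` fixes a stratified split once per run (80/20 hold-out by
default; a 50/30/20 train/validation/test scheme via
`split_spec("three-way")`, where the validation part scores the search and
the test part is only reported at the end), min-max scales features using
*training* statistics only (zero-range columns collapse to 0, so constants
carry no distance), and evaluates masks with a deterministic KNN:
Euclidean distance, majority vote over the $k = 5$ nearest neighbours,
distance ties broken by training-row order and vote ties by the nearest
neighbour's label among the tied classes.  The determinism is a contract —
it is what makes exhaustive-oracle comparisons and byte-identical replays
possible — and is why the classifier is implemented in the package (with a
compiled kernel in `src/`, as KNN implementations usually are) rather than
delegated to an implementation with randomized tie-breaking.  A pure-R
reference implementation with identical semantics is kept and
cross-checked in the test suite, alongside an external check against
`class::knn` on tie-free instances.  `k = 5` is a robust small-$k$ default;
$k$ must stay below the training-set size.

## Synthetic data and what it does (not) show

`generate_dataset()` emulates the structure the wrapper assumes: a minority
of informative columns, optional redundant columns, and pure noise.
Informative columns are class-conditional Gaussians with unit within-class
standard deviation; `class_separation` is the *Euclidean distance between
adjacent class means in the informative subspace*, i.e. each informative
dimension contributes a spacing of `class_separation / sqrt(n_informative)`.
This joint definition makes informative features individually weak but
jointly strong — exactly the regime where subset search beats univariate
ranking; defined per-dimension instead, one feature would suffice at
moderate separations and the size penalty would make singleton masks
optimal, which defeats the purpose of the generator.  Redundant columns are
random $\pm$[0.5, 1.5]-weighted linear mixes of the informative block plus
10% relative Gaussian noise; Gaussian class-conditionals were chosen as the
simplest structure under which KNN is consistent.  Columns are shuffled
with a recorded permutation and the ground truth is stored in
`informative_mask`.

Passing tests on this generator show that the optimizer recovers planted
low-dimensional structure under Gaussian noise.  They do not show
robustness to heavy-tailed features, label noise, strongly unbalanced
classes, or the autocorrelated feature blocks of real biomedical panels —
real datasets should be run through the CSV reader and judged on their own
validation errors.

`exhaustive_best_subset()` enumerates all non-empty masks (refused above
$D = 16$) with *the same* split, scaling and classifier as the optimizer,
so its minimum is a true lower bound for any search result under identical
seeds.

## Validation problem sizes

The shipped validation suite uses deliberately small study sizes: the
oracle-equivalence check runs $n = 60$, $D = 8$ (3 informative,
separation 4), population 20, 50 iterations over seeds 1–20 against the
255-mask enumeration; the recovery check runs $n = 200$, $D = 10$ with the
same swarm sizes (population and iteration budget chosen once to match the
oracle study).  The runtime-scaling check measures one doubling in each of
$L$, $N$ and $D$ from a base of $L = 30$, $N = 10$, $D = 64$ on
$n = 1000$ samples — sized so the per-evaluation KNN distance work
dominates interpreter overhead — and interleaves base and doubled runs,
keeping the minimum of four timings per arm to suppress one-sided timer
noise.  The expected cost is $O(L \cdot N \cdot (C_{\mathrm{eval}} + D))$;
with the KNN evaluation linear in the number of selected columns the
doubling slopes should all sit near 1.

## Metrics

`run_statistics()` reports the across-run mean best fitness, mean accuracy
of the best subsets, and the mean feature-selection ratio (subset size over
$D$).  `confusion_metrics()` computes TPR, PPV, TNR, NPV and ACC from
binary confusion counts, reporting an index as `NA` when its denominator
is zero rather than substituting 0 — this keeps identities such as
$\min(\mathrm{TPR}, \mathrm{TNR}) \le \mathrm{ACC} \le \max(\mathrm{TPR},
\mathrm{TNR})$ true whenever both sides are defined.  For more than two
classes `classification_indices()` macro-averages one-vs-rest TPR/PPV/
TNR/NPV (undefined classes excluded), but reports *overall* accuracy
rather than a macro-average of one-vs-rest accuracies: the latter inflates
towards 1 as the class count grows and does not measure the fraction of
correct predictions.  Binary inputs reduce to the plain definitions
exactly.

## Known limitations

* The swarm interaction is $O(N^2 D)$ per iteration; for the small
  populations customary in wrapper selection (20–40) this is negligible
  next to the $N$ classifier evaluations, but very large swarms would
  change the balance.
* Only a KNN wrapper ships.  The objective contract (`mask` in, finite
  fitness out) accepts any user-supplied evaluator, and `fs_problem()` is
  the template for plugging in a different classifier.
* Late in a run the comfort coefficient is tiny and all continuous
  positions sit near the target; exploration then rests entirely on the
  transfer schedules.  With the default ranges the final-iteration flip
  probabilities do not vanish, so the search never fully freezes — an
  intentional property of the time-varying design.
* Hold-out errors on small evaluation sets are quantized; with fewer than
  ~50 evaluation samples, distinct masks frequently tie at zero error and
  the size term alone decides among them.
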