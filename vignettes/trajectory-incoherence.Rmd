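---
title: "Trajectory incoherence: detecting deterministic drift in multi-trial dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory incoherence: detecting deterministic drift in multi-trial dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajcoh)
```

## The problem

Repeated measurements of a dynamical process -- neural population activity
across trials of a task, daily cycles of atmospheric chemistry, repeated runs
of any multi-stable system -- rarely repeat exactly. The scientific question
this package addresses is *why*: is the trial-to-trial variability driven by
a slow, deterministic change of the underlying dynamics (a *non-autonomous*
system whose parameters drift in time), or is it stochastic fluctuation
around a fixed law? Standard per-trial statistics (classification error,
Wilks' $\Lambda$, divergences between posterior distributions, moment tests)
are largely blind to sufficiently subtle parameter drift, because the
single-trial distributions barely move.

The package's core statistic, the **trajectory incoherence** (TI), exploits
the one thing i.i.d.-style statistics ignore: the temporal coherence of whole
trajectories relative to the attractor structure of the dynamics.

## The canonical benchmark: a drifting double well

The benchmark generator simulates the damped, unforced Duffing oscillator

$$\dot x = y,\qquad \dot y = -\delta y + \alpha x - \beta x^3 ,$$

which for $\alpha,\beta,\delta > 0$ has a saddle at the origin and two
attracting equilibria at $(\pm\sqrt{\alpha/\beta},\,0)$ -- spiral sinks when
$\delta^2 < 8\alpha$. Each trajectory starts from an isotropic Gaussian
initial condition centred at the origin and is integrated for $N$ samples;
its **class** ($\pm 1$) is the sink its continuation converges to, decided by
a long-horizon integration oracle with a capture rule (radius
$0.05\sqrt{\alpha/\beta}$ around a sink at speed below $10^{-3}$). The basins
of attraction interleave in spiral bands, so the two classes are not linearly
separable in the phase plane.

Non-stationarity is modelled as a *per-trial* increment of the cubic
coefficient, $\beta_k = \beta + (k-1)\varepsilon$ on trial $k$. Growing
$\beta$ pulls the sinks together (inter-sink distance $2\sqrt{\alpha/\beta}$)
while preserving the qualitative dynamics; bifurcating parameter changes are
rejected by construction, since abrupt regime changes are detectable by
ordinary change-point methods and are not the phenomenon of interest.

### Default study conditions and why

The generator's defaults define the study conditions used throughout the
tests and the acceptance analyses:

| parameter | default | rationale |
|---|---|---|
| $\alpha,\beta$ | 1, 1 | canonical two-sink well, sinks at $\pm 1$ |
| $\delta$ | 0.9 | moderately damped spirals: the basin boundary curves visibly but winds only a few times inside the sampled region, so a low-order polynomial boundary can essentially separate the classes (per-vector error $\approx 1\%$). At light damping (e.g. $\delta = 0.25$) the basin spiral is so finely interleaved that *no* low-order expansion separates it (error above 10%), which contradicts the regime the method is designed for -- a classifier that is near Bayes-optimal on the reference trial. |
| $dt$, $N$ | 0.05, 100 | a 5-time-unit observation window, roughly the relaxation time at $\delta=0.9$: typical trajectories settle within the window while marginal (near-boundary) trajectories commit only near its end -- the regime in which the TI tail rule is informative |
| $\sigma$ | 1 | initial conditions span the saddle region and the first basin windings (draws reach out to about four standard deviations) |
| $\varepsilon$ | 0.01 | small enough that single-trial statistics stay quiet (the drift bands are thin, so flipped trajectories commit late and only their tails are misclassified), large enough that at least one of 1000 trajectories flips basin within a 14-trial schedule |
| trials | 14 | a 14-trial schedule, evaluated on trials 2..14 |
| $L$ | $0.1\,N$ | convergence tail (below) |

These values are the package's own calibration of the qualitative
phenomenology the method requires; all are overridable.

## TI, CE, and the bound chain

Fit a classifier $f$ on a reference trial. For a trajectory
$x_1,\dots,x_N$ of class $c$, the trajectory is **convergent** if its last
$L$ predicted labels all equal $c$ -- it has settled into the region of
state space assigned to its class. The per-trial statistics are

* **TI** -- the fraction of trajectories that are *not* convergent, and
* **CE** -- the fraction of individual vectors misclassified.

Their different sensitivity to drift is arithmetic. If a parameter
perturbation flips the basin of exactly one of $D$ trajectories, that
trajectory's tail settles at the other attractor, so TI moves by exactly
$1/D$; and if (as for late-committing marginal trajectories) only its last
$L$ of $N$ vectors are misclassified, CE moves by only $(L/N)\cdot(1/D)$.
When all errors are tail errors, $CE = (L/N)\,TI$ exactly. TI therefore
reacts to a deterministic drift roughly $N/L$ times more abruptly than CE --
and, unlike CE, it collapses to noise when the temporal order inside
trajectories is destroyed, which is what the surrogate tests exploit.

### The reference frame

In the trial-wise protocol (`trialwise_protocol()`) the discriminant is
fitted on the reference trial and frozen. Later trials are evaluated against
the *reference frame*: each trajectory is labelled by the basin its initial
condition belongs to under the **reference** trial's parameters, while the
trajectory itself evolves under the drifted parameters. This is the frame in
which the bound chain above holds: a trajectory whose basin changed carries
its old label but settles at the new attractor, so exactly its tail is
misclassified. (Evaluating against each trial's own labels is available via
`label_frame = "generation"`; in that frame a basin flip changes the label
*and* the trajectory together, so the near-sink tail is classified correctly
and TI is insensitive by construction.) The generator therefore stores both
labels per trajectory: `class` (own dynamics) and `class_ref` (reference
dynamics).

## Reconstructing the state space

Basins of a nonlinear flow are generally not separable in the raw phase
space, so classification happens in a polynomial feature space: all
monomials of total degree $\le p$, scaled by square-root multinomial
coefficients so that the dot product of two feature vectors is exactly the
inhomogeneous polynomial kernel $(1 + x\cdot z)^p$ -- a Mercer kernel. The
implementation uses the explicit map whenever the expanded dimension
$\binom{d+p}{p}$ is moderate ($\le 2000$) and the kernel dual form otherwise;
both solve the same regularized problem and agree exactly on predictions
(this equality is tested). For multivariate recordings (e.g. binned spike
densities) a delay-coordinate map can precede the expansion
(`delay_embed()`, defaults: one lag of one bin).

The classifier is a regularized Fisher discriminant in that space: the
discriminant direction $w = (S_w + r I)^{-1}(m_2 - m_1)$ with
$r = \lambda\,\overline{\mathrm{diag}(S_w)}$. The ridge is *scale-relative*
(proportional to the mean diagonal of the within-class scatter) so a single
dimensionless $\lambda$ is comparable across expansion orders; no feature
standardization is applied -- the kernel itself defines the geometry.
Posterior scores come from class-conditional Gaussians fitted to the
projected training scores (empirical priors), with the decision at their
equal-posterior point; a midpoint-of-means threshold is available as an
option. For $K > 2$ classes the top $K-1$ generalized eigendirections are
Gram-Schmidt orthonormalized and decisions are by nearest projected class
mean. The penalty $\lambda$ is tuned on an independent validation block by
minimizing TI, with ties broken toward stronger regularization.

### Choosing the expansion order

`select_expansion_order()` sweeps the order, tunes $\lambda$ per order, and
runs 20-fold trajectory-blocked cross-validation of TI (folds never split a
trajectory). Because the polynomial spaces are nested, the mean CV TI is in
practice non-increasing in $p$ up to estimation noise, so a strict argmin is
unstable; the default selection is the **one-standard-error parsimony
rule** -- the smallest order whose mean CV TI lies within one SEM of the
minimum, i.e. the space of lowest dimensionality that already attains the
optimal out-of-sample trajectory coherence. For the cubic Duffing flow the
informative transition is from order 2 to 3: the basin boundary's curvature
is cubic at leading order, and even-degree terms are useless by the $x
\mapsto -x$ symmetry of the well (orders 1 and 2 perform alike, as do 3 and
4 -- a structure visible in the sweep tables). At the default study
conditions the stationary problem is solved at the TI floor from low orders
on, so the parsimony rule may legitimately return an order below 3.

## Surrogate nulls

Two null constructions certify that a TI trend reflects non-autonomous
deterministic dynamics:

* `shuffle_within_trajectories()` permutes the vector order inside each
  trajectory. The vector multiset per trajectory is conserved, so any
  pointwise classifier's CE is *bit-identical*; but the tail of a shuffled
  trajectory is a random sample of its whole path, so tail-concentrated
  errors are diluted ($q^L$ for per-vector error rate $q$) and the TI trend
  disappears.
* `random_drift_surrogate()` redraws each trial's $\beta$ i.i.d. uniformly
  over the deterministic schedule's range: deterministic within-trial
  dynamics, stochastic across-trial parameters. No systematic basin creep
  accumulates, so TI shows no trend.

`surrogate_battery()` wraps either mode into an empirical null distribution
(default 200 replicates) with add-one empirical p-values,
$(r+1)/(n+1)$. The decision logic: a significant TI trend in the observed
data, absent in both surrogates, is the signature of deterministic drift;
`run_pipeline()` reports exactly this flag.

## Supporting statistics

* `psr_test()` -- an evolutionary-spectrum stationarity test: the series is
  segmented in time, log-periodogram ordinates are averaged in frequency
  bands, and because the log of a (scaled) $\chi^2_2$ ordinate has known
  variance $\pi^2/6$, the two-way decomposition of the time-by-frequency
  table gives chi-squared tests for the between-time effect and the
  interaction. The default 6 x 6 layout needs a few hundred samples per
  segment; no data taper is applied by default so that the known-variance
  calibration holds (a Hann taper is available, at the cost of correlated
  ordinates). Calibration (type-I error at nominal level on white noise) and
  power (variance step) are asserted in the test suite.
* `wilks_lambda()`, `js_divergence()`, `certainty_measure()` -- the
  conventional per-trial separation measures TI is compared against; in the
  univariate two-group limit $\Lambda = 1/(1 + t^2/(n-2))$, an identity used
  as a test oracle.
* `trial_comparison()` -- the Lilliefors-gated two-sample rule: Welch t when
  normality is accepted for both samples, Mann-Whitney U otherwise.
* `lilliefors_test()` -- normality against estimated Gaussian parameters
  (wrapping the standard Dallal-Wilkinson approximation).

## The spike-train pathway

Neural recordings enter as per-unit spike-time lists
(`read_spike_events()`). `spike_density()` convolves each unit's spikes with
a Gaussian of per-unit bandwidth (plug-in selection via `select_bandwidths()`,
Sheather-Jones with a Silverman fallback) and averages the intensity within
100-ms bins (the bin value is the exact Gaussian-mixture average over the
bin, so density mass equals spike count up to edge truncation). The binned
rate matrix, optionally delay-embedded, then feeds the same expansion /
discriminant / TI machinery.

## Numerical choices

* **Integration**: fixed-step classical Runge-Kutta (RK4) for dataset
  generation -- bit-reproducible and, at the default $dt$, converged to well
  below the capture tolerances (step-halving and an adaptive Dormand-Prince
  reference are asserted in the tests). Divergence beyond $|x| = 10^6$
  errors out.
* **Labelling oracle**: continuation at step 0.1 up to 400 time units;
  undecided trajectories raise an error rather than a guess.
* **Seeds**: one root seed; all random streams (initial conditions per
  trial, folds, shuffles, surrogate draws) are derived with a counter-based
  scheme, so adding trials or replicates never perturbs existing draws, and
  every derived seed stays below $2^{31}$.
* **Degenerate inputs**: singular scatter without regularization, empty
  trials, constant samples, too-short series and schema-violating files all
  raise informative errors; they are exercised in the tests.
* **Tie-breaks**: $\lambda$ ties go to the stronger penalty; order ties go
  to the smaller order (parsimony).

## What the synthetic generator does and does not emulate

The Duffing benchmark reproduces the features the method needs: multiple
attractors, interleaved basins, trial-structured sampling, and a
parametrically drifting (or randomized) generating law with exact
ground-truth labels. The multi-class epoch generator
(`generate_multiclass_epochs()`) adds a rotating multi-attractor layout as a
desk-scale analogue of task-epoch data. Neither emulates key features of
real recordings: observation noise and missing data, non-Gaussian and
non-stationary within-trial noise, unknown and high-dimensional state
spaces, or attractors that are themselves transient. Green tests on the
synthetic conditions therefore certify the statistic's behaviour under its
own assumptions -- not performance on any particular real dataset.

## Problem sizes used in the shipped analyses

The acceptance analyses use the full default block (1000 trajectories of
100 patterns; 20-fold CV; 14-trial schedules; 20 replicate experiments for
the trend properties; 500 Monte-Carlo series for the test calibrations).
Unit tests use scaled-down blocks (tens of trajectories) of the same
generators.

## Known limitations

* TI presumes a meaningful trajectory segmentation and an attractor-like
  class structure; on genuinely i.i.d. data it reduces to a noisy function
  of CE and adds nothing (by design -- that contrast *is* the diagnostic).
* The tail length $L$ trades sensitivity against noise: too small and TI
  saturates at 0 on converged data, too large and it approaches a per-vector
  statistic. Results should report $L$; the default is $0.1\,N$.
* The kernel dual form is implemented for binary problems; multi-class fits
  use the explicit map (ample for the expansions used here).
* The PSR test assumes enough samples per segment for periodogram
  asymptotics; it is a large-sample tool.
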