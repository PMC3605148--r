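---
title: "Reconstructing past changes in locus-specific recombination rates"
author: "recombpast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing past changes in locus-specific recombination rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombpast)
```

## The problem

Linkage-disequilibrium (LD) methods estimate a *long-term average* of the
population recombination rate $\rho = 4 N_e r$ of a locus. But recombination
rates are transient: hotspots are born and die, so the historical average can
be a poor description of any particular epoch. This package implements a
simulation-based framework for asking a sharper question: *has the
recombination rate of this locus changed through time, and in which
direction?*

The core idea is **n-tuple subsampling**. Polymorphisms in a sample have very
different ages; so do the genealogical paths connecting random subsets of
lineages. A small subsample (a quartet, $n$-tuple of 4) of closely related
lineages carries information about *recent* recombination; a subsample
spanning deep branches mixes old and recent signal. Repeatedly drawing
subsamples and recomputing recombination-sensitive summary statistics on each
therefore yields feature *distributions* whose shape encodes when
recombination happened — not just how much. A discriminant classifier trained
on simulated datasets with known recombination histories can then assign an
observed locus to a history (constant, increasing, decreasing), with accuracy
evaluated by leave-one-out (jackknife) cross-validation.

## The model

### Coalescent with a time-varying recombination rate

Datasets are generated under the Kingman $n$-coalescent with crossover
recombination for a neutrally evolving, panmictic, constant-size diploid
population ($N_e$ diploids). Time is measured in units of $2 N_e$
generations, in which a pair of lineages coalesces at rate 1; among $k$
lineages coalescence occurs at rate $k(k-1)/2$, each lineage recombines at
rate $(\rho(t)/2)\,\ell$ where $\ell$ is the breakable span of its ancestral
material (the distance between its leftmost and rightmost ancestral sites;
events in trapped non-ancestral material are counted, the convention of the
classic `ms` simulator), and infinite-sites mutations fall on the recorded
ancestral branches at rate $\theta/2$ per unit time per unit sequence length.
With $\theta = 4 N_e \mu L$ this reproduces Watterson's
$\mathbb{E}[S] = \theta \sum_{i<n} 1/i$, which the test suite checks, along
with distributional agreement with an independent coalescent simulator
(msprime) at matched parameters.

The only nonstandard ingredient is that $\rho(t)$ follows a **rate profile**
backward in time. A `RateProfile` has a change window of $T = 10^4$
generations (default) and one of four shapes — constant, linear, exponential,
logistic — normalized so that the *time-averaged rate over the window equals
the background mean rate* $\bar r$. This is the equal-total-recombination
constraint: all profiles imply the same amount of recombination, apportioned
differently through time, so that a classifier cannot separate histories
merely by the total. Beyond the window every profile reverts to $\bar r$;
confining the variation to the window keeps the totals equal over *any*
horizon (the genealogy of a sample of 100 typically extends several times
deeper than the window). The `constant-low` and `constant-high` presets used
by the four-model control hold 15% and 85% of the matched linear maximum
($2\bar r$) inside the window, again reverting to $\bar r$ outside, so that
they differ from the trend models only within the window.

Directions are read toward the present: an *increasing* profile has its
maximum at the sampling generation. The linear shape runs from 0 at one end
of the window to $2\bar r$ at the other (pinned at zero; a positive floor
would change the 15%/85% constants). The exponential shape follows
$e^{\pm\lambda t}$ with $\lambda = 5\times10^{-4}$/generation; the logistic
shape follows the standard growth curve $K N_0 e^{g s}/(K + N_0(e^{g s}-1))$
with $K = 100$, $N_0 = 1$, $g = 9\times10^{-4}$/generation. The increasing
variants are the *time-mirrors* of the decreasing ones (the curve evaluated
at $T - t$), matching the mirror construction of the linear pair; a
sign-flipped exponent happens to equal the mirror for the exponential but not
for the logistic, where it would produce an unrelated decaying shape.

For simulation the profile is discretized into piecewise-constant epochs
(default 20 generations, the grid of the time-series experiment); within an
epoch competing exponential waiting times are exact, and a waiting time
crossing an epoch boundary is re-drawn from the boundary (memorylessness
makes this exact given the discretized profile). Midpoint rates preserve the
integrated recombination over the window to well under $10^{-3}$ relative
error. A guard cap of $10^7$ events per replicate turns a runaway
parameterization into an error rather than a hang.

### Default parameters

Defaults describe a human-like deme with a strongly recombining 10-kb locus:
$N_e = 10^4$, $n = 100$ haplotypes, $L = 10^4$ bp,
$\mu = r = 3.75\times10^{-8}$ events/bp/generation, hence
$\theta = \rho = 15$; change window $10^4$ generations. These are the
conditions under which all headline numbers are computed.

## The summary suite

Nine statistics are computed per dataset or subsample: $S$ (segregating
sites, a negative control — its mean does not depend on recombination);
$R_\min$ (Hudson–Kaplan lower bound on recombination events: the maximum
number of disjoint open intervals between four-gamete-incompatible site
pairs); *rmmg* (the Myers–Griffiths haplotype bound
$\max(0, H - S - 1)$ over the whole locus, a conservative lower bound on
$R_\min$); `nHaps` (distinct haplotypes); `HapDiv` (sample-corrected
haplotype diversity $\frac{n}{n-1}(1 - \sum_h p_h^2)$); Wall's $B$ and $Q$
(adjacent segregating-site pairs inducing identical sample bipartitions:
$B = B'/(S-1)$, $Q = (B' + A)/S$ with $A$ the number of distinct bipartitions
among congruent pairs — distinct-partition counting is restricted to
congruent pairs); Hudson's $C$ (a moment estimator of $\rho$ from the
variance of pairwise differences, below); and $Z_{nS}$ (mean pairwise $r^2$
over all site pairs).

**Undefined values are flagged, not zeroed.** Wall's $B$ and $Z_{nS}$ need
$S \ge 2$; the $S$-scaled variants need $S > 0$. Young quartets frequently
have $S \le 1$, and silently substituting zeros would bias their feature
distributions, so undefined values are `NA` and the feature aggregation
skips them (retaining per-statistic counts of defined values).

**Scaling by S.** Because $S$ is a robust proxy for subsample age, dividing
the eight recombination summaries by $S$ yields age-normalized variants that
couple the amount of recombination to the age of the subsample. Scaling is
division by default (a multiplicative variant is exposed as an option).

**Hudson's C.** For a pair of sequences at a locus with total scaled
recombination $C$, the number of differences is Poisson with mean
$\theta \bar T$ given the genealogy, where $\bar T$ is the locus-averaged
pair coalescence time, so
$\mathrm{Var}(k) = \theta + \theta^2 \sigma_T^2(C)$ with
$$\sigma_T^2(C) = \frac{2}{C^2}\int_0^C (C-y)\,\frac{y+18}{y^2+13y+18}\,dy,$$
the classical two-locus covariance of pair coalescence times (evaluated in
closed form by partial fractions). The estimator equates this expectation —
with $\hat\theta$ the observed mean pairwise difference — to the observed
variance of pairwise differences and solves for $C$ by bisection (tolerance
$10^{-6}$), clamped to 0 when the observed variance exceeds the $C=0$
expectation and to a cap $C_{\max}$ when below the $C_{\max}$ expectation.
This is a pair-level moment version of the classical estimator: the original
finite-sample expectation also carries $n$-dependent cross-pair terms whose
absence biases our $C$ upward and gives it a heavy upper tail. The cap
defaults to $10^4$, the conventional ceiling of moment-based $\rho$
estimators. The tail matters downstream: a tight cap (for example $10\rho$)
compresses it and roughly triples the magnitude of the $C$–$Z_{nS}$
correlation across simulated datasets, while under the wide cap the few
near-cap estimates act as leverage points that make that Pearson
correlation noticeably seed-dependent. Correlation summaries involving $C$
should therefore be read as properties of this documented variant.

**rmmg at full scale.** With $n = 100$ and $\theta = 15$ the whole-locus
haplotype bound is zero for essentially every full dataset (it varies only
within small subsamples), so its full-sample correlations are undefined and
are reported as missing. A composite interval decomposition (RecMin-style)
would give it more resolution but is deliberately out of scope.

## Subsampling, features, classification

A subsample is drawn uniformly without replacement within a draw; draws are
independent (a lineage may appear in many subsamples, and duplicate
subsamples are allowed). Sites monomorphic within the subsample are dropped.
For each dataset, the mean, unbiased variance and maximum of each of the
9 unscaled and 8 scaled statistics over the subsample distribution form a
51-dimensional feature vector.

Classification is Gaussian discriminant analysis with uniform priors —
linear (pooled covariance) by default, quadratic optionally. Features are
standardized *inside each training fold* (no leakage; the experiment designs
are balanced), `NA` features are imputed with the training-fold mean,
zero-variance features are dropped, and a ridge
$\varepsilon = 10^{-6}\,\mathrm{tr}(\Sigma)/d$ (escalated tenfold as needed)
repairs singular covariances. Ties break deterministically by label order.
Accuracy is leave-one-out: each dataset is classified by a model trained on
all others. A rank-one downdate path reproduces the refitted LDA fold
exactly (up to ridge effects) and is available for large designs; at the
package's default scales plain refits are used.

## Closed-form power bounds

Waiting times while $i$ lineages remain are exponential with mean
$2/(i(i-1))$ (variance the square) in units of $2N_e$ generations for
autosomal loci, so the last two lineages account for on average half the
tree height: deep history is recorded by very few lineages, and the
information about old recombination decays accordingly. The probability
that a uniform subsample of $n$ lineages spans the basal split is
$(n-1)/(n+1)$ in expectation over genealogies — already 0.60 for a quartet —
and for a fixed basal split of sizes $(a, b)$ it is
$1 - [\binom{a}{k} + \binom{b}{k}]/\binom{a+b}{k}$. Every subsample that
spans the basal split returns the *same* information about the oldest
events, which is why accuracy saturates well below 1 regardless of how many
subsamples are drawn.

## Experiment drivers and problem sizes

The package ships the five experiment designs as functions: `runThreeModel()`
(constant vs linearly increasing vs decreasing), `runFourModel()` (adds the
constant-low/high level controls), `runNtupleSweep()` (accuracy versus
subsample size), `runTimeSeries()` (summary trajectories across sampling
times), `runConstantSweep()` (summary response to constant $\rho$), and
`runCorrelation()` (pairwise correlation structure of the suite). All
consume a root seed and derive per-replicate streams deterministically from
`(seed, index)`, so any replicate can be regenerated in isolation and whole
experiments are bit-reproducible.

The method's full operating scale is $10^4$ datasets per model with
$10^3$ quartets each. The package's working scale is **300 datasets per model with 200
quartet subsamples**, which keeps a full three-model experiment around one
minute on one CPU; the subsample-size sweep evaluates a coarse grid of
sizes including the optimal size (77) with 200 subsamples per dataset.
At 300 datasets/model the binomial standard error of an accuracy near 0.7
is about 1.5 percentage points; training-set size and the subsample count
both shift LOOCV accuracies by a few points relative to the full scale
(fewer subsamples add feature noise that attenuates single-feature
accuracies such as mean-nHaps by several points; more subsamples push the
multi-feature suites a few points *above* their full-scale reference
values), which is
why desk-scale accuracy checks carry ±5-percentage-point bands and
single-feature accuracies can brush the band edge.

The correlation study pools the per-dataset full-sample summaries of an
equal three-model mix (dataset-level pooling; subsample-level pooling would
mix within- and between-dataset variation). The headline mean correlation
can be read over all nine summaries or over the eight recombination
summaries only; both variants are computed, and the with-$S$ variant is
used as the headline (the negative control is displayed alongside the
suite throughout the package's outputs).

## What the generator emulates — and what it does not

The simulator realizes an idealized world:
neutrality, panmixia, constant $N_e$, uniform rate along the locus within
any instant, infinite-sites mutation, complete phased haplotypes, no gene
conversion, no selection or transmission distortion, and a perfectly known
demography. Passing the package's tests therefore demonstrates that the
method works *under its own assumptions*; it says nothing about robustness
to demographic change, population structure, unphased or error-prone data,
fine-scale hotspot structure, or cis-driven recombination evolution.
Complex demography in particular can mimic recombination signal; treat
real-data applications as requiring their own simulation study with a
demography matched to the data.

## Numerical choices

* Bisection tolerance $10^{-6}$ for Hudson's $C$; clamps as above.
* Midpoint-rule epoch rates; 20-generation step.
* Sample variance uses the $n-1$ denominator everywhere (including the
  observed variance of pairwise differences).
* Positions are continuous in $[0,1)$; the ms reader restores strict
  ordering of positions that collide at printed precision by minimal
  nudges.
* Quantile bands in the sweep/time-series tables are empirical 2.5%/97.5%
  quantiles, not normal approximations.
* The curve smoother is local degree-2 weighted least squares with a
  cubic-spline (SPH) kernel, bandwidth at the 50% nearest-neighbour
  distance plus a 10% constant weight component; display only.

## Worked example

```{r example, eval = FALSE}
library(recombpast)

## a locus whose recombination rate collapsed logistically toward today
cfg <- simConfig(profile = profilePreset("logistic-dec"))
set.seed(1)
d <- simulateDataset(cfg)
summaryStats(d)

## quartet subsampling features
featureVector(d, tupleN = 4, nSubsamples = 1000)[c("mean_nHaps", "var_ZnS")]

## small three-model experiment (minutes at the default desk scale)
res <- runThreeModel(nPerModel = 100, nSubsamples = 500, seed = 1)
vapply(res$reports, overallAccuracy, numeric(1))
```

## Known limitations

* Hudson's $C$ uses the pair-level moment equation, not the original
  finite-sample expectation; its distribution (and everything downstream of
  it) differs in detail from libsequence's estimator.
* The whole-locus *rmmg* bound is uninformative at the default full-sample
  scale (see above).
* LOOCV by full refit scales linearly in dataset count times the cost of a
  covariance factorization; for full-scale designs ($3\times10^4$ rows)
  use the downdate path.
* Accuracies quoted for the classification experiments are properties of
  the *default* simulation conditions; changing $\theta$, $\rho$, the window, or
  the sample size changes them, and the optimal subsample size in
  particular is known to be dataset-dependent.
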