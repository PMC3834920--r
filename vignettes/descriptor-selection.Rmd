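---
title: "Selecting molecular descriptors for penetration-enhancer QSAR with replacement methods"
author: "ermsel package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting molecular descriptors for penetration-enhancer QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ermsel)
```

## The problem

Chemical penetration enhancers (CPEs) are excipients added to transdermal
formulations to raise drug flux across the stratum corneum. Their
effectiveness is summarised by the enhancement ratio (ER): steady-state
flux with the enhancer divided by flux without it. QSAR modelling of ER
asks which of the dozens of computable molecular descriptors — hydrogen
bond counts, polar surface area, glass-transition temperature, radius of
gyration, dipole moment, and so on — carry the signal, and with what
coefficients. A typical study supplies a pool of roughly thirty candidate
descriptors for some tens of compounds, so an unconstrained fit would be
wildly over-parameterised; the scientific task is subset selection:
find the `M` descriptors whose intercept-containing linear model

$$\hat{ER} = a_0 + \sum_{j=1}^{M} a_j x_j$$

has the smallest residual standard deviation
$S = \sqrt{RSS/(n - M - 1)}$. `ermsel` implements the replacement-method
family for this search, the classical stepwise procedures it is compared
against, an exhaustive-enumeration oracle for certifying answers at small
scale, and a small feed-forward neural network that refines the selected
linear model.

A widely used guard against chance correlation keeps `M` below one fifth
of the number of compounds; `validatePool()` warns when a requested subset
size violates it (for 61 compounds, `M = 8` passes since $8 < 61/5$).

## The replacement family

All three algorithms walk through subsets of fixed size `M`, scoring every
candidate by the `S` of its OLS fit.

**RM** starts from an arbitrary subset `V` (seeded random when the caller
gives none) and runs `M` *paths*, one per starting position. A path first
replaces its designated descriptor by every descriptor outside `V`,
accepting the substitution with the smallest `S` provided it is an
improvement. Each later cycle ranks the current descriptors by the
relative error of their coefficients (standard error over absolute
coefficient — the "worst" descriptor is the least reliably estimated one),
excludes the descriptor optimised in the immediately preceding cycle for
exactly one cycle, and tries to replace the worst eligible descriptor,
again accepting only strict improvements. A path ends when a full sweep
changes nothing. The best model over all paths is returned.

**MRM** uses the same worst-descriptor targeting but *forces* the best
available substitution even when it raises `S`. Forced walks can cycle, so
the search memoises visited subsets and stops on recurrence, or after
`maxCycles` (default `2M`) forced moves. The best subset ever visited is
returned.

**ERM** is the sequence RM → MRM → RM: the forced stage perturbs the RM
minimum out of its basin, and the final RM polishes the perturbed subset.
Because the result is best-ever over all three stages,
$S_{\mathrm{ERM}} \le S_{\mathrm{RM}}$ holds for identical inputs by
construction.

Several details of the sweep are underdetermined in verbal descriptions of
the method, and this package fixes them as follows. A "cycle" attempts
positions in decreasing relative-error order and restarts as soon as one
substitution is accepted; if a sweep under the one-cycle exclusion stalls,
one final unrestricted sweep decides termination, so the exclusion can
never hide the only remaining improvement. Ties between equally good
replacements go to the candidate earliest in pool order. The acceptance
rule is a strict decrease in `S` everywhere in RM, including the first
step of the first path. Candidate subsets whose design is collinear
(condition number above $10^{10}$, or rank-deficient at QR tolerance
$10^{-10}$ in the fast scanning path) are scored $S = +\infty$ and thus
never accepted; a coefficient that is exactly zero gets relative error
$+\infty$ so it always ranks worst. The intercept is never ranked and
never replaced. These choices make every search fully deterministic given
the table, `M`, the initial subset and the seed.

**Stepwise baselines.** `forwardStepwise()` adds, at each step, the
candidate with the largest partial F

$$F = \frac{RSS_{\text{small}} - RSS_{\text{big}}}
          {RSS_{\text{big}} / (n - d_{\text{big}} - 1)}$$

provided it exceeds `FEnter`; `backwardEliminate()` deletes the member
with the smallest F while it stays below `FRemove`. Both thresholds
default to 4.0, the usual rule of thumb (about a 5% single-coefficient
test); the thresholds are user-settable because no canonical value exists.
A big model that fits perfectly (RSS zero to round-off) yields the
$+\infty$ sentinel, so perfect predictors always enter and never leave.

**Exhaustive oracle.** `exhaustiveBestSubset()` enumerates all
$\binom{N}{M}$ subsets (refusing above a fit budget, default $2\times
10^5$) with ties broken lexicographically on sorted descriptor names. Its
trace records successive incumbents rather than every visited subset, so
traces stay small while the best-ever contract remains checkable. In the
test suite it certifies that ERM attains the global optimum on small
seeded instances (50 of 50 at pool 10, 30 compounds, `M = 3` in the
shipped runs).

## Degenerate-input conventions

A constant response gives $R^2 = 0$ and zero coefficients rather than
0/0. Constant descriptor columns are *flagged* by `validatePool()` — not
dropped, so column indexing still matches the user's CSV — and the
searches treat flagged names as never selectable. $R^2$ is always
$1 - RSS/TSS$ about the response mean, never a squared correlation, for
all models including the network, so train/test and linear/ANN numbers
are directly comparable. The `log10(ER)` response transform (a common
convention in the permeation literature; base 10 chosen, since published
work rarely states the base) refuses non-positive responses and refuses to
compound transforms.

## The refinement network

The network is deliberately tiny: inputs are the `M` selected descriptors
(8 in the reference workflow), one hidden layer of two logistic-sigmoid
units, and one linear output — an 8:2:1 net, about as many weights (21)
as a 46-compound training partition can support. Inputs and response are
min–max scaled onto $[0.1, 0.9]$, the conventional range for sigmoid
networks; scaling is fitted on the training partition only, test-set
values outside the training range scale outside the interval and are
passed through unclipped, and a constant column maps to the midpoint 0.5.
`splitTrainTest()` assigns `round(0.75 n)` compounds (round half up; 46 of
61, leaving 15) to training after a seeded shuffle. Published figures for
the 61-compound study imply a 47/14 split, so the original rounding rule
differed in some unstated way; this package documents its rule rather
than reverse-engineering one.

Training minimises the MSE of the scaled response, full batch, capped at
150 iterations with early stopping: once the best MSE has not improved by
at least $10^{-8}$ for 10 consecutive iterations, training stops and the
best-ever weights are returned. Two learning rules are available. The
default is damped Gauss–Newton (Levenberg–Marquardt with multiplicative
damping adaptation): for a 21-parameter network the Jacobian is tiny, each
iteration costs microseconds, and convergence typically takes a few dozen
iterations — consistent with commercial trainers, which converge in
similar iteration counts and are invariably second-order at this scale. A
fixed-rate full-batch gradient-descent rule (`learningRate = 0.05`) is
provided for comparison; it needs far more than 150 iterations to match
the linear model and is not the default for exactly that reason.

Single random initialisations of tiny sigmoid networks land in poor local
minima distressingly often — in our replicated experiments roughly a
quarter of uniform$(-0.5, 0.5)$ starts collapsed to near-constant
predictors. `trainAnn()` therefore burns in several seeded starts (5 by
default, 10 iterations each, all drawn from one seeded uniform stream) and
spends the remaining budget on the most promising one; the total number of
iterations across all starts never exceeds `maxIterations`, so the
150-iteration cap is respected in aggregate, not just per start.

## The synthetic generator

Real descriptor tables for this problem come from commercial descriptor
software and cannot be redistributed, so `generateDataset()` produces
tables with the statistical geometry the methods face. Descriptors are
zero-mean unit-variance equicorrelated Gaussians built by the one-factor
decomposition $x_j = \sqrt{\rho}\,z_0 + \sqrt{1-\rho}\,z_j$; the response
is a sparse linear signal over a known subset plus homoscedastic Gaussian
noise and, optionally, a squared term of the first true descriptor. The
defaults mirror the 61-compound nonpolar study: 61 compounds, a pool of
31 named descriptors, 8 true descriptors with unit coefficients,
$\rho = 0.3$, noise sd 0.1. Column names come from a list of descriptor
labels conventional in this literature, and the true subset is planted on
the eight canonically selected descriptors when present.

What the generator does *not* emulate: physically coupled descriptors
(molar volume tracks molecular weight in real tables; here correlation is
exchangeable), non-Gaussian marginals (counts, bounded fractions),
heteroscedastic or skewed ER error, and block-structured correlation
(size/polarity clusters). Passing recovery tests therefore show that the
algorithms work on correlated sparse-signal tables of the right shape —
not that any particular real dataset would yield any particular model.

For the nonlinear experiments the package uses `nonlinearWeight = 2` with
`noiseSd = 1`. Under the equicorrelated defaults the linear signal has
variance near 25, the squared term (orthogonal in expectation to every
linear term) adds about 8, and the noise 1, so the best linear model
attains $R^2 \approx 0.75{-}0.8$ on training data — the regime reported
for real enhancer tables, where the linear model is good but visibly
incomplete — and the network has genuine curvature to capture. In 25
replicated runs the trained network matched or beat the linear training
$R^2$ in 23.

## Problem sizes and run times

The shipped tests certify ERM against exhaustive enumeration on 50
instances at pool 10 / 30 compounds / `M = 3` (about a second), run the
recovery comparison at the full 61 × 31, `M = 8` geometry over 50
replicates (a few seconds), and replicate the network-versus-linear
comparison 25 times (a few seconds). These sizes were chosen as the
smallest at which the claims are statistically meaningful; all scale
linearly if larger certification runs are wanted.

## Known limitations

- The replacement family is a heuristic: no optimality guarantee exists
  off the certified instance classes, and on highly collinear pools
  ($\rho$ near 1) all descendant subsets of a path can be singular.
- Selection uses training `S` only, as the method prescribes; no
  cross-validation guard is built in, so selected models inherit the
  optimism of training-set selection.
- The network reports end-quality, not trajectory fidelity to any
  particular historical trainer; only the architecture, scaling, budget
  and stopping conventions are fixed.
- Published-model fixtures can only be as complete as what was printed:
  the stored network fixture carries the one published hidden-unit
  combination and synthetic placeholder output weights, and supports
  evaluation of the hidden layer, not reproduction of unpublished
  predictions.
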