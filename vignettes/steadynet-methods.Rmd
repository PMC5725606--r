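---
title: "Inferring microbial ecological networks from steady-state samples"
author: "steadynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microbial ecological networks from steady-state samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steadynet)
```

## The inference problem

Cross-sectional microbiome surveys deliver many *steady-state* samples of
the same underlying community: abundance vectors
$x \in \mathbb{R}^N_{\ge 0}$ in which different subsets of taxa are
present.  If the community follows autonomous population dynamics
$dx_i/dt = x_i f_i(x)$, each sample with taxon $i$ present satisfies
$f_i(x) = 0$.  The ecological interaction of taxon $j$ on taxon $i$ —
promotion, inhibition, or absence — is the sign of the Jacobian entry
$J_{ij} = \partial f_i / \partial x_j$.  `steadynet` infers the ternary
sign-pattern of $J$ from such samples **without choosing a dynamics
model**, and, when the data are consistent with generalized Lotka–Volterra
(GLV) dynamics, additionally infers quantitative interaction strengths and
intrinsic growth rates.

The one substantive assumption is that $\mathrm{sign}(J(x))$ is constant
over the observed states.  It is falsifiable from the data themselves:
if two samples share the same set of present taxa but differ in abundance
("true multi-stability"), the assumption fails and `inferSignMatrix()`
refuses to run (`detectMultistability()`).

### Sign-pattern inference

For two samples $x^I, x^K$ sharing taxon $i$, the mean-value theorem makes
the averaged Jacobian row orthogonal to $x^I - x^K$; under the
constant-sign assumption the row sign-pattern $s_i \in \{-,0,+\}^N$ must
therefore be *realizable* by some vector orthogonal to every pairwise
difference.  Whether a sign-pattern can be orthogonal to a given vector
$w$ is the sign-satisfaction problem; it holds iff the products $s_j w_j$
either all vanish or take both signs (`signSatisfies()`), which is also
decidable as a small linear feasibility program (`lpFeasible()`) — the two
routes are tested against each other on tens of thousands of random
instances.

Two algorithms recover $s_i$:

* **Brute force** (`admissiblePatterns()`): test all $3^N$ patterns
  against all pairwise differences.  Exact, but exponential in $N$; a
  guard refuses $N > 12$ unless overridden.  With informative data the
  admissible set shrinks to $\{-a, 0, a\}$.
* **Heuristic** (`heuristicInferRow()`): repeatedly draw $N-1$ pairwise
  differences, intersect their orthogonal hyperplanes into a line (the
  1-dimensional null space of the stacked differences, via SVD), and
  score the line's sign-pattern by the fraction $\phi$ of *all* pairwise
  differences it sign-satisfies.  The candidate from the most probable
  maximal-$\phi$ line wins.  The solution space is the number of drawn
  lines $\Psi$ (default $5N$; the validation experiments use $10N$).

Candidate sets are closed under negation, so one known sign is needed to
orient them; the default prior is the self-limitation assumption
$s_{ii} = -$ (`resolveSigns()`).

### Quantitative GLV inference

Under GLV dynamics, $f_i(x) = r_i + \sum_j a_{ij} x_j$, all samples
containing taxon $i$ lie on one hyperplane with normal $a_i$.  The $R^2$
of the per-row regression (`glvConsistency()`) measures how well the data
support GLV; rows below `r2Threshold = 0.9` are flagged and should only be
interpreted qualitatively.  With a known diagonal $a_{ii}$, noiseless data
give exact recovery (`fitRowExact()`), and
$r_i = \mathrm{mean}(-a_i \cdot x^I)$ (`estimateGrowthRate()`).  Noisy
data use a cross-validated Lasso (`lassoInferRow()`, `glmnet`, 10-fold,
100-point $\lambda$ grid, `lambda.min`), with the selected support
re-fitted by ordinary least squares so the reported strengths are
unshrunk; selection — and hence the false-discovery rate — is unaffected
by the refit.  When $a_{ii}$ is unknown it is drawn from the half-normal
$-|N(-1, 0.1^2)|$, which injects an irreducible ~10% scale uncertainty
per row.

Cross-validated Lasso is deliberately liberal — the validation suite
measures its matrix-wide FDR on simulated noisy communities.  The
**knockoff filter** (`knockoffFilterRow()`) controls FDR at a chosen
$q$: fixed-X equi-correlated knockoff copies are built from the row
design (centered, column-normalized), variables are ranked by the Lasso
signed-max-$\lambda$ statistic, and the knockoff+ threshold selects the
support.  When the row has $p < n < 2p$ samples the standard augmentation
(zero rows in the design, $N(0, \hat\sigma^2)$ rows in the response) is
applied; with $n \le p + 1$ the construction is infeasible and the row
falls back to the unfiltered Lasso with a warning.

### Error metrics

Sign accuracy is the percentage of correctly inferred signs; the default
denominator is the full matrix including the diagonal, with undetermined
entries counting against accuracy (both the determined-only and
off-diagonal variants are available).  Parameter error is reported as
NRMSE — root-mean-square error normalized by the range of the true values
— for $A$, for $r$, and as one number over the stacked parameter set
(`glvNRMSE()`; a Frobenius-relative variant is provided for comparison,
but for sparse weak interaction matrices it is dominated by the many
near-zero entries and is roughly an order of magnitude larger, so the
range-normalized form is the default).

## The synthetic-data generator

`randomNetwork()` + `generateSampleSet()` emulate the validation setting
used throughout the package's tests:

* **Network**: each directed off-diagonal interaction exists independently
  with probability `connectivity` (default 0.4); $a_{ii} = -1$.
* **Weights**: uniform on $\pm[0.2, 1]$ scaled by
  $0.35/\sqrt{N \cdot \text{connectivity}}$.  The scale was calibrated
  once against two phenomenological requirements and then frozen:
  (i) restricted equilibria must be broadly feasible, so that any two taxa
  co-occur in some sample — at scales near $1/\sqrt{NC}$ and above,
  competitive exclusion leaves taxon pairs that never co-occur and whole
  rows become structurally unidentifiable; (ii) interactions must remain
  strong enough to be identified against multiplicative measurement
  noise, which rules out scales near $1/N$.  The chosen scale sits
  comfortably inside the May-stability region while keeping pairwise
  coexistence generic.
* **Growth rates**: $r_i \sim U[0.1, 1]$.
* **Dynamics**: GLV solved in closed form per support (feasible iff all
  abundances positive; linear stability checked via the eigenvalues of
  $\mathrm{diag}(x) A$), or one of three saturating models integrated to
  steady state (`deSolve::lsoda`, rtol $10^{-9}$/atol $10^{-11}$,
  residual tolerance $10^{-9}$, horizon $10^5$): Holling type II
  $f_i = r_i + \sum_j a_{ij} x_j/(1 + c x_j)$, Beddington–DeAngelis
  $f_i = r_i + \sum_j a_{ij} x_j/(1 + c x_j + d x_i)$, Crowley–Martin
  $f_i = r_i + \sum_j a_{ij} x_j/((1+c x_j)(1+d x_i))$, with
  $c = d = 0.1$.  These are standard textbook response forms chosen to
  preserve a constant Jacobian sign-pattern, which the test-suite verifies
  numerically at 100 random positive states per instance.
* **Presence patterns**: uniform (every taxon present with probability
  0.5) or heterogeneous (25% common taxa at 0.9, the rest at 0.3,
  emulating the skewed prevalence of host-associated communities).
  Duplicate supports are rejected so samples carry distinct taxa
  collections.
* **Noise**: each non-zero abundance $x \to x + \eta u$,
  $u \sim U[-x, x]$; zeros stay zero, and values stay non-negative for
  $\eta \le 1$.

What the generator does *not* emulate: compositional (relative-abundance)
measurement, sequencing-depth artefacts, taxon invasion/migration,
demographic stochasticity, environment-dependent interaction signs, and
higher-order interactions beyond the four response forms.  Passing tests
therefore demonstrate correctness of the algorithms under the stated
assumptions, not robustness to every failure mode of real survey data —
the two failure modes the method *can* detect (compositionality and true
multi-stability) are guarded explicitly.

## Numerical choices

* Zero threshold for supports: abundance $\le 10^{-8}$ counts as absent.
* A "1-dimensional null space" means exactly one singular value below
  $10^{-10}$ times the largest; degenerate draws are retried up to 50
  times per requested line.
* Sign extraction from unit-norm intersection directions uses a numerical
  zero threshold of 0.03, chosen to sit in the gap between the direction
  entries observed at truly-zero versus truly-nonzero Jacobian entries on
  saturating-model data (the two distributions separate by roughly a
  factor of three around that value).  GLV kernels carry exact zeros and
  are insensitive to this choice.
* The LP encoding of strict sign constraints uses margin
  $\epsilon = 10^{-6}$ on the unit box; it is exact whenever entry
  magnitudes are within a factor $10^6$ of each other.
* Max-$\phi$ ties in the heuristic are resolved by the most frequently
  sampled pattern, then by first occurrence — "the most probable
  intersection line" — keeping runs seed-reproducible.  (Marking tied
  entries undetermined instead was evaluated and rejected: on saturating
  dynamics ties are the norm and that rule leaves roughly half the matrix
  undetermined.)
* Replicate samples sharing a support are averaged (arithmetic mean)
  before inference, after the multistability guard has seen the raw
  samples.

## Study sizes used in the validation suite

The test-suite and `scripts/acceptance.R` run the full pipeline at the
following sizes, chosen to exercise the published operating points of the
method: quantitative inference at $N = 50$, connectivity 0.4, with
$\Omega = 5N$ samples (noisy case, 10 realizations per noise level) and
$\Omega = 10N$ for the noiseless exact-recovery check (feasibility
rejection skews supports away from some taxa, and exact recovery needs
every taxon present in at least $N$ samples); sign inference at $N = 8$
with $\Psi = 10N$; minimal-sample-size scans over $N \in \{6,8,10,12\}$.
On one CPU the whole suite completes in well under half an hour.

## Known limitations

* Absolute abundances are required; compositional input is rejected, not
  corrected.
* The heuristic needs $\Omega \gtrsim 3N$ samples with distinct supports;
  below that it fails outright (the brute force degrades more gracefully).
* Taxa that never co-occur with taxon $i$ leave the corresponding entries
  of row $i$ undetermined — a property of the data, not the algorithm.
* Fixed-X knockoffs need at least $p + 2$ samples per row; rarer taxa fall
  back to unfiltered Lasso and are flagged.
* FDR control is exact for fixed designs with homoscedastic Gaussian
  noise; under the multiplicative noise model it holds empirically to
  within Monte-Carlo error at the tested levels.
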