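# steadynet

Infers the ecological network of a microbial community — who promotes,
inhibits, or ignores whom — from **cross-sectional steady-state samples of
absolute abundances**, with no population-dynamics model assumed.  It is
aimed at microbial ecologists working with communities sampled at
equilibrium under many different taxon combinations (synthetic
communities, host-associated microbiota surveys with absolute
quantification), where time-series perturbation experiments are
impractical or unethical.

## What it computes

Writing the community dynamics as `dx_i/dt = x_i f_i(x)`, interaction
types are the signs of the Jacobian `J_ij = ∂f_i/∂x_j`.  Assuming only
that `sign(J)` is constant across the observed states (an assumption the
package can falsify from the data), every pair of steady-state samples
`x^I, x^K` sharing taxon *i* constrains the row sign-pattern
`s_i ∈ {-,0,+}^N`: some vector with that sign-pattern must be orthogonal
to `x^I − x^K`.  Two solvers recover the candidate set for each row —
exhaustive enumeration of all `3^N` patterns (N ≲ 12), and a scalable
heuristic that intersects randomly chosen (N−1)-tuples of difference
hyperplanes into candidate lines and scores each line by the fraction φ of
all hyperplanes crossing its orthants.  A single known sign (by default
the self-limitation `s_ii = −`) orients the result.

If, additionally, samples containing taxon *i* lie on a hyperplane
(checked by the per-row R² of `glvConsistency()`), the community is
consistent with generalized Lotka–Volterra dynamics
`f_i = r_i + Σ_j a_ij x_j`, and the package quantitatively infers the
interaction matrix `A` and growth rates `r`: exactly for noiseless data
with known `a_ii`, by cross-validated Lasso for noisy data, and with
false-discovery-rate control at a user level `q` via fixed-X
equi-correlated knockoffs (Lasso signed-max statistic, knockoff+
threshold).

Simulators for GLV, Holling type II, Beddington–DeAngelis and
Crowley–Martin dynamics generate validation data on random
taxon-presence supports with multiplicative uniform measurement noise
(`x → x + ηu`, `u ~ U[−x, x]`).

## Worked example

```r
library(steadynet)
set.seed(42)
mod <- randomNetwork(8, connectivity = 0.4)        # ground-truth community
x   <- generateSampleSet(mod, omega = 40, presence = "uniform")
x
#> SteadyStateSamples: 40 samples x 8 taxa
#>   distinct supports: 40 | zeroTol: 1e-08

inf <- inferSignMatrix(x, method = "heuristic", psi = 80)
inf
#> SignInference (heuristic): 8 x 8 interaction types
#>   determined: 64 / 64  (+: 10  -: 15  0: 39 )
#>   mean best phi: 1

signAccuracy(inf, jacobianSignTruth(mod))$accuracy
#> [1] 100
```

All 64 interaction types (10 promotions, 15 inhibitions, 39 absent edges)
are recovered from 40 samples; `phi = 1` means every candidate line was
consistent with all sample pairs.  Since these data are exactly GLV, the
interaction strengths are recovered to machine precision once one
diagonal entry is known:

```r
fit <- inferGLV(x, method = "exact", aii = -1)
max(abs(interactionMatrix(fit) - mod@A))
#> [1] 4.440892e-16
```

On noisy data use `inferGLV(x, method = "knockoff", aii = "halfnormal",
q = 0.2)` to keep the expected fraction of spurious inferred interactions
below 20%.  `vignettes/steadynet-methods.Rmd` documents the models,
parameters and design choices; `inst/scripts/steadynet-cli.R` exposes the
pipeline (`simulate`, `infer-signs`, `infer-glv`, `check-glv`,
`check-multistability`, `evaluate`) from the shell.

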