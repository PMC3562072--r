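---
title: "Inferring gene regulatory networks from knockout fitness data"
author: "fitnessGRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene regulatory networks from knockout fitness data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitnessGRN)
```

## The problem

Genome-wide deletion libraries assay the *fitness* (e.g. growth rate in
stationary phase) of thousands of single-knockout strains across many
conditions. Fitness is an organism-scale readout: each measurement is one
real number summarizing the behaviour of the whole regulatory network with
one gene removed. This package infers a directed gene regulatory network —
which genes regulate which, and whether the influence is linear or
sigmoidal — from such knockout fitness matrices.

## The model

Gene expression follows a discrete-time nonlinear state-space model. For
$n$ genes with expression levels $x_i(t)$,

$$x_i(t+1) = \sum_j a_{ij}\, x_j(t) + \sum_j b_{ij}\, f_j(x_j(t)) + I_i + w_i(t),$$

where $a_{ij}$ and $b_{ij}$ are the linear and nonlinear regulation
coefficients from gene $j$ to gene $i$, $f_j(x) = 1/(1+e^{-\mu_j x})$ is a
logistic basis with per-gene steepness $\mu_j$, $I_i$ is an expression
bias, and $w(t)$ is zero-mean Gaussian process noise with covariance $Q$.
"Time" is a generalized experiment index, not physical time. A deletion
strain is modelled by zeroing the deleted gene's row and column in both
coefficient matrices, zeroing its bias, and clamping its expression to
zero: a deleted gene neither regulates nor is expressed
(`apply_knockout()`).

The scalar fitness of a strain is a radial-basis expansion of the hidden
expression state,

$$F(x) = \sum_{k=1}^{K} c_k\, \sqrt{\lVert x - m_k \rVert^2 + h^2},$$

a Hardy multiquadric basis with centres $m_k$ and shape constant $h$ fixed
a priori, and coefficients $c_k$ unknown. The multiquadric is a classical
choice for radial-basis function approximation: it converges faster than a
power-series expansion and keeps the number of unknowns at $K$ rather than
growing with polynomial order.

## Joint estimation by unscented Kalman filtering

All unknowns — the current expression state plus $a_{ij}$, $b_{ij}$,
$\mu_j$, $I_i$ and $c_k$ — are concatenated into one augmented state
vector of dimension $2n^2 + 3n + K$ (`augmented_layout()`). Parameters
follow identity dynamics with a small random-walk variance; the expression
slice follows the knockout-masked regulation model of the strain being
observed. Each scalar fitness measurement updates the joint belief through
one predict/update cycle of an unscented Kalman filter (UKF), which
propagates $2L+1$ deterministically placed sigma points through the
nonlinear dynamics and observation maps and so captures posterior moments
without derivatives. The filter runs in a single on-line pass: one step
per observation, rounds outermost, strains within a round in feeding
order.

Observations are not fed in arbitrary order. Deleting a highly connected
gene perturbs the whole network, and in sequential inference early
observations dominate where the belief settles. The correlation score
$S_i = \sum_r \sum_{j \neq i} y_{r,i}\, y_{r,j}$ ranks strains by how
strongly their fitness co-varies with the rest of the library, and strains
are fed hub-first by descending score (`correlation_score()`,
`feeding_order()`). Finding a truly optimal order would require knowing
the network and testing permutations; the score is a one-pass heuristic.
Condition (round) order is left as given: with many conditions the gain
from permuting them is small relative to the cost.

After the final observation, the posterior-mean coefficient matrices are
thresholded: per coefficient type, entries whose magnitude is at least a
fraction (default 0.4) of the largest off-diagonal magnitude of that type
become typed edges. An edge's linear and nonlinear components count
separately throughout evaluation.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold_fraction` | 0.4 | edge threshold as a fraction of the largest off-diagonal estimate per type (dimensionless) |
| `q_expr` | 0.01 | filter process-noise variance per expression level per step |
| `q_param` | 1e-4 | parameter random-walk variance per step; prevents covariance collapse in sequential mode |
| `prior_x_mean`, `prior_x_var` | 0.5, 1 | initial expression belief (mid-sigmoid mean, diffuse) |
| `prior_coef_var` | 1 | prior variance of regulation coefficients and biases (mean 0) |
| `prior_mu_mean`, `prior_mu_var` | 1, 0.25 | prior on sigmoid steepness; draws are soft-clipped at `mu_floor = 1e-3` to preserve positivity |
| `prior_rbf_var` | 1 | prior variance of fitness basis coefficients (mean 0) |
| `alpha, beta, kappa` | 1, 2, 0 | UKF scaling; `beta = 2` is optimal for Gaussian priors |
| `settle_steps` (filter) | 1 | dynamics applications per observation — the strict one-step reading |
| `reset_expression` | FALSE | whether to re-initialize the expression belief before every strain |

The priors are diffuse because nothing is known about a network before
inference; all are exposed through `infer_control()`.

## The synthetic benchmark

`reference_network()` loads a 5-gene benchmark with six directed
interactions (2→1, 3→1, 3→2, 3→4, 3→5, 4→2), each carrying linear
coefficient 0.7 and nonlinear coefficient 0.5 — twelve typed edges. Gene 3
is the hub (out-degree 4). Sigmoid steepness is 1 and the bias 0.2 per
gene; process-noise variance is 0.01 per gene and observation-noise
variance 0.01. The accompanying 5-basis fitness model is a constructed
(synthetic) fixture: its centres are scattered over the expression range
$[0,2]^5$ so that fitness is sensitive to every gene's expression — a
requirement for any of the coefficients to be identifiable — and its
coefficients solve the noise-free interpolation problem that assigns the
five knockout strains the distinct fitness levels (1.5, 2.0, 2.5, 1.2,
1.0). Under these levels the correlation score ranks the hub first,
producing the feeding order 3, 2, 1, 4, 5.

`simulate_knockout_dataset()` emulates the assay: per round and per gene,
the masked dynamics are propagated `settle_steps = 20` times from initial
level 0.5 with process noise each step (a settling horizon standing in for
stationary-phase growth), and the fitness of the final state is recorded
with observation noise. Ten rounds of five strains give 50 observations.
The generator reproduces bit-identically from its seed.

What the simulator does *not* emulate: barcode-sequencing read counts and
their overdispersion, condition-specific fitness functions (rounds are
i.i.d. replicates of one condition), fitness normalization artefacts,
multi-gene knockouts (supported by the masking API but not generated), and
regulatory rewiring across conditions. Passing the benchmark therefore
demonstrates that the estimator recovers structure when the model class
matches the data-generating process; it does not certify performance on
real compendia, where model mismatch dominates.

## Numerical choices

* Covariance square roots use a lower-triangular Cholesky factor; on
  failure a diagonal jitter of $10^{-9}\,\mathrm{tr}(P)/L$ is added and
  doubled up to six times before a covariance-degenerate error is raised.
* Sigma points for the measurement update are re-drawn from the predicted
  belief after adding process noise, which keeps the filter exactly
  equivalent to the closed-form Kalman recursion on linear-Gaussian
  models (verified against an independent implementation in the tests).
* The innovation variance is floored at the observation-noise variance;
  posterior covariances are symmetrized after every update.
* Feeding-order ties break by ascending gene index, making the order a
  deterministic function of the scores.
* The threshold reads "maximal variation" as the largest absolute
  off-diagonal estimate per coefficient type; self-regulation entries are
  permitted in the data model but never extracted as edges, since the
  benchmark protocol counts directed pairs $i \neq j$.
* For the 5-gene benchmark the non-edge denominator of the false rate is
  the protocol constant 228; for any other network it falls back to
  $2n(n-1) - (\text{true typed edges})$.

## Design choices on open points

* **Expression belief across strains.** The belief carries over from
  strain to strain (a single filter over the generalized time axis). The
  alternative — re-initializing per strain (`reset_expression = TRUE`) —
  makes each prediction a pure function of the parameters, but in our
  experiments it removed the benefit of informative ordering and halved
  recovery; carry-over is the default.
* **One filter step per observation.** Matching the settling horizon
  inside the filter (`settle_steps > 1`) is possible but iterating the
  estimated dynamics over wide sigma-point excursions is numerically
  fragile and recovered less in practice; the one-step reading is the
  default.
* **Raw versus centred correlation score.** The raw within-round
  cross-product sum is the default; a per-round mean-centred
  (covariance-style) variant is available via `centred = TRUE`.

## Known limitations

Fifty scalar observations cannot identify 65 parameters at their absolute
scale: the fitness coefficients $c_k$ can explain the five strain-level
fitness values with the regulation coefficients near zero, so
posterior-mean coefficient estimates are shrunk far below their generative
values. Network recovery rests on the *relative* pattern — true edges
receive systematically larger updates than non-edges — which the relative
threshold then converts into an edge set. A side effect is that runs that
learn more (informative feeding orders) spread estimates over more
above-threshold entries and can report more false positives than runs
that learn little, even while recovering many more true edges; the
missing rate is the more faithful summary of inference quality at this
data scale. Problem sizes used throughout the package's own validation:
the 5-gene benchmark, 10 rounds (50 observations), 10 simulation seeds,
and 10 random feeding orders per seed in the ordering comparison.
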