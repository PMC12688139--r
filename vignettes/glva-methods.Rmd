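---
title: "Methods: the Lotka-Volterra reduction of microbial consumer-resource dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Lotka-Volterra reduction of microbial consumer-resource dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glvapprox)
```

This vignette documents the models, the sampling scheme, the numerical
machinery and — importantly — the judgment calls behind `glvapprox`. The
package's purpose is to quantify when a pairwise (generalized
Lotka-Volterra, GLV) description of a microbial community faithfully
represents the consumer-resource dynamics it abstracts.

## 1. The consumer-resource model

Biomasses $C_i$ of $N$ consumers and abundances $R_\beta$ of $M$ resources
evolve as

$$\dot C_i = C_i\Big(\sum_{\alpha}(1-l^i_{\alpha})u_{i\alpha}R_\alpha - m_i\Big),
\qquad
\dot R_\beta = \rho_\beta-\sum_i u_{i\beta}R_\beta C_i
 +\sum_{i,\alpha} l^i_{\alpha\beta}u_{i\alpha}C_iR_\alpha .$$

Uptake $u_{i\alpha}$ has units mass$^{-1}$time$^{-1}$; maintenance $m_i$
(time$^{-1}$) is a linear respiration loss; $\rho_\beta$ (mass
time$^{-1}$) is a constant external supply; the unitless leakage tensor
$l^i_{\alpha\beta}$ is the fraction of resource $\alpha$ consumed by
species $i$ released back as resource $\beta$, with total leakage
$l^i_\alpha=\sum_\beta l^i_{\alpha\beta}\le 1$ (energy feasibility).
Summing the equations, the leakage terms cancel and

$$\tfrac{d}{dt}\Big(\sum_iC_i+\sum_\beta R_\beta\Big)
 =\sum_\beta\rho_\beta-\sum_i m_iC_i ,$$

a mass budget the test suite verifies at machine precision for the vector
field and along integrated trajectories. A useful corollary: at any
equilibrium, total consumer biomass is exactly
$\sum_iC_i^* = \sum_\beta\rho_\beta/m$ (with shared $m$), independent of
leakage.

The model assumes a well-mixed habitat, linear (mass-action) uptake, and
constant leakage fractions. Saturating uptake, essential-nutrient
colimitation and spatial structure are out of scope.

## 2. The exact first-order reduction

Two steps produce the GLV approximation.

**Quasi-steady-state (QSS) elimination.** Setting $\dot R=0$ at fixed $C$
gives the linear balance $M(C)R=\rho$ with
$M_{\beta\gamma}(C)=\delta_{\beta\gamma}\sum_iu_{i\beta}C_i-\sum_il^i_{\gamma\beta}u_{i\gamma}C_i$,
solved by `resource_qss()`. The per-capita growth on this manifold is
$g_i(C)=\sum_\alpha(1-l^i_\alpha)u_{i\alpha}R^*_\alpha(C)-m_i$.

**Linearization.** Taylor-expanding $g$ to first order at the equilibrium
$C^*$ the full model actually reaches:

$$A_{ij}=\sum_\alpha(1-l^i_\alpha)u_{i\alpha}
 \frac{\partial R^*_\alpha}{\partial C_j},\qquad
 r_i=g_i(C^*)-\textstyle\sum_jA_{ij}C^*_j,$$

with the sensitivity obtained by implicit differentiation,
$\partial R^*/\partial C_j=-M^{-1}(\partial M/\partial C_j)R^*$, sharing
one dense factorization of $M(C^*)$ across all columns
(`resource_sensitivity()`, `effective_glv()`). A test computes $A$ a
second, independent way — central finite differences of $g_i(C)$ — and
requires agreement to $10^{-5}$.

Because $M(C)$ is linear in $C$, $R^*(\lambda C)=R^*(C)/\lambda$; Euler's
relation then gives $\sum_j(\partial R^*/\partial C_j)C_j=-R^*$ and hence
$r_i=m_i$ for every surviving species. The single-species community with
$u=1$, $m=\rho=0.2$ has closed forms $C^*=\rho/m=1$,
$R^*=m/((1-l)u)$, $A_{11}=-m^2/\rho=-0.2$, $r_1=0.2$, used as exact
oracles throughout the tests.

**Expansion point.** The reduction is built at the equilibrium reached
from the shared initial conditions — including extinct species at
$C^*_i=0$, which keep their row and column of $A$ and get
$r_i=g_i(C^*)<0$ (their invasion deficit). An all-coexistence expansion
point would make the comparison about feasibility rather than about the
reduction.

## 3. Sampling synthetic communities

`sample_community()` draws one community:

- **Preferences** $\theta_i \sim$ symmetric Dirichlet($k_\theta$) per
  consumer. $k_\theta$ tunes heterogeneity: small values give spiky,
  specialist-like preferences.
- **Uptake** $u_i\sim$ Dirichlet($\Omega_i\theta_i$), scaled by the
  capacity $T_i$ (default 1, so every row sums to 1 and all consumers have
  equal total uptake ability). Large $\Omega$ makes realized uptake track
  $\theta$ closely (generalists); small $\Omega$ adds specialist noise.
- **Leakage**: for every pair $(i,\alpha)$,
  $l_{i\alpha\cdot}=l\times$ Dirichlet($\bar\phi_{i\alpha}$), so each slice
  sums exactly to the leakage magnitude $l\in(0,1]$. The default
  concentration is symmetric ($\bar\phi=1$); a `"structured"` option
  biases each consumer's leakage toward resources the *other* consumers
  prefer, generating cooperative, cross-feeding-prone communities.
  Self-leakage is permitted. Magnitudes above 0.8 warn (outside the
  empirically plausible range 0.01-0.8).
- **Maintenance and supply** are held equal and constant,
  $m_i=\rho_\alpha=0.2$ — consumers are energetically equivalent, which
  costs no generality for the questions asked here.
- Dirichlet draws are normalized gammas with a $10^{-8}$ concentration
  floor so structurally-zero preferences cannot produce degenerate rows.

Community size defaults to $N=M=10$: large enough for nontrivial overlap
and cross-feeding structure, small enough that ensembles of hundreds run
in minutes on one CPU.

**Balanced ensembles.** `balanced_ensemble()` stratifies draws over a grid
of leakage magnitudes and realized niche-overlap bins (low $<0.4$, medium
$0.4$-$0.7$, high $>0.7$; cutoffs configurable). Each cell is filled by
rejection sampling from a bin-specific preset — low: $(k_\theta,\Omega) =
(0.3, 3)$; medium: $(3, 10)$; high: $(10, 50)$ — calibrated once so each
preset lands in its bin with high probability at $N=M=10$. Cells that
cannot be filled within the retry budget are reported as underfilled, not
silently dropped. Realized overlap and cross-feeding are recorded per
community, since they — not the knob settings — are the scientifically
meaningful covariates.

What the generator does *not* emulate: taxonomic realism, fitted
empirical uptake/leakage spectra, uneven supply, or consumer-specific
maintenance. Conclusions from passing tests are about the model class
under this parameterization, not about any particular real community.

## 4. Integration, equilibration and polishing

Both models are integrated with `deSolve::lsoda` (relative tolerance
$10^{-8}$, absolute $10^{-10}$) with the analytic Jacobian supplied;
high-leakage communities are stiff. The output grid is dense over the
early transient (step 0.1 to $t=10$, 0.5 to $t=100$) and geometric to
`t_max` (default $10^5$).

**Equilibration time.** $t_{eq}$ is the first saved time from which the
residual $\max_k|\dot x_k| / \max(\|x\|_\infty,10^{-6})$ stays below
`eq_tol` (default $10^{-4}$) through the end of the run, sustained for at
least 10 time units. Two choices here deserve explanation:

- *Community-scale normalization.* A per-component relative criterion
  never triggers while any species is slowly going extinct (a decaying
  exponential has constant per-capita rate), and near-marginal stragglers
  with rates $10^{-3}$-$10^{-4}$ are common at these community sizes.
  Normalizing by the community scale makes $t_{eq}$ measure the
  equilibration of the community, not of its most slowly dying member.
- *Tolerance $10^{-4}$.* The equilibrium error metric is meaningful only
  if it is evaluated when the system has *dynamically* settled, not after
  both models have been sitting on their (identical, by construction)
  attractor for thousands of time units — in the latter regime the metric
  is identically zero and carries no information. $10^{-4}$ corresponds to
  abundance change per unit time below 0.01% of the community scale, a
  standard plateau-detection level. The tolerance is configurable;
  precision experiments in the test suite tighten it to $10^{-7}$.

**Polishing.** The reached equilibrium is refined to machine precision by
a Newton iteration on the survivor/resource block (per-capita growth
equations for survivors, resource balances), using the analytic Jacobian,
with an active-set rule: a nominal survivor the solve pushes below the
extinction threshold ($10^{-8}$) is moved to the extinct set and the solve
repeated — with it retained the consumer equations have no solution and
the iteration stalls. Polishing decouples the accuracy of $C^*$ (and hence
of the reduction's fixed-point preservation, tested at $10^{-8}$) from the
equilibration criterion. If polishing fails the integration endpoint is
used and flagged. The reduced model's equilibrium is polished analogously;
its survivor block solves the linear system $A_{ss}C_s=-r_s$.

**Nonnegativity.** States the solver drives below zero by less than the
absolute tolerance are clipped; larger excursions are integrator errors.

## 5. Accuracy metrics

With both models on the shared grid over $[0,t_{eq}]$ from identical
initial abundances (default: everything at 0.1),

$$\mathrm{Err}(t)=\frac1N\sum_i\log\frac{C^{LV}_i(t)}{C^{CR}_i(t)},$$

`error_metrics()` reports the time average $\mathrm{Err}_{traj}$
(trapezoidal quadrature on the solver grid) and the terminal value
$\mathrm{Err}_{eq}$, both signed (positive = the reduction overshoots) and
in absolute value. Abundances are floored at $10^{-8}$ before logs; a
floored per-species $|\log$-ratio$|$ exceeding $\log 10^6$ flags the
comparison as diverged — the log-ratio error diverges when one model
predicts an extinction the other does not, and that sensitivity to
compositional mismatch is intentional. Composition itself is compared
between the two *attractors* (the full model's polished equilibrium and
the reduction integrated to its own equilibrium), not at $t_{eq}$, where
slowly dying species would spuriously count as survivors.

## 6. Community structure metrics

- **Niche overlap** $N_o$: mean pairwise cosine similarity of uptake rows
  (1 = identical diets). Invariant to row rescaling and consumer/resource
  relabeling.
- **Average preference** $\bar u$: the arithmetic row mean.
- **Effective leakage** $L^{eff}_i[\beta]=\sum_\alpha u_{i\alpha}l^i_{\alpha\beta}$:
  what consumer $i$ leaks when all resources are equally available; each
  row sums to the leakage magnitude.
- **Cross-feeding** $C_{feed}$: mean cosine similarity between
  $L^{eff}_i$ and the diets $u_j$ of the other consumers. The conventional
  formula sums over ordered pairs $(i,j\ne i)$ while normalizing by the
  unordered pair count $N(N-1)/2$, giving range $[0,2]$ for nonnegative
  inputs; `cfeed()` implements that convention as the default
  (`normalization = "printed"`) and offers the ordered-pair mean
  (`"mean"`, range $[0,1]$). The two differ by an exact factor of 2; the
  documentation of range matters more than the choice.

## 7. Stability, reactivity, and timescale separation

At the paired equilibrium, `stability_reactivity_report()` compares the
dominant eigenvalue (stability) and the leading eigenvalue of the
Hermitian part $H(J)=(J+J^\top)/2$ (reactivity: positive means transient
amplification of some perturbation) of:

- the consumer-resource Jacobian restricted to **surviving consumers plus
  all resources**, and
- the reduced model's Jacobian restricted to survivors (at $C^*$ this is
  $\mathrm{diag}(C^*)A$ on the survivor block).

Extinct consumers are excluded from both. This is a deliberate choice:
their rows decouple at $C_i=0$ and their diagonal entries equal their
(often near-zero) invasion deficits, which would otherwise *be* the
dominant eigenvalue in a large fraction of communities — the comparison
would then measure invasion margins of absent species rather than the
resident community's response to perturbation. With the restriction, the
reduction's dominant eigenvalue lies on or above the full model's in
essentially all converged runs (it underestimates stability), while
reactivity of the full model is positive universally and the reduction
frequently misses it entirely.

**Return times.** Resource return times come from the resource-block
diagonal of the consumer-resource Jacobian,
$\tau_{R,\beta}=1/|J^{RR}_{\beta\beta}|$. The full model's *consumer*
diagonal is identically zero at equilibrium (it equals per-capita growth),
so consumer return times use the reduced Jacobian diagonal,
$\tau_{C,i}=1/|C^*_iA_{ii}|$, for survivors — consistent with reading the
diagonal as the self-regulation rate where that reading is well-posed.

**Separation.** `timescale_separation()` forms all fast/slow ratios
$\tau_{R,\beta}/\tau_{C,i}$ and collapses them with an aggregator.
Orientation: $\varepsilon$ must be small when resources are *fast*, since
the reduction's error is $O(\varepsilon)$ and its validity horizon
$t\sim O(\varepsilon^{-1})$; writing the ratio resource-over-consumer
makes every quantitative statement consistent. The default aggregator is
the **largest** ratio — the least-separated consumer-resource pair, which
is the *smallest* ratio in the conventional consumer-over-resource
orientation and the conservative proxy: $\varepsilon\to 1$ marks the
breakdown of the fast-resource assumption, and across ensembles
$\varepsilon$ correlates strongly and positively with
$|\mathrm{Err}_{eq}|$. The most-separated pair (`"smallest"`) and the
median are available for sensitivity analysis; note the most-separated
pair is dominated by rare survivors, whose weak self-regulation inflates
$\tau_C$ (apparent separation) at exactly the same time as their
near-marginal dynamics inflate the error, making that reading
anti-predictive. The validity ratio
$\log_{10}(\varepsilon^{-1}/t_{eq})$ is reported with the flag
`predicted_valid` ($\ge 0$); under the default study conditions
$t_{eq}$ is far longer than the conservative horizon, so the flag's
threshold form rarely fires and the diagnostic's value is its monotone
relationship with error.

## 8. The fast-resource limit as a consistency check

Scaling $u$ and $\rho$ by $s$ sends the community to the singular
perturbation limit: in scaled variables ($C/s$, $sR$) the resource
equations accelerate as $s^2$ while the consumer equations are unchanged,
so as $s\to\infty$ the full model converges to the nonlinear QSS-reduced
flow. Two details make the numerical experiment faithful to that
statement:

- the $O(\varepsilon)$ error bound concerns relaxation near the slow
  manifold, so the comparison starts from a *perturbed equilibrium*
  ($\pm 30\%$ lognormal on survivors) with resources initialized on the
  QSS manifold — from far-from-equilibrium assembly inits the
  scale-invariant linearization error dominates and does not shrink
  with $s$;
- initial abundances and extinction/flooring scales must be scaled with
  $s$ (equilibrium abundances scale as $s$), otherwise species that were
  floored at $s=1$ un-floor at $s=10$ and create spurious error.

Under that protocol $\varepsilon$ falls as $1/s^2$ and the median
$|\mathrm{Err}_{eq}|$ falls monotonically toward zero, as the test suite
checks.

## 9. Ensemble experiments and problem sizes

`run_pair()` never throws on a valid community: every stage failure
becomes a reason code in the one-row comparison record, so ensemble tables
always have one row per community. The acceptance-level experiments use a
balanced ensemble of 5 leakage magnitudes $\times$ 3 overlap bins
$\times$ 30 replicates at $N=M=10$ (450 paired fits, about a minute of
desk-scale compute); `scripts/acceptance.R` re-runs a 150-community
version from a command-line seed. Within medium and high overlap bins the
error metrics rise with leakage (tested as a positive rank correlation
plus an endpoint-median comparison — with 30 replicates per cell the
sampling noise of individual cell medians is comparable to the trend
between adjacent leakage levels, so stepwise monotonicity of cell medians
is not a reliable statistic). Signed error distributions are retained in
the records so skew can be examined.

## 10. Known limitations

- The reduction is first-order only; no triplet (higher-order) interaction
  coefficients are computed.
- No statistical inference of GLV coefficients from time series — the
  package constructs the reduction analytically from known mechanism, so
  identifiability questions about fitting are out of scope.
- The equilibration time, and with it everything measured "at $t_{eq}$",
  depends on an explicit, configurable criterion; results should be read
  as conditional on that definition.
- At the default community size the two models almost always share an
  attractor from shared initial conditions; compositional mismatch — a
  major error channel in larger or more strongly coupled systems — is
  correspondingly rare here, and the error medians are dominated by
  transient and near-threshold discrepancies.
- Aggregating the timescale ratios is genuinely ambiguous; both readings
  are implemented and the default is the one that is empirically
  predictive and consistent with the conventional orientation.
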