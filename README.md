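# glvapprox

Microbial communities are routinely modelled with the generalized
Lotka-Volterra (GLV) equations, in which species interact only through
pairwise coefficients. But microbes mostly interact *indirectly* — by
competing for substrates and by cross-feeding on each other's leaked
metabolites — and whether a pairwise model can represent such
resource-mediated dynamics is an open question with real consequences for
anyone fitting GLV models to abundance time series.

`glvapprox` makes that question computable. It

1. samples random **microbial consumer-resource communities** (uptake
   matrices from Dirichlet distributions with controlled niche overlap,
   metabolite-leakage tensors with controlled total leakage, constant
   maintenance and supply),
2. derives, for each community, its **exact first-order Lotka-Volterra
   reduction** around the equilibrium the full model reaches, and
3. quantifies where the reduction fails: trajectory and equilibrium
   **log-ratio errors**, **stability** and **reactivity** of the paired
   Jacobians, and a **consumer-resource timescale-separation** diagnostic
   that predicts the reduction's validity horizon.

## The model and its reduction

The consumer-resource dynamics for biomasses \(C_i\) (i = 1..N) and
resources \(R_\beta\) (β = 1..M) are

$$\dot C_i = C_i\Big(\sum_\alpha (1-l^i_\alpha)\,u_{i\alpha} R_\alpha - m_i\Big),\qquad
\dot R_\beta = \rho_\beta - \sum_i u_{i\beta} R_\beta C_i
 + \sum_{i,\alpha} l^i_{\alpha\beta}\,u_{i\alpha} C_i R_\alpha,$$

where \(u_{i\alpha}\) is uptake, \(m_i\) maintenance, \(\rho_\beta\) supply,
and \(l^i_{\alpha\beta}\) the fraction of resource α consumed by species *i*
that is leaked back as resource β (total leakage
\(l^i_\alpha=\sum_\beta l^i_{\alpha\beta}\)).

Assuming resources equilibrate fast, \(R^*(C)\) solves the linear balance
\(M(C)R=\rho\); Taylor-expanding the per-capita growth on that manifold
around the reached equilibrium \(C^*\) gives a GLV system
\(\dot C_i = C_i(r_i + \sum_j A_{ij}C_j)\) with

$$A_{ij} = \sum_\alpha (1-l^i_\alpha)\,u_{i\alpha}\,
\frac{\partial R^*_\alpha}{\partial C_j}\Big|_{C^*},\qquad
r_i = g_i(C^*) - \sum_j A_{ij}C^*_j,$$

computed by implicit differentiation
\(\partial R^*/\partial C_j = -M^{-1}(\partial M/\partial C_j)R^*\). By
construction \(C^*\) is a fixed point of the reduction; the science is in
how the two models *get there*, and how they respond to perturbations once
there.

## Worked example

```r
library(glvapprox)
comm <- sample_community(N = 10, M = 10, leakage = 0.4, seed = 42)
fit  <- glva(comm)
summary(fit)
```

```
Lotka-Volterra approximation summary
  community: N = 10 , M = 10 , leakage = 0.4 , niche overlap = 0.489
  t_eq = 885.87 ; survivors (CR model / LV): 7 / 7
  accuracy: Err_traj = -0.001339 , Err_eq = 0.002864 , diverged = FALSE
  stability: Re lambda_dom CR = -0.003753 , LV = -0.003739
  reactivity: CR = 0.134 , LV = -0.00112
  timescales: epsilon = 0.08606 , validity ratio = -1.882 , predicted valid = FALSE
```

Reading this: the community equilibrated at `t_eq = 886` with 7 of 10
species surviving, and the reduction reached the same composition. The
time-averaged and terminal log-ratio errors are small (~0.1-0.3%). Both
models are locally stable with nearly identical dominant eigenvalues, but
they disagree qualitatively about the transient: the consumer-resource
model amplifies perturbations before decaying (reactivity +0.134) while its
GLV reduction predicts damping (−0.001) — the reduction cannot represent the
resource-mediated feedback that causes transient amplification. The
timescale diagnostic ε = 0.086 (least-separated consumer-resource pair)
says resources are ~12× faster than the slowest relevant consumer.

`coef(fit)` returns the effective growth rates and interaction matrix
(surviving species all get `r = m = 0.2`, an exact consequence of the
degree-−1 homogeneity of `R*(C)`):

```
       r
[1,] 0.2 -0.0364 -0.0128 -0.0144 -0.0207 ...
[2,] 0.2 -0.0132 -0.0370 -0.0210 -0.0196 ...
```

`predict()`, `simulate()`, `residuals()` and `plot()` integrate the
reduction from new initial conditions, probe random initial conditions,
return per-species log-ratio series, and overlay the paired trajectories.

For ensembles:

```r
ens <- balanced_ensemble(leakage_levels = c(0.01, 0.2, 0.4, 0.6, 0.8),
                         replicates = 10, N = 10, M = 10, seed = 1)
rec <- run_ensemble(ens)       # one comparison record per community
summarize_ensemble(rec)        # medians/IQRs per (leakage, overlap) cell
```

## Documentation

The methods vignette (`vignettes/glva-methods.Rmd`) describes the sampling
scheme, the derivation, the equilibration and polishing machinery, the
metric definitions (including the two cross-feeding normalizations and the
timescale-aggregator choices), and the package's known limitations.
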