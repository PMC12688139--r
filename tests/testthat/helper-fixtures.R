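# shared fixtures: closed-form communities and a cached study ensemble

# 1-consumer 1-resource community with u = 1, m = rho = 0.2 and total
# leakage l; closed forms: C* = rho/m = 1, R* = m/((1-l)u),
# A11 = -m^2/rho = -0.2, r1 = m (at l = 0), tau_R = 1/((1-l)uC*),
# tau_C = 1/|C* A11| = 5
community_1x1 <- function(l = 0) {
  community_params(matrix(1, 1, 1), array(l, c(1, 1, 1)), 0.2, 0.2,
                   metadata = list(leakage_magnitude = l))
}

# small random feasible community for oracle checks
random_community <- function(seed, N = NULL, M = NULL, leakage = NULL) {
  set.seed(seed)
  N <- N %||% sample(2:5, 1)
  M <- M %||% sample(2:5, 1)
  leakage <- leakage %||% stats::runif(1, 0.05, 0.7)
  sample_community(N = N, M = M, leakage = leakage, k_theta = 1, omega = 5,
                   seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# central finite-difference Jacobian of a vector field
fd_jacobian <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    hp <- h * max(abs(x[k]), 1)
    xp <- x; xp[k] <- xp[k] + hp
    xm <- x; xm[k] <- xm[k] - hp
    (f(xp) - f(xm)) / (2 * hp)
  }, numeric(length(f(x))))
}

# scale resource turnover: u and rho multiplied by s (leakage fractions and
# maintenance unchanged), pushing the community toward the fast-resource limit
scale_turnover <- function(community, s) {
  community_params(community$uptake * s, community$leakage,
                   community$maintenance, community$supply * s,
                   metadata = community$metadata)
}

# paired comparison in the fast-resource limit: the community's uptake and
# supply are scaled by s and both models relax from the same perturbed
# equilibrium state (abundances, floors and thresholds scaled consistently,
# resources started on the quasi-steady-state manifold), the regime where
# the reduction's O(epsilon) error bound applies
turnover_relaxation <- function(community, s, perturbation,
                                control = solver_control(eq_tol = 1e-7,
                                                         t_max = 2e5)) {
  base <- glva(community, control = control)
  if (!base$converged) return(NULL)
  Cs <- base$micrm$equilibrium$C_star
  surv <- base$micrm$equilibrium$survivors
  comm_s <- scale_turnover(community, s)
  C0 <- s * Cs * perturbation
  C0[-surv] <- 0
  R0 <- tryCatch(as.vector(resource_qss(C0, comm_s)),
                 error = function(e) NULL)
  if (is.null(R0) || any(R0 < 0)) return(NULL)
  run_pair(comm_s, init = list(C = C0, R = R0), err_floor = 1e-8 * s,
           control = control)
}

# the study ensemble used by the acceptance tests: balanced over leakage x
# niche-overlap bins, 30 replicates per cell, N = M = 10; computed once and
# cached for the session
.ens_cache <- new.env(parent = emptyenv())
study_ensemble <- function() {
  if (is.null(.ens_cache$rec)) {
    ens <- balanced_ensemble(
      leakage_levels = c(0.01, 0.2, 0.4, 0.6, 0.8),
      bins = c("low", "medium", "high"),
      replicates = 30, N = 10, M = 10, seed = 20260926)
    .ens_cache$ens <- ens
    .ens_cache$rec <- run_ensemble(ens)
  }
  list(communities = .ens_cache$ens, records = .ens_cache$rec)
}
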