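test_that("resource sensitivity matches finite differences of the QSS", {
  for (seed in 1:8) {
    comm <- random_community(seed + 400, N = 4, M = 4)
    C <- stats::runif(4, 0.3, 2)
    S <- resource_sensitivity(C, comm)
    Sfd <- fd_jacobian(function(Cv) as.vector(resource_qss(Cv, comm)), C)
    expect_lt(max(abs(S - Sfd)), 1e-5)
  }
})

test_that("1x1 sensitivity and linearity in supply follow the closed form", {
  # R*(C) = rho / (u C) so dR*/dC = -R*/C
  one <- community_1x1(0)
  expect_equal(as.vector(resource_sensitivity(1, one)), -0.2,
               tolerance = 1e-12)
  # M(C) R = rho is linear in rho: doubling rho doubles R* and dR*/dC
  comm <- random_community(61, N = 3, M = 3)
  comm2 <- community_params(comm$uptake, comm$leakage, comm$maintenance,
                            comm$supply * 2)
  C <- c(0.5, 1, 1.5)
  expect_equal(as.vector(resource_qss(C, comm2)),
               2 * as.vector(resource_qss(C, comm)), tolerance = 1e-10)
  expect_equal(resource_sensitivity(C, comm2),
               2 * resource_sensitivity(C, comm), tolerance = 1e-10)
})

test_that("the 1x1 reduction recovers A = -m^2/rho and r = m", {
  one <- community_1x1(0)
  eq <- list(C_star = 1, R_star = 0.2, survivors = 1L, converged = TRUE)
  glv <- effective_glv(one, eq)
  expect_equal(as.vector(glv$A), -0.2, tolerance = 1e-12)
  expect_equal(glv$r, 0.2, tolerance = 1e-12)
  expect_equal(glv_rhs(1, glv), 0, tolerance = 1e-12)
})

test_that("the interaction matrix matches finite differences of QSS growth", {
  # independent route: differentiate g_i(C) = (1-l) u R*(C) - m numerically
  for (seed in 1:8) {
    comm <- random_community(seed + 500, N = 4, M = 4)
    C <- stats::runif(4, 0.3, 2)
    R <- as.vector(resource_qss(C, comm))
    A <- effective_glv(comm, list(C_star = C, R_star = R,
                                  survivors = 1:4))$A
    g <- function(Cv) {
      as.vector(((1 - comm$l_total) * comm$uptake) %*%
                  as.vector(resource_qss(Cv, comm))) - comm$maintenance
    }
    expect_lt(max(abs(A - fd_jacobian(g, C))), 1e-5)
  }
})

test_that("single shared resource without leakage gives pure competition", {
  set.seed(71)
  u <- matrix(stats::runif(2, 0.5, 1.5), 2, 1)
  comm <- community_params(u, array(0, c(2, 1, 1)), 0.2, 0.2)
  C <- c(0.8, 1.2)
  glv <- effective_glv(comm, list(C_star = C,
                                  R_star = as.vector(resource_qss(C, comm)),
                                  survivors = 1:2))
  expect_true(all(glv$A < 0))
})

test_that("two identical specialists without leakage have symmetric closed-form interactions", {
  # both consumers eat the single resource with u = 1: R*(C) = rho/(C1+C2),
  # so A_ij = dR*/dC_j = -rho/(C1+C2)^2 for all i, j
  u <- matrix(1, 2, 1)
  comm <- community_params(u, array(0, c(2, 1, 1)), 0.2, 0.2)
  C <- c(0.4, 0.6)
  glv <- effective_glv(comm, list(C_star = C,
                                  R_star = as.vector(resource_qss(C, comm)),
                                  survivors = 1:2))
  expect_equal(glv$A, matrix(-0.2 / 1, 2, 2), tolerance = 1e-10)
  expect_equal(glv$A, t(glv$A), tolerance = 1e-12)
})

test_that("the GLV vector field and Jacobian follow the standard form", {
  glv <- structure(list(r = 0.2, A = matrix(-0.2, 1, 1), C_star = 1,
                        survivors = 1L), class = "glv_system")
  expect_equal(glv_rhs(0.5, glv), 0.5 * (0.2 - 0.1))
  expect_equal(glv_rhs(0, glv), 0)
  expect_equal(glv_jacobian(1, glv)[1, 1], -0.2, tolerance = 1e-12)
  # random system: Jacobian vs finite differences
  set.seed(81)
  rN <- 4
  sys <- structure(list(r = stats::runif(rN, -1, 1),
                        A = matrix(stats::rnorm(rN * rN, 0, 0.3), rN),
                        C_star = rep(1, rN), survivors = seq_len(rN)),
                   class = "glv_system")
  C <- stats::runif(rN, 0.1, 2)
  expect_lt(max(abs(glv_jacobian(C, sys) -
                    fd_jacobian(function(x) glv_rhs(x, sys), C))), 1e-5)
  expect_error(glv_rhs(c(1, 2), glv), "mismatch")
})

test_that("GLV integration finds the logistic fixed point and stays there", {
  glv <- structure(list(r = 0.2, A = matrix(-0.2, 1, 1), C_star = 1,
                        survivors = 1L), class = "glv_system")
  sim <- integrate_glv(glv, init = 0.1)
  expect_true(sim$equilibrium$converged)
  expect_equal(as.vector(sim$equilibrium$C_star), 1, tolerance = 1e-6)
  # starting at the fixed point: constant trajectory
  sim0 <- integrate_glv(glv, init = 1)
  expect_lt(max(abs(sim0$C - 1)), 1e-8)
})

test_that("converged fits preserve the expansion fixed point", {
  for (seed in c(601, 602, 603, 604)) {
    comm <- sample_community(N = 6, M = 6, leakage = 0.4, seed = seed)
    fit <- glva(comm)
    expect_true(fit$converged)
    surv <- fit$micrm$equilibrium$survivors
    resid <- (fit$system$r +
                as.vector(fit$system$A %*% fit$system$C_star))[surv]
    expect_lt(max(abs(resid)), 1e-8)
    # and the reduced vector field vanishes there
    expect_lt(max(abs(glv_rhs(fit$system$C_star, fit$system)[surv])), 1e-8)
  }
})

test_that("fit methods expose coefficients, predictions and residuals", {
  comm <- sample_community(N = 4, M = 4, leakage = 0.2, seed = 11)
  fit <- glva(comm)
  expect_true(fit$converged)
  cf <- coef(fit)
  expect_equal(dim(cf), c(4L, 5L))
  expect_equal(cf[, "r"], fit$system$r)
  pr <- predict(fit, init = fit$system$C_star)
  expect_lt(max(abs(t(pr$C) - fit$system$C_star)), 1e-6)
  res <- residuals(fit)
  expect_equal(ncol(res), 4L)
  expect_equal(nrow(res), length(fit$accuracy$times))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_output(print(fit), "Lotka-Volterra")
  expect_output(print(summary(fit)), "timescales")
})

test_that("accelerating resource turnover shrinks both epsilon and the error", {
  # scale u and rho by s: resources equilibrate ever faster and the
  # reduction approaches the true dynamics around equilibrium
  comm <- sample_community(N = 5, M = 5, leakage = 0.4, seed = 17)
  set.seed(17)
  pert <- exp(stats::runif(5, -0.3, 0.3))
  eps <- err <- numeric(0)
  for (s in c(1, 10, 100)) {
    rec <- turnover_relaxation(comm, s, pert)
    expect_true(rec$converged)
    eps <- c(eps, rec$epsilon)
    err <- c(err, rec$abs_err_eq)
  }
  expect_true(all(diff(eps) < 0))
  expect_lt(err[3], err[1])
})
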