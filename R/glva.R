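#' Sensitivity of quasi-steady-state resources to consumer abundances
#'
#' Implicitly differentiates the resource balance \eqn{M(C) R = \rho}:
#' \deqn{\partial R^*/\partial C_j = -M(C)^{-1} (\partial M/\partial C_j) R^*,}
#' with \eqn{(\partial M/\partial C_j)_{\beta\gamma} = \delta_{\beta\gamma}
#' u_{j\beta} - l^j_{\gamma\beta} u_{j\gamma}}. One dense factorization of
#' \eqn{M(C)} is shared across all consumer columns.
#'
#' @param C_star consumer abundance vector at the expansion point.
#' @param params a \code{community_params} object.
#' @param R_star optional quasi-steady-state resources at \code{C_star}
#'   (computed if missing).
#' @return an \code{M x N} matrix; column \eqn{j} is
#'   \eqn{\partial R^*/\partial C_j}.
#' @export
resource_sensitivity <- function(C_star, params, R_star = NULL) {
  R_star <- R_star %||% as.vector(resource_qss(C_star, params))
  Mmat <- qss_matrix(C_star, params)
  if (rcond(Mmat) < 1e-12)
    stop("quasi-steady state undefined at the expansion point")
  u <- params$uptake
  G <- matrix(vapply(seq_len(params$N), function(j) {
    lj <- matrix(params$leakage[j, , ], params$M, params$M)  # [alpha, beta]
    dMj <- diag(u[j, ], params$M, params$M) - t(lj * u[j, ])
    as.vector(dMj %*% R_star)
  }, numeric(params$M)), nrow = params$M)
  -solve(Mmat, G)
}

#' Effective Lotka-Volterra system from a consumer-resource equilibrium
#'
#' Builds the exact first-order Lotka-Volterra reduction of a
#' consumer-resource community around a reached equilibrium: resources are
#' eliminated at quasi-steady state and the per-capita growth on that
#' manifold, \eqn{g_i(C) = \sum_\alpha (1 - l^i_\alpha) u_{i\alpha}
#' R^*_\alpha(C) - m_i}, is Taylor-expanded to first order at \eqn{C^*}.
#' The interaction matrix and growth rates are
#' \deqn{A_{ij} = \sum_\alpha (1 - l^i_\alpha) u_{i\alpha}
#'   \frac{\partial R^*_\alpha}{\partial C_j},\qquad
#'   r_i = g_i(C^*) - \sum_j A_{ij} C^*_j.}
#' By construction the expansion point is a fixed point of the reduced
#' dynamics for every surviving species (\eqn{g_i(C^*) = 0} so
#' \eqn{r_i = -\sum_j A_{ij} C^*_j}); extinct species keep their row and
#' column with \eqn{r_i = g_i(C^*)}, their (generally negative) invasion
#' growth rate.
#'
#' @param params a \code{community_params} object.
#' @param equilibrium an equilibrium list as produced by [integrate_micrm()]
#'   (components \code{C_star}, \code{R_star}, \code{converged},
#'   \code{survivors}).
#' @return an object of class \code{glv_system}: list with \code{r},
#'   \code{A}, \code{C_star}, \code{R_star}, \code{survivors}.
#' @export
effective_glv <- function(params, equilibrium) {
  C_star <- equilibrium$C_star
  R_star <- equilibrium$R_star %||% as.vector(resource_qss(C_star, params))
  S <- resource_sensitivity(C_star, params, R_star = R_star)
  net <- (1 - params$l_total) * params$uptake
  A <- net %*% S
  g <- as.vector(net %*% R_star) - params$maintenance
  r <- g - as.vector(A %*% C_star)
  if (!all(is.finite(A)) || !all(is.finite(r)))
    stop("non-finite Lotka-Volterra coefficients")
  structure(list(r = r, A = A, C_star = C_star, R_star = R_star,
                 survivors = equilibrium$survivors %||%
                   which(C_star > 0)),
            class = "glv_system")
}

#' Lotka-Volterra vector field
#'
#' @param C consumer abundance vector.
#' @param glv a \code{glv_system} from [effective_glv()].
#' @return the derivative vector \eqn{\dot C_i = C_i (r_i + \sum_j A_{ij} C_j)}.
#' @export
glv_rhs <- function(C, glv) {
  if (length(C) != length(glv$r)) stop("dimension mismatch")
  C * (glv$r + as.vector(glv$A %*% C))
}

#' Jacobian of the Lotka-Volterra dynamics
#'
#' \eqn{J_{ij} = \delta_{ij}(r_i + \sum_k A_{ik} C_k) + C_i A_{ij}}. At the
#' expansion point the diagonal residual term vanishes for survivors, so the
#' survivor block reduces to \eqn{\mathrm{diag}(C^*) A}.
#'
#' @inheritParams glv_rhs
#' @return an \code{N x N} matrix.
#' @export
glv_jacobian <- function(C, glv) {
  if (length(C) != length(glv$r)) stop("dimension mismatch")
  growth <- glv$r + as.vector(glv$A %*% C)
  diag(growth, length(C)) + C * glv$A
}

#' Integrate a Lotka-Volterra system
#'
#' Consumer-only companion to [integrate_micrm()]: same solver, grid
#' construction and equilibration criterion, so paired runs share initial
#' abundances and output times.
#'
#' @param glv a \code{glv_system}.
#' @param init initial consumer abundances (default: all 0.1).
#' @param control a [solver_control()] list.
#' @param times optional explicit output grid (use the saved grid of the
#'   paired consumer-resource run for trajectory comparison).
#' @return an object of class \code{crm_sim} with \code{model = "GLVA"} and
#'   \code{R = NULL}.
#' @export
integrate_glv <- function(glv, init = NULL, control = solver_control(),
                          times = NULL) {
  N <- length(glv$r)
  init <- init %||% rep(0.1, N)
  if (any(init < 0)) stop("initial state must be nonnegative")
  times <- times %||% default_grid(control$t_max)
  func <- function(t, y, p) list(glv_rhs(pmax(y, 0), glv))
  jac <- function(t, y, p) glv_jacobian(pmax(y, 0), glv)
  sol <- deSolve::ode(y = init, times = times, func = func, parms = NULL,
                      jacfunc = jac, jactype = "fullusr",
                      method = control$method,
                      rtol = control$rtol, atol = control$atol)
  sol <- as.matrix(sol)
  states <- sol[, -1, drop = FALSE]
  states[states < 0] <- 0
  scan <- equilibration_scan(sol[, 1], states,
                             function(x) glv_rhs(x, glv), control)
  k <- if (scan$converged) scan$idx_eq else nrow(states)
  C_star <- unname(states[k, ])
  if (scan$converged) {
    # refine: the surviving block of a GLV equilibrium solves a linear system
    pol <- polish_glv_equilibrium(glv, unname(states[nrow(states), ]),
                                  extinction = control$extinction)
    if (!is.null(pol)) C_star <- pol
  }
  out <- list(times = sol[, 1], C = states, R = NULL, model = "GLVA",
              init = list(C = init),
              equilibrium = list(C_star = C_star, R_star = NULL,
                                 t_eq = scan$t_eq, converged = scan$converged,
                                 survivors = which(C_star >= control$extinction),
                                 residual = scan$residual),
              control = control)
  class(out) <- "crm_sim"
  out
}

# active-set refinement of a reached GLV equilibrium: solve
# A[s, s] C_s = -r_s on the survivor set, dropping components the solve
# makes negative; NULL on failure
polish_glv_equilibrium <- function(glv, C, extinction = 1e-8) {
  N <- length(glv$r)
  surv <- which(C >= extinction)
  for (round in seq_len(N + 1L)) {
    if (!length(surv)) return(NULL)
    As <- glv$A[surv, surv, drop = FALSE]
    if (!all(is.finite(As)) || rcond(As) < 1e-14) return(NULL)
    Cs <- tryCatch(solve(As, -glv$r[surv]), error = function(e) NULL)
    if (is.null(Cs)) return(NULL)
    drop <- surv[Cs < extinction]
    if (!length(drop)) {
      out <- numeric(N)
      out[surv] <- Cs
      if (max(abs(out - C)) > max(1, max(C))) return(NULL)  # wandered off
      return(out)
    }
    surv <- setdiff(surv, drop)
  }
  NULL
}

#' Fit the Lotka-Volterra approximation to a consumer-resource community
#'
#' The central estimator of the package. Given a community parameterization,
#' it (1) integrates the full consumer-resource dynamics from shared initial
#' conditions to equilibrium, (2) derives the exact first-order
#' Lotka-Volterra reduction at the reached equilibrium via [effective_glv()],
#' (3) re-integrates the reduced model from the same initial consumer
#' abundances on the same time grid, and (4) scores the reduction: log-ratio
#' trajectory and equilibrium errors, stability and reactivity of both
#' Jacobians, and the consumer-resource timescale-separation diagnostic
#' \eqn{\varepsilon} with its validity ratio
#' \eqn{\log_{10}(\varepsilon^{-1}/t_{eq})}.
#'
#' @param community a \code{community_params} object from
#'   [sample_community()] or [community_params()].
#' @param init optional list with initial \code{C} and \code{R} vectors
#'   (default: everything at 0.1), shared by both models.
#' @param control a [solver_control()] list.
#' @param err_floor abundance floor applied before taking log-ratios.
#' @param err_cap divergence cap: a floored per-species |log-ratio| above
#'   this flags the comparison as diverged.
#' @param aggregator how the set of resource/consumer return-time ratios is
#'   collapsed into \eqn{\varepsilon}; the default \code{"largest"} takes the
#'   least-separated pair (see [timescale_separation()]).
#' @return an object of class \code{glva} with components \code{community},
#'   \code{micrm} and \code{glv_sim} (both \code{crm_sim}), \code{system}
#'   (the \code{glv_system}), \code{accuracy}, \code{stability},
#'   \code{timescales}, and \code{converged}.
#' @examples
#' comm <- sample_community(N = 4, M = 4, leakage = 0.2, seed = 11)
#' fit <- glva(comm)
#' coef(fit)
#' summary(fit)
#' @export
glva <- function(community, init = NULL, control = solver_control(),
                 err_floor = 1e-8, err_cap = log(1e6),
                 aggregator = c("largest", "smallest", "median")) {
  aggregator <- match.arg(aggregator)
  sim_mi <- integrate_micrm(community, init = init, control = control)
  out <- list(community = community, micrm = sim_mi,
              converged = sim_mi$equilibrium$converged)
  class(out) <- "glva"
  if (!sim_mi$equilibrium$converged) {
    out$reason <- "micrm_not_converged"
    return(out)
  }
  eq <- sim_mi$equilibrium
  system <- tryCatch(effective_glv(community, eq), error = function(e) e)
  if (inherits(system, "error")) {
    out$converged <- FALSE
    out$reason <- paste("glv_construction_failed:",
                        conditionMessage(system))
    return(out)
  }
  out$system <- system
  # paired reduced run on the shared grid restricted to [0, t_eq]
  keep <- sim_mi$times <= eq$t_eq
  times_pair <- sim_mi$times[keep]
  if (length(times_pair) < 2L)
    times_pair <- c(0, max(eq$t_eq, sim_mi$times[2]))
  if (max(times_pair) < eq$t_eq) times_pair <- c(times_pair, eq$t_eq)
  sim_lv <- tryCatch(
    integrate_glv(system, init = sim_mi$init$C, control = control,
                  times = times_pair),
    error = function(e) e)
  if (inherits(sim_lv, "error")) {
    out$reason <- paste("glv_integration_failed:", conditionMessage(sim_lv))
    return(out)
  }
  out$glv_sim <- sim_lv
  mi_pair <- list(times = times_pair,
                  C = sim_mi$C[seq_along(times_pair), , drop = FALSE])
  if (sum(keep) < length(times_pair))   # t_eq appended beyond saved grid
    mi_pair$C <- rbind(sim_mi$C[keep, , drop = FALSE],
                       eq$C_star)
  out$accuracy <- error_metrics(
    structure(list(times = times_pair, C = mi_pair$C, model = "MiCRM"),
              class = "crm_sim"),
    sim_lv, t_eq = max(eq$t_eq, times_pair[2]),
    extinction_floor = err_floor, cap = err_cap)
  # composition is compared between the two settled systems, so the reduced
  # model is also run out to its own attractor (the paired run above stops
  # at t_eq for the trajectory-error comparison)
  sim_lv_full <- tryCatch(
    integrate_glv(system, init = sim_mi$init$C, control = control),
    error = function(e) NULL)
  out$glv_attractor <- if (!is.null(sim_lv_full)) sim_lv_full$equilibrium
                       else sim_lv$equilibrium
  out$accuracy$composition_match <-
    identical(out$glv_attractor$survivors, eq$survivors)
  out$stability <- stability_reactivity_report(community, eq, system)
  taus <- return_times(community, eq, system)
  out$timescales <- if (length(taus$tau_C))
    timescale_separation(taus$tau_C, taus$tau_R, eq$t_eq,
                         aggregator = aggregator)
  else NULL
  out$timescales$tau_C <- taus$tau_C
  out$timescales$tau_R <- taus$tau_R
  out
}

#' @export
print.glva <- function(x, ...) {
  cat("Lotka-Volterra approximation of a consumer-resource community\n")
  cat("  consumers:", x$community$N, " resources:", x$community$M,
      " leakage:", format(mean(x$community$l_total), digits = 3), "\n")
  if (!x$converged) {
    cat("  fit failed:", x$reason %||% "not converged", "\n")
    return(invisible(x))
  }
  cat("  equilibrated at t =", format(x$micrm$equilibrium$t_eq, digits = 5),
      "with", length(x$micrm$equilibrium$survivors), "survivors\n")
  cat("  Err_traj =", format(x$accuracy$err_traj, digits = 4),
      " Err_eq =", format(x$accuracy$err_eq, digits = 4),
      if (x$accuracy$diverged) " (diverged)" else "", "\n")
  invisible(x)
}

#' @export
coef.glva <- function(object, ...) {
  if (!object$converged) return(NULL)
  cbind(r = object$system$r, object$system$A)
}

#' @export
summary.glva <- function(object, ...) {
  out <- list(converged = object$converged,
              N = object$community$N, M = object$community$M,
              leakage = mean(object$community$l_total),
              niche_overlap = if (object$community$N >= 2)
                niche_overlap(object$community$uptake) else NA_real_)
  if (object$converged) {
    out$t_eq <- object$micrm$equilibrium$t_eq
    out$survivors_micrm <- length(object$micrm$equilibrium$survivors)
    out$survivors_glva <- length((object$glv_attractor %||%
                                    object$glv_sim$equilibrium)$survivors)
    out$accuracy <- object$accuracy[c("err_traj", "err_eq", "abs_err_eq",
                                      "diverged", "composition_match")]
    out$stability <- object$stability
    out$timescales <- object$timescales[c("epsilon", "validity_ratio",
                                          "predicted_valid")]
  } else out$reason <- object$reason
  class(out) <- "summary.glva"
  out
}

#' @export
print.summary.glva <- function(x, ...) {
  cat("Lotka-Volterra approximation summary\n")
  cat("  community: N =", x$N, ", M =", x$M,
      ", leakage =", format(x$leakage, digits = 3),
      ", niche overlap =", format(x$niche_overlap, digits = 3), "\n")
  if (!x$converged) {
    cat("  fit failed:", x$reason %||% "not converged", "\n")
    return(invisible(x))
  }
  cat("  t_eq =", format(x$t_eq, digits = 5),
      "; survivors (CR model / LV):", x$survivors_micrm, "/",
      x$survivors_glva, "\n")
  cat("  accuracy: Err_traj =", format(x$accuracy$err_traj, digits = 4),
      ", Err_eq =", format(x$accuracy$err_eq, digits = 4),
      ", diverged =", x$accuracy$diverged, "\n")
  cat("  stability: Re lambda_dom CR =",
      format(Re(x$stability$lam_dom_mi), digits = 4),
      ", LV =", format(Re(x$stability$lam_dom_lv), digits = 4), "\n")
  cat("  reactivity: CR =", format(x$stability$react_mi, digits = 4),
      ", LV =", format(x$stability$react_lv, digits = 4), "\n")
  cat("  timescales: epsilon =", format(x$timescales$epsilon, digits = 4),
      ", validity ratio =", format(x$timescales$validity_ratio, digits = 4),
      ", predicted valid =", x$timescales$predicted_valid, "\n")
  invisible(x)
}

#' Predict Lotka-Volterra trajectories from a fitted approximation
#'
#' Integrates the reduced model from new initial abundances.
#'
#' @param object a fitted \code{glva} object.
#' @param init initial consumer abundances (default: the shared initial
#'   conditions of the fit).
#' @param times output time grid (default: the fit's paired grid).
#' @param ... unused.
#' @return a \code{crm_sim} object.
#' @export
predict.glva <- function(object, init = NULL, times = NULL, ...) {
  if (!object$converged) stop("cannot predict from an unconverged fit")
  integrate_glv(object$system, init = init %||% object$micrm$init$C,
                control = object$micrm$control,
                times = times %||% object$glv_sim$times)
}

#' Simulate reduced-model trajectories from random initial conditions
#'
#' Draws \code{nsim} uniform-random initial consumer abundance vectors (on
#' (0, 2 x mean initial abundance]) and integrates the reduced model from
#' each, e.g. to probe basins of attraction of the approximation.
#'
#' @param object a fitted \code{glva} object.
#' @param nsim number of trajectories.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of \code{crm_sim} objects.
#' @export
simulate.glva <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from an unconverged fit")
  if (!is.null(seed)) set.seed(seed)
  scale <- 2 * mean(object$micrm$init$C)
  lapply(seq_len(nsim), function(k) {
    init <- stats::runif(object$community$N, 0, scale)
    integrate_glv(object$system, init = init,
                  control = object$micrm$control)
  })
}

#' Per-species log-ratio residuals of the approximation
#'
#' @param object a fitted \code{glva} object.
#' @param ... unused.
#' @return matrix (times x N) of floored log-ratios
#'   \eqn{\log(C^{LV}_i(t) / C^{CR}_i(t))} on the paired grid.
#' @export
residuals.glva <- function(object, ...) {
  if (!object$converged) stop("no residuals for an unconverged fit")
  object$accuracy$log_ratios
}

#' Plot paired consumer-resource and Lotka-Volterra trajectories
#'
#' @param x a fitted \code{glva} object.
#' @param log_time plot time on a log axis (default FALSE).
#' @param ... further graphical parameters.
#' @export
plot.glva <- function(x, log_time = FALSE, ...) {
  if (!x$converged) stop("nothing to plot for an unconverged fit")
  keep <- x$micrm$times <= x$micrm$equilibrium$t_eq
  tm <- x$micrm$times[keep]
  Cm <- x$micrm$C[keep, , drop = FALSE]
  N <- ncol(Cm)
  cols <- grDevices::hcl.colors(N, "Dark 3")
  graphics::matplot(tm, Cm, type = "l", lty = 1, col = cols,
                    log = if (log_time) "x" else "",
                    xlab = "time", ylab = "consumer abundance", ...)
  graphics::matlines(x$glv_sim$times, x$glv_sim$C, lty = 2, col = cols)
  graphics::legend("topright", legend = c("consumer-resource", "LV reduction"),
                   lty = c(1, 2), col = "black", bty = "n")
  invisible(x)
}
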