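#' Right-hand side of the microbial consumer-resource model
#'
#' Evaluates the coupled consumer-resource dynamics
#' \deqn{\dot C_i = C_i\Big(\sum_\alpha (1 - l^i_\alpha) u_{i\alpha} R_\alpha - m_i\Big)}
#' \deqn{\dot R_\beta = \rho_\beta - \sum_i u_{i\beta} R_\beta C_i +
#'   \sum_{i,\alpha} l^i_{\alpha\beta} u_{i\alpha} C_i R_\alpha}
#' where \eqn{l^i_\alpha = \sum_\beta l^i_{\alpha\beta}} is the total leakage
#' fraction. The mass budget
#' \eqn{\frac{d}{dt}(\sum C + \sum R) = \sum_\beta \rho_\beta - \sum_i m_i C_i}
#' holds identically: leakage only redistributes resource mass.
#'
#' @param C consumer biomass vector (length \code{N}).
#' @param R resource abundance vector (length \code{M}).
#' @param params a \code{community_params} object.
#' @return list with components \code{dC} and \code{dR}.
#' @export
micrm_rhs <- function(C, R, params) {
  if (length(C) != params$N || length(R) != params$M)
    stop("state dimensions do not match the community")
  if (anyNA(C) || anyNA(R)) stop("state contains NA/NaN")
  u <- params$uptake
  net <- (1 - params$l_total) * u            # (1 - l) * u, N x M
  dC <- C * (as.vector(net %*% R) - params$maintenance)
  w <- u * C                                  # w[i, a] = u_ia C_i
  consumption <- R * as.vector(crossprod(u, C))
  # leak[b] = sum_{i,a} l[i,a,b] * u_ia C_i R_a
  wr <- as.vector(t(t(w) * R))                # w[i, a] * R_a, flattened (i, a)
  leak <- as.vector(crossprod(matrix(params$leakage, params$N * params$M,
                                     params$M), wr))
  dR <- params$supply - consumption + leak
  list(dC = dC, dR = dR)
}

#' Analytic Jacobian of the consumer-resource model
#'
#' Returns the full \eqn{(N+M)\times(N+M)} Jacobian of [micrm_rhs()] at an
#' arbitrary state (consumers first, then resources). At an interior
#' equilibrium the consumer-consumer block diagonal vanishes, because it
#' equals the per-capita growth rate.
#'
#' @inheritParams micrm_rhs
#' @return a numeric matrix of dimension \code{(N + M) x (N + M)}.
#' @export
micrm_jacobian <- function(C, R, params) {
  N <- params$N; M <- params$M
  u <- params$uptake
  l <- params$leakage
  net <- (1 - params$l_total) * u
  J <- matrix(0, N + M, N + M)
  # dCdot/dC: diagonal, per-capita growth
  diag(J)[seq_len(N)] <- as.vector(net %*% R) - params$maintenance
  # dCdot/dR
  J[seq_len(N), N + seq_len(M)] <- C * net
  # dRdot/dC and dRdot/dR
  for (b in seq_len(M)) {
    lb <- matrix(l[, , b], N, M)              # lb[i, a] = l[i, a, b]
    # d(dR_b)/dC_i = -u_ib R_b + sum_a l[i,a,b] u_ia R_a
    J[N + b, seq_len(N)] <- -u[, b] * R[b] + as.vector((lb * u) %*% R)
    # d(dR_b)/dR_g = -delta_bg sum_i u_ib C_i + sum_i l[i,g,b] u_ig C_i
    J[N + b, N + seq_len(M)] <- colSums(lb * u * C)
    J[N + b, N + b] <- J[N + b, N + b] - sum(u[, b] * C)
  }
  J
}

#' Quasi-steady-state resource abundances
#'
#' Solves \eqn{\dot R = 0} at fixed consumer abundances: the linear balance
#' \eqn{M(C) R = \rho} with
#' \eqn{M_{\beta\gamma}(C) = \delta_{\beta\gamma}\sum_i u_{i\beta} C_i -
#' \sum_i l^i_{\gamma\beta} u_{i\gamma} C_i}. This is the resource manifold
#' on which the Lotka-Volterra reduction lives.
#'
#' @param C consumer abundance vector.
#' @param params a \code{community_params} object.
#' @return the resource vector solving the balance; carries attribute
#'   \code{feasible = FALSE} when any component is negative.
#' @export
resource_qss <- function(C, params) {
  Mmat <- qss_matrix(C, params)
  if (rcond(Mmat) < 1e-12)
    stop("quasi-steady state undefined: resource balance matrix is singular ",
         "(e.g. no consumption at C = 0)")
  R <- solve(Mmat, params$supply)
  if (any(R < 0)) attr(R, "feasible") <- FALSE
  R
}

# the linear resource-balance operator M(C)
qss_matrix <- function(C, params) {
  N <- params$N; M <- params$M
  u <- params$uptake
  w <- u * C
  Mmat <- diag(colSums(w), M, M)
  for (b in seq_len(M)) {
    lb <- matrix(params$leakage[, , b], N, M)
    Mmat[b, ] <- Mmat[b, ] - colSums(lb * w)
  }
  Mmat
}

#' Integration control settings
#'
#' Collects solver and equilibration settings shared by [integrate_micrm()]
#' and [integrate_glv()]. The defaults use a stiff-capable solver with tight
#' tolerances because strongly coupled (high-leakage) communities produce
#' stiff dynamics.
#'
#' @param rtol,atol relative and absolute integration tolerances.
#' @param t_max maximum integration time.
#' @param eq_tol equilibration tolerance on the residual scaled by the
#'   community abundance scale,
#'   \eqn{\max_k |\dot x_k| / \max(\|x\|_\infty, 10^{-6})}; normalizing by
#'   the largest state component (rather than per component) keeps slow
#'   straggler extinctions at tiny abundance from stalling the criterion.
#' @param eq_window time the residual must stay below \code{eq_tol} for the
#'   system to count as equilibrated.
#' @param extinction abundance below which a consumer counts as extinct at
#'   equilibrium.
#' @param method a \pkg{deSolve} method name.
#' @return a list of class \code{solver_control}.
#' @export
solver_control <- function(rtol = 1e-8, atol = 1e-10, t_max = 1e5,
                           eq_tol = 1e-4, eq_window = 10,
                           extinction = 1e-8, method = "lsoda") {
  structure(list(rtol = rtol, atol = atol, t_max = t_max, eq_tol = eq_tol,
                 eq_window = eq_window, extinction = extinction,
                 method = method), class = "solver_control")
}

# output grid: dense at early times where the transient lives, geometric later
default_grid <- function(t_max) {
  g <- seq(0, min(10, t_max), by = 0.1)
  if (t_max > 10) g <- c(g, seq(10.5, min(100, t_max), by = 0.5))
  if (t_max > 100)
    g <- c(g, exp(seq(log(100), log(t_max), length.out = 400))[-1])
  unique(c(pmin(g, t_max), t_max))
}

# shared equilibration scan: residual(t) on the saved grid, t_eq = first
# saved time from which the residual (scaled by the community abundance
# scale, so straggler extinctions at tiny abundance do not stall it) stays
# below eq_tol through the end of the run, for at least eq_window time units
equilibration_scan <- function(times, states, deriv_fn, control) {
  resid <- vapply(seq_along(times), function(k) {
    x <- states[k, ]
    d <- deriv_fn(x)
    max(abs(d)) / max(abs(x), 1e-6)
  }, numeric(1))
  ok <- resid < control$eq_tol
  n <- length(times)
  sustained <- rev(cumprod(rev(ok))) > 0   # ok from here to the end
  idx <- which(sustained)
  if (length(idx) &&
      (times[n] - times[idx[1]] >= control$eq_window || idx[1] == 1L)) {
    k <- idx[1]
    list(converged = TRUE, t_eq = times[k], idx_eq = k, residual = resid[k],
         resid = resid)
  } else {
    list(converged = FALSE, t_eq = NA_real_, idx_eq = NA_integer_,
         residual = resid[n], resid = resid)
  }
}

# Newton refinement of a reached equilibrium. Consumers below the extinction
# threshold are pinned at zero; the survivor/resource block is solved with
# the analytic Jacobian. Survivors that Newton drives below the threshold are
# moved to the extinct set and the solve repeated. Falls back to the
# unpolished state if the iteration fails or wanders.
polish_equilibrium <- function(params, C, R, extinction = 1e-8,
                               tol = 1e-13, max_newton = 50) {
  N <- params$N; M <- params$M
  surv <- which(C >= extinction)
  C0 <- C; R0 <- R
  for (round in seq_len(N + 1L)) {
    if (!length(surv)) return(NULL)
    Cw <- numeric(N); Cw[surv] <- pmax(C0[surv], extinction); Rw <- R0
    ok <- FALSE; dying <- integer(0)
    for (it in seq_len(max_newton)) {
      d <- micrm_rhs(Cw, Rw, params)
      # per-capita consumer residual so survivor rows are well-scaled
      Fv <- c((as.vector(((1 - params$l_total) * params$uptake) %*% Rw) -
                 params$maintenance)[surv], d$dR)
      if (max(abs(Fv)) < tol) { ok <- TRUE; break }
      J <- micrm_jacobian(Cw, Rw, params)
      # rows: per-capita growth of survivors (d g_i / d .), resources
      rows <- c(surv, N + seq_len(M))
      Jr <- J[rows, rows, drop = FALSE]
      Jr[seq_along(surv), ] <- Jr[seq_along(surv), , drop = FALSE] /
        pmax(Cw[surv], .Machine$double.eps)
      step <- tryCatch(solve(Jr, Fv), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      x <- c(Cw[surv], Rw) - step
      Cw[surv] <- x[seq_along(surv)]
      Rw <- x[length(surv) + seq_len(M)]
      if (any(!is.finite(x)) || max(abs(x)) > 1e6) return(NULL)
      # a nominal survivor the solve pushes below the extinction threshold
      # is not viable at this equilibrium: move it to the extinct set now
      # (with it retained, the consumer equations have no solution and the
      # iteration stalls)
      dying <- surv[Cw[surv] < extinction]
      if (length(dying)) { surv <- setdiff(surv, dying); break }
    }
    if (!ok && !length(dying)) return(NULL)  # stalled without progress
    if (ok) {
      if (any(Rw < -1e-10)) return(NULL)
      Cw[Cw < 0] <- 0; Rw[Rw < 0] <- 0
      return(list(C = Cw, R = Rw, survivors = surv))
    }
  }
  NULL
}

#' Integrate the consumer-resource model to equilibrium
#'
#' Integrates [micrm_rhs()] with a stiff-capable solver (analytic Jacobian
#' supplied) on a dense-then-geometric output grid up to \code{t_max},
#' detects equilibration as the first saved time from which the scaled
#' residual stays below tolerance, and thresholds the survivor set.
#'
#' @param params a \code{community_params} object.
#' @param init optional initial state: list with \code{C} and \code{R}
#'   vectors. Default: all consumers and resources at 0.1.
#' @param control a [solver_control()] list.
#' @param times optional explicit output time grid.
#' @return an object of class \code{crm_sim}: list with \code{times},
#'   \code{C} (times x N), \code{R} (times x M), \code{model = "MiCRM"}, and
#'   an \code{equilibrium} list (\code{C_star}, \code{R_star}, \code{t_eq},
#'   \code{converged}, \code{survivors}, \code{residual}).
#' @examples
#' comm <- sample_community(N = 3, M = 3, leakage = 0.2, seed = 7)
#' sim <- integrate_micrm(comm)
#' sim$equilibrium$t_eq
#' @export
integrate_micrm <- function(params, init = NULL, control = solver_control(),
                            times = NULL) {
  N <- params$N; M <- params$M
  init <- init %||% list(C = rep(0.1, N), R = rep(0.1, M))
  if (any(init$C < 0) || any(init$R < 0))
    stop("initial state must be nonnegative")
  y0 <- c(init$C, init$R)
  times <- times %||% default_grid(control$t_max)
  func <- function(t, y, p) {
    d <- micrm_rhs(y[seq_len(N)], y[N + seq_len(M)], params)
    list(c(d$dC, d$dR))
  }
  jac <- function(t, y, p) micrm_jacobian(y[seq_len(N)], y[N + seq_len(M)],
                                          params)
  sol <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      jacfunc = jac, jactype = "fullusr",
                      method = control$method,
                      rtol = control$rtol, atol = control$atol)
  sol <- as.matrix(sol)
  states <- sol[, -1, drop = FALSE]
  if (min(states) < -1e-6)
    stop("integrator produced a significantly negative state (min ",
         format(min(states)), ")")
  states[states < 0] <- 0
  got <- sol[, 1]
  scan <- equilibration_scan(got, states, function(x) {
    d <- micrm_rhs(x[seq_len(N)], x[N + seq_len(M)], params)
    c(d$dC, d$dR)
  }, control)
  k <- if (scan$converged) scan$idx_eq else nrow(states)
  C_star <- unname(states[k, seq_len(N)])
  R_star <- unname(states[k, N + seq_len(M)])
  polished <- FALSE
  if (scan$converged) {
    # refine the reached equilibrium to machine precision (the GLV reduction
    # is expanded there, so its accuracy should not inherit solver error)
    pol <- polish_equilibrium(params, unname(states[nrow(states), seq_len(N)]),
                              unname(states[nrow(states), N + seq_len(M)]),
                              extinction = control$extinction)
    if (!is.null(pol)) {
      C_star <- pol$C; R_star <- pol$R; polished <- TRUE
    }
  }
  out <- list(times = got,
              C = states[, seq_len(N), drop = FALSE],
              R = states[, N + seq_len(M), drop = FALSE],
              model = "MiCRM",
              init = init,
              equilibrium = list(C_star = C_star, R_star = R_star,
                                 t_eq = scan$t_eq, converged = scan$converged,
                                 survivors = which(C_star >= control$extinction),
                                 residual = scan$residual,
                                 polished = polished),
              control = control)
  class(out) <- "crm_sim"
  out
}

#' @export
print.crm_sim <- function(x, ...) {
  eq <- x$equilibrium
  cat(x$model, "simulation:", ncol(x$C), "consumers",
      if (!is.null(x$R)) paste0(", ", ncol(x$R), " resources") else "", "\n")
  if (eq$converged)
    cat("  equilibrated at t =", format(eq$t_eq, digits = 5), "with",
        length(eq$survivors), "survivors\n")
  else cat("  did not equilibrate by t =", max(x$times), "\n")
  invisible(x)
}
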