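#' Hermitian part of a matrix
#'
#' \eqn{H(A) = (A + A^T)/2} for real \eqn{A}. Its leading eigenvalue is the
#' reactivity of the linearized dynamics: positive means small perturbations
#' are transiently amplified even at a stable equilibrium.
#'
#' @param A a square numeric matrix.
#' @return the symmetric matrix \eqn{(A + A^T)/2}.
#' @export
hermitian_part <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("matrix must be square")
  (A + t(A)) / 2
}

#' Dominant eigenvalue
#'
#' Eigenvalue with the largest real part; ties broken by larger absolute
#' imaginary part, then by nonnegative imaginary part (deterministic).
#'
#' @param A a square numeric matrix with finite entries.
#' @return a complex scalar.
#' @export
dominant_eigenvalue <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("matrix must be square")
  if (!all(is.finite(A))) stop("matrix contains non-finite entries")
  ev <- eigen(A, only.values = TRUE)$values
  ev <- as.complex(ev)
  ord <- order(-Re(ev), -abs(Im(ev)), -sign(Im(ev)))
  ev[ord[1]]
}

#' Stability and reactivity of paired equilibria
#'
#' Evaluates the consumer-resource Jacobian at \eqn{(C^*, R^*)} restricted to
#' surviving consumers plus all resources, and the survivor-restricted
#' Lotka-Volterra Jacobian at \eqn{C^*}, and reports dominant eigenvalues
#' (stability) and leading eigenvalues of the Hermitian parts (reactivity)
#' for both. Both matrices describe the local response of the community that
#' actually persists at the attractor; extinct consumers are excluded from
#' both, since their (near-neutral) invasion modes would otherwise dominate
#' the spectrum without being part of the resident dynamics.
#'
#' @param params a \code{community_params} object.
#' @param equilibrium equilibrium list from [integrate_micrm()].
#' @param glv the matching \code{glv_system}.
#' @return list with \code{lam_dom_mi}, \code{lam_dom_lv} (complex),
#'   \code{react_mi}, \code{react_lv} (real), and logical flags
#'   \code{stable_mi}, \code{stable_lv}, \code{reactive_mi},
#'   \code{reactive_lv}.
#' @export
stability_reactivity_report <- function(params, equilibrium, glv) {
  surv <- equilibrium$survivors
  J_full <- micrm_jacobian(equilibrium$C_star, equilibrium$R_star, params)
  keep <- c(surv, params$N + seq_len(params$M))
  J_mi <- J_full[keep, keep, drop = FALSE]
  J_lv_full <- glv_jacobian(equilibrium$C_star, glv)
  J_lv <- J_lv_full[surv, surv, drop = FALSE]
  lam_mi <- dominant_eigenvalue(J_mi)
  lam_lv <- dominant_eigenvalue(J_lv)
  react_mi <- max(eigen(hermitian_part(J_mi), symmetric = TRUE,
                        only.values = TRUE)$values)
  react_lv <- max(eigen(hermitian_part(J_lv), symmetric = TRUE,
                        only.values = TRUE)$values)
  list(lam_dom_mi = lam_mi, lam_dom_lv = lam_lv,
       react_mi = react_mi, react_lv = react_lv,
       stable_mi = Re(lam_mi) < 0, stable_lv = Re(lam_lv) < 0,
       reactive_mi = react_mi > 0, reactive_lv = react_lv > 0)
}

#' Return times of consumers and resources
#'
#' Characteristic recovery times from the Jacobian diagonals at equilibrium.
#' Resource return times come from the resource-block diagonal of the
#' consumer-resource Jacobian, \eqn{\tau_{R,\beta} = 1/|J^{RR}_{\beta\beta}|}.
#' The consumer diagonal of that Jacobian is identically zero at equilibrium
#' (per-capita growth vanishes), so consumer return times are taken from the
#' effective Lotka-Volterra Jacobian diagonal,
#' \eqn{\tau_{C,i} = 1/|C^*_i A_{ii}|}, for surviving consumers only.
#'
#' @inheritParams stability_reactivity_report
#' @return list with \code{tau_C} (survivors) and \code{tau_R}; zero diagonal
#'   entries yield \code{Inf} return times.
#' @export
return_times <- function(params, equilibrium, glv) {
  N <- params$N; M <- params$M
  J <- micrm_jacobian(equilibrium$C_star, equilibrium$R_star, params)
  dR <- abs(diag(J)[N + seq_len(M)])
  tau_R <- ifelse(dR > 0, 1 / dR, Inf)
  surv <- equilibrium$survivors
  dC <- abs(equilibrium$C_star[surv] * diag(glv$A)[surv])
  tau_C <- ifelse(dC > 0, 1 / dC, Inf)
  list(tau_C = tau_C, tau_R = tau_R)
}

#' Consumer-resource timescale separation
#'
#' Forms all fast/slow return-time ratios \eqn{\tau_{R,\beta}/\tau_{C,i}}
#' (small \eqn{\varepsilon} = resources much faster than consumers, the
#' regime where the Lotka-Volterra reduction is trustworthy), collapses them
#' with the chosen aggregator, and compares the implied validity horizon
#' \eqn{\varepsilon^{-1}} against the time the system took to equilibrate:
#' \code{validity_ratio} = \eqn{\log_{10}(\varepsilon^{-1}/t_{eq})}, with the
#' approximation predicted valid when this is nonnegative (equilibration
#' completes within the horizon).
#'
#' The default aggregator \code{"largest"} is the least-separated
#' consumer-resource pair — equivalently the smallest ratio when timescales
#' are written consumer-over-resource, \eqn{\tau_C/\tau_R} — which is the
#' conservative proxy: \eqn{\varepsilon \to 1} marks the breakdown of the
#' fast-resource assumption. \code{"smallest"} (the most-separated pair) and
#' \code{"median"} are available for sensitivity analysis; note the
#' most-separated pair is dominated by rare survivors, whose huge return
#' times inflate the apparent separation.
#'
#' @param tau_C consumer return times (nonempty).
#' @param tau_R resource return times (nonempty).
#' @param t_eq equilibration time (> 0).
#' @param aggregator \code{"largest"} (default), \code{"smallest"}, or
#'   \code{"median"}.
#' @return list with \code{epsilon}, \code{validity_ratio},
#'   \code{predicted_valid}, \code{aggregator}.
#' @export
timescale_separation <- function(tau_C, tau_R, t_eq,
                                 aggregator = c("largest", "smallest",
                                                "median")) {
  aggregator <- match.arg(aggregator)
  if (!length(tau_C) || !length(tau_R))
    stop("return-time sets must be nonempty")
  if (!is.numeric(t_eq) || t_eq <= 0) stop("t_eq must be positive")
  ratios <- as.vector(outer(tau_R, 1 / tau_C))
  eps <- switch(aggregator,
                smallest = min(ratios),
                largest = max(ratios),
                median = stats::median(ratios))
  vr <- log10((1 / eps) / t_eq)
  list(epsilon = eps, validity_ratio = vr,
       predicted_valid = vr >= 0, aggregator = aggregator)
}
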