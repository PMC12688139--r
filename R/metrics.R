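#' Niche overlap of a community
#'
#' Mean pairwise cosine similarity between consumer uptake (preference) rows:
#' \deqn{N_o = \frac{2}{N(N-1)} \sum_{i<j}
#'   \frac{u_i \cdot u_j}{\|u_i\| \|u_j\|}.}
#' 1 means identical diets, 0 disjoint diets. Invariant to rescaling any row
#' and to consumer or resource reordering.
#'
#' @param u an \code{N x M} uptake matrix with \code{N >= 2} and no all-zero
#'   row.
#' @return scalar in [0, 1].
#' @export
niche_overlap <- function(u) {
  u <- as.matrix(u)
  if (nrow(u) < 2L) stop("niche overlap undefined for fewer than 2 consumers")
  S <- row_cosine(u)
  mean(S[lower.tri(S)])
}

#' Average consumer preference vector
#'
#' @param u an \code{N x M} uptake matrix.
#' @return length-\code{M} vector, the arithmetic mean of the rows.
#' @export
average_preference <- function(u) {
  colMeans(as.matrix(u))
}

#' Effective leakage vectors
#'
#' The expected distribution of metabolites leaked by each consumer when all
#' resources are equally available: each per-resource leakage vector weighted
#' by the consumer's uptake of that resource,
#' \eqn{L^{eff}_i[\beta] = \sum_\alpha u_{i\alpha} l_{i\alpha\beta}}. With
#' uptake rows summing to 1 and leakage slices summing to the leakage
#' magnitude \eqn{l}, every \eqn{L^{eff}_i} sums to \eqn{l}.
#'
#' @param u \code{N x M} uptake matrix.
#' @param l \code{N x M x M} leakage tensor.
#' @return list with \code{L_eff} (\code{N x M} matrix, row per consumer) and
#'   \code{L_avg_eff} (length-\code{M} column mean).
#' @export
effective_leakage <- function(u, l) {
  u <- as.matrix(u)
  N <- nrow(u); M <- ncol(u)
  if (!identical(dim(l), as.integer(c(N, M, M))))
    stop("leakage tensor shape does not match the uptake matrix")
  L <- t(vapply(seq_len(N), function(i)
    as.vector(u[i, ] %*% matrix(l[i, , ], M, M)), numeric(M)))
  list(L_eff = L, L_avg_eff = colMeans(L))
}

#' Cross-feeding index
#'
#' Similarity between what consumers leak and what consumers eat:
#' \deqn{C_{feed} = \frac{2}{N(N-1)} \sum_i \sum_{j \ne i}
#'   \frac{L^{eff}_i \cdot u_j}{\|L^{eff}_i\| \|u_j\|}.}
#' The summand is not symmetric in \eqn{(i, j)}, so this formula sums over
#' ordered pairs while normalizing by the unordered pair count; its range for
#' nonnegative inputs is therefore [0, 2] (the default, \code{normalization =
#' "printed"}). \code{normalization = "mean"} divides by the ordered-pair
#' count \eqn{N(N-1)} instead, giving the mean pairwise similarity in [0, 1].
#'
#' @param u \code{N x M} uptake matrix, \code{N >= 2}.
#' @param l \code{N x M x M} leakage tensor.
#' @param normalization \code{"printed"} (default) or \code{"mean"}.
#' @return scalar cross-feeding index.
#' @export
cfeed <- function(u, l, normalization = c("printed", "mean")) {
  normalization <- match.arg(normalization)
  u <- as.matrix(u)
  N <- nrow(u)
  if (N < 2L) stop("cross-feeding index undefined for fewer than 2 consumers")
  L <- effective_leakage(u, l)$L_eff
  S <- row_cosine(L, u)
  tot <- sum(S) - sum(diag(S))
  tot / switch(normalization,
               printed = N * (N - 1) / 2,
               mean = N * (N - 1))
}

#' Log-ratio accuracy of a reduced-model trajectory
#'
#' Scores a Lotka-Volterra trajectory against its paired consumer-resource
#' trajectory via the mean per-species log-ratio
#' \eqn{Err(t) = \frac{1}{N}\sum_i \log(C^{LV}_i(t) / C^{CR}_i(t))}:
#' the trajectory error \eqn{Err_{traj}} is its time average over
#' \eqn{[0, t_{eq}]} (trapezoidal quadrature on the shared grid) and the
#' equilibrium error \eqn{Err_{eq}} its value at \eqn{t_{eq}}. Abundances are
#' floored before taking logs; a floored per-species |log-ratio| at
#' \eqn{t_{eq}} exceeding \code{cap} flags the comparison as diverged (the
#' log-ratio error diverges when one model predicts an extinction the other
#' does not). Positive values mean the reduced model overshoots.
#'
#' @param traj_mi,traj_lv \code{crm_sim} objects (or lists with \code{times}
#'   and \code{C}) for the consumer-resource reference and the reduced model.
#'   Mismatched grids are linearly interpolated onto the reference grid with
#'   a warning.
#' @param t_eq equilibration time (> 0) bounding the comparison window.
#' @param extinction_floor abundance floor applied before logs.
#' @param cap divergence cap on per-species |log-ratio| at \eqn{t_{eq}}.
#' @return list with \code{times}, \code{err_t}, \code{err_traj},
#'   \code{err_eq}, \code{abs_err_eq}, \code{per_species_log_ratios} (at
#'   \eqn{t_{eq}}), \code{log_ratios} (full matrix), \code{diverged}.
#' @export
error_metrics <- function(traj_mi, traj_lv, t_eq,
                          extinction_floor = 1e-8, cap = log(1e6)) {
  if (!is.numeric(t_eq) || t_eq <= 0) stop("t_eq must be positive")
  tm <- traj_mi$times; Cm <- as.matrix(traj_mi$C)
  tl <- traj_lv$times; Cl <- as.matrix(traj_lv$C)
  if (ncol(Cm) != ncol(Cl)) stop("trajectories have different consumer counts")
  if (!isTRUE(all.equal(tm, tl))) {
    warning("trajectory grids differ; resampling the reduced model onto ",
            "the reference grid")
    Cl <- apply(Cl, 2, function(y)
      stats::approx(tl, y, xout = tm, rule = 2)$y)
  }
  keep <- tm <= t_eq + 1e-12
  tm <- tm[keep]
  lr <- log(pmax(Cl[keep, , drop = FALSE], extinction_floor) /
            pmax(Cm[keep, , drop = FALSE], extinction_floor))
  err_t <- rowMeans(lr)
  n <- length(tm)
  err_traj <- trapz(tm, err_t) / (tm[n] - tm[1])
  per_species <- lr[n, ]
  list(times = tm, err_t = err_t, err_traj = err_traj,
       err_eq = err_t[n], abs_err_eq = abs(err_t[n]),
       per_species_log_ratios = per_species,
       log_ratios = lr,
       diverged = any(abs(per_species) > cap))
}
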