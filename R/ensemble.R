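#' Run one paired consumer-resource / Lotka-Volterra comparison
#'
#' Fits the Lotka-Volterra approximation to one community with [glva()] and
#' flattens the result into a one-row data frame (a comparison record). Any
#' stage failure is encoded in the \code{reason} column; the function never
#' throws on a valid community, so ensemble runs cannot be aborted by a
#' single pathological draw.
#'
#' @param community a \code{community_params} object.
#' @param control a [solver_control()] list.
#' @param id optional community identifier carried into the record.
#' @param ... further arguments passed to [glva()].
#' @return a one-row data frame; unavailable metrics are \code{NA} with the
#'   failure stage named in \code{reason}.
#' @export
run_pair <- function(community, control = solver_control(), id = NA, ...) {
  meta <- community$metadata
  rec <- data.frame(
    id = id, seed = meta$seed %||% NA_integer_,
    N = community$N, M = community$M,
    leakage_magnitude = meta$leakage_magnitude %||% mean(community$l_total),
    niche_overlap = if (community$N >= 2) niche_overlap(community$uptake)
                    else NA_real_,
    bin = meta$bin %||% NA_character_,
    cfeed = if (community$N >= 2) cfeed(community$uptake, community$leakage)
            else NA_real_,
    converged = FALSE, reason = NA_character_,
    t_eq = NA_real_, survivors_micrm = NA_integer_,
    survivors_glva = NA_integer_, composition_match = NA,
    err_traj = NA_real_, err_eq = NA_real_, abs_err_eq = NA_real_,
    diverged = NA,
    lam_dom_mi_re = NA_real_, lam_dom_mi_im = NA_real_,
    lam_dom_lv_re = NA_real_, lam_dom_lv_im = NA_real_,
    react_mi = NA_real_, react_lv = NA_real_,
    stable_mi = NA, stable_lv = NA,
    epsilon = NA_real_, validity_ratio = NA_real_, predicted_valid = NA,
    fixed_point_residual = NA_real_, polished = NA,
    stringsAsFactors = FALSE)
  fit <- tryCatch(glva(community, control = control, ...),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    rec$reason <- paste("error:", conditionMessage(fit))
    return(rec)
  }
  if (!fit$converged || is.null(fit$accuracy)) {
    rec$reason <- fit$reason %||% "micrm_not_converged"
    return(rec)
  }
  rec$converged <- TRUE
  rec$polished <- isTRUE(fit$micrm$equilibrium$polished)
  surv <- fit$micrm$equilibrium$survivors
  rec$fixed_point_residual <- if (length(surv))
    max(abs((fit$system$r + as.vector(fit$system$A %*% fit$system$C_star))[surv]))
  else 0
  rec$t_eq <- fit$micrm$equilibrium$t_eq
  rec$survivors_micrm <- length(fit$micrm$equilibrium$survivors)
  rec$survivors_glva <- length((fit$glv_attractor %||%
                                  fit$glv_sim$equilibrium)$survivors)
  rec$composition_match <- fit$accuracy$composition_match
  rec$err_traj <- fit$accuracy$err_traj
  rec$err_eq <- fit$accuracy$err_eq
  rec$abs_err_eq <- fit$accuracy$abs_err_eq
  rec$diverged <- fit$accuracy$diverged
  st <- fit$stability
  rec$lam_dom_mi_re <- Re(st$lam_dom_mi); rec$lam_dom_mi_im <- Im(st$lam_dom_mi)
  rec$lam_dom_lv_re <- Re(st$lam_dom_lv); rec$lam_dom_lv_im <- Im(st$lam_dom_lv)
  rec$react_mi <- st$react_mi; rec$react_lv <- st$react_lv
  rec$stable_mi <- st$stable_mi; rec$stable_lv <- st$stable_lv
  if (!is.null(fit$timescales$epsilon)) {
    rec$epsilon <- fit$timescales$epsilon
    rec$validity_ratio <- fit$timescales$validity_ratio
    rec$predicted_valid <- fit$timescales$predicted_valid
  }
  rec
}

#' Run paired comparisons over an ensemble of communities
#'
#' Maps [run_pair()] over a list of communities (typically from
#' [balanced_ensemble()]); one record per community, in order, with reason
#' codes instead of dropped rows.
#'
#' @param communities list of \code{community_params} (a
#'   [balanced_ensemble()] result works directly and contributes its
#'   manifest).
#' @param control a [solver_control()] list.
#' @param progress print a dot per community.
#' @param ... passed to [run_pair()].
#' @return data frame of comparison records with attribute
#'   \code{underfilled} propagated from the ensemble, if present.
#' @export
run_ensemble <- function(communities, control = solver_control(),
                         progress = FALSE, ...) {
  recs <- lapply(seq_along(communities), function(k) {
    if (progress) cat(".")
    run_pair(communities[[k]], control = control, id = k, ...)
  })
  if (progress) cat("\n")
  out <- do.call(rbind, recs)
  attr(out, "underfilled") <- attr(communities, "underfilled")
  out
}

#' Summarize an ensemble of comparison records
#'
#' Per (leakage magnitude, niche-overlap bin) cell: counts, medians and
#' interquartile ranges of the error metrics, the stability gap
#' \eqn{Re\,\lambda_{LV} - Re\,\lambda_{CR}}, and reactivity sign fractions.
#'
#' @param records data frame from [run_ensemble()].
#' @return data frame with one row per cell.
#' @export
summarize_ensemble <- function(records) {
  conv <- records[records$converged %in% TRUE, , drop = FALSE]
  if (!nrow(conv)) return(data.frame())
  cells <- unique(conv[, c("leakage_magnitude", "bin")])
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    g <- conv[conv$leakage_magnitude == cells$leakage_magnitude[k] &
              conv$bin %in% cells$bin[k], , drop = FALSE]
    data.frame(
      leakage_magnitude = cells$leakage_magnitude[k], bin = cells$bin[k],
      n = nrow(g),
      median_err_traj = stats::median(g$err_traj),
      median_abs_err_traj = stats::median(abs(g$err_traj)),
      iqr_err_traj = stats::IQR(g$err_traj),
      median_err_eq = stats::median(g$err_eq),
      median_abs_err_eq = stats::median(g$abs_err_eq),
      iqr_err_eq = stats::IQR(g$err_eq),
      median_stability_gap = stats::median(g$lam_dom_lv_re - g$lam_dom_mi_re),
      frac_mi_reactive = mean(g$react_mi > 0),
      frac_lv_reactive = mean(g$react_lv > 0),
      frac_composition_match = mean(g$composition_match),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$bin, out$leakage_magnitude), ]
}
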