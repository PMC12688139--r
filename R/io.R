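#' Serialize a community parameterization to JSON
#'
#' Writes uptake, leakage, maintenance, supply and sampling metadata as
#' nested JSON arrays; [read_community_json()] reconstructs an identical
#' \code{community_params} object.
#'
#' @param community a \code{community_params} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_community_json <- function(community, path) {
  payload <- list(
    N = community$N, M = community$M,
    uptake = community$uptake,
    leakage = lapply(seq_len(community$N), function(i)
      matrix(community$leakage[i, , ], community$M, community$M)),
    maintenance = community$maintenance,
    supply = community$supply,
    metadata = community$metadata[setdiff(names(community$metadata), "theta")])
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a community parameterization from JSON
#'
#' @param path file written by [write_community_json()].
#' @return a \code{community_params} object.
#' @export
read_community_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  N <- p$N; M <- p$M
  l <- array(0, c(N, M, M))
  lk <- p$leakage
  for (i in seq_len(N))
    l[i, , ] <- if (is.list(lk)) as.matrix(lk[[i]]) else lk[i, , ]
  community_params(matrix(as.numeric(unlist(p$uptake)), N, M),
                   l, p$maintenance, p$supply,
                   metadata = as.list(p$metadata))
}

#' Write ensemble records and manifest
#'
#' @param records comparison-record data frame from [run_ensemble()].
#' @param dir output directory (created if needed).
#' @param manifest optional manifest data frame (e.g. the
#'   \code{manifest} attribute of [balanced_ensemble()]).
#' @return the directory, invisibly.
#' @export
write_ensemble <- function(records, dir, manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records, file.path(dir, "records.csv"), row.names = FALSE)
  if (!is.null(manifest))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  info <- list(n_records = nrow(records),
               n_converged = sum(records$converged %in% TRUE),
               underfilled = attr(records, "underfilled") %||% character(0))
  jsonlite::write_json(info, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
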