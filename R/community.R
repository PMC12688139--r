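#' Sample consumer preference vectors
#'
#' Draws the consumer preference matrix \eqn{\theta} whose row \eqn{i} gives
#' the expected distribution of consumer \eqn{i}'s uptake over the \eqn{M}
#' resources. Rows are independent draws from a symmetric Dirichlet with
#' concentration \code{k_theta}: small \code{k_theta} yields spiky,
#' specialist-like preference rows, large \code{k_theta} near-uniform ones.
#'
#' @param N number of consumers.
#' @param M number of resources.
#' @param k_theta positive scalar Dirichlet concentration controlling row
#'   heterogeneity.
#' @return an \code{N x M} matrix with nonnegative rows summing to 1.
#' @seealso [sample_uptake()], [sample_community()]
#' @export
sample_preferences <- function(N, M, k_theta) {
  if (N < 1 || M < 1) stop("N and M must be at least 1")
  if (!is.numeric(k_theta) || length(k_theta) != 1L || k_theta <= 0)
    stop("k_theta must be a positive scalar")
  rdirichlet_rows(matrix(k_theta, N, M))
}

#' Sample the consumer uptake matrix
#'
#' Row \eqn{i} of the uptake matrix is drawn from a Dirichlet distribution
#' with concentration \eqn{\Omega_i \theta_i} and then scaled by the uptake
#' capacity \eqn{T_i}, so that \eqn{\sum_\alpha u_{i\alpha} = T_i}. Large
#' \eqn{\Omega_i} makes consumer \eqn{i} a generalist whose realized uptake
#' tracks its preference vector closely; small \eqn{\Omega_i} a specialist.
#'
#' @param theta preference matrix from [sample_preferences()] (rows are
#'   probability vectors).
#' @param omega consumer specificity; positive scalar or length-\code{N}
#'   vector.
#' @param capacity total uptake capacity \eqn{T_i}; positive scalar or
#'   length-\code{N} vector (default 1).
#' @return an \code{N x M} uptake matrix with row \eqn{i} summing to
#'   \code{capacity[i]}.
#' @export
sample_uptake <- function(theta, omega, capacity = 1) {
  N <- nrow(theta)
  omega <- rep_len(omega, N)
  capacity <- rep_len(capacity, N)
  if (any(omega <= 0)) stop("omega must be positive")
  if (any(capacity <= 0)) stop("capacity must be positive")
  u <- rdirichlet_rows(theta * omega)
  u * capacity
}

#' Sample the metabolite leakage tensor
#'
#' For every consumer-resource pair \eqn{(i,\alpha)} the vector
#' \eqn{l_{i\alpha\cdot}} of leaked-resource fractions is a Dirichlet draw
#' with concentration \eqn{\bar\phi_{i\alpha}}, scaled by the total leakage
#' magnitude \eqn{l}, so that \eqn{\sum_\beta l_{i\alpha\beta} = l} for every
#' pair. Self-leakage (\eqn{\beta = \alpha}) is permitted.
#'
#' @param phi concentration array of dimension \code{c(N, M, M)} (entry
#'   \code{[i, alpha, beta]} weights leakage of resource \code{beta} upon
#'   consumption of \code{alpha}), or a single positive scalar for a
#'   symmetric concentration.
#' @param leakage total leakage magnitude in (0, 1]. Values above 0.8 are
#'   accepted with a warning: they exceed the range of empirically observed
#'   leakage fractions.
#' @param N,M dimensions, required when \code{phi} is scalar.
#' @return array of dimension \code{c(N, M, M)}; each \code{[i, alpha, ]}
#'   slice sums to \code{leakage}.
#' @export
sample_leakage <- function(phi, leakage, N = NULL, M = NULL) {
  if (!is.numeric(leakage) || length(leakage) != 1L || leakage <= 0)
    stop("leakage must be a positive scalar")
  if (leakage > 1)
    stop("leakage > 1 violates the consumer energy balance (1 - l must be >= 0)")
  if (leakage > 0.8)
    warning("leakage magnitude ", leakage,
            " is outside the empirically plausible range (0.01, 0.8]")
  if (!is.array(phi)) {
    if (length(phi) != 1L) stop("phi must be a scalar or an N x M x M array")
    if (is.null(N) || is.null(M)) stop("N and M required for scalar phi")
    phi <- array(phi, c(N, M, M))
  }
  d <- dim(phi)
  if (length(d) != 3L || d[2] != d[3])
    stop("phi must be an N x M x M array")
  N <- d[1]; M <- d[2]
  # rows of this matrix are the (i, alpha) concentration vectors over beta
  draws <- rdirichlet_rows(matrix(phi, N * M, M))
  array(draws, c(N, M, M)) * leakage
}

#' Assemble and validate a consumer-resource community parameterization
#'
#' Low-level constructor for \code{community_params} objects; checks shapes,
#' nonnegativity, uptake normalization and the leakage energy budget.
#'
#' @param uptake \code{N x M} uptake matrix \eqn{u_{i\alpha}}.
#' @param leakage \code{N x M x M} leakage tensor \eqn{l_{i\alpha\beta}}.
#' @param maintenance length-\code{N} maintenance rate \eqn{m_i}.
#' @param supply length-\code{M} resource supply \eqn{\rho_\alpha}.
#' @param metadata optional list of sampling provenance (seed, concentrations,
#'   leakage magnitude, ...).
#' @return an object of class \code{community_params}.
#' @export
community_params <- function(uptake, leakage, maintenance, supply,
                             metadata = list()) {
  uptake <- as.matrix(uptake)
  N <- nrow(uptake); M <- ncol(uptake)
  if (!identical(dim(leakage), as.integer(c(N, M, M))))
    stop("leakage must be an N x M x M array matching uptake")
  maintenance <- rep_len(as.numeric(maintenance), N)
  supply <- rep_len(as.numeric(supply), M)
  if (any(uptake < 0) || any(leakage < 0) || any(maintenance < 0) ||
      any(supply < 0))
    stop("all community parameters must be nonnegative")
  l_total <- apply(leakage, c(1, 2), sum)
  if (any(l_total > 1 + 1e-9))
    stop("total leakage exceeds 1 for some consumer-resource pair")
  obj <- list(N = N, M = M, uptake = uptake, leakage = leakage,
              l_total = l_total, maintenance = maintenance, supply = supply,
              metadata = metadata)
  class(obj) <- "community_params"
  obj
}

#' @export
print.community_params <- function(x, ...) {
  cat("Consumer-resource community:", x$N, "consumers,", x$M, "resources\n")
  cat("  mean total leakage:", format(mean(x$l_total), digits = 4), "\n")
  cat("  maintenance:", format(mean(x$maintenance), digits = 4),
      " supply:", format(mean(x$supply), digits = 4), "\n")
  if (!is.null(x$metadata$seed)) cat("  seed:", x$metadata$seed, "\n")
  invisible(x)
}

# concentration array for the leakage Dirichlets; "uniform" is symmetric,
# "structured" biases each consumer's leakage toward resources preferred by
# the other consumers, generating cross-feeding-prone (cooperative)
# communities.
build_phi <- function(theta, phi = c("uniform", "structured"),
                      phi_strength = 5) {
  phi <- match.arg(phi)
  N <- nrow(theta); M <- ncol(theta)
  conc <- array(1, c(N, M, M))
  if (phi == "structured") {
    for (i in seq_len(N)) {
      others <- if (N > 1L) colMeans(theta[-i, , drop = FALSE]) else rep(1 / M, M)
      for (a in seq_len(M)) conc[i, a, ] <- 1 + phi_strength * M * others
    }
  }
  conc
}

#' Sample a complete community parameterization
#'
#' Draws one consumer-resource community: preferences from a symmetric
#' Dirichlet (\code{k_theta}), uptake rows from Dirichlet(\eqn{\Omega\theta})
#' scaled to capacity, and per-pair leakage vectors from Dirichlet(\eqn{\phi})
#' scaled to the total leakage magnitude. Maintenance and supply are held
#' equal and constant across the community (default 0.2).
#'
#' @param N,M numbers of consumers and resources (default 10 each).
#' @param leakage total leakage magnitude in (0, 1]; the study range is
#'   0.01 to 0.8.
#' @param k_theta preference heterogeneity (symmetric Dirichlet
#'   concentration).
#' @param omega consumer specificity (scalar or length-\code{N}).
#' @param capacity uptake capacity \eqn{T_i} (default 1).
#' @param phi leakage concentration structure, \code{"uniform"} or
#'   \code{"structured"} (cross-feeding biased).
#' @param phi_strength strength of the structured leakage bias.
#' @param m maintenance rate, shared by all consumers.
#' @param rho supply rate, shared by all resources.
#' @param seed optional integer seed; identical seed and arguments give an
#'   identical community.
#' @return a \code{community_params} object.
#' @examples
#' comm <- sample_community(N = 4, M = 4, leakage = 0.3, seed = 1)
#' rowSums(comm$uptake)          # uptake capacity 1 per consumer
#' apply(comm$leakage, c(1, 2), sum)[1, ]  # each slice sums to 0.3
#' @export
sample_community <- function(N = 10, M = 10, leakage = 0.3, k_theta = 3,
                             omega = 10, capacity = 1,
                             phi = c("uniform", "structured"),
                             phi_strength = 5, m = 0.2, rho = 0.2,
                             seed = NULL) {
  phi <- match.arg(phi)
  if (!is.null(seed)) set.seed(seed)
  theta <- sample_preferences(N, M, k_theta)
  u <- sample_uptake(theta, omega, capacity)
  conc <- build_phi(theta, phi, phi_strength)
  l <- sample_leakage(conc, leakage)
  community_params(u, l, m, rho,
                   metadata = list(seed = seed, k_theta = k_theta,
                                   omega = omega, phi = phi,
                                   phi_strength = phi_strength,
                                   leakage_magnitude = leakage,
                                   theta = theta))
}

# bin presets: (k_theta, omega) pairs whose realized niche overlap at
# N = M = 10 falls in the low / medium / high bins with high probability
bin_presets <- function(bin) {
  switch(bin,
         low    = list(k_theta = 0.3, omega = 3),
         medium = list(k_theta = 3,   omega = 10),
         high   = list(k_theta = 10,  omega = 50),
         stop("unknown niche-overlap bin: ", bin))
}

no_bin <- function(no, breaks = c(0.4, 0.7)) {
  if (no < breaks[1]) "low" else if (no <= breaks[2]) "medium" else "high"
}

#' Generate a balanced ensemble of communities
#'
#' Samples communities stratified over a grid of leakage magnitudes and
#' niche-overlap bins, so that realized niche overlap (mean pairwise cosine
#' similarity of uptake rows) populates low, medium and high bins at every
#' leakage level. Each cell is filled by rejection sampling from a bin-specific
#' (\code{k_theta}, \code{omega}) preset within a retry budget; cells that
#' cannot be filled are reported as underfilled rather than silently dropped.
#'
#' @param leakage_levels numeric vector of leakage magnitudes.
#' @param bins character subset of \code{c("low","medium","high")}.
#' @param replicates communities per (leakage, bin) cell.
#' @param N,M community dimensions.
#' @param phi,phi_strength leakage structure, passed to [sample_community()].
#' @param seed base integer seed; per-community seeds are derived
#'   deterministically from it.
#' @param retry maximum draws per requested community before declaring the
#'   cell underfilled.
#' @param breaks the two niche-overlap cutoffs separating low / medium / high
#'   (default 0.4 and 0.7).
#' @return a list of \code{community_params} with a \code{manifest} attribute:
#'   a data frame with one row per community (id, seed, N, M,
#'   leakage_magnitude, niche_overlap, bin, cfeed) and an \code{underfilled}
#'   attribute listing unfillable cells.
#' @export
balanced_ensemble <- function(leakage_levels = c(0.01, 0.2, 0.4, 0.6, 0.8),
                              bins = c("low", "medium", "high"),
                              replicates = 10, N = 10, M = 10,
                              phi = "uniform", phi_strength = 5,
                              seed = 1, retry = 50, breaks = c(0.4, 0.7)) {
  grid <- expand.grid(leakage = leakage_levels, bin = bins,
                      rep = seq_len(replicates),
                      stringsAsFactors = FALSE)
  communities <- list()
  rows <- list()
  underfilled <- character(0)
  counter <- 0L
  for (k in seq_len(nrow(grid))) {
    preset <- bin_presets(grid$bin[k])
    found <- FALSE
    for (attempt in seq_len(retry)) {
      counter <- counter + 1L
      s <- (seed + counter * 1009L) %% .Machine$integer.max
      comm <- sample_community(N = N, M = M, leakage = grid$leakage[k],
                               k_theta = preset$k_theta, omega = preset$omega,
                               phi = phi, phi_strength = phi_strength,
                               seed = s)
      no <- niche_overlap(comm$uptake)
      if (no_bin(no, breaks) == grid$bin[k]) {
        comm$metadata$bin <- grid$bin[k]
        comm$metadata$niche_overlap <- no
        id <- length(communities) + 1L
        communities[[id]] <- comm
        rows[[id]] <- data.frame(
          id = id, seed = s, N = N, M = M,
          leakage_magnitude = grid$leakage[k], niche_overlap = no,
          bin = grid$bin[k],
          cfeed = cfeed(comm$uptake, comm$leakage),
          stringsAsFactors = FALSE)
        found <- TRUE
        break
      }
    }
    if (!found)
      underfilled <- c(underfilled,
                       sprintf("leakage=%g bin=%s rep=%d", grid$leakage[k],
                               grid$bin[k], grid$rep[k]))
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), seed = integer(0), N = integer(0),
               M = integer(0), leakage_magnitude = numeric(0),
               niche_overlap = numeric(0), bin = character(0),
               cfeed = numeric(0))
  attr(communities, "manifest") <- manifest
  attr(communities, "underfilled") <- underfilled
  communities
}
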