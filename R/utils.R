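# internal helpers shared across the package

# Dirichlet draws via normalized gammas; one draw per row of `alpha`.
# Concentrations are floored at `floor` so structurally-zero preferences do
# not produce NaN rows; a row whose gamma draws all underflow to zero falls
# back to a point mass on its largest concentration.
rdirichlet_rows <- function(alpha, floor = 1e-8) {
  alpha <- pmax(alpha, floor)
  g <- matrix(stats::rgamma(length(alpha), shape = alpha),
              nrow(alpha), ncol(alpha))
  s <- rowSums(g)
  dead <- which(s <= 0)
  for (i in dead) {
    g[i, ] <- 0
    g[i, which.max(alpha[i, ])] <- 1
    s[i] <- 1
  }
  g / s
}

# trapezoidal quadrature on an (unevenly spaced) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# cosine similarity between rows of two matrices (or one matrix with itself)
row_cosine <- function(a, b = a) {
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0))
    stop("cosine similarity undefined for zero vectors")
  (a %*% t(b)) / outer(na, nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
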