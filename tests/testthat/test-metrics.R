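test_that("niche overlap follows the pairwise cosine definition", {
  expect_equal(niche_overlap(matrix(c(1, 1, 0, 0), 2, 2)), 1)  # parallel
  expect_equal(niche_overlap(diag(2)), 0)                      # orthogonal
  expect_equal(niche_overlap(rbind(c(1, 0), c(0.5, 0.5))), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(niche_overlap(matrix(1, 1, 3)), "fewer than 2")
  expect_error(niche_overlap(rbind(c(1, 0), c(0, 0))), "zero")
})

test_that("niche overlap is invariant to row scaling and reordering", {
  set.seed(5)
  u <- matrix(stats::runif(20), 4, 5)
  no <- niche_overlap(u)
  expect_equal(niche_overlap(u * c(2, 0.1, 7, 1)), no, tolerance = 1e-12)
  perm_c <- sample(4); perm_r <- sample(5)
  expect_equal(niche_overlap(u[perm_c, perm_r]), no, tolerance = 1e-12)
})

test_that("average preference is the row mean and preserves normalization", {
  expect_equal(average_preference(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)),
               c(0.5, 0.5))
  u <- matrix(c(0.2, 0.8, 0.7, 0.3), 2, 2, byrow = TRUE)
  expect_equal(sum(average_preference(u)), 1)
  expect_equal(average_preference(u[1, , drop = FALSE]), u[1, ])
})

test_that("effective leakage is the uptake-weighted leakage mixture", {
  set.seed(6)
  N <- 3; M <- 4
  comm <- sample_community(N = N, M = M, leakage = 0.3, seed = 6)
  L <- effective_leakage(comm$uptake, comm$leakage)
  # each row sums to the leakage magnitude (convex mixture of slices)
  expect_equal(rowSums(L$L_eff), rep(0.3, N), tolerance = 1e-12)
  expect_equal(L$L_avg_eff, colMeans(L$L_eff))
  # identical slices: the mixture is the common slice
  slice <- c(0.1, 0.05, 0.1, 0.05)
  l_uni <- array(rep(slice, each = N * M), c(N, M, M))
  expect_equal(effective_leakage(comm$uptake, l_uni)$L_eff,
               matrix(slice, N, M, byrow = TRUE), tolerance = 1e-12)
  # single resource: everything funnels into it
  l1 <- array(0.3, c(2, 1, 1))
  expect_equal(as.vector(effective_leakage(matrix(1, 2, 1), l1)$L_eff),
               rep(0.3, 2))
})

test_that("cross-feeding index handles both pair-count conventions", {
  # consumer 1 eats resource 1 and leaks onto 2; consumer 2 vice versa, so
  # each leaks exactly onto the other's diet: perfect cross-feeding
  u <- diag(2)
  l <- array(0, c(2, 2, 2))
  l[1, , 2] <- 0.3   # species 1 leaks resource 2 whatever it consumes
  l[2, , 1] <- 0.3
  # formula as printed sums ordered pairs but normalizes by unordered count
  expect_equal(cfeed(u, l), 2, tolerance = 1e-12)
  expect_equal(cfeed(u, l, normalization = "mean"), 1, tolerance = 1e-12)
  # leakage orthogonal to every diet: no cross-feeding
  u3 <- cbind(diag(2), 0)
  l3 <- array(0, c(2, 3, 3))
  l3[, , 3] <- 0.3   # both leak only the unconsumed resource 3
  expect_equal(cfeed(u3, l3), 0)
  expect_error(cfeed(matrix(1, 1, 2), array(0.1, c(1, 2, 2))), "fewer than 2")
})

test_that("structure metrics are invariant under community relabeling", {
  comm <- sample_community(N = 5, M = 4, leakage = 0.4, seed = 12)
  set.seed(13)
  pc <- sample(5); pr <- sample(4)
  u2 <- comm$uptake[pc, pr]
  l2 <- comm$leakage[pc, pr, pr, drop = FALSE]
  expect_equal(cfeed(u2, l2), cfeed(comm$uptake, comm$leakage),
               tolerance = 1e-12)
  expect_equal(niche_overlap(u2), niche_overlap(comm$uptake),
               tolerance = 1e-12)
})

test_that("identical trajectories give zero error everywhere", {
  times <- seq(0, 10, by = 0.5)
  C <- outer(times, c(1, 2), function(t, a) a + 0.1 * exp(-t))
  tr <- list(times = times, C = C)
  out <- error_metrics(tr, tr, t_eq = 10)
  expect_equal(out$err_t, rep(0, length(times)))
  expect_equal(out$err_traj, 0)
  expect_equal(out$err_eq, 0)
  expect_false(out$diverged)
})

test_that("a constant abundance ratio gives log-ratio errors exactly", {
  times <- seq(0, 20, by = 0.25)
  C <- outer(times, c(0.5, 1.5), function(t, a) a + 0.2 * sin(t / 3) + 0.3)
  tr1 <- list(times = times, C = C)
  tr2 <- list(times = times, C = 2 * C)
  out <- error_metrics(tr1, tr2, t_eq = 20)
  expect_equal(out$err_eq, log(2), tolerance = 1e-12)
  # time average of a constant equals its endpoint value exactly
  expect_equal(out$err_traj, log(2), tolerance = 1e-12)
  expect_equal(out$err_traj, out$err_eq)
})

test_that("error metrics are antisymmetric under swapping the models", {
  set.seed(14)
  times <- seq(0, 5, by = 0.1)
  Ca <- matrix(stats::runif(length(times) * 3, 0.5, 2), ncol = 3)
  Cb <- matrix(stats::runif(length(times) * 3, 0.5, 2), ncol = 3)
  a <- error_metrics(list(times = times, C = Ca), list(times = times, C = Cb),
                     t_eq = 5)
  b <- error_metrics(list(times = times, C = Cb), list(times = times, C = Ca),
                     t_eq = 5)
  expect_equal(a$err_traj, -b$err_traj, tolerance = 1e-12)
  expect_equal(a$err_eq, -b$err_eq, tolerance = 1e-12)
})

test_that("an extinction mismatch floors the ratio and flags divergence", {
  times <- seq(0, 10, by = 1)
  # reference model drives the species to the floor, reduced model keeps it
  C_mi <- cbind(rep(1e-12, length(times)), rep(1, length(times)))
  C_lv <- cbind(rep(0.5, length(times)), rep(1, length(times)))
  out <- error_metrics(list(times = times, C = C_mi),
                       list(times = times, C = C_lv), t_eq = 10,
                       extinction_floor = 1e-8)
  expect_equal(out$per_species_log_ratios[1], log(0.5 / 1e-8),
               tolerance = 1e-12)
  expect_true(out$diverged)
  expect_error(error_metrics(list(times = times, C = C_mi),
                             list(times = times, C = C_lv), t_eq = 0),
               "positive")
})

test_that("mismatched grids are resampled with a warning", {
  t1 <- seq(0, 10, by = 0.5)
  t2 <- seq(0, 10, by = 0.25)
  C1 <- matrix(1 + t1, ncol = 1)
  C2 <- matrix(2 * (1 + t2), ncol = 1)
  expect_warning(
    out <- error_metrics(list(times = t1, C = C1), list(times = t2, C = C2),
                         t_eq = 10),
    "resampling")
  expect_equal(out$err_eq, log(2), tolerance = 1e-10)
})
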