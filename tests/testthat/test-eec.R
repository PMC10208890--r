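test_that("residue energy series equals hand-summed symmetrized couplings", {
  # 3-residue, 2-frame tensor assembled by hand
  E <- array(NA_real_, c(3, 3, 2))
  E[3, 1, 1] <- -2; E[3, 1, 2] <- -1.5
  E[1, 3, 1] <- -0.3; E[1, 3, 2] <- -0.1
  mask <- matrix(FALSE, 3, 3); mask[3, 1] <- mask[1, 3] <- TRUE
  tens <- structure(list(energies = E, mask = mask,
                         residues = data.frame(chain = "A", resid = 1:3,
                                               resname = "ALA")),
                    class = "energy_tensor")
  ser <- residue_energy_series(tens)
  # e_13 = E(1->3) + E(3->1); residue 2 is isolated
  expect_equal(ser[, 1], c(-2.3, -1.6))
  expect_equal(ser[, 3], c(-2.3, -1.6))
  expect_equal(ser[, 2], c(0, 0))
  expect_equal(attr(ser, "isolated"), 2L)
})

test_that("tensor route and streaming trajectory route are identical", {
  tr <- noisy_helix(8, 6, sigma = 0.1, seed = 2)
  s1 <- residue_energy_series(energy_tensor(tr))
  s2 <- residue_energy_series(tr)
  expect_equal(s1, s2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("adjacency is symmetric, bounded, zero-diagonal", {
  tr <- noisy_helix(10, 50, sigma = 0.1, seed = 3)
  a <- build_adjacency(residue_energy_series(tr))
  expect_equal(a, t(a))
  expect_true(all(diag(a) == 0))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("degenerate series: constant pairs get zero weight, <10 frames error", {
  ser <- cbind(rnorm(20), rep(1, 20), rnorm(20))
  expect_warning(a <- build_adjacency(ser), "zero variance")
  expect_true(all(a[2, ] == 0) && all(a[, 2] == 0))
  expect_error(build_adjacency(ser[1:5, ]), "at least 10")
})

test_that("latent-driven residues correlate, independent residues do not", {
  base <- build_ideal_helix(20)
  block <- c(6, 10)
  tr <- generate_fluctuating_trajectory(
    base, fluctuation_spec(20, 2000, 0.1,
                           correlated_blocks = list(list(residues = block,
                                                         weight = 0.9)),
                           seed = 5))
  a <- build_adjacency(residue_energy_series(tr))
  expect_gt(a[6, 10], 0.5)
  # residues far apart with no block share only sampling noise
  expect_lt(a[3, 17], 3 / sqrt(2000) * 3)
})

test_that("centrality matches closed forms and the dense eigensolver", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  expect_equal(eigenvector_centrality(k3)$centrality, rep(1 / sqrt(3), 3),
               tolerance = 1e-10)
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(eigenvector_centrality(path)$centrality,
               c(0.5, 1 / sqrt(2), 0.5), tolerance = 1e-10)
  set.seed(8)
  for (i in 1:25) {
    m <- matrix(runif(400), 20, 20); m <- (m + t(m)) / 2; diag(m) <- 0
    pc <- eigenvector_centrality(m)$centrality
    ev <- eigen(m, symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / sqrt(sum(ev^2))
    expect_lt(max(abs(pc - ev)), 1e-8)
  }
})

test_that("centrality is unit-norm, non-negative, scale-invariant, equivariant", {
  set.seed(9)
  m <- matrix(runif(100), 10, 10); m <- (m + t(m)) / 2; diag(m) <- 0
  ec <- eigenvector_centrality(m)
  expect_equal(sum(ec$centrality^2), 1, tolerance = 1e-10)
  expect_true(all(ec$centrality >= 0))
  expect_equal(eigenvector_centrality(3.7 * m)$centrality, ec$centrality,
               tolerance = 1e-9)
  p <- sample(10)
  expect_equal(eigenvector_centrality(m[p, p])$centrality, ec$centrality[p],
               tolerance = 1e-9)
  expect_error(eigenvector_centrality(matrix(0, 4, 4)), "all-zero")
  expect_error(eigenvector_centrality(matrix(-1, 2, 2)), "non-negative")
})

test_that("delta EEC: identical profiles are null; norm bound holds", {
  set.seed(11)
  m <- matrix(runif(64), 8, 8); m <- (m + t(m)) / 2; diag(m) <- 0
  ec <- eigenvector_centrality(m)
  d <- delta_eec(ec, ec)
  expect_true(all(d$delta == 0))
  expect_identical(d$hotspots, character(0))
  m2 <- m; m2[1, 2] <- m2[2, 1] <- 5
  ec2 <- eigenvector_centrality(m2)
  d2 <- delta_eec(ec, ec2)
  expect_lte(sqrt(sum(d2$delta^2)), 2)  # both unit-norm
})

test_that("an injected correlated block is recovered as EEC hotspots", {
  base <- build_ideal_helix(40)
  block <- c(8, 12, 24, 28)
  wt <- generate_fluctuating_trajectory(
    base, fluctuation_spec(40, 2500, 0.1, seed = 61))
  var <- generate_fluctuating_trajectory(
    base, fluctuation_spec(40, 2500, 0.1,
                           correlated_blocks = list(list(residues = block,
                                                         weight = 0.8)),
                           seed = 62))
  cw <- eigenvector_centrality(build_adjacency(residue_energy_series(wt)))
  cv <- eigenvector_centrality(build_adjacency(residue_energy_series(var)))
  d <- delta_eec(cw, cv, k = 2)
  expect_true(all(block %in% as.integer(d$hotspots)))
})
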