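test_that("amide H placement follows the DSSP reconstruction", {
  # forced example: H = N + unit vector from O(i-1) toward C(i-1)
  co <- array(0, c(2, 4, 3, 1))
  co[1, 3, , 1] <- c(0, 0, 0)          # C(1)
  co[1, 4, , 1] <- c(1.23, 0, 0)       # O(1)
  co[1, 1, , 1] <- c(-1.3, 0.5, 0)     # N(1), arbitrary
  co[1, 2, , 1] <- c(-0.5, 1.2, 0)     # CA(1)
  co[2, 1, , 1] <- c(2, 2, 2)          # N(2)
  co[2, 2, , 1] <- c(3, 2, 2)
  co[2, 3, , 1] <- c(4, 2, 2)
  co[2, 4, , 1] <- c(4, 3, 2)
  tr <- backbone_trajectory(co, data.frame(chain = "A", resid = 1:2,
                                           resname = "ALA"), check = FALSE)
  H <- place_amide_hydrogens(tr)
  expect_equal(H[2, ], c(1, 2, 2))
  expect_true(all(is.na(H[1, ])))  # chain start has no amide H
})

test_that("prolines and chain starts cannot donate", {
  h <- build_ideal_helix(8)
  h$residues$resname[4] <- "PRO"
  H <- place_amide_hydrogens(h)
  expect_true(all(is.na(H[4, ])))
  tens <- energy_tensor(h)
  expect_true(all(is.na(tens$energies[4, , 1])))  # proline donor row masked
  expect_true(all(is.na(tens$energies[1, , 1])))  # chain-start donor row
  # acceptor side of the proline still evaluated
  expect_false(all(is.na(tens$energies[, 4, 1])))
})

test_that("helix N-H bond length is 1.0 A for interior residues", {
  h <- build_ideal_helix(10)
  H <- place_amide_hydrogens(h)
  for (i in 2:10)
    expect_equal(sqrt(sum((H[i, ] - h$coords[i, 1, , 1])^2)), 1.0,
                 tolerance = 1e-10)
})

test_that("energy formula matches hand evaluation and its symmetries", {
  expect_equal(ks_constants()$coupling, 27.888)
  # symmetric distances cancel exactly
  expect_equal(ks_energy(3.1, 2.4, 3.1, 2.4), 0)
  # hand-evaluated geometry
  e <- ks_energy(2.9, 3.0, 3.9, 1.9)
  by_hand <- 27.888 * (1 / 2.9 + 1 / 3.0 - 1 / 3.9 - 1 / 1.9)
  expect_equal(e, by_hand, tolerance = 1e-12)
  expect_equal(e, -2.92, tolerance = 0.01)
  # homogeneity of degree -1
  expect_equal(ks_energy(2 * 2.9, 2 * 3.0, 2 * 3.9, 2 * 1.9), e / 2,
               tolerance = 1e-12)
  # clash guard
  expect_true(is.na(ks_energy(0.4, 3.0, 3.9, 1.9)))
})

test_that("2-residue chain leaves no evaluable pair", {
  h <- build_ideal_helix(2)
  tens <- energy_tensor(h)
  # residue 1 cannot donate (chain start); pair (2 -> 1) is sequence-adjacent
  expect_true(all(is.na(tens$energies)))
})

test_that("tensor equals the brute-force per-pair loop exactly", {
  tr <- noisy_helix(10, 5, sigma = 0.15, seed = 17)
  tr$residues$resname[6] <- "PRO"
  tens <- energy_tensor(tr)
  expect_identical(dim(tens$energies), c(10L, 10L, 5L))
  expect_equal(tens$energies, brute_ks_tensor(tr), tolerance = 1e-12)
})

test_that("static trajectories give frame-constant energies", {
  h <- build_ideal_helix(8)
  co <- array(h$coords[, , , 1], c(8, 4, 3, 3))
  tr <- backbone_trajectory(co, h$residues)
  tens <- energy_tensor(tr)
  v <- apply(tens$energies, c(1, 2), function(x) if (all(is.na(x))) 0 else var(x))
  expect_true(all(v == 0))
})

test_that("energies are invariant under rigid-body motion", {
  tr <- noisy_helix(8, 2, sigma = 0.1, seed = 5)
  moved <- transform_traj(tr)
  e1 <- energy_tensor(tr)$energies
  e2 <- energy_tensor(moved)$energies
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("ideal helix i+4 -> i donor energies are below the H-bond cutoff", {
  h <- build_ideal_helix(12)
  tens <- energy_tensor(h)
  for (i in 1:8) expect_lt(tens$energies[i + 4, i, 1], -0.5)
})

test_that("directionality is preserved (E(j->i) != E(i->j) in general)", {
  h <- build_ideal_helix(12)
  tens <- energy_tensor(h)
  expect_false(isTRUE(all.equal(tens$energies[5, 1, 1],
                                tens$energies[1, 5, 1])))
})

test_that("clash handling: sentinel flags the pair, clamp mode floors it", {
  h <- build_ideal_helix(8)
  co <- h$coords
  co[6, 1, , 1] <- co[2, 4, , 1] + c(0.1, 0, 0)  # N(6) on top of O(2)
  tr <- backbone_trajectory(co, h$residues, check = FALSE)
  tens <- energy_tensor(tr)
  expect_gt(nrow(tens$clashes), 0)
  expect_true(any(tens$clashes$donor == 6 & tens$clashes$acceptor == 2))
  expect_true(is.na(tens$energies[6, 2, 1]))
  tens2 <- energy_tensor(tr, clash = "clamp")
  expect_equal(tens2$energies[6, 2, 1], -9.9)
})
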