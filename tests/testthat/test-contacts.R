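## Two single-atom "residues" pinned at a fixed distance d for all frames.
pinned_pair_traj <- function(d, nf = 10) {
  atoms <- data.frame(chain = c("A", "A", "A", "B", "B", "B"),
                      resno = c(1, 1, 1, 1, 1, 1),
                      resname = "GLY",
                      atom = c("N", "CA", "C", "N", "CA", "C"),
                      element = c("N", "C", "C", "N", "C", "C"),
                      mass = c(14, 12, 12, 14, 12, 12),
                      stringsAsFactors = FALSE)
  ## place each residue's atoms at the same point so COM distance is exact
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
               c(d, 0, 0), c(d, 0, 0), c(d, 0, 0))
  s <- md_structure(atoms, xyz)
  coords <- array(NA_real_, c(nf, 6, 3))
  for (t in seq_len(nf)) coords[t, , ] <- xyz
  list(structure = s, traj = md_trajectory(coords))
}

pair1 <- data.frame(chain_i = "A", resno_i = 1, chain_j = "B", resno_j = 1,
                    stringsAsFactors = FALSE)

test_that("contact cutoff is strict: 4.9 A counts, 5.0 A does not", {
  inside <- pinned_pair_traj(4.9)
  expect_equal(contact_occupancy(inside$traj, inside$structure,
                                 pair1)$occupancy, 1)
  boundary <- pinned_pair_traj(5.0)
  expect_equal(contact_occupancy(boundary$traj, boundary$structure,
                                 pair1)$occupancy, 0)
  expect_equal(contact_occupancy(boundary$traj, boundary$structure, pair1,
                                 inclusive = TRUE)$occupancy, 1)
})

test_that("single-frame trajectories score occupancy 0 or 1 per pair", {
  fx <- pinned_pair_traj(4.9, nf = 1)
  expect_equal(contact_occupancy(fx$traj, fx$structure, pair1)$occupancy, 1)
  fx2 <- pinned_pair_traj(5.4, nf = 1)
  expect_equal(contact_occupancy(fx2$traj, fx2$structure, pair1)$occupancy, 0)
})

test_that("occupancy matches the per-frame brute-force oracle on noisy runs", {
  s <- make_toy_dimer(8)
  pairs <- rbind(intra_pairs(s, "A"), inter_pairs(s))
  for (seed in c(11, 12)) {
    sim <- simulate_trajectory(s, n_frames = 40, sigma = 0.8,
                               n_replicates = 1, seed = seed)
    tr <- sim$trajectories[[1]]
    fast <- contact_occupancy(tr, s, pairs)$occupancy
    slow <- naive_contact_occupancy(tr, s, pairs)
    expect_equal(fast, slow)
    expect_true(all(fast >= 0 & fast <= 1))
  }
})

test_that("trailing windows drop early frames and full window changes nothing", {
  base <- pinned_pair_traj(4, nf = 10)
  s <- base$structure
  coords <- base$traj$coords
  ## first half far apart, second half in contact
  for (t in 1:5) coords[t, 4:6, 1] <- 20
  tr <- md_trajectory(coords, dt = 1)
  expect_equal(contact_occupancy(tr, s, pair1)$occupancy, 0.5)
  expect_equal(contact_occupancy(tr, s, pair1, window_ns = 5)$occupancy, 1)
  expect_equal(contact_occupancy(tr, s, pair1, frac = 0.5)$occupancy, 1)
  full <- contact_occupancy(tr, s, pair1, window_ns = 10)
  expect_equal(full$occupancy, contact_occupancy(tr, s, pair1)$occupancy)
  expect_error(contact_occupancy(tr, s, pair1, window_ns = 11), "longer")
})

test_that("difference maps follow the WT-minus-mutant sign convention", {
  mk <- function(occ) {
    out <- cbind(pair1, data.frame(occupancy = occ, replicate = 1))
    class(out) <- c("occupancy_matrix", "data.frame")
    out
  }
  d1 <- contact_difference_map(mk(0.98), mk(0.01))
  expect_equal(d1$diff_pp, 97)
  d2 <- contact_difference_map(mk(0.70), mk(1.00))
  expect_equal(d2$diff_pp, -30)
  d3 <- contact_difference_map(mk(0.5), mk(0.5))
  expect_equal(d3$diff_pp, 0)
  expect_true(all(abs(d1$diff_pp) <= 100))
})

test_that("difference maps require identical pair sets", {
  a <- cbind(pair1, data.frame(occupancy = 0.5, replicate = 1))
  b <- a
  b$resno_j <- 2
  expect_error(contact_difference_map(a, b), "mismatch")
})

test_that("replicate means and spreads aggregate per pair", {
  reps <- lapply(c(0.98, 0.97, 0.99), function(o) {
    cbind(pair1, data.frame(occupancy = o, replicate = which(o == c(0.98, 0.97, 0.99))))
  })
  m <- occupancy_mean(reps)
  expect_equal(m$mean, 0.98)
  expect_equal(m$n, 3L)
  expect_equal(m$sd, sd(c(0.98, 0.97, 0.99)))
})
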