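dimer <- make_toy_dimer(10)

test_that("zero noise with no planting reproduces the reference every frame", {
  sim <- simulate_trajectory(dimer, n_frames = 5, sigma = 0,
                             n_replicates = 2, seed = 1)
  for (tr in sim$trajectories) {
    for (t in seq_len(n_frames(tr))) {
      expect_equal(tr$coords[t, , ], dimer$xyz)
    }
  }
  prof <- rmsf_profile(sim$trajectories, dimer)
  expect_equal(prof$mean, rep(0, nrow(prof)))
})

test_that("planted contacts occupy exactly round(f * n) frames", {
  pc <- data.frame(chain_i = "A", resno_i = 2, chain_j = "B", resno_j = 7,
                   occupancy = 0.25, stringsAsFactors = FALSE)
  sim <- simulate_trajectory(dimer, n_frames = 200, sigma = 0.3,
                             planted_contacts = pc, n_replicates = 1,
                             seed = 42)
  expect_equal(sim$truth$contacts$frames_in_contact, 50)
  # brute-force per-frame distance count on the emitted coordinates
  occ <- naive_contact_occupancy(sim$trajectories[[1]], dimer, pc, cutoff = 5)
  expect_equal(occ, 0.25)
})

test_that("planted occupancies {0, 0.25, 0.5, 1} are recovered exactly", {
  pc <- data.frame(chain_i = c("A", "A", "B", "A"),
                   resno_i = c(1, 4, 2, 8),
                   chain_j = c("B", "B", "B", "A"),
                   resno_j = c(5, 9, 6, 10),
                   occupancy = c(0, 0.25, 0.5, 1), stringsAsFactors = FALSE)
  sim <- simulate_trajectory(dimer, n_frames = 200, sigma = 0.3,
                             planted_contacts = pc, n_replicates = 2,
                             seed = 3)
  for (tr in sim$trajectories) {
    occ <- contact_occupancy(tr, dimer, pc)
    expect_equal(occ$occupancy, c(0, 0.25, 0.5, 1))
  }
})

test_that("a fixed seed reproduces the coordinate tensors exactly", {
  a <- simulate_trajectory(dimer, n_frames = 10, sigma = 0.4,
                           n_replicates = 2, seed = 9)
  b <- simulate_trajectory(dimer, n_frames = 10, sigma = 0.4,
                           n_replicates = 2, seed = 9)
  expect_identical(a$trajectories[[1]]$coords, b$trajectories[[1]]$coords)
  expect_identical(a$trajectories[[2]]$coords, b$trajectories[[2]]$coords)
  c <- simulate_trajectory(dimer, n_frames = 10, sigma = 0.4,
                           n_replicates = 1, seed = 10)
  expect_false(identical(a$trajectories[[1]]$coords,
                         c$trajectories[[1]]$coords))
})

test_that("planting specs are validated", {
  bad <- data.frame(chain_i = "A", resno_i = 99, chain_j = "B", resno_j = 1,
                    occupancy = 0.5, stringsAsFactors = FALSE)
  expect_error(simulate_trajectory(dimer, planted_contacts = bad),
               "unknown residue")
  out <- data.frame(chain_i = "A", resno_i = 1, chain_j = "B", resno_j = 1,
                    occupancy = 1.5, stringsAsFactors = FALSE)
  expect_error(simulate_trajectory(dimer, planted_contacts = out),
               "\\[0, 1\\]")
  shared <- data.frame(chain_i = c("A", "A"), resno_i = c(1, 1),
                       chain_j = c("B", "B"), resno_j = c(2, 3),
                       occupancy = 0.5, stringsAsFactors = FALSE)
  expect_error(simulate_trajectory(dimer, planted_contacts = shared),
               "disjoint")
  expect_error(simulate_trajectory(dimer, sigma = -1), "sigma")
  expect_error(simulate_trajectory(dimer, n_replicates = 0), "n_replicates")
})

test_that("planted hydrogen bonds satisfy the geometric criteria exactly", {
  hb <- data.frame(donor_chain = "A", donor_resno = 3, donor_atom = "N",
                   acceptor_chain = "A", acceptor_resno = 6,
                   acceptor_atom = "O", occupancy = 0.5,
                   stringsAsFactors = FALSE)
  sim <- simulate_trajectory(dimer, n_frames = 200, sigma = 0.3,
                             planted_hbonds = hb, n_replicates = 1, seed = 5)
  res <- hbond_occupancy(sim$trajectories[[1]], dimer,
                         c(chain = "A", resno = 3, atom = "N"),
                         c(chain = "A", resno = 6, atom = "O"))
  expect_true(res$angle_checked)
  expect_equal(res$occupancy, 0.5)
  expect_equal(sim$truth$hbonds$frames_bonded, 100)
})
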