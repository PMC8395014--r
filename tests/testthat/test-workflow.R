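test_that("the genetics arm ranks the planted causal variant first", {
  sim <- simulate_family_vcf(n_background = 200, seed = 55)
  rep <- run_prioritize(sim$vcf, sim$ped)
  expect_equal(rep$n_input, sim$truth$n_records)
  expect_identical(rep$candidates$id[1], sim$truth$causal_id)
  expect_equal(nrow(rep$candidates), 1)
  expect_setequal(rep$cosegregating_ids, sim$truth$survivors_cosegregation)
  expect_equal(rep$cascade_counts$n_excluded,
               sim$truth$stage_counts$n_excluded)
  ## conservation across all stages
  expect_equal(sum(rep$cascade_counts$n_excluded) +
                 rep$n_excluded_cosegregation + rep$n_excluded_roh +
                 nrow(rep$candidates), rep$n_input)
})

test_that("report artifacts are deterministic for identical inputs", {
  sim <- simulate_family_vcf(n_background = 20, seed = 56)
  p1 <- file.path(tempfile("runA"), "out")
  p2 <- file.path(tempfile("runB"), "out")
  run_prioritize(sim$vcf, sim$ped, out_prefix = p1)
  run_prioritize(sim$vcf, sim$ped, out_prefix = p2)
  for (suffix in c(".candidates.tsv", ".stage_counts.tsv", ".roh.bed",
                   ".survivors.vcf", ".report.json")) {
    expect_identical(readLines(paste0(p1, suffix)),
                     readLines(paste0(p2, suffix)))
  }
})

test_that("an empty VCF yields a zero-count report, not an error", {
  sim <- simulate_family_vcf(n_background = 1, seed = 57)
  empty_vcf <- tempfile(fileext = ".vcf")
  lines <- readLines(sim$vcf)
  writeLines(lines[startsWith(lines, "#")], empty_vcf)
  rep <- run_prioritize(empty_vcf, sim$ped)
  expect_equal(rep$n_input, 0)
  expect_equal(nrow(rep$candidates), 0)
  expect_true(all(rep$cascade_counts$n_excluded == 0))
})

test_that("comparing a trajectory set to itself gives a zero difference map", {
  s <- make_toy_dimer(8)
  sim <- simulate_trajectory(s, n_frames = 30, sigma = 0.3,
                             n_replicates = 2, seed = 8)
  cmp <- run_compare_trajectories(sim$trajectories, sim$trajectories, s)
  expect_true(all(cmp$difference_map$diff_pp == 0))
  expect_equal(unname(cmp$n_replicates), c(2, 2))
})

test_that("a planted contact break dominates the WT-mutant difference map", {
  s <- make_toy_dimer(8)
  pair <- data.frame(chain_i = "A", resno_i = 3, chain_j = "B", resno_j = 3,
                     stringsAsFactors = FALSE)
  wt <- simulate_trajectory(s, n_frames = 100, sigma = 0.2,
                            planted_contacts = cbind(pair, occupancy = 0.98),
                            n_replicates = 3, seed = 9)
  mut <- simulate_trajectory(s, n_frames = 100, sigma = 0.2,
                             planted_contacts = cbind(pair, occupancy = 0.01),
                             n_replicates = 3, seed = 10)
  cmp <- run_compare_trajectories(wt$trajectories, mut$trajectories, s)
  dm <- cmp$difference_map
  top <- dm[which.max(abs(dm$diff_pp)), ]
  expect_equal(top[, c("chain_i", "resno_i", "chain_j", "resno_j")], pair,
               ignore_attr = TRUE)
  ## more contact in WT at the planted pair => positive sign
  expect_gt(top$diff_pp, 0)
  expect_equal(top$diff_pp, 97)
  ## every summary reports the triplicate design
  expect_equal(unname(cmp$n_replicates), c(3, 3))
  expect_equal(attr(cmp$rmsf$wt, "n_replicates"), 3)
})

test_that("structural comparison validates residue indexing", {
  a <- make_toy_dimer(6)
  b <- make_toy_dimer(7)
  sim <- simulate_trajectory(a, n_frames = 3, sigma = 0.1,
                             n_replicates = 1, seed = 2)
  expect_error(run_compare_trajectories(sim$trajectories, sim$trajectories,
                                        a, b), "residue-index mismatch")
})

test_that("hydrogen bonds and CA distances feed through the comparison", {
  s <- make_toy_dimer(8)
  hbspec <- data.frame(donor_chain = "A", donor_resno = 2, donor_atom = "N",
                       acceptor_chain = "A", acceptor_resno = 6,
                       acceptor_atom = "O", occupancy = 1,
                       stringsAsFactors = FALSE)
  wt <- simulate_trajectory(s, n_frames = 40, sigma = 0.2,
                            planted_hbonds = hbspec, n_replicates = 2,
                            seed = 11)
  hb0 <- hbspec
  hb0$occupancy <- 0
  mut <- simulate_trajectory(s, n_frames = 40, sigma = 0.2,
                             planted_hbonds = hb0, n_replicates = 2,
                             seed = 12)
  cmp <- run_compare_trajectories(
    wt$trajectories, mut$trajectories, s,
    pairs = data.frame(chain_i = "A", resno_i = 4, chain_j = "B",
                       resno_j = 4, stringsAsFactors = FALSE),
    hbond = list(donor = c(chain = "A", resno = 2, atom = "N"),
                 acceptor = c(chain = "A", resno = 6, atom = "O")),
    ca_pairs = data.frame(chain_i = "A", resno_i = 2, chain_j = "A",
                          resno_j = 6, stringsAsFactors = FALSE))
  expect_equal(cmp$hbond$wt$mean, 1)
  expect_equal(cmp$hbond$mut$mean, 0)
  expect_equal(cmp$hbond$wt$n, 2)
  dw <- cmp$ca_distances
  expect_equal(nrow(dw), 2)
  expect_true(all(dw$n == 2))
})
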