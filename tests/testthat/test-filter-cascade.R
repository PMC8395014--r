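ped <- ccd_pedigree()

test_that("common variants fall at the MAF stage", {
  v <- make_test_vset(list(maf = 0.05))
  res <- apply_filter_cascade(v, filter_config(), ped)
  expect_equal(n_variants(res$survivors), 0)
  expect_identical(res$excluded_at, "maf")
  expect_equal(res$counts$n_excluded[res$counts$stage == "maf"], 1L)
})

test_that("a database-absent, high-quality homozygous record survives", {
  ## mirrors the causal site: unreported in population databases (absent
  ## MAF/in-house AF), high per-sample and site quality
  v <- make_test_vset(list(maf = NA_real_, ihaf = NA_real_,
                           rankscore = 0.79, cadd = 26.9))
  res <- apply_filter_cascade(v, filter_config(), ped)
  expect_equal(n_variants(res$survivors), 1)
  expect_true(is.na(res$excluded_at))
})

test_that("absent quality metrics fail conservatively, absent frequencies pass", {
  v_nofs <- make_test_vset(list(fs = NA_real_))
  expect_identical(apply_filter_cascade(v_nofs, filter_config(),
                                        ped)$excluded_at, "strand_bias_fs")
  v_nomq <- make_test_vset(list(mq = NA_real_))
  expect_identical(apply_filter_cascade(v_nomq, filter_config(),
                                        ped)$excluded_at, "mapping_quality")
  v_nosplc <- make_test_vset(list(splc = NA_real_))
  expect_true(is.na(apply_filter_cascade(v_nosplc, filter_config(),
                                         ped)$excluded_at))
})

test_that("per-sample depth, GQ and hom-alt ARF thresholds are enforced", {
  v <- make_test_vset()
  v$dp[1, "IV-3"] <- 5   # threshold is exclusive: 5 fails
  expect_identical(apply_filter_cascade(v, filter_config(), ped)$excluded_at,
                   "depth")
  v <- make_test_vset()
  v$gq[1, "III-1"] <- 10
  expect_identical(apply_filter_cascade(v, filter_config(), ped)$excluded_at,
                   "genotype_quality")
  v <- make_test_vset()
  v$arf[1, "IV-5"] <- 0.6  # hom-alt call below 75%
  expect_identical(apply_filter_cascade(v, filter_config(), ped)$excluded_at,
                   "allele_read_fraction")
  ## het ARF near 50% must NOT veto (carrier parents)
  v <- make_test_vset()
  v$arf[1, "III-1"] <- 0.48
  expect_true(is.na(apply_filter_cascade(v, filter_config(), ped)$excluded_at))
})

test_that("the optional quorum stage applies only when the field is present", {
  v <- make_test_vset(list(quorum = 1))      # SNV needs >= 2
  expect_identical(apply_filter_cascade(v, filter_config(), ped)$excluded_at,
                   "quorum")
  v2 <- make_test_vset(list(quorum = 2))
  expect_true(is.na(apply_filter_cascade(v2, filter_config(), ped)$excluded_at))
  v3 <- make_test_vset(list(quorum = 1, ref = "A", alt = "AT"))  # indel: >= 1
  expect_true(is.na(apply_filter_cascade(v3, filter_config(), ped)$excluded_at))
  v4 <- make_test_vset(list(quorum = 1))
  cfg <- filter_config(use_quorum = FALSE)
  expect_true(is.na(apply_filter_cascade(v4, cfg, ped)$excluded_at))
})

test_that("stage counts conserve the input and match the emitted truth", {
  for (seed in c(101, 102, 103)) {
    sim <- simulate_family_vcf(n_background = 60, seed = seed)
    v <- read_vcf(sim$vcf)
    res <- apply_filter_cascade(v, filter_config(), ped)
    expect_equal(sum(res$counts$n_excluded) + n_variants(res$survivors),
                 n_variants(v))
    expect_equal(res$counts$n_excluded, sim$truth$stage_counts$n_excluded)
    expect_setequal(res$survivors$site$id, sim$truth$survivors_cascade)
  }
})

test_that("the cascade agrees with an independent naive filter", {
  for (seed in c(201, 202, 203, 204, 205)) {
    sim <- simulate_family_vcf(n_background = 40, seed = seed)
    v <- read_vcf(sim$vcf)
    res <- apply_filter_cascade(v, filter_config(), ped)
    expect_setequal(res$survivors$site$id,
                    naive_filter_survivors(v, filter_config(), ped))
  }
})

test_that("tightening any single threshold never increases the survivors", {
  sim <- simulate_family_vcf(n_background = 80, seed = 301)
  v <- read_vcf(sim$vcf)
  base <- apply_filter_cascade(v, filter_config(), ped)
  n_base <- n_variants(base$survivors)
  tighter <- list(
    filter_config(min_depth = 10), filter_config(min_gq = 30),
    filter_config(min_arf = 0.95), filter_config(max_maf = 1e-5),
    filter_config(max_inhouse_af = 1e-5), filter_config(max_fs = 5),
    filter_config(min_mqranksum = -1), filter_config(min_qd = 15),
    filter_config(min_mq = 58), filter_config(min_readposranksum = -1),
    filter_config(max_splice_change = 1),
    filter_config(retained_classes = "missense"))
  for (cfg in tighter) {
    res <- apply_filter_cascade(v, cfg, ped)
    expect_lte(n_variants(res$survivors), n_base)
    ## tightened survivors are a subset of the baseline survivors
    expect_true(all(res$survivors$site$id %in% base$survivors$site$id))
  }
})

test_that("an empty record set yields zero counts, not an error", {
  sim <- simulate_family_vcf(n_background = 2, seed = 1)
  empty <- subset_variants(read_vcf(sim$vcf), integer(0))
  res <- apply_filter_cascade(empty, filter_config(), ped)
  expect_equal(n_variants(res$survivors), 0)
  expect_true(all(res$counts$n_excluded == 0))
})

test_that("pedigree members absent from the VCF are an error", {
  v <- make_test_vset()
  ped2 <- rbind(ped, data.frame(id = "X-1", father = NA, mother = NA,
                                sex = "male", affection = "unaffected"))
  class(ped2) <- class(ped)
  expect_error(apply_filter_cascade(v, filter_config(), ped2), "X-1")
})

test_that("flat key=value configuration files round-trip the defaults", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("# cascade thresholds", "min_depth = 5", "min_gq = 10",
               "max_maf = 0.001",
               "retained_classes = missense, nonsense, splice, frameshift",
               "use_quorum = TRUE"), path)
  cfg <- read_filter_config(path)
  expect_equal(cfg$min_depth, 5)
  expect_equal(cfg$retained_classes,
               c("missense", "nonsense", "splice", "frameshift"))
  writeLines("not_a_key = 3", path)
  expect_error(read_filter_config(path), "unknown")
})
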