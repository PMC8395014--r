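## Hand-built single-sample variant set with chosen genotypes/positions.
roh_vset <- function(gt_codes, pos, chrom = rep("1", length(pos))) {
  n <- length(pos)
  site <- data.frame(chrom = chrom, pos = as.integer(pos),
                     id = paste0("m", seq_len(n)), ref = "A", alt = "G",
                     csq = "other", maf = NA_real_, ihaf = NA_real_,
                     fs = 1, mq = 60, qd = 20, mqrs = 0, rprs = 0,
                     splc = NA_real_, rankscore = 0, cadd = 0,
                     quorum = NA_real_, stringsAsFactors = FALSE)
  m <- matrix(gt_codes, n, 1, dimnames = list(NULL, "S1"))
  num <- matrix(50, n, 1, dimnames = list(NULL, "S1"))
  variant_set(site, m, num, num, num * 0 + 0.5)
}

test_that("a clean homozygous run is reported with exact marker bounds", {
  pos <- seq(1e6, by = 40816, length.out = 50)  # spans ~2 Mb
  v <- roh_vset(rep("hom_alt", 50), pos)
  r <- detect_roh(v, "S1", min_markers = 25, max_het = 0,
                  min_length_bp = 1e6)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_markers, 50)
  expect_equal(r$start, pos[1] - 1)
  expect_equal(r$end, pos[50])
})

test_that("an all-heterozygous sample has no runs", {
  v <- roh_vset(rep("het", 40), seq(1e6, by = 1e5, length.out = 40))
  expect_equal(nrow(detect_roh(v, "S1", min_markers = 5,
                               min_length_bp = 1e5)), 0)
})

test_that("het calls split runs at max_het 0 but bridge at max_het 1", {
  gt <- c(rep("hom_alt", 10), "het", rep("hom_ref", 10))
  v <- roh_vset(gt, seq(1e6, by = 2e5, length.out = 21))
  strict <- detect_roh(v, "S1", min_markers = 10, max_het = 0,
                       min_length_bp = 1e6)
  expect_equal(nrow(strict), 2)
  expect_equal(strict$n_markers, c(10, 10))
  loose <- detect_roh(v, "S1", min_markers = 21, max_het = 1,
                      min_length_bp = 1e6)
  expect_equal(nrow(loose), 1)
  expect_equal(loose$n_markers, 21)
})

test_that("missing calls break runs and span/marker minima filter regions", {
  gt <- c(rep("hom_alt", 10), "missing", rep("hom_alt", 10))
  v <- roh_vset(gt, seq(1e6, by = 2e5, length.out = 21))
  r <- detect_roh(v, "S1", min_markers = 10, max_het = 1,
                  min_length_bp = 1e6)
  expect_equal(nrow(r), 2)  # not bridged across the missing call
  ## too short a span
  v2 <- roh_vset(rep("hom_ref", 30), seq(1e6, by = 100, length.out = 30))
  expect_equal(nrow(detect_roh(v2, "S1", min_markers = 10,
                               min_length_bp = 1e6)), 0)
  ## too few markers
  v3 <- roh_vset(rep("hom_ref", 10), seq(1e6, by = 2e5, length.out = 10))
  expect_equal(nrow(detect_roh(v3, "S1", min_markers = 25,
                               min_length_bp = 1e6)), 0)
})

test_that("unsorted input is rejected", {
  v <- roh_vset(rep("hom_alt", 3), c(3e6, 1e6, 2e6))
  expect_error(detect_roh(v, "S1"), "sorted")
  expect_error(detect_roh(roh_vset("het", 1), "nope"), "unknown sample")
})

test_that("planted homozygosity blocks are recovered marker-exactly", {
  for (seed in c(41, 42, 43)) {
    sim <- simulate_family_vcf(n_background = 30, seed = seed)
    v <- read_vcf(sim$vcf)
    for (aff in c("IV-3", "IV-5")) {
      r <- detect_roh(v, aff, min_markers = 25, max_het = 0,
                      min_length_bp = 1e6)
      truth <- sim$truth$roh$detectable
      truth <- truth[truth$sample == aff, ]
      hit <- r[r$chrom == truth$chrom & r$start == truth$start, ]
      expect_equal(nrow(hit), 1)
      expect_equal(hit$end, truth$end)
      expect_equal(hit$n_markers, truth$n_markers)
    }
  }
})

test_that("region intersection and membership use half-open coordinates", {
  a <- data.frame(chrom = "1", start = 100L, end = 300L)
  b <- data.frame(chrom = "1", start = 200L, end = 400L)
  i <- intersect_regions(a, b)
  expect_equal(i$start, 200L)
  expect_equal(i$end, 300L)
  expect_equal(nrow(intersect_regions(a, data.frame(chrom = "2", start = 1L,
                                                    end = 1e6))), 0)
  ## position 300 (1-based) = coordinate 299, inside; 301 is outside
  expect_true(in_regions("1", 300, a))
  expect_false(in_regions("1", 301, a))
  expect_true(in_regions("1", 101, a))
  expect_false(in_regions("1", 100, a))
})
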