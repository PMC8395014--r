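#' Planted causal-variant specification
#'
#' Defaults emulate the study's discovery setting: a novel homozygous
#' missense variant on chromosome 1, absent from population databases,
#' with a normalized rank score of 0.79 and a phred-scaled CADD of 26.9,
#' lying inside a 2 Mb homozygosity block.
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles (1-based pos).
#' @param consequence Consequence class.
#' @param rank_score Normalized pathogenicity rank score in [0, 1].
#' @param cadd Phred-scaled CADD score.
#' @param roh_start,roh_end Planted ROH block (0-based half-open); must
#'   contain `pos`.
#' @return List of class `causal_spec`.
#' @export
causal_spec <- function(chrom = "1", pos = 74510000L, ref = "T", alt = "C",
                        consequence = "missense", rank_score = 0.79,
                        cadd = 26.9, roh_start = 74000000L,
                        roh_end = 76000000L) {
  if (rank_score < 0 || rank_score > 1) stop("rank_score must be in [0, 1]")
  if (!(roh_start <= pos - 1 && pos - 1 < roh_end)) {
    stop("invalid argument: causal position outside its ROH block")
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt, consequence = consequence,
                 rank_score = rank_score, cadd = cadd,
                 roh_start = as.integer(roh_start),
                 roh_end = as.integer(roh_end)),
            class = "causal_spec")
}

#' Default background-variant violation mix
#'
#' Fractions of background variants planted to fail each cascade stage, the
#' co-segregation pattern, or ROH membership; fractions are renormalised
#' and allocated deterministically (largest remainder).
#' @export
default_violation_mix <- function() {
  c(depth = 0.10, genotype_quality = 0.10, allele_read_fraction = 0.05,
    maf = 0.25, inhouse_af = 0.05, strand_bias_fs = 0.05,
    mq_rank_sum = 0.03, quality_by_depth = 0.05, mapping_quality = 0.05,
    read_pos_rank_sum = 0.03, splice_change = 0.04, consequence = 0.10,
    cosegregation = 0.07, roh = 0.03)
}

## Deterministic largest-remainder allocation of n into proportions p.
.allocate_counts <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

## Genotype patterns over the pedigree, as named code vectors.
.coseg_pattern <- function(pedigree) {
  aff <- pedigree$affection == "affected"
  parents <- pedigree$id %in% stats::na.omit(
    c(pedigree$father[aff], pedigree$mother[aff]))
  g <- ifelse(aff, "hom_alt", ifelse(parents, "het", "het"))
  stats::setNames(g, pedigree$id)
}

.random_pattern <- function(pedigree) {
  g <- sample(c("hom_ref", "het", "hom_alt"), nrow(pedigree),
              replace = TRUE, prob = c(0.55, 0.35, 0.10))
  stats::setNames(g, pedigree$id)
}

.broken_coseg_pattern <- function(pedigree) {
  g <- .coseg_pattern(pedigree)
  aff <- pedigree$id[pedigree$affection == "affected"]
  g[aff[1]] <- "het"
  g
}

## Per-sample metrics consistent with a genotype vector; all pass defaults.
.call_metrics <- function(g) {
  n <- length(g)
  dp <- sample(20:80, n, replace = TRUE)
  gq <- sample(60:99, n, replace = TRUE)
  arf <- numeric(n)
  arf[g == "hom_alt"] <- stats::runif(sum(g == "hom_alt"), 0.92, 1.0)
  arf[g == "het"] <- stats::runif(sum(g == "het"), 0.40, 0.60)
  arf[g == "hom_ref"] <- stats::runif(sum(g == "hom_ref"), 0, 0.03)
  arf[g == "missing"] <- NA
  dp[g == "missing"] <- NA
  gq[g == "missing"] <- NA
  list(dp = dp, gq = gq, arf = round(arf, 4))
}

## Site annotations that pass every filter.
.clean_site <- function() {
  list(maf = if (stats::runif(1) < 0.5) NA else stats::runif(1, 0, 9e-4),
       ihaf = if (stats::runif(1) < 0.7) NA else stats::runif(1, 0, 9e-4),
       fs = round(stats::runif(1, 0, 10), 3),
       mq = round(stats::runif(1, 55, 60), 2),
       qd = round(stats::runif(1, 6, 30), 2),
       mqrs = round(stats::runif(1, -2, 2), 3),
       rprs = round(stats::runif(1, -2, 2), 3),
       splc = NA,
       csq = sample(c("missense", "nonsense", "splice", "frameshift"), 1,
                    prob = c(0.8, 0.05, 0.1, 0.05)),
       rankscore = round(stats::runif(1), 4),
       cadd = round(stats::runif(1, 0, 40), 2),
       quorum = NA)
}

#' Simulate a family VCF with a planted causal variant
#'
#' Emits a multi-sample VCF, a PED file, a BED file of planted homozygosity
#' blocks and a ground-truth record. The causal variant is
#' homozygous-alternate in affected members, heterozygous in the parents,
#' non-hom-alt in unaffected members, passes every cascade threshold and
#' lies inside an emitted run of homozygosity for the affected samples
#' (`n_roh_markers` common homozygous markers span the block; they fall at
#' the MAF stage and so never become candidates). Each background variant
#' is planted to violate exactly one stated filter stage, the
#' co-segregation pattern, or ROH membership, per `violation_mix`;
#' background variants are placed on chromosomes 2-22 so they cannot
#' disturb the planted block. The emitted truth records each variant's
#' category and violation, the expected per-stage attrition, the expected
#' survivor sets, and the marker-exact ROH coordinates.
#'
#' A fixed seed gives byte-identical output files.
#'
#' @param pedigree A [family_pedigree()] with at least one affected member
#'   whose two parents are in the pedigree (default: [ccd_pedigree()]).
#' @param n_background Number of background variants (>= 0).
#' @param causal A [causal_spec()].
#' @param n_roh_markers Homozygosity markers spanning the planted block.
#' @param violation_mix Named fractions over violation types (see
#'   [default_violation_mix()]).
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return List with `vcf`, `ped`, `bed` (file paths) and `truth` (class
#'   `sim_truth`); also `vset`, the emitted records in memory.
#' @export
simulate_family_vcf <- function(pedigree = ccd_pedigree(),
                                n_background = 100,
                                causal = causal_spec(),
                                n_roh_markers = 60,
                                violation_mix = default_violation_mix(),
                                seed = 1,
                                dir = tempfile("famvcf")) {
  aff <- pedigree$affection == "affected"
  if (!any(aff)) stop("pedigree must contain an affected member")
  parent_ids <- unique(stats::na.omit(c(pedigree$father[aff],
                                        pedigree$mother[aff])))
  if (length(parent_ids) < 2) {
    stop("pedigree must contain >= 2 genotyped parents of affected members")
  }
  if (n_background < 0) stop("n_background must be >= 0")
  set.seed(seed)
  samples <- pedigree$id
  ns <- length(samples)

  rows <- list()
  add_row <- function(chrom, pos, ref, alt, site, g, metrics, category,
                      violation) {
    rows[[length(rows) + 1]] <<- c(
      list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt),
      site, list(g = g, dp = metrics$dp, gq = metrics$gq, arf = metrics$arf,
                 category = category, violation = violation))
  }

  ## causal record ----------------------------------------------------------
  g_causal <- .coseg_pattern(pedigree)
  site_causal <- .clean_site()
  site_causal$maf <- NA
  site_causal$ihaf <- NA
  site_causal$csq <- causal$consequence
  site_causal$rankscore <- causal$rank_score
  site_causal$cadd <- causal$cadd
  add_row(causal$chrom, causal$pos, causal$ref, causal$alt, site_causal,
          g_causal, .call_metrics(g_causal), "causal", "none")

  ## ROH markers: common homozygous variants spanning the block -------------
  if (n_roh_markers > 0) {
    span <- causal$roh_end - causal$roh_start
    mpos <- causal$roh_start + 1 +
      round(seq(0.01, 0.99, length.out = n_roh_markers) * span) +
      sample(-200:200, n_roh_markers, replace = TRUE)
    mpos <- pmin(pmax(mpos, causal$roh_start + 1), causal$roh_end)
    mpos[mpos == causal$pos] <- mpos[mpos == causal$pos] + 301L
    mpos <- unique(sort(mpos))
    for (p in mpos) {
      g <- .coseg_pattern(pedigree)
      site <- .clean_site()
      site$maf <- round(stats::runif(1, 0.1, 0.4), 4)
      site$csq <- "other"
      site$rankscore <- round(stats::runif(1, 0, 0.1), 4)
      site$cadd <- round(stats::runif(1, 0, 5), 2)
      alleles <- sample(c("A", "C", "G", "T"), 2)
      add_row(causal$chrom, p, alleles[1], alleles[2], site, g,
              .call_metrics(g), "roh_marker", "maf")
    }
  }

  ## background variants ----------------------------------------------------
  if (n_background > 0) {
    mix <- violation_mix[violation_mix > 0]
    counts <- .allocate_counts(n_background, mix)
    labels <- rep(names(counts), counts)
    bg_chrom <- sample(as.character(2:22), n_background, replace = TRUE)
    bg_pos <- sample.int(199000000L, n_background) + 1000000L
    aff_ids <- pedigree$id[aff]
    for (i in seq_len(n_background)) {
      lab <- labels[i]
      site <- .clean_site()
      g <- switch(lab,
        cosegregation = .broken_coseg_pattern(pedigree),
        roh = .coseg_pattern(pedigree),
        allele_read_fraction = .coseg_pattern(pedigree),
        .random_pattern(pedigree))
      metrics <- .call_metrics(g)
      member <- sample(seq_len(ns), 1)
      switch(lab,
        depth = { metrics$dp[member] <- sample(0:5, 1) },
        genotype_quality = { metrics$gq[member] <- sample(0:10, 1) },
        allele_read_fraction = {
          hom <- which(g == "hom_alt")
          metrics$arf[hom[1]] <- round(stats::runif(1, 0.3, 0.7), 4)
        },
        maf = { site$maf <- round(stats::runif(1, 0.01, 0.5), 4) },
        inhouse_af = { site$ihaf <- round(stats::runif(1, 0.002, 0.1), 4) },
        strand_bias_fs = { site$fs <- round(stats::runif(1, 40, 200), 2) },
        mq_rank_sum = { site$mqrs <- round(stats::runif(1, -12, -5.1), 3) },
        quality_by_depth = { site$qd <- round(stats::runif(1, 0, 4.9), 2) },
        mapping_quality = { site$mq <- round(stats::runif(1, 10, 49.9), 2) },
        read_pos_rank_sum = { site$rprs <- round(stats::runif(1, -12, -5.1), 3) },
        splice_change = { site$splc <- round(stats::runif(1, 15.5, 60), 2) },
        consequence = { site$csq <- sample(c("synonymous", "other"), 1) },
        cosegregation = NULL,
        roh = NULL)
      alleles <- sample(c("A", "C", "G", "T"), 2)
      add_row(bg_chrom[i], bg_pos[i], alleles[1], alleles[2], site, g,
              metrics, "background", lab)
    }
  }

  ## assemble, sort, emit ---------------------------------------------------
  chrom <- vapply(rows, function(r) r$chrom, character(1))
  pos <- vapply(rows, function(r) r$pos, integer(1))
  ord <- order(.chrom_rank(chrom), pos)
  rows <- rows[ord]
  pull_num <- function(k) vapply(rows, function(r) {
    v <- r[[k]]
    if (is.null(v) || length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  pull_chr <- function(k) vapply(rows, function(r) as.character(r[[k]]),
                                 character(1))
  site <- data.frame(chrom = pull_chr("chrom"),
                     pos = vapply(rows, function(r) r$pos, integer(1)),
                     id = NA_character_, ref = pull_chr("ref"),
                     alt = pull_chr("alt"), csq = pull_chr("csq"),
                     stringsAsFactors = FALSE)
  site$id <- variant_id(site$chrom, site$pos, site$ref, site$alt)
  for (k in c("maf", "ihaf", "fs", "mq", "qd", "mqrs", "rprs", "splc",
              "rankscore", "cadd", "quorum")) {
    site[[k]] <- pull_num(k)
  }
  mat <- function(k, mode = "numeric") {
    m <- t(vapply(rows, function(r) as.vector(r[[k]], mode = mode),
                  vector(mode, ns)))
    colnames(m) <- samples
    m
  }
  gt <- t(vapply(rows, function(r) unname(r$g[samples]), character(ns)))
  colnames(gt) <- samples
  vset <- variant_set(site, gt, mat("dp"), mat("gq"), mat("arf"))

  category <- vapply(rows, function(r) r$category, character(1))
  violation <- vapply(rows, function(r) r$violation, character(1))
  names(category) <- names(violation) <- site$id
  causal_id <- site$id[category == "causal"]

  ## expected pipeline outcome, from the planted labels ---------------------
  stage_counts <- data.frame(stage = .CASCADE_STAGES,
                             n_excluded = vapply(.CASCADE_STAGES, function(st) {
                               sum(violation == st)
                             }, numeric(1)), stringsAsFactors = FALSE)
  survivors_cascade <-
    site$id[violation %in% c("none", "cosegregation", "roh")]
  survivors_coseg <- site$id[violation %in% c("none", "roh")]
  survivors_roh <- causal_id

  marker_pos <- sort(c(site$pos[category == "roh_marker"],
                       site$pos[category == "causal"]))
  aff_ids <- pedigree$id[aff]
  detectable <- data.frame(chrom = causal$chrom,
                           start = min(marker_pos) - 1L,
                           end = max(marker_pos),
                           sample = aff_ids,
                           n_markers = length(marker_pos),
                           stringsAsFactors = FALSE)

  truth <- structure(list(
    seed = seed, causal_id = causal_id, n_records = nrow(site),
    category = category, violation = violation,
    stage_counts = stage_counts,
    survivors_cascade = survivors_cascade,
    survivors_cosegregation = survivors_coseg,
    survivors_roh = survivors_roh,
    roh = list(chrom = causal$chrom, block_start = causal$roh_start,
               block_end = causal$roh_end, marker_positions = marker_pos,
               detectable = detectable)), class = "sim_truth")

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(dir, "family.vcf")
  ped_path <- file.path(dir, "family.ped")
  bed_path <- file.path(dir, "roh_blocks.bed")
  truth_path <- file.path(dir, "truth.json")
  write_vcf(vset, vcf_path)
  write_ped(pedigree, ped_path)
  write_bed(data.frame(chrom = causal$chrom, start = causal$roh_start,
                       end = causal$roh_end, name = aff_ids,
                       stringsAsFactors = FALSE), bed_path)
  jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(vcf = vcf_path, ped = ped_path, bed = bed_path, truth = truth,
       vset = vset, pedigree = pedigree)
}
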