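## Site-level INFO keys carried by the variant container (all optional).
.INFO_NUM_KEYS <- c(maf = "MAF", ihaf = "IHAF", fs = "FS", mq = "MQ",
                    qd = "QD", mqrs = "MQRS", rprs = "RPRS", splc = "SPLC",
                    rankscore = "RANKSCORE", cadd = "CADD",
                    quorum = "QUORUM")

#' Multi-sample variant container
#'
#' Bundles the site table (one row per biallelic variant, file order) with
#' per-sample genotype matrices. Genotypes are coded `"hom_ref"`, `"het"`,
#' `"hom_alt"` or `"missing"`; `dp`, `gq` and `arf` hold per-call depth,
#' genotype quality and alternate allele read fraction. Missing INFO
#' annotations are `NA`, never zero.
#'
#' @param site data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `csq` and the numeric annotation columns `maf`, `ihaf`, `fs`, `mq`,
#'   `qd`, `mqrs`, `rprs`, `splc`, `rankscore`, `cadd`, `quorum`.
#' @param gt,dp,gq,arf Matrices `n_variants x n_samples` (sample names as
#'   column names).
#' @return Object of class `variant_set`.
#' @export
variant_set <- function(site, gt, dp, gq, arf) {
  samples <- colnames(gt)
  stopifnot(nrow(site) == nrow(gt), identical(colnames(dp), samples),
            identical(colnames(gq), samples), identical(colnames(arf), samples))
  if (nrow(site) > 0 && any(site$pos < 1)) stop("positions must be >= 1")
  rownames(site) <- NULL
  structure(list(site = site, gt = gt, dp = dp, gq = gq, arf = arf,
                 samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants x %d samples (%s)\n",
              nrow(x$site), length(x$samples),
              paste(x$samples, collapse = ", ")))
  invisible(x)
}

#' Number of variants
#' @param vset A `variant_set`.
#' @export
n_variants <- function(vset) nrow(vset$site)

#' Subset a variant set by row index
#' @param vset A `variant_set`.
#' @param idx Integer or logical row index.
#' @export
subset_variants <- function(vset, idx) {
  variant_set(vset$site[idx, , drop = FALSE],
              vset$gt[idx, , drop = FALSE], vset$dp[idx, , drop = FALSE],
              vset$gq[idx, , drop = FALSE], vset$arf[idx, , drop = FALSE])
}

.empty_variant_set <- function(samples) {
  site <- data.frame(chrom = character(0), pos = integer(0), id = character(0),
                     ref = character(0), alt = character(0),
                     csq = character(0), stringsAsFactors = FALSE)
  for (k in names(.INFO_NUM_KEYS)) site[[k]] <- numeric(0)
  m <- matrix(character(0), 0, length(samples),
              dimnames = list(NULL, samples))
  mn <- matrix(numeric(0), 0, length(samples),
               dimnames = list(NULL, samples))
  variant_set(site, m, mn, mn, mn)
}

.gt_code <- function(gt) {
  out <- rep("missing", length(gt))
  gt2 <- sub("\\|", "/", gt)
  out[gt2 %in% "0/0"] <- "hom_ref"
  out[gt2 %in% c("0/1", "1/0")] <- "het"
  out[gt2 %in% "1/1"] <- "hom_alt"
  out
}

.gt_string <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                missing = "./.")

#' Read a multi-sample VCF into a variant set
#'
#' Parses a VCF v4.2 file (via vcfR) with the INFO keys MAF, IHAF, FS, MQ,
#' QD, MQRS, RPRS, SPLC, CSQ, RANKSCORE, CADD, QUORUM and FORMAT
#' GT:DP:GQ:ARF. Records appear in file order; absent INFO keys become
#' `NA`. Multiallelic ALT records are rejected.
#'
#' @param path Path to an uncompressed or gzipped VCF.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1] %||% character(0)
  if (nrow(fix) == 0) return(.empty_variant_set(samples))
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop("unsupported record: multiallelic ALT at ",
         paste(sprintf("%s:%s", fix$CHROM[multi], fix$POS[multi])[
           seq_len(min(5, sum(multi)))], collapse = ", "))
  }
  site <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = fix$ID, ref = fix$REF, alt = fix$ALT,
                     csq = as.character(vcfR::extract.info(v, "CSQ")),
                     stringsAsFactors = FALSE)
  noid <- is.na(site$id) | site$id == "."
  site$id[noid] <- variant_id(site$chrom, site$pos, site$ref, site$alt)[noid]
  for (k in names(.INFO_NUM_KEYS)) {
    val <- vcfR::extract.info(v, .INFO_NUM_KEYS[[k]], as.numeric = TRUE)
    site[[k]] <- if (is.null(val)) rep(NA_real_, nrow(site)) else val
  }
  gt <- vcfR::extract.gt(v, "GT")
  num <- function(el) {
    m <- suppressWarnings(apply(vcfR::extract.gt(v, el), 2, as.numeric))
    if (nrow(site) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, samples))
    m
  }
  gtc <- apply(gt, 2, .gt_code)
  if (nrow(site) == 1) {
    gtc <- matrix(gtc, nrow = 1, dimnames = list(NULL, samples))
  }
  colnames(gtc) <- samples
  variant_set(site, gtc, num("DP"), num("GQ"), num("ARF"))
}

#' Write a variant set as VCF v4.2
#'
#' Emits biallelic records sorted as stored, with the package's INFO and
#' FORMAT keys; absent annotations are omitted from INFO. Output is plain
#' text and byte-deterministic.
#'
#' @param vset A [variant_set()].
#' @param path Output path.
#' @export
write_vcf <- function(vset, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"gnomAD minor allele frequency\">",
    "##INFO=<ID=IHAF,Number=1,Type=Float,Description=\"In-house population allele frequency\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQRS,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=RPRS,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=SPLC,Number=1,Type=Float,Description=\"Splice/initiation site score change (percent)\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=RANKSCORE,Number=1,Type=Float,Description=\"Normalized pathogenicity rank score (0 benign - 1 pathogenic)\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"Phred-scaled CADD score\">",
    "##INFO=<ID=QUORUM,Number=1,Type=Integer,Description=\"Caller concordance count\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=ARF,Number=1,Type=Float,Description=\"Alternate allele read fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vset$samples), collapse = "\t"))
  s <- vset$site
  n <- nrow(s)
  body <- character(0)
  if (n > 0) {
    info <- vapply(seq_len(n), function(i) {
      parts <- character(0)
      for (k in names(.INFO_NUM_KEYS)) {
        val <- s[[k]][i]
        if (!is.na(val)) {
          key <- .INFO_NUM_KEYS[[k]]
          parts <- c(parts, paste0(key, "=", if (key == "QUORUM")
            sprintf("%d", as.integer(val)) else sprintf("%.10g", val)))
        }
      }
      if (!is.na(s$csq[i])) parts <- c(parts, paste0("CSQ=", s$csq[i]))
      if (length(parts) == 0) "." else paste(parts, collapse = ";")
    }, character(1))
    calls <- vapply(seq_len(n), function(i) {
      per <- vapply(vset$samples, function(sm) {
        g <- vset$gt[i, sm]
        dpv <- vset$dp[i, sm]
        gqv <- vset$gq[i, sm]
        arfv <- vset$arf[i, sm]
        paste(.gt_string[[g]],
              if (is.na(dpv)) "." else sprintf("%d", as.integer(dpv)),
              if (is.na(gqv)) "." else sprintf("%d", as.integer(gqv)),
              if (is.na(arfv)) "." else sprintf("%.4g", arfv),
              sep = ":")
      }, character(1))
      paste(per, collapse = "\t")
    }, character(1))
    body <- paste(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", info,
                  "GT:DP:GQ:ARF", calls, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
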