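## Cascade stage names, in the order thresholds are listed in the config.
.CASCADE_STAGES <- c("depth", "genotype_quality", "allele_read_fraction",
                     "maf", "inhouse_af", "strand_bias_fs", "mq_rank_sum",
                     "quality_by_depth", "mapping_quality",
                     "read_pos_rank_sum", "splice_change", "consequence",
                     "quorum")

#' Hard-filter cascade configuration
#'
#' Defaults reproduce the exome-pipeline thresholds used to retain rare,
#' well-supported variants: per-sample coverage > 5 reads, genotype quality
#' > 10 and (on homozygous-alternate calls) allele read fraction >= 75%;
#' site-level gnomAD MAF < 0.001, in-house allele frequency < 0.001, Fisher
#' strand bias FS < 40, MQRankSum >= -5, QD > 5, MQ > 50, ReadPosRankSum
#' >= -5, splice/initiation score change <= 15%, and a retained-consequence
#' whitelist. "Quality score > 10" is interpreted as the per-sample
#' genotype quality (GQ); the duplicated mapping-quality criteria collapse
#' into the single site-level MQ filter. The ARF threshold applies to
#' homozygous-alternate calls only, since heterozygous carriers sit near
#' 50% by construction yet must be retained for a recessive candidate.
#' When an integer `QUORUM` INFO field (caller-concordance count) is
#' present, SNVs require >= 2 and indels >= 1; records without the field
#' skip the stage.
#'
#' Comparisons are exclusive except `min_arf`, `min_mqranksum`,
#' `min_readposranksum` and `max_splice_change`, which are inclusive.
#'
#' @param min_depth,min_gq Per-sample depth / genotype-quality thresholds
#'   (exclusive).
#' @param min_arf Minimum alternate allele read fraction on hom-alt calls
#'   (inclusive).
#' @param max_maf,max_inhouse_af Population-frequency ceilings (exclusive);
#'   absent annotations pass (a variant unseen in any database is maximally
#'   rare).
#' @param max_fs,min_mqranksum,min_qd,min_mq,min_readposranksum Site
#'   quality thresholds; absent values fail conservatively.
#' @param max_splice_change Maximum absolute splice/initiation-site score
#'   change in percent (inclusive); absent annotations pass.
#' @param retained_classes Consequence classes kept by the cascade.
#' @param use_quorum Apply the optional QUORUM stage when the field is
#'   present.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_depth = 5, min_gq = 10, min_arf = 0.75,
                          max_maf = 0.001, max_inhouse_af = 0.001,
                          max_fs = 40, min_mqranksum = -5, min_qd = 5,
                          min_mq = 50, min_readposranksum = -5,
                          max_splice_change = 15,
                          retained_classes = c("missense", "nonsense",
                                               "splice", "frameshift"),
                          use_quorum = TRUE) {
  cfg <- list(min_depth = min_depth, min_gq = min_gq, min_arf = min_arf,
              max_maf = max_maf, max_inhouse_af = max_inhouse_af,
              max_fs = max_fs, min_mqranksum = min_mqranksum,
              min_qd = min_qd, min_mq = min_mq,
              min_readposranksum = min_readposranksum,
              max_splice_change = max_splice_change,
              retained_classes = retained_classes,
              use_quorum = isTRUE(use_quorum))
  num <- unlist(cfg[1:11])
  if (any(!is.finite(num))) stop("all thresholds must be finite")
  class(cfg) <- "filter_config"
  cfg
}

#' Read a flat key=value filter configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines are ignored. `retained_classes` takes a comma-separated
#' list. Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A [filter_config()].
#' @export
read_filter_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("[=:]", lines)])
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (!(key %in% names(formals(filter_config)))) {
      stop("unknown filter configuration key: ", key)
    }
    args[[key]] <- switch(key,
      retained_classes = trimws(strsplit(val, ",")[[1]]),
      use_quorum = as.logical(val),
      as.numeric(val))
  }
  do.call(filter_config, args)
}

## Per-stage pass matrix (n_records x stages). Per-sample stages consider
## only genotyped pedigree members; NA metrics fail except where the filter
## semantics make absence a pass (population frequencies, splice change).
.stage_pass_matrix <- function(vset, config, pedigree) {
  s <- vset$site
  n <- nrow(s)
  ids <- pedigree$id
  missing_cols <- setdiff(ids, vset$samples)
  if (length(missing_cols)) {
    stop("pedigree member(s) not genotyped in the VCF: ",
         paste(missing_cols, collapse = ", "))
  }
  gt <- vset$gt[, ids, drop = FALSE]
  dp <- vset$dp[, ids, drop = FALSE]
  gq <- vset$gq[, ids, drop = FALSE]
  arf <- vset$arf[, ids, drop = FALSE]
  genotyped <- gt != "missing"
  ok_num <- function(m, cond) {
    r <- cond(m)
    r[is.na(r)] <- FALSE
    r
  }
  all_over <- function(mask, ok) rowSums(mask & !ok) == 0
  pass <- matrix(TRUE, n, length(.CASCADE_STAGES),
                 dimnames = list(NULL, .CASCADE_STAGES))
  pass[, "depth"] <- all_over(genotyped, ok_num(dp, function(x) x > config$min_depth))
  pass[, "genotype_quality"] <-
    all_over(genotyped, ok_num(gq, function(x) x > config$min_gq))
  pass[, "allele_read_fraction"] <-
    all_over(genotyped & gt == "hom_alt",
             ok_num(arf, function(x) x >= config$min_arf))
  site_pass <- function(x, cond, absent_pass) {
    out <- cond(x)
    out[is.na(out)] <- absent_pass
    out
  }
  pass[, "maf"] <- site_pass(s$maf, function(x) x < config$max_maf, TRUE)
  pass[, "inhouse_af"] <-
    site_pass(s$ihaf, function(x) x < config$max_inhouse_af, TRUE)
  pass[, "strand_bias_fs"] <-
    site_pass(s$fs, function(x) x < config$max_fs, FALSE)
  pass[, "mq_rank_sum"] <-
    site_pass(s$mqrs, function(x) x >= config$min_mqranksum, FALSE)
  pass[, "quality_by_depth"] <-
    site_pass(s$qd, function(x) x > config$min_qd, FALSE)
  pass[, "mapping_quality"] <-
    site_pass(s$mq, function(x) x > config$min_mq, FALSE)
  pass[, "read_pos_rank_sum"] <-
    site_pass(s$rprs, function(x) x >= config$min_readposranksum, FALSE)
  pass[, "splice_change"] <-
    site_pass(s$splc, function(x) abs(x) <= config$max_splice_change, TRUE)
  pass[, "consequence"] <- !is.na(s$csq) & s$csq %in% config$retained_classes
  if (config$use_quorum) {
    snv <- nchar(s$ref) == 1 & nchar(s$alt) == 1
    need <- ifelse(snv, 2, 1)
    pass[, "quorum"] <- is.na(s$quorum) | s$quorum >= need
  }
  pass
}

#' Apply the hard-filter cascade
#'
#' A record survives when every site metric satisfies the configuration and
#' the per-sample depth/GQ/ARF thresholds hold for every genotyped pedigree
#' member (ARF on homozygous-alternate calls). Per-stage counts report the
#' attrition at each threshold in configuration order: a record is charged
#' to the first stage it fails.
#'
#' @param vset A [variant_set()].
#' @param config A [filter_config()].
#' @param pedigree A [family_pedigree()]; every member must have a genotype
#'   column in `vset` (missing calls are tolerated).
#' @return List with `survivors` (a `variant_set`), `counts` (data.frame
#'   `stage`, `n_in`, `n_excluded`, `n_out` in stage order) and
#'   `excluded_at` (per input record, the failing stage or `NA`).
#' @export
apply_filter_cascade <- function(vset, config = filter_config(), pedigree) {
  n <- n_variants(vset)
  stages <- .CASCADE_STAGES
  if (n == 0) {
    counts <- data.frame(stage = stages, n_in = 0L, n_excluded = 0L,
                         n_out = 0L, stringsAsFactors = FALSE)
    return(list(survivors = vset, counts = counts,
                excluded_at = character(0)))
  }
  pass <- .stage_pass_matrix(vset, config, pedigree)
  first_fail <- apply(pass, 1, function(p) {
    w <- which(!p)
    if (length(w)) stages[w[1]] else NA_character_
  })
  n_in <- integer(length(stages))
  n_exc <- integer(length(stages))
  remaining <- n
  for (k in seq_along(stages)) {
    n_in[k] <- remaining
    n_exc[k] <- sum(first_fail == stages[k], na.rm = TRUE)
    remaining <- remaining - n_exc[k]
  }
  counts <- data.frame(stage = stages, n_in = n_in, n_excluded = n_exc,
                       n_out = n_in - n_exc, stringsAsFactors = FALSE)
  list(survivors = subset_variants(vset, is.na(first_fail)),
       counts = counts, excluded_at = first_fail)
}
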