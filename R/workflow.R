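#' End-to-end recessive variant prioritization
#'
#' Runs the genetics arm on a multi-sample VCF and pedigree: ROH detection
#' per affected sample (intersected across affected members), the
#' hard-filter cascade, the autosomal-recessive co-segregation test, ROH
#' intersection, and score-based ranking. Deterministic given its inputs.
#'
#' @param vcf Path to a VCF, or a [variant_set()].
#' @param ped Path to a PED file, or a [family_pedigree()].
#' @param config A [filter_config()].
#' @param roh_min_markers,roh_max_het,roh_min_length_bp Parameters of
#'   [detect_roh()].
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>.candidates.tsv`, `<prefix>.stage_counts.tsv`,
#'   `<prefix>.roh.bed`, `<prefix>.survivors.vcf` and `<prefix>.report.json`.
#' @return List of class `prioritization_report`: per-stage counts,
#'   co-segregating and ROH-intersected id sets, shared ROH regions, and
#'   the ranked candidate table.
#' @export
run_prioritize <- function(vcf, ped, config = filter_config(),
                           roh_min_markers = 25, roh_max_het = 0,
                           roh_min_length_bp = 1e6, out_prefix = NULL) {
  vset <- if (inherits(vcf, "variant_set")) vcf else read_vcf(vcf)
  pedigree <- if (inherits(ped, "pedigree")) ped else read_ped(ped)
  aff_ids <- pedigree$id[pedigree$affection == "affected"]
  aff_ids <- intersect(aff_ids, vset$samples)

  roh_per_sample <- lapply(aff_ids, function(s) {
    detect_roh(vset, s, min_markers = roh_min_markers,
               max_het = roh_max_het, min_length_bp = roh_min_length_bp)
  })
  shared_roh <- if (length(roh_per_sample) == 0) {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  } else {
    Reduce(function(a, b) intersect_regions(a, b[, c("chrom", "start", "end")]),
           roh_per_sample[-1],
           init = roh_per_sample[[1]][, c("chrom", "start", "end")])
  }

  casc <- apply_filter_cascade(vset, config, pedigree)
  coseg <- cosegregation_flags(casc$survivors, pedigree)
  coseg_set <- subset_variants(casc$survivors, coseg)
  inroh <- if (n_variants(coseg_set) == 0) logical(0) else {
    in_regions(coseg_set$site$chrom, coseg_set$site$pos, shared_roh)
  }
  final_set <- subset_variants(coseg_set, inroh)
  ranked <- rank_candidates(final_set)

  report <- structure(list(
    n_input = n_variants(vset),
    cascade_counts = casc$counts,
    n_cascade_survivors = n_variants(casc$survivors),
    cosegregating_ids = coseg_set$site$id,
    n_excluded_cosegregation = sum(!coseg),
    in_roh_ids = final_set$site$id,
    n_excluded_roh = sum(!inroh),
    roh_regions = shared_roh,
    candidates = ranked,
    parameters = list(filter = unclass(config),
                      roh_min_markers = roh_min_markers,
                      roh_max_het = roh_max_het,
                      roh_min_length_bp = roh_min_length_bp)),
    class = "prioritization_report")

  if (!is.null(out_prefix)) {
    dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
    utils::write.table(ranked, paste0(out_prefix, ".candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(casc$counts, paste0(out_prefix, ".stage_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(shared_roh, paste0(out_prefix, ".roh.bed"))
    write_vcf(final_set, paste0(out_prefix, ".survivors.vcf"))
    jsonlite::write_json(unclass(report), paste0(out_prefix, ".report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.prioritization_report <- function(x, ...) {
  cat(sprintf(paste0("prioritization_report: %d variants in, %d past cascade, ",
                     "%d co-segregating, %d in shared ROH\n"),
              x$n_input, x$n_cascade_survivors, length(x$cosegregating_ids),
              length(x$in_roh_ids)))
  if (nrow(x$candidates) > 0) {
    cat("top candidate:", x$candidates$id[1], "\n")
  }
  invisible(x)
}

#' Compare wild-type and mutant trajectory sets
#'
#' Runs the structural arm end to end: per-replicate contact occupancy for
#' both genotypes with the wild-type-minus-mutant difference map, RMSF
#' profiles, optional hydrogen-bond occupancy and C-alpha distance
#' statistics, and the hydrophobic-surface comparison of the two
#' structures. Every table is labelled with the window, cutoff and
#' replicate counts.
#'
#' @param wt,mut Lists of `md_trajectory` (replicates per genotype).
#' @param structure_wt,structure_mut Matching `md_structure` objects; the
#'   two must index the same residues (chain/resno), or an error lists the
#'   mismatches.
#' @param pairs Residue pairs for contact analysis (default: all intra- and
#'   inter-chain pairs).
#' @param hbond Optional list with `donor` and `acceptor` atom specs (and
#'   optionally `criteria`), evaluated on both genotypes.
#' @param ca_pairs Optional data.frame of residue pairs
#'   (`chain_i`,`resno_i`,`chain_j`,`resno_j`) for CA distance statistics.
#' @param cutoff Contact cutoff in Angstrom.
#' @param window_ns Trailing analysis window in ns (`NULL` = full).
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return List of class `trajectory_comparison`.
#' @export
run_compare_trajectories <- function(wt, mut, structure_wt,
                                     structure_mut = structure_wt,
                                     pairs = NULL, hbond = NULL,
                                     ca_pairs = NULL, cutoff = 5,
                                     window_ns = NULL, out_dir = NULL) {
  if (inherits(wt, "md_trajectory")) wt <- list(wt)
  if (inherits(mut, "md_trajectory")) mut <- list(mut)
  if (length(wt) < 1 || length(mut) < 1) {
    stop("at least one replicate per genotype is required")
  }
  rt_wt <- residue_table(structure_wt)
  rt_mut <- residue_table(structure_mut)
  kw <- paste(rt_wt$chain, rt_wt$resno)
  km <- paste(rt_mut$chain, rt_mut$resno)
  if (!identical(kw, km)) {
    stop("residue-index mismatch between WT and mutant structures: ",
         paste(c(setdiff(kw, km), setdiff(km, kw)), collapse = ", "))
  }
  if (is.null(pairs)) {
    pairs <- rbind(intra_pairs(structure_wt), inter_pairs(structure_wt))
  }

  occ_wt <- lapply(wt, contact_occupancy, structure = structure_wt,
                   pairs = pairs, cutoff = cutoff, window_ns = window_ns)
  occ_mut <- lapply(mut, contact_occupancy, structure = structure_mut,
                    pairs = pairs, cutoff = cutoff, window_ns = window_ns)
  diff_map <- contact_difference_map(occ_wt, occ_mut)

  rmsf_wt <- rmsf_profile(wt, structure_wt)
  rmsf_mut <- rmsf_profile(mut, structure_mut)

  hb <- NULL
  if (!is.null(hbond)) {
    crit <- hbond$criteria %||% hbond_criteria()
    hb_one <- function(trajs, strc) {
      per <- vapply(trajs, function(tr) {
        hbond_occupancy(tr, strc, hbond$donor, hbond$acceptor,
                        criteria = crit, window_ns = window_ns)$occupancy
      }, numeric(1))
      reps <- as.data.frame(t(per))
      names(reps) <- paste0("rep_", seq_along(per))
      cbind(aggregate_replicates(per), reps)
    }
    hb <- list(wt = hb_one(wt, structure_wt),
               mut = hb_one(mut, structure_mut), criteria = crit)
  }

  dist_stats <- NULL
  if (!is.null(ca_pairs)) {
    dist_one <- function(trajs, strc, genotype) {
      do.call(rbind, lapply(seq_len(nrow(ca_pairs)), function(p) {
        per <- vapply(trajs, function(tr) {
          ca_distance_stats(tr, strc,
                            c(chain = ca_pairs$chain_i[p],
                              resno = ca_pairs$resno_i[p]),
                            c(chain = ca_pairs$chain_j[p],
                              resno = ca_pairs$resno_j[p]),
                            window_ns = window_ns)$mean
        }, numeric(1))
        agg <- aggregate_replicates(per)
        data.frame(genotype = genotype, chain_i = ca_pairs$chain_i[p],
                   resno_i = ca_pairs$resno_i[p],
                   chain_j = ca_pairs$chain_j[p],
                   resno_j = ca_pairs$resno_j[p],
                   mean = agg$mean, sd = agg$sd, n = agg$n,
                   stringsAsFactors = FALSE)
      }))
    }
    dist_stats <- rbind(dist_one(wt, structure_wt, "WT"),
                        dist_one(mut, structure_mut, "MUT"))
  }

  sasa <- list(wt = hydrophobic_surface_score(structure_wt),
               mut = hydrophobic_surface_score(structure_mut))

  report <- structure(list(
    n_replicates = c(wt = length(wt), mut = length(mut)),
    cutoff = cutoff, window_ns = window_ns,
    occupancy_wt = occ_wt, occupancy_mut = occ_mut,
    difference_map = diff_map,
    rmsf = list(wt = rmsf_wt, mut = rmsf_mut),
    hbond = hb, ca_distances = dist_stats,
    sasa = list(wt = sasa$wt[c("total_sasa", "apolar_sasa",
                               "kd_weighted_sasa")],
                mut = sasa$mut[c("total_sasa", "apolar_sasa",
                                 "kd_weighted_sasa")],
                per_residue_wt = sasa$wt$per_residue,
                per_residue_mut = sasa$mut$per_residue)),
    class = "trajectory_comparison")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wtsv(diff_map, "contact_difference_map.tsv")
    wtsv(as.data.frame(rmsf_wt), "rmsf_wt.tsv")
    wtsv(as.data.frame(rmsf_mut), "rmsf_mut.tsv")
    wtsv(report$sasa$per_residue_wt, "sasa_wt.tsv")
    wtsv(report$sasa$per_residue_mut, "sasa_mut.tsv")
    if (!is.null(dist_stats)) wtsv(dist_stats, "ca_distances.tsv")
    summary <- list(n_replicates = report$n_replicates, cutoff = cutoff,
                    window_ns = window_ns,
                    sasa = report$sasa[c("wt", "mut")],
                    hbond_occupancy = if (is.null(hb)) NULL else
                      list(wt = hb$wt$mean, mut = hb$mut$mean))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  top <- x$difference_map[order(-abs(x$difference_map$diff_pp)), ][1, ]
  cat(sprintf(paste0("trajectory_comparison: %d WT / %d MUT replicates, ",
                     "cutoff %g A, window %s\n"),
              x$n_replicates["wt"], x$n_replicates["mut"], x$cutoff,
              if (is.null(x$window_ns)) "full" else
                paste0(x$window_ns, " ns")))
  cat(sprintf("largest contact difference: %s%d-%s%d (%+.1f pp)\n",
              top$chain_i, top$resno_i, top$chain_j, top$resno_j,
              top$diff_pp))
  invisible(x)
}
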