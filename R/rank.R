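#' Rank prioritized candidates
#'
#' Orders surviving candidates by normalized pathogenicity rank score
#' (descending, 0 = benign to 1 = pathogenic), breaking ties by
#' phred-scaled CADD (descending), then chromosome/position (ascending).
#'
#' @param x A [variant_set()] of candidates, or a data.frame with columns
#'   `chrom`, `pos`, `rankscore`, `cadd`.
#' @return data.frame with a leading `rank` column and the site columns,
#'   in rank order.
#' @export
rank_candidates <- function(x) {
  site <- if (inherits(x, "variant_set")) x$site else x
  if (nrow(site) == 0) {
    return(cbind(data.frame(rank = integer(0)), site))
  }
  ord <- order(-site$rankscore, -site$cadd, .chrom_rank(site$chrom), site$pos)
  out <- cbind(data.frame(rank = seq_len(nrow(site))), site[ord, ])
  rownames(out) <- NULL
  out
}
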