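#' Detect runs of homozygosity for one sample
#'
#' A run-of-homozygosity heuristic over the biallelic calls of one sample:
#' maximal runs of consecutive homozygous calls (hom-ref or hom-alt),
#' allowing at most `max_het` heterozygous interruptions, with at least
#' `min_markers` markers and a genomic span of at least `min_length_bp`.
#' Missing calls break a run. Regions are emitted as 0-based half-open
#' intervals covering the first to last marker (+1).
#'
#' @param vset A [variant_set()], sorted by chromosome and position.
#' @param sample Sample id (a column of the genotype matrix).
#' @param min_markers Minimum markers per region.
#' @param max_het Maximum heterozygous interruptions tolerated inside a run.
#' @param min_length_bp Minimum region span in bp.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `sample`, `n_markers`.
#' @export
detect_roh <- function(vset, sample, min_markers = 25, max_het = 0,
                       min_length_bp = 1e6) {
  s <- vset$site
  if (!(sample %in% vset$samples)) stop("unknown sample: ", sample)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sample = character(0),
                      n_markers = integer(0), stringsAsFactors = FALSE)
  if (nrow(s) == 0) return(empty)
  ord <- order(.chrom_rank(s$chrom), s$pos)
  if (!identical(ord, seq_len(nrow(s)))) {
    stop("invalid input: records must be sorted by chromosome and position")
  }
  g <- vset$gt[, sample]
  out <- list()
  for (chrom in unique(s$chrom)) {
    ci <- which(s$chrom == chrom)
    gi <- g[ci]
    pos <- s$pos[ci]
    usable <- gi %in% c("hom_ref", "hom_alt", "het")
    ## split at missing calls; scan each segment independently
    seg_id <- cumsum(!usable)
    for (seg in split(seq_along(gi)[usable], seg_id[usable])) {
      het <- gi[seg] == "het"
      m <- length(seg)
      if (m == 0) next
      ## maximal windows with <= max_het het interruptions (two-pointer);
      ## a window ending at r is maximal when the next window's left edge
      ## strictly advances
      left <- 1L
      nhet <- 0L
      lmin <- integer(m)
      for (r in seq_len(m)) {
        nhet <- nhet + het[r]
        while (nhet > max_het) {
          nhet <- nhet - het[left]
          left <- left + 1L
        }
        lmin[r] <- left
      }
      keep_r <- which(seq_len(m) == m | c(lmin[-1] > lmin[-m], TRUE))
      for (r in keep_r) {
        a <- lmin[r]
        b <- r
        while (a <= b && het[a]) a <- a + 1L
        while (b >= a && het[b]) b <- b - 1L
        if (a > b) next
        nm <- b - a + 1L
        p1 <- pos[seg[a]]
        p2 <- pos[seg[b]]
        if (nm >= min_markers && (p2 - p1 + 1) >= min_length_bp) {
          out[[length(out) + 1]] <-
            data.frame(chrom = chrom, start = p1 - 1L, end = p2,
                       sample = sample, n_markers = nm,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- unique(res)
  rownames(res) <- NULL
  res
}

#' Intersect two region sets
#'
#' @param a,b data.frames with `chrom`, `start`, `end` (0-based half-open).
#' @return data.frame of overlapping intervals (chrom, start, end).
#' @export
intersect_regions <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    hits <- which(b$chrom == a$chrom[i] & b$start < a$end[i] &
                    b$end > a$start[i])
    for (j in hits) {
      out[[length(out) + 1]] <- data.frame(
        chrom = a$chrom[i],
        start = max(a$start[i], b$start[j]),
        end = min(a$end[i], b$end[j]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Membership of 1-based positions in 0-based half-open regions
#'
#' @param chrom,pos Vectors of variant coordinates (1-based positions).
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @return Logical vector.
#' @export
in_regions <- function(chrom, pos, regions) {
  vapply(seq_along(pos), function(i) {
    any(regions$chrom == chrom[i] & regions$start <= pos[i] - 1 &
          regions$end > pos[i] - 1)
  }, logical(1))
}

#' Write regions as a BED file
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally a
#'   name column (`sample` or `name`).
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  nm <- regions$name %||% regions$sample %||% rep(".", nrow(regions))
  writeLines(paste(regions$chrom, regions$start, regions$end, nm,
                   sep = "\t"), path)
  invisible(path)
}
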