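## Residue pair helpers ------------------------------------------------------

.pair_df <- function(res_i, res_j) {
  data.frame(chain_i = res_i$chain, resno_i = res_i$resno,
             chain_j = res_j$chain, resno_j = res_j$resno,
             stringsAsFactors = FALSE)
}

#' All intra-chain residue pairs
#'
#' @param structure An `md_structure`.
#' @param chain Restrict to one chain (default: all chains).
#' @return data.frame with columns `chain_i`, `resno_i`, `chain_j`, `resno_j`.
#' @export
intra_pairs <- function(structure, chain = NULL) {
  rt <- residue_table(structure)
  if (!is.null(chain)) rt <- rt[rt$chain == chain, ]
  out <- lapply(split(rt, rt$chain), function(r) {
    if (nrow(r) < 2) return(NULL)
    idx <- utils::combn(nrow(r), 2)
    .pair_df(r[idx[1, ], ], r[idx[2, ], ])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' All inter-chain residue pairs
#'
#' @param structure An `md_structure`.
#' @return data.frame with columns `chain_i`, `resno_i`, `chain_j`, `resno_j`.
#' @export
inter_pairs <- function(structure) {
  rt <- residue_table(structure)
  chains <- unique(rt$chain)
  out <- list()
  for (a in seq_along(chains)) {
    for (b in seq_along(chains)) {
      if (b <= a) next
      ra <- rt[rt$chain == chains[a], ]
      rb <- rt[rt$chain == chains[b], ]
      g <- expand.grid(i = seq_len(nrow(ra)), j = seq_len(nrow(rb)))
      out[[length(out) + 1]] <- .pair_df(ra[g$i, ], rb[g$j, ])
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.pair_key <- function(pairs) {
  paste(pairs$chain_i, pairs$resno_i, pairs$chain_j, pairs$resno_j, sep = ":")
}

## Center-of-mass time series for a set of residues: array [frames, res, 3].
.residue_com_series <- function(trajectory, structure, residues, frames) {
  nf <- length(frames)
  out <- array(NA_real_, dim = c(nf, nrow(residues), 3))
  for (r in seq_len(nrow(residues))) {
    idx <- residue_atoms(structure, residues$chain[r], residues$resno[r])
    m <- structure$atoms$mass[idx]
    M <- sum(m)
    for (d in 1:3) {
      out[, r, d] <- (trajectory$coords[frames, idx, d, drop = FALSE][, , 1] %*% m) / M
    }
  }
  out
}

#' Residue contact occupancy for one replicate
#'
#' A contact is scored in a frame when the mass-weighted centers of mass of
#' the two residues lie strictly within `cutoff` Angstrom of each other
#' (set `inclusive = TRUE` for a `<=` comparison). Occupancy is the fraction
#' of in-window frames in contact.
#'
#' @param trajectory An `md_trajectory`.
#' @param structure The matching `md_structure`.
#' @param pairs data.frame with `chain_i`, `resno_i`, `chain_j`, `resno_j`.
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @param window_ns,frac Trailing analysis window (see [window_frames()]).
#' @param inclusive Use `<=` instead of the default strict `<` comparison.
#' @return data.frame of class `occupancy_matrix`: the pair columns plus
#'   `occupancy` and `replicate`; attributes record cutoff and window.
#' @export
contact_occupancy <- function(trajectory, structure, pairs, cutoff = 5,
                              window_ns = NULL, frac = NULL,
                              inclusive = FALSE) {
  stopifnot(dim(trajectory$coords)[2] == n_atoms(structure))
  frames <- window_frames(trajectory, window_ns, frac)
  res <- unique(rbind(
    data.frame(chain = pairs$chain_i, resno = pairs$resno_i,
               stringsAsFactors = FALSE),
    data.frame(chain = pairs$chain_j, resno = pairs$resno_j,
               stringsAsFactors = FALSE)))
  coms <- .residue_com_series(trajectory, structure, res, frames)
  rkey <- paste(res$chain, res$resno)
  ii <- match(paste(pairs$chain_i, pairs$resno_i), rkey)
  jj <- match(paste(pairs$chain_j, pairs$resno_j), rkey)
  occ <- vapply(seq_len(nrow(pairs)), function(p) {
    a <- matrix(coms[, ii[p], , drop = FALSE], ncol = 3)
    b <- matrix(coms[, jj[p], , drop = FALSE], ncol = 3)
    d <- sqrt(rowSums((a - b)^2))
    if (inclusive) mean(d <= cutoff) else mean(d < cutoff)
  }, numeric(1))
  out <- cbind(pairs[, c("chain_i", "resno_i", "chain_j", "resno_j")],
               data.frame(occupancy = occ, replicate = trajectory$replicate))
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "window_ns") <- window_ns
  attr(out, "n_frames") <- length(frames)
  class(out) <- c("occupancy_matrix", "data.frame")
  out
}

## Accept a single occupancy data.frame or a list of per-replicate ones.
.bind_occupancy <- function(x) {
  if (is.data.frame(x)) return(x)
  do.call(rbind, c(lapply(x, as.data.frame), list(make.row.names = FALSE)))
}

#' Replicate-mean occupancy per pair
#'
#' @param occ An `occupancy_matrix` or list of per-replicate ones.
#' @return data.frame with pair columns, `mean`, `sd` (sample sd across
#'   replicates; 0 when a single replicate), and `n` replicates.
#' @export
occupancy_mean <- function(occ) {
  occ <- .bind_occupancy(occ)
  key <- .pair_key(occ)
  first <- !duplicated(key)
  pairs <- occ[first, c("chain_i", "resno_i", "chain_j", "resno_j")]
  grp <- match(key, key[first])
  n <- as.integer(tabulate(grp))
  mean_ <- as.numeric(tapply(occ$occupancy, grp, mean))
  sd_ <- as.numeric(tapply(occ$occupancy, grp,
                           function(v) if (length(v) > 1) stats::sd(v) else 0))
  out <- cbind(pairs, data.frame(mean = mean_, sd = sd_, n = n))
  rownames(out) <- NULL
  out
}

#' Wild-type minus mutant contact difference map
#'
#' Per pair, `100 * (mean_WT - mean_MUT)` in percentage points: positive
#' values mean more contact in the wild type, negative more contact in the
#' mutant.
#'
#' @param wt,mut `occupancy_matrix` objects or lists of per-replicate ones;
#'   both sides must index the same residue pairs.
#' @return data.frame with pair columns, `mean_wt`, `mean_mut`, `diff_pp`
#'   (percentage points in [-100, 100]).
#' @export
contact_difference_map <- function(wt, mut) {
  mwt <- occupancy_mean(wt)
  mmut <- occupancy_mean(mut)
  kw <- .pair_key(mwt)
  km <- .pair_key(mmut)
  if (!setequal(kw, km) || length(kw) != length(km)) {
    stop("pair-set mismatch between WT and mutant occupancy: ",
         paste(c(setdiff(kw, km), setdiff(km, kw)), collapse = ", "))
  }
  mmut <- mmut[match(kw, km), ]
  out <- mwt[, c("chain_i", "resno_i", "chain_j", "resno_j")]
  out$mean_wt <- mwt$mean
  out$mean_mut <- mmut$mean
  out$diff_pp <- 100 * (mwt$mean - mmut$mean)
  rownames(out) <- NULL
  out
}
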