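## Align all frames of the selected atoms onto a reference coordinate set.
.align_frames <- function(coords, sel, ref_sel) {
  nf <- dim(coords)[1]
  out <- array(NA_real_, dim = c(nf, length(sel), 3))
  for (t in seq_len(nf)) {
    frame <- coords[t, , ]
    fit <- kabsch_superpose(frame[sel, , drop = FALSE], ref_sel)
    out[t, , ] <- apply_transform(frame[sel, , drop = FALSE], fit)
  }
  out
}

#' Per-residue RMSF profile
#'
#' For each replicate, frames are rigid-body superposed onto the replicate's
#' mean structure using a two-pass scheme: frames are first aligned to the
#' first frame, averaged, then re-aligned to that average (a single pass is
#' available via `two_pass = FALSE`). The per-atom fluctuation is
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` over the selection, and the
#' cross-replicate mean and sample standard deviation are reported.
#'
#' @param trajectories An `md_trajectory` or list of them (replicates).
#' @param structure The matching `md_structure`.
#' @param sel Atom selection (default: C-alpha atoms).
#' @param two_pass Use the two-pass mean-structure reference (default TRUE).
#' @return data.frame of class `rmsf_profile` with `chain`, `resno`, `atom`,
#'   one `rep_<i>` column per replicate, and `mean` / `sd` columns.
#' @export
rmsf_profile <- function(trajectories, structure, sel = NULL, two_pass = TRUE) {
  if (inherits(trajectories, "md_trajectory")) trajectories <- list(trajectories)
  if (length(trajectories) < 1) stop("at least one trajectory is required")
  if (is.null(sel)) sel <- ca_selection(structure)
  if (length(sel) == 0) stop("empty atom selection")
  per_rep <- vapply(trajectories, function(traj) {
    stopifnot(dim(traj$coords)[2] == n_atoms(structure))
    ref <- traj$coords[1, sel, , drop = TRUE]
    aligned <- .align_frames(traj$coords, sel, ref)
    if (two_pass) {
      m1 <- apply(aligned, c(2, 3), mean)
      aligned <- .align_frames(traj$coords, sel, m1)
    }
    m <- apply(aligned, c(2, 3), mean)
    dev2 <- (aligned - rep(m, each = dim(aligned)[1]))^2
    sqrt(apply(dev2, 2, mean) * 3)
  }, numeric(length(sel)))
  per_rep <- matrix(per_rep, nrow = length(sel))
  reps <- vapply(trajectories, function(x) x$replicate, integer(1))
  out <- data.frame(chain = structure$atoms$chain[sel],
                    resno = structure$atoms$resno[sel],
                    atom = structure$atoms$atom[sel],
                    stringsAsFactors = FALSE)
  colnames(per_rep) <- paste0("rep_", reps)
  out <- cbind(out, as.data.frame(per_rep))
  out$mean <- rowMeans(per_rep)
  out$sd <- if (ncol(per_rep) > 1) apply(per_rep, 1, stats::sd) else 0
  attr(out, "n_replicates") <- length(trajectories)
  class(out) <- c("rmsf_profile", "data.frame")
  out
}
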