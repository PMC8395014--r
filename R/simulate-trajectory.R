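## Residues named by any planting spec, as "chain resno" keys.
.plant_residues <- function(planted_contacts, planted_hbonds) {
  keys <- character(0)
  if (!is.null(planted_contacts) && nrow(planted_contacts) > 0) {
    keys <- c(keys,
              paste(planted_contacts$chain_i, planted_contacts$resno_i),
              paste(planted_contacts$chain_j, planted_contacts$resno_j))
  }
  if (!is.null(planted_hbonds) && nrow(planted_hbonds) > 0) {
    keys <- c(keys,
              paste(planted_hbonds$donor_chain, planted_hbonds$donor_resno),
              paste(planted_hbonds$acceptor_chain, planted_hbonds$acceptor_resno))
  }
  keys
}

#' Simulate replicate trajectories with planted contact and H-bond events
#'
#' Stand-in for molecular-dynamics production runs: each replicate's frames
#' are the reference coordinates plus i.i.d. Gaussian per-coordinate noise
#' of standard deviation `sigma`. For every planted contact with target
#' occupancy `f`, exactly `round(f * n_frames)` frames — a deterministic
#' prefix of the frame list — place the residue pair's centers of mass at
#' `contact_in` Angstrom (inside the cutoff) and the remaining frames at
#' `contact_out` (outside), by rigidly translating the second residue along
#' the center-of-mass axis after the noise is applied, so occupancy recovery
#' is exact rather than statistical. Planted hydrogen bonds likewise pin the
#' acceptor atom at `hbond_in`/`hbond_out` from the donor, with the donor
#' hydrogen (when present) placed on the donor-acceptor axis so the angle
#' criterion is met in bonded frames.
#'
#' Residues involved in different planting specs must be disjoint.
#'
#' @param structure An `md_structure` (e.g. [make_toy_dimer()]).
#' @param n_frames Frames per replicate.
#' @param dt Frame spacing in ns.
#' @param sigma Per-coordinate fluctuation sd in Angstrom (>= 0).
#' @param planted_contacts data.frame with `chain_i`, `resno_i`, `chain_j`,
#'   `resno_j`, `occupancy` (in [0, 1]), or `NULL`.
#' @param planted_hbonds data.frame with `donor_chain`, `donor_resno`,
#'   `donor_atom`, `acceptor_chain`, `acceptor_resno`, `acceptor_atom`,
#'   `occupancy`, or `NULL`.
#' @param n_replicates Number of replicates (>= 1; the study design uses 3).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param contact_cutoff Contact cutoff the planting honours (Angstrom).
#' @param contact_in,contact_out Planted center-of-mass distances for
#'   in-contact / out-of-contact frames. The defaults keep the moved
#'   residue close enough to its own chain that planted events do not flip
#'   the contact state of neighbouring pairs.
#' @param hbond_in,hbond_out Planted donor-acceptor distances.
#' @return List with `trajectories` (list of `md_trajectory`) and `truth`
#'   (planted counts and occupancies per pair; class `sim_truth`).
#' @export
simulate_trajectory <- function(structure, n_frames = 200, dt = 1,
                                sigma = 0.3, planted_contacts = NULL,
                                planted_hbonds = NULL, n_replicates = 3,
                                seed = 1, contact_cutoff = 5,
                                contact_in = 3.5, contact_out = 6.5,
                                hbond_in = 2.9, hbond_out = 6) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  occs <- c(planted_contacts$occupancy, planted_hbonds$occupancy)
  if (length(occs) && (any(occs < 0) || any(occs > 1))) {
    stop("planted occupancies must lie in [0, 1]")
  }
  keys <- .plant_residues(planted_contacts, planted_hbonds)
  if (anyDuplicated(keys)) {
    stop("invalid argument: residues in planting specs must be disjoint")
  }
  na <- n_atoms(structure)
  ref <- structure$xyz

  ## Resolve all planted atoms up front (errors on unknown residues/atoms).
  contacts <- NULL
  if (!is.null(planted_contacts) && nrow(planted_contacts) > 0) {
    contacts <- lapply(seq_len(nrow(planted_contacts)), function(p) {
      pc <- planted_contacts[p, ]
      list(Ii = residue_atoms(structure, pc$chain_i, pc$resno_i),
           Ij = residue_atoms(structure, pc$chain_j, pc$resno_j),
           k = round(pc$occupancy * n_frames))
    })
  }
  hbonds <- NULL
  if (!is.null(planted_hbonds) && nrow(planted_hbonds) > 0) {
    hbonds <- lapply(seq_len(nrow(planted_hbonds)), function(p) {
      hb <- planted_hbonds[p, ]
      hi <- which(structure$atoms$chain == hb$donor_chain &
                    structure$atoms$resno == hb$donor_resno &
                    structure$atoms$atom == "H")
      list(di = atom_index(structure, hb$donor_chain, hb$donor_resno,
                           hb$donor_atom),
           ai = atom_index(structure, hb$acceptor_chain, hb$acceptor_resno,
                           hb$acceptor_atom),
           hi = if (length(hi) == 1) hi else NA_integer_,
           k = round(hb$occupancy * n_frames))
    })
  }

  set.seed(seed)
  masses <- structure$atoms$mass
  trajectories <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    X <- array(stats::rnorm(n_frames * na * 3, 0, sigma),
               dim = c(n_frames, na, 3))
    for (d in 1:3) X[, , d] <- sweep(X[, , d, drop = FALSE][, , 1], 2,
                                     ref[, d], `+`)
    com_series <- function(idx) {
      m <- masses[idx]
      out <- matrix(NA_real_, n_frames, 3)
      for (d in 1:3) {
        out[, d] <- (X[, idx, d, drop = FALSE][, , 1] %*% m) / sum(m)
      }
      out
    }
    unit_rows <- function(u) {
      nrm <- sqrt(rowSums(u^2))
      zero <- nrm < 1e-12
      u[zero, ] <- matrix(rep(c(1, 0, 0), sum(zero)), ncol = 3, byrow = TRUE)
      nrm[zero] <- 1
      u / nrm
    }
    for (ct in contacts %||% list()) {
      ci <- com_series(ct$Ii)
      cj <- com_series(ct$Ij)
      diff <- cj - ci
      dcur <- sqrt(rowSums(diff^2))
      u <- unit_rows(diff)
      target <- rep(contact_out, n_frames)
      if (ct$k > 0) target[seq_len(ct$k)] <- contact_in
      shift <- (target - dcur) * u
      for (d in 1:3) {
        X[, ct$Ij, d] <- X[, ct$Ij, d, drop = FALSE][, , 1] + shift[, d]
      }
    }
    for (hb in hbonds %||% list()) {
      D <- X[, hb$di, , drop = FALSE][, 1, ]
      A <- X[, hb$ai, , drop = FALSE][, 1, ]
      if (n_frames == 1) {
        D <- matrix(D, nrow = 1)
        A <- matrix(A, nrow = 1)
      }
      u <- unit_rows(A - D)
      target <- rep(hbond_out, n_frames)
      if (hb$k > 0) target[seq_len(hb$k)] <- hbond_in
      X[, hb$ai, ] <- D + target * u
      if (!is.na(hb$hi)) X[, hb$hi, ] <- D + 1.0 * u
    }
    trajectories[[r]] <- md_trajectory(X, dt = dt, replicate = r)
  }

  truth_contacts <- NULL
  if (!is.null(planted_contacts) && nrow(planted_contacts) > 0) {
    truth_contacts <- planted_contacts
    truth_contacts$frames_in_contact <-
      vapply(contacts, function(ct) ct$k, numeric(1))
    truth_contacts$occupancy_planted <-
      truth_contacts$frames_in_contact / n_frames
  }
  truth_hbonds <- NULL
  if (!is.null(planted_hbonds) && nrow(planted_hbonds) > 0) {
    truth_hbonds <- planted_hbonds
    truth_hbonds$frames_bonded <- vapply(hbonds, function(h) h$k, numeric(1))
    truth_hbonds$occupancy_planted <- truth_hbonds$frames_bonded / n_frames
  }
  truth <- structure(list(n_frames = n_frames, n_replicates = n_replicates,
                          sigma = sigma, seed = seed,
                          contact_cutoff = contact_cutoff,
                          contacts = truth_contacts, hbonds = truth_hbonds),
                     class = "sim_truth")
  list(trajectories = trajectories, truth = truth)
}
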