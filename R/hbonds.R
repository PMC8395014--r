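#' Geometric hydrogen-bond criteria
#'
#' The defaults (donor-acceptor distance <= 3.5 Angstrom, donor-H-acceptor
#' angle >= 120 degrees) are conventional geometric thresholds; both are
#' configurable.
#'
#' @param max_distance Maximum donor-acceptor distance in Angstrom (> 0).
#' @param min_angle Minimum D-H-A angle in degrees, in (0, 180].
#' @return List of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.5, min_angle = 120) {
  if (max_distance <= 0) stop("max_distance must be positive")
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

.resolve_atom <- function(structure, spec) {
  atom_index(structure, spec[["chain"]], as.integer(spec[["resno"]]),
             spec[["atom"]])
}

#' Hydrogen-bond occupancy and length series
#'
#' A frame counts the bond as present when the donor-acceptor distance is
#' within `criteria$max_distance` and, if a hydrogen atom is available, the
#' donor-H-acceptor angle (measured at the hydrogen) is at least
#' `criteria$min_angle`. When no hydrogen can be found on the donor residue
#' the check falls back to distance-only with a warning. The donor-acceptor
#' length series is reported for every in-window frame regardless of bond
#' state.
#'
#' @param trajectory An `md_trajectory`.
#' @param structure The matching `md_structure`.
#' @param donor,acceptor Named vectors/lists `c(chain=, resno=, atom=)`.
#' @param hydrogen Optional explicit hydrogen atom spec; by default an atom
#'   named `"H"` in the donor residue is used when present.
#' @param criteria An [hbond_criteria()].
#' @param window_ns,frac Trailing analysis window (see [window_frames()]).
#' @return List with `occupancy` (fraction in [0, 1]), `lengths` (Angstrom,
#'   one per in-window frame), `times` (ns) and `angle_checked` (logical).
#' @export
hbond_occupancy <- function(trajectory, structure, donor, acceptor,
                            hydrogen = NULL, criteria = hbond_criteria(),
                            window_ns = NULL, frac = NULL) {
  di <- .resolve_atom(structure, donor)
  ai <- .resolve_atom(structure, acceptor)
  hi <- NULL
  if (!is.null(hydrogen)) {
    hi <- .resolve_atom(structure, hydrogen)
  } else {
    cand <- which(structure$atoms$chain == donor[["chain"]] &
                    structure$atoms$resno == as.integer(donor[["resno"]]) &
                    structure$atoms$atom == "H")
    if (length(cand) == 1) hi <- cand
  }
  frames <- window_frames(trajectory, window_ns, frac)
  D <- trajectory$coords[frames, di, , drop = FALSE][, 1, ]
  A <- trajectory$coords[frames, ai, , drop = FALSE][, 1, ]
  if (length(frames) == 1) {
    D <- matrix(D, nrow = 1)
    A <- matrix(A, nrow = 1)
  }
  len <- sqrt(rowSums((A - D)^2))
  present <- len <= criteria$max_distance
  angle_checked <- FALSE
  if (is.null(hi)) {
    warning("no hydrogen atom available on the donor residue; ",
            "using distance-only hydrogen-bond criterion")
  } else {
    H <- trajectory$coords[frames, hi, , drop = FALSE][, 1, ]
    if (length(frames) == 1) H <- matrix(H, nrow = 1)
    v1 <- D - H
    v2 <- A - H
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    present <- present & ang >= criteria$min_angle
    angle_checked <- TRUE
  }
  list(occupancy = mean(present), lengths = len,
       times = trajectory$times[frames], angle_checked = angle_checked)
}
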