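## Near-uniform points on the unit sphere (golden-spiral construction).
.sphere_points <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by the classic sphere-sampling construction: points are
#' distributed near-uniformly on each atom's solvent-expanded sphere
#' (radius = vdW radius + probe) and a point is accessible when it lies
#' outside every neighbouring atom's expanded sphere. The atom's SASA is
#' the accessible fraction of its expanded-sphere area.
#'
#' @param structure An `md_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_sphere_points Sample points per atom (default 960).
#' @param radii Named vdW radii by element (default [VDW_RADII]).
#' @return Numeric vector of per-atom SASA (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(structure, probe_radius = 1.4,
                               n_sphere_points = 960, radii = VDW_RADII) {
  n <- n_atoms(structure)
  if (n == 0) stop("structure has no atoms")
  el <- structure$atoms$element
  if (any(!(el %in% names(radii)))) {
    stop("no vdW radius for element(s): ",
         paste(unique(el[!(el %in% names(radii))]), collapse = ", "))
  }
  r <- unname(radii[el]) + probe_radius
  xyz <- structure$xyz
  pts <- .sphere_points(n_sphere_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    area <- 4 * pi * r[i]^2
    if (length(nb) == 0) {
      sasa[i] <- area
      next
    }
    sp <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(sp, 2, xyz[j, ])^2)
      ## boundary ties (points exactly on a neighbour's expanded sphere,
      ## as with coincident duplicate atoms) bury only on the
      ## earlier-indexed atom, so duplicates expose one surface, not two
      tol <- 1e-9 * r[j]^2
      buried <- dj2 < r[j]^2 - tol | (abs(dj2 - r[j]^2) <= tol & j < i)
      exposed <- exposed & !buried
      if (!any(exposed)) break
    }
    sasa[i] <- area * mean(exposed)
  }
  sasa
}

#' Hydrophobic-surface score of a structure
#'
#' Computes per-atom Shrake-Rupley SASA and summarises protein surface
#' hydrophobicity two ways. The primary score is the apolar SASA: the
#' summed surface area of carbon and sulfur atoms, the standard apolar
#' decomposition, which directly increases when a polar side-chain atom is
#' replaced by an apolar one (e.g. a serine-to-proline-like swap). A
#' residue-level score weighting each residue's SASA by its
#' Kyte-Doolittle hydropathy normalised to [0, 1] is reported alongside.
#' Scores are comparable across structures with identical atom counts per
#' residue class.
#'
#' @inheritParams shrake_rupley_sasa
#' @return List with `total_sasa`, `apolar_sasa`, `kd_weighted_sasa`
#'   (all Angstrom^2) and `per_residue` (data.frame: `chain`, `resno`,
#'   `resname`, `sasa`, `apolar_sasa`, `kd_weight`).
#' @export
hydrophobic_surface_score <- function(structure, probe_radius = 1.4,
                                      n_sphere_points = 960,
                                      radii = VDW_RADII) {
  sasa <- shrake_rupley_sasa(structure, probe_radius, n_sphere_points, radii)
  apolar <- structure$atoms$element %in% c("C", "S")
  rt <- residue_table(structure)
  rkey <- paste(structure$atoms$chain, structure$atoms$resno)
  grp <- match(rkey, paste(rt$chain, rt$resno))
  res_sasa <- as.numeric(tapply(sasa, grp, sum))
  res_apolar <- as.numeric(tapply(sasa * apolar, grp, sum))
  w <- (unname(.KD_SCALE[rt$resname]) + 4.5) / 9
  per_residue <- data.frame(chain = rt$chain, resno = rt$resno,
                            resname = rt$resname, sasa = res_sasa,
                            apolar_sasa = res_apolar, kd_weight = w,
                            stringsAsFactors = FALSE)
  list(total_sasa = sum(sasa),
       apolar_sasa = sum(sasa[apolar]),
       kd_weighted_sasa = sum(res_sasa * w, na.rm = TRUE),
       per_residue = per_residue)
}
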