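## Atomic constants ----------------------------------------------------------

#' Standard atomic masses (amu) by element symbol
#' @export
ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06)

#' Van der Waals radii (Angstrom) by element symbol
#'
#' Bondi-style radii used for solvent-accessible surface area.
#' @export
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)

## Kyte-Doolittle hydropathy, normalised later to [0, 1].
.KD_SCALE <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5)

## Residues whose pseudo side-chain atom (CB) carries a polar (O) element in
## the toy dimer; everything else gets an apolar carbon pseudo-atom.
.POLAR_TOY_RESIDUES <- c("SER", "THR", "TYR", "ASN", "GLN", "ASP", "GLU",
                         "LYS", "ARG", "HIS", "CYS")

## Structure container -------------------------------------------------------

#' Molecular structure container
#'
#' A lightweight container pairing an atom table with reference coordinates.
#' The atom table carries one row per atom with chain id, residue number
#' (1-based, PDB numbering), residue name, atom name, element and mass (amu);
#' `xyz` is an `n_atoms x 3` matrix of coordinates in Angstrom.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `mass`.
#' @param xyz numeric matrix, `nrow(atoms) x 3`.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz) {
  xyz <- unname(as.matrix(xyz))
  stopifnot(is.data.frame(atoms), ncol(xyz) == 3, nrow(atoms) == nrow(xyz))
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key)) {
    stop("duplicate atom key: ", key[duplicated(key)][1])
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("all atom masses must be positive and finite")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("md_structure: %d atoms, %d residues, chains {%s}\n",
              nrow(x$atoms), nrow(rt),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure An `md_structure`.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Residue table of a structure
#'
#' @param structure An `md_structure`.
#' @return data.frame with one row per residue (`chain`, `resno`, `resname`)
#'   in atom order.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  keep <- !duplicated(paste(a$chain, a$resno))
  data.frame(chain = a$chain[keep], resno = a$resno[keep],
             resname = a$resname[keep], stringsAsFactors = FALSE)
}

#' Atom indices of one residue
#'
#' @param structure An `md_structure`.
#' @param chain Chain identifier.
#' @param resno Residue number.
#' @return Integer vector of row indices into the atom table.
#' @export
residue_atoms <- function(structure, chain, resno) {
  idx <- which(structure$atoms$chain == chain & structure$atoms$resno == resno)
  if (length(idx) == 0) {
    stop(sprintf("unknown residue %s:%s", chain, resno))
  }
  idx
}

#' Index of a named atom
#'
#' @inheritParams residue_atoms
#' @param atom Atom name (e.g. `"CA"`).
#' @export
atom_index <- function(structure, chain, resno, atom) {
  idx <- which(structure$atoms$chain == chain &
                 structure$atoms$resno == resno &
                 structure$atoms$atom == atom)
  if (length(idx) != 1) {
    stop(sprintf("unknown atom %s:%s:%s", chain, resno, atom))
  }
  idx
}

#' C-alpha atom selection
#'
#' @param structure An `md_structure`.
#' @return Integer indices of all CA atoms, in atom order.
#' @export
ca_selection <- function(structure) {
  which(structure$atoms$atom == "CA")
}

#' Mass-weighted residue center of mass
#'
#' All atoms of the residue present in the model contribute (hydrogens
#' included when present).
#'
#' @param frame `n_atoms x 3` coordinate matrix for one frame, or `NULL` to
#'   use the structure's reference coordinates.
#' @param structure An `md_structure`.
#' @param chain,resno Residue address.
#' @return Numeric length-3 vector (Angstrom).
#' @export
residue_center_of_mass <- function(frame, structure, chain, resno) {
  if (is.null(frame)) frame <- structure$xyz
  idx <- residue_atoms(structure, chain, resno)
  m <- structure$atoms$mass[idx]
  colSums(frame[idx, , drop = FALSE] * m) / sum(m)
}

## Toy dimer -----------------------------------------------------------------

.toy_cb_element <- function(resname) {
  ifelse(toupper(resname) %in% .POLAR_TOY_RESIDUES, "O", "C")
}

#' Build a toy two-chain dimer
#'
#' Constructs an idealised homodimer for simulation tests: two identical
#' chains (ids A and B) whose C-alpha traces follow a circular arc with
#' exact 3.8 Angstrom consecutive C-alpha chords, giving the compact,
#' globular footprint of a folded chain rather than an extended rod (so
#' rigid-body superposition treats all residues with comparable leverage).
#' Each residue carries backbone atoms N, H, CA, C, O and a single pseudo
#' side-chain atom CB. Chain B is chain A translated by `chain_offset`
#' (default: stacked 4 Angstrom above), which places every aligned
#' inter-chain residue pair within 5 Angstrom center-of-mass distance (an
#' interface region). CB carries a polar oxygen pseudo-atom for polar
#' residue names (the default serine) and carbon otherwise.
#'
#' @param n_res_per_chain Residues per chain (>= 5).
#' @param resname Residue name applied to all residues (default `"SER"`).
#' @param chain_offset Length-3 translation of chain B relative to chain A.
#' @return An `md_structure` with `2 * n_res_per_chain` residues.
#' @export
make_toy_dimer <- function(n_res_per_chain = 20, resname = "SER",
                           chain_offset = c(0, 0, 4)) {
  if (!is.numeric(n_res_per_chain) || n_res_per_chain < 5) {
    stop("invalid argument: n_res_per_chain must be >= 5")
  }
  n_res_per_chain <- as.integer(n_res_per_chain)
  resname <- toupper(resname)
  cb_elem <- .toy_cb_element(resname)
  template <- data.frame(
    atom = c("N", "H", "CA", "C", "O", "CB"),
    element = c("N", "H", "C", "C", "O", cb_elem),
    dx = c(-1.2, -1.2, 0.0, 1.2, 1.2, 0.0),
    dy = c(0.9, 1.9, 0.0, 0.9, 2.1, -1.5),
    dz = c(0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  ## arc spanning 270 degrees; the radius keeps consecutive chords at
  ## exactly 3.8 A
  phi <- (270 / (n_res_per_chain - 1)) * pi / 180
  radius <- 3.8 / (2 * sin(phi / 2))
  one_chain <- function(chain, shift) {
    res <- lapply(seq_len(n_res_per_chain), function(i) {
      cx <- radius * cos((i - 1) * phi)
      cy <- radius * sin((i - 1) * phi)
      data.frame(chain = chain, resno = i, resname = resname,
                 atom = template$atom, element = template$element,
                 mass = unname(ELEMENT_MASSES[template$element]),
                 x = cx + template$dx + shift[1],
                 y = cy + template$dy + shift[2],
                 z = template$dz + shift[3],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  ab <- rbind(one_chain("A", c(0, 0, 0)), one_chain("B", chain_offset))
  md_structure(ab[, c("chain", "resno", "resname", "atom", "element", "mass")],
               as.matrix(ab[, c("x", "y", "z")]))
}

#' Swap the chemical character of a toy residue
#'
#' Renames one residue of a toy dimer and updates its pseudo side-chain (CB)
#' element accordingly: polar residue names carry an oxygen pseudo-atom,
#' apolar ones a carbon. Used to emulate a serine-to-proline-like
#' polar-to-apolar substitution.
#'
#' @param structure An `md_structure` built by [make_toy_dimer()].
#' @param chain,resno Residue to mutate.
#' @param resname New residue name (e.g. `"PRO"`).
#' @return The modified `md_structure`.
#' @export
mutate_toy_residue <- function(structure, chain, resno, resname) {
  resname <- toupper(resname)
  idx <- residue_atoms(structure, chain, resno)
  structure$atoms$resname[idx] <- resname
  cb <- idx[structure$atoms$atom[idx] == "CB"]
  if (length(cb) == 1) {
    el <- .toy_cb_element(resname)
    structure$atoms$element[cb] <- el
    structure$atoms$mass[cb] <- unname(ELEMENT_MASSES[el])
  }
  structure
}

## PDB I/O -------------------------------------------------------------------

.infer_element <- function(name) {
  core <- sub("^[0-9']*", "", name)
  el <- toupper(substr(core, 1, 1))
  el
}

#' Read a structure from a PDB file
#'
#' Parses the first model of a PDB file (via bio3d) into an
#' [md_structure()]. Elements are taken from the element column when
#' present, otherwise inferred from the atom name; masses are assigned by
#' element.
#'
#' @param path Path to a PDB file.
#' @return An `md_structure`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  el[is.na(el) | !nzchar(trimws(el))] <- NA
  el <- ifelse(is.na(el), .infer_element(at$elety), toupper(trimws(el)))
  unknown <- !(el %in% names(ELEMENT_MASSES))
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop(sprintf("unknown element for atom %s:%s:%s",
                 at$chain[i], at$resno[i], at$elety[i]))
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                      atom = trimws(at$elety), element = el,
                      mass = unname(ELEMENT_MASSES[el]),
                      stringsAsFactors = FALSE)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  md_structure(atoms, xyz)
}

## One PDB ATOM record per atom; fixed-column format readable by bio3d.
.pdb_atom_lines <- function(structure, xyz) {
  a <- structure$atoms
  name4 <- ifelse(nchar(a$atom) <= 3, sprintf(" %-3s", a$atom),
                  sprintf("%-4s", a$atom))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(a)), name4, a$resname, a$chain, a$resno,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
}

#' Write a structure to a PDB file
#'
#' @param structure An `md_structure`.
#' @param path Output path.
#' @export
write_structure_pdb <- function(structure, path) {
  writeLines(c(.pdb_atom_lines(structure, structure$xyz), "END"), path)
  invisible(path)
}
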