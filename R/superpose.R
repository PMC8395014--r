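#' Kabsch least-squares rigid-body superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between a
#' mobile and a reference point set over a selection, by singular value
#' decomposition of the cross-covariance matrix with the usual determinant
#' correction (so the returned rotation is always proper, det = +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices.
#' @param sel Integer atom selection (default: all rows). At least 3
#'   non-collinear points are required.
#' @return List with `rotation` (3x3), `translation` (length 3; the optimal
#'   transform is `x %*% t(rotation) + translation`) and `rmsd` (Angstrom,
#'   computed on the selection after the transform).
#' @export
kabsch_superpose <- function(mobile, reference, sel = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (is.null(sel)) sel <- seq_len(nrow(mobile))
  if (length(sel) < 3) stop("superposition needs at least 3 selected atoms")
  A <- mobile[sel, , drop = FALSE]
  B <- reference[sel, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selection sizes differ between mobile and reference")
  ca <- colMeans(A)
  cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  if (s$d[1] <= 0 || s$d[2] <= s$d[1] * 1e-10) {
    stop("degenerate geometry: selection is (near-)collinear or coincident")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cb - R %*% ca)
  fitted <- sweep(A %*% t(R), 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a rigid-body transform
#'
#' @param xyz `n x 3` coordinate matrix.
#' @param fit Result of [kabsch_superpose()] (or any list with `rotation`
#'   and `translation`).
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Root mean square deviation between two coordinate sets
#'
#' Plain (unfitted) RMSD over a selection.
#'
#' @param a,b `n x 3` matrices.
#' @param sel Optional integer selection.
#' @export
coord_rmsd <- function(a, b, sel = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.null(sel)) {
    a <- a[sel, , drop = FALSE]
    b <- b[sel, , drop = FALSE]
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame superposed RMSD series
#'
#' Superposes every frame onto a reference (Kabsch, on the selection) and
#' reports the post-fit RMSD of the selection, frame by frame.
#'
#' @param trajectory An `md_trajectory`.
#' @param structure The matching `md_structure`.
#' @param reference `n_atoms x 3` reference coordinates (default: the
#'   structure's reference coordinates).
#' @param sel Atom selection (default: all C-alpha atoms).
#' @return Numeric vector of length `n_frames` (Angstrom).
#' @export
rmsd_series <- function(trajectory, structure, reference = NULL, sel = NULL) {
  if (is.null(reference)) reference <- structure$xyz
  if (is.null(sel)) sel <- ca_selection(structure)
  vapply(seq_len(n_frames(trajectory)), function(t) {
    kabsch_superpose(trajectory$coords[t, , ], reference, sel = sel)$rmsd
  }, numeric(1))
}
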