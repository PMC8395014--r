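#' C-alpha distance statistics for a residue pair
#'
#' Mean and population standard deviation of the CA-CA distance over the
#' in-window frames of one replicate.
#'
#' @param trajectory An `md_trajectory`.
#' @param structure The matching `md_structure`.
#' @param res_i,res_j Named vectors/lists `c(chain=, resno=)`.
#' @param window_ns,frac Trailing analysis window (see [window_frames()]).
#' @return data.frame with the pair address, `mean` (Angstrom), `sd`
#'   (population sd, Angstrom), `n_frames` and the window used.
#' @export
ca_distance_stats <- function(trajectory, structure, res_i, res_j,
                              window_ns = NULL, frac = NULL) {
  ii <- atom_index(structure, res_i[["chain"]], as.integer(res_i[["resno"]]), "CA")
  jj <- atom_index(structure, res_j[["chain"]], as.integer(res_j[["resno"]]), "CA")
  frames <- window_frames(trajectory, window_ns, frac)
  P <- trajectory$coords[frames, ii, , drop = FALSE][, 1, ]
  Q <- trajectory$coords[frames, jj, , drop = FALSE][, 1, ]
  if (length(frames) == 1) {
    P <- matrix(P, nrow = 1)
    Q <- matrix(Q, nrow = 1)
  }
  d <- sqrt(rowSums((P - Q)^2))
  m <- mean(d)
  data.frame(chain_i = res_i[["chain"]], resno_i = as.integer(res_i[["resno"]]),
             chain_j = res_j[["chain"]], resno_j = as.integer(res_j[["resno"]]),
             atom = "CA", mean = m, sd = sqrt(mean((d - m)^2)),
             n_frames = length(d),
             window_ns = if (is.null(window_ns)) NA_real_ else window_ns,
             stringsAsFactors = FALSE)
}
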