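#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Sort rank for chromosome labels: 1..22, then X, Y, MT; unknown labels last.
.chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  n <- suppressWarnings(as.integer(x))
  extra <- match(toupper(x), c("X", "Y", "MT", "M"))
  n[is.na(n)] <- 22L + extra[is.na(n)]
  n[is.na(n)] <- 99L
  n
}

#' Canonical variant identifier
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles.
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## Stable numeric formatting for text outputs (C locale via sprintf).
.num <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.10g", x))
}
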