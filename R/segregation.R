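#' Autosomal-recessive co-segregation test
#'
#' Under full penetrance, a biallelic variant co-segregates with a
#' recessive phenotype when every affected member is homozygous-alternate,
#' every unaffected member is NOT homozygous-alternate, and every genotyped
#' parent of an affected member is heterozygous (an obligate carrier).
#' Members with a missing genotype are ignored; ungenotyped relatives never
#' veto.
#'
#' @param genotypes Named character vector of genotype codes (`"hom_ref"`,
#'   `"het"`, `"hom_alt"`, `"missing"`), names = member ids.
#' @param pedigree A [family_pedigree()].
#' @return `TRUE` or `FALSE`.
#' @export
cosegregates_recessive <- function(genotypes, pedigree) {
  g <- function(id) {
    if (!(id %in% names(genotypes))) return("missing")
    v <- genotypes[[id]]
    if (is.na(v)) "missing" else v
  }
  aff <- pedigree$id[pedigree$affection == "affected"]
  unaff <- pedigree$id[pedigree$affection == "unaffected"]
  for (id in aff) {
    gv <- g(id)
    if (gv != "missing" && gv != "hom_alt") return(FALSE)
  }
  for (id in unaff) {
    if (g(id) == "hom_alt") return(FALSE)
  }
  parents <- unique(stats::na.omit(c(
    pedigree$father[pedigree$affection == "affected"],
    pedigree$mother[pedigree$affection == "affected"])))
  for (id in parents) {
    gv <- g(id)
    if (gv != "missing" && gv != "het") return(FALSE)
  }
  TRUE
}

#' Co-segregation flags for every record of a variant set
#'
#' @param vset A [variant_set()].
#' @param pedigree A [family_pedigree()].
#' @return Logical vector, one flag per record.
#' @export
cosegregation_flags <- function(vset, pedigree) {
  if (n_variants(vset) == 0) return(logical(0))
  apply(vset$gt, 1, cosegregates_recessive, pedigree = pedigree)
}
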