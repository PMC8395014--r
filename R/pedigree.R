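#' Pedigree constructor
#'
#' @param id Member identifiers.
#' @param father,mother Parent ids (`NA` when unknown); when present they
#'   must refer to members of the pedigree.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param affection `"affected"`, `"unaffected"` or `"unknown"`; at least
#'   one member must be affected.
#' @return data.frame of class `pedigree`.
#' @export
family_pedigree <- function(id, father, mother, sex, affection) {
  ped <- data.frame(id = as.character(id), father = as.character(father),
                    mother = as.character(mother), sex = sex,
                    affection = affection, stringsAsFactors = FALSE)
  bad <- stats::na.omit(c(ped$father, ped$mother))
  bad <- bad[!(bad %in% ped$id)]
  if (length(bad)) stop("parent id(s) not in pedigree: ",
                        paste(unique(bad), collapse = ", "))
  if (!any(ped$affection == "affected")) {
    stop("pedigree must contain at least one affected member")
  }
  if (!all(ped$affection %in% c("affected", "unaffected", "unknown"))) {
    stop("affection must be affected/unaffected/unknown")
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Six-member consanguineous CCD study pedigree
#'
#' The sequenced nuclear family of the cardiac conduction disease study:
#' two consanguineous carrier parents, two affected and two unaffected
#' siblings.
#'
#' @return A [family_pedigree()].
#' @export
ccd_pedigree <- function() {
  family_pedigree(
    id = c("III-1", "III-2", "IV-3", "IV-4", "IV-5", "IV-6"),
    father = c(NA, NA, "III-1", "III-1", "III-1", "III-1"),
    mother = c(NA, NA, "III-2", "III-2", "III-2", "III-2"),
    sex = c("male", "female", "female", "male", "female", "male"),
    affection = c("unaffected", "unaffected", "affected", "unaffected",
                  "affected", "unaffected"))
}

#' Read a 6-column PED file
#'
#' Columns: family id, member id, father, mother, sex (1 male / 2 female /
#' 0 unknown), phenotype (2 affected / 1 unaffected / 0 or -9 unknown).
#'
#' @param path Path to a tab-separated PED file.
#' @return A [family_pedigree()].
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "id", "father", "mother",
                                         "sex", "pheno"))
  family_pedigree(
    id = tab$id,
    father = ifelse(tab$father == "0", NA, tab$father),
    mother = ifelse(tab$mother == "0", NA, tab$mother),
    sex = c("unknown", "male", "female")[match(tab$sex, c(0, 1, 2))],
    affection = ifelse(tab$pheno == 2, "affected",
                       ifelse(tab$pheno == 1, "unaffected", "unknown")))
}

#' Write a pedigree as a 6-column PED file
#'
#' @param pedigree A [family_pedigree()].
#' @param path Output path.
#' @param family_id Family identifier for column 1.
#' @export
write_ped <- function(pedigree, path, family_id = "FAM1") {
  sex <- match(pedigree$sex, c("male", "female"))
  sex[is.na(sex)] <- 0
  pheno <- ifelse(pedigree$affection == "affected", 2,
                  ifelse(pedigree$affection == "unaffected", 1, 0))
  lines <- paste(family_id, pedigree$id,
                 ifelse(is.na(pedigree$father), "0", pedigree$father),
                 ifelse(is.na(pedigree$mother), "0", pedigree$mother),
                 sex, pheno, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
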