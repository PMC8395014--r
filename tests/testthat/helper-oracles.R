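## Independent brute-force oracles, deliberately written as plain loops and
## kept separate from the package implementation paths they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Mass-weighted center of mass by explicit summation.
naive_com <- function(frame, structure, chain, resno) {
  num <- c(0, 0, 0)
  den <- 0
  for (i in seq_len(nrow(structure$atoms))) {
    a <- structure$atoms[i, ]
    if (a$chain == chain && a$resno == resno) {
      num <- num + a$mass * frame[i, ]
      den <- den + a$mass
    }
  }
  num / den
}

## Per-frame double loop over pairs; strict < cutoff.
naive_contact_occupancy <- function(trajectory, structure, pairs,
                                    cutoff = 5, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(dim(trajectory$coords)[1])
  rt <- residue_table(structure)
  ridx <- lapply(seq_len(nrow(rt)), function(r) {
    which(structure$atoms$chain == rt$chain[r] &
            structure$atoms$resno == rt$resno[r])
  })
  rkey <- paste(rt$chain, rt$resno)
  hits <- numeric(nrow(pairs))
  for (t in frames) {
    frame <- trajectory$coords[t, , ]
    coms <- matrix(NA_real_, nrow(rt), 3)
    for (r in seq_len(nrow(rt))) {
      idx <- ridx[[r]]
      m <- structure$atoms$mass[idx]
      coms[r, ] <- colSums(frame[idx, , drop = FALSE] * m) / sum(m)
    }
    for (p in seq_len(nrow(pairs))) {
      i <- match(paste(pairs$chain_i[p], pairs$resno_i[p]), rkey)
      j <- match(paste(pairs$chain_j[p], pairs$resno_j[p]), rkey)
      d <- sqrt(sum((coms[i, ] - coms[j, ])^2))
      if (d < cutoff) hits[p] <- hits[p] + 1
    }
  }
  hits / length(frames)
}

## Straight re-statement of the recessive pattern, one condition at a time.
naive_coseg <- function(genotypes, pedigree) {
  get <- function(id) {
    v <- genotypes[[id]]
    if (is.null(v) || is.na(v)) "missing" else v
  }
  ok <- TRUE
  for (i in seq_len(nrow(pedigree))) {
    id <- pedigree$id[i]
    g <- get(id)
    if (pedigree$affection[i] == "affected") {
      if (g != "missing" && g != "hom_alt") ok <- FALSE
      for (par in c(pedigree$father[i], pedigree$mother[i])) {
        if (!is.na(par)) {
          gp <- get(par)
          if (gp != "missing" && gp != "het") ok <- FALSE
        }
      }
    }
    if (pedigree$affection[i] == "unaffected" && g == "hom_alt") ok <- FALSE
  }
  ok
}

## Independent per-record threshold re-application; returns survivor ids.
naive_filter_survivors <- function(vset, config, pedigree) {
  keep <- character(0)
  for (i in seq_len(nrow(vset$site))) {
    s <- vset$site[i, ]
    ok <- TRUE
    for (sm in pedigree$id) {
      g <- vset$gt[i, sm]
      if (g == "missing") next
      dp <- vset$dp[i, sm]
      gq <- vset$gq[i, sm]
      if (is.na(dp) || dp <= config$min_depth) ok <- FALSE
      if (is.na(gq) || gq <= config$min_gq) ok <- FALSE
      if (g == "hom_alt") {
        arf <- vset$arf[i, sm]
        if (is.na(arf) || arf < config$min_arf) ok <- FALSE
      }
    }
    if (!is.na(s$maf) && s$maf >= config$max_maf) ok <- FALSE
    if (!is.na(s$ihaf) && s$ihaf >= config$max_inhouse_af) ok <- FALSE
    if (is.na(s$fs) || s$fs >= config$max_fs) ok <- FALSE
    if (is.na(s$mqrs) || s$mqrs < config$min_mqranksum) ok <- FALSE
    if (is.na(s$qd) || s$qd <= config$min_qd) ok <- FALSE
    if (is.na(s$mq) || s$mq <= config$min_mq) ok <- FALSE
    if (is.na(s$rprs) || s$rprs < config$min_readposranksum) ok <- FALSE
    if (!is.na(s$splc) && abs(s$splc) > config$max_splice_change) ok <- FALSE
    if (is.na(s$csq) || !(s$csq %in% config$retained_classes)) ok <- FALSE
    if (config$use_quorum && !is.na(s$quorum)) {
      need <- if (nchar(s$ref) == 1 && nchar(s$alt) == 1) 2 else 1
      if (s$quorum < need) ok <- FALSE
    }
    if (ok) keep <- c(keep, s$id)
  }
  keep
}

## Minimal hand-built variant_set for crafted filter/segregation cases.
make_test_vset <- function(site_overrides = list(), gt = NULL,
                           pedigree = ccd_pedigree(), n = 1) {
  ids <- pedigree$id
  site <- data.frame(chrom = rep("1", n), pos = seq_len(n) * 1000L,
                     id = paste0("v", seq_len(n)), ref = "A", alt = "G",
                     csq = "missense", maf = NA_real_, ihaf = NA_real_,
                     fs = 1, mq = 60, qd = 20, mqrs = 0, rprs = 0,
                     splc = NA_real_, rankscore = 0.5, cadd = 20,
                     quorum = NA_real_, stringsAsFactors = FALSE)
  for (k in names(site_overrides)) site[[k]] <- site_overrides[[k]]
  if (is.null(gt)) {
    gt <- matrix("het", n, length(ids), dimnames = list(NULL, ids))
    aff <- ids[pedigree$affection == "affected"]
    gt[, aff] <- "hom_alt"
  }
  dp <- matrix(50, n, length(ids), dimnames = list(NULL, ids))
  gq <- matrix(99, n, length(ids), dimnames = list(NULL, ids))
  arf <- ifelse(gt == "hom_alt", 0.98, ifelse(gt == "het", 0.5, 0.01))
  arf <- matrix(as.numeric(arf), n, length(ids), dimnames = list(NULL, ids))
  variant_set(site, gt, dp, gq, arf)
}
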