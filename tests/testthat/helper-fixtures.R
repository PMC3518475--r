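# shared fixtures, all built in code

# tiny CtSet: 3 assayed microRNAs + the two controls, 4 samples
tinyCtSet <- function() {
  ct <- rbind(
    "hsa-miR-1" = c(30, 28, 31, 29),
    "hsa-miR-2" = c(25, 26, 24, 27),
    "hsa-miR-3" = c(36, NA, 39, 35),
    "RNU-44"    = c(25, 24, 26, 25),
    "RNU-48"    = c(27, 26, 28, 27)
  )
  colnames(ct) <- paste0("s", 1:4)
  CtSet(ct)
}

# pure-noise cohort spec (nothing planted)
noiseSpec <- function(seed, ...) {
  cohortSpec(plantedMirnas = data.frame(mirna_id = character(),
                                        effect_size_cycles = numeric()),
             plantedFamilies = character(), seed = seed, ...)
}

# spec with a single congruent 4-member family shifted by `shift` cycles
plantedFamilySpec <- function(seed, shift = 3, ...) {
  cohortSpec(plantedMirnas = data.frame(
    mirna_id = paste0("hsa-miR-501", letters[1:4]),
    effect_size_cycles = shift),
    plantedFamilies = "mir-501", seed = seed, ...)
}

# family catalog for the default synthetic card
syntheticCatalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- tempfile(fileext = ".dat")
      makeSyntheticMiFam(path)
      fams <- parseMiFam(path)
      co <- generateCohort(noiseSpec(1))
      cache <<- familyCatalog(
        fams, setdiff(rownames(cohortCt(co)), controlIds(cohortCt(co))))
    }
    cache
  }
})

# normalized matrix + labels straight from a cohort
normalizedCohort <- function(co) {
  x <- deltaCtNormalize(flagEntries(cohortCt(co)))
  list(x = x, labels = cohortTruth(co)$rate_class)
}

# full-enumeration oracle for the two-sided Fisher exact test: walks every
# table with the observed margins using choose() directly
fisherEnumOracle <- function(tbl) {
  r1 <- sum(tbl[1, ]); r2 <- sum(tbl[2, ]); c1 <- sum(tbl[, 1])
  n <- sum(tbl)
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1), 0)
  pObs <- prob[support == tbl[1, 1]]
  sum(prob[prob <= pObs * (1 + 1e-7)])
}
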