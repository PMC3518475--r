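#' Parse a miRBase-style family flat file
#'
#' Reads the miFam.dat dialect: records of `AC` (family accession), `ID`
#' (family name) and one `MI` line per member (`MI   <accession>  <name>`),
#' each record terminated by `//`. Members are filtered to one species prefix
#' (default human, `hsa-`).
#'
#' @param path path to the flat file.
#' @param species member-name prefix to retain; `NULL` keeps all members.
#' @return Named list: family id -> character vector of member names.
#' @export
parseMiFam <- function(path, species = "hsa") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fams <- list()
  cur <- NULL; members <- character(); open <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1L, 2L)
    if (tag == "AC") {
      if (open) stop("record starting at line ", i,
                     " opened before previous record was terminated by '//'")
      open <- TRUE
    } else if (tag == "ID") {
      if (!open) stop("ID line outside a record at line ", i)
      cur <- trimws(substring(ln, 3L))
    } else if (tag == "MI") {
      if (!open) stop("MI line outside a record at line ", i)
      fields <- strsplit(trimws(substring(ln, 3L)), "[ \t]+")[[1L]]
      if (length(fields) < 2L)
        stop("malformed MI line at line ", i, ": ", ln)
      members <- c(members, fields[2L])
    } else if (tag == "//") {
      if (!open) stop("unmatched record terminator at line ", i)
      if (is.null(cur)) stop("record terminated at line ", i, " has no ID")
      fams[[cur]] <- members
      cur <- NULL; members <- character(); open <- FALSE
    } else stop("unrecognized line ", i, ": ", ln)
  }
  if (open)
    stop("last record ('", if (is.null(cur)) "?" else cur,
         "') missing terminator '//'")
  if (!is.null(species))
    fams <- lapply(fams, function(m)
      m[startsWith(m, paste0(species, "-"))])
  lapply(fams, function(m) {
    if (anyDuplicated(m))
      stop("duplicated member within a family: ",
           paste(unique(m[duplicated(m)]), collapse = ", "))
    m
  })
}

# canonical stem of a microRNA id: lower-case, precursor-style "mir", mature
# -3p/-5p/-star suffixes stripped; used to match mature assay ids to
# precursor names in family files and to pair complementary strands
mirnaStem <- function(ids) {
  s <- tolower(ids)
  s <- sub("[*]$", "", s)
  s <- sub("-(3p|5p)$", "", s)
  sub("mir", "mir", s, fixed = TRUE)
}

#' Derive -3p/-5p strand pairs from assayed microRNA ids
#'
#' Returns every pair of assayed ids that are the two mature strands of one
#' hairpin, i.e. whose ids match after stripping a `-3p` / `-5p` suffix. Ids
#' without an assayed partner are omitted.
#'
#' @param assayedIds character vector of ids on the card.
#' @return data.frame with columns `stem`, `id_3p`, `id_5p`.
#' @export
derivePairs <- function(assayedIds) {
  is3 <- grepl("-3p$", assayedIds)
  is5 <- grepl("-5p$", assayedIds)
  st3 <- mirnaStem(assayedIds[is3])
  st5 <- mirnaStem(assayedIds[is5])
  common <- intersect(st3, st5)
  if (!length(common))
    return(data.frame(stem = character(), id_3p = character(),
                      id_5p = character()))
  out <- data.frame(
    stem = common,
    id_3p = assayedIds[is3][match(common, st3)],
    id_5p = assayedIds[is5][match(common, st5)],
    stringsAsFactors = FALSE
  )
  out[order(out$stem), , drop = FALSE]
}

#' Build the evaluable family/pair catalog for a card
#'
#' Matches a parsed family list ([parseMiFam()]) against the assayed ids
#' (mature ids are matched to precursor member names on their shared stem)
#' and derives the -3p/-5p pairs. Families need at least `minFamilyMembers`
#' assayed members to be evaluable; pairs need both strands assayed.
#'
#' @param families named list from [parseMiFam()].
#' @param assayedIds ids present on the card (controls excluded).
#' @param minFamilyMembers minimum assayed members per evaluable family.
#' @return List with `families` (family id -> assayed member ids),
#'   `pairs` (data.frame from [derivePairs()]), and `assayedIds`.
#' @export
familyCatalog <- function(families, assayedIds, minFamilyMembers = 3) {
  stems <- mirnaStem(assayedIds)
  matched <- lapply(families, function(members) {
    assayedIds[stems %in% mirnaStem(members)]
  })
  matched <- matched[vapply(matched, length, 0L) >= minFamilyMembers]
  list(families = matched, pairs = derivePairs(assayedIds),
       assayedIds = assayedIds)
}

#' Prioritized microRNAs with their direction of change
#'
#' Applies the enrichment-analysis inclusion rule to a differential table:
#' absolute signed fold change at least `foldThreshold` (default 2) and
#' unadjusted `p <= pThreshold` (default 0.05). Each passing microRNA is
#' tagged with its direction (`"down"`/`"up"` in the A group).
#'
#' @param results a [differentialTable()] data.frame.
#' @param foldThreshold,pThreshold inclusion thresholds.
#' @return data.frame `mirna_id`, `direction`.
#' @export
prioritizedMemberSet <- function(results, foldThreshold = 2,
                                 pThreshold = 0.05) {
  keep <- abs(results$signed_fold) >= foldThreshold &
    results$p_value <= pThreshold
  data.frame(mirna_id = results$mirna_id[keep],
             direction = ifelse(results$signed_fold[keep] < 0, "down", "up"),
             stringsAsFactors = FALSE)
}

# direction vector over all assayed ids: "down"/"up" for prioritized ids,
# NA otherwise
.directionVector <- function(assayed, memberSet) {
  dir <- rep(NA_character_, length(assayed))
  names(dir) <- assayed
  dir[memberSet$mirna_id] <- memberSet$direction
  dir
}

#' Is a microRNA family congruently prioritized?
#'
#' A family counts as prioritized when at least `minCongruent` of its assayed
#' members are significantly deregulated in the same direction (the modal
#' direction among its prioritized members) and the odds ratio of that
#' congruent deregulation, comparing family members against all other
#' assayed microRNAs, exceeds `orThreshold` (default 3). The odds ratio is
#' the cross-product of the 2x2 table {in family vs other assayed} x
#' {prioritized in the modal direction vs not}, with a Haldane-Anscombe 0.5
#' correction when any cell is zero.
#'
#' @param memberIds assayed member ids of the family.
#' @param memberSet output of [prioritizedMemberSet()].
#' @param assayedIds all assayed ids on the card.
#' @param minCongruent minimum congruent significant members (default 3).
#' @param orThreshold odds-ratio cutoff (default 3).
#' @return List `prioritized` (logical), `oddsRatio`, `direction`,
#'   `nCongruent`.
#' @export
familyIsPrioritized <- function(memberIds, memberSet, assayedIds,
                                minCongruent = 3, orThreshold = 3) {
  dir <- .directionVector(assayedIds, memberSet)
  mdir <- dir[memberIds]
  nDown <- sum(mdir == "down", na.rm = TRUE)
  nUp <- sum(mdir == "up", na.rm = TRUE)
  modal <- if (nDown >= nUp) "down" else "up"
  k <- max(nDown, nUp)
  others <- setdiff(assayedIds, memberIds)
  cOut <- sum(dir[others] == modal, na.rm = TRUE)
  a <- k; b <- length(memberIds) - k
  cc <- cOut; d <- length(others) - cOut
  if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5
                               cc <- cc + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * cc)
  list(prioritized = k >= minCongruent && or > orThreshold,
       oddsRatio = or, direction = modal, nCongruent = k)
}

#' Is a -3p/-5p strand pair congruently prioritized?
#'
#' TRUE when both mature strands pass the fold/p inclusion rule with the
#' same direction of change.
#'
#' @param id3p,id5p the two strand ids.
#' @param memberSet output of [prioritizedMemberSet()].
#' @return Logical.
#' @export
pairIsPrioritized <- function(id3p, id5p, memberSet) {
  d3 <- memberSet$direction[match(id3p, memberSet$mirna_id)]
  d5 <- memberSet$direction[match(id5p, memberSet$mirna_id)]
  !is.na(d3) && !is.na(d5) && d3 == d5
}

# precomputed row-index maps so the permutation loop never touches names
.catalogIndex <- function(catalog, rowIds) {
  famIdx <- lapply(catalog$families, function(mem) {
    i <- match(mem, rowIds)
    if (anyNA(i)) stop("family member(s) absent from the matrix: ",
                       paste(mem[is.na(i)], collapse = ", "))
    i
  })
  pr <- catalog$pairs
  i3 <- match(pr$id_3p, rowIds); i5 <- match(pr$id_5p, rowIds)
  if (anyNA(i3) || anyNA(i5))
    stop("pair strand(s) absent from the matrix: ",
         paste(c(pr$id_3p[is.na(i3)], pr$id_5p[is.na(i5)]), collapse = ", "))
  list(famIdx = famIdx, i3 = i3, i5 = i5,
       nAssayed = length(catalog$assayedIds))
}

# count of prioritized families + pairs for one labelling; the unit statistic
# of the permutation test. The counting path is pure index arithmetic (it
# runs once per permutation); detail = TRUE additionally rebuilds the
# evidence through the reference functions familyIsPrioritized() /
# pairIsPrioritized().
countPrioritizedGroups <- function(m, idxA, idxB, catalog, minN = 3,
                                   foldThreshold = 2, pThreshold = 0.05,
                                   minCongruent = 3, orThreshold = 3,
                                   detail = FALSE, index = NULL) {
  if (is.null(index)) index <- .catalogIndex(catalog, rownames(m))
  tt <- rowTTest(m, idxA, idxB)
  keep <- tt$nA >= minN & tt$nB >= minN
  ddct <- tt$meanA - tt$meanB
  sig <- keep & tt$p <= pThreshold & abs(ddct) >= log2(foldThreshold)
  down <- sig & ddct > 0  # higher delta-Ct = lower expression in group A
  up <- sig & ddct < 0
  totD <- sum(down); totU <- sum(up)
  nCount <- 0L
  famHitIdx <- integer()
  for (j in seq_along(index$famIdx)) {
    idx <- index$famIdx[[j]]
    kD <- sum(down[idx]); kU <- sum(up[idx])
    k <- max(kD, kU)
    if (k < minCongruent) next
    tot <- if (kD >= kU) totD else totU
    mlen <- length(idx)
    a <- k; b <- mlen - k
    cc <- tot - k; d <- index$nAssayed - mlen - cc
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5
                                 cc <- cc + 0.5; d <- d + 0.5 }
    if ((a * d) / (b * cc) > orThreshold) {
      nCount <- nCount + 1L
      famHitIdx <- c(famHitIdx, j)
    }
  }
  pairHit <- (down[index$i3] & down[index$i5]) |
    (up[index$i3] & up[index$i5])
  nCount <- nCount + sum(pairHit)
  if (!detail) return(nCount)
  memberSet <- data.frame(mirna_id = rownames(m)[sig],
                          direction = ifelse(down[sig], "down", "up"),
                          stringsAsFactors = FALSE)
  famHits <- names(catalog$families)[famHitIdx]
  famOR <- vapply(famHits, function(fid)
    familyIsPrioritized(catalog$families[[fid]], memberSet,
                        catalog$assayedIds, minCongruent,
                        orThreshold)$oddsRatio, 0)
  list(count = nCount, families = famHits, familyOR = unname(famOR),
       pairs = catalog$pairs$stem[pairHit], memberSet = memberSet)
}

#' Permutation test for family / strand-pair co-expression enrichment
#'
#' The enrichment statistic counts how many microRNA families and -3p/-5p
#' strand pairs are congruently prioritized between the two phenotype groups
#' (see [familyIsPrioritized()], [pairIsPrioritized()]). Its null
#' distribution is built by label shuffling: each resampling draws
#' `nA + nB` samples without replacement from *all* samples in the matrix
#' (the full cohort, including any samples outside the two compared groups),
#' assigns `nA` and `nB` pseudo-labels, recomputes the entire differential
#' table and re-counts. The empirical p-value uses the add-one convention
#' `(1 + #(null >= observed)) / (1 + nPerm)`, so it is never exactly zero.
#'
#' @param x a normalized [CtSet-class] or numeric matrix (features x all
#'   samples).
#' @param labels per-sample labels over all columns; entries equal to
#'   `groupA`/`groupB` define the observed comparison, other samples
#'   participate only in the shuffled draws.
#' @param catalog a [familyCatalog()].
#' @param groupA,groupB the compared labels (defaults HRP vs LRP).
#' @param nPerm number of permutation resamplings (default 10000).
#' @param seed integer RNG seed.
#' @param minN,foldThreshold,pThreshold,minCongruent,orThreshold rule
#'   parameters, as in the component functions.
#' @return List of class `"enrichmentResult"`: `observed` (detail list with
#'   prioritized families/pairs), `observedCount`, `nullCounts`,
#'   `empiricalP`, `nPerm`, `seed`.
#' @export
familyPermutationTest <- function(x, labels, catalog, groupA = "HRP",
                                  groupB = "LRP", nPerm = 10000,
                                  seed = 1L, minN = 3, foldThreshold = 2,
                                  pThreshold = 0.05, minCongruent = 3,
                                  orThreshold = 3) {
  if (nPerm <= 0) stop("nPerm must be positive")
  if (is(x, "CtSet")) {
    m <- normValues(x)[assayedIds(x), , drop = FALSE]
  } else m <- x
  stopifnot(length(labels) == ncol(m))
  idxA <- which(labels == groupA)
  idxB <- which(labels == groupB)
  nA <- length(idxA); nB <- length(idxB)
  if (nA < minN || nB < minN)
    stop("groups too small for the t-test (need >= ", minN, " per group)")
  index <- .catalogIndex(catalog, rownames(m))
  obs <- countPrioritizedGroups(m, idxA, idxB, catalog, minN, foldThreshold,
                                pThreshold, minCongruent, orThreshold,
                                detail = TRUE, index = index)
  nAll <- ncol(m)
  nullCounts <- integer(nPerm)
  set.seed(seed)
  for (i in seq_len(nPerm)) {
    drawn <- sample.int(nAll, nA + nB)
    nullCounts[i] <- countPrioritizedGroups(
      m, drawn[seq_len(nA)], drawn[nA + seq_len(nB)], catalog, minN,
      foldThreshold, pThreshold, minCongruent, orThreshold, index = index)
  }
  empiricalP <- (1 + sum(nullCounts >= obs$count)) / (1 + nPerm)
  structure(list(observed = obs, observedCount = obs$count,
                 nullCounts = nullCounts, empiricalP = empiricalP,
                 nPerm = nPerm, seed = seed),
            class = "enrichmentResult")
}

#' @export
print.enrichmentResult <- function(x, ...) {
  cat("Family / -3p/-5p co-expression enrichment\n")
  cat("  prioritized families:",
      if (length(x$observed$families)) paste(x$observed$families, collapse = ", ")
      else "none", "\n")
  cat("  prioritized pairs:",
      if (length(x$observed$pairs)) paste(x$observed$pairs, collapse = ", ")
      else "none", "\n")
  cat("  observed count:", x$observedCount, "\n")
  cat(sprintf("  empirical p = %.4g (%d permutations, seed %d)\n",
              x$empiricalP, x$nPerm, x$seed))
  invisible(x)
}

#' Serialize an enrichment result
#'
#' Writes a TSV of prioritized groups (`group_id`, `type`, `member_ids`) and
#' a JSON with the observed count, null-count histogram, empirical p, seed
#' and permutation count.
#'
#' @param result a [familyPermutationTest()] result.
#' @param tsvPath,jsonPath output paths (`NULL` to skip either).
#' @export
writeEnrichmentResult <- function(result, tsvPath = NULL, jsonPath = NULL) {
  if (!is.null(tsvPath)) {
    fams <- result$observed$families
    prs <- result$observed$pairs
    df <- data.frame(
      group_id = c(fams, prs),
      type = c(rep("family", length(fams)), rep("pair", length(prs))))
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(jsonPath)) {
    hist <- table(result$nullCounts)
    jsonlite::write_json(list(
      observed_count = result$observedCount,
      empirical_p = result$empiricalP,
      n_perm = result$nPerm, seed = result$seed,
      null_histogram = list(count = as.integer(names(hist)),
                            n = as.integer(hist))),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
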