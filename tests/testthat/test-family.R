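writeToyMiFam <- function(lines) {
  path <- tempfile(fileext = ".dat")
  writeLines(lines, path)
  path
}

test_that("miFam-dialect parsing: species filter, malformed records", {
  path <- writeToyMiFam(c(
    "AC   MIPF0000001", "ID   mir-154",
    "MI   MI0000001  hsa-mir-154", "MI   MI0000002  hsa-mir-369",
    "MI   MI0000003  hsa-mir-655", "MI   MI0000004  hsa-mir-656",
    "MI   MI0000005  mmu-mir-154", "//"))
  fams <- parseMiFam(path)
  expect_equal(names(fams), "mir-154")
  expect_length(fams[["mir-154"]], 4)          # mouse member filtered out
  expect_length(parseMiFam(path, species = NULL)[["mir-154"]], 5)
  # missing terminator
  bad <- writeToyMiFam(c("AC   MIPF1", "ID   mir-1", "MI   MI1  hsa-mir-1"))
  expect_error(parseMiFam(bad), "terminator")
  # stray content
  bad2 <- writeToyMiFam(c("AC   MIPF1", "ID   mir-1", "XX junk", "//"))
  expect_error(parseMiFam(bad2), "line 3")
})

test_that("-3p/-5p pairs derive from matching stems only", {
  ids <- c("hsa-miR-127-3p", "hsa-miR-127-5p", "hsa-miR-205",
           "hsa-miR-485-3p", "hsa-miR-9-5p")
  pr <- derivePairs(ids)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$id_3p, "hsa-miR-127-3p")
  expect_equal(pr$id_5p, "hsa-miR-127-5p")
  expect_equal(nrow(derivePairs("hsa-miR-205")), 0)
  # the default synthetic card carries exactly 50 complete pairs
  cat <- syntheticCatalog()
  expect_equal(nrow(cat$pairs), 50)
  expect_length(cat$families, 15)  # and 15 evaluable families
})

test_that("families need >= 3 assayed members to be evaluable", {
  fams <- list("mir-a" = c("hsa-mir-10a", "hsa-mir-10b", "hsa-mir-10c"),
               "mir-b" = c("hsa-mir-20a", "hsa-mir-20b", "hsa-mir-20c"))
  assayed <- c("hsa-miR-10a", "hsa-miR-10b", "hsa-miR-10c",
               "hsa-miR-20a", "hsa-miR-20b")
  cat <- familyCatalog(fams, assayed)
  expect_equal(names(cat$families), "mir-a")   # mir-b has only 2 assayed
  # mature -3p/-5p ids match precursor member names on the stem
  cat2 <- familyCatalog(fams, c("hsa-miR-10a-3p", "hsa-miR-10b-5p",
                                "hsa-miR-10c", "other"))
  expect_length(cat2$families[["mir-a"]], 3)
})

test_that("inclusion rule for enrichment: |fold| >= 2 and p <= 0.05, with direction", {
  tab <- data.frame(
    mirna_id = c("miR-655", "miR-191", "miR-205", "miR-x"),
    signed_fold = c(-4.93, -1.41, 4.55, -2.5),
    p_value = c(0.0066, 0.0524, 0.0275, 0.2))
  ms <- prioritizedMemberSet(tab)
  expect_setequal(ms$mirna_id, c("miR-655", "miR-205"))
  expect_equal(ms$direction[ms$mirna_id == "miR-655"], "down")
  expect_equal(ms$direction[ms$mirna_id == "miR-205"], "up")
  expect_equal(nrow(prioritizedMemberSet(tab[0, ])), 0)
})

test_that("family prioritization needs 3 congruent members and OR > 3", {
  assayed <- c(paste0("fam", 1:5), paste0("bg", 1:95))
  down <- function(ids) data.frame(mirna_id = ids,
                                   direction = rep("down", length(ids)))
  # 3 of 5 members down, quiet background -> prioritized, large OR
  r <- familyIsPrioritized(paste0("fam", 1:5), down(paste0("fam", 1:3)),
                           assayed)
  expect_true(r$prioritized)
  expect_gt(r$oddsRatio, 3)
  expect_equal(r$nCongruent, 3)
  # only 2 members -> not prioritized
  r2 <- familyIsPrioritized(paste0("fam", 1:5), down(paste0("fam", 1:2)),
                            assayed)
  expect_false(r2$prioritized)
  # everything down-regulated -> no enrichment (Haldane-corrected OR small)
  r3 <- familyIsPrioritized(paste0("fam", 1:5), down(assayed), assayed)
  expect_false(r3$prioritized)
  expect_lt(r3$oddsRatio, 3)
  # brute-force 2x2 check of the odds ratio with a mixed background
  ev <- down(c(paste0("fam", 1:3), paste0("bg", 1:10)))
  r4 <- familyIsPrioritized(paste0("fam", 1:5), ev, assayed)
  a <- 3; b <- 2; cc <- 10; d <- 85
  expect_equal(r4$oddsRatio, (a * d) / (b * cc))
  # opposite directions break congruence
  ev5 <- data.frame(mirna_id = paste0("fam", 1:4),
                    direction = c("down", "down", "up", "up"))
  r5 <- familyIsPrioritized(paste0("fam", 1:5), ev5, assayed)
  expect_equal(r5$nCongruent, 2)
  expect_false(r5$prioritized)
})

test_that("pair prioritization requires both strands congruent", {
  ev <- data.frame(mirna_id = c("hsa-miR-485-3p", "hsa-miR-485-5p",
                                "hsa-miR-127-3p", "hsa-miR-127-5p",
                                "hsa-miR-9-3p"),
                   direction = c("down", "down", "down", "up", "down"))
  expect_true(pairIsPrioritized("hsa-miR-485-3p", "hsa-miR-485-5p", ev))
  expect_false(pairIsPrioritized("hsa-miR-127-3p", "hsa-miR-127-5p", ev))
  expect_false(pairIsPrioritized("hsa-miR-9-3p", "hsa-miR-9-5p", ev))
})

test_that("permutation counting matches the component-function route", {
  cat <- syntheticCatalog()
  co <- generateCohort(plantedFamilySpec(21))
  nc <- normalizedCohort(co)
  m <- normValues(nc$x)[cat$assayedIds, ]
  set.seed(77)
  for (i in 1:5) {
    d <- sample(ncol(m), 48); ia <- d[1:16]; ib <- d[17:48]
    fast <- oligomiR:::countPrioritizedGroups(m, ia, ib, cat)
    # independent route through the public per-group functions
    lab <- rep(NA_character_, ncol(m)); lab[ia] <- "HRP"; lab[ib] <- "LRP"
    tab <- differentialTable(m, lab)
    ms <- prioritizedMemberSet(tab)
    nFam <- sum(vapply(cat$families, function(mem)
      familyIsPrioritized(mem, ms, cat$assayedIds)$prioritized, NA))
    nPair <- sum(vapply(seq_len(nrow(cat$pairs)), function(j)
      pairIsPrioritized(cat$pairs$id_3p[j], cat$pairs$id_5p[j], ms), NA))
    expect_equal(fast, nFam + nPair)
  }
})

test_that("permutation test: reproducibility, p bounds, self-consistency", {
  cat <- syntheticCatalog()
  co <- generateCohort(plantedFamilySpec(31))
  nc <- normalizedCohort(co)
  r1 <- familyPermutationTest(nc$x, nc$labels, cat, nPerm = 200, seed = 5)
  r2 <- familyPermutationTest(nc$x, nc$labels, cat, nPerm = 200, seed = 5)
  expect_identical(r1$nullCounts, r2$nullCounts)
  expect_identical(r1$empiricalP, r2$empiricalP)
  expect_gte(r1$empiricalP, 1 / 201)
  expect_lte(r1$empiricalP, 1)
  # planted congruent family is seen
  expect_gte(r1$observedCount, 1)
  expect_true("mir-501" %in% r1$observed$families)
  # the true labelling pushed through the null machinery gives the observed
  m <- normValues(nc$x)[cat$assayedIds, ]
  ia <- which(nc$labels == "HRP"); ib <- which(nc$labels == "LRP")
  expect_equal(oligomiR:::countPrioritizedGroups(m, ia, ib, cat),
               r1$observedCount)
  expect_error(familyPermutationTest(nc$x, nc$labels, cat, nPerm = 0),
               "positive")
})

test_that("result is invariant to row and column permutations", {
  cat <- syntheticCatalog()
  co <- generateCohort(plantedFamilySpec(41))
  nc <- normalizedCohort(co)
  m <- normValues(nc$x)[cat$assayedIds, ]
  set.seed(8)
  ro <- sample(nrow(m)); colo <- sample(ncol(m))
  r1 <- familyPermutationTest(m, nc$labels, cat, nPerm = 10, seed = 2)
  r2 <- familyPermutationTest(m[ro, colo], nc$labels[colo], cat,
                              nPerm = 10, seed = 2)
  expect_equal(r2$observedCount, r1$observedCount)
  expect_setequal(r2$observed$families, r1$observed$families)
  expect_setequal(r2$observed$pairs, r1$observed$pairs)
})

test_that("tiny-instance Monte-Carlo null matches exhaustive label enumeration", {
  # 6 samples, groups of 2 and 2 drawn from all 6: compare the permutation
  # null distribution against complete enumeration of ordered draws
  set.seed(12)
  m <- matrix(rnorm(8 * 6, 0, 1), 8,
              dimnames = list(c(paste0("hsa-miR-10", letters[1:3]),
                                "hsa-miR-11-3p", "hsa-miR-11-5p",
                                paste0("x", 1:3)), paste0("s", 1:6)))
  m[1:5, 1:2] <- m[1:5, 1:2] + 4   # family + pair strongly shifted
  fams <- list("mir-10" = paste0("hsa-mir-10", letters[1:3]))
  cat <- familyCatalog(fams, rownames(m))
  cnt <- function(ia, ib) oligomiR:::countPrioritizedGroups(
    m, ia, ib, cat, minN = 2)
  # exhaustive: all ordered (A, B) splits of size 2+2 out of 6
  combos <- utils::combn(6, 2, simplify = FALSE)
  exact <- unlist(lapply(combos, function(ia) {
    rest <- setdiff(1:6, ia)
    vapply(utils::combn(rest, 2, simplify = FALSE),
           function(ib) cnt(ia, ib), 0L)
  }))
  # Monte-Carlo: label shuffles through the same statistic
  set.seed(99)
  mc <- vapply(1:400, function(i) {
    d <- sample(6, 4); cnt(d[1:2], d[3:4])
  }, 0L)
  pExact <- mean(exact >= 1)
  pMC <- mean(mc >= 1)
  expect_lt(abs(pExact - pMC), 0.08)  # binomial error at 400 draws
  expect_true(all(unique(mc) %in% unique(exact)))
})
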