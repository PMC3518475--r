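test_that("entry flagging follows the 10/37 rules and leaves values intact", {
  ct <- matrix(c(9.5, 37.5, 25, NA), 4, 1,
               dimnames = list(c("a", "b", "c", "RNU-44"), "s1"))
  ct <- rbind(ct, "RNU-48" = 20)
  x <- flagEntries(CtSet(ct))
  fl <- ctFlags(x)
  expect_equal(unname(fl[c("a", "b", "c"), 1]),
               c("Unreliable", "Undetermined", "OK"))
  expect_equal(unname(fl["RNU-44", 1]), "Undetermined")  # missing entry
  expect_identical(ctValues(x), ct)                      # values untouched
})

test_that("detectable counts apply the Ct<38 rule and skip controls", {
  n <- 376
  ct <- matrix(25, n + 2, 2,
               dimnames = list(c(sprintf("m%03d", 1:n), "RNU-44", "RNU-48"),
                               c("s1", "s2")))
  ct[1:176, 2] <- 39              # above threshold
  ct[177:200, 2] <- NA            # missing
  x <- CtSet(ct)
  expect_equal(unname(countDetectable(x)), c(376L, 176L))
  expect_equal(unname(countDetectable(x, "s2")), 176L)
  expect_error(countDetectable(x, "nope"), "unknown sample")
  # all-missing column counts zero
  ct[, 1] <- NA
  expect_equal(unname(countDetectable(CtSet(ct), "s1")), 0L)
})

test_that("sample QC drops exactly the low-detectable samples, untouched otherwise", {
  co <- generateCohort(cohortSpec())
  x <- cohortCt(co)
  # plant two low-quality samples by blanking most of their wells
  ct <- ctValues(x)
  bad <- c("P002", "P010")
  ct[seq_len(nrow(ct) - 150), bad] <- NA
  ct[c("RNU-44", "RNU-48"), bad] <- 20   # keep controls alive
  y <- CtSet(ct)
  res <- applySampleQC(y, minDetectable = 230)
  expect_setequal(res$excluded$sample_id, bad)
  expect_true(all(res$excluded$detectable < 230))
  expect_identical(ctValues(res$ctset),
                   ct[, setdiff(colnames(ct), bad)])   # pure subset
  # no sample below threshold -> identity; threshold 0 -> identity
  expect_equal(ncol(applySampleQC(x, 230)$ctset), ncol(x))
  expect_equal(ncol(applySampleQC(y, 0)$ctset), ncol(y))
  # everything excluded -> explicit error
  expect_error(applySampleQC(y, 1e6), "all .* samples")
})

test_that("delta-Ct normalization centers controls and ignores sample-wide shifts", {
  x <- tinyCtSet()
  n <- deltaCtNormalize(x)
  dct <- normValues(n)
  # Ct 30 against controls 25/27 -> deltaCt 4
  expect_equal(unname(dct["hsa-miR-1", "s1"]), 4)
  # control rows average zero per sample
  expect_equal(unname(colMeans(dct[c("RNU-44", "RNU-48"), ])), rep(0, 4))
  expect_equal(normMethod(n), "deltaCt")
  # shift invariance: +2 cycles on one whole sample is a no-op
  ct2 <- ctValues(x); ct2[, "s2"] <- ct2[, "s2"] + 2
  dct2 <- normValues(deltaCtNormalize(CtSet(ct2)))
  expect_equal(dct2, dct)
  # missing control -> error naming the sample
  ct3 <- ctValues(x); ct3["RNU-44", "s3"] <- NA
  expect_error(deltaCtNormalize(CtSet(ct3)), "s3")
})

test_that("control CV gate passes at <=5% and names failures", {
  ct <- rbind("m1" = c(30, 31, 29, 30),
              "RNU-44" = c(20, 20, 20, 20),
              "RNU-48" = c(20, 22, 18, 24))
  colnames(ct) <- paste0("s", 1:4)
  cv <- controlCV(CtSet(ct))
  expect_equal(cv$cv_percent[cv$control_id == "RNU-44"], 0)
  expect_true(cv$pass[cv$control_id == "RNU-44"])
  expect_false(cv$pass[cv$control_id == "RNU-48"])  # sd/mean > 5%
  expect_false(attr(cv, "qc_pass"))
  # generator controls pass by construction
  co <- generateCohort(cohortSpec())
  expect_true(attr(controlCV(cohortCt(co)), "qc_pass"))
})

test_that("quantile normalization equals the rank-mean table and shares one multiset", {
  ct <- matrix(c(15, 12, 13, 14, 11, 16, 19, 17, 18), 3,
               dimnames = list(c("m1", "m2", "RNU-44"), paste0("s", 1:3)))
  x <- quantileNormalize(CtSet(ct, controlIds = "RNU-44"))
  # hand-computed rank means: sorted columns (12,13,15),(11,14,16),(17,18,19)
  expected <- matrix(c(50/3, 40/3, 15, 15, 40/3, 50/3, 50/3, 40/3, 15), 3,
                     dimnames = dimnames(ct))
  expect_equal(normValues(x), expected)
  expect_equal(normMethod(x), "quantile")
  # columns that are permutations of one another become identical
  ct2 <- matrix(c(11, 15, 19, 19, 11, 15), 3,
                dimnames = list(c("m1", "m2", "RNU-44"), c("a", "b")))
  q2 <- normValues(quantileNormalize(CtSet(ct2, controlIds = "RNU-44")))
  expect_equal(unname(sort(q2[, 1])), unname(sort(q2[, 2])))
  # identical columns unchanged
  ct3 <- matrix(rep(c(12, 20, 30), 2), 3,
                dimnames = list(c("m1", "m2", "RNU-44"), c("a", "b")))
  expect_equal(normValues(quantileNormalize(CtSet(ct3, controlIds = "RNU-44"))),
               ct3)
  expect_error(quantileNormalize(CtSet(ct3[, 1, drop = FALSE],
                                       controlIds = "RNU-44")),
               "at least 2")
})

test_that("quantile-normalized complete columns share one value multiset", {
  set.seed(42)
  ct <- matrix(runif(50 * 8, 15, 35), 50, 8,
               dimnames = list(c(sprintf("m%02d", 1:48), "RNU-44", "RNU-48"),
                               sprintf("s%d", 1:8)))
  q <- normValues(quantileNormalize(CtSet(ct)))
  ref <- unname(sort(q[, 1]))
  for (j in 2:8) expect_equal(unname(sort(q[, j])), ref)
})

test_that("Ct TSV round-trips losslessly including missing wells", {
  co <- generateCohort(cohortSpec(seed = 3))
  x <- cohortCt(co)
  path <- tempfile(fileext = ".tsv")
  writeCtMatrix(x, path)
  y <- readCtMatrix(path)
  expect_equal(ctValues(y), ctValues(x), tolerance = 1e-12)
  expect_identical(is.na(ctValues(y)), is.na(ctValues(x)))
  # duplicated ids rejected on read
  tab <- readLines(path)
  writeLines(c(tab, tab[2]), path)
  expect_error(readCtMatrix(path), "duplicated")
})
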