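test_that("two planted expression blocks separate perfectly", {
  set.seed(1)
  profile <- rnorm(30)                 # one shared feature profile
  m <- matrix(profile, 30, 10,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%d", 1:10)))
  m[1:15, 1:5] <- m[1:15, 1:5] + 10    # block structure for samples 1-5
  m <- m + matrix(rnorm(300, 0, 0.01), 30, 10)  # break exact ties only
  part <- clusterSamples(m)
  groups <- list(sort(part$left), sort(part$right))
  expect_true(identical(groups[[1]], paste0("s", 1:5)) ||
                identical(groups[[2]], paste0("s", 1:5)))
  expect_length(c(part$left, part$right), 10)
})

test_that("duplicated samples sit at distance zero and merge first", {
  set.seed(2)
  m <- matrix(rnorm(20 * 4), 20,
              dimnames = list(sprintf("f%02d", 1:20), c("a", "b", "c", "d")))
  m[, "b"] <- m[, "a"]
  part <- clusterSamples(m)
  dm <- as.matrix(part$dist)
  expect_equal(dm["a", "b"], 0, tolerance = 1e-12)
  # first merge joins the duplicated pair (two singleton leaves)
  first <- part$hclust$merge[1, ]
  expect_setequal(part$hclust$labels[-first], c("a", "b"))
})

test_that("average-linkage merge order matches a hand-traced toy example", {
  # 4 samples over 4 features; correlations traced by hand via cor()
  m <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 5,
                4, 3, 2, 1,
                1, 3, 2, 4), 4,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
  part <- clusterSamples(m)
  hc <- part$hclust
  d <- as.matrix(1 - cor(m))
  # closest pair: s1-s2 (r ~ 0.982); they merge first
  expect_setequal(hc$labels[-hc$merge[1, ]], c("s1", "s2"))
  expect_equal(hc$height[1], d["s1", "s2"], tolerance = 1e-12)
  # next, s4 joins {s1,s2} at the average of its two distances
  expect_equal(hc$height[2], mean(d["s4", c("s1", "s2")]), tolerance = 1e-12)
  # root merges s3 against the other three at the average distance
  expect_equal(hc$height[3], mean(d["s3", c("s1", "s2", "s4")]),
               tolerance = 1e-12)
  expect_setequal(part$left, c("s1", "s2", "s4"))
  expect_setequal(part$right, "s3")
  # merge heights non-decreasing
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("feature subsetting and degenerate inputs are handled", {
  set.seed(3)
  m <- matrix(rnorm(40 * 6), 40,
              dimnames = list(sprintf("f%02d", 1:40), sprintf("s%d", 1:6)))
  p <- clusterSamples(m, featureSubset = sprintf("f%02d", 1:20))
  expect_length(c(p$left, p$right), 6)
  expect_error(clusterSamples(m, featureSubset = "nope"), "not in matrix")
  expect_error(clusterSamples(m[, 1, drop = FALSE]), "at least 2")
  # too little pairwise overlap is a named error
  m2 <- m
  m2[1:37, 1] <- NA
  m2[4:40, 2] <- NA
  expect_error(clusterSamples(m2), "fewer than 3 complete features")
})

test_that("branch phenotype enrichment reproduces printed contingency statistics", {
  # discovery clustering: 13/16 HRP left, 20/32 LRP right
  t1 <- matrix(c(13, 12, 3, 20), 2, byrow = TRUE)
  r1 <- contingencyStats(t1)
  expect_equal(r1$oddsRatio, 7.22, tolerance = 5e-4)
  expect_equal(r1$p, 0.006, tolerance = 0.02)
  # validation clustering: 8/10 LRP left, 9/14 HRP right
  r2 <- contingencyStats(matrix(c(8, 5, 2, 9), 2, byrow = TRUE))
  expect_equal(r2$oddsRatio, 7.2, tolerance = 1e-12)
  expect_equal(r2$p, 0.047, tolerance = 0.02)
  # no association
  r3 <- contingencyStats(matrix(c(1, 1, 1, 1), 2))
  expect_equal(r3$oddsRatio, 1)
  expect_equal(r3$p, 1)
})

test_that("branchEnrichment builds the table from a labelled partition", {
  part <- list(left = paste0("s", 1:10), right = paste0("s", 11:20))
  labels <- setNames(rep(c("HRP", "LRP", "HRP", "LRP"), c(8, 2, 5, 5)),
                     paste0("s", 1:20))
  r <- branchEnrichment(part, labels, positive = "HRP")
  expect_equal(as.vector(r$table), c(8, 5, 2, 5))
  # swapping branches inverts the odds ratio, p unchanged
  r2 <- branchEnrichment(list(left = part$right, right = part$left),
                         labels, positive = "HRP")
  expect_equal(r2$oddsRatio, 1 / r$oddsRatio, tolerance = 1e-12)
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  expect_error(branchEnrichment(part, labels[1:12]), "without phenotype")
})

test_that("Fisher exact two-tailed agrees with enumeration and fisher.test (n <= 20)", {
  worstOracle <- 0; worstRef <- 0; nTables <- 0
  for (n in 2:20) {
    for (r1 in 1:(n - 1)) {
      for (c1 in 1:(n - 1)) {
        lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
        for (a in lo:hi) {
          tbl <- matrix(c(a, r1 - a, c1 - a, n - r1 - c1 + a), 2,
                        byrow = TRUE)
          p <- fisherExactTwoTailed(tbl)
          worstOracle <- max(worstOracle, abs(p - fisherEnumOracle(tbl)))
          worstRef <- max(worstRef, abs(p - fisher.test(tbl)$p.value))
          nTables <- nTables + 1
        }
      }
    }
  }
  expect_gt(nTables, 8000)        # the sweep really covered the lattice
  expect_lt(worstOracle, 1e-12)
  expect_lt(worstRef, 1e-9)
})

test_that("degenerate and extreme tables behave per the exact-test definition", {
  # fully concordant 5/5 split: p = 2 * C(5,5)C(5,0)/C(10,5)
  tbl <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(fisherExactTwoTailed(tbl), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_error(fisherExactTwoTailed(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
  expect_error(fisherExactTwoTailed(matrix(c(1.5, 1, 1, 1), 2)),
               "integers")
})

test_that("distance matrix is a valid 1-Pearson dissimilarity", {
  set.seed(4)
  m <- matrix(rnorm(25 * 8), 25,
              dimnames = list(sprintf("f%02d", 1:25), sprintf("s%d", 1:8)))
  part <- clusterSamples(m)
  dm <- as.matrix(part$dist)
  expect_equal(dm, t(dm), tolerance = 1e-12)
  expect_true(all(dm >= 0 - 1e-12 & dm <= 2 + 1e-12))
  expect_equal(unname(diag(dm)), rep(0, 8))
})

test_that("enrichment p on label-permuted nulls is roughly uniform", {
  set.seed(5)
  ps <- replicate(60, {
    m <- matrix(rnorm(30 * 12), 30,
                dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:12)))
    part <- clusterSamples(m)
    labels <- setNames(sample(rep(c("A", "B"), 6)), colnames(m))
    tryCatch(branchEnrichment(part, labels, positive = "A")$p,
             error = function(e) NA_real_)
  })
  ps <- ps[!is.na(ps)]
  # conservative discrete test: small p's are not produced in excess
  expect_lt(mean(ps <= 0.05), 0.12)
  expect_gt(mean(ps > 0.3), 0.5)
})

test_that("proportion intervals: boundary cases and printed-example coverage", {
  ci <- proportionCI(13, 16)
  expect_equal(ci$estimate, 13 / 16)
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  # Clopper-Pearson 90% bounds for 13/16 (documented against the printed
  # 56%-93%; the lower bound differs by ~2 points, see vignette)
  expect_equal(ci$lower, qbeta(0.05, 13, 4), tolerance = 1e-12)
  expect_equal(ci$upper, qbeta(0.95, 14, 3), tolerance = 1e-12)
  expect_equal(proportionCI(5, 5)$upper, 1)
  expect_equal(proportionCI(0, 7)$lower, 0)
  jf <- proportionCI(13, 16, method = "jeffreys")
  expect_true(jf$lower > 0 && jf$upper < 1)
  expect_error(proportionCI(3, 0), "positive")
  expect_error(proportionCI(8, 5), "successes")
})
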