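#' Hierarchical clustering of samples with a two-branch cut
#'
#' Unsupervised clustering of samples by average-linkage agglomeration on
#' the 1 - Pearson correlation distance, computed across features on
#' pairwise-complete entries (minimum overlap of 3 shared features per
#' sample pair). Zero-variance features are dropped before distances are
#' computed. The reported partition is the pair of subtrees under the final
#' merge (the dendrogram's two main branches).
#'
#' @param x a normalized [CtSet-class] or numeric matrix (features x
#'   samples).
#' @param featureSubset optional feature ids to cluster on (e.g. a
#'   prioritized list); default all features.
#' @return List of class `"dendrogramPartition"`: `left`/`right` (sample id
#'   sets, left = branch containing the first sample), `hclust` (the merge
#'   record), `dist` (the distance matrix).
#' @export
clusterSamples <- function(x, featureSubset = NULL) {
  if (is(x, "CtSet")) m <- normValues(x) else m <- x
  if (!is.null(featureSubset)) {
    missing <- setdiff(featureSubset, rownames(m))
    if (length(missing))
      stop("feature(s) not in matrix: ", paste(missing, collapse = ", "))
    m <- m[featureSubset, , drop = FALSE]
  }
  if (ncol(m) < 2L) stop("need at least 2 samples to cluster")
  v <- apply(m, 1L, stats::var, na.rm = TRUE)
  m <- m[!is.na(v) & v > 0, , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 informative features after filtering")
  overlap <- crossprod(!is.na(m))
  if (any(overlap < 3L)) {
    bad <- which(overlap < 3L, arr.ind = TRUE)[1L, ]
    stop("samples '", colnames(m)[bad[1L]], "' and '", colnames(m)[bad[2L]],
         "' share fewer than 3 complete features")
  }
  cors <- stats::cor(m, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = "average")
  cut <- stats::cutree(hc, k = 2L)
  left <- names(cut)[cut == cut[1L]]
  right <- names(cut)[cut != cut[1L]]
  structure(list(left = left, right = right, hclust = hc, dist = d),
            class = "dendrogramPartition")
}

#' @export
print.dendrogramPartition <- function(x, ...) {
  cat("Dendrogram partition (average linkage, 1 - Pearson):\n")
  cat("  left branch: ", length(x$left), "samples\n")
  cat("  right branch:", length(x$right), "samples\n")
  invisible(x)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact conditional test: with margins fixed, sums the hypergeometric
#' probabilities of every table whose point probability does not exceed
#' that of the observed table (the point-probability two-sided rule).
#'
#' @param tbl 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return The two-sided p-value.
#' @examples
#' fisherExactTwoTailed(matrix(c(8, 2, 5, 9), 2)) # 0.047
#' @export
fisherExactTwoTailed <- function(tbl) {
  stopifnot(is.matrix(tbl), all(dim(tbl) == 2L))
  if (any(tbl < 0) || any(tbl != round(tbl)))
    stop("counts must be non-negative integers")
  r1 <- sum(tbl[1L, ]); r2 <- sum(tbl[2L, ])
  c1 <- sum(tbl[, 1L]); n <- sum(tbl)
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tbl[, 2L]) == 0)
    stop("all margins of the 2x2 table must be positive")
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  pObs <- stats::dhyper(tbl[1L, 1L], r1, r2, c1)
  # tolerance guards ties between equal point probabilities computed in fp
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' Phenotype enrichment in dendrogram branches
#'
#' Builds the 2x2 branch-by-phenotype contingency table for a two-branch
#' partition, and reports the uncorrected cross-product odds ratio
#' `(a*d)/(b*c)` (`Inf` when `b*c = 0` with `a*d > 0`) together with the
#' exact two-sided Fisher p-value.
#'
#' @param partition a [clusterSamples()] result (or any list with `left` and
#'   `right` sample id vectors).
#' @param labels named per-sample labels covering every clustered sample.
#' @param positive the label treated as the positive phenotype; defaults to
#'   the first level encountered.
#' @return List of class `"contingencyTest"`: `table` (2x2: rows
#'   left/right branch, columns positive/other), `oddsRatio`, `p`.
#' @export
branchEnrichment <- function(partition, labels, positive = NULL) {
  samples <- c(partition$left, partition$right)
  unlabeled <- samples[!(samples %in% names(labels)) |
                         is.na(labels[samples])]
  if (length(unlabeled))
    stop("clustered sample(s) without phenotype label: ",
         paste(unlabeled, collapse = ", "))
  lab <- labels[samples]
  if (is.null(positive)) positive <- lab[1L]
  pos <- lab == positive
  branch <- rep(c("left", "right"),
                c(length(partition$left), length(partition$right)))
  tbl <- matrix(c(sum(pos & branch == "left"), sum(!pos & branch == "left"),
                  sum(pos & branch == "right"), sum(!pos & branch == "right")),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("left", "right"),
                                c(positive, paste0("not_", positive))))
  if (any(rowSums(tbl) == 0))
    stop("a branch contains no labelled samples")
  contingencyStats(tbl)
}

#' Odds ratio and exact p for a 2x2 contingency table
#'
#' @param tbl 2x2 count matrix `(a, b; c, d)`.
#' @return List of class `"contingencyTest"`: `table`, `oddsRatio`
#'   (`a*d/(b*c)`, uncorrected), `p` (two-sided Fisher exact).
#' @export
contingencyStats <- function(tbl) {
  a <- tbl[1L, 1L]; b <- tbl[1L, 2L]; cc <- tbl[2L, 1L]; d <- tbl[2L, 2L]
  or <- if (b * cc == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * cc)
  structure(list(table = tbl, oddsRatio = or, p = fisherExactTwoTailed(tbl)),
            class = "contingencyTest")
}

#' @export
print.contingencyTest <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio = %.3g, two-tailed Fisher exact p = %.3g\n",
              x$oddsRatio, x$p))
  invisible(x)
}

#' F-distribution (Clopper-Pearson) confidence interval for a proportion
#'
#' Central 90% interval (5% to 95% bounds by default) of a binomial
#' proportion from the F-distribution representation of the Clopper-Pearson
#' exact bounds, equivalently beta quantiles. A Bayesian variant with a
#' Jeffreys Beta(1/2, 1/2) prior is available via `method = "jeffreys"`.
#'
#' @param successes,trials counts, `0 <= successes <= trials`, `trials > 0`.
#' @param level central coverage (default 0.90 for 5%-95% bounds).
#' @param method `"clopper-pearson"` (default) or `"jeffreys"`.
#' @return List `estimate`, `lower`, `upper`, `method`.
#' @export
proportionCI <- function(successes, trials, level = 0.90,
                         method = c("clopper-pearson", "jeffreys")) {
  method <- match.arg(method)
  if (trials <= 0) stop("trials must be positive")
  if (successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]")
  alpha <- (1 - level) / 2
  s <- successes; n <- trials
  if (method == "clopper-pearson") {
    lower <- if (s == 0) 0 else stats::qbeta(alpha, s, n - s + 1)
    upper <- if (s == n) 1 else stats::qbeta(1 - alpha, s + 1, n - s)
  } else {
    lower <- if (s == 0) 0 else stats::qbeta(alpha, s + 0.5, n - s + 0.5)
    upper <- if (s == n) 1 else stats::qbeta(1 - alpha, s + 0.5, n - s + 0.5)
  }
  list(estimate = s / n, lower = lower, upper = upper, method = method)
}

#' Export a sample dendrogram as Newick
#'
#' @param partition a [clusterSamples()] result.
#' @param path output path.
#' @export
writeNewick <- function(partition, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the 'ape' package")
  ape::write.tree(ape::as.phylo(partition$hclust), file = path)
  invisible(path)
}

#' Serialize clustering outputs
#'
#' Writes the linkage table (merge indices, height, cluster size) and the
#' branch assignment TSV.
#'
#' @param partition a [clusterSamples()] result.
#' @param linkagePath,branchPath output paths (`NULL` to skip).
#' @export
writePartition <- function(partition, linkagePath = NULL, branchPath = NULL) {
  hc <- partition$hclust
  if (!is.null(linkagePath)) {
    size <- integer(nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
      sz <- function(j) if (j < 0) 1L else size[j]
      size[i] <- sz(hc$merge[i, 1L]) + sz(hc$merge[i, 2L])
    }
    utils::write.table(
      data.frame(merge_i = hc$merge[, 1L], merge_j = hc$merge[, 2L],
                 height = hc$height, size = size),
      linkagePath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(branchPath)) {
    utils::write.table(
      data.frame(sample_id = c(partition$left, partition$right),
                 branch = rep(c("left", "right"),
                              c(length(partition$left),
                                length(partition$right)))),
      branchPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(partition)
}
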