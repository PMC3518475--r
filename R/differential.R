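#' Row-wise two-sample t statistics (pooled or Welch)
#'
#' Vectorized two-tailed two-sample t-tests across the rows of a matrix,
#' missing values removed per row. Written as a tight matrix computation
#' because the permutation enrichment statistic re-runs it thousands of
#' times. Degenerate rows (zero pooled variance) get p = 1 when the group
#' means agree and p = 0 otherwise.
#'
#' @param m numeric matrix (features x samples).
#' @param idxA,idxB column indices of the two groups.
#' @param var.equal pooled-variance Student's t (default) or Welch.
#' @return List of vectors `meanA`, `meanB`, `nA`, `nB`, `t`, `df`, `p`.
#' @keywords internal
rowTTest <- function(m, idxA, idxB, var.equal = TRUE) {
  a <- m[, idxA, drop = FALSE]
  b <- m[, idxB, drop = FALSE]
  okA <- !is.na(a); okB <- !is.na(b)
  nA <- rowSums(okA); nB <- rowSums(okB)
  a0 <- a; a0[!okA] <- 0
  b0 <- b; b0[!okB] <- 0
  sA <- rowSums(a0); sB <- rowSums(b0)
  mA <- sA / nA; mB <- sB / nB
  ssA <- rowSums(a0 * a0) - sA^2 / nA
  ssB <- rowSums(b0 * b0) - sB^2 / nB
  ssA <- pmax(ssA, 0); ssB <- pmax(ssB, 0)  # guard fp cancellation
  if (var.equal) {
    df <- nA + nB - 2
    sp2 <- (ssA + ssB) / df
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
  } else {
    vA <- ssA / (nA - 1) / nA
    vB <- ssB / (nB - 1) / nB
    se <- sqrt(vA + vB)
    df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
  }
  diff <- mA - mB
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: zero pooled spread up to fp rounding of constant input
  tol <- 1e-9 * pmax(abs(mA), abs(mB), 1)
  deg <- is.finite(se) & se <= tol
  zero <- deg & abs(diff) <= tol
  t[zero] <- 0; p[zero] <- 1; diff[zero] <- 0
  mB[zero] <- mA[zero]  # report identical means for constant-diff rows
  t[deg & !zero] <- sign(diff[deg & !zero]) * Inf
  p[deg & !zero] <- 0
  list(meanA = mA, meanB = mB, nA = nA, nB = nB, t = t, df = df, p = p)
}

# signed fold change from a delta-delta-Ct (cycles):
# fold = 2^(-ddct) when >= 1, else -2^(+ddct); never in (-1, 1)
signedFold <- function(ddct) ifelse(ddct <= 0, 2^(-ddct), -(2^ddct))

#' Differential microRNA table between two phenotype groups
#'
#' For every microRNA with at least `minN` non-missing normalized values in
#' each group, computes group mean delta-Ct values, the delta-delta-Ct
#' `ddct = mean(group A) - mean(group B)` (A is the HRP-like group), the
#' signed fold change `2^(-ddct)` reported with sign (negative =
#' down-regulated in A; since higher delta-Ct means lower expression, a
#' positive ddct gives a negative fold), and the unadjusted two-tailed
#' t-test p-value. A Benjamini-Hochberg column is appended for information
#' only; prioritization uses unadjusted p-values.
#'
#' @param x a normalized [CtSet-class] (see [deltaCtNormalize()]) or a
#'   numeric matrix of normalized values.
#' @param labels per-sample group labels (length = samples); samples with
#'   labels outside `groupA`/`groupB` are ignored.
#' @param groupA,groupB the two group labels; A is reported against B.
#' @param minN minimum non-missing observations per group per microRNA.
#' @param var.equal pooled-variance Student's t (default) or Welch.
#' @param excludeControls drop endogenous-control rows (CtSet input only).
#' @return data.frame with `mirna_id`, `mean_dct_a`, `mean_dct_b`, `ddct`,
#'   `signed_fold`, `p_value`, `bh_fdr`, `n_a`, `n_b`. Skipped microRNAs
#'   (too few observations) are listed in `attr(, "skipped")`.
#' @export
differentialTable <- function(x, labels, groupA = "HRP", groupB = "LRP",
                              minN = 3, var.equal = TRUE,
                              excludeControls = TRUE) {
  if (is(x, "CtSet")) {
    m <- normValues(x)
    if (excludeControls) m <- m[assayedIds(x), , drop = FALSE]
  } else m <- x
  stopifnot(length(labels) == ncol(m))
  idxA <- which(labels == groupA)
  idxB <- which(labels == groupB)
  if (!length(idxA) || !length(idxB))
    stop("both groups must be present among the labels")
  tt <- rowTTest(m, idxA, idxB, var.equal = var.equal)
  keep <- tt$nA >= minN & tt$nB >= minN
  skipped <- rownames(m)[!keep]
  ddct <- (tt$meanA - tt$meanB)[keep]
  out <- data.frame(
    mirna_id = rownames(m)[keep],
    mean_dct_a = unname(tt$meanA[keep]),
    mean_dct_b = unname(tt$meanB[keep]),
    ddct = unname(ddct),
    signed_fold = unname(signedFold(ddct)),
    p_value = unname(tt$p[keep]),
    n_a = unname(tt$nA[keep]),
    n_b = unname(tt$nB[keep]),
    stringsAsFactors = FALSE
  )
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "skipped") <- skipped
  out
}

#' Prioritize differentially expressed microRNAs
#'
#' Filters a [differentialTable()] to unadjusted `p <= pThreshold` (and
#' `|signed fold| >= foldThreshold` when given) and orders it most
#' down-regulated first (ascending signed fold, ties broken by microRNA id).
#'
#' @param results a [differentialTable()] data.frame.
#' @param pThreshold unadjusted p-value cutoff (default 0.05).
#' @param foldThreshold optional minimum absolute signed fold change.
#' @return The prioritized, ordered subset.
#' @export
prioritize <- function(results, pThreshold = 0.05, foldThreshold = NULL) {
  if (!nrow(results)) stop("empty differential table")
  keep <- results$p_value <= pThreshold
  if (!is.null(foldThreshold))
    keep <- keep & abs(results$signed_fold) >= foldThreshold
  out <- results[keep, , drop = FALSE]
  out[order(out$signed_fold, out$mirna_id), , drop = FALSE]
}

#' Serialize a differential table
#'
#' Writes the prioritized-microRNA TSV (`mirna_id`, `fold_change`,
#' `p_value`, `n_a`, `n_b`, `bh_fdr`).
#'
#' @param results a [differentialTable()] data.frame.
#' @param path output TSV path.
#' @export
writeDifferentialTable <- function(results, path) {
  df <- data.frame(mirna_id = results$mirna_id,
                   fold_change = results$signed_fold,
                   p_value = results$p_value,
                   n_a = results$n_a, n_b = results$n_b,
                   bh_fdr = results$bh_fdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
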