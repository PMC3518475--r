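#' Accessors for CtSet objects
#'
#' `ctValues()` returns the raw Ct matrix, `ctFlags()` the per-entry flag
#' matrix (or `NULL` before [flagEntries()] is applied), `controlIds()` the
#' endogenous-control row names, `normValues()` the normalized matrix and
#' `normMethod()` the normalization method (`"none"` until normalized).
#'
#' @param x a [CtSet-class].
#' @param ... ignored.
#' @return Matrices / character vectors as described.
#' @name ctAccessors
NULL

#' @rdname ctAccessors
#' @export
setMethod("ctValues", "CtSet", function(x, ...) assay(x, "ct"))

#' @rdname ctAccessors
#' @export
setMethod("ctFlags", "CtSet", function(x, ...) {
  if ("flag" %in% assayNames(x)) assay(x, "flag") else NULL
})

#' @rdname ctAccessors
#' @export
setMethod("controlIds", "CtSet", function(x) metadata(x)$controlIds)

#' @rdname ctAccessors
#' @export
setMethod("normValues", "CtSet", function(x) {
  if (!("norm" %in% assayNames(x)))
    stop("object has not been normalized; see deltaCtNormalize()/quantileNormalize()")
  assay(x, "norm")
})

#' @rdname ctAccessors
#' @export
setMethod("normMethod", "CtSet", function(x) x@normMethod)

assayedIds <- function(x) setdiff(rownames(x), controlIds(x))

#' Flag Ct entries as OK / Unreliable / Undetermined
#'
#' Applies the per-well flagging rules used for TaqMan array QC: entries with
#' Ct below `unreliableBelow` (default 10 cycles) are flagged `"Unreliable"`,
#' entries missing or above `undeterminedAbove` (default 37) are
#' `"Undetermined"`, everything else `"OK"`. Ct values themselves are never
#' altered.
#'
#' @param x a [CtSet-class].
#' @param unreliableBelow Ct below which a well is unreliable (cycles).
#' @param undeterminedAbove Ct above which a well is undetermined (cycles).
#' @param ... ignored.
#' @return The `CtSet` with its `flag` assay set.
#' @export
setMethod("flagEntries", "CtSet",
  function(x, unreliableBelow = 10, undeterminedAbove = 37, ...) {
    ct <- ctValues(x)
    fl <- matrix("OK", nrow(ct), ncol(ct), dimnames = dimnames(ct))
    fl[!is.na(ct) & ct < unreliableBelow] <- "Unreliable"
    fl[is.na(ct) | ct > undeterminedAbove] <- "Undetermined"
    assay(x, "flag", withDimnames = FALSE) <- fl
    validObject(x)
    x
  })

#' Count detectable microRNAs per sample
#'
#' A microRNA is detectable in a sample when its Ct is non-missing and below
#' `thresholdCt` (default Ct < 38). Endogenous-control rows are excluded:
#' detectable counts describe the assayed microRNAs only.
#'
#' @param x a [CtSet-class].
#' @param sample sample id(s) to count; default all samples.
#' @param thresholdCt detectability cutoff in cycles.
#' @param ... ignored.
#' @return Named integer vector of detectable counts.
#' @export
setMethod("countDetectable", "CtSet",
  function(x, sample = NULL, thresholdCt = 38, ...) {
    if (is.null(sample)) sample <- colnames(x)
    unknown <- setdiff(sample, colnames(x))
    if (length(unknown))
      stop("unknown sample(s): ", paste(unknown, collapse = ", "))
    ct <- ctValues(x)[assayedIds(x), sample, drop = FALSE]
    counts <- colSums(!is.na(ct) & ct < thresholdCt)
    as.integer(counts) |> stats::setNames(sample)
  })

#' Exclude samples with too few detectable microRNAs
#'
#' Discovery-dialect array QC: samples whose detectable-microRNA count
#' (Ct < `thresholdCt`) falls below `minDetectable` are removed. The retained
#' Ct values are untouched (pure column subset).
#'
#' @param x a [CtSet-class].
#' @param minDetectable minimum detectable microRNAs to retain a sample.
#' @param thresholdCt detectability cutoff in cycles (default 38).
#' @param ... ignored.
#' @return A list with `ctset` (the retained [CtSet-class]) and `excluded`, a
#'   data.frame of removed samples with their detectable counts.
#' @export
setMethod("applySampleQC", "CtSet",
  function(x, minDetectable = 230, thresholdCt = 38, ...) {
    counts <- countDetectable(x, thresholdCt = thresholdCt)
    drop <- counts < minDetectable
    if (all(drop))
      stop("all ", length(counts), " samples fall below the detectable-count ",
           "threshold (", minDetectable, "); nothing retained")
    excluded <- data.frame(sample_id = names(counts)[drop],
                           detectable = unname(counts[drop]),
                           min_required = rep(minDetectable, sum(drop)))
    list(ctset = x[, !drop], excluded = excluded)
  })

#' Delta-Ct normalization against pooled endogenous controls
#'
#' For every sample, subtracts the pooled mean Ct of the endogenous-control
#' rows (default RNU-44 and RNU-48): `dCt[i, s] = Ct[i, s] - mean(Ct[ctrl, s])`.
#' Lower delta-Ct means higher expression. After normalization the
#' control-row values average exactly zero within each sample, and the
#' transform is invariant to any sample-wide Ct shift. Flags are carried
#' through unchanged.
#'
#' @param x a [CtSet-class].
#' @param controls control row names; defaults to `controlIds(x)`.
#' @param ... ignored.
#' @return The `CtSet` with a `"norm"` assay and `normMethod()` `"deltaCt"`.
#' @export
setMethod("deltaCtNormalize", "CtSet", function(x, controls = NULL, ...) {
  if (is.null(controls)) controls <- controlIds(x)
  missingCtrl <- setdiff(controls, rownames(x))
  if (length(missingCtrl))
    stop("control row(s) absent from matrix: ",
         paste(missingCtrl, collapse = ", "))
  ct <- ctValues(x)
  ctrl <- ct[controls, , drop = FALSE]
  bad <- colnames(ct)[colSums(is.na(ctrl)) > 0]
  if (length(bad))
    stop("missing control Ct in retained sample(s): ",
         paste(bad, collapse = ", "))
  dct <- sweep(ct, 2L, colMeans(ctrl), "-")
  assay(x, "norm", withDimnames = FALSE) <- dct
  x@normMethod <- "deltaCt"
  validObject(x)
  x
})

#' Quantile normalization of Ct values
#'
#' Validation-dialect normalization: classic quantile normalization across
#' samples, computed on `"OK"`-flagged entries only (flag first with
#' [flagEntries()]; unflagged objects are flagged with default rules).
#' Non-OK and missing entries stay missing in the output. The engine is
#' \code{\link[limma]{normalizeQuantiles}}, which handles unequal numbers of
#' available values per sample by interpolating the mean quantile function.
#'
#' @param x a [CtSet-class] with at least two samples.
#' @param ... ignored.
#' @return The `CtSet` with a `"norm"` assay and `normMethod()` `"quantile"`.
#' @export
setMethod("quantileNormalize", "CtSet", function(x, ...) {
  if (ncol(x) < 2L)
    stop("quantile normalization requires at least 2 samples")
  if (!("flag" %in% assayNames(x))) x <- flagEntries(x)
  ct <- ctValues(x)
  ct[ctFlags(x) != "OK"] <- NA_real_
  nq <- limma::normalizeQuantiles(ct, ties = TRUE)
  dimnames(nq) <- dimnames(ct)
  assay(x, "norm", withDimnames = FALSE) <- nq
  x@normMethod <- "quantile"
  validObject(x)
  x
})

#' Coefficient of variation of control assays
#'
#' CV (%) of each control row across samples, `100 * sd / |mean|`. The array
#' run passes QC when every control CV is at or below `maxCV` (default 5%).
#' A zero-mean control row has undefined CV and fails.
#'
#' @param x a [CtSet-class] (raw or normalized; raw Ct values are used).
#' @param controls control row names; defaults to `controlIds(x)`.
#' @param maxCV pass threshold in percent.
#' @param ... ignored.
#' @return A data.frame with `control_id`, `cv_percent`, `pass`, and an
#'   attribute `qc_pass` (logical, all controls pass).
#' @export
setMethod("controlCV", "CtSet", function(x, controls = NULL, maxCV = 5, ...) {
  if (is.null(controls)) controls <- controlIds(x)
  stopifnot(all(controls %in% rownames(x)))
  ct <- ctValues(x)[controls, , drop = FALSE]
  m <- rowMeans(ct, na.rm = TRUE)
  s <- apply(ct, 1L, stats::sd, na.rm = TRUE)
  cv <- ifelse(m == 0, NA_real_, 100 * s / abs(m))
  out <- data.frame(control_id = controls, cv_percent = unname(cv),
                    pass = !is.na(cv) & cv <= maxCV)
  attr(out, "qc_pass") <- all(out$pass)
  out
})

#' Read / write Ct matrices as TSV
#'
#' Tab-separated dialect used throughout the package: first column
#' `mirna_id`, one column per sample, empty cells for undetermined wells.
#'
#' @param path file path.
#' @param controlIds endogenous-control row names expected in the file.
#' @return `readCtMatrix()` returns a [CtSet-class]; `writeCtMatrix()` its
#'   path, invisibly.
#' @export
readCtMatrix <- function(path, controlIds = c("RNU-44", "RNU-48")) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (names(df)[1L] != "mirna_id")
    stop("Ct TSV must start with a 'mirna_id' column: ", path)
  if (anyDuplicated(df$mirna_id))
    stop("duplicated microRNA id(s) in ", path, ": ",
         paste(unique(df$mirna_id[duplicated(df$mirna_id)]), collapse = ", "))
  ct <- as.matrix(df[, -1L, drop = FALSE])
  mode(ct) <- "double"
  rownames(ct) <- df$mirna_id
  CtSet(ct, controlIds = controlIds)
}

#' @rdname readCtMatrix
#' @param x a [CtSet-class] to serialize (raw `ct` assay is written).
#' @export
writeCtMatrix <- function(x, path) {
  ct <- ctValues(x)
  df <- data.frame(mirna_id = rownames(ct), ct, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
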