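#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' CtSet: qPCR threshold-cycle matrices with per-entry flags
#'
#' `CtSet` extends \linkS4class{SummarizedExperiment} and is the central
#' container of the package. It holds one primary assay of Ct (threshold
#' cycle) values -- microRNAs in rows, patient samples in columns, `NA` for
#' undetermined wells -- and a parallel character assay of per-entry flags
#' (`"OK"`, `"Unreliable"`, `"Undetermined"`). A subset of row names is
#' designated as endogenous controls (by default the small ncRNAs RNU-44 and
#' RNU-48) used for delta-Ct normalization.
#'
#' After normalization the object carries a `"norm"` assay and records the
#' method used (`"deltaCt"` or `"quantile"`) in `normMethod()`.
#'
#' @slot normMethod character; `"none"`, `"deltaCt"` or `"quantile"`.
#'
#' @seealso [CtSet()] for construction, [deltaCtNormalize()],
#'   [quantileNormalize()], [flagEntries()], [applySampleQC()].
#' @export
setClass("CtSet",
  contains = "SummarizedExperiment",
  slots = c(normMethod = "character"),
  prototype = prototype(normMethod = "none")
)

setValidity("CtSet", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!("ct" %in% an))
    msg <- c(msg, "CtSet must carry a 'ct' assay")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "row names (microRNA ids) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "column names (sample ids) must be present and unique")
  ctrl <- metadata(object)$controlIds
  if (is.null(ctrl) || !is.character(ctrl))
    msg <- c(msg, "metadata(object)$controlIds must be a character vector")
  else if (!all(ctrl %in% rownames(object)))
    msg <- c(msg, paste0("control ids not in matrix: ",
                         paste(setdiff(ctrl, rownames(object)), collapse = ", ")))
  if ("flag" %in% an) {
    fl <- assay(object, "flag")
    bad <- setdiff(unique(as.vector(fl)), c("OK", "Unreliable", "Undetermined", NA))
    if (length(bad))
      msg <- c(msg, paste0("invalid flag values: ", paste(bad, collapse = ", ")))
  }
  if (!(object@normMethod %in% c("none", "deltaCt", "quantile")))
    msg <- c(msg, "normMethod must be one of 'none', 'deltaCt', 'quantile'")
  if (length(msg)) msg else TRUE
})

#' Construct a CtSet
#'
#' @param ct numeric matrix of raw Ct values (microRNAs x samples) with
#'   dimnames; `NA` encodes undetermined wells.
#' @param controlIds character; row names of the endogenous-control assays.
#' @param colData optional `DataFrame`/`data.frame` of per-sample annotation
#'   (e.g. clinical phenotype), rows matching columns of `ct`.
#' @param flag optional character matrix of per-entry flags; when omitted the
#'   object is created unflagged (see [flagEntries()]).
#' @return A [CtSet-class] object.
#' @examples
#' ct <- matrix(c(25, 20, 21, 27, 20, 21), nrow = 3,
#'              dimnames = list(c("hsa-miR-1", "RNU-44", "RNU-48"),
#'                              c("s1", "s2")))
#' x <- CtSet(ct)
#' controlIds(x)
#' @export
CtSet <- function(ct, controlIds = c("RNU-44", "RNU-48"), colData = NULL,
                  flag = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("'ct' must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("'ct' must have row and column names")
  assays <- list(ct = ct)
  if (!is.null(flag)) {
    stopifnot(identical(dim(flag), dim(ct)))
    dimnames(flag) <- dimnames(ct)
    assays$flag <- flag
  }
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(ct))
  se <- SummarizedExperiment(assays = assays, colData = colData,
                             metadata = list(controlIds = controlIds))
  new("CtSet", se, normMethod = "none")
}

#' @describeIn CtSet-class number of microRNAs and samples plus flag/QC state.
#' @param object a `CtSet`.
#' @export
setMethod("show", "CtSet", function(object) {
  cat("CtSet:", nrow(object), "microRNAs x", ncol(object), "samples\n")
  cat("  controls:", paste(metadata(object)$controlIds, collapse = ", "), "\n")
  cat("  normalization:", object@normMethod, "\n")
  if ("flag" %in% assayNames(object)) {
    fl <- table(factor(assay(object, "flag"),
                       levels = c("OK", "Unreliable", "Undetermined")))
    cat("  flags: ", paste(names(fl), fl, sep = "=", collapse = " "), "\n")
  } else cat("  flags: not set\n")
})

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Describes the cohort structure to simulate: group sizes, card layout,
#' planted differential microRNAs and families, noise and dropout levels, the
#' coupling between progression rate and time to first recurrence, per-group
#' survival medians, and the RNG seed. See [cohortSpec()].
#'
#' @export
setClass("CohortSpec", representation(
  nLRP = "integer", nHRP = "integer", nIRP = "integer",
  nMirnas = "integer",
  plantedMirnas = "data.frame",     # columns: mirna_id, effect_size_cycles
  plantedFamilies = "character",    # family ids whose members are planted
  noiseSdCycles = "numeric",
  dropoutCtThreshold = "numeric",
  rateTimeCoupling = "numeric",
  survivalMedians = "numeric",      # named: LRP, HRP, IRP (months)
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  ns <- c(object@nLRP, object@nHRP, object@nIRP)
  if (any(is.na(ns)) || any(ns < 0L))
    msg <- c(msg, "group sizes must be non-negative")
  if (sum(ns) < 1L) msg <- c(msg, "cohort must contain at least one patient")
  if (object@nMirnas < 1L) msg <- c(msg, "nMirnas must be positive")
  if (object@noiseSdCycles < 0) msg <- c(msg, "noiseSdCycles must be >= 0")
  if (object@rateTimeCoupling < 0 || object@rateTimeCoupling > 1)
    msg <- c(msg, "rateTimeCoupling must lie in [0, 1]")
  if (!all(c("LRP", "HRP", "IRP") %in% names(object@survivalMedians)))
    msg <- c(msg, "survivalMedians must be named LRP, HRP, IRP")
  if (any(object@survivalMedians <= 0))
    msg <- c(msg, "survival medians must be positive")
  if (nrow(object@plantedMirnas) &&
      !all(c("mirna_id", "effect_size_cycles") %in% names(object@plantedMirnas)))
    msg <- c(msg, "plantedMirnas needs columns mirna_id, effect_size_cycles")
  # group-dependent effects need both comparison groups populated
  if ((nrow(object@plantedMirnas) || length(object@plantedFamilies)) &&
      (object@nLRP == 0L || object@nHRP == 0L))
    msg <- c(msg, "planted group effects require non-empty LRP and HRP groups")
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortSpec-class compact parameter summary.
#' @param object a `CohortSpec`.
#' @export
setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec: LRP =", object@nLRP, "| HRP =", object@nHRP,
      "| IRP =", object@nIRP, "\n")
  cat("  card:", object@nMirnas, "assayed microRNAs + 2 endogenous controls\n")
  cat("  planted:", nrow(object@plantedMirnas), "microRNAs,",
      length(object@plantedFamilies), "families\n")
  cat("  noise sd:", object@noiseSdCycles, "cycles | dropout Ct >",
      object@dropoutCtThreshold, "\n")
  cat("  seed:", object@seed, "\n")
})

#' SyntheticCohort: generated clinical table, Ct matrix and ground truth
#'
#' Produced by [generateCohort()]. Bundles the per-patient clinical table
#' (recurrence timeline, survival), the raw [CtSet-class], and the `truth`
#' list recording planted phenotype labels and planted differential
#' microRNAs so downstream recovery can be scored.
#'
#' @export
setClass("SyntheticCohort", representation(
  clinical = "data.frame",
  ct = "CtSet",
  truth = "list",
  spec = "CohortSpec"
))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!nrow(object@clinical)) msg <- c(msg, "empty clinical table")
  if (!identical(object@clinical$patient_id, colnames(object@ct)))
    msg <- c(msg, "clinical rows must match Ct matrix columns in order")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticCohort-class cohort size and truth summary.
#' @param object a `SyntheticCohort`.
#' @export
setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@clinical), "patients\n")
  print(table(object@truth$rate_class))
  cat("Ct matrix:", nrow(object@ct), "rows x", ncol(object@ct), "samples\n")
})
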