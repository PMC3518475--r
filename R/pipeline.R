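#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [runPipeline()]:
#' input paths, analysis thresholds and the RNG seed. Unknown keys are
#' rejected.
#'
#' @param clinicalCsv,ctTsv,miFam input paths (clinical table, Ct matrix,
#'   family flat file).
#' @param outDir run directory for stage outputs.
#' @param lrpBelow,hrpAbove rate-band thresholds (per year).
#' @param minDetectable discovery-QC minimum detectable microRNAs per
#'   sample.
#' @param detectableCt detectability cutoff (Ct).
#' @param pThreshold,foldThreshold differential/enrichment cutoffs.
#' @param minN minimum per-group observations per microRNA.
#' @param nPerm permutation resamplings for the enrichment test.
#' @param seed integer RNG seed.
#' @param qcDialect `"discovery"` (delta-Ct, detectable-count QC) or
#'   `"validation"` (flag rules 10/37, quantile normalization).
#' @param ... rejected; catches misspelled keys.
#' @return A list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(clinicalCsv, ctTsv, miFam = NULL, outDir,
                           lrpBelow = 0.6, hrpAbove = 3.6,
                           minDetectable = 230, detectableCt = 38,
                           pThreshold = 0.05, foldThreshold = 2,
                           minN = 3, nPerm = 10000, seed = 1L,
                           qcDialect = c("discovery", "validation"), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  qcDialect <- match.arg(qcDialect)
  for (v in c(lrpBelow, hrpAbove, minDetectable, detectableCt, pThreshold,
              foldThreshold, minN, nPerm))
    if (!is.numeric(v) || v < 0) stop("thresholds must be non-negative")
  structure(list(clinicalCsv = clinicalCsv, ctTsv = ctTsv, miFam = miFam,
                 outDir = outDir, lrpBelow = lrpBelow, hrpAbove = hrpAbove,
                 minDetectable = minDetectable, detectableCt = detectableCt,
                 pThreshold = pThreshold, foldThreshold = foldThreshold,
                 minN = minN, nPerm = nPerm, seed = as.integer(seed),
                 qcDialect = qcDialect),
            class = "pipelineConfig")
}

#' Validate pipeline inputs
#'
#' Schema checks over the input files: required columns, duplicated ids,
#' negative follow-up, control rows present. Issues are classified as fatal
#' or warning.
#'
#' @param clinicalCsv,ctTsv,miFam input paths (`miFam` optional).
#' @return data.frame with columns `severity` (`"fatal"`/`"warning"`) and
#'   `message`; zero rows means a clean bill. Attribute `ok` is `TRUE` when
#'   no fatal issue was found.
#' @export
validateInputs <- function(clinicalCsv, ctTsv, miFam = NULL) {
  issues <- data.frame(severity = character(), message = character())
  note <- function(sev, msg)
    rbind(issues, data.frame(severity = sev, message = msg))
  for (p in c(clinicalCsv, ctTsv, miFam))
    if (!file.exists(p))
      issues <- note("fatal", paste("missing file:", p))
  if (!nrow(issues)) {
    cl <- tryCatch(readClinical(clinicalCsv), error = function(e)
      conditionMessage(e))
    if (is.character(cl)) issues <- note("fatal", cl)
    else {
      if (anyDuplicated(cl$patient_id))
        issues <- note("fatal", "duplicated patient_id in clinical CSV")
      if (all(cl$n_recurrent_mets == 0))
        issues <- note("warning", "no recurrences anywhere in cohort")
    }
    ct <- tryCatch(readCtMatrix(ctTsv), error = function(e)
      conditionMessage(e))
    if (is.character(ct)) issues <- note("fatal", ct)
    else if (!all(controlIds(ct) %in% rownames(ct)))
      issues <- note("fatal", "endogenous control rows missing from Ct TSV")
    if (!is.character(cl) && !is.character(ct) &&
        !identical(sort(cl$patient_id), sort(colnames(ct))))
      issues <- note("warning",
                     "clinical patients and Ct samples do not coincide")
    if (!is.null(miFam)) {
      fam <- tryCatch(parseMiFam(miFam), error = function(e)
        conditionMessage(e))
      if (is.character(fam)) issues <- note("fatal", fam)
    }
  }
  attr(issues, "ok") <- !any(issues$severity == "fatal")
  issues
}

.stage <- function(name, runDir, expr) {
  res <- tryCatch(expr, error = function(e) {
    writeLines(paste0("FAILED at stage '", name, "': ",
                      conditionMessage(e)),
               file.path(runDir, "FAILED"))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message("[oligomiR] stage '", name, "' complete")
  res
}

#' Run the full analysis pipeline
#'
#' Executes stratify -> QC/normalize -> differential -> family enrichment ->
#' clustering/enrichment -> survival on the configured inputs, writing every
#' stage's artifacts plus a machine-readable run manifest (input checksums,
#' seed, thresholds, stage list) into the run directory. Any stage error
#' aborts with the stage name; partial outputs are retained next to a
#' `FAILED` marker file.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with the in-memory stage results (`phenotypes`,
#'   `qc`, `ctset`, `differential`, `prioritized`, `enrichment`,
#'   `partition`, `branch`, `km`, `logrank`, `manifest`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  runDir <- config$outDir
  issues <- validateInputs(config$clinicalCsv, config$ctTsv, config$miFam)
  if (!attr(issues, "ok"))
    stop("input validation failed:\n  ",
         paste(issues$message[issues$severity == "fatal"], collapse = "\n  "))

  clinical <- readClinical(config$clinicalCsv)
  raw <- readCtMatrix(config$ctTsv)

  phen <- .stage("stratify", runDir, {
    ph <- stratifyCohort(clinical, config$lrpBelow, config$hrpAbove)
    utils::write.table(ph, file.path(runDir, "phenotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ph
  })

  qc <- .stage("qc", runDir, {
    flagged <- flagEntries(raw)
    res <- applySampleQC(flagged, minDetectable = config$minDetectable,
                         thresholdCt = config$detectableCt)
    jsonlite::write_json(res$excluded, file.path(runDir, "qc_exclusions.json"),
                         auto_unbox = TRUE, digits = NA)
    cv <- controlCV(res$ctset)
    utils::write.table(cv, file.path(runDir, "control_cv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })

  norm <- .stage("normalize", runDir, {
    x <- if (config$qcDialect == "discovery") deltaCtNormalize(qc$ctset)
         else quantileNormalize(qc$ctset)
    utils::write.table(
      data.frame(mirna_id = rownames(x), normValues(x), check.names = FALSE),
      file.path(runDir, "normalized.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    x
  })

  labels <- stats::setNames(phen$rate_class, phen$patient_id)[colnames(norm)]
  de <- .stage("differential", runDir, {
    tab <- differentialTable(norm, labels, minN = config$minN)
    pri <- prioritize(tab, config$pThreshold)
    writeDifferentialTable(pri, file.path(runDir, "prioritized.tsv"))
    list(table = tab, prioritized = pri)
  })

  enr <- NULL
  if (!is.null(config$miFam)) {
    enr <- .stage("famenrich", runDir, {
      fams <- parseMiFam(config$miFam)
      cat <- familyCatalog(fams, setdiff(rownames(norm), controlIds(norm)))
      res <- familyPermutationTest(norm, labels, cat,
                                   nPerm = config$nPerm, seed = config$seed,
                                   minN = config$minN,
                                   foldThreshold = config$foldThreshold,
                                   pThreshold = config$pThreshold)
      writeEnrichmentResult(res,
                            tsvPath = file.path(runDir, "enrichment.tsv"),
                            jsonPath = file.path(runDir, "enrichment.json"))
      res
    })
  }

  clus <- .stage("cluster", runDir, {
    part <- clusterSamples(norm)
    writePartition(part,
                   linkagePath = file.path(runDir, "linkage.tsv"),
                   branchPath = file.path(runDir, "branches.tsv"))
    hl <- labels[labels %in% c("HRP", "LRP")]
    be <- branchEnrichment(
      list(left = intersect(part$left, names(hl)),
           right = intersect(part$right, names(hl))), hl, positive = "HRP")
    jsonlite::write_json(list(table = as.vector(be$table),
                              odds_ratio = be$oddsRatio, p = be$p),
                         file.path(runDir, "branch_enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    list(partition = part, branch = be)
  })

  surv <- .stage("survive", runDir, {
    keep <- phen$rate_class %in% c("HRP", "LRP")
    cl <- clinical[match(phen$patient_id[keep], clinical$patient_id), ]
    km <- kmEstimate(cl$survival_months, cl$alive == 0,
                     phen$rate_class[keep])
    lr <- logrankTest(cl$survival_months, cl$alive == 0,
                      phen$rate_class[keep])
    writeSurvival(km, lr, curvePath = file.path(runDir, "km_curves.tsv"),
                  summaryPath = file.path(runDir, "survival_summary.json"))
    list(km = km, logrank = lr)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("oligomiR")),
    seed = config$seed,
    thresholds = config[c("lrpBelow", "hrpAbove", "minDetectable",
                          "detectableCt", "pThreshold", "foldThreshold",
                          "minN", "nPerm")],
    qc_dialect = config$qcDialect,
    inputs = lapply(stats::setNames(
      c(config$clinicalCsv, config$ctTsv, config$miFam),
      c("clinical", "ct", "mifam")[seq_len(2 + !is.null(config$miFam))]),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = c("stratify", "qc", "normalize", "differential",
               if (!is.null(enr)) "famenrich", "cluster", "survive")
  )
  jsonlite::write_json(manifest, file.path(runDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(phenotypes = phen, qc = qc, ctset = norm,
                 differential = de$table, prioritized = de$prioritized,
                 enrichment = enr, partition = clus$partition,
                 branch = clus$branch, km = surv$km, logrank = surv$logrank,
                 manifest = manifest))
}
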