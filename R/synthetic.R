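#' Default planted differential microRNAs
#'
#' Forty microRNAs shifted between the HRP and LRP groups, emulating the
#' structure of the discovery comparison: 37 down-regulated in HRP (positive
#' delta-Ct shifts of 1.5 to 3.011 cycles, i.e. ~2.8- to 8.06-fold down) and
#' 3 up-regulated. The planted set covers one complete 4-member family
#' (stem `mir-501`), two complete -3p/-5p pairs (stems `mir-601`,
#' `mir-602`), and 29 down / 3 up singletons.
#'
#' @return data.frame `mirna_id`, `effect_size_cycles` (positive = higher
#'   delta-Ct, i.e. lower expression, in HRP).
#' @export
defaultPlantedMirnas <- function() {
  fam <- paste0("hsa-miR-501", letters[1:4])
  pairs <- c("hsa-miR-601-3p", "hsa-miR-601-5p",
             "hsa-miR-602-3p", "hsa-miR-602-5p")
  downSingles <- paste0("hsa-miR-70", sprintf("%02d", 1:29))
  upSingles <- paste0("hsa-miR-70", sprintf("%02d", 30:32))
  data.frame(
    mirna_id = c(fam, pairs, downSingles, upSingles),
    effect_size_cycles = c(
      c(2.6, 2.4, 2.8, 2.3),            # family members, congruent down
      c(2.0, 2.2, 1.9, 2.5),            # both strands of two pairs, down
      c(3.011, seq(2.9, 1.5, length.out = 28)),  # singletons incl. 8.06x
      c(-2.2, -1.8, -3.5)               # up-regulated in HRP
    ),
    stringsAsFactors = FALSE
  )
}

# deterministic card layout: 15 four-member families, 50 complete -3p/-5p
# pairs, singletons up to nMirnas assayed ids, plus the two controls
cardLayout <- function(nMirnas = 376L) {
  famIds <- unlist(lapply(500 + 1:15, function(k)
    paste0("hsa-miR-", k, letters[1:4])))
  pairIds <- unlist(lapply(600 + 1:50, function(k)
    paste0("hsa-miR-", k, c("-3p", "-5p"))))
  core <- c(famIds, pairIds)
  if (nMirnas < length(core))
    stop("nMirnas must be at least ", length(core),
         " to hold the family/pair layout")
  singles <- paste0("hsa-miR-70", sprintf("%02d", seq_len(nMirnas - length(core))))
  c(core, singles)
}

#' Specify a synthetic cohort
#'
#' Parameters of [generateCohort()]. Defaults reproduce the structure of the
#' discovery cohort: 32 LRP / 16 HRP / 15 IRP patients (n = 63), a 376
#' assayed-microRNA card with RNU-44/RNU-48 endogenous controls, 40 planted
#' differential microRNAs ([defaultPlantedMirnas()]) including one congruent
#' family and two -3p/-5p pairs, a strong negative coupling between the rate
#' of recurrent metastases and time to first recurrence, and per-group
#' exponential survival with medians 63.5 (LRP) and 18 (HRP) months.
#'
#' @param nLRP,nHRP,nIRP group sizes.
#' @param nMirnas assayed microRNAs on the card (controls not counted).
#' @param plantedMirnas data.frame `mirna_id`, `effect_size_cycles`
#'   (delta-Ct shift of HRP relative to LRP; positive = down in HRP); empty
#'   data.frame for a pure-noise cohort.
#' @param plantedFamilies family stems whose members are planted (recorded
#'   in the truth list; membership itself comes from `plantedMirnas`).
#' @param noiseSdCycles per-well biological + technical noise sd in Ct
#'   cycles (default 1.65, roughly 3-fold inter-patient variability).
#' @param dropoutCtThreshold latent Ct above which a well reads undetermined
#'   (missing); `Inf` disables dropout.
#' @param rateTimeCoupling in `[0, 1]`; 1 couples the first-recurrence time
#'   deterministically to the simulated event process, lower values add
#'   lognormal jitter.
#' @param survivalMedians named per-group median survival in months.
#' @param seed integer RNG seed; the whole cohort is drawn from a single
#'   seeded stream.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nLRP = 32L, nHRP = 16L, nIRP = 15L,
                       nMirnas = 376L,
                       plantedMirnas = defaultPlantedMirnas(),
                       plantedFamilies = "mir-501",
                       noiseSdCycles = 1.65,
                       dropoutCtThreshold = 38,
                       rateTimeCoupling = 0.8,
                       survivalMedians = c(LRP = 63.5, HRP = 18, IRP = 30),
                       seed = 20121210L) {
  new("CohortSpec", nLRP = as.integer(nLRP), nHRP = as.integer(nHRP),
      nIRP = as.integer(nIRP), nMirnas = as.integer(nMirnas),
      plantedMirnas = plantedMirnas,
      plantedFamilies = as.character(plantedFamilies),
      noiseSdCycles = noiseSdCycles,
      dropoutCtThreshold = dropoutCtThreshold,
      rateTimeCoupling = rateTimeCoupling,
      survivalMedians = survivalMedians, seed = as.integer(seed))
}

# one patient's clinical record; draws consume the active RNG stream in a
# fixed order: survival, censoring, intensity, event count (rejection),
# event times, first-recurrence jitter, cavity flag
.simulatePatient <- function(group, medianSurv, coupling) {
  death <- stats::rexp(1L, rate = log(2) / medianSurv)
  # an intermediate-rate patient needs enough follow-up for an integer
  # event count to land in the 0.6-3.6/yr band; below ~4 months none can
  if (group == "IRP")
    while (death < 6) death <- stats::rexp(1L, rate = log(2) / medianSurv)
  censor <- stats::runif(1L, 16, 120)
  alive <- death > censor
  survMonths <- min(death, censor)
  followup <- survMonths
  fy <- followup / 12
  lambda <- switch(group,
    LRP = if (stats::runif(1L) < 0.5) 0 else stats::runif(1L, 0.05, 0.5),
    IRP = stats::runif(1L, 0.9, 3.2),
    HRP = stats::runif(1L, 4.5, 9))
  inBand <- function(n) {
    r <- n / fy
    switch(group, LRP = r < 0.6 && n <= 4, HRP = r > 3.6,
           IRP = r >= 0.6 && r <= 3.6)
  }
  n <- NA_integer_
  for (i in seq_len(200L)) {
    cand <- stats::rpois(1L, lambda * fy)
    if (inBand(cand)) { n <- cand; break }
  }
  if (is.na(n))  # deterministic in-band fallback
    n <- switch(group, LRP = 0L, HRP = as.integer(floor(3.6 * fy)) + 1L,
                IRP = max(1L, as.integer(ceiling(0.6 * fy))))
  events <- if (n > 0L) sort(stats::runif(n, 0, followup)) else numeric()
  t1 <- NA_real_
  if (n > 0L) {
    # first recurrence pinned near the expected first order statistic of the
    # event process, followup/(n+1); (1 - coupling) controls the jitter
    jitter <- stats::rlnorm(1L, 0, (1 - coupling))
    t1 <- min(followup / (n + 1L) * jitter, followup)
    events[1L] <- t1
    events <- sort(events)
  }
  burstMax <- if (n > 0L) slidingWindowMax(events) else 0L
  cavity <- 0L
  if (group == "HRP") {
    # every HRP patient progresses polymetastatically: cavity progression
    # planted whenever the event process itself shows no >5-in-4-month burst
    cavity <- if (burstMax > 5L) stats::rbinom(1L, 1L, 0.3) else 1L
  } else if (group == "IRP") {
    cavity <- stats::rbinom(1L, 1L, 0.15)
  }
  list(followup = followup, alive = alive, surv = survMonths,
       n = n, t1 = t1, events = events, burstMax = burstMax,
       cavity = cavity)
}

#' Generate a synthetic cohort
#'
#' Simulates a clinical table and a raw Ct matrix with the statistical
#' structure the downstream analysis assumes. Recurrence timelines are a
#' per-patient Poisson event process over follow-up with group-specific
#' intensity, constrained so the recomputed rate of progression lands in the
#' planted LRP/HRP/IRP band; every HRP patient meets a polymetastatic
#' criterion and no LRP patient does. Survival is exponential per group with
#' administrative censoring. The Ct matrix has per-microRNA baselines,
#' per-sample global offsets (removed by delta-Ct normalization), low-noise
#' endogenous-control rows, planted HRP-vs-LRP delta-Ct shifts, and
#' missingness wherever the latent Ct exceeds the dropout threshold (values
#' retained are never altered by dropout).
#'
#' @param spec a [CohortSpec-class]; regeneration from an identical spec is
#'   bit-identical.
#' @return A [SyntheticCohort-class].
#' @export
setMethod("generateCohort", "CohortSpec", function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  groups <- rep(c("LRP", "HRP", "IRP"), c(spec@nLRP, spec@nHRP, spec@nIRP))
  nPat <- length(groups)
  ids <- sprintf("P%03d", seq_len(nPat))

  sims <- lapply(groups, function(g)
    .simulatePatient(g, spec@survivalMedians[[g]], spec@rateTimeCoupling))
  clinical <- data.frame(
    patient_id = ids,
    n_mets_at_surgery = sample(1:5, nPat, replace = TRUE),
    surgery_date_or_t0 = 0,
    time_to_first_recurrence_months =
      vapply(sims, function(s) s$t1, 0),
    n_recurrent_mets = vapply(sims, function(s) s$n, 0L),
    max_new_mets_in_4_months = vapply(sims, function(s) s$burstMax, 0L),
    cavity_progression = vapply(sims, function(s) s$cavity, 0L),
    followup_months = vapply(sims, function(s) s$followup, 0),
    alive = vapply(sims, function(s) as.integer(s$alive), 0L),
    survival_months = vapply(sims, function(s) s$surv, 0),
    stringsAsFactors = FALSE
  )

  assayed <- cardLayout(spec@nMirnas)
  controls <- c("RNU-44", "RNU-48")
  planted <- spec@plantedMirnas
  if (nrow(planted)) {
    unknown <- setdiff(planted$mirna_id, assayed)
    if (length(unknown))
      stop("planted microRNA(s) not on the card: ",
           paste(unknown, collapse = ", "))
  }

  # latent Ct: baseline + sample offset + planted effect + noise
  baseline <- stats::runif(spec@nMirnas, 22, 33)
  hi <- sample.int(spec@nMirnas, max(1L, round(0.1 * spec@nMirnas)))
  baseline[hi] <- stats::runif(length(hi), 34.5, 37.5)  # dropout-prone
  names(baseline) <- assayed
  sampleOffset <- stats::rnorm(nPat, 0, 0.3)
  noise <- matrix(stats::rnorm(spec@nMirnas * nPat, 0, spec@noiseSdCycles),
                  spec@nMirnas, nPat)
  ct <- baseline + noise
  ct <- sweep(ct, 2L, sampleOffset, "+")
  dimnames(ct) <- list(assayed, ids)
  if (nrow(planted)) {
    isHRP <- groups == "HRP"
    for (i in seq_len(nrow(planted)))
      ct[planted$mirna_id[i], isHRP] <-
        ct[planted$mirna_id[i], isHRP] + planted$effect_size_cycles[i]
  }
  ct[ct > spec@dropoutCtThreshold] <- NA_real_

  ctrlBase <- c(`RNU-44` = 19.5, `RNU-48` = 20.5)
  ctrlNoise <- matrix(stats::rnorm(2L * nPat, 0, 0.15 * spec@noiseSdCycles),
                      2L, nPat)
  ctrl <- ctrlBase + ctrlNoise
  ctrl <- sweep(ctrl, 2L, sampleOffset, "+")
  dimnames(ctrl) <- list(controls, ids)

  ctset <- CtSet(rbind(ct, ctrl), controlIds = controls,
                 colData = DataFrame(rate_class = groups, row.names = ids))

  truth <- list(
    rate_class = stats::setNames(groups, ids),
    pattern = stats::setNames(
      vapply(seq_len(nPat), function(i)
        classifyPattern(clinical$cavity_progression[i],
                        clinical$max_new_mets_in_4_months[i]), ""), ids),
    planted_mirnas = planted,
    planted_families = spec@plantedFamilies
  )
  new("SyntheticCohort", clinical = clinical, ct = ctset, truth = truth,
      spec = spec)
})

#' Accessors for SyntheticCohort
#'
#' @param cohort a [SyntheticCohort-class].
#' @return `cohortClinical()` the clinical data.frame, `cohortCt()` the
#'   [CtSet-class], `cohortTruth()` the ground-truth list.
#' @export
cohortClinical <- function(cohort) cohort@clinical

#' @rdname cohortClinical
#' @export
cohortCt <- function(cohort) cohort@ct

#' @rdname cohortClinical
#' @export
cohortTruth <- function(cohort) cohort@truth

#' Write a synthetic cohort as plain-text fixtures
#'
#' Writes `clinical.csv`, `ct_matrix.tsv` and `truth.json` into `dir` in the
#' dialects consumed by [readClinical()], [readCtMatrix()] and
#' [readCohortTruth()]; the round trip is lossless up to numeric printing.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
setMethod("writeCohortFixtures", "SyntheticCohort", function(cohort, dir) {
  if (!nrow(cohort@clinical)) stop("refusing to write an empty cohort")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  paths <- c(clinical = file.path(dir, "clinical.csv"),
             ct = file.path(dir, "ct_matrix.tsv"),
             truth = file.path(dir, "truth.json"))
  writeClinical(cohort@clinical, paths["clinical"])
  writeCtMatrix(cohort@ct, paths["ct"])
  jsonlite::write_json(list(
    rate_class = as.list(cohort@truth$rate_class),
    pattern = as.list(cohort@truth$pattern),
    planted_mirnas = cohort@truth$planted_mirnas,
    planted_families = cohort@truth$planted_families,
    seed = cohort@spec@seed), paths["truth"],
    auto_unbox = TRUE, digits = NA)
  invisible(paths)
})

#' @rdname writeCohortFixtures
#' @param path path to a `truth.json` written by [writeCohortFixtures()].
#' @export
readCohortTruth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$rate_class <- unlist(tr$rate_class)
  tr$pattern <- unlist(tr$pattern)
  tr
}

#' Synthetic miRBase-dialect family file for the default card
#'
#' Writes a family flat file (miFam.dat dialect) describing the synthetic
#' card layout of [generateCohort()]: 15 four-member families plus a few
#' non-human decoy members exercising the species filter. This catalog is
#' synthetic -- it is not miRBase content.
#'
#' @param path output path.
#' @param nMirnas card size; must match the generated cohort.
#' @return The path, invisibly.
#' @export
makeSyntheticMiFam <- function(path, nMirnas = 376L) {
  assayed <- cardLayout(nMirnas)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in 1:15) {
    stem <- paste0("mir-", 500 + k)
    writeLines(sprintf("AC   MIPFS%05d", k), con)
    writeLines(paste0("ID   ", stem), con)
    for (j in 1:4)
      writeLines(sprintf("MI   MI%07d  hsa-%s%s", k * 10 + j, stem,
                         letters[j]), con)
    # decoy member from another species, dropped by the hsa filter
    writeLines(sprintf("MI   MI%07d  mmu-%sa", k * 10 + 9, stem), con)
    writeLines("//", con)
  }
  invisible(path)
}
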