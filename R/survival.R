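#' Kaplan-Meier survival estimates per group
#'
#' Product-limit curves per phenotype group, with the median defined as the
#' first time at which the survival function drops to 0.5 or below
#' (undefined -- `NA` -- when the curve never reaches 0.5). Fitting is done
#' with \code{\link[survival]{survfit}}; the median rule above is applied to
#' the fitted step function.
#'
#' @param time survival times in months from lung metastasis surgery.
#' @param event logical/0-1; `TRUE` = death from any cause, `FALSE` =
#'   censored alive at last follow-up.
#' @param group per-patient group labels.
#' @return List of class `"kmResult"`: `curves` (per-group data.frame of
#'   `time`, `at_risk`, `events`, `surv`), `medians` (named vector, months).
#' @export
kmEstimate <- function(time, event, group = rep("all", length(time))) {
  if (any(time <= 0)) stop("survival times must be positive")
  stopifnot(length(event) == length(time), length(group) == length(time))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ grp,
                           data = data.frame(time = time,
                                             event = as.integer(event),
                                             grp = group))
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(group)[1L], length(sm$time))
         else sub("^grp=", "", as.character(sm$strata))
  curves <- split(data.frame(time = sm$time, at_risk = sm$n.risk,
                             events = sm$n.event, surv = sm$surv), grp)
  medians <- vapply(curves, function(cv) {
    i <- which(cv$surv <= 0.5)
    if (length(i)) cv$time[min(i)] else NA_real_
  }, 0)
  structure(list(curves = curves, medians = medians), class = "kmResult")
}

#' @export
print.kmResult <- function(x, ...) {
  cat("Kaplan-Meier estimate;", length(x$curves), "group(s)\n")
  for (g in names(x$medians))
    cat(sprintf("  %s: median %s months\n", g,
                if (is.na(x$medians[g])) "not reached"
                else format(x$medians[g])))
  invisible(x)
}

#' Log-rank (Mantel-Cox) comparison of two survival curves
#'
#' Standard Mantel-Cox observed-vs-expected statistic on 1 degree of
#' freedom via \code{\link[survival]{survdiff}}, with a two-sided p-value
#' from the chi-square distribution.
#'
#' @inheritParams kmEstimate
#' @return List `chi2`, `p`, `n` (per-group sizes).
#' @export
logrankTest <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  ev <- tapply(as.integer(event), group, sum)
  if (all(ev == 0))
    stop("no events in either group; log-rank statistic undefined")
  d <- data.frame(time = time, event = as.integer(event), grp = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = d)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       n = table(group))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided comparison of two unpaired samples via
#' \code{\link[stats]{wilcox.test}}: exact p for small samples without ties,
#' normal approximation with tie correction otherwise.
#'
#' @param a,b numeric vectors.
#' @param exactMax use the exact distribution when both groups have at most
#'   this many observations and no ties are present.
#' @return List `U`, `p`.
#' @export
mannWhitney <- function(a, b, exactMax = 12) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= exactMax && length(b) <= exactMax
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks, with a two-sided p-value:
#' exact permutation distribution for n <= 9 without ties, the
#' t-approximation otherwise (\code{\link[stats]{cor.test}}).
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return List `rho`, `p`.
#' @export
spearmanCor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Serialize survival outputs
#'
#' Per-group survival curve TSV (`group`, `time`, `at_risk`, `events`,
#' `surv`) and a JSON test summary.
#'
#' @param km a [kmEstimate()] result.
#' @param logrank optional [logrankTest()] result.
#' @param curvePath,summaryPath output paths (`NULL` to skip).
#' @export
writeSurvival <- function(km, logrank = NULL, curvePath = NULL,
                          summaryPath = NULL) {
  if (!is.null(curvePath)) {
    df <- do.call(rbind, lapply(names(km$curves), function(g)
      cbind(group = g, km$curves[[g]])))
    utils::write.table(df, curvePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(summaryPath)) {
    out <- list(medians = as.list(km$medians))
    if (!is.null(logrank))
      out$logrank <- list(chi2 = logrank$chi2, p = logrank$p)
    jsonlite::write_json(out, summaryPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(km)
}
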