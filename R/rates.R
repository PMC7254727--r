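#' Select constitutively expressed genes
#'
#' A gene is constitutively expressed when its expression metric meets the
#' threshold in strictly more than `fraction` of samples. Four canonical
#' definitions (TPM >= 5, TPM >= 10, COV >= 20, COV >= 30, each in > 75\%
#' of samples) give rate estimates that should agree closely; comparing
#' them probes the robustness of the extrapolation.
#'
#' @param expression long data.frame with columns `gene`, `sample`, the
#'   metric columns (`tpm` and/or `cov`), or a gene x sample matrix.
#' @param metric `"tpm"` or `"cov"`.
#' @param threshold expression threshold.
#' @param fraction required sample fraction, strict inequality (default
#'   0.75).
#' @param exonicLength named vector gene -> exonic bp (used for the total
#'   interrogated length `L`).
#' @return list with `genes` (character), `L` (total exonic bp, NA when no
#'   lengths given), `metric`, `threshold`, `fraction`
#' @export
selectConstitutiveGenes <- function(expression, metric = c("tpm", "cov"),
                                    threshold, fraction = 0.75,
                                    exonicLength = NULL) {
  metric <- match.arg(metric)
  if (is.matrix(expression)) {
    m <- expression
  } else {
    expression <- as.data.frame(expression)
    if (!metric %in% names(expression))
      stop("unknown metric column: ", metric)
    stopifnot(nrow(expression) > 0L)
    dt <- data.table::as.data.table(expression)
    m <- as.matrix(data.table::dcast(
      dt, gene ~ sample, value.var = metric, fill = 0),
      rownames = "gene")
    storage.mode(m) <- "numeric"
  }
  frac <- rowMeans(m >= threshold)
  genes <- rownames(m)[frac > fraction]      # strictly more than
  L <- if (is.null(exonicLength)) NA_real_ else
    sum(exonicLength[genes], na.rm = TRUE)
  list(genes = genes, L = L, metric = metric, threshold = threshold,
       fraction = fraction)
}

#' Per-nucleotide mosaic mutation rate with bootstrap CI
#'
#' rate = n_mutations / (L x n_individuals), with a seeded percentile
#' bootstrap over individuals for the 95\% confidence interval. The exome
#' extrapolation (rate x 45 Mbp by default) and the precision/sensitivity
#' correction are attached.
#'
#' @param mutations data.frame of calls of one class with an `individual`
#'   column; calls must already be restricted to the gene set.
#' @param L total interrogated exonic length in bp (> 0).
#' @param nIndividuals cohort size (> 0; may exceed the individuals with
#'   calls).
#' @param bootReps bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param exomeBp exome extrapolation length (default 4.5e7).
#' @param precision,sensitivity calling performance used for the corrected
#'   count (defaults 0.85 and 0.71).
#' @return list with `n_mutations`, `L`, `n_individuals`, `rate`,
#'   `ci_low`, `ci_high`, `exome_count`, `corrected_count`
#' @export
mutationRate <- function(mutations, L, nIndividuals, bootReps = 1000L,
                         seed = 1L, exomeBp = 4.5e7, precision = 0.85,
                         sensitivity = 0.71) {
  if (!is.finite(L) || L <= 0) stop("interrogated length L must be > 0")
  stopifnot(nIndividuals > 0)
  n <- nrow(as.data.frame(mutations))
  rate <- n / (L * nIndividuals)
  ci <- c(NA_real_, NA_real_)
  if (n > 0) {
    perInd <- table(factor(mutations$individual,
                           levels = unique(mutations$individual)))
    counts <- c(as.integer(perInd),
                rep(0L, max(0L, nIndividuals - length(perInd))))
    set.seed(seed)
    bootRates <- vapply(seq_len(bootReps), function(b)
      sum(sample(counts, replace = TRUE)) / (L * nIndividuals), numeric(1))
    ci <- unname(stats::quantile(bootRates, c(0.025, 0.975)))
  } else {
    ci <- c(0, 0)
  }
  ex <- extrapolateExome(rate, exomeBp)
  list(n_mutations = n, L = L, n_individuals = nIndividuals, rate = rate,
       ci_low = min(ci[1L], rate), ci_high = max(ci[2L], rate),
       exome_count = ex,
       corrected_count = correctForPerformance(round(ex, 2), precision,
                                               sensitivity))
}

#' Extrapolate a per-nucleotide rate to the exome
#'
#' Linear extrapolation of a per-nucleotide per-individual rate to the
#' total coding-exon length (45 Mbp), as used for projecting tumor
#' mutation burden from gene panels to exomes.
#'
#' @param rate per-nucleotide per-individual rate (>= 0)
#' @param exomeBp exome length in bp (default 4.5e7)
#' @return expected mutations per exome
#' @export
extrapolateExome <- function(rate, exomeBp = 4.5e7) {
  if (any(rate < 0)) stop("rate must be >= 0")
  rate * exomeBp
}

#' Precision / sensitivity correction of an extrapolated count
#'
#' Corrects an expected mutation count for the measured performance of the
#' variant caller: count x precision / sensitivity (false positives are
#' removed, missed variants added back).
#'
#' @param count expected count (typically the rounded extrapolated value)
#' @param precision,sensitivity in (0, 1]
#' @return corrected count
#' @export
correctForPerformance <- function(count, precision = 0.85,
                                  sensitivity = 0.71) {
  stopifnot(precision > 0, precision <= 1, sensitivity <= 1)
  if (sensitivity <= 0) stop("sensitivity must be > 0")
  count * precision / sensitivity
}

#' Per-tissue late-embryonic mutation rate and cohort exome total
#'
#' Single-tissue mutations are normalized per base and individual against
#' the per-sample interrogated region (genes highly expressed in that
#' tissue), extrapolated to the exome per tissue, and summed over tissues
#' for the expected late-embryonic burden per individual.
#'
#' @param calls data.frame of single-tissue calls with `individual` and
#'   `tissue` columns.
#' @param tissueL named vector tissue -> interrogated exonic bp.
#' @param nIndividuals cohort size.
#' @param nTissues number of examined tissues for the summed expectation
#'   (default: `length(tissueL)`).
#' @param exomeBp exome length (default 4.5e7).
#' @return list with `per_tissue` (data.frame tissue, n, L, rate,
#'   exome_count) and `total_per_individual` (mean exome count x nTissues)
#' @export
lemmRate <- function(calls, tissueL, nIndividuals, nTissues = NULL,
                     exomeBp = 4.5e7) {
  if (is.null(nTissues)) nTissues <- length(tissueL)
  if (nTissues == 0L) stop("nTissues must be > 0")
  calls <- as.data.frame(calls)
  per <- do.call(rbind, lapply(names(tissueL), function(t) {
    n <- sum(calls$tissue == t)
    r <- n / (tissueL[[t]] * nIndividuals)
    data.frame(tissue = t, n = n, L = tissueL[[t]], rate = r,
               exome_count = extrapolateExome(r, exomeBp))
  }))
  list(per_tissue = per,
       total_per_individual = mean(per$exome_count) * nTissues)
}

#' Sample-level QC exclusions for tissue-specific somatic rates
#'
#' Excludes samples in the top duplicate-rate percentile band, outliers for
#' callable sites (top and bottom), RIN (bottom) and mutation rate (top) -
#' all per tissue - plus cultured-cell tissues and individuals affected by
#' cancer, and finally tissues left with fewer than `minSamples` samples.
#'
#' @param records data.frame with columns `sample`, `tissue`,
#'   `individual`, `raw_rate`, `duplicates`, `rin`, `callable_sites`, and
#'   optionally `cultured` and `cancer` logicals.
#' @param dupTop,callableTail,rinBottom,rateTop quantile cutoffs (defaults
#'   0.05, 0.01, 0.01, 0.01).
#' @param minSamples minimum per-tissue sample count (default 50).
#' @return the filtered records
#' @export
qcFilterSamples <- function(records, dupTop = 0.05, callableTail = 0.01,
                            rinBottom = 0.01, rateTop = 0.01,
                            minSamples = 50L) {
  records <- as.data.frame(records)
  keep <- rep(TRUE, nrow(records))
  keep[records$duplicates > stats::quantile(records$duplicates,
                                            1 - dupTop)] <- FALSE
  for (t in unique(records$tissue)) {
    i <- records$tissue == t
    cs <- records$callable_sites[i]
    keep[i][cs > stats::quantile(cs, 1 - callableTail) |
              cs < stats::quantile(cs, callableTail)] <- FALSE
    keep[i][records$rin[i] < stats::quantile(records$rin[i],
                                             rinBottom)] <- FALSE
    keep[i][records$raw_rate[i] > stats::quantile(records$raw_rate[i],
                                                  1 - rateTop)] <- FALSE
  }
  if ("cultured" %in% names(records)) keep[records$cultured] <- FALSE
  if ("cancer" %in% names(records)) keep[records$cancer] <- FALSE
  records <- records[keep, , drop = FALSE]
  tab <- table(records$tissue)
  records[records$tissue %in% names(tab)[tab >= minSamples], ,
          drop = FALSE]
}

#' Confounder correction of raw somatic mutation rates
#'
#' Ordinary least squares of the raw per-sample mutation rate on technical
#' covariates (`raw_rate ~ duplicates + cohort + rin + trischd +
#' dp_median`); the residuals carry the biological signal used for
#' age-association tests.
#'
#' @param records data.frame with `raw_rate` and covariate columns
#'   `duplicates`, `cohort` (categorical), `rin`, `trischd`, `dp_median`.
#' @param formula model formula; constant covariates are dropped
#'   automatically (constant-only designs reduce to an intercept fit, so
#'   the residuals are the centered raw rates).
#' @return list with `records` (input + `residual` column) and `fit` (the
#'   `lm` object)
#' @export
residualRates <- function(records, formula = raw_rate ~ duplicates +
                            cohort + rin + trischd + dp_median) {
  records <- as.data.frame(records)
  vars <- all.vars(formula)[-1L]
  present <- vars[vapply(vars, function(v)
    length(unique(records[[v]])) > 1L, logical(1))]
  if (!length(present)) {
    fit <- stats::lm(raw_rate ~ 1, data = records)
  } else {
    f <- stats::reformulate(present, response = "raw_rate")
    records$cohort <- if ("cohort" %in% present)
      factor(records$cohort) else records$cohort
    fit <- stats::lm(f, data = records)
    alias <- stats::alias(fit)$Complete
    if (!is.null(alias))
      stop("rank-deficient design; collinear term(s): ",
           paste(rownames(alias), collapse = ", "))
  }
  records$residual <- unname(stats::resid(fit))
  list(records = records, fit = fit)
}

#' Per-tissue age association of residual mutation rates
#'
#' Spearman rank correlation between the confounder-corrected mutation-rate
#' residuals and donor age, per tissue, with BH correction applied across
#' tissues (not within).
#'
#' @param records output records of [residualRates()] with `tissue` and
#'   `age` columns.
#' @param minSamples minimum samples per tested tissue (default 3).
#' @return data.frame `tissue`, `rho`, `p`, `q`, `n`, `defined`,
#'   `significant` (q < 0.05)
#' @export
ageAssociation <- function(records, minSamples = 3L) {
  records <- as.data.frame(records)
  out <- do.call(rbind, lapply(unique(records$tissue), function(t) {
    i <- records$tissue == t
    n <- sum(i)
    if (n < minSamples || length(unique(records$residual[i])) < 2L ||
        length(unique(records$age[i])) < 2L)
      return(data.frame(tissue = t, rho = NA_real_, p = NA_real_, n = n,
                        defined = FALSE))
    ct <- suppressWarnings(stats::cor.test(records$residual[i],
                                           records$age[i],
                                           method = "spearman"))
    data.frame(tissue = t, rho = unname(ct$estimate), p = ct$p.value,
               n = n, defined = TRUE)
  }))
  out$q <- NA_real_
  out$q[out$defined] <- fdrAdjust(out$p[out$defined])
  out$significant <- !is.na(out$q) & out$q < 0.05
  out
}
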