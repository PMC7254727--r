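#' Strand-collapsed substitution class of a (ref, alt) pair
#'
#' Sequencing error rates differ per nucleotide change (e.g. oxidation
#' artifacts), so the error model is fitted independently per change. The
#' twelve possible changes collapse to six classes; changes with a G or T
#' reference are mapped through the reverse complement, which makes the
#' mapping involutive under complementation.
#'
#' @param ref,alt single reference / alternative bases (vectorised)
#' @return character vector with levels `A>C, A>T, A>G, C>A, C>T, C>G`
#' @examples
#' substitutionClass("G", "A")  # "C>T"
#' @export
substitutionClass <- function(ref, alt) {
  key <- paste0(toupper(ref), ">", toupper(alt))
  map <- c(
    "A>C" = "A>C", "A>T" = "A>T", "A>G" = "A>G",
    "C>A" = "C>A", "C>T" = "C>T", "C>G" = "C>G",
    "T>G" = "A>C", "T>A" = "A>T", "T>C" = "A>G",
    "G>T" = "C>A", "G>A" = "C>T", "G>C" = "C>G")
  out <- unname(map[key])
  bad <- is.na(out) & !is.na(ref) & !is.na(alt)
  if (any(bad))
    stop("invalid (ref, alt) pair(s): ",
         paste(unique(key[bad]), collapse = ", "))
  out
}

reverseComplement <- function(x) {
  chartr("ACGT", "TGCA", toupper(x))
}

fallbackParams <- function() data.frame(alpha = 1, beta = 1000)

## Kleinman method-of-moments estimator for beta-binomial shapes from
## per-site (alt, coverage) pairs with unequal coverage.
fitClassMoments <- function(alt, cov) {
  keep <- cov > 0
  alt <- alt[keep]; cov <- cov[keep]
  m <- length(alt)
  if (m < 2L) return(NULL)
  N <- sum(cov)
  p <- sum(alt) / N
  if (p <= 0 || p >= 1) return(NULL)
  S <- sum(cov * (alt / cov - p)^2)
  denom <- N - sum(cov^2) / N - (m - 1)
  if (denom <= 0) return(NULL)
  rho <- (S / (p * (1 - p)) - (m - 1)) / denom
  rho <- min(max(rho, 1e-8), 0.999)
  M <- 1 / rho - 1
  c(alpha = p * M, beta = (1 - p) * M)
}

fitClassMle <- function(alt, cov, init) {
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(dbetabinom(alt, cov, a, b, log = TRUE))
  }
  fit <- tryCatch(
    stats::optim(log(init), nll, method = "Nelder-Mead"),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$par))) return(NULL)
  out <- exp(fit$par)
  if (!all(is.finite(out)) || any(out <= 0)) return(NULL)
  names(out) <- c("alpha", "beta")
  out
}

#' Fit the beta-binomial sequencing-error model
#'
#' Models alternative read counts at putatively homozygous-reference
#' positions as `Alt ~ Bin(Coverage, error rate)` with
#' `error rate ~ Beta(alpha, beta)`, independently for each of the six
#' strand-collapsed substitution classes. Classes with fewer than
#' `minFitSites` usable positions, or degenerate counts (e.g. all zero),
#' receive the fallback prior `Beta(1, 1000)` and are flagged.
#'
#' @param homRef data.frame of homozygous-reference observations with
#'   columns `ref`, `alt` (the monitored alternative base), `alt_count` (or
#'   `alt_fwd` + `alt_rev`) and `coverage`.
#' @param method `"moments"` (default; closed-form, robust on sparse
#'   classes) or `"mle"` (maximum likelihood refinement started from the
#'   moment estimates; falls back to moments on a non-finite optimum).
#' @param minFitSites minimum sites per class before the fallback prior
#'   applies (default 500).
#' @param sample sample label stored in the model.
#' @return an [ErrorModel-class] object
#' @export
fitErrorModel <- function(homRef, method = c("moments", "mle"),
                          minFitSites = 500L, sample = "pooled") {
  method <- match.arg(method)
  if (is.null(homRef) || nrow(homRef) == 0L) {
    warning("no homozygous-reference observations; ",
            "fallback prior used for all classes")
    homRef <- data.frame(ref = character(), alt = character(),
                         alt_count = integer(), coverage = integer())
  }
  homRef <- normaliseCounts(homRef)
  cls <- if (nrow(homRef)) substitutionClass(homRef$ref, homRef$alt) else
    character()
  rows <- lapply(SUBSTITUTION_CLASSES, function(cl) {
    idx <- which(cls == cl & homRef$coverage > 0)
    nUse <- length(idx)
    fit <- NULL
    if (nUse >= minFitSites) {
      fit <- fitClassMoments(homRef$alt_count[idx], homRef$coverage[idx])
      if (!is.null(fit) && method == "mle") {
        mle <- fitClassMle(homRef$alt_count[idx], homRef$coverage[idx], fit)
        if (!is.null(mle)) fit <- mle
      }
      ## the error model describes errors, not variants: keep the mean
      ## strictly below 0.5
      if (!is.null(fit) && fit[["alpha"]] / sum(fit) >= 0.5) fit <- NULL
    }
    fb <- is.null(fit)
    if (fb) fit <- unlist(fallbackParams())
    data.frame(class = cl, alpha = unname(fit[["alpha"]]),
               beta = unname(fit[["beta"]]), n_sites = nUse, fallback = fb)
  })
  new("ErrorModel", params = do.call(rbind, rows), sample = sample,
      method = method)
}

## Accept either alt_count/ref_count totals or strand-resolved columns.
normaliseCounts <- function(df) {
  df <- as.data.frame(df)
  if (!"alt_count" %in% names(df)) {
    if (all(c("alt_fwd", "alt_rev") %in% names(df)))
      df$alt_count <- df$alt_fwd + df$alt_rev
    else stop("counts need alt_count or alt_fwd/alt_rev columns")
  }
  if (!"ref_count" %in% names(df) &&
      all(c("ref_fwd", "ref_rev") %in% names(df)))
    df$ref_count <- df$ref_fwd + df$ref_rev
  if (!"coverage" %in% names(df)) {
    if (!"ref_count" %in% names(df))
      stop("counts need coverage or ref/alt count columns")
    df$coverage <- df$ref_count + df$alt_count
  }
  df
}

#' Upper-tail error-model p-value per site
#'
#' `P(X >= alt_count | coverage, alpha, beta)` under the substitution
#' class's fitted error distribution: the probability of seeing at least as
#' many alternative reads by sequencing error alone. Sites without coverage
#' return p = 1 (no expression, defined-null).
#'
#' @param obs data.frame of observations (columns `ref`, `alt`,
#'   `alt_count`/`alt_fwd`+`alt_rev`, `coverage`).
#' @param model an [ErrorModel-class]
#' @return numeric vector of p-values in `[0, 1]`, one per row
#' @export
sitePvalue <- function(obs, model) {
  stopifnot(is(model, "ErrorModel"))
  obs <- normaliseCounts(obs)
  if (!nrow(obs)) return(numeric())
  cls <- substitutionClass(obs$ref, obs$alt)
  par <- errorParams(model)
  i <- match(cls, par$class)
  p <- pbetabinomUpper(obs$alt_count, obs$coverage, par$alpha[i], par$beta[i])
  p[obs$coverage <= 0] <- 1
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] used throughout the pipeline for
#' FDR control.
#'
#' @param p vector of p-values in `[0, 1]`
#' @return vector of BH-adjusted q-values
#' @export
fdrAdjust <- function(p) {
  if (!length(p)) return(numeric())
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

## Fisher's exact strand-bias p-value on (ref_fwd, ref_rev / alt_fwd,
## alt_rev); vectorised loop, evaluated on candidate rows only.
strandBiasP <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  n <- length(ref_fwd)
  out <- rep(1, n)
  for (i in seq_len(n)) {
    m <- matrix(c(ref_fwd[i], ref_rev[i], alt_fwd[i], alt_rev[i]), nrow = 2)
    if (any(is.na(m))) next
    out[i] <- stats::fisher.test(m)$p.value
  }
  out
}

## Count alt base qualities >= minBq from the comma-separated alt_bq column;
## when qualities are absent all alt reads count. Parsing is restricted to
## rows where the answer can differ from alt_count in a way that matters.
altHighBq <- function(obs, minBq = 20L, onlyIfAtLeast = 0L) {
  out <- obs$alt_count
  if (!"alt_bq" %in% names(obs)) return(out)
  todo <- which(obs$alt_count >= onlyIfAtLeast & !is.na(obs$alt_bq) &
                  nzchar(obs$alt_bq))
  out[todo] <- vapply(todo, function(i) {
    sum(as.integer(strsplit(obs$alt_bq[i], ",", fixed = TRUE)[[1L]]) >= minBq)
  }, integer(1))
  out
}

#' Single-sample post-filters for candidate variant sites
#'
#' Applies the step-1 hard filters to sites already tested against the error
#' model: minimum alternative allele count of 4 reads at base quality >= 20,
#' minimum coverage of 10, VAF >= 5\%, FDR significance, a Fisher
#' strand-bias test (alternative reads must follow the reference strand
#' distribution), and a minimum distance of 20 bp between candidate sites in
#' the same sample (both members of a close pair are removed). Every failed
#' criterion is listed as a reason code.
#'
#' @param obs data.frame of candidate observations (one sample), with
#'   strand-resolved counts, optional `alt_bq`, and `chrom`/`pos` for the
#'   proximity rule.
#' @param q BH-adjusted q-values for the rows of `obs`.
#' @param minAlt,minCov,minVaf,minDist,minBq,qMax,strandP filter settings.
#' @param neighbors optional integer positions (same chromosome space as
#'   `obs`) of other candidates in the sample; defaults to `obs` itself.
#' @return data.frame `pass` (logical) + `reasons` (";"-joined codes, ""
#'   when passing)
#' @export
singleSampleFilter <- function(obs, q, minAlt = 4L, minCov = 10L,
                               minVaf = 0.05, minDist = 20L, minBq = 20L,
                               qMax = 0.05, strandP = 0.01,
                               neighbors = NULL) {
  obs <- normaliseCounts(obs)
  n <- nrow(obs)
  stopifnot(length(q) == n)
  vaf <- ifelse(obs$coverage > 0, obs$alt_count / obs$coverage, 0)
  fail <- matrix(FALSE, n, 6,
                 dimnames = list(NULL, c("not_significant", "min_alt_count",
                                         "min_coverage", "min_vaf",
                                         "strand_bias", "proximity")))
  fail[, "not_significant"] <- !(q < qMax)
  fail[, "min_alt_count"] <- altHighBq(obs, minBq,
                                       onlyIfAtLeast = minAlt) < minAlt
  fail[, "min_coverage"] <- obs$coverage < minCov
  fail[, "min_vaf"] <- vaf < minVaf
  ## strand-bias and proximity are defined among candidate (significant)
  ## sites; evaluating them there keeps the pass set identical and the cost
  ## proportional to the number of candidates
  cand <- which(q < qMax)
  if (length(cand) &&
      all(c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev") %in% names(obs))) {
    sb <- strandBiasP(obs$ref_fwd[cand], obs$ref_rev[cand],
                      obs$alt_fwd[cand], obs$alt_rev[cand])
    fail[cand[sb < strandP], "strand_bias"] <- TRUE
  }
  if (length(cand) && all(c("chrom", "pos") %in% names(obs))) {
    if (is.null(neighbors))
      neighbors <- obs[cand, c("chrom", "pos"), drop = FALSE]
    for (i in cand) {
      d <- abs(neighbors$pos - obs$pos[i])
      close <- neighbors$chrom == obs$chrom[i] & d <= minDist & d > 0
      if (any(close)) fail[i, "proximity"] <- TRUE   # both sides removed
    }
  }
  reasons <- rep("", n)
  for (code in colnames(fail)) {
    i <- fail[, code]
    reasons[i] <- ifelse(nzchar(reasons[i]),
                         paste(reasons[i], code, sep = ";"), code)
  }
  data.frame(pass = rowSums(fail) == 0L, reasons = reasons)
}

#' Step-1 single-sample variant calling over a multi-sample count table
#'
#' Fits (or reuses) a beta-binomial error model per sample, computes the
#' upper-tail p-value for every observation, applies BH correction within
#' each sample and then the single-sample post-filters. Rows passing all
#' criteria in at least one sample are the candidate sites for multi-sample
#' re-genotyping.
#'
#' @param counts pileup count table (data.frame) with columns `chrom`,
#'   `pos`, `ref`, `alt`, `individual`, `tissue`, `ref_fwd`, `ref_rev`,
#'   `alt_fwd`, `alt_rev` and optionally `alt_bq`.
#' @param models optional named list of [ErrorModel-class] objects keyed by
#'   `individual.tissue`; fitted from the data when `NULL`.
#' @param pooled fit one pooled error model across samples instead of one
#'   per sample (for sparse cohorts).
#' @param maxFitVaf rows with VAF below this are treated as putatively
#'   homozygous-reference for model fitting (default 0.05).
#' @param minFitSites passed to [fitErrorModel()].
#' @param ... filter settings passed to [singleSampleFilter()].
#' @return list with `calls` (the input table + `p`, `q`, `pass`,
#'   `reasons`), `candidates` (unique passing sites) and `models`.
#' @export
callVariants <- function(counts, models = NULL, pooled = FALSE,
                         maxFitVaf = 0.05, minFitSites = 500L, ...) {
  counts <- normaliseCounts(counts)
  dt <- data.table::as.data.table(counts)
  dt[, `:=`(.sample = paste(individual, tissue, sep = "."))]
  vaf <- ifelse(dt$coverage > 0, dt$alt_count / dt$coverage, 0)
  if (is.null(models)) {
    fitIdx <- which(vaf < maxFitVaf)
    if (pooled) {
      m <- fitErrorModel(as.data.frame(dt[fitIdx]), minFitSites = minFitSites)
      models <- list(pooled = m)
    } else {
      models <- lapply(split(fitIdx, dt$.sample[fitIdx]), function(ix)
        fitErrorModel(as.data.frame(dt[ix]), minFitSites = minFitSites,
                      sample = dt$.sample[ix[1]]))
    }
  }
  ## one vectorised p-value pass: map each row to its model's class params
  cls <- substitutionClass(dt$ref, dt$alt)
  par <- data.table::rbindlist(lapply(names(models), function(s)
    data.table::data.table(.sample = s, errorParams(models[[s]]))))
  if (pooled || length(models) == 1L) {
    i <- match(cls, par$class)
  } else {
    i <- match(paste(dt$.sample, cls), paste(par$.sample, par$class))
    miss <- is.na(i)   # samples without a model: first model's params
    if (any(miss))
      i[miss] <- match(cls[miss], par$class[par$.sample == names(models)[1]])
  }
  pv <- pbetabinomUpper(dt$alt_count, dt$coverage, par$alpha[i], par$beta[i])
  pv[dt$coverage <= 0] <- 1
  dt[, p := pv]
  dt[, q := fdrAdjust(p), by = .sample]
  ## post-filters per sample; proximity among that sample's significant sites
  filterArgs <- list(...)
  idxList <- split(seq_len(nrow(dt)), dt$.sample)
  dt[, pass := FALSE]
  dt[, reasons := ""]
  for (ix in idxList) {
    sub <- as.data.frame(dt[ix])
    flt <- do.call(singleSampleFilter, c(list(sub, sub$q), filterArgs))
    data.table::set(dt, i = ix, j = "pass", value = flt$pass)
    data.table::set(dt, i = ix, j = "reasons", value = flt$reasons)
  }
  calls <- as.data.frame(dt)
  calls$.sample <- NULL
  cand <- unique(calls[calls$pass,
                       c("chrom", "pos", "ref", "alt"), drop = FALSE])
  list(calls = calls, candidates = cand, models = models)
}
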