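siteId <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
}

#' Multi-sample re-genotyping into the 3D genotype array
#'
#' Every site that passed single-sample calling in at least one sample is
#' re-evaluated in every sample with the beta-binomial test but relaxed
#' post-filters (no strand-bias test, no proximity rule, alternative count
#' requirement lowered to 3). Each (site, tissue, individual) cell receives
#' one of four states: `NO_EXPRESSION` (coverage below `cExpr`), `PASS`
#' (significant with `alt >= minAlt` and `VAF >= minVaf`), `LOW_QUALITY`
#' (`alt >= 2` or significant but below the PASS thresholds), else
#' `HOM_REF`. Sites absent from a sample's count table stay missing (`NA`),
#' distinct from `NO_EXPRESSION`.
#'
#' @param candidates data.frame of candidate sites (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @param counts full pileup count table across all samples (same columns
#'   as [callVariants()]).
#' @param models named list of [ErrorModel-class] objects (per sample or a
#'   single pooled model).
#' @param cExpr minimum coverage to count a cell as expressed (default 5).
#' @param qMax significance threshold on the BH-adjusted p (default 0.05).
#' @param minAlt,minVaf relaxed PASS thresholds (defaults 3 and 0.05).
#' @param tissues,individuals optional full axes (so tissues assayed in no
#'   retained row still appear as missing columns).
#' @return a [GenotypeArray-class]
#' @export
recallSites <- function(candidates, counts, models, cExpr = 5L, qMax = 0.05,
                        minAlt = 3L, minVaf = 0.05,
                        tissues = NULL, individuals = NULL) {
  stopifnot(nrow(candidates) > 0L)
  counts <- normaliseCounts(counts)
  dt <- data.table::as.data.table(counts)
  cid <- siteId(candidates$chrom, candidates$pos, candidates$ref,
                candidates$alt)
  dt[, site := siteId(chrom, pos, ref, alt)]
  dt <- dt[site %in% cid]
  dt[, .sample := paste(individual, tissue, sep = ".")]
  ## beta-binomial p per cell under the sample's model
  cls <- substitutionClass(dt$ref, dt$alt)
  par <- data.table::rbindlist(lapply(names(models), function(s)
    data.table::data.table(.sample = s, errorParams(models[[s]]))))
  if (length(models) == 1L) {
    i <- match(cls, par$class)
  } else {
    i <- match(paste(dt$.sample, cls), paste(par$.sample, par$class))
    miss <- is.na(i)
    if (any(miss))
      i[miss] <- match(cls[miss], par$class[par$.sample == names(models)[1]])
  }
  pv <- pbetabinomUpper(dt$alt_count, dt$coverage, par$alpha[i], par$beta[i])
  pv[dt$coverage <= 0] <- 1
  dt[, p := pv]
  dt[, q := fdrAdjust(p), by = .sample]
  vafv <- ifelse(dt$coverage > 0, dt$alt_count / dt$coverage, 0)
  sig <- dt$q < qMax
  st <- integer(nrow(dt))
  st[] <- 2L                                   # HOM_REF
  st[dt$alt_count >= 2L | sig] <- 3L           # LOW_QUALITY
  st[sig & dt$alt_count >= minAlt & vafv >= minVaf] <- 4L  # PASS
  st[dt$coverage < cExpr] <- 1L                # NO_EXPRESSION
  dt[, state := st]
  dt[, vaf := vafv]
  ## LOW_QUALITY cells that are individually significant mark possible
  ## systematic errors; kept for the cohort-level recurrence filter
  dt[, sigLQ := state == 3L & q < qMax]
  buildGenotypeArray(dt, tissues = tissues, individuals = individuals,
                     siteIds = cid,
                     siteInfo = data.frame(
                       site = cid, chrom = candidates$chrom,
                       pos = as.integer(candidates$pos),
                       ref = candidates$ref, alt = candidates$alt,
                       stringsAsFactors = FALSE))
}

buildGenotypeArray <- function(dt, tissues = NULL, individuals = NULL,
                               siteIds = NULL, siteInfo = NULL) {
  if (is.null(siteIds)) siteIds <- unique(dt$site)
  if (is.null(tissues)) tissues <- sort(unique(dt$tissue))
  if (is.null(individuals)) individuals <- sort(unique(dt$individual))
  dn <- list(site = siteIds, tissue = tissues, individual = individuals)
  d <- lengths(dn)
  mk <- function(what, init) {
    a <- array(init, dim = d, dimnames = dn)
    idx <- cbind(match(dt$site, siteIds), match(dt$tissue, tissues),
                 match(dt$individual, individuals))
    a[idx] <- dt[[what]]
    a
  }
  if (is.null(siteInfo)) {
    first <- dt[!duplicated(dt$site)]
    siteInfo <- data.frame(site = first$site, chrom = first$chrom,
                           pos = as.integer(first$pos), ref = first$ref,
                           alt = first$alt, stringsAsFactors = FALSE)
    siteInfo <- siteInfo[match(siteIds, siteInfo$site), ]
  }
  rownames(siteInfo) <- NULL
  arr <- new("GenotypeArray",
             state = mk("state", NA_integer_),
             refCount = mk("ref_count", NA_integer_),
             altCount = mk("alt_count", NA_integer_),
             vafArr = mk("vaf", NA_real_),
             siteInfo = siteInfo)
  if ("sigLQ" %in% names(dt)) {
    attr(arr@state, "sigLQ") <- mk("sigLQ", FALSE)
  }
  arr
}

subsetSites <- function(array, keep) {
  st <- array@state
  sl <- attr(st, "sigLQ")
  sub3 <- function(a) a[keep, , , drop = FALSE]
  st2 <- sub3(st)
  if (!is.null(sl)) attr(st2, "sigLQ") <- sub3(sl)
  new("GenotypeArray", state = st2,
      refCount = sub3(array@refCount), altCount = sub3(array@altCount),
      vafArr = sub3(array@vafArr),
      siteInfo = array@siteInfo[keep, , drop = FALSE])
}

#' Remove germline variants from the genotype array
#'
#' Any site present in ANY individual's germline variant set is removed for
#' the whole cohort (cohort-wide subtraction). Matching is allele-aware on
#' (chrom, pos, ref, alt); the same position with a different alternative
#' allele is retained.
#'
#' @param array a [GenotypeArray-class]
#' @param germline data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (an `individual` column may be present and is ignored for matching),
#'   or a path to a VCF file read via `vcfR`.
#' @return the filtered [GenotypeArray-class]
#' @export
subtractGermline <- function(array, germline) {
  if (is.character(germline)) germline <- readGermlineVcf(germline)
  germline <- as.data.frame(germline)
  if (!nrow(germline)) return(array)
  bad <- !complete.cases(germline[, c("chrom", "pos", "ref", "alt")])
  if (any(bad)) {
    warning(sum(bad), " malformed germline record(s) skipped")
    germline <- germline[!bad, ]
  }
  gid <- siteId(germline$chrom, germline$pos, germline$ref, germline$alt)
  keep <- !(siteInfo(array)$site %in% gid)
  subsetSites(array, keep)
}

#' Read a germline variant set from VCF
#'
#' SNV records only; multi-allelic records are expanded into one row per
#' alternative allele.
#'
#' @param path path to an (uncompressed or gzipped) VCF
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`
#' @export
readGermlineVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts, stringsAsFactors = FALSE)
  }))
  out[nchar(out$ref) == 1L & nchar(out$alt) == 1L, , drop = FALSE]
}

#' Cohort-level artifact filters on the genotype array
#'
#' Removes sites that are unlikely to be genuine mosaic mutations: population
#' allele frequency >= `popAfMax` (boundary inclusive), known RNA-editing
#' sites, overlap with repeat or low-complexity intervals, systematic-error
#' sites, sites detected in the expressed tissues of every individual
#' (systematic errors / editing / de novo germline), sites with significant
#' low-quality calls recurring across more than `lqFrac` of individuals, and
#' sites with PASS calls in more than `maxIndividuals` individuals
#' (mosaic mutations are not expected to recur across a cohort). Filters
#' drop whole sites and never mutate counts, so they commute.
#'
#' @param array a [GenotypeArray-class]
#' @param popAF data.frame (`chrom`, `pos`, `ref`, `alt`, `af`) or NULL.
#' @param editingSites,systematicSites data.frames with `chrom`, `pos` (or
#'   full allele columns) or NULL.
#' @param repeats,lowComplexity interval sets: `GRanges`, a BED file path
#'   (0-based half-open; read via rtracklayer) or a data.frame with
#'   `chrom`, `start`, `end` in BED convention.
#' @param maxIndividuals maximum number of individuals with a PASS call
#'   (default 2).
#' @param lqFrac maximum tolerated fraction of individuals with recurrent
#'   significant LOW_QUALITY calls (default 0.05).
#' @param popAfMax population-frequency cutoff (default 0.01, inclusive).
#' @param countLowQuality also count LOW_QUALITY cells towards the
#'   recurrence-across-individuals rule (default FALSE: PASS only).
#' @return list with `array` (filtered) and `removed` (data.frame site +
#'   ";"-joined filter reasons)
#' @export
cohortFilters <- function(array, popAF = NULL, editingSites = NULL,
                          repeats = NULL, lowComplexity = NULL,
                          systematicSites = NULL, maxIndividuals = 2L,
                          lqFrac = 0.05, popAfMax = 0.01,
                          countLowQuality = FALSE) {
  info <- siteInfo(array)
  st <- array@state
  nSite <- dim(st)[1L]
  drop <- matrix(FALSE, nSite, 7,
                 dimnames = list(NULL, c("pop_af", "editing", "repeat",
                                         "low_complexity", "systematic",
                                         "ubiquitous", "lq_recurrent")))
  matchSites <- function(res) {
    res <- as.data.frame(res)
    if (all(c("ref", "alt") %in% names(res)))
      info$site %in% siteId(res$chrom, res$pos, res$ref, res$alt)
    else paste(info$chrom, info$pos) %in% paste(res$chrom, res$pos)
  }
  if (!is.null(popAF) && nrow(as.data.frame(popAF))) {
    popAF <- as.data.frame(popAF)
    hit <- popAF[popAF$af >= popAfMax, , drop = FALSE]
    drop[, "pop_af"] <- matchSites(hit)
  }
  if (!is.null(editingSites)) drop[, "editing"] <- matchSites(editingSites)
  if (!is.null(systematicSites))
    drop[, "systematic"] <- matchSites(systematicSites)
  if (!is.null(repeats))
    drop[, "repeat"] <- overlapsIntervals(info, repeats)
  if (!is.null(lowComplexity))
    drop[, "low_complexity"] <- overlapsIntervals(info, lowComplexity)
  ## per-individual summaries
  isPass <- !is.na(st) & st == 4L
  passCells <- if (countLowQuality) (!is.na(st) & st >= 3L) else isPass
  nIndCalled <- apply(passCells, c(1, 3), any)        # site x individual
  expressed <- !is.na(st) & st != 1L
  indExpressed <- apply(expressed, c(1, 3), any)
  nExprInd <- rowSums(indExpressed)
  ## "present in expressed tissues of all individuals": every individual
  ## expressing the site carries a PASS, and at least two individuals do
  ubi <- nExprInd >= 2L &
    rowSums(indExpressed & apply(isPass, c(1, 3), any)) == nExprInd
  drop[, "ubiquitous"] <- ubi
  sl <- attr(st, "sigLQ")
  if (!is.null(sl)) {
    ## recurrence evidence: individuals with a significant LOW_QUALITY call
    ## but no PASS at the site (a carrier's own marginal tissues are not
    ## artifact evidence); needs at least two such individuals
    lqOnly <- apply(!is.na(sl) & sl, c(1, 3), any) &
      !apply(isPass, c(1, 3), any)
    drop[, "lq_recurrent"] <- rowSums(lqOnly) >= 2L &
      rowMeans(lqOnly) > lqFrac
  }
  recurrent <- rowSums(nIndCalled) > maxIndividuals
  drop <- cbind(drop, recurrent = recurrent)
  removedIdx <- which(rowSums(drop) > 0L)
  removed <- data.frame(
    site = info$site[removedIdx],
    reasons = apply(drop[removedIdx, , drop = FALSE], 1L, function(r)
      paste(colnames(drop)[r], collapse = ";")))
  list(array = subsetSites(array, rowSums(drop) == 0L), removed = removed)
}

## sites (1-based) vs BED-convention intervals (0-based half-open)
overlapsIntervals <- function(info, intervals) {
  gr <- asIntervalRanges(intervals)
  sitesGr <- GenomicRanges::GRanges(
    info$chrom, IRanges::IRanges(info$pos, width = 1L))
  IRanges::overlapsAny(sitesGr, gr)
}

asIntervalRanges <- function(intervals) {
  if (is(intervals, "GRanges")) return(intervals)
  if (is.character(intervals)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading BED requires the rtracklayer package")
    return(rtracklayer::import(intervals, format = "BED"))
  }
  df <- as.data.frame(intervals)
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$end < df$start | df$start < 0)
  if (length(bad))
    stop("invalid interval coordinates at line(s): ",
         paste(bad, collapse = ", "))
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Serialize / read a genotype array
#'
#' `writeGenotypeArray` writes two TSVs: `<prefix>_states.tsv`, a site x
#' sample table where PASS cells show the alternative base letter, HOM_REF
#' and LOW_QUALITY show `"."`, NO_EXPRESSION shows `"NA"` and cells never
#' assayed show `"-"`; and `<prefix>_cells.tsv`, a long-format companion
#' carrying the full state and the exact reference/alternative counts for
#' every non-missing cell. `readGenotypeArray` reconstructs the identical
#' array from the companion table (lossless round trip).
#'
#' @param array a [GenotypeArray-class]
#' @param prefix output path prefix
#' @return `writeGenotypeArray`: the two file paths, invisibly.
#'   `readGenotypeArray`: a [GenotypeArray-class].
#' @export
writeGenotypeArray <- function(array, prefix) {
  st <- array@state
  info <- siteInfo(array)
  d <- dim(st); dn <- dimnames(st)
  ## display table: sites x (individual.tissue)
  letter <- array("-", dim = d, dimnames = dn)
  letter[!is.na(st) & st == 1L] <- "NA"
  letter[!is.na(st) & (st == 2L | st == 3L)] <- "."
  passIdx <- which(!is.na(st) & st == 4L, arr.ind = TRUE)
  letter[passIdx] <- info$alt[passIdx[, 1L]]
  flat <- matrix(letter, nrow = d[1L])
  colnames(flat) <- as.vector(outer(dn$tissue, dn$individual,
                                    function(t, i) paste(i, t, sep = ".")))
  stTab <- data.frame(info[, c("site", "chrom", "pos", "ref", "alt")],
                      flat, check.names = FALSE)
  fStates <- paste0(prefix, "_states.tsv")
  utils::write.table(stTab, fStates, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ## lossless long-format companion
  nm <- which(!is.na(st), arr.ind = TRUE)
  sl <- attr(st, "sigLQ")
  cells <- data.frame(
    site = dn$site[nm[, 1L]], tissue = dn$tissue[nm[, 2L]],
    individual = dn$individual[nm[, 3L]],
    chrom = info$chrom[nm[, 1L]], pos = info$pos[nm[, 1L]],
    ref = info$ref[nm[, 1L]], alt = info$alt[nm[, 1L]],
    state = CALL_STATES[st[nm]],
    ref_count = array@refCount[nm], alt_count = array@altCount[nm],
    vaf = array@vafArr[nm],
    sig_lq = if (is.null(sl)) FALSE else sl[nm])
  fCells <- paste0(prefix, "_cells.tsv")
  utils::write.table(cells, fCells, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(states = fStates, cells = fCells))
}

#' @rdname writeGenotypeArray
#' @param tissues,individuals optional full axes for the reconstruction
#'   (defaults to those present in the file; supply these to preserve
#'   all-missing columns).
#' @export
readGenotypeArray <- function(prefix, tissues = NULL, individuals = NULL) {
  fCells <- paste0(prefix, "_cells.tsv")
  cells <- utils::read.delim(fCells, stringsAsFactors = FALSE,
                             colClasses = list(chrom = "character",
                                               tissue = "character",
                                               individual = "character"))
  sidx <- match(cells$state, CALL_STATES)
  if (anyNA(sidx)) {
    bad <- which(is.na(sidx))[1L]
    stop(sprintf("unknown state token '%s' at site %s (%s, %s)",
                 cells$state[bad], cells$site[bad], cells$tissue[bad],
                 cells$individual[bad]))
  }
  dt <- data.table::as.data.table(cells)
  dt[, state := sidx]
  dt[, sigLQ := cells$sig_lq]
  buildGenotypeArray(dt, tissues = tissues, individuals = individuals)
}
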