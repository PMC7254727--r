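#' Run the full mosaic-mutation pipeline on a count table
#'
#' Convenience composition of the calling steps: per-sample (or pooled)
#' error-model calling, multi-sample re-genotyping into the 3D genotype
#' array, cohort-wide germline subtraction, cohort-level artifact filters
#' and lineage-tree classification.
#'
#' @param counts pileup count table (see [callVariants()]).
#' @param tree a [LineageTree-class].
#' @param germline germline variant set (data.frame or VCF path), or NULL.
#' @param editingSites,systematicSites,repeats,lowComplexity,popAF cohort
#'   filter resources (see [cohortFilters()]), or NULL.
#' @param pooled fit a pooled error model (default TRUE: a synthetic or
#'   sparse cohort rarely has enough homozygous-reference sites per sample
#'   and class).
#' @param minTissues individual inclusion threshold for classification.
#' @param maxIndividuals cohort recurrence cutoff.
#' @param ... further arguments to [callVariants()].
#' @return list with `step1` (calls + candidates + models), `array` (the
#'   filtered [GenotypeArray-class]), `removed` (site filter log), `calls`
#'   (classified mosaic calls)
#' @export
runPipeline <- function(counts, tree, germline = NULL, editingSites = NULL,
                        systematicSites = NULL, repeats = NULL,
                        lowComplexity = NULL, popAF = NULL, pooled = TRUE,
                        minTissues = 10L, maxIndividuals = 2L, ...) {
  step1 <- callVariants(counts, pooled = pooled, ...)
  if (!nrow(step1$candidates))
    return(list(step1 = step1, array = NULL, removed = NULL,
                calls = data.frame()))
  arr <- recallSites(step1$candidates, counts, step1$models)
  if (!is.null(germline)) arr <- subtractGermline(arr, germline)
  flt <- cohortFilters(arr, popAF = popAF, editingSites = editingSites,
                       repeats = repeats, lowComplexity = lowComplexity,
                       systematicSites = systematicSites,
                       maxIndividuals = maxIndividuals)
  calls <- classifyMosaic(flt$array, tree, minTissues = minTissues)
  list(step1 = step1, array = flt$array, removed = flt$removed,
       calls = calls)
}
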