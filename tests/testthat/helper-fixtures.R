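## Shared fixtures, built once per test run.

fixtureEnv <- new.env()

## 12-tissue subset spanning all germ layers, incl. the flagged leaves
smallTissues <- function() {
  c("brain-cortex", "brain-cerebellum", "skin-sun-exposed",
    "skin-not-sun-exposed", "whole-blood", "heart-left-ventricle",
    "muscle-skeletal", "adrenal-gland", "liver", "lung", "stomach",
    "colon-transverse")
}

## cached noisy cohort used across module tests
smallCohort <- function() {
  if (is.null(fixtureEnv$cohort)) {
    cfg <- simConfig(seed = 3L, nIndividuals = 10L,
                     tissues = smallTissues())
    fixtureEnv$cohort <- simulateCohort(cfg)
    fixtureEnv$config <- cfg
  }
  fixtureEnv$cohort
}

smallConfig <- function() {
  smallCohort()
  fixtureEnv$config
}

## cached step-1 + recall results on the small cohort
smallRecall <- function() {
  if (is.null(fixtureEnv$recall)) {
    cohort <- smallCohort()
    s1 <- callVariants(cohort$counts, pooled = TRUE)
    arr <- recallSites(s1$candidates, cohort$counts, s1$models)
    fixtureEnv$recall <- list(step1 = s1, array = arr)
  }
  fixtureEnv$recall
}

## minimal single-sample observation row
obsRow <- function(ref = "C", alt = "T", altF = 3L, altR = 3L,
                   refF = 50L, refR = 50L, pos = 100L, chrom = "chr1",
                   bq = NULL) {
  altN <- altF + altR
  if (is.null(bq)) bq <- paste(rep(35L, altN), collapse = ",")
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             individual = "ind1", tissue = "liver",
             ref_fwd = refF, ref_rev = refR, alt_fwd = altF,
             alt_rev = altR, alt_bq = bq, stringsAsFactors = FALSE)
}
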