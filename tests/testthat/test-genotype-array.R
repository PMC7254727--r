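## Two-individual, two-tissue toy cohort with hand-planted cells, built in
## code: one clear variant in ind1/liver, a silent tissue, and a missing
## (never assayed) cell.
toyCounts <- function() {
  base <- expand.grid(individual = c("ind1", "ind2"),
                      tissue = c("liver", "lung"),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(base)), function(i)
    cbind(base[i, ], data.frame(chrom = "chr1", pos = 500L, ref = "C",
                                alt = "T", ref_fwd = 50L, ref_rev = 50L,
                                alt_fwd = 0L, alt_rev = 0L, alt_bq = ""))))
  ## carrier cell
  rows$alt_fwd[rows$individual == "ind1" & rows$tissue == "liver"] <- 10L
  rows$alt_rev[rows$individual == "ind1" & rows$tissue == "liver"] <- 10L
  rows$ref_fwd[rows$individual == "ind1" & rows$tissue == "liver"] <- 40L
  rows$ref_rev[rows$individual == "ind1" & rows$tissue == "liver"] <- 40L
  rows$alt_bq[rows$individual == "ind1" & rows$tissue == "liver"] <-
    paste(rep(36L, 20), collapse = ",")
  ## unexpressed cell
  rows[rows$individual == "ind2" & rows$tissue == "lung",
       c("ref_fwd", "ref_rev")] <- 0L
  ## drop ind2/liver entirely -> missing, not NO_EXPRESSION
  rows <- rows[!(rows$individual == "ind2" & rows$tissue == "liver"), ]
  ## null filler sites so the per-sample FDR correction has a backdrop
  fill <- do.call(rbind, lapply(1:30, function(k)
    cbind(expand.grid(individual = c("ind1", "ind2"),
                      tissue = c("liver", "lung"),
                      stringsAsFactors = FALSE),
          data.frame(chrom = "chr1", pos = 1000L + 40L * k, ref = "A",
                     alt = "G", ref_fwd = 50L, ref_rev = 50L,
                     alt_fwd = 0L, alt_rev = 0L, alt_bq = ""))))
  fill <- fill[!(fill$individual == "ind2" & fill$tissue == "liver"), ]
  rbind(rows, fill)
}

toyModels <- function() {
  list(pooled = suppressWarnings(fitErrorModel(NULL)))
}

test_that("re-genotyping assigns exactly the four states and keeps missing cells apart", {
  counts <- toyCounts()
  cand <- data.frame(chrom = "chr1", pos = 500L, ref = "C", alt = "T")
  arr <- recallSites(cand, counts, toyModels())
  st <- arrayStates(arr)
  expect_equal(unname(dim(st)), c(1L, 2L, 2L))
  expect_identical(st["chr1:500:C>T", "liver", "ind1"], "PASS")
  expect_identical(st["chr1:500:C>T", "lung", "ind1"], "HOM_REF")
  expect_identical(st["chr1:500:C>T", "lung", "ind2"], "NO_EXPRESSION")
  ## ind2/liver was never assayed
  expect_true(is.na(st["chr1:500:C>T", "liver", "ind2"]))
  ## counts stored for every non-missing cell
  expect_equal(altCounts(arr)["chr1:500:C>T", "liver", "ind1"], 20L)
  expect_equal(refCounts(arr)["chr1:500:C>T", "liver", "ind1"], 80L)
})

test_that("a step-1 PASS is re-called PASS (re-call criteria are a subset)", {
  cohort <- smallCohort()
  rec <- smallRecall()
  s1pass <- rec$step1$calls[rec$step1$calls$pass, ]
  st <- arrayStates(rec$array)
  sid <- sprintf("%s:%d:%s>%s", s1pass$chrom, s1pass$pos, s1pass$ref,
                 s1pass$alt)
  states <- st[cbind(sid, s1pass$tissue, s1pass$individual)]
  expect_true(all(states == "PASS"))
})

test_that("re-calling the re-called states is idempotent", {
  counts <- toyCounts()
  cand <- data.frame(chrom = "chr1", pos = 500L, ref = "C", alt = "T")
  arr1 <- recallSites(cand, counts, toyModels())
  arr2 <- recallSites(cand, counts, toyModels())
  expect_identical(arrayStates(arr1), arrayStates(arr2))
})

test_that("germline subtraction is cohort-wide and allele-aware", {
  cohort <- smallCohort()
  arr <- smallRecall()$array
  germSite <- cohort$germline[1, ]
  arr2 <- subtractGermline(arr, germSite)
  gid <- sprintf("%s:%d:%s>%s", germSite$chrom, germSite$pos,
                 germSite$ref, germSite$alt)
  expect_false(gid %in% arraySites(arr2))
  ## removed for every individual, not only the carrier
  expect_equal(length(arrayIndividuals(arr2)), length(arrayIndividuals(arr)))
  ## different alt allele at the same position is retained
  other <- data.frame(chrom = germSite$chrom, pos = germSite$pos,
                      ref = germSite$ref,
                      alt = setdiff(c("A", "C", "G", "T"),
                                    c(germSite$ref, germSite$alt))[1])
  arr3 <- subtractGermline(arr, other)
  if (gid %in% arraySites(arr)) expect_true(gid %in% arraySites(arr3))
  ## empty set leaves the array unchanged
  arr4 <- subtractGermline(arr, cohort$germline[0, ])
  expect_identical(arraySites(arr4), arraySites(arr))
})

test_that("cohort filters remove planted artifacts and honor boundaries", {
  cohort <- smallCohort()
  arr <- subtractGermline(smallRecall()$array, cohort$germline)
  ## empty resources, no recurrence beyond planted -> truth sites retained
  flt <- cohortFilters(arr, editingSites = cohort$editingSites)
  edIds <- sprintf("%s:%d:%s>%s", cohort$editingSites$chrom,
                   cohort$editingSites$pos, cohort$editingSites$ref,
                   cohort$editingSites$alt)
  expect_false(any(edIds %in% arraySites(flt$array)))
  ## recurrent artifact sites (PASS in > 2 individuals) removed even
  ## without a resource file
  recIds <- sprintf("%s:%d:%s>%s", cohort$systematicSites$chrom,
                    cohort$systematicSites$pos, cohort$systematicSites$ref,
                    cohort$systematicSites$alt)
  present <- intersect(recIds, arraySites(arr))
  expect_false(any(present %in% arraySites(flt$array)))
  ## popAF boundary: af exactly 0.01 is removed (inclusive)
  info <- siteInfo(flt$array)[1, ]
  pa <- data.frame(chrom = info$chrom, pos = info$pos, ref = info$ref,
                   alt = info$alt, af = 0.01)
  flt2 <- cohortFilters(flt$array, popAF = pa)
  expect_false(info$site %in% arraySites(flt2$array))
  pa$af <- 0.005
  flt3 <- cohortFilters(flt$array, popAF = pa)
  expect_true(info$site %in% arraySites(flt3$array))
})

test_that("cohort filter criteria commute (order-independent surviving set)", {
  cohort <- smallCohort()
  arr <- subtractGermline(smallRecall()$array, cohort$germline)
  a <- cohortFilters(arr, editingSites = cohort$editingSites,
                     systematicSites = cohort$systematicSites)
  b0 <- cohortFilters(arr, systematicSites = cohort$systematicSites)
  b <- cohortFilters(b0$array, editingSites = cohort$editingSites)
  expect_setequal(arraySites(a$array), arraySites(b$array))
})

test_that("interval overlap removal uses BED half-open convention", {
  arr <- smallRecall()$array
  info <- siteInfo(arr)[1, ]
  ## interval covering the site (BED: 0-based half-open)
  bed <- data.frame(chrom = info$chrom, start = info$pos - 1L,
                    end = info$pos)
  flt <- cohortFilters(arr, repeats = bed)
  expect_false(info$site %in% arraySites(flt$array))
  ## interval ending just before the site leaves it alone
  bed2 <- data.frame(chrom = info$chrom, start = info$pos - 10L,
                     end = info$pos - 1L)
  flt2 <- cohortFilters(arr, repeats = bed2)
  expect_true(info$site %in% arraySites(flt2$array))
  expect_error(cohortFilters(arr, repeats = data.frame(
    chrom = "chr1", start = 10, end = 5)), "line")
})

test_that("serialization round-trips states, counts and missingness", {
  counts <- toyCounts()
  cand <- data.frame(chrom = "chr1", pos = 500L, ref = "C", alt = "T")
  arr <- recallSites(cand, counts, toyModels())
  pre <- withr::local_tempfile()
  writeGenotypeArray(arr, pre)
  back <- readGenotypeArray(pre, tissues = arrayTissues(arr),
                            individuals = arrayIndividuals(arr))
  expect_identical(arrayStates(back), arrayStates(arr))
  expect_equal(altCounts(back), altCounts(arr))
  expect_equal(refCounts(back), refCounts(arr))
  ## the display table uses the alt letter for PASS, NA for no expression,
  ## "-" for never-assayed
  states <- utils::read.delim(paste0(pre, "_states.tsv"),
                              check.names = FALSE, na.strings = "",
                              colClasses = "character")
  expect_identical(states[["ind1.liver"]], "T")
  expect_identical(states[["ind2.lung"]], "NA")
  expect_identical(states[["ind2.liver"]], "-")
  expect_identical(states[["ind1.lung"]], ".")
})

test_that("unknown state tokens are rejected with cell coordinates", {
  counts <- toyCounts()
  cand <- data.frame(chrom = "chr1", pos = 500L, ref = "C", alt = "T")
  arr <- recallSites(cand, counts, toyModels())
  pre <- withr::local_tempfile()
  writeGenotypeArray(arr, pre)
  cells <- utils::read.delim(paste0(pre, "_cells.tsv"))
  cells$state[1] <- "BOGUS"
  utils::write.table(cells, paste0(pre, "_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(readGenotypeArray(pre), "BOGUS")
})

test_that("germline VCF round trip through the VCF reader", {
  skip_if_not_installed("vcfR")
  cohort <- smallCohort()
  path <- withr::local_tempfile(fileext = ".vcf")
  writeGermlineVcf(cohort$germline, path)
  back <- readGermlineVcf(path)
  orig <- unique(cohort$germline[, c("chrom", "pos", "ref", "alt")])
  expect_equal(nrow(back), nrow(orig))
  expect_setequal(paste(back$chrom, back$pos, back$ref, back$alt),
                  paste(orig$chrom, orig$pos, orig$ref, orig$alt))
})
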