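test_that("the default tree has the germ-layer structure and flags", {
  tr <- defaultLineageTree()
  expect_setequal(
    names(which(tr@parent == treeRoot(tr))), c("ectoderm", "mesendoderm"))
  expect_equal(length(treeLeaves(tr)), 49L)
  expect_equal(length(tissueLeaf(tr)), 49L)
  expect_identical(dualOriginLeaves(tr), "adrenal-gland")
  expect_setequal(clonalExpansionLeaves(tr),
                  c("skin-sun-exposed", "esophagus-mucosa", "whole-blood"))
})

test_that("tree construction rejects duplicate and unmapped leaves", {
  expect_error(LineageTree(rbind(c("zygote", "ectoderm"),
                                 c("zygote", "mesendoderm"),
                                 c("ectoderm", "skin"),
                                 c("mesendoderm", "skin"))),
               "duplicate")
  expect_error(LineageTree(rbind(c("zygote", "ectoderm"),
                                 c("zygote", "mesendoderm"),
                                 c("ectoderm", "skin"),
                                 c("mesendoderm", "liver")),
                           tissueMap = c(kidney = "kidney-leaf")),
               "kidney")
})

test_that("JSON and Newick round trips preserve topology", {
  tr <- defaultLineageTree()
  path <- withr::local_tempfile(fileext = ".json")
  writeLineageTree(tr, path)
  back <- loadLineageTree(path)
  expect_setequal(treeNodes(back), treeNodes(tr))
  expect_identical(back@parent[sort(names(back@parent))],
                   tr@parent[sort(names(tr@parent))])
  expect_identical(sort(tissueLeaf(back)), sort(tissueLeaf(tr)))
  ## Newick: check isomorphism through ape's unrooted topology distance
  nwk <- treeToNewick(tr)
  back2 <- lineageTreeFromNewick(nwk)
  ph1 <- ape::read.tree(text = nwk)
  ph2 <- ape::read.tree(text = treeToNewick(back2))
  expect_equal(ape::dist.topo(ape::unroot(ph1), ape::unroot(ph2)), 0,
               ignore_attr = TRUE)
})

test_that("ancestral node is the LCA, with adrenal excluded across germ layers", {
  tr <- defaultLineageTree()
  expect_identical(ancestralNode("lung", tr), "lung")
  expect_identical(ancestralNode(c("brain-cortex", "liver"), tr), "zygote")
  expect_identical(ancestralNode(c("brain-cortex", "brain-cerebellum"), tr),
                   "neural")
  expect_identical(ancestralNode(c("whole-blood", "liver"), tr),
                   "mesendoderm")
  ## adrenal + cortex would span layers; exclusion pins it to the cortex
  expect_identical(ancestralNode(c("adrenal-gland", "brain-cortex"), tr),
                   "brain-cortex")
  expect_error(ancestralNode(character(), tr), "at least one")
})

test_that("LCA can only move shallower when a tissue is removed", {
  tr <- defaultLineageTree()
  set.seed(21)
  tis <- names(tissueLeaf(tr))
  for (i in 1:25) {
    pick <- sample(tis, sample(2:6, 1))
    full <- ancestralNode(pick, tr)
    sub <- ancestralNode(pick[-1], tr)
    ## ancestor set of the subset's LCA must contain the full LCA
    expect_true(full %in% c(sub, rnamosaic:::ancestorPath(tr, sub)))
  }
})

test_that("coherence applies the per-branch detection fraction rule", {
  tr <- defaultLineageTree()
  ecto <- names(tissueLeaf(tr))[rnamosaic:::germLayerOf(
    tr, names(tissueLeaf(tr))) == "ectoderm"]
  endo <- c("liver", "lung", "stomach", "pancreas", "colon-sigmoid",
            "colon-transverse", "small-intestine", "thyroid",
            "esophagus-mucosa")
  ## 1 of 8 expressed ectoderm + 1 of 9 expressed endoderm: 1/8 < 0.2
  passT <- c(ecto[1], endo[1])
  exprT <- c(ecto[1:8], endo[1:9])
  expect_false(coherence(passT, exprT, "zygote", tr, fMin = 0.2))
  ## each branch's only expressed tissue is PASS -> coherent
  expect_true(coherence(passT, passT, "zygote", tr, fMin = 0.2))
  ## full detection is always coherent
  expect_true(coherence(exprT, exprT, "zygote", tr, fMin = 0.2))
})

test_that("classification follows the timing rules on constructed calls", {
  tr <- defaultLineageTree()
  tis <- names(tissueLeaf(tr))
  inds <- c("indA", "indB")
  mkArray <- function(passMap, vaf = 0.18, altReads = 20L, nExprAll = TRUE) {
    ## one site per entry of passMap (a list of tissue vectors), all cells
    ## expressed, VAF attached to PASS cells
    dt <- data.table::rbindlist(lapply(seq_along(passMap), function(i) {
      cells <- data.table::CJ(tissue = tis, individual = inds,
                              sorted = FALSE)
      cells[, site := sprintf("chr1:%d:C>T", 1000L + i)]
      cells[, chrom := "chr1"]; cells[, pos := 1000L + i]
      cells[, ref := "C"]; cells[, alt := "T"]
      isPass <- cells$tissue %in% passMap[[i]] & cells$individual == "indA"
      cells[, state := ifelse(isPass, 4L, 2L)]
      v <- if (length(vaf) >= i) vaf[[i]] else vaf[[1]]
      a <- if (length(altReads) >= i) altReads[[i]] else altReads[[1]]
      cells[, vaf := ifelse(isPass, v, 0)]
      cells[, alt_count := ifelse(isPass, a, 0L)]
      cells[, ref_count := 100L]
      cells
    }))
    rnamosaic:::buildGenotypeArray(dt, tissues = tis, individuals = inds)
  }
  arr <- mkArray(list(
    c("brain-cortex", "skin-not-sun-exposed", "liver"),   # EEMM
    c("heart-left-ventricle", "whole-blood"),             # MEMM (mesoderm)
    "esophagus-mucosa",                                   # clonal -> SOMATIC
    "liver",                                              # LEMM
    c("adrenal-gland", "brain-cortex")),                  # adrenal rule
    vaf = list(0.18, 0.18, 0.3, 0.25, 0.18),
    altReads = list(20L, 20L, 30L, 25L, 20L))
  calls <- classifyMosaic(arr, tr, minTissues = 10L)
  k <- setNames(calls$klass, calls$site)
  expect_identical(unname(k["chr1:1001:C>T"]), "EEMM")
  expect_identical(unname(k["chr1:1002:C>T"]), "MEMM")
  expect_identical(unname(k["chr1:1003:C>T"]), "SOMATIC")
  expect_identical(unname(k["chr1:1004:C>T"]), "LEMM")
  expect_false(k[["chr1:1005:C>T"]] == "EEMM")
  ## classification is a partition: one class per call
  expect_equal(anyDuplicated(paste(calls$site, calls$individual)), 0L)
})

test_that("high-VAF and ubiquitous calls are flagged as de novo suspects", {
  tr <- defaultLineageTree()
  tis <- names(tissueLeaf(tr))[1:12]
  dt <- data.table::rbindlist(lapply(1:2, function(i) {
    cells <- data.table::CJ(tissue = tis, individual = c("i1", "i2"),
                            sorted = FALSE)
    cells[, site := sprintf("chr1:%d:C>T", i)]
    cells[, chrom := "chr1"]; cells[, pos := i]
    cells[, ref := "C"]; cells[, alt := "T"]
    carrier <- cells$individual == "i1"
    if (i == 1L) {            # ubiquitous at modest VAF
      cells[, state := ifelse(carrier, 4L, 2L)]
      cells[, vaf := ifelse(carrier, 0.2, 0)]
    } else {                  # high VAF in a tissue subset
      isPass <- carrier & cells$tissue %in% tis[1:5]
      cells[, state := ifelse(isPass, 4L, 2L)]
      cells[, vaf := ifelse(isPass, 0.45, 0)]
    }
    cells[, alt_count := as.integer(vaf * 100)]
    cells[, ref_count := as.integer(100 - vaf * 100)]
    cells
  }))
  arr <- rnamosaic:::buildGenotypeArray(dt, tissues = tis,
                                        individuals = c("i1", "i2"))
  calls <- classifyMosaic(arr, tr, minTissues = 10L)
  expect_true(all(calls$klass == "DENOVO_SUSPECT"))
})

test_that("individuals failing inclusion are skipped with a message", {
  tr <- defaultLineageTree()
  tis <- names(tissueLeaf(tr))[1:4]      # too few tissues
  cells <- data.table::CJ(tissue = tis, individual = "solo", sorted = FALSE)
  cells[, site := "chr1:10:C>T"]
  cells[, chrom := "chr1"]; cells[, pos := 10L]
  cells[, ref := "C"]; cells[, alt := "T"]
  cells[, state := c(4L, 2L, 2L, 2L)]
  cells[, vaf := c(0.25, 0, 0, 0)]
  cells[, alt_count := c(25L, 0L, 0L, 0L)]; cells[, ref_count := 75L]
  arr <- rnamosaic:::buildGenotypeArray(dt <- cells, tissues = tis,
                                        individuals = "solo")
  expect_message(calls <- classifyMosaic(arr, tr, minTissues = 10L),
                 "inclusion")
  expect_equal(nrow(calls), 0L)
  expect_identical(attr(calls, "skipped"), "solo")
})

test_that("noise-free simulated cohorts are classified exactly", {
  cfg <- simConfig(seed = 8L, nIndividuals = 8L, tissues = smallTissues(),
                   readNoise = FALSE)
  cohort <- simulateCohort(cfg)
  res <- runPipeline(cohort$counts, cfg$tree, germline = cohort$germline,
                     editingSites = cohort$editingSites)
  tc <- cohort$truthClasses
  tk <- paste(tc$site, tc$individual)
  ck <- paste(res$calls$site, res$calls$individual)
  ## zero false positives
  expect_true(all(ck %in% tk))
  ## every ideal-detectable mutation recovered, classes identical
  det <- tc[tc$klass != "UNDETECTABLE", ]
  expect_true(all(paste(det$site, det$individual) %in% ck))
  m <- match(ck, tk)
  expect_identical(res$calls$klass, tc$klass[m])
})

test_that("VAF/tissue-support correlations behave as the halving model predicts", {
  ## strictly increasing VAF with support -> rho = 1
  calls <- data.frame(mean_vaf = c(0.05, 0.1, 0.2, 0.3),
                      n_pass = 1:4, node_depth = c(4L, 3L, 2L, 1L))
  ct <- vafTissueCorrelation(calls)
  expect_equal(ct$rho[ct$relation == "mean_vaf~n_pass"], 1)
  expect_equal(ct$rho[ct$relation == "node_depth~mean_vaf"], -1)
  ## permuted VAFs decorrelate
  set.seed(31)
  n <- 200
  perm <- data.frame(mean_vaf = sample(runif(n)), n_pass = sample(1:6, n,
                                                                  TRUE),
                     node_depth = sample(1:5, n, TRUE))
  cp <- vafTissueCorrelation(perm)
  expect_true(all(abs(cp$rho) < 0.2))
  ## calls drawn from the cell-fraction-halving model: one extra division
  ## per depth level halves the carrier fraction, so depth anti-correlates
  ## with VAF
  set.seed(32)
  depth <- sample(0:4, 300, replace = TRUE)
  halv <- data.frame(
    mean_vaf = 0.5^(depth + 1) * exp(rnorm(300, 0, 0.25)),
    n_pass = pmax(1L, rpois(300, 6 - depth)),
    node_depth = depth)
  ch <- vafTissueCorrelation(halv)
  expect_lt(ch$rho[ch$relation == "node_depth~mean_vaf"], -0.5)
  expect_gt(ch$rho[ch$relation == "mean_vaf~n_pass"], 0)
  ## constant input is flagged undefined
  const <- data.frame(mean_vaf = rep(0.1, 5), n_pass = rep(2L, 5),
                      node_depth = rep(2L, 5))
  cc <- vafTissueCorrelation(const)
  expect_false(any(cc$defined))
})
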