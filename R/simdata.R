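#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort generator. Mutations are
#' placed per (lineage node, cell division) as Poisson counts with rate
#' `mutationsPerDivision * regionFraction` (three genome-wide mutations per
#' cell per division during early embryogenesis, scaled to the monitored
#' target region). A mutation at division `d` of its lineage starts at cell
#' fraction `0.5^d` there and is propagated to descendant lineages through
#' binomial founder-cell sampling (`founderCells` cells per lineage split),
#' which both preserves the expected VAF of `0.5^(d+1)` (diploid
#' heterozygous, VAF = cell fraction / 2) and generates the lineage dropout
#' seen in real cohorts. Sequencing noise is beta-binomial per substitution
#' class; coverage is negative binomial; per-gene-per-tissue expression
#' dropout silences sites.
#'
#' @param seed integer seed; fully determines the cohort.
#' @param nIndividuals number of individuals.
#' @param tree a [LineageTree-class] (default [defaultLineageTree()]).
#' @param tissues optional tissue subset (tree is pruned).
#' @param zygoteDivisions divisions modeled at the zygote (default 3:
#'   cleavage through implantation).
#' @param nodeDivisions divisions modeled per later node (default 2).
#' @param mutationsPerDivision genome-wide mutations per cell division
#'   (default 3).
#' @param regionFraction fraction of the genome monitored (default 0.04,
#'   an up-scaled target region that yields a few hundred mutations in a
#'   50-individual cohort; a 13.6-Mbp panel would be ~0.004).
#' @param founderCells founder cells sampled at each lineage split
#'   (default 8; `Inf` disables drift).
#' @param asymmetric use Dirichlet-weighted (unequal) contributions of
#'   early cells at each split (default FALSE = symmetric).
#' @param coverageMean,coverageDispersion negative-binomial coverage model
#'   (defaults 100 and 0.3; dispersion 0 = fixed coverage).
#' @param errorAlpha,errorBeta beta-binomial error shapes applied to every
#'   substitution class (defaults 2 and 1998: mean error 1e-3, mildly
#'   overdispersed).
#' @param dropoutProb per-gene-per-tissue expression dropout (default 0.1).
#' @param readNoise simulate read sampling (binomial alt reads plus error
#'   reads); FALSE gives deterministic counts `alt = round(cov * VAF)` and
#'   no error reads (the noise-free mode).
#' @param nGenes,nHomRef gene-panel size and homozygous-reference
#'   monitoring sites (defaults 60 and 600).
#' @param nGermline,nEditing,nRecurrent planted artifact counts: germline
#'   het variants per individual, cohort-wide RNA-editing sites, recurrent
#'   systematic-error sites (defaults 4, 8, 5).
#' @return a list of class `simConfig`
#' @export
simConfig <- function(seed = 1L, nIndividuals = 10L, tree = NULL,
                      tissues = NULL, zygoteDivisions = 3L,
                      nodeDivisions = 2L, mutationsPerDivision = 3,
                      regionFraction = 0.04, founderCells = 8,
                      asymmetric = FALSE, coverageMean = 100,
                      coverageDispersion = 0.3, errorAlpha = 2,
                      errorBeta = 1998, dropoutProb = 0.1,
                      readNoise = TRUE, nGenes = 60L, nHomRef = 600L,
                      nGermline = 4L, nEditing = 8L, nRecurrent = 5L) {
  if (is.null(tree)) tree <- defaultLineageTree()
  if (!is.null(tissues)) tree <- pruneLineageTree(tree, tissues)
  stopifnot(mutationsPerDivision >= 0, regionFraction >= 0,
            coverageMean > 0, errorAlpha > 0, errorBeta > 0,
            dropoutProb >= 0, dropoutProb < 1)
  cfg <- list(seed = as.integer(seed), nIndividuals = as.integer(nIndividuals),
              tree = tree, tissues = names(tissueLeaf(tree)),
              zygoteDivisions = zygoteDivisions,
              nodeDivisions = nodeDivisions,
              mutationsPerDivision = mutationsPerDivision,
              regionFraction = regionFraction, founderCells = founderCells,
              asymmetric = asymmetric, coverageMean = coverageMean,
              coverageDispersion = coverageDispersion,
              errorAlpha = errorAlpha, errorBeta = errorBeta,
              dropoutProb = dropoutProb, readNoise = readNoise,
              nGenes = as.integer(nGenes), nHomRef = as.integer(nHomRef),
              nGermline = as.integer(nGermline),
              nEditing = as.integer(nEditing),
              nRecurrent = as.integer(nRecurrent))
  class(cfg) <- "simConfig"
  cfg
}

## gene panel: chrom/interval/exonic length per gene
simGenePanel <- function(config) {
  set.seed(config$seed + 11L)
  n <- config$nGenes
  len <- round(runif(n, 1000, 3000))
  start <- seq_len(n) * 1e6L
  data.frame(gene = sprintf("gene%03d", seq_len(n)), chrom = "chr1",
             start = start, end = start + len, exonic_length = len,
             base_tpm = exp(stats::rnorm(n, 3, 1)),
             stringsAsFactors = FALSE)
}

## expression dropout matrix gene x tissue (shared across individuals)
simExpressedMatrix <- function(config, genes) {
  set.seed(config$seed + 12L)
  tis <- config$tissues
  m <- matrix(runif(nrow(genes) * length(tis)) >= config$dropoutProb,
              nrow(genes), length(tis),
              dimnames = list(genes$gene, tis))
  m
}

## propagate a carrier fraction from an origin node to all leaves
propagateFraction <- function(tree, origin, f0, founderCells, asymmetric) {
  frac <- setNames(numeric(length(treeNodes(tree))), treeNodes(tree))
  frac[origin] <- f0
  ## breadth-first below origin
  queue <- origin
  while (length(queue)) {
    node <- queue[[1L]]; queue <- queue[-1L]
    kids <- childrenOf(tree, node)
    for (k in kids) {
      f <- frac[[node]]
      if (is.finite(founderCells) && f > 0 && f < 1) {
        if (asymmetric) {
          ## unequal parental-cell contribution: weight carrier cells
          w <- stats::rgamma(2, shape = 1)
          f <- f * w[1L] / mean(w)
          f <- min(f, 1)
        }
        f <- stats::rbinom(1L, founderCells, f) / founderCells
      }
      frac[k] <- f
      queue <- c(queue, k)
    }
  }
  tm <- tissueLeaf(tree)
  setNames(frac[unname(tm)], names(tm))
}

#' Place mosaic mutations on the lineage tree
#'
#' For every individual, node and division, draws a Poisson number of
#' mutations and propagates their carrier fractions to the tissues. True
#' VAF is cell fraction / 2 (diploid heterozygous, no allele-specific
#' expression).
#'
#' @param config a [simConfig()]
#' @return list with `truth` (data.frame: site, gene, chrom, pos, ref,
#'   alt, individual, origin_node, division) and `tissueVaf` (matrix
#'   mutation x tissue of true VAFs)
#' @export
simulateLineageMutations <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  genes <- simGenePanel(config)
  tree <- config$tree
  set.seed(config$seed + 13L)
  nodes <- treeNodes(tree)
  divs <- setNames(rep(config$nodeDivisions, length(nodes)), nodes)
  divs[treeRoot(tree)] <- config$zygoteDivisions
  mu <- config$mutationsPerDivision * config$regionFraction
  rows <- list(); vafs <- list()
  bases <- c("A", "C", "G", "T")
  usedPos <- integer()
  for (ind in sprintf("ind%03d", seq_len(config$nIndividuals))) {
    for (node in nodes) {
      for (d in seq_len(divs[[node]])) {
        nMut <- stats::rpois(1L, mu)
        if (nMut == 0L) next
        for (m in seq_len(nMut)) {
          g <- sample.int(nrow(genes), 1L)
          repeat {
            pos <- genes$start[g] +
              sample.int(genes$end[g] - genes$start[g], 1L)
            if (!pos %in% usedPos) break
          }
          usedPos <- c(usedPos, pos)
          ref <- sample(bases, 1L)
          alt <- sample(setdiff(bases, ref), 1L)
          frac <- propagateFraction(tree, node, 0.5^d,
                                    config$founderCells,
                                    config$asymmetric)
          rows[[length(rows) + 1L]] <- data.frame(
            site = siteId(genes$chrom[g], pos, ref, alt),
            gene = genes$gene[g], chrom = genes$chrom[g], pos = pos,
            ref = ref, alt = alt, individual = ind, origin_node = node,
            division = d, stringsAsFactors = FALSE)
          vafs[[length(rows)]] <- frac / 2
        }
      }
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = character(), gene = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               individual = character(), origin_node = character(),
               division = integer())
  tv <- if (length(vafs)) do.call(rbind, vafs) else
    matrix(0, 0, length(config$tissues),
           dimnames = list(NULL, config$tissues))
  rownames(tv) <- truth$site
  list(truth = truth, tissueVaf = tv, genes = genes)
}

## deterministic ideal-observer genotype array from truth VAFs: PASS where
## the gene is expressed and the true VAF clears the detection threshold
idealTruthArray <- function(sim, expressed, config, minVaf = 0.05,
                            idealCov = 10000L) {
  truth <- sim$truth
  tv <- sim$tissueVaf
  tis <- config$tissues
  inds <- sprintf("ind%03d", seq_len(config$nIndividuals))
  cells <- data.table::CJ(mi = seq_len(nrow(truth)), tissue = tis,
                          individual = inds, sorted = FALSE)
  cells[, site := truth$site[mi]]
  cells[, gene := truth$gene[mi]]
  expr <- expressed[cbind(cells$gene, cells$tissue)]
  carrier <- cells$individual == truth$individual[cells$mi]
  v <- ifelse(carrier,
              tv[cbind(cells$mi, match(cells$tissue, colnames(tv)))], 0)
  st <- ifelse(!expr, 1L, ifelse(v >= minVaf, 4L, 2L))
  dt <- data.table::data.table(
    site = cells$site, tissue = cells$tissue,
    individual = cells$individual,
    chrom = truth$chrom[cells$mi], pos = truth$pos[cells$mi],
    ref = truth$ref[cells$mi], alt = truth$alt[cells$mi],
    state = st, alt_count = as.integer(round(idealCov * v)),
    ref_count = as.integer(idealCov - round(idealCov * v)), vaf = v)
  buildGenotypeArray(dt, tissues = tis, individuals = inds,
                     siteIds = unique(truth$site))
}

#' Simulate the pileup count table and companion inputs
#'
#' Generates per-cell coverage (negative binomial), carrier alt reads
#' (binomial at the true VAF), beta-binomial error reads, symmetric strand
#' split and base qualities for every site x tissue x individual cell,
#' plus planted germline variants, RNA-editing sites, recurrent artifact
#' sites and a homozygous-reference monitoring panel; also emits the
#' per-sample expression table and technical covariates.
#'
#' @param sim output of [simulateLineageMutations()]
#' @param config the same [simConfig()]
#' @return list with `counts` (data.frame, pileup dialect), `expression`
#'   (gene x sample long table with `tpm` and `cov`), `germline`
#'   (data.frame chrom/pos/ref/alt/individual), `editingSites`,
#'   `systematicSites` (recurrent artifacts, for reference),
#'   `covariates`, `expressed` (gene x tissue logical), `truthClasses`
#'   (ideal-observer classification of every planted mutation)
#' @export
simulateCounts <- function(sim, config) {
  stopifnot(inherits(config, "simConfig"))
  genes <- sim$genes
  tree <- config$tree
  tis <- config$tissues
  inds <- sprintf("ind%03d", seq_len(config$nIndividuals))
  expressed <- simExpressedMatrix(config, genes)
  set.seed(config$seed + 14L)
  bases <- c("A", "C", "G", "T")
  newSites <- function(n, tag) {
    g <- sample.int(nrow(genes), n, replace = TRUE)
    pos <- genes$start[g] + sample.int(900, n, replace = TRUE) + 50L
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    data.frame(site = siteId(genes$chrom[g], pos, ref, alt),
               gene = genes$gene[g], chrom = genes$chrom[g], pos = pos,
               ref = ref, alt = unname(alt), type = tag,
               stringsAsFactors = FALSE)
  }
  truthSites <- if (nrow(sim$truth))
    cbind(sim$truth[, c("site", "gene", "chrom", "pos", "ref", "alt")],
          type = "truth") else NULL
  germ <- newSites(config$nGermline * config$nIndividuals, "germline")
  germ$individual <- rep(inds, each = config$nGermline)
  edit <- newSites(config$nEditing, "editing")
  recur <- newSites(config$nRecurrent, "recurrent")
  ## homozygous-reference panel balanced over the 6 substitution classes
  nHR <- config$nHomRef
  hrClass <- rep(SUBSTITUTION_CLASSES, length.out = nHR)
  hrRef <- sub(">.*", "", hrClass)
  hrAlt <- sub(".*>", "", hrClass)
  hr <- newSites(nHR, "homref")
  hr$ref <- hrRef; hr$alt <- hrAlt
  hr$site <- siteId(hr$chrom, hr$pos, hr$ref, hr$alt)
  sites <- rbind(truthSites,
                 germ[, names(germ) != "individual"], edit, recur, hr)
  sites <- sites[!duplicated(sites$site), ]
  nS <- nrow(sites)
  ## full cell grid
  grid <- data.table::CJ(s = seq_len(nS), tissue = tis, individual = inds,
                         sorted = FALSE)
  grid[, gene := sites$gene[s]]
  expr <- expressed[cbind(grid$gene, grid$tissue)]
  nC <- nrow(grid)
  cov <- integer(nC)
  if (config$coverageDispersion > 0 && config$readNoise) {
    cov[expr] <- stats::rnbinom(sum(expr),
                                size = 1 / config$coverageDispersion,
                                mu = config$coverageMean)
  } else {
    cov[expr] <- as.integer(round(config$coverageMean))
  }
  ## true VAF per cell
  v <- numeric(nC)
  if (!is.null(truthSites) && nrow(sim$truth)) {
    ti <- match(sites$site[grid$s], sim$truth$site)
    isTruth <- !is.na(ti)
    carrier <- isTruth & grid$individual == sim$truth$individual[ti]
    v[carrier] <- sim$tissueVaf[cbind(
      ti[carrier], match(grid$tissue[carrier], colnames(sim$tissueVaf)))]
  }
  gIdx <- match(sites$site[grid$s], germ$site)
  isGermCell <- !is.na(gIdx) & grid$individual == germ$individual[gIdx]
  v[isGermCell] <- 0.5
  eIdx <- match(sites$site[grid$s], edit$site)
  set.seed(config$seed + 15L)
  editInds <- lapply(seq_len(nrow(edit)), function(i)
    sample(inds, min(length(inds), max(3L, round(0.6 * length(inds))))))
  isEdit <- !is.na(eIdx)
  isEdit[isEdit] <- mapply(function(e, ind) ind %in% editInds[[e]],
                           eIdx[isEdit], grid$individual[isEdit])
  v[isEdit] <- 0.3
  rIdx <- match(sites$site[grid$s], recur$site)
  recurInds <- lapply(seq_len(nrow(recur)), function(i)
    sample(inds, min(length(inds), max(4L, round(0.3 * length(inds))))))
  isRec <- !is.na(rIdx)
  isRec[isRec] <- mapply(function(e, ind) ind %in% recurInds[[e]],
                         rIdx[isRec], grid$individual[isRec])
  v[isRec] <- 0.2
  ## read sampling
  set.seed(config$seed + 16L)
  if (config$readNoise) {
    altTrue <- stats::rbinom(nC, cov, v)
    err <- rbetabinom(nC, pmax(cov - altTrue, 0L),
                      config$errorAlpha, config$errorBeta)
    altN <- pmin(altTrue + err, cov)
  } else {
    altN <- as.integer(round(cov * v))
  }
  refN <- cov - altN
  altF <- stats::rbinom(nC, altN, 0.5)
  refF <- stats::rbinom(nC, refN, 0.5)
  ## base qualities for alternative reads
  bq <- rep("", nC)
  withAlt <- which(altN > 0L)
  if (length(withAlt)) {
    allQ <- pmin(40L, pmax(2L, round(stats::rnorm(sum(altN[withAlt]),
                                                  35, 3))))
    splitIdx <- rep(seq_along(withAlt), altN[withAlt])
    bq[withAlt] <- vapply(split(allQ, splitIdx), paste,
                          character(1), collapse = ",")
  }
  counts <- data.frame(
    chrom = sites$chrom[grid$s], pos = sites$pos[grid$s],
    ref = sites$ref[grid$s], alt = sites$alt[grid$s],
    individual = grid$individual, tissue = grid$tissue,
    ref_fwd = refF, ref_rev = refN - refF,
    alt_fwd = altF, alt_rev = altN - altF,
    alt_bq = bq, stringsAsFactors = FALSE)
  ## expression table (per sample) and covariates
  set.seed(config$seed + 17L)
  eg <- data.table::CJ(gene = genes$gene, tissue = tis, individual = inds,
                       sorted = FALSE)
  onoff <- expressed[cbind(eg$gene, eg$tissue)]
  baseT <- genes$base_tpm[match(eg$gene, genes$gene)]
  expression <- data.frame(
    gene = eg$gene, sample = paste(eg$individual, eg$tissue, sep = "."),
    individual = eg$individual, tissue = eg$tissue,
    tpm = ifelse(onoff, baseT * exp(stats::rnorm(nrow(eg), 0, 0.2)), 0),
    cov = ifelse(onoff, config$coverageMean *
                   exp(stats::rnorm(nrow(eg), 0, 0.1)), 0),
    stringsAsFactors = FALSE)
  covariates <- data.frame(
    sample = as.vector(outer(tis, inds, function(t, i)
      paste(i, t, sep = "."))),
    tissue = rep(tis, times = length(inds)),
    individual = rep(inds, each = length(tis)),
    duplicates = runif(length(tis) * length(inds), 0.05, 0.4),
    cohort = sample(c("siteA", "siteB"), length(tis) * length(inds),
                    replace = TRUE),
    rin = stats::rnorm(length(tis) * length(inds), 7.5, 0.8),
    trischd = stats::rnorm(length(tis) * length(inds), 400, 150),
    dp_median = config$coverageMean *
      exp(stats::rnorm(length(tis) * length(inds), 0, 0.05)),
    stringsAsFactors = FALSE)
  ages <- setNames(round(runif(length(inds), 20, 75)), inds)
  covariates$age <- ages[covariates$individual]
  truthClasses <- NULL
  if (nrow(sim$truth)) {
    ideal <- idealTruthArray(sim, expressed, config)
    tc <- classifyMosaic(ideal, tree)
    key <- paste(sim$truth$site, sim$truth$individual)
    hit <- match(key, paste(tc$site, tc$individual))
    truthClasses <- cbind(sim$truth,
                          klass = ifelse(is.na(hit), "UNDETECTABLE",
                                         tc$klass[hit]),
                          max_true_vaf = apply(sim$tissueVaf, 1L, max),
                          max_expressed_vaf = vapply(
                            seq_len(nrow(sim$truth)), function(i) {
                              e <- expressed[sim$truth$gene[i], ]
                              if (!any(e)) 0 else
                                max(sim$tissueVaf[i, names(e)[e]])
                            }, numeric(1)))
  }
  list(counts = counts,
       expression = expression,
       germline = germ[, c("chrom", "pos", "ref", "alt", "individual")],
       editingSites = edit[, c("chrom", "pos", "ref", "alt")],
       systematicSites = recur[, c("chrom", "pos", "ref", "alt")],
       covariates = covariates, expressed = expressed,
       truthClasses = truthClasses, sites = sites)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: [simulateLineageMutations()] +
#' [simulateCounts()].
#'
#' @param config a [simConfig()]
#' @return the [simulateCounts()] list plus `truth`, `tissueVaf`,
#'   `genes`, `config`
#' @export
simulateCohort <- function(config) {
  sim <- simulateLineageMutations(config)
  out <- simulateCounts(sim, config)
  c(out, list(truth = sim$truth, tissueVaf = sim$tissueVaf,
              genes = sim$genes, config = config))
}

#' Simulate labeled calls for the random-forest filter
#'
#' Emulates the construction of a labeled variant set: true calls are
#' carrier sites with VAFs spread over (0, 1); false calls are half
#' error-driven (low VAF, low base quality, strand bias) and half
#' artifact-like (editing / systematic errors: any VAF, biased strands,
#' enriched in blacklisted genes), so every VAF stratum holds both
#' classes. Labels follow the truth rule (true iff truth VAF >= 5\% with
#' >= 2 supporting truth reads).
#'
#' @param n total number of calls (default 2000, half per origin).
#' @param seed RNG seed.
#' @param separable widen the feature gap between classes (for
#'   sanity-check fits; default FALSE).
#' @param errorAlpha,errorBeta error model for false-call alt reads.
#' @return data.frame with the feature columns, `truth_vaf`, `truth_alt`
#'   and `label`
#' @export
simulateLabeledCalls <- function(n = 2000L, seed = 1L, separable = FALSE,
                                 errorAlpha = 2, errorBeta = 998) {
  set.seed(seed)
  nTrue <- n %/% 2L
  nFalse <- n - nTrue
  nErr <- nFalse %/% 2L
  nArt <- nFalse - nErr
  ## true-origin calls
  tv <- runif(nTrue, 0.02, 0.98)
  covT <- stats::rnbinom(nTrue, size = 4, mu = 120) + 10L
  altT <- stats::rbinom(nTrue, covT, tv)
  truthCov <- stats::rnbinom(nTrue, size = 4, mu = 100) + 10L
  truthAltT <- stats::rbinom(nTrue, truthCov, tv)
  sbT <- runif(nTrue)^0.5                 # mostly balanced strands
  bqT <- stats::rnorm(nTrue, if (separable) 38 else 35, 2)
  blkT <- runif(nTrue) < 0.02
  ## error-driven false calls: low VAF, poor base quality; a small Poisson
  ## component stands in for residual mapping noise
  covE <- stats::rnbinom(nErr, size = 4, mu = 120) + 10L
  altE <- pmin(rbetabinom(nErr, covE, errorAlpha, errorBeta) +
                 stats::rpois(nErr, 1), covE)
  sbE <- runif(nErr)^(if (separable) 4 else 2)
  bqE <- stats::rnorm(nErr, if (separable) 22 else 28, 4)
  blkE <- runif(nErr) < 0.3
  ## artifact-like false calls: any VAF, strand-biased, blacklist-enriched
  va <- runif(nArt, 0.02, 0.98)
  covA <- stats::rnbinom(nArt, size = 4, mu = 120) + 10L
  altA <- stats::rbinom(nArt, covA, va)
  sbA <- runif(nArt)^(if (separable) 6 else 3)
  bqA <- stats::rnorm(nArt, if (separable) 24 else 30, 4)
  blkA <- runif(nArt) < 0.5
  df <- data.frame(
    alt_count = c(altT, altE, altA), coverage = c(covT, covE, covA),
    vaf = c(altT / covT, altE / covE, altA / covA),
    strand_bias = c(sbT, sbE, sbA),
    blacklisted_gene = c(blkT, blkE, blkA),
    mean_alt_bq = c(bqT, bqE, bqA),
    truth_vaf = c(tv, rep(0, nFalse)),
    truth_alt = c(truthAltT, rep(0L, nFalse)),
    origin = rep(c("carrier", "error", "artifact"),
                 c(nTrue, nErr, nArt)))
  df$label <- labelCalls(df$truth_vaf, df$truth_alt)
  df[sample.int(nrow(df)), , drop = FALSE]
}

#' Sample a mutation catalog from a signature mixture
#'
#' Multinomial sample of `n` mutations from `reference %*% weights`.
#'
#' @param weights nonnegative mixture weights summing to 1.
#' @param reference 96 x K signature matrix.
#' @param n number of mutations.
#' @param seed RNG seed.
#' @return named 96-vector of counts
#' @export
simulateSignatureCatalog <- function(weights, reference, n, seed = 1L) {
  reference <- as.matrix(reference)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1")
  stopifnot(nrow(reference) == 96L, length(weights) == ncol(reference))
  p <- as.numeric(reference %*% weights)
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1L, n, p))
  setNames(counts, rownames(reference))
}

#' Write the simulated germline set as a minimal VCF
#'
#' @param germline data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param path output path
#' @return the path, invisibly
#' @export
writeGermlineVcf <- function(germline, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  g <- unique(as.data.frame(germline)[, c("chrom", "pos", "ref", "alt")])
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", g$chrom,
                     as.integer(g$pos), g$ref, g$alt), con)
  invisible(path)
}
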