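test_that("constitutive gene selection applies the strict fraction rule", {
  ## gene at TPM 6 in 80% of samples is in; at exactly 75% it is out
  m <- matrix(c(rep(6, 8), rep(0, 2)), 1, dimnames = list("geneA", NULL))
  gsA <- selectConstitutiveGenes(m, "tpm", 5)
  expect_true("geneA" %in% gsA$genes)
  m2 <- matrix(c(rep(6, 6), rep(0, 2)), 1, byrow = TRUE,
               dimnames = list("geneB", NULL))
  gsB <- selectConstitutiveGenes(m2, "tpm", 5)    # exactly 75%
  expect_false("geneB" %in% gsB$genes)
  expect_error(selectConstitutiveGenes(
    data.frame(gene = "g", sample = "s", tpm = 1), "bogus", 5))
})

test_that("gene-set membership equals a brute-force row scan", {
  set.seed(41)
  m <- matrix(rexp(100 * 50, 1 / 8), 100, 50,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  gs <- selectConstitutiveGenes(m, "tpm", 5, fraction = 0.75)
  brute <- rownames(m)[vapply(seq_len(nrow(m)), function(i)
    mean(m[i, ] >= 5) > 0.75, logical(1))]
  expect_setequal(gs$genes, brute)
  ## long-format input agrees with the matrix path
  long <- data.frame(gene = rep(rownames(m), ncol(m)),
                     sample = rep(seq_len(ncol(m)), each = nrow(m)),
                     tpm = as.vector(m))
  gsl <- selectConstitutiveGenes(long, "tpm", 5)
  expect_setequal(gsl$genes, brute)
  ## interrogated length is the sum of member exonic lengths
  len <- setNames(rep(1500, 100), rownames(m))
  gsL <- selectConstitutiveGenes(m, "tpm", 5, exonicLength = len)
  expect_equal(gsL$L, 1500 * length(brute))
})

test_that("the four canonical gene-set definitions give agreeing rates", {
  ## uniform mutation placement: rate estimates across the four sets
  ## differ by < 10%
  set.seed(42)
  nG <- 400; nS <- 60
  base <- exp(rnorm(nG, log(12), 1))     # per-gene constitutive level
  tpm <- matrix(base * exp(rnorm(nG * nS, 0, 0.2)), nG, nS,
                dimnames = list(sprintf("g%03d", 1:nG), NULL))
  cov <- tpm * 4
  len <- setNames(round(runif(nG, 1200, 2000)), rownames(tpm))
  defs <- list(list(m = tpm, th = 5), list(m = tpm, th = 10),
               list(m = cov, th = 20), list(m = cov, th = 30))
  perBase <- 2e-4                        # uniform truth rate per bp
  muts <- data.frame(gene = rep(rownames(tpm), round(len * perBase * 50)),
                     individual = "ind1")
  rates <- vapply(defs, function(d) {
    gs <- selectConstitutiveGenes(d$m, "tpm", d$th, exonicLength = len)
    n <- sum(muts$gene %in% gs$genes)
    n / (gs$L * 50)
  }, numeric(1))
  expect_lt(diff(range(rates)) / mean(rates), 0.1)
})

test_that("rate arithmetic reproduces the published extrapolations", {
  ## per-nucleotide rates x 45 Mbp
  expect_equal(round(extrapolateExome(8.1164e-9), 2), 0.37)
  expect_equal(round(extrapolateExome(5.1166e-9), 2), 0.23)
  expect_equal(round(extrapolateExome(2.44e-9), 2), 0.11)
  expect_equal(extrapolateExome(0), 0)
  expect_error(extrapolateExome(-1), ">= 0")
  ## linearity
  expect_equal(extrapolateExome(3e-9 + 4e-9),
               extrapolateExome(3e-9) + extrapolateExome(4e-9))
  ## performance correction on the rounded counts
  expect_equal(round(correctForPerformance(0.37), 2), 0.44)
  expect_equal(round(correctForPerformance(0.23), 3), 0.275)
  expect_equal(correctForPerformance(0.5, precision = 0.7,
                                     sensitivity = 0.7), 0.5)
  expect_error(correctForPerformance(1, sensitivity = 0), "> 0")
})

test_that("mutationRate composes count, length and cohort size", {
  ## n = 58 with L and N chosen to match the published per-base rate
  N <- 526
  L <- 58 / (8.1164e-9 * N)
  mut <- data.frame(individual = sample(sprintf("i%03d", 1:N), 58,
                                        replace = TRUE))
  est <- mutationRate(mut, L, N, bootReps = 200L, seed = 1L)
  expect_equal(est$rate, 8.1164e-9, tolerance = 1e-12)
  expect_equal(round(est$exome_count, 2), 0.37)
  expect_equal(round(est$corrected_count, 2), 0.44)
  expect_true(est$ci_low <= est$rate && est$rate <= est$ci_high)
  ## zero mutations
  z <- mutationRate(data.frame(individual = character()), L, N)
  expect_equal(z$rate, 0)
  expect_equal(z$exome_count, 0)
  expect_error(mutationRate(mut, 0, N), "L must be > 0")
})

test_that("the rate estimator is unbiased and its bootstrap CI covers", {
  r <- 8e-9; L <- 1.3e7; N <- 150
  hits <- 0; relErr <- numeric(50)
  for (b in 1:50) {
    set.seed(500 + b)
    counts <- rpois(N, L * r)
    mut <- data.frame(individual = rep(seq_len(N), counts))
    est <- mutationRate(mut, L, N, bootReps = 400L, seed = b)
    hits <- hits + (est$ci_low <= r && r <= est$ci_high)
    relErr[b] <- est$rate / r - 1
  }
  expect_lt(abs(mean(relErr)), 0.05)            # unbiased
  expect_gte(hits / 50, 0.88)                   # CI coverage
  expect_lte(hits / 50, 1.00)
})

test_that("single-tissue rates extrapolate and sum over tissues", {
  ## published arithmetic: 2.44e-9 over 43 tissues -> 4.7 per individual
  tissueL <- setNames(rep(5e7, 43), sprintf("t%02d", 1:43))
  ## 61 calls per tissue over 5e7 bp x 500 individuals = 2.44e-9 exactly
  calls <- data.frame(tissue = rep(names(tissueL), times = 61),
                      individual = "x")
  lr <- lemmRate(calls, tissueL, nIndividuals = 500)
  expect_equal(round(lr$per_tissue$rate[1], 12), 2.44e-9)
  expect_equal(round(lr$per_tissue$exome_count[1], 2), 0.11)
  expect_equal(round(lr$total_per_individual, 1), 4.7)
  ## single tissue: the total is that tissue's exome count
  one <- lemmRate(calls[calls$tissue == "t01", ], tissueL["t01"], 500)
  expect_equal(one$total_per_individual, one$per_tissue$exome_count)
  ## per-tissue rates agree with a brute-force tally
  brute <- table(calls$tissue) / (5e7 * 500)
  expect_equal(lr$per_tissue$rate,
               unname(as.numeric(brute[lr$per_tissue$tissue])))
  expect_error(lemmRate(calls, tissueL, 500, nTissues = 0), "> 0")
})

test_that("confounder regression recovers planted coefficients and centers residuals", {
  set.seed(43)
  n <- 400
  rec <- data.frame(
    duplicates = runif(n, 0.05, 0.4),
    cohort = sample(c("a", "b"), n, TRUE),
    rin = rnorm(n, 7.5, 1), trischd = rnorm(n, 400, 150),
    dp_median = rnorm(n, 100, 10))
  beta <- c(dup = 4e-7, rin = -2e-8, tri = 1e-10, dp = 5e-10)
  rec$raw_rate <- 1e-6 + beta["dup"] * rec$duplicates +
    beta["rin"] * rec$rin + beta["tri"] * rec$trischd +
    beta["dp"] * rec$dp_median + (rec$cohort == "b") * 3e-8 +
    rnorm(n, 0, 2e-8)
  rr <- residualRates(rec)
  cf <- coef(rr$fit); se <- coef(summary(rr$fit))[, "Std. Error"]
  expect_lt(abs(cf[["duplicates"]] - beta[["dup"]]),
            2 * se[["duplicates"]])
  expect_lt(abs(cf[["rin"]] - beta[["rin"]]), 2 * se[["rin"]])
  ## OLS normal equations: residuals centered and orthogonal to covariates
  expect_lt(abs(mean(rr$records$residual)), 1e-12)
  expect_lt(abs(sum(rr$records$residual * rec$duplicates)), 1e-8)
  expect_lt(abs(sum(rr$records$residual * rec$rin)), 1e-8)
  ## constant covariates: residuals are the centered raw rates
  cst <- rec; cst$duplicates <- 0.2; cst$cohort <- "a"; cst$rin <- 7
  cst$trischd <- 400; cst$dp_median <- 100
  rc <- residualRates(cst)
  expect_equal(rc$records$residual, cst$raw_rate - mean(cst$raw_rate))
})

test_that("age association tests per tissue with BH across tissues", {
  set.seed(44)
  nT <- 10; nS <- 40
  rec <- data.frame(
    tissue = rep(sprintf("t%02d", 1:nT), each = nS),
    age = rep(seq(25, 70, length.out = nS), nT))
  rec$residual <- rnorm(nrow(rec), 0, 1)
  ## plant a strong age effect in tissue t01
  i <- rec$tissue == "t01"
  rec$residual[i] <- rec$residual[i] + 0.15 * rec$age[i]
  aa <- ageAssociation(rec)
  expect_true(aa$significant[aa$tissue == "t01"])
  ## correction is across tissues: q is the BH transform of the p vector
  expect_equal(aa$q[aa$defined], fdrAdjust(aa$p[aa$defined]))
  ## monotone residuals give rho = 1
  mono <- data.frame(tissue = "t", age = 1:10, residual = (1:10) / 10)
  expect_equal(ageAssociation(mono)$rho, 1)
  ## constant residuals are flagged undefined
  flat <- data.frame(tissue = "t", age = 1:10, residual = 0)
  expect_false(ageAssociation(flat)$defined)
})

test_that("age-permuted residuals stay mostly non-significant", {
  set.seed(45)
  nT <- 12; nS <- 30
  sigFrac <- replicate(10, {
    rec <- data.frame(tissue = rep(sprintf("t%02d", 1:nT), each = nS),
                      age = sample(rep(seq(25, 70, length.out = nS), nT)),
                      residual = rnorm(nT * nS))
    mean(ageAssociation(rec)$significant)
  })
  expect_lte(mean(sigFrac), 0.05)
})

test_that("sample QC removes outliers, cultured cells and small tissues", {
  set.seed(46)
  n <- 300
  rec <- data.frame(
    sample = sprintf("s%03d", 1:n),
    tissue = rep(c("liver", "lung", "kidney"), each = 100),
    individual = sprintf("i%03d", 1:n),
    raw_rate = rexp(n, 1e6), duplicates = runif(n, 0.05, 0.4),
    rin = rnorm(n, 7.5, 1), callable_sites = rnorm(n, 1e6, 1e5),
    cultured = FALSE, cancer = FALSE)
  rec$tissue[201:300] <- "kidney"
  rec <- rec[1:240, ]                  # kidney has only 40 samples
  rec$cultured[1] <- TRUE
  qc <- qcFilterSamples(rec, minSamples = 50L)
  expect_false("kidney" %in% qc$tissue)
  expect_false("s001" %in% qc$sample)
  expect_lt(max(qc$duplicates), max(rec$duplicates))
})
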