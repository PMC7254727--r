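# rnamosaic

Detection, developmental timing and rate estimation of **mosaic mutations**
from multi-tissue, multi-individual RNA-seq count data.

Mosaic mutations arise post-zygotically, so they are present in only a
subset of a person's cells — and are often invisible in a blood sample.
When many tissues of the same individual have been RNA-sequenced, a
mutation's *pattern across tissues* reveals **when** in embryogenesis it
occurred: a mutation seen in derivatives of both primary germ layers must
predate gastrulation, one confined to a single germ layer arose during
gastrulation/neurulation, and a high-cell-fraction mutation restricted to
one organ points at organogenesis. `rnamosaic` implements this inference
chain end-to-end for pileup count tables, together with a synthetic cohort
generator so the whole pipeline can be exercised and validated without any
protected data.

## The model

**Error model.** At a homozygous-reference site, alternative read counts
are overdispersed relative to a binomial. Per strand-collapsed
substitution class (A>C, A>T, A>G, C>A, C>T, C>G):

```
Alt reads  ~  Bin(Coverage, e)
e          ~  Beta(alpha, beta)
```

fitted by method of moments (optional ML refinement) from reference
positions. A site's p-value is the beta-binomial upper tail
P(X >= alt | coverage, alpha, beta), corrected by Benjamini–Hochberg per
sample. Hard post-filters: alt reads >= 4 at base quality >= 20, coverage
>= 10, VAF >= 5%, no strand bias (Fisher test on the strand 2x2 table),
and >= 20 bp between candidate sites in a sample.

**3D genotype array.** Candidate sites are re-genotyped in *every* sample
with relaxed filters, giving a variant x tissue x individual array of
states `NO_EXPRESSION | HOM_REF | LOW_QUALITY | PASS` plus exact read
counts. Cohort-level filters then remove germline variants (any
individual's germline set, cohort-wide), population variants
(AF >= 1%), RNA-editing/repeat/low-complexity/systematic-error sites, and
sites recurring across more than 2 individuals.

**Random-forest call filter.** A forest over six features — alt count,
coverage, VAF, strand bias, blacklisted gene, mean alt base quality —
separates true from false calls; the response threshold is chosen by
maximum F1 on the training set, and a label-permutation null verifies the
model learned real signal.

**Lineage timing.** Surviving calls are mapped onto an embryogenesis
lineage tree (zygote → ectoderm/mesendoderm → ... → 49 tissues, bundled).
The ancestral node is the lowest common ancestor of the PASS tissues;
calls are classified as

* `EEMM` — zygote ancestor (both germ layers; adrenal gland excluded for
  its dual origin), mean VAF < 0.35, not ubiquitous;
* `MEMM` — >= 2 tissues confined to one germ layer, coherent distribution;
* `LEMM` — single tissue, >= 5 alt reads, VAF >= 0.2, tissue without known
  clonal expansions (sun-exposed skin, esophagus mucosa, whole blood are
  excluded);
* `SOMATIC` / `DENOVO_SUSPECT` otherwise.

**Rates.** Mutation counts over constitutively expressed gene sets
(TPM >= 5 or 10, COV >= 20 or 30, each in > 75% of samples) give
per-nucleotide per-individual rates `n / (L x N)` with bootstrap CIs,
extrapolated to a 45-Mbp exome and corrected by
`x precision / sensitivity`. Tissue-specific somatic rates are
confounder-corrected by OLS (`rate ~ duplicates + cohort + RIN + TRISCHD +
DP_median`) and tested for age association (Spearman, BH across tissues).

**Signatures.** 96-trinucleotide-context catalogs are refitted against a
reference signature matrix by constrained least squares (weights >= 0,
sum <= 1); weights > 0.1 are reported.

## Worked example

```r
library(rnamosaic)

cfg <- simConfig(seed = 1, nIndividuals = 12,
                 tissues = c("brain-cortex", "brain-cerebellum",
                             "skin-sun-exposed", "skin-not-sun-exposed",
                             "whole-blood", "heart-left-ventricle",
                             "muscle-skeletal", "adrenal-gland", "liver",
                             "lung", "stomach", "colon-transverse"))
cohort <- simulateCohort(cfg)

res <- runPipeline(cohort$counts, cfg$tree,
                   germline = cohort$germline,
                   editingSites = cohort$editingSites)
table(res$calls$klass)
#> DENOVO_SUSPECT  EEMM  LEMM  MEMM  SOMATIC
#>              6     2    10    12       32

head(res$calls[res$calls$klass == "EEMM",
     c("site", "individual", "ancestral_node", "n_pass", "mean_vaf")], 2)
#>                site individual ancestral_node n_pass  mean_vaf
#> 1 chr1:52000939:T>C     ind001         zygote      4 0.1281738
#> 9 chr1:36002478:C>A     ind003         zygote      9 0.2517125
```

Both example early-embryonic calls sit on the zygote node: they are PASS
in tissues of *both* germ layers at VAFs far below heterozygous, exactly
the fingerprint of a first-cleavage mutation. A rate estimate over the
simulated gene panel follows the same arithmetic as a real cohort:

```r
eemm <- res$calls[res$calls$klass == "EEMM", ]
est <- mutationRate(eemm, L = sum(cohort$genes$exonic_length),
                    nIndividuals = 12, seed = 1)
#> rate 1.42e-06 per bp per individual, 95% CI [0, 2.84e-06]
```

(The synthetic panel is deliberately small with an up-scaled mutation
target, so the absolute per-bp rate is orders of magnitude above a real
cohort's; the estimator, extrapolation and CI machinery are identical.)

A thin command-line front end covers the same steps:

```sh
Rscript inst/cli/rnamosaic.R simulate --seed 1 --individuals 10 \
    --tissues 20 --out-dir sim/
Rscript inst/cli/rnamosaic.R call --counts sim/counts.tsv --pooled \
    --out calls.tsv
Rscript inst/cli/rnamosaic.R classify --counts sim/counts.tsv \
    --germline sim/germline.vcf --editing sim/editing.tsv \
    --tree sim/lineage.json --out mosaic_calls.tsv
```

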