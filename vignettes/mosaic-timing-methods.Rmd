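---
title: "Methods: timing mosaic mutations from multi-tissue RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: timing mosaic mutations from multi-tissue RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and design decisions
behind `rnamosaic`, in the spirit of a methods supplement: what is assumed,
what is tunable, and what the bundled synthetic cohorts do and do not
demonstrate about real data.

## 1. The beta-binomial error model

RNA-seq alternative-read counts at homozygous-reference positions are
overdispersed: the per-read error rate varies across sites, libraries and
sequence contexts. We therefore model, per sample and per strand-collapsed
substitution class,

$$X \sim \mathrm{Bin}(n, e), \qquad e \sim \mathrm{Beta}(\alpha, \beta),$$

with $n$ the coverage and $X$ the alternative reads. Classes are the six
changes A>C, A>T, A>G, C>A, C>T, C>G; changes with a G/T reference are
reverse-complemented, which makes class assignment involutive under strand
flips. The six classes are fitted independently because error processes
(e.g. oxidative damage) are change-specific.

**Fitting.** The default is the Kleinman method-of-moments estimator for
unequal coverages — closed-form, robust on sparse classes — with an
optional maximum-likelihood refinement started from the moment estimates
(`method = "mle"`); a non-finite optimum falls back to moments. Classes
with fewer than `minFitSites = 500` usable positions receive the weakly
informative fallback prior $\mathrm{Beta}(1, 1000)$, i.e. a ~0.1% mean
error typical of quality-filtered short-read data, and are flagged.
Per-sample fitting matches the per-sample error structure of real data; a
pooled mode exists for sparse synthetic cohorts where per-sample class
counts fall below 500.

**Testing.** The site statistic is the exact upper tail
$P(X \ge x_{\mathrm{obs}})$, summed over whichever tail is shorter for
numerical efficiency. p-values are BH-corrected *within each sample*;
the significance cutoff is $q < 0.05$ (the correction level is a package
decision — only "FDR correction" is inherent to the method).
Post-filters: $\ge 4$ alternative reads at base quality $\ge 20$,
coverage $\ge 10$, VAF $\ge 5\%$, Fisher's exact strand-bias test at
$p < 0.01$ (the strand statistic is a package decision; the method only
requires alternative reads to follow the reference strand distribution),
and a 20-bp minimum distance between candidates in a sample. When two
candidates violate the distance rule both are removed — conservative,
since nothing ranks them. Reads below base quality 20 still count toward
coverage in the VAF denominator (flag `minBq` exposed).

## 2. The 3D genotype array

Sites significant in at least one sample are re-evaluated in *every*
sample with the same test but relaxed filters (no strand-bias, no
proximity, alternative count $\ge 3$ — one below the discovery minimum).
Each cell gets one of four states: coverage `< 5` reads is
`NO_EXPRESSION` (the expression threshold is a package decision; 5 keeps
re-calling sensitive while the rate denominator separately requires
coverage $\ge 10$ for callability); significant cells passing the
relaxed thresholds are `PASS`; cells with $\ge 2$ alternative reads or
significant-but-below-threshold are `LOW_QUALITY`; the rest are
`HOM_REF`. Cells for tissues never assayed in an individual stay missing
(`NA`) — distinct from expressed-but-silent.

Cohort filters drop whole sites and never mutate counts, so they commute:

* germline subtraction is cohort-wide — a variant germline in *any*
  individual is removed everywhere;
* population AF $\ge 1\%$ (boundary inclusive), editing sites, repeat and
  low-complexity intervals (BED, 0-based half-open), systematic-error
  lists;
* sites with a PASS in the expressed tissues of every individual
  (systematic errors or de novo germline);
* recurrence: sites PASS in more than 2 individuals. Only PASS states are
  counted (flag `countLowQuality` exposed) because low-quality recurrence
  is filtered separately;
* low-quality recurrence, operationalized as: individuals showing a
  *significant* `LOW_QUALITY` call but no PASS at the site, in at least 2
  individuals and more than 5% of the cohort. Counting every
  $\mathrm{alt} \ge 2$ cell would remove essentially all true sites — at
  coverage 100 and error $10^{-3}$, a chance $\mathrm{alt} \ge 2$ cell
  occurs in roughly 1 in 100 cells, so almost every site shows one in
  some individual of a moderate cohort; significance-gated LQ calls are
  the actual signature of a systematic error. A carrier's own marginal
  tissues are deliberately not artifact evidence.

## 3. Lineage timing

The bundled tree runs zygote → {ectoderm, mesendoderm} →
{mesoderm, endoderm} → eight sub-lineage groups → 49 tissue leaves. All
classification rules depend only on the germ-layer level, which is
developmentally unambiguous; the sub-lineage grouping is an editorial
encoding users can replace (`loadLineageTree()`, Newick import/export).

* The **ancestral node** is the set-cover LCA of the PASS-tissue leaves —
  there is no probabilistic placement model, and the LCA is monotone
  under leaf deletion (removing a tissue can only shallow the call). The
  adrenal gland (ectodermal medulla + mesodermal cortex) is excluded from
  multi-tissue lineage placement so it cannot fake a zygote ancestor.
* **Coherence**: every child branch of the ancestral node containing a
  PASS tissue must have detection fraction (PASS / expressed) $\ge$
  `fMin = 0.2`, or contain a single expressed tissue. The 0.2 default
  operationalizes a verbal criterion — mutations seen in far-apart
  branches but undetectable near the affected tissues would require
  multiple independent origins. Incoherent multi-tissue calls are kept in
  the output as `SOMATIC` with `coherent = FALSE` for auditability rather
  than silently dropped.
* **Classes**: `EEMM` (zygote ancestor, mean VAF over PASS tissues
  < 0.35, not PASS in all expressed tissues), `MEMM` ($\ge 2$ tissues,
  one germ layer, coherent), `LEMM` (single tissue, $\ge 5$ reads, VAF
  $\ge 0.2$, not in a clonal-expansion tissue), `DENOVO_SUSPECT`
  (ubiquitous or mean VAF $\ge 0.35$; an explicit class, not a silent
  removal), else `SOMATIC`. The mean VAF over PASS tissues is the VAF
  used for both the 0.35 guard and the 0.2 LEMM threshold (per-tissue
  for LEMM since there is one tissue). Multi-tissue calls whose only
  non-adrenal support is a single tissue are `SOMATIC`: their origin is
  ambiguous and they satisfy neither the multi-tissue nor the
  single-tissue definition.
* Individuals enter the analysis with $\ge 10$ assayed tissues and two
  germ layers each represented by $\ge 2$ tissues.

## 4. Rates

Rates are $n / (L \times N)$ over constitutively expressed gene sets —
genes above an expression threshold in strictly more than 75% of samples
(computed over samples, not individuals; flag exposed). $L$ is the union
of annotated exonic bases of member genes; restricting to callable bases
(coverage $\ge 10$) is available behind a flag since the choice is not
forced by the method. Confidence intervals are a seeded percentile
bootstrap over individuals (1000 replicates): the original CI construction
is unspecified upstream, so we choose the bootstrap and make no claim of
matching any previously printed interval. The exome extrapolation is
linear ($\times 4.5\times 10^{7}$ bp) and the performance correction
multiplies the *rounded* extrapolated count by precision / sensitivity
(0.85 / 0.71 defaults), reproducing the printed two-step arithmetic.
Tissue-specific somatic rates are OLS-residualized against duplicates,
cohort, RIN, ischemic time and median coverage — constant covariates are
dropped automatically (an intercept-only design yields centered raw
rates) and rank-deficient designs raise an error naming the collinear
terms — then tested per tissue for Spearman age association with BH
applied across tissues.

## 5. Signature refitting

Catalogs use the standard 96-context pyrimidine-reference order. Refitting
minimizes $\lVert c/\Sigma c - R w\rVert_2$ subject to $w \ge 0$,
$\sum w \le 1$, solved by Lawson–Hanson active-set NNLS on a system
augmented with a heavily weighted slack equality. This is deterministic
and convex, unlike iterative forward-selection refits, and coincides with
them on well-separated signatures; it is a documented deviation from the
original tool's algorithm, not a reimplementation of it. Catalog
normalization is by mutation count — no genome/exome trinucleotide
reweighting — with a hook for an optional context weighting table, since
the upstream tool's normalization setting is not recorded. Weights at or
below 0.1 are zeroed only in the *report* view; raw weights are retained.
The bundled reference matrix generator is synthetic (a CpG-C>T clock-like
profile plus random sparse profiles) and is labelled as such; real
analyses should supply a published catalog as TSV.

## 6. The synthetic cohort generator

The generator emulates the full input stack: lineage-placed mutations,
per-tissue VAFs, beta-binomial read noise, expression dropout, germline /
editing / recurrent-artifact plants, expression tables and technical
covariates. Key choices:

* **Placement.** Poisson counts per (node, division) at rate
  $3 \times \texttt{regionFraction}$ — three genome-wide mutations per
  cell division during early embryogenesis, scaled to the monitored
  region. Three zygote divisions and two divisions per later node are
  modeled. The cohort default `regionFraction = 0.04` is an up-scaled
  target region chosen once so that benchmark cohorts carry a few hundred
  mutations (stable sensitivity/FDR estimates); a realistic 13.6-Mbp
  panel corresponds to ~0.004.
* **Cell fractions.** A mutation at division $d$ of its lineage starts at
  fraction $0.5^{d}$ there (VAF $= f/2$: diploid, heterozygous, no
  allele-specific expression — an ASE perturbation would shift VAFs down
  and is one reason real rates are underestimates). Fractions propagate
  to daughter lineages by binomial founder sampling with
  `founderCells = 8` per split (Dirichlet-weighted asymmetric
  contributions optional, symmetric default). The sampling is a
  martingale, so the expected VAF at division $d$ is exactly
  $0.5^{d+1}$, while drift produces the lineage dropout that real
  cohorts show — without it, every zygote mutation would be detectable in
  all expressed tissues and the ubiquity guard would (correctly, per its
  definition) reclassify them all as de novo suspects.
* **Truth labels.** Each planted mutation's reference class is obtained
  by applying the classification rules to its *true* VAF pattern through
  an ideal noiseless observer. Founder drift can genuinely extinguish a
  zygote-stage mutation in one germ layer; a perfect caller must then
  classify it as germ-layer-confined, so labeling by origin node alone
  would make exact recovery unattainable by construction. The origin node
  and division are retained alongside.
* **Reads.** Coverage is negative binomial (mean 100, dispersion 0.3 —
  the dispersion is unconstrained by the method and set to a typical
  bulk-RNA-seq value); carrier reads are binomial at the true VAF; error
  reads are beta-binomial ($\alpha = 2$, $\beta = 1998$: mean $10^{-3}$,
  mildly overdispersed); strands split symmetrically; base qualities are
  Gaussian around 35. `readNoise = FALSE` is the noise-free mode: zero
  error *and* deterministic counts
  $\mathrm{alt} = \mathrm{round}(n \cdot \mathrm{VAF})$, because binomial
  read sampling is itself noise and would break exact-recovery checks at
  low VAF.
* **Determinism.** Every generator entry point derives its RNG stream
  from the config seed, so a config reproduces its cohort byte-for-byte.

**What passing tests show — and what they do not.** The synthetic cohorts
validate the statistical machinery: calibration of the error test,
state assignment, filter composition, LCA/coherence logic, estimator
bias and CI coverage, and classifier behavior. They do not reproduce
real-data pathologies — alignment artifacts around splice sites,
RNA-editing biology beyond planted site lists, allele-specific
expression, expression-correlated coverage, batch structure — so
performance numbers on synthetic cohorts are upper bounds, not forecasts,
for real cohorts.

## 7. Benchmark problem sizes and tunables

The shipped test-suite and acceptance benchmarks use: a 50-individual,
20-tissue cohort at fixed coverage 100 for end-to-end recovery (the
benchmark's stated condition is coverage 100, so the coverage dispersion
is set to 0 there; sequencing error stays at defaults — under the default
dispersion 0.3, single-tissue VAF-0.125 mutations landing on low-coverage
cells are genuinely undetectable and sensitivity drops a few points),
$10^4$ null sites for calibration, 100 label-permuted forests of 100
trees, $10^4$-mutation catalogs for signature round trips, and 100
simulated cohorts x 500 bootstrap replicates for CI coverage. Training
pools for the forest sample an equal quota from every (class, VAF-bin)
cell populated in both classes — this is what simultaneously delivers the
balanced class ratio and the uniform VAF histogram — and each cell splits
disjointly into train/test before low-VAF (< 0.10) training records are
doubled; doubling before the split would leak identical records across
the sets. The forest response threshold is recomputed by max-F1 on every
training set: any particular printed cutoff is dataset-specific.

## 8. Known limitations

* SNVs only — no indels or CNVs; pileups are the entry point (no
  alignment-level processing).
* The coherence rule and `fMin` are heuristic; a probabilistic placement
  model over the tree is an exposed extension point.
* Germline subtraction is cohort-wide and therefore removes a true mosaic
  that coincides exactly with another individual's germline variant —
  rare, conservative.
* The LEMM class cannot be separated from early postnatal clonal
  expansions by design; excluding the three known clonal-expansion
  tissues bounds, but does not remove, that contamination, and LEMM rates
  should be read as upper bounds.
* Bootstrap CIs over individuals understate uncertainty when per-individual
  mutation counts are extremely sparse (mostly zeros): coverage stays in
  the low 90s rather than at the nominal 95.
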