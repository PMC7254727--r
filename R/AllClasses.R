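#' @import methods
#' @importFrom stats p.adjust fisher.test optim lm resid coef cor.test
#'   wilcox.test quantile rbinom rbeta rpois rnbinom rmultinom runif
#'   setNames complete.cases predict median sd
#' @importFrom utils read.delim write.table head
NULL

## Six strand-collapsed substitution classes (pyrimidine/adenine reference frame
## for the error model; G/T reference changes map via reverse complement).
SUBSTITUTION_CLASSES <- c("A>C", "A>T", "A>G", "C>A", "C>T", "C>G")

CALL_STATES <- c("NO_EXPRESSION", "HOM_REF", "LOW_QUALITY", "PASS")

#' Beta-binomial sequencing-error model
#'
#' One (alpha, beta) shape pair per strand-collapsed substitution class,
#' fitted from alternative read counts at putatively homozygous-reference
#' positions. Classes with fewer than the minimum number of fitting sites
#' carry the weakly informative fallback prior (alpha = 1, beta = 1000,
#' ~0.1\% mean error) and are flagged.
#'
#' @slot params data.frame with columns `class`, `alpha`, `beta`,
#'   `n_sites`, `fallback` (one row per substitution class).
#' @slot sample Sample identifier ("pooled" for a pooled fit).
#' @slot method Fitting method used ("moments" or "mle").
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(params = "data.frame", sample = "character",
                 method = "character"))

setValidity("ErrorModel", function(object) {
  p <- object@params
  if (!all(c("class", "alpha", "beta", "n_sites", "fallback") %in% names(p)))
    return("params must have columns class, alpha, beta, n_sites, fallback")
  if (!setequal(p$class, SUBSTITUTION_CLASSES))
    return("params must contain exactly the six substitution classes")
  if (!all(is.finite(p$alpha)) || !all(is.finite(p$beta)))
    return("alpha and beta must be finite")
  if (any(p$alpha <= 0) || any(p$beta <= 0))
    return("alpha and beta must be > 0")
  mu <- p$alpha / (p$alpha + p$beta)
  if (any(mu <= 0 | mu >= 0.5))
    return("implied mean error rate must lie in (0, 0.5)")
  TRUE
})

#' Variant x tissue x individual genotype array
#'
#' Three-dimensional call-state and read-count array produced by multi-sample
#' re-genotyping of candidate sites. Cells for tissues never assayed in an
#' individual are `NA` (missing), which is distinct from the
#' `NO_EXPRESSION` state (assayed but no reads).
#'
#' @slot state integer array (site x tissue x individual), values index
#'   into `c("NO_EXPRESSION","HOM_REF","LOW_QUALITY","PASS")`, `NA` = cell
#'   never assayed.
#' @slot refCount,altCount integer arrays with the same dimensions.
#' @slot vafArr numeric array of per-cell variant allele frequencies.
#' @slot siteInfo data.frame keyed by site id with columns `chrom`, `pos`,
#'   `ref`, `alt` plus optional annotation flags.
#' @exportClass GenotypeArray
setClass("GenotypeArray",
  representation(state = "array", refCount = "array", altCount = "array",
                 vafArr = "array", siteInfo = "data.frame"))

setValidity("GenotypeArray", function(object) {
  d <- dim(object@state)
  if (length(d) != 3L) return("state must be a 3D array")
  for (s in c("refCount", "altCount", "vafArr"))
    if (!identical(dim(slot(object, s)), d))
      return(sprintf("%s dimensions differ from state", s))
  if (nrow(object@siteInfo) != d[1L])
    return("siteInfo rows must match the site dimension")
  st <- object@state
  if (any(!is.na(st) & (st < 1L | st > 4L)))
    return("state codes must be in 1..4 or NA")
  TRUE
})

#' Embryogenesis lineage tree
#'
#' Rooted tree from zygote through the primary germ layers down to tissue
#' leaves, used to time mosaic mutations. Leaves of dual germ-layer origin
#' (adrenal gland) are excluded from zygote-ancestor calls; leaves with known
#' postnatal clonal expansions (sun-exposed skin, esophagus mucosa, whole
#' blood) are excluded from single-tissue late-embryonic calls.
#'
#' @slot parent named character vector mapping each non-root node to its
#'   parent; the root ("zygote") is absent from the names.
#' @slot root root node name.
#' @slot tissueMap named character vector tissue -> leaf node.
#' @slot dualOriginLeaves,clonalExpansionLeaves character vectors of flagged
#'   leaf names.
#' @exportClass LineageTree
setClass("LineageTree",
  representation(parent = "character", root = "character",
                 tissueMap = "character",
                 dualOriginLeaves = "character",
                 clonalExpansionLeaves = "character"))

setValidity("LineageTree", function(object) {
  nodes <- c(object@root, names(object@parent))
  if (anyDuplicated(nodes)) return("duplicate node names")
  if (!all(object@parent %in% nodes)) return("parent refers to unknown node")
  kids <- names(object@parent)[object@parent == object@root]
  if (length(kids) != 2L)
    return("root must have exactly two children (ectoderm, mesendoderm)")
  leaves <- setdiff(nodes, c(object@parent, object@root))
  if (!all(object@tissueMap %in% leaves))
    return("tissueMap must point at leaf nodes")
  if (anyDuplicated(names(object@tissueMap)))
    return("a tissue is mapped to more than one leaf")
  ## cycle check: every node must reach the root
  for (n in names(object@parent)) {
    seen <- character(); cur <- n
    while (cur != object@root) {
      if (cur %in% seen) return("cycle in parent map")
      seen <- c(seen, cur); cur <- object@parent[[cur]]
    }
  }
  TRUE
})

#' Random-forest call-filter model
#'
#' Fitted forest over the six call features (alt count, coverage, VAF,
#' strand bias, blacklisted gene, mean alt base quality) plus the response
#' threshold chosen by maximum F1 on the training set. The printed threshold
#' of any particular study is dataset-specific; it is always recomputed.
#'
#' @slot forest the fitted `randomForest` object.
#' @slot threshold response threshold in (0, 1) (strict "exceeding" rule).
#' @slot metadata list with seed, training sizes and the training F1 curve.
#' @exportClass RfModel
setClass("RfModel",
  representation(forest = "ANY", threshold = "numeric", metadata = "list"))

setValidity("RfModel", function(object) {
  if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
      object@threshold <= 0 || object@threshold >= 1)
    return("threshold must be a single value in (0,1)")
  TRUE
})

#' @describeIn ErrorModel compact display
#' @param object an `ErrorModel`
#' @export
setMethod("show", "ErrorModel", function(object) {
  cat(sprintf("ErrorModel (sample: %s, method: %s)\n",
              object@sample, object@method))
  p <- object@params
  p$mean_error <- signif(p$alpha / (p$alpha + p$beta), 3)
  print(p, row.names = FALSE)
})

#' @describeIn GenotypeArray compact display
#' @param object a `GenotypeArray`
#' @export
setMethod("show", "GenotypeArray", function(object) {
  d <- dim(object@state)
  cat(sprintf("GenotypeArray: %d sites x %d tissues x %d individuals\n",
              d[1], d[2], d[3]))
  tab <- table(factor(CALL_STATES[object@state], levels = CALL_STATES))
  cat("  states:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("(missing=%d)\n", sum(is.na(object@state))))
})

#' @describeIn LineageTree compact display
#' @param object a `LineageTree`
#' @export
setMethod("show", "LineageTree", function(object) {
  leaves <- treeLeaves(object)
  cat(sprintf("LineageTree: %d nodes, %d leaves, %d mapped tissues\n",
              length(object@parent) + 1L, length(leaves),
              length(object@tissueMap)))
  cat("  root children:",
      paste(names(object@parent)[object@parent == object@root],
            collapse = ", "), "\n")
})

#' @describeIn RfModel compact display
#' @param object an `RfModel`
#' @export
setMethod("show", "RfModel", function(object) {
  cat(sprintf("RfModel: threshold = %.2f (max training F1 = %.3f), %d trees\n",
              object@threshold,
              max(object@metadata$f1_curve$f1, na.rm = TRUE),
              object@metadata$ntree))
})
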