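#' Construct a lineage tree from an edge list
#'
#' @param edges two-column matrix/data.frame of (parent, child) node names.
#' @param root root node name (default `"zygote"`).
#' @param tissueMap named character vector tissue -> leaf; defaults to the
#'   identity map over the leaves.
#' @param dualOriginLeaves leaves of mixed germ-layer origin, excluded from
#'   zygote-ancestor (early-embryonic) analysis (default: `"adrenal-gland"`
#'   when present).
#' @param clonalExpansionLeaves leaves with known postnatal clonal
#'   expansions, excluded from single-tissue late-embryonic calls (default:
#'   sun-exposed skin, esophagus mucosa, whole blood when present).
#' @return a [LineageTree-class]
#' @export
LineageTree <- function(edges, root = "zygote", tissueMap = NULL,
                        dualOriginLeaves = NULL,
                        clonalExpansionLeaves = NULL) {
  edges <- as.matrix(edges)
  parent <- setNames(as.character(edges[, 1L]), as.character(edges[, 2L]))
  nodes <- c(root, names(parent))
  leaves <- setdiff(nodes, parent)
  if (is.null(tissueMap)) tissueMap <- setNames(leaves, leaves)
  if (is.null(dualOriginLeaves))
    dualOriginLeaves <- intersect("adrenal-gland", leaves)
  if (is.null(clonalExpansionLeaves))
    clonalExpansionLeaves <- intersect(
      c("skin-sun-exposed", "esophagus-mucosa", "whole-blood"), leaves)
  unmapped <- names(tissueMap)[!tissueMap %in% leaves]
  if (length(unmapped))
    stop("tissue(s) mapped to no leaf: ", paste(unmapped, collapse = ", "))
  new("LineageTree", parent = parent, root = root, tissueMap = tissueMap,
      dualOriginLeaves = dualOriginLeaves,
      clonalExpansionLeaves = clonalExpansionLeaves)
}

## path from node up to (and including) the root
ancestorPath <- function(tree, node) {
  path <- node
  while (node != tree@root) {
    node <- tree@parent[[node]]
    path <- c(path, node)
  }
  path
}

nodeDepth <- function(tree, node) {
  vapply(node, function(n) length(ancestorPath(tree, n)) - 1L, integer(1))
}

subtreeLeaves <- function(tree, node) {
  leaves <- treeLeaves(tree)
  leaves[vapply(leaves, function(l) node %in% ancestorPath(tree, l),
                logical(1))]
}

childrenOf <- function(tree, node) {
  names(tree@parent)[tree@parent == node]
}

#' Lowest common ancestor of a set of tissues on the lineage tree
#'
#' The most likely ancestral node of a mosaic call is the lowest common
#' ancestor (LCA) of the leaves of all its PASS tissues. Leaves of dual
#' germ-layer origin (adrenal gland) are excluded from the LCA whenever
#' other leaves are present, so that they cannot pull a germ-layer-confined
#' call up to the zygote.
#'
#' @param tissues character vector of tissue names with a PASS call (>= 1).
#' @param tree a [LineageTree-class]
#' @param excludeDual drop dual-origin leaves when other leaves remain
#'   (default TRUE).
#' @return the LCA node name
#' @export
ancestralNode <- function(tissues, tree, excludeDual = TRUE) {
  if (!length(tissues)) stop("ancestralNode needs at least one PASS tissue")
  leaves <- unname(tissueLeaf(tree)[tissues])
  if (anyNA(leaves))
    stop("unmapped tissue(s): ",
         paste(tissues[is.na(leaves)], collapse = ", "))
  if (excludeDual) {
    keep <- setdiff(leaves, dualOriginLeaves(tree))
    if (length(keep)) leaves <- keep
  }
  paths <- lapply(unique(leaves), function(l) rev(ancestorPath(tree, l)))
  common <- paths[[1L]]
  for (p in paths[-1L]) {
    k <- min(length(common), length(p))
    same <- common[seq_len(k)] == p[seq_len(k)]
    common <- common[seq_len(max(which(same)))]
  }
  common[length(common)]
}

#' Coherence of a mosaic call on the lineage tree
#'
#' A call is coherent with a single developmental origin if, in every child
#' subtree of its ancestral node that contains at least one PASS tissue, the
#' detection fraction (PASS tissues / expressed tissues in that subtree) is
#' at least `fMin`, or the subtree contains exactly one expressed tissue.
#' Calls observed in far-apart branches but undetectable near the affected
#' tissues would require multiple independent origins and are incoherent.
#'
#' @param passTissues,expressedTissues tissue name vectors.
#' @param node the call's ancestral node (see [ancestralNode()]).
#' @param tree a [LineageTree-class]
#' @param fMin minimum per-branch detection fraction (default 0.2).
#' @return logical
#' @export
coherence <- function(passTissues, expressedTissues, node, tree,
                      fMin = 0.2) {
  tm <- tissueLeaf(tree)
  passLeaves <- unname(tm[passTissues])
  exprLeaves <- unname(tm[expressedTissues])
  kids <- childrenOf(tree, node)
  if (!length(kids)) return(TRUE)    # leaf node
  for (k in kids) {
    sub <- subtreeLeaves(tree, k)
    nPass <- sum(passLeaves %in% sub)
    if (nPass == 0L) next
    nExpr <- sum(exprLeaves %in% sub)
    if (nExpr <= 1L) next
    if (nPass / nExpr < fMin) return(FALSE)
  }
  TRUE
}

germLayerOf <- function(tree, tissues) {
  kids <- childrenOf(tree, tree@root)
  tm <- tissueLeaf(tree)
  vapply(tissues, function(t) {
    path <- ancestorPath(tree, tm[[t]])
    hit <- intersect(path, kids)
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
}

#' Classify mosaic calls by developmental timing
#'
#' Maps every (site, individual) with at least one PASS cell in the genotype
#' array onto the lineage tree and assigns one of five classes:
#' * `DENOVO_SUSPECT` - PASS in all expressed tissues, or mean VAF over
#'   PASS tissues >= 0.35 (likely de novo germline; excluded from rates);
#' * `EEMM` - ancestral node is the zygote, i.e. PASS tissues span both the
#'   ectoderm and mesendoderm branches (adrenal gland excluded), mean VAF
#'   < 0.35, not ubiquitous;
#' * `MEMM` - >= 2 PASS tissues confined to one germ-layer subtree with a
#'   coherent distribution;
#' * `LEMM` - exactly one PASS tissue with >= `lemmMinAlt` alternative reads
#'   and VAF >= `lemmMinVaf`, in a tissue without known clonal expansions;
#' * `SOMATIC` - everything else (postnatal somatic / unclassifiable).
#'
#' Only individuals with at least `minTissues` assayed tissues and at least
#' two germ layers each represented by two assayed tissues are analyzed;
#' calls from other individuals are skipped (returned in the `skipped`
#' attribute).
#'
#' @param array a filtered [GenotypeArray-class]
#' @param tree a [LineageTree-class]
#' @param minTissues individual inclusion threshold (default 10).
#' @param lemmMinAlt,lemmMinVaf LEMM support thresholds (defaults 5 reads,
#'   VAF 0.2).
#' @param denovoVaf mean-VAF guard against de novo germline (default 0.35).
#' @param fMin coherence detection fraction (default 0.2).
#' @return data.frame with one row per (site, individual): `site`,
#'   `individual`, `klass`, `ancestral_node`, `node_depth`, `n_pass`,
#'   `n_expressed`, `mean_vaf`, `max_alt`, `coherent`
#' @export
classifyMosaic <- function(array, tree, minTissues = 10L, lemmMinAlt = 5L,
                           lemmMinVaf = 0.2, denovoVaf = 0.35, fMin = 0.2) {
  st <- array@state
  vafA <- array@vafArr
  altA <- array@altCount
  dn <- dimnames(st)
  tm <- tissueLeaf(tree)
  known <- dn$tissue %in% names(tm)
  if (!all(known))
    stop("tissue(s) missing from the lineage tree: ",
         paste(dn$tissue[!known], collapse = ", "))
  ## individual inclusion: assayed tissues and germ-layer representation
  assayed <- apply(!is.na(st), c(2, 3), any)     # tissue x individual
  layer <- germLayerOf(tree, dn$tissue)
  inclOk <- vapply(dn$individual, function(ind) {
    tiss <- dn$tissue[assayed[, ind]]
    if (length(tiss) < minTissues) return(FALSE)
    tab <- table(layer[match(tiss, dn$tissue)])
    sum(tab >= 2L) >= 2L
  }, logical(1))
  skipped <- dn$individual[!inclOk]
  if (length(skipped))
    message("skipping ", length(skipped),
            " individual(s) failing inclusion criteria")
  rows <- list()
  dual <- names(tm)[tm %in% dualOriginLeaves(tree)]
  clonal <- names(tm)[tm %in% clonalExpansionLeaves(tree)]
  hasPass <- which(apply(!is.na(st) & st == 4L, c(1, 3), any),
                   arr.ind = TRUE)
  for (r in seq_len(nrow(hasPass))) {
    si <- hasPass[r, 1L]; ii <- hasPass[r, 2L]
    ind <- dn$individual[ii]
    if (!inclOk[[ind]]) next
    states <- st[si, , ii]
    passT <- dn$tissue[!is.na(states) & states == 4L]
    exprT <- dn$tissue[!is.na(states) & states != 1L]
    vafs <- vafA[si, passT, ii]
    meanVaf <- mean(vafs)
    maxAlt <- max(altA[si, passT, ii])
    nPass <- length(passT); nExpr <- length(exprT)
    node <- NA_character_; coh <- NA
    if (nPass == nExpr || meanVaf >= denovoVaf) {
      klass <- "DENOVO_SUSPECT"
    } else if (nPass == 1L) {
      node <- unname(tm[passT])
      ok <- maxAlt >= lemmMinAlt && vafs[1L] >= lemmMinVaf &&
        !(passT %in% clonal)
      klass <- if (ok) "LEMM" else "SOMATIC"
    } else {
      passLin <- setdiff(passT, dual)
      exprLin <- setdiff(exprT, dual)
      if (length(passLin) < 2L) {
        ## multi-tissue only through the adrenal gland: ambiguous origin
        klass <- "SOMATIC"
      } else {
        node <- ancestralNode(passLin, tree, excludeDual = TRUE)
        coh <- coherence(passLin, exprLin, node, tree, fMin = fMin)
        if (node == treeRoot(tree)) {
          klass <- "EEMM"
        } else if (coh) {
          klass <- "MEMM"
        } else {
          klass <- "SOMATIC"
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      site = dn$site[si], individual = ind, klass = klass,
      ancestral_node = node,
      node_depth = if (is.na(node)) NA_integer_ else
        unname(nodeDepth(tree, node)),
      n_pass = nPass, n_expressed = nExpr, mean_vaf = meanVaf,
      max_alt = maxAlt, coherent = coh, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = character(), individual = character(),
               klass = character(), ancestral_node = character(),
               node_depth = integer(), n_pass = integer(),
               n_expressed = integer(), mean_vaf = numeric(),
               max_alt = numeric(), coherent = logical())
  attr(out, "skipped") <- skipped
  out
}

#' VAF / tissue-support correlations over mosaic calls
#'
#' Spearman rank correlation (a) between the mean VAF of a call and the
#' number of supporting tissues, and (b) between the depth of the ancestral
#' node and the mean VAF. Under the cell-fraction-halving model, earlier
#' (shallower) origins carry larger cell fractions, so (a) is expected
#' positive and (b) negative.
#'
#' @param calls output of [classifyMosaic()] (needs >= 3 rows).
#' @return data.frame with one row per relationship: `relation`, `rho`,
#'   `p`, `n`, `defined`
#' @export
vafTissueCorrelation <- function(calls) {
  stopifnot(nrow(calls) >= 3L)
  one <- function(x, y, label) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || length(unique(x)) < 2L ||
        length(unique(y)) < 2L)
      return(data.frame(relation = label, rho = NA_real_, p = NA_real_,
                        n = length(x), defined = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(relation = label, rho = unname(ct$estimate), p = ct$p.value,
               n = length(x), defined = TRUE)
  }
  rbind(one(calls$mean_vaf, calls$n_pass, "mean_vaf~n_pass"),
        one(calls$node_depth, calls$mean_vaf, "node_depth~mean_vaf"))
}

#' Serialize a lineage tree to JSON / read one back
#'
#' The JSON schema carries the edge list, tissue map and leaf flags.
#'
#' @param tree a [LineageTree-class]
#' @param path output / input file path
#' @return `loadLineageTree`: a [LineageTree-class]
#' @export
writeLineageTree <- function(tree, path) {
  obj <- list(root = tree@root,
              edges = unname(Map(c, unname(tree@parent),
                                 names(tree@parent))),
              tissues = as.list(tree@tissueMap),
              dual_origin = tree@dualOriginLeaves,
              clonal_expansion = tree@clonalExpansionLeaves)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeLineageTree
#' @export
loadLineageTree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- obj$edges
  if (is.list(edges)) edges <- do.call(rbind, lapply(edges, unlist))
  edges <- matrix(as.character(edges), ncol = 2)
  tm <- unlist(obj$tissues)
  LineageTree(edges, root = obj$root, tissueMap = tm,
              dualOriginLeaves = as.character(obj$dual_origin),
              clonalExpansionLeaves = as.character(obj$clonal_expansion))
}

#' Newick export / import
#'
#' `treeToNewick` writes the topology with internal node labels;
#' `lineageTreeFromNewick` rebuilds a [LineageTree-class] from such a
#' string (tissue map defaults to the identity over leaf labels).
#'
#' @param tree a [LineageTree-class]
#' @param newick a Newick string with named internal nodes
#' @param ... passed to [LineageTree()]
#' @return `treeToNewick`: character; `lineageTreeFromNewick`: a
#'   [LineageTree-class]
#' @export
treeToNewick <- function(tree) {
  build <- function(node) {
    kids <- childrenOf(tree, node)
    if (!length(kids)) return(node)
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
           ")", node)
  }
  paste0(build(tree@root), ";")
}

#' @rdname treeToNewick
#' @export
lineageTreeFromNewick <- function(newick, ...) {
  ph <- ape::read.tree(text = newick)
  labs <- c(ph$tip.label, ph$node.label)
  edges <- cbind(labs[ph$edge[, 1L]], labs[ph$edge[, 2L]])
  root <- labs[ph$edge[1L, 1L]]
  ## ape roots at the first internal node of the edge table's topology
  rootIdx <- setdiff(ph$edge[, 1L], ph$edge[, 2L])[1L]
  LineageTree(edges, root = labs[rootIdx], ...)
}

#' Prune a lineage tree to a tissue subset
#'
#' Keeps the leaves of the given tissues and all their ancestors; unary
#' internal chains are retained (classification depends only on topology
#' above the kept leaves).
#'
#' @param tree a [LineageTree-class]
#' @param tissues tissues to keep
#' @return a [LineageTree-class]
#' @export
pruneLineageTree <- function(tree, tissues) {
  tm <- tissueLeaf(tree)
  stopifnot(all(tissues %in% names(tm)))
  keepLeaves <- unname(tm[tissues])
  keepNodes <- unique(unlist(lapply(keepLeaves, ancestorPath,
                                    tree = tree)))
  parent <- tree@parent[names(tree@parent) %in% keepNodes]
  LineageTree(cbind(unname(parent), names(parent)), root = tree@root,
              tissueMap = tm[tissues],
              dualOriginLeaves = intersect(tree@dualOriginLeaves, keepLeaves),
              clonalExpansionLeaves = intersect(tree@clonalExpansionLeaves,
                                                keepLeaves))
}

#' Bundled default embryogenesis lineage tree (49 tissues)
#'
#' Zygote splits into ectoderm and mesendoderm; mesendoderm into mesoderm
#' and endoderm; sub-lineage nodes (neural, surface ectoderm, hematopoietic,
#' cardiovascular, musculoskeletal, urogenital, foregut, mid-hindgut) group
#' the 49 tissue leaves. The adrenal gland is flagged dual-origin (ectoderm
#' medulla / mesoderm cortex); sun-exposed skin, esophagus mucosa and whole
#' blood are flagged for postnatal clonal expansion. Classification rules
#' depend only on the germ-layer level, which is unambiguous; the
#' sub-lineage grouping is a decided encoding users may replace with their
#' own tree file.
#'
#' @return a [LineageTree-class]
#' @export
defaultLineageTree <- function() {
  grp <- list(
    neural = c("brain-amygdala", "brain-anterior-cingulate-cortex",
               "brain-caudate-basal-ganglia", "brain-cerebellar-hemisphere",
               "brain-cerebellum", "brain-cortex", "brain-frontal-cortex",
               "brain-hippocampus", "brain-hypothalamus",
               "brain-nucleus-accumbens", "brain-putamen-basal-ganglia",
               "brain-spinal-cord", "brain-substantia-nigra", "pituitary",
               "nerve-tibial"),
    `surface-ectoderm` = c("skin-sun-exposed", "skin-not-sun-exposed",
                           "minor-salivary-gland", "breast-mammary"),
    hematopoietic = c("whole-blood", "spleen", "cells-ebv-lymphocytes"),
    cardiovascular = c("heart-atrial-appendage", "heart-left-ventricle",
                       "artery-aorta", "artery-coronary", "artery-tibial"),
    musculoskeletal = c("muscle-skeletal", "adipose-subcutaneous",
                        "adipose-visceral", "cells-transformed-fibroblasts"),
    urogenital = c("ovary", "testis", "uterus", "vagina", "kidney-cortex",
                   "adrenal-gland"),
    foregut = c("esophagus-mucosa", "esophagus-muscularis",
                "esophagus-gastroesophageal-junction", "stomach", "liver",
                "pancreas", "lung", "thyroid"),
    `mid-hindgut` = c("colon-sigmoid", "colon-transverse",
                      "small-intestine", "prostate"))
  layerOf <- c(neural = "ectoderm", `surface-ectoderm` = "ectoderm",
               hematopoietic = "mesoderm", cardiovascular = "mesoderm",
               musculoskeletal = "mesoderm", urogenital = "mesoderm",
               foregut = "endoderm", `mid-hindgut` = "endoderm")
  edges <- rbind(c("zygote", "ectoderm"), c("zygote", "mesendoderm"),
                 c("mesendoderm", "mesoderm"), c("mesendoderm", "endoderm"))
  for (g in names(grp)) {
    edges <- rbind(edges, c(layerOf[[g]], g))
    for (leaf in grp[[g]]) edges <- rbind(edges, c(g, leaf))
  }
  LineageTree(edges)
}
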