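#' The 96 trinucleotide mutation contexts
#'
#' Fixed index order of the mutation catalog: the six pyrimidine-reference
#' substitutions (C>A, C>G, C>T, T>A, T>C, T>G) each over the 16 (5' base,
#' 3' base) flanking combinations in lexicographic order, written
#' `"A[C>A]A"`, `"A[C>A]C"`, ... (COSMIC convention).
#'
#' @return character vector of length 96
#' @export
contexts96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(f, t3)
      paste0(f, "[", s, "]", t3))))))
}

#' Build a 96-context mutation catalog
#'
#' Counts mutations into the 96 trinucleotide contexts. Purine-reference
#' mutations (ref A or G) are reverse-complemented into the
#' pyrimidine-reference frame, including their flanking bases. Mutations
#' whose flanks contain `N` are dropped and counted.
#'
#' @param mutations data.frame with columns `ref`, `alt`, `fiveprime`,
#'   `threeprime` (single flanking bases).
#' @return named integer vector of length 96 (attribute `dropped` = number
#'   of context-less mutations removed)
#' @export
buildCatalog <- function(mutations) {
  mutations <- as.data.frame(mutations)
  ctx <- contexts96()
  counts <- setNames(integer(96), ctx)
  if (!nrow(mutations)) {
    attr(counts, "dropped") <- 0L
    return(counts)
  }
  ref <- toupper(mutations$ref); alt <- toupper(mutations$alt)
  f5 <- toupper(mutations$fiveprime); f3 <- toupper(mutations$threeprime)
  bad <- !(f5 %in% c("A", "C", "G", "T")) | !(f3 %in% c("A", "C", "G", "T"))
  ref <- ref[!bad]; alt <- alt[!bad]; f5 <- f5[!bad]; f3 <- f3[!bad]
  pur <- ref %in% c("A", "G")
  ## reverse complement flips the strand: 5' flank <- revcomp(3' flank)
  tmp5 <- f5
  f5[pur] <- reverseComplement(f3[pur])
  f3[pur] <- reverseComplement(tmp5[pur])
  ref[pur] <- reverseComplement(ref[pur])
  alt[pur] <- reverseComplement(alt[pur])
  key <- paste0(f5, "[", ref, ">", alt, "]", f3)
  tab <- table(factor(key, levels = ctx))
  counts[] <- as.integer(tab)
  attr(counts, "dropped") <- sum(bad)
  counts
}

## Nonnegative least squares with a simplex cap: minimize ||b - A w||_2
## subject to w >= 0 and sum(w) <= 1. Solved by Lawson-Hanson NNLS on the
## system augmented with the slack variable s >= 0 and the heavily weighted
## equality sum(w) + s = 1 (weight rho makes the cap effectively exact).
nnlsSimplex <- function(A, b, rho = 1e6) {
  K <- ncol(A)
  Aaug <- rbind(cbind(A, 0), rho * rep(1, K + 1))
  baug <- c(b, rho)
  w <- nnlsLawsonHanson(Aaug, baug)
  w <- w[seq_len(K)]
  w[w < 0] <- 0
  if (sum(w) > 1) w <- w / sum(w)       # guard against penalty slack
  w
}

## Lawson-Hanson active-set NNLS (deterministic).
nnlsLawsonHanson <- function(A, b, tol = NULL, maxIter = NULL) {
  n <- ncol(A)
  if (is.null(maxIter)) maxIter <- 10L * n
  x <- numeric(n)
  P <- logical(n)
  w <- crossprod(A, b - A %*% x)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(A)) * nrow(A)
  iter <- 0L
  while (any(!P) && any(w[!P] > tol) && iter < maxIter) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, P, drop = FALSE]
      s[P] <- qr.coef(qr(Ap), b)
      s[P][is.na(s[P])] <- 0
      if (all(s[P] > tol)) break
      qidx <- P & s <= tol
      alphaStep <- min(x[qidx] / (x[qidx] - s[qidx]))
      x <- x + alphaStep * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  pmax(x, 0)
}

#' Refit a mutation catalog against reference signatures
#'
#' Expresses the normalized catalog as a nonnegative mixture of reference
#' signatures by constrained least squares: minimize
#' `||catalog/sum - R w||_2` subject to `w >= 0`, `sum(w) <= 1`. The fit is
#' deterministic and convex. For display, weights of at most `minWeight`
#' (default 0.1) are zeroed; raw weights are always retained.
#'
#' @param catalog 96-vector of context counts (see [buildCatalog()]).
#' @param reference 96 x K matrix of reference signatures, columns summing
#'   to 1.
#' @param minWeight report cutoff: only weights strictly greater than this
#'   appear in the reported set (default 0.1).
#' @return list with `weights` (raw, named), `reported` (thresholded),
#'   `residual_norm`
#' @export
refitSignatures <- function(catalog, reference, minWeight = 0.1) {
  reference <- as.matrix(reference)
  stopifnot(nrow(reference) == 96L, length(catalog) == 96L)
  colsum <- colSums(reference)
  if (any(abs(colsum - 1) > 1e-6))
    stop("reference signature columns must sum to 1")
  total <- sum(catalog)
  if (total <= 0) stop("catalog has no mutations")
  b <- as.numeric(catalog) / total
  w <- nnlsSimplex(reference, b)
  names(w) <- colnames(reference)
  reported <- w
  reported[reported <= minWeight] <- 0
  list(weights = w, reported = reported,
       residual_norm = sqrt(sum((b - reference %*% w)^2)))
}

#' Compare per-sample signature exposures between two groups
#'
#' Two-sided Mann-Whitney-Wilcoxon rank test on per-sample weights of one
#' signature (e.g. aflatoxin exposure in older vs younger donors).
#'
#' @param weightsA,weightsB numeric vectors of per-sample signature
#'   weights (>= 3 each).
#' @return list with `p`, `statistic`, `nA`, `nB`
#' @export
compareExposures <- function(weightsA, weightsB) {
  if (length(weightsA) < 3L || length(weightsB) < 3L)
    stop("each group needs at least 3 samples")
  wt <- suppressWarnings(stats::wilcox.test(weightsA, weightsB,
                                            alternative = "two.sided"))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       nA = length(weightsA), nB = length(weightsB))
}

#' Synthetic reference signature matrix
#'
#' Generates a synthetic 96 x K signature matrix for testing and
#' simulation: the first column is a clock-like profile concentrated on
#' C>T at NpCpG contexts (spontaneous deamination of methylated
#' cytosines), the remaining columns are sparse random profiles. Columns
#' sum to 1. This is a synthetic stand-in; supply a real catalog (e.g.
#' COSMIC) as a TSV for real analyses.
#'
#' @param K number of signatures (default 4).
#' @param seed RNG seed.
#' @param concentration sparsity of the random profiles (smaller = more
#'   peaked; default 0.08).
#' @return 96 x K matrix with context rownames and `sigN` colnames
#' @export
syntheticSignatures <- function(K = 4L, seed = 7L, concentration = 0.08) {
  ctx <- contexts96()
  set.seed(seed)
  ref <- matrix(0, 96L, K, dimnames = list(ctx, paste0("sig", seq_len(K))))
  ## clock-like: C>T at NpCpG (3' G) dominates, some other C>T, flat rest
  cpg <- grep("\\[C>T\\]G$", ctx)
  otherCT <- setdiff(grep("\\[C>T\\]", ctx), cpg)
  rest <- setdiff(seq_along(ctx), c(cpg, otherCT))
  ref[cpg, 1L] <- 0.70 / length(cpg)
  ref[otherCT, 1L] <- 0.20 / length(otherCT)
  ref[rest, 1L] <- 0.10 / length(rest)
  for (k in seq_len(K)[-1L]) {
    g <- stats::rgamma(96L, shape = concentration)
    ref[, k] <- g / sum(g)
  }
  ref
}

#' Read / write a signature matrix TSV
#'
#' TSV with a `context` column (the 96 contexts in the documented order)
#' and one column per signature.
#'
#' @param path file path
#' @param reference 96 x K matrix
#' @return `readSignatureMatrix`: the matrix
#' @export
readSignatureMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("context" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "context"), drop = FALSE])
  rownames(m) <- df$context
  m <- m[match(contexts96(), rownames(m)), , drop = FALSE]
  if (anyNA(m)) stop("signature matrix is missing contexts")
  m
}

#' @rdname readSignatureMatrix
#' @export
writeSignatureMatrix <- function(reference, path) {
  df <- data.frame(context = rownames(reference), reference,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
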