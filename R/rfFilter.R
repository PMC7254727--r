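RF_FEATURES <- c("alt_count", "coverage", "vaf", "strand_bias",
                 "blacklisted_gene", "mean_alt_bq")

checkFeatures <- function(calls) {
  calls <- as.data.frame(calls)
  miss <- setdiff(RF_FEATURES, names(calls))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  calls$blacklisted_gene <- as.numeric(calls$blacklisted_gene)
  calls
}

#' Label calls against a truth set
#'
#' A call is a true variant iff its truth VAF is >= 0.05 with at least 2
#' supporting reads in the truth data; everything else is a false variant.
#'
#' @param truthVaf truth-set VAF per call
#' @param truthAlt truth-set supporting read count per call
#' @return character vector `"true_variant"` / `"false_variant"`
#' @export
labelCalls <- function(truthVaf, truthAlt) {
  ifelse(truthVaf >= 0.05 & truthAlt >= 2L, "true_variant", "false_variant")
}

#' Build balanced train / test sets for the call filter
#'
#' An equal quota of records is sampled from every (class, VAF-bin) cell
#' populated in both classes, giving each set a similar number of true and
#' false events and an approximately uniform VAF distribution across
#' `nBins` bins of width 1/`nBins`; each cell is then split disjointly
#' between the train and test halves. To boost sensitivity for subclonal
#' variants, records with VAF < 0.10 are duplicated within the training
#' set (each contributes two training rows). The split is reproducible
#' from `seed`.
#'
#' @param labeled data.frame with the six feature columns plus `label`
#'   (`true_variant` / `false_variant`) and `truth_vaf`.
#' @param seed integer RNG seed.
#' @param trainFrac fraction of records assigned to training (default 0.5).
#' @param nBins VAF bins used for the uniformity stratification (default
#'   10).
#' @param lowVaf VAF below which training records are doubled (default
#'   0.10).
#' @return list with `train` and `test` data.frames
#' @export
buildTrainTest <- function(labeled, seed = 1L, trainFrac = 0.5,
                           nBins = 10L, lowVaf = 0.10) {
  labeled <- checkFeatures(labeled)
  stopifnot(all(c("label", "truth_vaf") %in% names(labeled)))
  bins <- pmin(floor(labeled$vaf * nBins), nBins - 1L)
  if (length(unique(bins)) < 2L)
    stop("need at least 2 populated VAF strata, got ",
         length(unique(bins)))
  minPer <- min(table(labeled$label))
  if (minPer < 2L)
    stop("too few records per class to balance: minimum class size ",
         minPer)
  set.seed(seed)
  ## uniform VAF distribution with similar true/false counts: sample the
  ## same quota from every (class x VAF bin) cell populated in both
  ## classes, then split each cell between train and test
  labs <- unique(labeled$label)
  cellIdx <- split(seq_len(nrow(labeled)),
                   list(labeled$label, bins), drop = FALSE)
  sharedBins <- Filter(function(b)
    all(vapply(labs, function(l)
      length(cellIdx[[paste(l, b, sep = ".")]]) > 0L, logical(1))),
    sort(unique(bins)))
  if (length(sharedBins) < 2L)
    stop("need at least 2 VAF strata populated in both classes, got ",
         length(sharedBins))
  quota <- min(vapply(sharedBins, function(b)
    min(vapply(labs, function(l)
      length(cellIdx[[paste(l, b, sep = ".")]]), integer(1))), integer(1)))
  inTrain <- logical(nrow(labeled))
  inPool <- logical(nrow(labeled))
  for (b in sharedBins) for (l in labs) {
    idx <- sample(cellIdx[[paste(l, b, sep = ".")]], quota)
    inPool[idx] <- TRUE
    inTrain[sample(idx, round(quota * trainFrac))] <- TRUE
  }
  train <- labeled[inPool & inTrain, , drop = FALSE]
  test <- labeled[inPool & !inTrain, , drop = FALSE]
  ## double low-VAF records inside the training set only (keeping the
  ## split disjoint at the record level)
  dup <- train[train$vaf < lowVaf, , drop = FALSE]
  train <- rbind(train, dup)
  list(train = train, test = test)
}

f1Score <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Train the random-forest call filter
#'
#' Fits a random forest on the six call features and selects the response
#' threshold maximizing F1 on the *training* set over a 0.01-step grid
#' (lowest threshold on ties). The threshold is always recomputed; any
#' previously published value is dataset-specific.
#'
#' @param train training data.frame from [buildTrainTest()].
#' @param seed integer RNG seed.
#' @param ntree number of trees (default 500).
#' @param ... further arguments to [randomForest::randomForest()].
#' @return an [RfModel-class]
#' @export
trainRf <- function(train, seed = 1L, ntree = 500L, ...) {
  train <- checkFeatures(train)
  stopifnot(nrow(train) > 0L)
  y <- factor(train$label, levels = c("false_variant", "true_variant"))
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = train[, RF_FEATURES], y = y, ntree = ntree, ...)
  resp <- predict(forest, train[, RF_FEATURES], type = "prob")[,
                                                               "true_variant"]
  grid <- seq(0.01, 0.99, by = 0.01)
  truth <- y == "true_variant"
  f1 <- vapply(grid, function(th) f1Score(truth, resp > th), numeric(1))
  thr <- grid[which.max(f1)]           # which.max takes the lowest on ties
  oob <- forest$err.rate[ntree, "OOB"]
  new("RfModel", forest = forest, threshold = thr,
      metadata = list(seed = seed, ntree = ntree, n_train = nrow(train),
                      train_f1 = max(f1), oob_error = unname(oob),
                      f1_curve = data.frame(threshold = grid, f1 = f1)))
}

#' Apply the call filter
#'
#' Returns the subset of calls whose forest response strictly exceeds the
#' model threshold, with response values attached for audit.
#'
#' @param calls data.frame with the six feature columns.
#' @param model an [RfModel-class]
#' @return data.frame of confident calls with a `response` column; the
#'   full response vector is attached as attribute `"response"`.
#' @export
classifyCalls <- function(calls, model) {
  stopifnot(is(model, "RfModel"))
  calls <- checkFeatures(calls)
  if (!nrow(calls)) {
    out <- cbind(calls, response = numeric(0))
    attr(out, "response") <- numeric(0)
    return(out)
  }
  resp <- predict(model@forest, calls[, RF_FEATURES],
                  type = "prob")[, "true_variant"]
  keep <- resp > model@threshold       # strict "exceeding"
  out <- cbind(calls[keep, , drop = FALSE],
               response = resp[keep])
  rownames(out) <- NULL
  attr(out, "response") <- resp
  out
}

#' Evaluate the call filter on labeled data
#'
#' Precision (TP / (TP + FP)) and recall (TP / (TP + FN)) overall and per
#' VAF stratum (germline-like, truth VAF >= `vafSplit`, vs somatic-like
#' below it). Empty strata report `NA` metrics, not 0.
#'
#' @param test labeled test data.frame.
#' @param model an [RfModel-class]
#' @param vafSplit stratum boundary (default 0.35).
#' @return data.frame with `stratum`, `precision`, `recall`, `f1`, `tp`,
#'   `fp`, `fn`, `tn`, `n`
#' @export
evaluateRf <- function(test, model, vafSplit = 0.35) {
  test <- checkFeatures(test)
  stopifnot("label" %in% names(test))
  resp <- predict(model@forest, test[, RF_FEATURES],
                  type = "prob")[, "true_variant"]
  pred <- resp > model@threshold
  truth <- test$label == "true_variant"
  strata <- list(
    overall = rep(TRUE, nrow(test)),
    germline_like = test$truth_vaf >= vafSplit,
    somatic_like = test$truth_vaf < vafSplit)
  do.call(rbind, lapply(names(strata), function(s) {
    i <- strata[[s]]
    tp <- sum(truth[i] & pred[i]); fp <- sum(!truth[i] & pred[i])
    fn <- sum(truth[i] & !pred[i]); tn <- sum(!truth[i] & !pred[i])
    data.frame(stratum = s,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
                    else NA_real_,
               tp = tp, fp = fp, fn = fn, tn = tn, n = sum(i))
  }))
}

#' Label-permutation null for the call filter
#'
#' Retrains the forest `nPerm` times on label-permuted training data and
#' returns the held-out F1 of each permuted model plus the real model's F1.
#' A real model whose F1 exceeds the permutation distribution demonstrates
#' signal beyond overfitting.
#'
#' @param train,test data.frames from [buildTrainTest()].
#' @param nPerm number of permutations (default 100).
#' @param seed integer RNG seed.
#' @param ntree trees per permuted forest (default 100; the permuted models
#'   only need the null F1, not a production fit).
#' @return list with `real_f1`, `perm_f1` (vector), `exceeds_q95`
#' @export
rfPermutationNull <- function(train, test, nPerm = 100L, seed = 1L,
                              ntree = 100L) {
  model <- trainRf(train, seed = seed, ntree = max(ntree, 200L))
  realF1 <- evaluateRf(test, model)$f1[1L]
  truthTest <- test$label == "true_variant"
  permF1 <- numeric(nPerm)
  set.seed(seed + 1L)
  for (b in seq_len(nPerm)) {
    ptrain <- train
    ptrain$label <- sample(ptrain$label)
    if (length(unique(ptrain$label)) < 2L) { permF1[b] <- 0; next }
    pm <- trainRf(ptrain, seed = seed + b, ntree = ntree)
    permF1[b] <- evaluateRf(test, pm)$f1[1L]
  }
  list(real_f1 = realF1, perm_f1 = permF1,
       exceeds_q95 = realF1 > stats::quantile(permF1, 0.95, names = FALSE))
}
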