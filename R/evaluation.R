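# Evaluation protocol: negative sampling, stratified k-fold splits, ranking
# metrics (AUROC / AUPR), redundancy-removal filters, and end-to-end
# cross-validation.

#' Sample negative drug-protein pairs
#'
#' All known interactions are positives; `ratio` unlabeled pairs per
#' positive are drawn uniformly without replacement from the zero entries of
#' the label matrix. If fewer zero pairs exist than requested, all of them
#' are taken with a warning. Deterministic per seed.
#'
#' @param Y binary drug x protein label matrix.
#' @param ratio negatives per positive (>= 1).
#' @param seed RNG seed.
#' @return data.frame with columns `drug`, `protein` (1-based indices) and
#'   `label` (1/0); attributes `ratio` and `seed`.
#' @export
sampleNegatives <- function(Y, ratio = 10, seed = 1L) {
  if (ratio < 1) stop("ratio must be >= 1")
  Y <- as.matrix(Y)
  pos <- which(Y == 1, arr.ind = TRUE)
  neg <- which(Y == 0, arr.ind = TRUE)
  if (nrow(pos) == 0) stop("label matrix has no positive pairs")
  want <- round(ratio * nrow(pos))
  if (nrow(neg) < want) {
    warning("only ", nrow(neg), " negative pairs available (wanted ", want,
            "); taking all of them")
    take <- seq_len(nrow(neg))
  } else {
    take <- .withSeed(seed, sample.int(nrow(neg), want))
  }
  out <- data.frame(
    drug    = c(pos[, 1], neg[take, 1]),
    protein = c(pos[, 2], neg[take, 2]),
    label   = c(rep(1L, nrow(pos)), rep(0L, length(take))))
  attr(out, "ratio") <- ratio
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Stratified k-fold split of a pair sample
#'
#' Positives and negatives are shuffled separately and dealt round-robin, so
#' the folds partition the sample, sizes differ by at most one per stratum,
#' and every fold preserves the global positive:negative ratio within
#' rounding. Deterministic per seed.
#'
#' @param sample pair data.frame from [sampleNegatives()].
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return list of `k` integer vectors of row indices into `sample`.
#' @export
kfoldSplit <- function(sample, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (!nrow(sample)) stop("empty pair sample")
  posIdx <- which(sample$label == 1)
  negIdx <- which(sample$label == 0)
  if (length(posIdx) < k)
    stop("stratification error: ", length(posIdx), " positives for ", k, " folds")
  .withSeed(seed, {
    posIdx <- sample(posIdx)
    negIdx <- sample(negIdx)
  })
  folds <- lapply(seq_len(k), function(f)
    sort(c(posIdx[seq(f, length(posIdx), by = k)],
           negIdx[seq_along(negIdx)[(seq_along(negIdx) - 1L) %% k + 1L == f]])))
  folds
}

#' Ranking metrics: AUROC and AUPR
#'
#' AUROC uses the Mann-Whitney pairwise formulation via mean ranks, so tied
#' scores earn half credit. AUPR is the step-wise (non-interpolated)
#' integral of precision over recall across descending distinct-score
#' thresholds, with tied scores entering together.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels, same length.
#' @return named numeric vector `c(auroc = , aupr = )`.
#' @export
rankingMetrics <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("undefined metric: need at least one positive and one negative label")
  r <- rank(scores)  # mean ranks on ties
  auroc <- (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))            # distinct-score groups, descending
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  last <- which(diff(c(grp, Inf)) != 0)    # last index of each group
  tpg <- tp[last]; fpg <- fp[last]
  rec <- tpg / P
  prec <- tpg / (tpg + fpg)
  aupr <- sum(diff(c(0, rec)) * prec)
  c(auroc = auroc, aupr = aupr)
}

#' Redundancy-removal filter for the label matrix
#'
#' Homology and near-duplicate drugs inflate cross-validation performance:
#' a held-out interaction is trivially recoverable when an almost identical
#' drug (or protein) with the same partner stays in training. The filter
#' scans the positive pairs in lexicographic (drug, protein) order and
#' removes a pair when an already-kept positive shares its protein with a
#' drug more similar than a drug threshold, or shares its drug with a
#' protein whose sequence identity exceeds the protein threshold
#' (keep-first rule, deterministic and order-independent by construction).
#'
#' Which similarity matrices are supplied selects the filtering mode:
#' chemical structure only, a single association-Jaccard similarity
#' (disease or side-effect), the protein sequence identity, or any
#' combination (a pair is removed when any enabled rule fires).
#'
#' @param Y binary label matrix.
#' @param drugSims named list of drug x drug similarity matrices (or
#'   [SimilarityMatrix-class]); may be empty.
#' @param proteinSims named list of protein x protein similarity matrices;
#'   may be empty.
#' @param drugThreshold similarity above which two drugs are redundant
#'   (default 0.6; applies to chemical structure and association Jaccard).
#' @param proteinThreshold sequence identity above which two proteins are
#'   redundant (default 0.4).
#' @return list with `Y` (reduced matrix) and `removed` (data.frame log with
#'   columns `drug`, `protein`, `rule`).
#' @export
redundancyFilter <- function(Y, drugSims = list(), proteinSims = list(),
                             drugThreshold = 0.6, proteinThreshold = 0.4) {
  Y <- as.matrix(Y)
  if (!length(drugSims) && !length(proteinSims))
    stop("configuration error: no similarity matrix supplied for any filter mode")
  asMat <- function(s) if (is(s, "SimilarityMatrix")) s@matrix else as.matrix(s)
  drugSims <- lapply(drugSims, asMat)
  proteinSims <- lapply(proteinSims, asMat)

  pos <- which(Y == 1, arr.ind = TRUE)
  pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
  keptByProtein <- vector("list", ncol(Y))  # drugs of kept pairs per protein
  keptByDrug <- vector("list", nrow(Y))     # proteins of kept pairs per drug
  removed <- list()
  Yout <- Y
  for (idx in seq_len(nrow(pos))) {
    i <- pos[idx, 1]; j <- pos[idx, 2]
    rule <- NULL
    for (nm in names(drugSims)) {
      others <- keptByProtein[[j]]
      if (length(others) && any(drugSims[[nm]][i, others] > drugThreshold)) {
        rule <- paste0("drug:", nm); break
      }
    }
    if (is.null(rule)) for (nm in names(proteinSims)) {
      others <- keptByDrug[[i]]
      if (length(others) && any(proteinSims[[nm]][j, others] > proteinThreshold)) {
        rule <- paste0("protein:", nm); break
      }
    }
    if (is.null(rule)) {
      keptByProtein[[j]] <- c(keptByProtein[[j]], i)
      keptByDrug[[i]] <- c(keptByDrug[[i]], j)
    } else {
      Yout[i, j] <- 0
      removed[[length(removed) + 1L]] <- data.frame(drug = i, protein = j,
                                                    rule = rule)
    }
  }
  list(Y = Yout,
       removed = if (length(removed)) do.call(rbind, removed)
                 else data.frame(drug = integer(), protein = integer(),
                                 rule = character()))
}

#' K-fold cross-validated evaluation of the full pipeline
#'
#' Builds the similarity inventory and the diffusion embeddings once -- the
#' drug-protein label matrix is excluded from every similarity network and
#' diffusion input by construction, so these stages are identical for every
#' fold and held-out edges cannot leak through them. Per fold, the fold's
#' positives are zeroed in the training label matrix, all held-out pairs
#' (positives and sampled negatives) are masked out of the loss, the model
#' is trained, and the held-out pairs are scored.
#'
#' @param set a [HetNetSet-class].
#' @param config configuration list; missing keys take [defaultConfig()]
#'   values.
#' @param inventory,embeddings optional precomputed similarity inventory and
#'   `list(drug =, protein =)` embeddings (reused across e.g. sweep cells).
#' @return An [EvalReport-class].
#' @export
crossValidate <- function(set, config = list(), inventory = NULL,
                          embeddings = NULL) {
  cfg <- .mergeConfig(defaultConfig(), config)
  Y <- labelMatrix(set)
  cfg <- .capDims(cfg, nrow(Y), ncol(Y))
  if (is.null(inventory))
    inventory <- buildInventory(set,
      drugNetworks = cfg$networks$drug,
      proteinNetworks = cfg$networks$protein,
      intraMode = cfg$networks$intraMode)
  if (is.null(embeddings))
    embeddings <- list(
      drug = embedNodeType(inventory@drugNetworks, d = cfg$embedding$dDrug,
                           p = cfg$diffusion$p,
                           pseudocount = .naToNull(cfg$embedding$pseudocount),
                           tol = cfg$diffusion$tol, maxIter = cfg$diffusion$maxIter,
                           backend = cfg$diffusion$backend),
      protein = embedNodeType(inventory@proteinNetworks, d = cfg$embedding$dProtein,
                              p = cfg$diffusion$p,
                              pseudocount = .naToNull(cfg$embedding$pseudocount),
                              tol = cfg$diffusion$tol, maxIter = cfg$diffusion$maxIter,
                              backend = cfg$diffusion$backend))

  sampleDf <- sampleNegatives(Y, ratio = cfg$cv$ratio, seed = cfg$cv$seed)
  folds <- kfoldSplit(sampleDf, k = cfg$cv$folds,
                      seed = .childSeed(cfg$cv$seed, 1))

  rows <- lapply(seq_along(folds), function(f) {
    test <- sampleDf[folds[[f]], , drop = FALSE]
    testIdx <- cbind(test$drug, test$protein)
    Ytrain <- Y
    Ytrain[testIdx[test$label == 1, , drop = FALSE]] <- 0
    if (cfg$train$negatives == "sampled") {
      mask <- matrix(0, nrow(Y), ncol(Y))
      trainPairs <- sampleDf[-folds[[f]], , drop = FALSE]
      mask[cbind(trainPairs$drug, trainPairs$protein)] <- 1
    } else {
      mask <- matrix(1, nrow(Y), ncol(Y))
    }
    mask[testIdx] <- 0  # leakage guard: held-out pairs never enter the loss
    fit <- trainModel(Ytrain, embeddings$drug, embeddings$protein,
                      inventory = inventory, mask = mask,
                      gcnEnabled = cfg$gcn$enabled,
                      activation = cfg$gcn$activation,
                      adjacencyMode = cfg$gcn$adjacencyMode,
                      k = .naToNull(cfg$train$k), lr = cfg$train$lr,
                      epochs = cfg$train$epochs,
                      optimizer = cfg$train$optimizer,
                      weightDecay = cfg$train$weightDecay,
                      seed = .childSeed(cfg$train$seed, f))
    met <- rankingMetrics(fit$scores[testIdx], test$label)
    data.frame(fold = f, aupr = met[["aupr"]], auroc = met[["auroc"]],
               n_test = nrow(test), n_test_pos = sum(test$label))
  })
  report <- new("EvalReport", perFold = do.call(rbind, rows),
                ratio = cfg$cv$ratio, seed = as.integer(cfg$cv$seed),
                config = cfg)
  validObject(report)
  report
}

#' Summarise an evaluation report
#' @param object an [EvalReport-class].
#' @param ... unused.
#' @return named list with mean and sd of AUROC and AUPR.
#' @export
setMethod("summary", "EvalReport", function(object, ...) {
  df <- object@perFold
  list(meanAUROC = mean(df$auroc), sdAUROC = stats::sd(df$auroc),
       meanAUPR = mean(df$aupr), sdAUPR = stats::sd(df$aupr),
       folds = nrow(df), ratio = object@ratio)
})
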