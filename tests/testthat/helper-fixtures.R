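# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

# Random valid similarity matrix (symmetric, [0,1], unit diagonal).
randomSimilarity <- function(n, seed, nodeType = "drug") {
  set.seed(seed)
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  SimilarityMatrix(m, nodeType)
}

# Small synthetic collection for fast structural tests.
tinyDataset <- function(seed = 11) {
  simulateHetNet(syntheticConfig(
    nDrugs = 15L, nProteins = 20L, nDiseases = 8L, nSideEffects = 6L,
    latentRank = 2L, seed = as.integer(seed),
    densities = list(label = 0.15, drugDisease = 0.2, proteinDisease = 0.2,
                     drugSideEffect = 0.25, drugDrug = 0.2,
                     proteinProtein = 0.2)))
}

# Fast CV settings for structural (non-acceptance) tests.
fastCvConfig <- function(...) {
  base <- list(embedding = list(dDrug = 5L, dProtein = 6L),
               train = list(epochs = 300L),
               cv = list(folds = 5L, ratio = 5))
  utils::modifyList(base, list(...))
}

# --- independent oracles ---------------------------------------------------

# Jaccard over explicit neighbour sets.
bruteJaccard <- function(m, excludeSelf = FALSE) {
  n <- nrow(m)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    Ni <- which(m[i, ] != 0); Nj <- which(m[j, ] != 0)
    if (excludeSelf) { Ni <- setdiff(Ni, i); Nj <- setdiff(Nj, j) }
    u <- length(union(Ni, Nj))
    out[i, j] <- if (u == 0) 0 else length(intersect(Ni, Nj)) / u
  }
  out
}

# Pairwise Mann-Whitney AUROC with half credit on ties.
bruteAuroc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

# AUPR by direct threshold counting (independent code path from the
# cumulative-sum implementation).
bruteAupr <- function(scores, labels) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prevRec <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(sel & labels == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
  }
  area
}

# Alternating least squares for the shared-feature objective
# sum_r ||X t(W^r) - L^r||_F^2 at rank d; one run from a random start.
alsObjective <- function(Ls, d, iters = 300, seed = 1) {
  set.seed(seed)
  Lcat <- do.call(cbind, Ls)
  n <- nrow(Lcat)
  X <- matrix(rnorm(n * d), n, d)
  W <- matrix(rnorm(ncol(Lcat) * d), ncol(Lcat), d)
  for (it in seq_len(iters)) {
    X <- t(solve(crossprod(W) + 1e-12 * diag(d), t(Lcat %*% W)))
    W <- t(solve(crossprod(X) + 1e-12 * diag(d), crossprod(X, Lcat)))
  }
  sum((X %*% t(W) - Lcat)^2)
}

# Certificate check for the redundancy filter: no two kept positives
# conflict, and every removed positive conflicts with a lexicographically
# earlier kept one.
checkRedundancyCertificate <- function(Yin, Yout, drugSims, proteinSims,
                                       drugThreshold, proteinThreshold) {
  conflict <- function(p1, p2) {
    # p = c(drug, protein)
    if (p1[2] == p2[2] && p1[1] != p2[1])
      for (s in drugSims) if (s[p1[1], p2[1]] > drugThreshold) return(TRUE)
    if (p1[1] == p2[1] && p1[2] != p2[2])
      for (s in proteinSims) if (s[p1[2], p2[2]] > proteinThreshold) return(TRUE)
    FALSE
  }
  kept <- which(Yout == 1, arr.ind = TRUE)
  kept <- kept[order(kept[, 1], kept[, 2]), , drop = FALSE]
  removed <- which(Yin == 1 & Yout == 0, arr.ind = TRUE)
  for (a in seq_len(nrow(kept))) for (b in seq_len(nrow(kept)))
    if (a < b && conflict(kept[a, ], kept[b, ])) return(FALSE)
  for (r in seq_len(nrow(removed))) {
    rp <- removed[r, ]
    earlier <- kept[kept[, 1] < rp[1] |
                    (kept[, 1] == rp[1] & kept[, 2] < rp[2]), , drop = FALSE]
    hit <- FALSE
    for (a in seq_len(nrow(earlier)))
      if (conflict(rp, earlier[a, ])) { hit <- TRUE; break }
    if (!hit) return(FALSE)
  }
  TRUE
}
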