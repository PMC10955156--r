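# Diffusion component analysis: compress (possibly many) diffusion-state
# matrices into shared low-dimensional node features by SVD of the
# log-transformed diffusion matrices. Node features X are shared across
# networks; each network keeps its own context block W^r, and X %*% t(W^r)
# is the best shared-feature rank-d approximation of log diffusion matrix r.

#' Elementwise log of a diffusion state with pseudocount smoothing
#'
#' `L = log(S + pseudocount)`. Diffusion states contain exact zeros (e.g.
#' unreachable nodes, or any off-diagonal entry at p = 1), so a strictly
#' positive pseudocount is required for finiteness; the customary choice is
#' `1/n`, the visiting probability of a uniform walk.
#'
#' @param state a [DiffusionState-class] or plain matrix.
#' @param pseudocount strictly positive smoothing constant; `NULL` (default)
#'   means `1/n`.
#' @return n x n numeric matrix.
#' @export
logDiffusion <- function(state, pseudocount = NULL) {
  S <- if (is(state, "DiffusionState")) state@matrix else as.matrix(state)
  if (is.null(pseudocount)) pseudocount <- 1 / nrow(S)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  log(S + pseudocount)
}

# Deterministic sign convention: flip each singular-vector pair so the
# largest-magnitude entry of the U column is positive.
.fixSigns <- function(U, V) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  list(U = U, V = V)
}

.dcaFromConcat <- function(Lcat, n, K, d) {
  sv <- svd(Lcat, nu = d, nv = d)
  fx <- .fixSigns(sv$u, sv$v)
  scale <- sqrt(sv$d[seq_len(d)])
  X <- fx$U * rep(scale, each = n)
  Wall <- fx$V * rep(scale, each = nrow(fx$V))
  contexts <- lapply(seq_len(K), function(r)
    Wall[((r - 1) * n + 1):(r * n), , drop = FALSE])
  new("EmbeddingPair", features = X, contexts = contexts, d = as.integer(d),
      singularValues = sv$d[seq_len(d)])
}

#' Rank-d embedding of a single log diffusion matrix
#'
#' SVD `L = U S V^T`; features `X = U_d S_d^0.5`, contexts
#' `W = V_d S_d^0.5`, so `X %*% t(W)` is the best rank-d approximation of
#' `L` in Frobenius norm (the minimiser of the sum-of-squared-errors
#' objective). A deterministic sign convention (largest-magnitude entry of
#' each feature column positive) removes the SVD sign ambiguity.
#'
#' @param L n x n log diffusion matrix from [logDiffusion()].
#' @param d target dimension, `1 <= d <= n`.
#' @return An [EmbeddingPair-class] with one context matrix.
#' @export
dcaSingle <- function(L, d) {
  L <- as.matrix(L)
  n <- nrow(L)
  if (d < 1 || d > n) stop("d must satisfy 1 <= d <= n (got d = ", d,
                           ", n = ", n, ")")
  .dcaFromConcat(L, n, 1L, as.integer(d))
}

#' Shared-feature rank-d embedding of several log diffusion matrices
#'
#' Minimises `sum_r || X %*% t(W^r) - L^r ||_F^2` with the node features X
#' shared across all K networks. Stacking the unknown contexts as
#' `W = [W^1; ...; W^K]` turns this into a single rank-d approximation of
#' the horizontal concatenation `[L^1 ... L^K]` (n x Kn), solved exactly by
#' its SVD; `W^r` is the r-th n-row block of `V_d S_d^0.5`.
#'
#' @param Ls list of K square log diffusion matrices of identical size.
#' @param d target dimension, `1 <= d <= n`.
#' @return An [EmbeddingPair-class] with K context matrices.
#' @export
dcaMulti <- function(Ls, d) {
  if (!length(Ls)) stop("need at least one log diffusion matrix")
  Ls <- lapply(Ls, as.matrix)
  n <- nrow(Ls[[1]])
  for (L in Ls)
    if (!identical(dim(L), c(n, n)))
      stop("all log diffusion matrices must be ", n, " x ", n)
  if (d < 1 || d > n) stop("d must satisfy 1 <= d <= n (got d = ", d,
                           ", n = ", n, ")")
  .dcaFromConcat(do.call(cbind, Ls), n, length(Ls), as.integer(d))
}

#' Embed one node type: diffusion, log transform, shared SVD features
#'
#' Composes [transitionMatrix()] -> [rwr()] -> [logDiffusion()] ->
#' [dcaMulti()] over the similarity networks of one node type.
#'
#' @param networks named list of [SimilarityMatrix-class] for the node type.
#' @param d embedding dimension.
#' @param p restart probability (default 0.5).
#' @param pseudocount log smoothing constant (`NULL` = `1/n`).
#' @param tol,maxIter,backend passed to [diffuseNetworks()].
#' @return An [EmbeddingPair-class]; feature rows carry the node ids.
#' @export
embedNodeType <- function(networks, d, p = 0.5, pseudocount = NULL,
                          tol = 1e-8, maxIter = 1000L,
                          backend = c("iterative", "closed_form")) {
  if (!length(networks)) stop("need at least one similarity network")
  states <- diffuseNetworks(networks, p = p, tol = tol, maxIter = maxIter,
                            backend = match.arg(backend))
  Ls <- lapply(states, logDiffusion, pseudocount = pseudocount)
  emb <- dcaMulti(Ls, d)
  ids <- rownames(states[[1]]@matrix)
  if (!is.null(ids)) rownames(emb@features) <- ids
  emb
}

#' Dump embedding features as TSV (node id + d columns)
#' @param emb an [EmbeddingPair-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEmbedding <- function(emb, path) {
  X <- emb@features
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(X)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("id", paste0("dim", seq_len(ncol(X)))), collapse = "\t"), con)
  for (i in seq_len(nrow(X)))
    writeLines(paste(c(ids[i], format(X[i, ], digits = 12, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}
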