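# Spectral graph-convolution feature update: one dimension-preserving layer
# per node type, H = sigma(Ahat X W) with the self-loop symmetric
# normalisation Ahat = Dtilde^{-1/2} (A + I) Dtilde^{-1/2}.

#' Self-loop symmetric normalisation of a similarity network
#'
#' `Atilde = A + I`, `Dtilde = diag(rowSums(Atilde))`,
#' `Ahat = Dtilde^{-1/2} Atilde Dtilde^{-1/2}`. Distinct from the row
#' normalisation used for diffusion: this one is symmetric and its spectrum
#' lies in \[-1, 1\]. Since a [SimilarityMatrix-class] already carries a unit
#' diagonal, the explicit self-loop is added on top of it; degrees are
#' strictly positive either way.
#'
#' @param sim a [SimilarityMatrix-class] or symmetric nonnegative matrix.
#' @return symmetric normalised adjacency matrix.
#' @export
normalizeAdjacency <- function(sim) {
  A <- if (is(sim, "SimilarityMatrix")) sim@matrix else as.matrix(sim)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (length(A) && max(abs(A - t(A))) > 1e-10) stop("adjacency must be symmetric")
  if (any(A < 0)) stop("adjacency must be nonnegative")
  At <- A + diag(nrow(A))
  dis <- 1 / sqrt(rowSums(At))
  Ahat <- At * outer(dis, dis)
  Ahat <- (Ahat + t(Ahat)) / 2  # kill rounding asymmetry
  dimnames(Ahat) <- dimnames(A)
  Ahat
}

#' One spectral graph-convolution layer
#'
#' `H = sigma(Ahat %*% X %*% W)`: a one-hop smoothing of the node features
#' over the normalised adjacency followed by a linear map and nonlinearity.
#'
#' @param adj normalised adjacency from [normalizeAdjacency()].
#' @param X node feature matrix (rows match `adj`).
#' @param W weight matrix (rows match `ncol(X)`).
#' @param activation `"relu"` (default), `"sigmoid"` or `"identity"`.
#' @return feature matrix H with `ncol(W)` columns.
#' @export
gcnLayer <- function(adj, X, W, activation = "relu") {
  if (nrow(X) != nrow(adj)) stop("feature rows must match adjacency size")
  if (nrow(W) != ncol(X)) stop("weight rows must match feature width")
  act <- .getActivation(activation)
  H <- act$f(adj %*% X %*% W)
  rownames(H) <- rownames(X)
  H
}

#' Combine a node type's similarity networks into one GCN adjacency
#'
#' The convolution uses a single similarity network per node type; when the
#' inventory holds several, `mode = "mean"` (default) takes their
#' elementwise mean before normalising, while `mode = "primary"` uses only
#' the precomputed chemical (drug) / sequence (protein) similarity.
#'
#' @param inventory a [SimilarityInventory-class].
#' @param nodeType `"drug"` or `"protein"`.
#' @param mode `"mean"` or `"primary"`.
#' @return normalised adjacency matrix.
#' @export
buildGcnAdjacency <- function(inventory, nodeType = c("drug", "protein"),
                              mode = c("mean", "primary")) {
  nodeType <- match.arg(nodeType)
  mode <- match.arg(mode)
  nets <- if (nodeType == "drug") inventory@drugNetworks
          else inventory@proteinNetworks
  if (!length(nets)) stop("empty inventory for node type '", nodeType, "'")
  if (mode == "primary") {
    want <- if (nodeType == "drug") "chemical" else "sequence"
    if (!want %in% names(nets))
      stop("mode 'primary' needs the '", want, "' network in the inventory")
    A <- nets[[want]]@matrix
  } else {
    A <- Reduce(`+`, lapply(nets, function(s) s@matrix)) / length(nets)
  }
  normalizeAdjacency(A)
}

#' Seeded Glorot-style initial GCN weights for both node types
#'
#' Dimension-preserving square weight matrices (output width = input width),
#' drawn from a symmetric uniform range scaled by fan-in + fan-out.
#'
#' @param dDrug,dProtein feature widths of the two sides.
#' @param seed RNG seed.
#' @return list with `drug` and `protein` weight matrices.
#' @export
initGcnWeights <- function(dDrug, dProtein, seed = 1L) {
  .withSeed(seed, list(drug = .glorotInit(dDrug, dDrug),
                       protein = .glorotInit(dProtein, dProtein)))
}
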