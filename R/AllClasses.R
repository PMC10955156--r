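#' @import methods
NULL

.NODE_TYPES <- c("drug", "protein", "disease", "side_effect")

# ---------------------------------------------------------------------------
# SimilarityMatrix
# ---------------------------------------------------------------------------

#' Square symmetric similarity matrix for one node type
#'
#' Entries are unitless similarities in \[0, 1\]; the diagonal is forced to 1
#' on construction (self-similarity), which guarantees strictly positive row
#' sums for the random-walk normalisation and positive degrees for the
#' graph-convolution normalisation.
#'
#' @slot matrix square numeric matrix with node ids as dimnames.
#' @slot nodeType one of `"drug"`, `"protein"`, `"disease"`, `"side_effect"`.
#'
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(matrix = "matrix", nodeType = "character"))

setValidity("SimilarityMatrix", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (!(object@nodeType %in% .NODE_TYPES))
    msg <- c(msg, sprintf("unknown node type '%s'", object@nodeType))
  if (nrow(m) > 0) {
    if (max(abs(m - t(m))) > 1e-10) msg <- c(msg, "matrix must be symmetric (tol 1e-10)")
    if (min(m) < -1e-12 || max(m) > 1 + 1e-12) msg <- c(msg, "entries must lie in [0, 1]")
    if (max(abs(diag(m) - 1)) > 1e-12) msg <- c(msg, "diagonal entries must equal 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#'
#' Applies the standard load-time repairs: symmetrisation as `(M + t(M))/2`
#' when the asymmetry is at most `1e-6`, clipping of entries that overshoot
#' `[0, 1]` by at most `1e-9`, and forcing a unit diagonal. Violations
#' beyond these tolerances are errors, not repairs.
#'
#' @param m square numeric matrix.
#' @param nodeType node type label.
#' @param ids optional character vector of node ids (defaults to existing
#'   dimnames or `n1..nN`).
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(m, nodeType, ids = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m))
    stop("similarity matrix must be square, got ", nrow(m), "x", ncol(m))
  storage.mode(m) <- "double"
  asym <- if (nrow(m)) max(abs(m - t(m))) else 0
  if (asym > 1e-6)
    stop("similarity matrix asymmetric beyond tolerance (max |M - t(M)| = ",
         format(asym), ")")
  m <- (m + t(m)) / 2
  if (nrow(m)) {
    lo <- min(m); hi <- max(m)
    if (lo < -1e-9 || hi > 1 + 1e-9)
      stop("similarity entries outside [0, 1]: range [",
           format(lo), ", ", format(hi), "]")
    m[m < 0] <- 0
    m[m > 1] <- 1
    diag(m) <- 1
  }
  if (is.null(ids)) ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  new("SimilarityMatrix", matrix = m, nodeType = nodeType)
}

# ---------------------------------------------------------------------------
# BipartiteAssociation
# ---------------------------------------------------------------------------

#' Binary bipartite association matrix between two node types
#'
#' Rows and columns are indexed by the node registries of the two types.
#' When `rowType == colType` the matrix is a square symmetric interaction
#' network (drug-drug, protein-protein).
#'
#' @slot matrix binary numeric matrix, node ids as dimnames.
#' @slot rowType,colType node types of the rows and columns.
#'
#' @exportClass BipartiteAssociation
setClass("BipartiteAssociation",
  representation(matrix = "matrix", rowType = "character", colType = "character"))

setValidity("BipartiteAssociation", function(object) {
  m <- object@matrix
  msg <- character()
  if (!all(c(object@rowType, object@colType) %in% .NODE_TYPES))
    msg <- c(msg, "unknown node type")
  if (length(m) && !all(m %in% c(0, 1)))
    msg <- c(msg, "association entries must be binary (0/1)")
  if (object@rowType == object@colType) {
    if (nrow(m) != ncol(m)) msg <- c(msg, "intra-type association must be square")
    else if (length(m) && max(abs(m - t(m))) > 0)
      msg <- c(msg, "intra-type association must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BipartiteAssociation
#' @param m numeric matrix (coerced to binary unless already 0/1).
#' @param rowType,colType node types.
#' @param rowIds,colIds optional id vectors (default: dimnames).
#' @param binarize set nonzero entries to 1 (default `TRUE`).
#' @return A [BipartiteAssociation-class] object.
#' @export
BipartiteAssociation <- function(m, rowType, colType,
                                 rowIds = NULL, colIds = NULL, binarize = TRUE) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (binarize) m[] <- as.numeric(m != 0)
  if (is.null(rowIds)) rowIds <- rownames(m)
  if (is.null(colIds)) colIds <- colnames(m)
  if (is.null(rowIds)) rowIds <- paste0(substr(rowType, 1, 1), seq_len(nrow(m)))
  if (is.null(colIds)) colIds <- paste0(substr(colType, 1, 1), seq_len(ncol(m)))
  dimnames(m) <- list(rowIds, colIds)
  new("BipartiteAssociation", matrix = m, rowType = rowType, colType = colType)
}

# ---------------------------------------------------------------------------
# HetNetSet
# ---------------------------------------------------------------------------

#' Heterogeneous drug/protein/disease/side-effect network collection
#'
#' The single source of truth for node indexing. Holds the four node
#' registries, the bipartite association networks, the two intra-type
#' interaction networks, and the two precomputed similarity matrices
#' (drug chemical structure, protein sequence).
#'
#' The drug-protein association is the supervision label matrix `Y`. It is
#' deliberately kept out of every similarity network, diffusion input and
#' embedding: only the training mask and the decoder loss ever see it
#' (leakage guard).
#'
#' @slot registries named list of character id vectors, one per node type.
#' @slot associations named list of [BipartiteAssociation-class]:
#'   `drug_protein` (the label matrix), `drug_disease`, `protein_disease`,
#'   `drug_side_effect`.
#' @slot intraType named list: `drug_drug`, `protein_protein`.
#' @slot precomputed named list of [SimilarityMatrix-class]:
#'   `drug_chemical`, `protein_sequence`.
#'
#' @exportClass HetNetSet
setClass("HetNetSet",
  representation(registries = "list", associations = "list",
                 intraType = "list", precomputed = "list"))

setValidity("HetNetSet", function(object) {
  msg <- character()
  reg <- object@registries
  for (ty in names(reg)) {
    if (anyDuplicated(reg[[ty]]))
      msg <- c(msg, sprintf("duplicate ids in %s registry", ty))
  }
  chk <- function(a, nm) {
    rt <- a@rowType; ct <- a@colType
    if (!identical(rownames(a@matrix), reg[[rt]]))
      msg <<- c(msg, sprintf("%s rows inconsistent with %s registry", nm, rt))
    if (!identical(colnames(a@matrix), reg[[ct]]))
      msg <<- c(msg, sprintf("%s columns inconsistent with %s registry", nm, ct))
  }
  for (nm in names(object@associations)) chk(object@associations[[nm]], nm)
  for (nm in names(object@intraType)) chk(object@intraType[[nm]], nm)
  for (nm in names(object@precomputed)) {
    s <- object@precomputed[[nm]]
    if (!identical(rownames(s@matrix), reg[[s@nodeType]]))
      msg <- c(msg, sprintf("%s inconsistent with %s registry", nm, s@nodeType))
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# DiffusionState
# ---------------------------------------------------------------------------

#' Random-walk-with-restart diffusion states of one similarity network
#'
#' Row `i` is the stationary visiting-probability distribution of a restart
#' walk seeded at node `i`; a topology-aware signature of the node.
#'
#' @slot matrix n x n row-stochastic matrix.
#' @slot restartProb restart probability `p` in (0, 1\].
#' @slot iterations iterations used by the power iteration (0 for the
#'   closed-form backend).
#' @slot converged logical convergence flag.
#' @slot source name of the similarity network diffused over.
#'
#' @exportClass DiffusionState
setClass("DiffusionState",
  representation(matrix = "matrix", restartProb = "numeric",
                 iterations = "integer", converged = "logical",
                 source = "character"))

setValidity("DiffusionState", function(object) {
  m <- object@matrix
  p <- object@restartProb
  msg <- character()
  if (length(p) != 1 || p <= 0 || p > 1) msg <- c(msg, "restartProb must be in (0, 1]")
  if (length(m)) {
    if (min(m) < -1e-12) msg <- c(msg, "diffusion entries must be nonnegative")
    if (max(abs(rowSums(m) - 1)) > 1e-8) msg <- c(msg, "rows must sum to 1 (tol 1e-8)")
    if (min(diag(m)) < p - 1e-8)
      msg <- c(msg, "diagonal below restart mass lower bound p")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# EmbeddingPair
# ---------------------------------------------------------------------------

#' Shared node features and per-network context features
#'
#' The result of diffusion component analysis: `X = U_d S_d^0.5` from the SVD
#' of the (concatenated) log diffusion matrices, with one context block
#' `W^r = V_d^r S_d^0.5` per input network so that `X %*% t(W^r)` is the best
#' shared-feature rank-d approximation of the r-th log diffusion matrix.
#'
#' @slot features n x d matrix `X`, one row per node.
#' @slot contexts list of n x d context matrices, one per network.
#' @slot d embedding dimension.
#' @slot singularValues the d retained singular values (non-increasing).
#'
#' @exportClass EmbeddingPair
setClass("EmbeddingPair",
  representation(features = "matrix", contexts = "list", d = "integer",
                 singularValues = "numeric"))

setValidity("EmbeddingPair", function(object) {
  msg <- character()
  if (ncol(object@features) != object@d) msg <- c(msg, "features must have d columns")
  if (object@d > nrow(object@features)) msg <- c(msg, "d must not exceed n")
  sv <- object@singularValues
  if (length(sv) != object@d) msg <- c(msg, "need exactly d singular values")
  if (length(sv) && (any(sv < -1e-12) || any(diff(sv) > 1e-8)))
    msg <- c(msg, "singular values must be nonnegative and non-increasing")
  for (w in object@contexts)
    if (!identical(dim(w)[2], dim(object@features)[2]))
      msg <- c(msg, "context width must equal d")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SimilarityInventory
# ---------------------------------------------------------------------------

#' The per-node-type similarity network inventory
#'
#' Ordered, named lists of [SimilarityMatrix-class] objects. With all inputs
#' present the drug side has 4 networks (chemical structure; Jaccard from
#' drug-drug interactions; Jaccard from drug-disease; Jaccard from
#' drug-side-effect) and the protein side has 3 (sequence; Jaccard from
#' protein-protein; Jaccard from protein-disease). Partial inventories are
#' allowed for network-ablation experiments.
#'
#' @slot drugNetworks named list of drug [SimilarityMatrix-class].
#' @slot proteinNetworks named list of protein [SimilarityMatrix-class].
#'
#' @exportClass SimilarityInventory
setClass("SimilarityInventory",
  representation(drugNetworks = "list", proteinNetworks = "list"))

setValidity("SimilarityInventory", function(object) {
  msg <- character()
  for (s in object@drugNetworks)
    if (!is(s, "SimilarityMatrix") || s@nodeType != "drug")
      msg <- c(msg, "drugNetworks must hold drug SimilarityMatrix objects")
  for (s in object@proteinNetworks)
    if (!is(s, "SimilarityMatrix") || s@nodeType != "protein")
      msg <- c(msg, "proteinNetworks must hold protein SimilarityMatrix objects")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# DTIModel
# ---------------------------------------------------------------------------

#' Trained interaction model: GCN weights, decoder projections, loss trace
#'
#' Everything gradient descent touches: the per-type graph-convolution weight
#' matrices (when feature update is enabled) and the bilinear decoder
#' projections `drugProj` (h_d x k) and `proteinProj` (h_p x k), so that the
#' reconstructed interaction matrix is
#' `H_drug %*% drugProj %*% t(proteinProj) %*% t(H_protein)`.
#'
#' @slot drugProj,proteinProj decoder projection matrices.
#' @slot gcnDrugWeight,gcnProteinWeight GCN weight matrices (0 x 0 when the
#'   feature-update layer is disabled).
#' @slot gcnEnabled logical; was the feature-update layer used.
#' @slot activation activation name ("relu", "sigmoid" or "identity").
#' @slot lossTrace numeric vector of per-epoch training losses.
#' @slot config list snapshot of the training hyperparameters.
#'
#' @exportClass DTIModel
setClass("DTIModel",
  representation(drugProj = "matrix", proteinProj = "matrix",
                 gcnDrugWeight = "matrix", gcnProteinWeight = "matrix",
                 gcnEnabled = "logical", activation = "character",
                 lossTrace = "numeric", config = "list"))

setValidity("DTIModel", function(object) {
  msg <- character()
  if (ncol(object@drugProj) != ncol(object@proteinProj))
    msg <- c(msg, "drugProj and proteinProj must share the projection dimension k")
  if (any(!is.finite(object@drugProj)) || any(!is.finite(object@proteinProj)))
    msg <- c(msg, "decoder projections must be finite")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# EvalReport
# ---------------------------------------------------------------------------

#' Cross-validation report
#'
#' @slot perFold data.frame with one row per fold: `fold`, `aupr`, `auroc`,
#'   `n_test`, `n_test_pos`.
#' @slot ratio negatives sampled per positive.
#' @slot seed the seed that produced the sampling and folds.
#' @slot config list snapshot of the configuration used.
#'
#' @exportClass EvalReport
setClass("EvalReport",
  representation(perFold = "data.frame", ratio = "numeric",
                 seed = "integer", config = "list"))

setValidity("EvalReport", function(object) {
  df <- object@perFold
  msg <- character()
  need <- c("fold", "aupr", "auroc")
  if (!all(need %in% names(df))) msg <- c(msg, "perFold needs fold/aupr/auroc columns")
  else if (nrow(df) && (any(df$aupr < 0 | df$aupr > 1) || any(df$auroc < 0 | df$auroc > 1)))
    msg <- c(msg, "metric values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
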