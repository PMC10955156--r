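# Similarity network construction: Jaccard similarity over shared neighbours
# in association networks, plus the precomputed chemical/sequence matrices.

#' Jaccard similarity between rows of a binary association matrix
#'
#' For nodes i and j with neighbour sets N(i), N(j) given by the rows,
#' `Sim[i,j] = |N(i) & N(j)| / |N(i) | N(j)|`. The self-similarity is 1, and
#' two nodes with empty neighbour sets get similarity 0 (rather than the
#' indeterminate 0/0): annotation-free nodes carry no evidence of
#' relatedness. For intra-type networks the node itself is excluded from its
#' own neighbour set before comparison.
#'
#' @param assoc a [BipartiteAssociation-class] whose rows are the node type
#'   being compared.
#' @return A [SimilarityMatrix-class] for the row type.
#' @export
jaccardSimilarity <- function(assoc) {
  stopifnot(is(assoc, "BipartiteAssociation"))
  m <- assoc@matrix
  if (length(m) && !all(m %in% c(0, 1)))
    stop("Jaccard similarity requires a binary association matrix")
  if (assoc@rowType == assoc@colType) diag(m) <- 0
  inter <- m %*% t(m)
  deg <- rowSums(m)
  uni <- outer(deg, deg, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  diag(sim) <- 1
  SimilarityMatrix(sim, assoc@rowType, ids = rownames(m))
}

.DRUG_NETWORKS <- c("chemical", "drug_drug", "drug_disease", "drug_side_effect")
.PROTEIN_NETWORKS <- c("sequence", "protein_protein", "protein_disease")

#' Build the similarity network inventory of a heterogeneous network set
#'
#' With every input present the drug side gets 4 networks and the protein
#' side 3, in this fixed order: drugs = (chemical structure, Jaccard from
#' drug-drug interactions, Jaccard from drug-disease, Jaccard from
#' drug-side-effect); proteins = (sequence, Jaccard from protein-protein
#' interactions, Jaccard from protein-disease). Partial inventories for
#' network-ablation experiments are requested explicitly through
#' `drugNetworks` / `proteinNetworks`.
#'
#' The drug-protein label matrix is never an inventory member.
#'
#' Intra-type interaction networks (drug-drug, protein-protein) are turned
#' into similarities by Jaccard over interaction partners by default
#' (`intraMode = "jaccard"`); `intraMode = "binary"` instead uses the binary
#' adjacency itself (with unit diagonal) as the similarity network, i.e.
#' diffusion runs directly on the interaction network.
#'
#' @param set a [HetNetSet-class].
#' @param drugNetworks,proteinNetworks ordered character vectors naming the
#'   networks to include (defaults: all).
#' @param intraMode `"jaccard"` (default) or `"binary"`.
#' @return A [SimilarityInventory-class].
#' @export
buildInventory <- function(set,
                           drugNetworks = .DRUG_NETWORKS,
                           proteinNetworks = .PROTEIN_NETWORKS,
                           intraMode = c("jaccard", "binary")) {
  stopifnot(is(set, "HetNetSet"))
  intraMode <- match.arg(intraMode)
  if (length(drugNetworks) == 0 && length(proteinNetworks) == 0)
    stop("configuration error: empty similarity inventory requested")

  intraSim <- function(a) {
    if (intraMode == "jaccard") return(jaccardSimilarity(a))
    m <- a@matrix
    SimilarityMatrix(m, a@rowType, ids = rownames(m))  # unit diagonal forced
  }
  getNet <- function(name) {
    switch(name,
      chemical         = set@precomputed[["drug_chemical"]],
      sequence         = set@precomputed[["protein_sequence"]],
      drug_drug        = intraSim(set@intraType[["drug_drug"]]),
      protein_protein  = intraSim(set@intraType[["protein_protein"]]),
      drug_disease     = jaccardSimilarity(set@associations[["drug_disease"]]),
      drug_side_effect = jaccardSimilarity(set@associations[["drug_side_effect"]]),
      protein_disease  = jaccardSimilarity(set@associations[["protein_disease"]]),
      stop("configuration error: unknown similarity network '", name, "'"))
  }
  bad <- setdiff(drugNetworks, .DRUG_NETWORKS)
  if (length(bad)) stop("configuration error: '", bad[1],
                        "' is not a drug similarity network")
  bad <- setdiff(proteinNetworks, .PROTEIN_NETWORKS)
  if (length(bad)) stop("configuration error: '", bad[1],
                        "' is not a protein similarity network")

  inv <- new("SimilarityInventory",
    drugNetworks = stats::setNames(lapply(drugNetworks, getNet), drugNetworks),
    proteinNetworks = stats::setNames(lapply(proteinNetworks, getNet),
                                      proteinNetworks))
  validObject(inv)
  inv
}
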