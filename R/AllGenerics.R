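# Accessor generics. Slot access stays internal; users go through these.

#' @rdname accessors
#' @param x an object from this package.
#' @param ... unused.
#' @export
setGeneric("nodeType", function(x, ...) standardGeneric("nodeType"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x, ...) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("features", function(x, ...) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("contexts", function(x, ...) standardGeneric("contexts"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x, ...) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("restartProb", function(x, ...) standardGeneric("restartProb"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x, ...) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x, ...) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("drugNetworks", function(x, ...) standardGeneric("drugNetworks"))

#' @rdname accessors
#' @export
setGeneric("proteinNetworks", function(x, ...) standardGeneric("proteinNetworks"))

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(x, ...) standardGeneric("lossTrace"))

#' @rdname accessors
#' @export
setGeneric("perFold", function(x, ...) standardGeneric("perFold"))

#' Accessors for hetDTI classes
#'
#' Small read-only accessors: `nodeType()` and `nodeIds()` for matrices,
#' `features()`, `contexts()` and `singularValues()` for embeddings,
#' `restartProb()` and `converged()` for diffusion states, `labelMatrix()`
#' for the drug-protein supervision matrix of a [HetNetSet-class],
#' `drugNetworks()` / `proteinNetworks()` for inventories, `lossTrace()` for
#' trained models and `perFold()` for evaluation reports. `as.matrix()` is
#' defined for all matrix-backed classes.
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("nodeType", "SimilarityMatrix", function(x, ...) x@nodeType)

#' @rdname accessors
#' @export
setMethod("nodeIds", "SimilarityMatrix", function(x, ...) rownames(x@matrix))

#' @rdname accessors
#' @param type for a `HetNetSet`: which registry to return.
#' @export
setMethod("nodeIds", "HetNetSet",
  function(x, type = c("drug", "protein", "disease", "side_effect"), ...) {
    x@registries[[match.arg(type)]]
  })

#' @rdname accessors
#' @export
setMethod("labelMatrix", "HetNetSet",
  function(x, ...) x@associations[["drug_protein"]]@matrix)

#' @rdname accessors
#' @export
setMethod("features", "EmbeddingPair", function(x, ...) x@features)

#' @rdname accessors
#' @export
setMethod("contexts", "EmbeddingPair", function(x, ...) x@contexts)

#' @rdname accessors
#' @export
setMethod("singularValues", "EmbeddingPair", function(x, ...) x@singularValues)

#' @rdname accessors
#' @export
setMethod("restartProb", "DiffusionState", function(x, ...) x@restartProb)

#' @rdname accessors
#' @export
setMethod("converged", "DiffusionState", function(x, ...) x@converged)

#' @rdname accessors
#' @export
setMethod("drugNetworks", "SimilarityInventory", function(x, ...) x@drugNetworks)

#' @rdname accessors
#' @export
setMethod("proteinNetworks", "SimilarityInventory", function(x, ...) x@proteinNetworks)

#' @rdname accessors
#' @export
setMethod("lossTrace", "DTIModel", function(x, ...) x@lossTrace)

#' @rdname accessors
#' @export
setMethod("perFold", "EvalReport", function(x, ...) x@perFold)

#' @rdname accessors
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@matrix)

#' @rdname accessors
#' @export
setMethod("as.matrix", "BipartiteAssociation", function(x, ...) x@matrix)

#' @rdname accessors
#' @export
setMethod("as.matrix", "DiffusionState", function(x, ...) x@matrix)

#' @rdname accessors
#' @export
setMethod("as.matrix", "EmbeddingPair", function(x, ...) x@features)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d %s nodes, mean off-diagonal %.4f\n",
              nrow(object@matrix), object@nodeType,
              if (nrow(object@matrix) > 1)
                mean(object@matrix[upper.tri(object@matrix)]) else NA_real_))
})

setMethod("show", "BipartiteAssociation", function(object) {
  m <- object@matrix
  cat(sprintf("BipartiteAssociation %s x %s: %d x %d, %d edges (density %.4f)\n",
              object@rowType, object@colType, nrow(m), ncol(m), sum(m),
              if (length(m)) sum(m) / length(m) else NA_real_))
})

setMethod("show", "HetNetSet", function(object) {
  r <- object@registries
  cat("HetNetSet\n")
  cat(sprintf("  nodes: %d drugs, %d proteins, %d diseases, %d side effects\n",
              length(r$drug), length(r$protein), length(r$disease),
              length(r$side_effect)))
  cat(sprintf("  associations: %s\n", paste(names(object@associations), collapse = ", ")))
  cat(sprintf("  intra-type: %s\n", paste(names(object@intraType), collapse = ", ")))
  cat(sprintf("  precomputed similarities: %s\n",
              paste(names(object@precomputed), collapse = ", ")))
  y <- object@associations[["drug_protein"]]
  if (!is.null(y))
    cat(sprintf("  label matrix: %d known interactions\n", sum(y@matrix)))
})

setMethod("show", "DiffusionState", function(object) {
  cat(sprintf("DiffusionState on '%s': %d nodes, p = %.2f, %s after %d iterations\n",
              object@source, nrow(object@matrix), object@restartProb,
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
})

setMethod("show", "EmbeddingPair", function(object) {
  cat(sprintf("EmbeddingPair: %d nodes x %d dims, %d context network(s)\n",
              nrow(object@features), object@d, length(object@contexts)))
})

setMethod("show", "SimilarityInventory", function(object) {
  cat(sprintf("SimilarityInventory: %d drug network(s) [%s]; %d protein network(s) [%s]\n",
              length(object@drugNetworks),
              paste(names(object@drugNetworks), collapse = ", "),
              length(object@proteinNetworks),
              paste(names(object@proteinNetworks), collapse = ", ")))
})

setMethod("show", "DTIModel", function(object) {
  cat(sprintf("DTIModel: decoder %d x %d (k = %d), feature update %s, final loss %.6g\n",
              nrow(object@drugProj), nrow(object@proteinProj), ncol(object@drugProj),
              if (object@gcnEnabled) sprintf("ON (%s)", object@activation) else "OFF",
              if (length(object@lossTrace)) utils::tail(object@lossTrace, 1) else NA_real_))
})

setMethod("show", "EvalReport", function(object) {
  df <- object@perFold
  cat(sprintf("EvalReport: %d folds, 1:%g negative sampling, seed %d\n",
              nrow(df), object@ratio, object@seed))
  cat(sprintf("  AUROC %.4f +/- %.4f | AUPR %.4f +/- %.4f\n",
              mean(df$auroc), stats::sd(df$auroc),
              mean(df$aupr), stats::sd(df$aupr)))
})
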