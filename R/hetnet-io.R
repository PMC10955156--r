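# Reading, validating, indexing and writing the heterogeneous network
# collection. Formats: edge lists and node registries are plain TSV ('#'
# starts a comment line); similarity matrices are dense TSV, optionally with
# id header row/column.

#' Read a node registry
#'
#' One id per line; line order defines the 0-based internal index. Blank
#' lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return character vector of unique node ids.
#' @export
readNodeRegistry <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (anyDuplicated(ids))
    stop("duplicate ids in registry file '", path, "'")
  ids
}

#' Read a bipartite (or intra-type) edge list as an association matrix
#'
#' Tab-separated lines `row_id<TAB>col_id[<TAB>weight]`. When a registry is
#' frozen (supplied), ids not in it are an error; when `NULL`, the registry
#' is populated in first-appearance file order. For intra-type networks
#' (`rowType == colType`) edges are mirrored so the matrix is symmetric, and
#' both endpoint ids share the row registry.
#'
#' @param path file path.
#' @param rowType,colType node types of the two columns.
#' @param rowIds,colIds frozen id registries, or `NULL` to infer from the file.
#' @param binarize treat any listed pair as 1 regardless of weight
#'   (default `TRUE`; associations in this problem are binary).
#' @return A [BipartiteAssociation-class].
#' @export
readEdgeList <- function(path, rowType, colType,
                         rowIds = NULL, colIds = NULL, binarize = TRUE) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  intra <- identical(rowType, colType)
  if (intra && !is.null(colIds) && !identical(rowIds, colIds))
    stop("intra-type edge list needs a single shared registry")

  rr <- character(0); cc <- character(0); ww <- numeric(0)
  for (i in keep) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(parts[1]) || !nzchar(parts[2]))
      stop("malformed line ", i, " in '", path, "': expected at least 2 ",
           "tab-separated fields")
    w <- 1
    if (length(parts) >= 3) {
      w <- suppressWarnings(as.numeric(parts[3]))
      if (is.na(w)) stop("malformed line ", i, " in '", path,
                         "': non-numeric weight '", parts[3], "'")
    }
    rr <- c(rr, parts[1]); cc <- c(cc, parts[2]); ww <- c(ww, w)
  }

  frozenRows <- !is.null(rowIds); frozenCols <- !is.null(colIds) || (intra && frozenRows)
  if (!frozenRows) rowIds <- unique(if (intra) c(rbind(rr, cc)) else rr)
  if (intra) colIds <- rowIds
  else if (is.null(colIds)) colIds <- unique(cc)

  bad <- setdiff(unique(c(rr, if (intra) cc)), rowIds)
  if (frozenRows && length(bad))
    stop("unknown ", rowType, " node(s) in '", path, "': ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!intra) {
    badc <- setdiff(unique(cc), colIds)
    if (frozenCols && length(badc))
      stop("unknown ", colType, " node(s) in '", path, "': ",
           paste(utils::head(badc, 5), collapse = ", "))
  }

  m <- matrix(0, length(rowIds), length(colIds), dimnames = list(rowIds, colIds))
  if (length(rr)) {
    ri <- match(rr, rowIds); ci <- match(cc, colIds)
    m[cbind(ri, ci)] <- ww
    if (intra) m[cbind(ci, ri)] <- ww
  }
  BipartiteAssociation(m, rowType, colType, binarize = binarize)
}

#' Read a dense similarity matrix
#'
#' Dense tab-separated numeric square table; a header row and first column of
#' ids are auto-detected. The matrix is symmetrised as `(M + t(M))/2` when
#' the asymmetry is at most `1e-6`, entries overshooting `[0, 1]` by at most
#' `1e-9` are clipped, and the diagonal is forced to 1. Anything worse is an
#' error.
#'
#' @param path file path.
#' @param nodeType node type of the matrix.
#' @param ids frozen registry, or `NULL` to take ids from the file header
#'   (or generate `n1..nN`).
#' @return A [SimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path, nodeType, ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  first <- suppressWarnings(as.numeric(cells[[1]]))
  hasHeader <- anyNA(first)
  fileIds <- NULL
  if (hasHeader) {
    hdr <- cells[[1]]
    cells <- cells[-1]
    # header may or may not carry a leading corner cell for the id column
    firstData <- suppressWarnings(as.numeric(cells[[1]][1]))
    hasIdCol <- is.na(firstData)
    if (hasIdCol) {
      fileIds <- vapply(cells, `[`, character(1), 1)
      cells <- lapply(cells, `[`, -1)
    } else fileIds <- hdr
  }
  m <- do.call(rbind, lapply(cells, function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("non-numeric entry in similarity table '", path, "'")
    v
  }))
  if (nrow(m) != ncol(m))
    stop("similarity table '", path, "' is not square: ",
         nrow(m), " x ", ncol(m))
  if (!is.null(ids)) {
    if (length(ids) != nrow(m))
      stop("registry has ", length(ids), " ids but table is ", nrow(m), "-square")
    if (!is.null(fileIds)) {
      if (!setequal(fileIds, ids))
        stop("ids in '", path, "' disagree with the frozen registry")
      ord <- match(ids, fileIds)
      m <- m[ord, ord, drop = FALSE]
    }
  } else ids <- fileIds
  SimilarityMatrix(m, nodeType, ids = ids)
}

#' Write predicted interaction scores as a ranked TSV
#'
#' Writes `drug_id<TAB>protein_id<TAB>score` sorted by descending score, with
#' ties broken lexicographically by (drug id, protein id) so the output is
#' deterministic. Pairs flagged in `trainMask` (known training interactions)
#' are excluded; `topK` truncates to the strongest predictions.
#'
#' @param scores numeric drug x protein matrix with id dimnames.
#' @param path output file path.
#' @param topK optional row limit after ranking.
#' @param trainMask optional binary matrix; pairs with 1 are dropped.
#' @return `path`, invisibly.
#' @export
writeScoreMatrix <- function(scores, path, topK = NULL, trainMask = NULL) {
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("score matrix needs drug/protein ids as dimnames")
  df <- data.frame(
    drug    = rep(rownames(scores), times = ncol(scores)),
    protein = rep(colnames(scores), each = nrow(scores)),
    score   = as.vector(scores),
    stringsAsFactors = FALSE)
  if (!is.null(trainMask)) {
    if (!identical(dim(trainMask), dim(scores)))
      stop("trainMask shape does not match the score matrix")
    df <- df[as.vector(trainMask) == 0, , drop = FALSE]
  }
  df <- df[order(-df$score, df$drug, df$protein), , drop = FALSE]
  if (!is.null(topK)) df <- utils::head(df, topK)
  lines <- sprintf("%s\t%s\t%.10g", df$drug, df$protein, df$score)
  writeLines(lines, path)
  invisible(path)
}

#' Write a binary association matrix as an edge list
#'
#' Inverse of [readEdgeList()] for binary matrices: one `row<TAB>col` line
#' per nonzero entry (upper triangle only for intra-type networks), in
#' row-major registry order.
#'
#' @param assoc a [BipartiteAssociation-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(assoc, path) {
  m <- assoc@matrix
  idx <- which(m != 0, arr.ind = TRUE)
  if (assoc@rowType == assoc@colType)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(sprintf("%s\t%s", rownames(m)[idx[, 1]], colnames(m)[idx[, 2]]), path)
  invisible(path)
}

#' Write a similarity matrix as dense TSV with id headers
#' @param sim a [SimilarityMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  m <- sim@matrix
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 12, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Assemble and validate a heterogeneous network set
#'
#' Collects the six association networks and two precomputed similarity
#' matrices into one consistently indexed [HetNetSet-class]. Registries are
#' taken from the drug-protein label matrix (drugs = rows, proteins =
#' columns), the drug-disease matrix (diseases = columns) and the
#' drug-side-effect matrix (side effects = columns); every other input must
#' agree with them.
#'
#' Nodes with zero degree across all their networks are dropped once, here
#' (`dropIsolated = TRUE`), and reported via a message.
#'
#' @param drugProtein the drug-protein label matrix (never used to build
#'   similarity or diffusion inputs downstream).
#' @param drugDisease,proteinDisease,drugSideEffect bipartite associations.
#' @param drugDrug,proteinProtein intra-type interaction networks.
#' @param drugChemical,proteinSequence precomputed [SimilarityMatrix-class].
#' @param dropIsolated drop nodes isolated in every network (default `TRUE`).
#' @return A validated [HetNetSet-class].
#' @export
hetNetSet <- function(drugProtein, drugDisease, proteinDisease, drugSideEffect,
                      drugDrug, proteinProtein, drugChemical, proteinSequence,
                      dropIsolated = TRUE) {
  stopifnot(is(drugProtein, "BipartiteAssociation"),
            is(drugDisease, "BipartiteAssociation"),
            is(proteinDisease, "BipartiteAssociation"),
            is(drugSideEffect, "BipartiteAssociation"),
            is(drugDrug, "BipartiteAssociation"),
            is(proteinProtein, "BipartiteAssociation"),
            is(drugChemical, "SimilarityMatrix"),
            is(proteinSequence, "SimilarityMatrix"))
  reg <- list(
    drug        = rownames(drugProtein@matrix),
    protein     = colnames(drugProtein@matrix),
    disease     = colnames(drugDisease@matrix),
    side_effect = colnames(drugSideEffect@matrix))

  set <- new("HetNetSet",
    registries = reg,
    associations = list(drug_protein = drugProtein, drug_disease = drugDisease,
                        protein_disease = proteinDisease,
                        drug_side_effect = drugSideEffect),
    intraType = list(drug_drug = drugDrug, protein_protein = proteinProtein),
    precomputed = list(drug_chemical = drugChemical,
                       protein_sequence = proteinSequence))
  validObject(set)
  if (dropIsolated) set <- .dropIsolated(set)
  set
}

# Degree of each node across ALL its networks (label matrix included;
# similarity counts via off-diagonal mass).
.nodeDegrees <- function(set) {
  reg <- set@registries
  deg <- lapply(reg, function(ids) stats::setNames(numeric(length(ids)), ids))
  add <- function(type, ids, v) deg[[type]][ids] <<- deg[[type]][ids] + v
  for (a in c(set@associations, set@intraType)) {
    m <- a@matrix
    add(a@rowType, rownames(m), rowSums(m))
    if (a@rowType != a@colType) add(a@colType, colnames(m), colSums(m))
  }
  for (s in set@precomputed) {
    m <- s@matrix
    add(s@nodeType, rownames(m), rowSums(m) - diag(m))
  }
  deg
}

.dropIsolated <- function(set) {
  deg <- .nodeDegrees(set)
  keep <- lapply(deg, function(d) names(d)[d > 0])
  nDropped <- sum(lengths(set@registries)) - sum(lengths(keep))
  if (nDropped == 0) return(set)
  dropped <- unlist(lapply(names(deg), function(ty)
    paste0(ty, ":", names(deg[[ty]])[deg[[ty]] == 0])))
  message("dropping ", nDropped, " isolated node(s): ",
          paste(utils::head(dropped, 10), collapse = ", "),
          if (nDropped > 10) ", ..." else "")
  subsetHetNet(set, keep)
}

#' Subset a HetNetSet to a list of node ids per type
#'
#' @param set a [HetNetSet-class].
#' @param keep named list (`drug`, `protein`, `disease`, `side_effect`) of
#'   ids to keep; missing entries keep all nodes of that type.
#' @return The subsetted, re-validated [HetNetSet-class].
#' @export
subsetHetNet <- function(set, keep) {
  reg <- set@registries
  for (ty in names(reg))
    if (!is.null(keep[[ty]])) reg[[ty]] <- reg[[ty]][reg[[ty]] %in% keep[[ty]]]
  sub <- function(a) {
    m <- a@matrix[reg[[a@rowType]], reg[[a@colType]], drop = FALSE]
    new("BipartiteAssociation", matrix = m, rowType = a@rowType, colType = a@colType)
  }
  out <- new("HetNetSet",
    registries = reg,
    associations = lapply(set@associations, sub),
    intraType = lapply(set@intraType, sub),
    precomputed = lapply(set@precomputed, function(s) {
      ids <- reg[[s@nodeType]]
      new("SimilarityMatrix", matrix = s@matrix[ids, ids, drop = FALSE],
          nodeType = s@nodeType)
    }))
  validObject(out)
  out
}

#' Write the full network collection to a directory
#'
#' Edge lists for the six association networks, dense TSV for the two
#' similarity matrices, one registry file per node type. The layout matches
#' what [readHetNetSet()] expects.
#'
#' @param set a [HetNetSet-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeHetNetSet <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ty in names(set@registries))
    writeLines(set@registries[[ty]], file.path(dir, paste0(ty, "_ids.txt")))
  for (nm in names(set@associations))
    writeEdgeList(set@associations[[nm]], file.path(dir, paste0(nm, ".tsv")))
  for (nm in names(set@intraType))
    writeEdgeList(set@intraType[[nm]], file.path(dir, paste0(nm, ".tsv")))
  for (nm in names(set@precomputed))
    writeSimilarityMatrix(set@precomputed[[nm]], file.path(dir, paste0(nm, ".tsv")))
  invisible(dir)
}

#' Read a network collection from a directory written by [writeHetNetSet()]
#'
#' @param dir directory containing the registry, edge-list and similarity
#'   files.
#' @param dropIsolated passed to [hetNetSet()].
#' @return A [HetNetSet-class].
#' @export
readHetNetSet <- function(dir, dropIsolated = TRUE) {
  reg <- lapply(stats::setNames(.NODE_TYPES, .NODE_TYPES), function(ty)
    readNodeRegistry(file.path(dir, paste0(ty, "_ids.txt"))))
  rd <- function(name, rt, ct)
    readEdgeList(file.path(dir, paste0(name, ".tsv")), rt, ct,
                 rowIds = reg[[rt]], colIds = if (rt == ct) NULL else reg[[ct]])
  hetNetSet(
    drugProtein    = rd("drug_protein", "drug", "protein"),
    drugDisease    = rd("drug_disease", "drug", "disease"),
    proteinDisease = rd("protein_disease", "protein", "disease"),
    drugSideEffect = rd("drug_side_effect", "drug", "side_effect"),
    drugDrug       = rd("drug_drug", "drug", "drug"),
    proteinProtein = rd("protein_protein", "protein", "protein"),
    drugChemical   = readSimilarityMatrix(file.path(dir, "drug_chemical.tsv"),
                                          "drug", ids = reg$drug),
    proteinSequence = readSimilarityMatrix(file.path(dir, "protein_sequence.tsv"),
                                           "protein", ids = reg$protein),
    dropIsolated = dropIsolated)
}
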