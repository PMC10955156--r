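# Seeded generator of heterogeneous network collections with planted
# low-rank drug-target structure. Every pipeline stage is testable on these
# without any external download. The generator is deliberately bilinear-
# latent -- matching the decoder's inductive bias -- so signal recovery is a
# meaningful end-to-end check; a no-structure null mode verifies the
# pipeline finds nothing where nothing is planted.

#' Default synthetic-dataset configuration
#'
#' 50 drugs, 80 proteins, 30 diseases, 20 side effects, planted latent rank
#' 3, seed 7. Densities approximate a sparsely annotated pharmacological
#' network; noise rates are modest but nonzero so the recovery problem is
#' not trivial. Sizes are small enough that full cross-validation runs in
#' seconds.
#'
#' @param ... overrides of the default fields.
#' @return named list: `nDrugs`, `nProteins`, `nDiseases`, `nSideEffects`,
#'   `latentRank`, `densities` (per network), `labelNoise` (flip
#'   probability), `assocNoise` (score jitter before thresholding),
#'   `simNoise` (similarity jitter sd), `structured` (FALSE = null
#'   generator), `seed`.
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    nDrugs = 50L, nProteins = 80L, nDiseases = 30L, nSideEffects = 20L,
    latentRank = 3L,
    densities = list(label = 0.06, drugDisease = 0.08, proteinDisease = 0.08,
                     drugSideEffect = 0.10, drugDrug = 0.10,
                     proteinProtein = 0.08),
    labelNoise = 0.01,
    assocNoise = 0.5,
    simNoise = 0.05,
    structured = TRUE,
    seed = 7L)
  over <- list(...)
  .mergeConfig(cfg, over)
}

.checkSynthConfig <- function(cfg) {
  counts <- c(cfg$nDrugs, cfg$nProteins, cfg$nDiseases, cfg$nSideEffects)
  if (any(counts < cfg$latentRank) || cfg$latentRank < 1)
    stop("all node counts must be >= latentRank >= 1")
  dens <- unlist(cfg$densities)
  if (any(dens <= 0 | dens >= 1)) stop("densities must lie in (0, 1)")
  if (cfg$labelNoise < 0 || cfg$labelNoise >= 1)
    stop("labelNoise must lie in [0, 1)")
  invisible(cfg)
}

# Binary matrix keeping the top `density` fraction of (jittered) scores.
.thresholdTop <- function(scores, density, jitterSd = 0) {
  if (jitterSd > 0)
    scores <- scores + matrix(stats::rnorm(length(scores), sd = jitterSd),
                              nrow(scores))
  cut <- stats::quantile(scores, 1 - density)
  (scores > cut) * 1
}

# Symmetric version for intra-type networks (upper triangle thresholded,
# mirrored; zero diagonal).
.thresholdTopSym <- function(scores, density, jitterSd = 0) {
  n <- nrow(scores)
  up <- upper.tri(scores)
  v <- scores[up]
  if (jitterSd > 0) v <- v + stats::rnorm(length(v), sd = jitterSd)
  cut <- stats::quantile(v, 1 - density)
  m <- matrix(0, n, n)
  m[up] <- (v > cut) * 1
  m + t(m)
}

.cosineSim <- function(F) {
  nrm <- sqrt(rowSums(F * F))
  nrm[nrm == 0] <- 1
  C <- tcrossprod(F / nrm)
  (C + 1) / 2  # map [-1, 1] onto [0, 1]
}

# Independent Bernoulli(rate) label flips.
.flipLabels <- function(Y, rate) {
  if (rate <= 0) return(Y)
  flips <- matrix(stats::runif(length(Y)) < rate, nrow(Y))
  abs(Y - flips)
}

#' Generate a synthetic heterogeneous network collection
#'
#' Structured mode plants rank-`latentRank` latent factors for every node
#' type. The drug-protein label matrix is the top-density quantile of the
#' drug-protein factor inner products, followed by independent label-noise
#' flips. Disease and side-effect associations are community-structured:
#' nodes with similar factors share annotations (thresholded jittered factor
#' inner products). Drug-drug and protein-protein interactions threshold the
#' within-type factor similarity. The precomputed chemical and sequence
#' similarities are the cosine similarity of the factors plus symmetric
#' noise, clipped to \[0, 1\] with unit diagonal.
#'
#' Null mode (`structured = FALSE`) draws every network independently at the
#' same densities with no planted relation to the label matrix, so a correct
#' pipeline scores held-out pairs at chance.
#'
#' Fully deterministic per `config$seed`.
#'
#' @param config list from [syntheticConfig()].
#' @return list with `set` (a [HetNetSet-class]), `factors` (planted latent
#'   factors per node type; `NULL` in null mode), `noiselessY` (label matrix
#'   before noise flips) and `config`.
#' @export
simulateHetNet <- function(config = syntheticConfig()) {
  cfg <- .checkSynthConfig(config)
  n <- cfg$nDrugs; m <- cfg$nProteins
  nd <- cfg$nDiseases; ns <- cfg$nSideEffects
  k <- cfg$latentRank
  ids <- list(drug = sprintf("d%03d", seq_len(n)),
              protein = sprintf("p%03d", seq_len(m)),
              disease = sprintf("z%03d", seq_len(nd)),
              side_effect = sprintf("s%03d", seq_len(ns)))

  out <- .withSeed(cfg$seed, {
    if (cfg$structured) {
      U <- matrix(stats::rnorm(n * k), n, k)
      V <- matrix(stats::rnorm(m * k), m, k)
      Gd <- matrix(stats::rnorm(nd * k), nd, k)
      Se <- matrix(stats::rnorm(ns * k), ns, k)
      noiselessY <- .thresholdTop(U %*% t(V), cfg$densities$label)
      Y <- .flipLabels(noiselessY, cfg$labelNoise)
      dd <- .thresholdTop(U %*% t(Gd), cfg$densities$drugDisease, cfg$assocNoise)
      pd <- .thresholdTop(V %*% t(Gd), cfg$densities$proteinDisease, cfg$assocNoise)
      dse <- .thresholdTop(U %*% t(Se), cfg$densities$drugSideEffect, cfg$assocNoise)
      ddr <- .thresholdTopSym(tcrossprod(U), cfg$densities$drugDrug, cfg$assocNoise)
      pp <- .thresholdTopSym(tcrossprod(V), cfg$densities$proteinProtein,
                             cfg$assocNoise)
      noisySim <- function(F) {
        C <- .cosineSim(F)
        E <- matrix(stats::rnorm(nrow(C)^2, sd = cfg$simNoise), nrow(C))
        C <- C + (E + t(E)) / 2
        C[C < 0] <- 0; C[C > 1] <- 1
        diag(C) <- 1
        C
      }
      chem <- noisySim(U)
      seqs <- noisySim(V)
      factors <- list(drug = U, protein = V, disease = Gd, side_effect = Se)
    } else {
      rb <- function(nr, nc, d) matrix((stats::runif(nr * nc) < d) * 1, nr, nc)
      rbs <- function(nn, d) {
        s <- matrix(0, nn, nn)
        up <- upper.tri(s)
        s[up] <- (stats::runif(sum(up)) < d) * 1
        s + t(s)
      }
      rsim <- function(nn) {
        E <- matrix(stats::runif(nn * nn, 0, 1), nn, nn)
        C <- (E + t(E)) / 2
        diag(C) <- 1
        C
      }
      noiselessY <- rb(n, m, cfg$densities$label)
      Y <- noiselessY
      dd <- rb(n, nd, cfg$densities$drugDisease)
      pd <- rb(m, nd, cfg$densities$proteinDisease)
      dse <- rb(n, ns, cfg$densities$drugSideEffect)
      ddr <- rbs(n, cfg$densities$drugDrug)
      pp <- rbs(m, cfg$densities$proteinProtein)
      chem <- rsim(n)
      seqs <- rsim(m)
      factors <- NULL
    }
    list(Y = Y, noiselessY = noiselessY, dd = dd, pd = pd, dse = dse,
         ddr = ddr, pp = pp, chem = chem, seqs = seqs, factors = factors)
  })

  ba <- function(mat, rt, ct)
    BipartiteAssociation(mat, rt, ct, rowIds = ids[[rt]], colIds = ids[[ct]])
  set <- hetNetSet(
    drugProtein = ba(out$Y, "drug", "protein"),
    drugDisease = ba(out$dd, "drug", "disease"),
    proteinDisease = ba(out$pd, "protein", "disease"),
    drugSideEffect = ba(out$dse, "drug", "side_effect"),
    drugDrug = ba(out$ddr, "drug", "drug"),
    proteinProtein = ba(out$pp, "protein", "protein"),
    drugChemical = SimilarityMatrix(out$chem, "drug", ids = ids$drug),
    proteinSequence = SimilarityMatrix(out$seqs, "protein", ids = ids$protein),
    dropIsolated = FALSE)  # the dense similarities leave no node isolated

  dimnames(out$noiselessY) <- list(ids$drug, ids$protein)
  list(set = set, factors = out$factors, noiselessY = out$noiselessY,
       config = cfg)
}

.DEGRADABLE <- c("drug_disease", "protein_disease", "drug_side_effect",
                 "drug_drug", "protein_protein")

# association name -> similarity-inventory network name
.ASSOC_TO_NET <- c(drug_disease = "drug_disease",
                   protein_disease = "protein_disease",
                   drug_side_effect = "drug_side_effect",
                   drug_drug = "drug_drug",
                   protein_protein = "protein_protein")

#' Degrade a synthetic dataset: extra label noise and/or a dropped network
#'
#' Returns a copy of the dataset with additional independent label flips
#' and/or one named association network removed (its edges are cleared and
#' the dataset's `networks` hint shrinks, so a downstream
#' [buildInventory()] / [crossValidate()] call excludes the derived
#' similarity network).
#'
#' @param dataset output of [simulateHetNet()].
#' @param extraLabelNoise additional flip probability (default 0).
#' @param dropNetwork name of an association network to remove, one of
#'   `drug_disease`, `protein_disease`, `drug_side_effect`, `drug_drug`,
#'   `protein_protein`; `NULL` drops nothing.
#' @param seed seed for the extra flips.
#' @return dataset list with the same structure plus a `networks` element
#'   (`drug` / `protein` name vectors for [buildInventory()]).
#' @export
degradeHetNet <- function(dataset, extraLabelNoise = 0, dropNetwork = NULL,
                          seed = 1L) {
  set <- dataset$set
  nets <- dataset$networks
  if (is.null(nets)) nets <- list(drug = .DRUG_NETWORKS,
                                  protein = .PROTEIN_NETWORKS)
  if (!is.null(dropNetwork)) {
    if (!dropNetwork %in% .DEGRADABLE)
      stop("unknown network '", dropNetwork, "'; expected one of ",
           paste(.DEGRADABLE, collapse = ", "))
    simName <- .ASSOC_TO_NET[[dropNetwork]]
    nets$drug <- setdiff(nets$drug, simName)
    nets$protein <- setdiff(nets$protein, simName)
    clear <- function(a) {
      a@matrix[] <- 0
      a
    }
    if (dropNetwork %in% names(set@associations))
      set@associations[[dropNetwork]] <- clear(set@associations[[dropNetwork]])
    else set@intraType[[dropNetwork]] <- clear(set@intraType[[dropNetwork]])
  }
  if (extraLabelNoise > 0) {
    y <- set@associations[["drug_protein"]]
    y@matrix <- .withSeed(seed, .flipLabels(y@matrix, extraLabelNoise))
    set@associations[["drug_protein"]] <- y
  }
  validObject(set)
  dataset$set <- set
  dataset$networks <- nets
  dataset
}
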