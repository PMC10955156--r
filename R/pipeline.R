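# Config-driven orchestration: the end-to-end pipeline (similarity inventory
# -> diffusion embeddings -> feature update -> bilinear reconstruction), in
# prediction or cross-validation mode, plus Cartesian parameter sweeps.

#' Default run configuration
#'
#' Every tunable of every stage with its documented default. Unknown keys in
#' overrides are rejected. `NA` means "auto": `embedding.pseudocount` = 1/n,
#' `train.k` = min(dDrug, dProtein), `input.dir` = simulate instead of read.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    mode = "cv",                      # "cv" or "predict"
    input = list(dir = NA),           # NA: generate with the simulate block
    simulate = syntheticConfig(),
    networks = list(drug = .DRUG_NETWORKS, protein = .PROTEIN_NETWORKS,
                    intraMode = "jaccard"),
    diffusion = list(p = 0.5, tol = 1e-8, maxIter = 1000L,
                     backend = "iterative"),
    embedding = list(dDrug = 200L, dProtein = 400L, pseudocount = NA,
                     capDims = TRUE),
    gcn = list(enabled = TRUE, activation = "relu", adjacencyMode = "mean"),
    train = list(k = NA, lr = 0.01, epochs = 1000L, optimizer = "adam",
                 weightDecay = 0, negatives = "all", seed = 1L),
    cv = list(folds = 10L, ratio = 10, seed = 1L),
    output = list(dir = NA, topK = NA))
}

#' Read a run configuration from a YAML or JSON file
#'
#' The document may specify any subset of [defaultConfig()] keys; unknown
#' keys are an error.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return full configuration list (defaults merged with the file).
#' @export
readRunConfig <- function(path) {
  over <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  .mergeConfig(defaultConfig(), over)
}

# Set a dotted path like "diffusion.p" in a nested config list.
.setConfigPath <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- defaultConfig()
  for (k in keys) {
    if (!k %in% names(ref)) stop("unknown configuration key '", path, "'")
    ref <- ref[[k]]
  }
  cfg[[keys]] <- value
  cfg
}

# Embedding dimensions cannot exceed the node count; cap with a message so
# one config serves datasets of different sizes.
.capDims <- function(cfg, n, m) {
  if (!isTRUE(cfg$embedding$capDims)) return(cfg)
  if (cfg$embedding$dDrug > n) {
    message("capping dDrug at the number of drugs (", n, ")")
    cfg$embedding$dDrug <- n
  }
  if (cfg$embedding$dProtein > m) {
    message("capping dProtein at the number of proteins (", m, ")")
    cfg$embedding$dProtein <- m
  }
  cfg
}

.naToNull <- function(x) if (length(x) == 1 && is.na(x)) NULL else x

# Shared stage runner: inventory + embeddings with stage logging.
.buildFeatures <- function(set, cfg, quiet = FALSE) {
  log <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  inventory <- buildInventory(set, drugNetworks = cfg$networks$drug,
                              proteinNetworks = cfg$networks$protein,
                              intraMode = cfg$networks$intraMode)
  log(sprintf("[inventory] %d drug + %d protein networks (%.2fs)",
              length(inventory@drugNetworks), length(inventory@proteinNetworks),
              as.numeric(Sys.time() - t0, units = "secs")))
  t0 <- Sys.time()
  emb <- list(
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
  log(sprintf("[embedding] drugs %d x %d, proteins %d x %d (%.2fs)",
              nrow(emb$drug@features), emb$drug@d,
              nrow(emb$protein@features), emb$protein@d,
              as.numeric(Sys.time() - t0, units = "secs")))
  list(inventory = inventory, embeddings = emb)
}

#' Run the full pipeline from a configuration
#'
#' Loads (or simulates) the network collection, builds the similarity
#' inventory and diffusion embeddings, then either trains on all known
#' interactions and writes the ranked score matrix (`mode = "predict"`) or
#' runs the cross-validated evaluation (`mode = "cv"`). When an output
#' directory is configured, a verbatim config snapshot, the per-fold metrics
#' (cv) or ranked scores and loss trace (predict) are written there;
#' re-running overwrites cleanly.
#'
#' @param config partial configuration; see [defaultConfig()].
#' @param set optional pre-built [HetNetSet-class] (overrides `input` /
#'   `simulate`).
#' @param quiet suppress stage logging.
#' @return for `mode = "cv"` an [EvalReport-class]; for `mode = "predict"` a
#'   list with `model`, `scores` and `lossTrace`.
#' @export
runPipeline <- function(config = list(), set = NULL, quiet = FALSE) {
  cfg <- .mergeConfig(defaultConfig(), config)
  if (!cfg$mode %in% c("cv", "predict"))
    stop("configuration error: unknown mode '", cfg$mode, "'")
  log <- function(...) if (!quiet) message(...)

  networksHint <- NULL
  if (is.null(set)) {
    if (length(cfg$input$dir) == 1 && is.na(cfg$input$dir)) {
      sim <- simulateHetNet(cfg$simulate)
      set <- sim$set
      networksHint <- sim$networks
      log(sprintf("[data] simulated collection (seed %d)", cfg$simulate$seed))
    } else {
      set <- readHetNetSet(cfg$input$dir)
      log(sprintf("[data] read collection from %s", cfg$input$dir))
    }
  }
  if (!is.null(networksHint)) cfg$networks[names(networksHint)] <- networksHint
  Y <- labelMatrix(set)
  cfg <- .capDims(cfg, nrow(Y), ncol(Y))

  outDir <- cfg$output$dir
  hasOut <- !(length(outDir) == 1 && is.na(outDir))
  if (hasOut) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    snap <- cfg
    snap$embedding$pseudocount <- .naToNull(snap$embedding$pseudocount)
    yaml::write_yaml(snap, file.path(outDir, "config_snapshot.yaml"))
  }

  feats <- .buildFeatures(set, cfg, quiet = quiet)

  if (cfg$mode == "cv") {
    report <- crossValidate(set, cfg, inventory = feats$inventory,
                            embeddings = feats$embeddings)
    s <- summary(report)
    log(sprintf("[cv] AUROC %.4f +/- %.4f | AUPR %.4f +/- %.4f",
                s$meanAUROC, s$sdAUROC, s$meanAUPR, s$sdAUPR))
    if (hasOut) {
      utils::write.csv(report@perFold, file.path(outDir, "per_fold_metrics.csv"),
                       row.names = FALSE)
      jsonlite::write_json(s, file.path(outDir, "cv_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    return(report)
  }
  if (cfg$mode != "predict") stop("configuration error: unknown mode '",
                                  cfg$mode, "'")
  t0 <- Sys.time()
  fit <- trainModel(Y, feats$embeddings$drug, feats$embeddings$protein,
                    inventory = feats$inventory,
                    gcnEnabled = cfg$gcn$enabled,
                    activation = cfg$gcn$activation,
                    adjacencyMode = cfg$gcn$adjacencyMode,
                    k = .naToNull(cfg$train$k), lr = cfg$train$lr,
                    epochs = cfg$train$epochs, optimizer = cfg$train$optimizer,
                    weightDecay = cfg$train$weightDecay, seed = cfg$train$seed)
  log(sprintf("[train] %d epochs, final loss %.6g (%.2fs)",
              cfg$train$epochs, utils::tail(fit$lossTrace, 1),
              as.numeric(Sys.time() - t0, units = "secs")))
  if (hasOut) {
    writeScoreMatrix(fit$scores, file.path(outDir, "predicted_scores.tsv"),
                     topK = .naToNull(cfg$output$topK), trainMask = Y)
    utils::write.csv(data.frame(epoch = seq_along(fit$lossTrace),
                                loss = fit$lossTrace),
                     file.path(outDir, "loss_trace.csv"), row.names = FALSE)
  }
  fit
}

#' Cartesian parameter sweep
#'
#' Runs [crossValidate()] once per cell of the grid, with all other settings
#' (and all seeds) shared, so metric differences are attributable to the
#' swept parameters alone.
#'
#' @param set a [HetNetSet-class].
#' @param grid named list; names are dotted config paths (e.g.
#'   `"diffusion.p"`, `"embedding.dDrug"`), values are the levels to sweep.
#'   Keys are validated before any run starts.
#' @param config shared base configuration.
#' @param quiet suppress per-cell logging.
#' @return data.frame with one row per cell: the swept values plus
#'   `meanAUROC`, `sdAUROC`, `meanAUPR`, `sdAUPR`.
#' @export
sweepGrid <- function(set, grid, config = list(), quiet = FALSE) {
  if (!length(grid) || is.null(names(grid)) || any(!nzchar(names(grid))))
    stop("configuration error: grid must be a named list of parameter levels")
  base <- .mergeConfig(defaultConfig(), config)
  for (key in names(grid)) .setConfigPath(base, key, grid[[key]][[1]])  # validate

  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- base
    for (key in names(grid)) cfg <- .setConfigPath(cfg, key, cells[[key]][i])
    Y <- labelMatrix(set)
    cfg <- .capDims(cfg, nrow(Y), ncol(Y))
    report <- crossValidate(set, cfg)
    s <- summary(report)
    if (!quiet)
      message(sprintf("[sweep %d/%d] %s -> AUROC %.4f, AUPR %.4f",
                      i, nrow(cells),
                      paste(names(grid), unlist(cells[i, , drop = FALSE]),
                            sep = "=", collapse = ", "),
                      s$meanAUROC, s$meanAUPR))
    cbind(cells[i, , drop = FALSE],
          data.frame(meanAUROC = s$meanAUROC, sdAUROC = s$sdAUROC,
                     meanAUPR = s$meanAUPR, sdAUPR = s$sdAUPR))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
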