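# Bilinear decoder and training loop. The reconstructed interaction matrix
# is Yrec = H_drug %*% Dr %*% t(Pr) %*% t(H_protein); the loss is the sum of
# squared reconstruction errors over the (masked) drug-protein pairs, and
# all trainable parameters -- decoder projections and, when the feature
# update is enabled, the GCN weights -- are fit by full-batch gradient
# descent on analytic gradients.

#' Bilinear interaction scores
#'
#' `Yrec = H_drug %*% drugProj %*% t(proteinProj) %*% t(H_protein)`: the
#' inner product of the projected drug and protein feature vectors.
#'
#' @param Hdrug n x h_d drug feature matrix.
#' @param Hprotein m x h_p protein feature matrix.
#' @param drugProj h_d x k projection.
#' @param proteinProj h_p x k projection.
#' @return n x m score matrix, dimnames carried over from the features.
#' @export
bilinearScores <- function(Hdrug, Hprotein, drugProj, proteinProj) {
  if (ncol(Hdrug) != nrow(drugProj))
    stop("drug feature width ", ncol(Hdrug), " does not match drugProj rows ",
         nrow(drugProj))
  if (ncol(Hprotein) != nrow(proteinProj))
    stop("protein feature width ", ncol(Hprotein),
         " does not match proteinProj rows ", nrow(proteinProj))
  if (ncol(drugProj) != ncol(proteinProj))
    stop("projection dimensions k differ between the two sides")
  S <- (Hdrug %*% drugProj) %*% t(Hprotein %*% proteinProj)
  dimnames(S) <- list(rownames(Hdrug), rownames(Hprotein))
  S
}

#' Masked squared reconstruction loss
#'
#' Sum over pairs with `mask == 1` of `(y_ij - yrec_ij)^2`. Held-out test
#' pairs must carry mask 0 so they contribute nothing to the loss or its
#' gradients.
#'
#' @param Y binary label matrix.
#' @param Yrec reconstructed score matrix of the same shape.
#' @param mask binary matrix of the same shape; `NULL` means all ones.
#' @return scalar loss.
#' @export
reconstructionLoss <- function(Y, Yrec, mask = NULL) {
  if (!identical(dim(Y), dim(Yrec))) stop("Y and Yrec shapes differ")
  D <- Y - Yrec
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(Y))) stop("mask shape differs from Y")
    D <- D * mask
  }
  sum(D * D)
}

# Forward pass + analytic gradients of the masked loss for all trainables.
# Returns loss, scores and gradients named like the parameter list.
.lossAndGrads <- function(par, fixed) {
  gcn <- fixed$gcnEnabled
  if (gcn) {
    act <- .getActivation(fixed$activation)
    Zd <- fixed$AXd %*% par$Wd
    Zp <- fixed$AXp %*% par$Wp
    Hd <- act$f(Zd); Hp <- act$f(Zp)
  } else {
    Hd <- fixed$Xd; Hp <- fixed$Xp
  }
  S <- (Hd %*% par$Dr) %*% t(Hp %*% par$Pr)
  Rm <- (S - fixed$Y) * fixed$mask
  loss <- sum(Rm * Rm)
  G <- 2 * Rm
  HpPr <- Hp %*% par$Pr
  HdDr <- Hd %*% par$Dr
  grads <- list(
    Dr = crossprod(Hd, G %*% HpPr),
    Pr = crossprod(Hp, crossprod(G, HdDr)))
  if (gcn) {
    gHd <- G %*% HpPr %*% t(par$Dr)
    gHp <- crossprod(G, HdDr %*% t(par$Pr))
    grads$Wd <- crossprod(fixed$AXd, gHd * act$df(Zd))
    grads$Wp <- crossprod(fixed$AXp, gHp * act$df(Zp))
  }
  list(loss = loss, scores = S, grads = grads, Hdrug = Hd, Hprotein = Hp)
}

#' Train the interaction model
#'
#' Runs the (optional) graph-convolution feature update, scores every
#' drug-protein pair with the bilinear decoder, and fits the decoder
#' projections and GCN weights by full-batch gradient descent on the masked
#' squared reconstruction loss. Gradients are analytic; `optimizer = "adam"`
#' (the default) uses adaptive moment estimates, `optimizer = "gd"` is plain
#' fixed-step descent.
#'
#' @param Y binary drug x protein label matrix (held-out test positives must
#'   already be zeroed and masked out).
#' @param Xdrug,Xprotein node features: [EmbeddingPair-class] or matrix.
#' @param inventory a [SimilarityInventory-class]; required when
#'   `gcnEnabled` to build the convolution adjacencies.
#' @param mask binary matrix, 1 = pair contributes to the loss (`NULL` = all
#'   pairs).
#' @param gcnEnabled run the feature-update layer (default `TRUE`).
#' @param activation GCN nonlinearity (default `"relu"`).
#' @param adjacencyMode `"mean"` or `"primary"`, see [buildGcnAdjacency()].
#' @param k decoder projection dimension; default `min(h_d, h_p)`.
#' @param lr learning rate (default 0.01).
#' @param epochs training epochs (default 1000).
#' @param optimizer `"adam"` (default) or `"gd"`.
#' @param weightDecay L2 penalty coefficient (default 0 = off).
#' @param seed seed for parameter initialisation.
#' @return list with `model` (a [DTIModel-class]), `scores` (the full n x m
#'   score matrix) and `lossTrace` (per-epoch loss).
#' @export
trainModel <- function(Y, Xdrug, Xprotein, inventory = NULL, mask = NULL,
                       gcnEnabled = TRUE, activation = "relu",
                       adjacencyMode = "mean", k = NULL,
                       lr = 0.01, epochs = 1000L,
                       optimizer = c("adam", "gd"),
                       weightDecay = 0, seed = 1L) {
  optimizer <- match.arg(optimizer)
  Xd <- if (is(Xdrug, "EmbeddingPair")) Xdrug@features else as.matrix(Xdrug)
  Xp <- if (is(Xprotein, "EmbeddingPair")) Xprotein@features else as.matrix(Xprotein)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(Xd) || ncol(Y) != nrow(Xp))
    stop("label matrix shape does not match the feature matrices")
  if (is.null(mask)) mask <- matrix(1, nrow(Y), ncol(Y))
  if (!identical(dim(mask), dim(Y))) stop("mask shape differs from Y")
  hd <- ncol(Xd); hp <- ncol(Xp)
  if (is.null(k)) k <- min(hd, hp)

  fixed <- list(Y = Y, mask = mask, Xd = Xd, Xp = Xp,
                gcnEnabled = gcnEnabled, activation = activation)
  par <- .withSeed(seed, {
    p <- list(Dr = .glorotInit(hd, k), Pr = .glorotInit(hp, k))
    if (gcnEnabled) {
      p$Wd <- .glorotInit(hd, hd)
      p$Wp <- .glorotInit(hp, hp)
    }
    p
  })
  if (gcnEnabled) {
    if (is.null(inventory))
      stop("gcnEnabled = TRUE needs a similarity inventory for the adjacency")
    Ad <- buildGcnAdjacency(inventory, "drug", adjacencyMode)
    Ap <- buildGcnAdjacency(inventory, "protein", adjacencyMode)
    fixed$AXd <- Ad %*% Xd
    fixed$AXp <- Ap %*% Xp
  }

  state <- NULL
  if (optimizer == "adam")
    state <- list(m = lapply(par, function(x) x * 0),
                  v = lapply(par, function(x) x * 0),
                  b1 = 0.9, b2 = 0.999, eps = 1e-8)
  trace <- numeric(epochs)
  fg <- NULL
  for (e in seq_len(epochs)) {
    fg <- .lossAndGrads(par, fixed)
    if (!is.finite(fg$loss))
      stop("training diverged (non-finite loss at epoch ", e,
           "); try a smaller learning rate")
    trace[e] <- fg$loss
    for (nm in names(par)) {
      g <- fg$grads[[nm]]
      if (weightDecay > 0) g <- g + 2 * weightDecay * par[[nm]]
      if (optimizer == "gd") {
        par[[nm]] <- par[[nm]] - lr * g
      } else {
        state$m[[nm]] <- state$b1 * state$m[[nm]] + (1 - state$b1) * g
        state$v[[nm]] <- state$b2 * state$v[[nm]] + (1 - state$b2) * g * g
        mh <- state$m[[nm]] / (1 - state$b1^e)
        vh <- state$v[[nm]] / (1 - state$b2^e)
        par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + state$eps)
      }
    }
  }
  final <- .lossAndGrads(par, fixed)
  scores <- final$scores
  dimnames(scores) <- list(rownames(Xd), rownames(Xp))

  model <- new("DTIModel",
    drugProj = par$Dr, proteinProj = par$Pr,
    gcnDrugWeight = if (gcnEnabled) par$Wd else matrix(0, 0, 0),
    gcnProteinWeight = if (gcnEnabled) par$Wp else matrix(0, 0, 0),
    gcnEnabled = gcnEnabled, activation = activation,
    lossTrace = trace,
    config = list(k = k, lr = lr, epochs = epochs, optimizer = optimizer,
                  weightDecay = weightDecay, seed = seed,
                  adjacencyMode = adjacencyMode))
  validObject(model)
  list(model = model, scores = scores, lossTrace = trace)
}
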