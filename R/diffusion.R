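# Random walk with restart: per-node diffusion states on each similarity
# network. Row-vector convention throughout: r^{t+1} = (1-p) r^t %*% Ahat +
# p r^0, with Ahat the row-normalised similarity matrix.

#' Row-normalised one-step transition matrix of a similarity network
#'
#' `Ahat = D^{-1} A` with `D` the diagonal of row sums. The unit diagonal of
#' a [SimilarityMatrix-class] guarantees positive row sums.
#'
#' @param sim a [SimilarityMatrix-class] or a nonnegative square matrix.
#' @return A row-stochastic matrix with the input's dimnames.
#' @export
transitionMatrix <- function(sim) {
  A <- if (is(sim, "SimilarityMatrix")) sim@matrix else as.matrix(sim)
  if (any(A < 0)) stop("similarity entries must be nonnegative")
  d <- rowSums(A)
  if (any(d <= 0))
    stop("degenerate row with zero sum at index ", which(d <= 0)[1])
  A / d
}

#' Diffusion states by iterated random walk with restart
#'
#' Runs the restart walk from every seed simultaneously: with `R0 = I`, the
#' update `R <- (1 - p) R %*% Ahat + p R0` is iterated until the maximum
#' row-wise L1 change drops below `tol` or `maxIter` is reached. Row `i` of
#' the result is the diffusion state of node `i`. The iteration is a
#' contraction with factor `(1 - p)`, so for `p > 0` it always converges;
#' hitting `maxIter` first is reported via the `converged` flag and a
#' warning, not an error.
#'
#' @param trans row-stochastic transition matrix from [transitionMatrix()].
#' @param p restart probability in (0, 1] (default 0.5, the centre of the
#'   stable 0.4-0.7 range).
#' @param tol convergence tolerance on the max row L1 change (default 1e-8).
#' @param maxIter iteration cap (default 1000).
#' @param source name recorded in the result.
#' @return A [DiffusionState-class].
#' @export
rwr <- function(trans, p = 0.5, tol = 1e-8, maxIter = 1000L, source = "network") {
  stopifnot(p > 0, p <= 1, tol > 0)
  n <- nrow(trans)
  R0 <- diag(n)
  R <- R0
  it <- 0L
  conv <- FALSE
  q <- 1 - p
  while (it < maxIter) {
    Rn <- q * (R %*% trans) + p * R0
    it <- it + 1L
    if (max(rowSums(abs(Rn - R))) < tol) { R <- Rn; conv <- TRUE; break }
    R <- Rn
  }
  if (!conv && p < 1) warning("random walk did not converge in ", maxIter,
                              " iterations (tol ", tol, ")")
  if (p == 1) conv <- TRUE
  dimnames(R) <- dimnames(trans)
  new("DiffusionState", matrix = R, restartProb = p, iterations = it,
      converged = conv, source = source)
}

#' Closed-form diffusion states (exact fixed point)
#'
#' The fixed point of the restart iteration solves
#' `R = p (I - (1-p) Ahat)^{-1}` (row convention), computed here by a direct
#' linear solve. Exact for any `p > 0`; used as the independent oracle for
#' [rwr()] and as an alternative backend for small networks.
#'
#' @inheritParams rwr
#' @return A [DiffusionState-class] with `iterations = 0`.
#' @export
rwrClosedForm <- function(trans, p = 0.5, source = "network") {
  stopifnot(p > 0, p <= 1)
  n <- nrow(trans)
  # R (I - (1-p) Ahat) = p I  =>  R = p solve(I - (1-p) Ahat) applied on the right
  M <- diag(n) - (1 - p) * trans
  R <- p * t(solve(t(M), diag(n)))
  R[R < 0 & R > -1e-12] <- 0  # clip solver noise
  dimnames(R) <- dimnames(trans)
  new("DiffusionState", matrix = R, restartProb = p, iterations = 0L,
      converged = TRUE, source = source)
}

#' Diffusion states for every network in a similarity inventory
#'
#' @param networks named list of [SimilarityMatrix-class] (one side of a
#'   [SimilarityInventory-class]).
#' @param p,tol,maxIter passed to [rwr()].
#' @param backend `"iterative"` (default) or `"closed_form"`.
#' @return named list of [DiffusionState-class].
#' @export
diffuseNetworks <- function(networks, p = 0.5, tol = 1e-8, maxIter = 1000L,
                            backend = c("iterative", "closed_form")) {
  backend <- match.arg(backend)
  stats::setNames(lapply(names(networks), function(nm) {
    tr <- transitionMatrix(networks[[nm]])
    if (backend == "iterative") rwr(tr, p = p, tol = tol, maxIter = maxIter,
                                    source = nm)
    else rwrClosedForm(tr, p = p, source = nm)
  }), names(networks))
}

#' Dump a diffusion state as dense TSV (for inspection)
#' @param state a [DiffusionState-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDiffusionState <- function(state, path) {
  m <- state@matrix
  con <- file(path, "w"); on.exit(close(con))
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(m)))
  writeLines(paste(c("id", ids), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(ids[i], format(m[i, ], digits = 12, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}
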