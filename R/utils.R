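# Internal helpers.

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed; stays below 2^31.
.childSeed <- function(seed, stream) {
  (as.numeric(seed) * 1103 + stream * 12007) %% 2147483647
}

# Symmetric-uniform (Glorot-style) initialisation of an a x b weight matrix.
.glorotInit <- function(a, b) {
  lim <- sqrt(6 / (a + b))
  matrix(stats::runif(a * b, -lim, lim), a, b)
}

.activations <- list(
  relu     = list(f = function(z) pmax(z, 0), df = function(z) (z > 0) * 1),
  sigmoid  = list(f = function(z) 1 / (1 + exp(-z)),
                  df = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) }),
  identity = list(f = function(z) z, df = function(z) array(1, dim(z)))
)

.getActivation <- function(name) {
  a <- .activations[[name]]
  if (is.null(a)) stop("unknown activation '", name,
                       "'; use one of ", paste(names(.activations), collapse = ", "))
  a
}

# Deep-merge override list into defaults; error on keys absent from defaults.
.mergeConfig <- function(defaults, override, path = character()) {
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(override[[key]]))
        stop("configuration key '", full, "' must be a section")
      defaults[[key]] <- .mergeConfig(defaults[[key]], override[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- override[[key]]
    }
  }
  defaults
}
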