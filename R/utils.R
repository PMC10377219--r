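# Internal numerical and RNG helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
softmax_cols <- function(e) {
  # column-wise softmax with max-subtraction; rows = positions, cols = samples
  m <- apply(e, 2L, max)
  ex <- exp(sweep(e, 2L, m, "-"))
  sweep(ex, 2L, colSums(ex), "/")
}

# Derive a reproducible sub-seed (< 2^31) for an independent stochastic stage.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) * 48271 + 7919 * as.numeric(offset)) %% 2147483629
  as.integer(s + 1)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Recursively apply f over matching leaves of nested parameter lists.
map_params <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) {
      map_params(f, a[[i]],
                 if (is.null(b)) NULL else b[[i]],
                 if (is.null(c)) NULL else c[[i]])
    })
    names(out) <- names(a)
    return(out)
  }
  if (is.null(b)) f(a) else if (is.null(c)) f(a, b) else f(a, b, c)
}

# Flatten the numeric leaves of a nested parameter list (non-numeric leaves,
# e.g. structural flags, are skipped and preserved by unflatten_params).
flatten_params <- function(p) {
  if (!is.list(p)) {
    if (!is.numeric(p)) return(numeric(0))
    return(as.numeric(p))
  }
  unlist(lapply(p, flatten_params), use.names = FALSE)
}

# Pour a flat numeric vector back into the shape of `skeleton`.
unflatten_params <- function(theta, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, fill)
      names(out) <- names(x)
      return(out)
    }
    if (!is.numeric(x)) return(x)
    k <- length(x)
    out <- theta[(pos + 1L):(pos + k)]
    pos <<- pos + k
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  out <- fill(skeleton)
  attributes(out) <- attributes(skeleton)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
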