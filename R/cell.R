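# LSTM memory-block cells. Two variants share one code path:
#   * peephole = TRUE (the E-LSTM cell): the input and forget gates read the
#     previous memory cell and the output gate reads the freshly updated one,
#     i.e. gates act on [c, h_prev, x];
#   * peephole = FALSE (the standard ablation cell): gates act on [h_prev, x].
# The candidate always acts on [h_prev, x]. Zeroing the memory-cell columns
# of every gate matrix of a peephole cell reduces it exactly to the standard
# cell - a structural identity exercised in the tests.

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize the parameters of one LSTM cell
#'
#' Gate weight matrices are Glorot-uniform; biases are zero except the forget
#' gate bias, which starts at 1 so that early training does not erase the
#' memory cell.
#'
#' @param n Hidden size (memory-cell length).
#' @param m Per-step input width.
#' @param peephole If `TRUE` the gate matrices span `[c, h_prev, x]`
#'   (dimension `2n + m`); if `FALSE` they span `[h_prev, x]` (`n + m`).
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return List of class `lstm_cell_params` with `Wi`, `Wf`, `Wo`
#'   (`n x (2n+m)` or `n x (n+m)`), `Wc` (`n x (n+m)`), biases `bi`, `bf`,
#'   `bo`, `bc`, and the `peephole` flag.
#' @export
lstm_cell_params <- function(n, m, peephole = TRUE, seed = NULL) {
  if (n < 1 || m < 1) stop("cell dimensions must be >= 1", call. = FALSE)
  build <- function() {
    dg <- if (peephole) 2L * n + m else n + m
    structure(list(
      Wi = glorot(n, dg), Wf = glorot(n, dg), Wo = glorot(n, dg),
      Wc = glorot(n, n + m),
      bi = numeric(n), bf = rep(1, n), bo = numeric(n), bc = numeric(n),
      peephole = isTRUE(peephole)), class = "lstm_cell_params")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

cell_dims <- function(p) {
  n <- nrow(p$Wc)
  m <- ncol(p$Wc) - n
  list(n = n, m = m)
}

# Batched single step. x: m x B, state: list(c, h) each n x B.
# Returns the new state plus the intermediate activations needed by backprop.
cell_step_batch <- function(x, state, p) {
  n <- cell_dims(p)$n
  zc <- rbind(state$h, x)
  zg <- if (p$peephole) rbind(state$c, zc) else zc
  i <- sigmoid(p$Wi %*% zg + p$bi)
  f <- sigmoid(p$Wf %*% zg + p$bf)
  cb <- tanh(p$Wc %*% zc + p$bc)
  cnew <- f * state$c + i * cb
  zo <- if (p$peephole) rbind(cnew, state$h, x) else rbind(state$h, x)
  o <- sigmoid(p$Wo %*% zo + p$bo)
  th <- tanh(cnew)
  h <- o * th
  list(state = list(c = cnew, h = h),
       cache = list(i = i, f = f, cb = cb, o = o, th = th, c = cnew,
                    c_prev = state$c, h_prev = state$h, x = x))
}

#' Advance an LSTM cell by one step
#'
#' Applies one gate update: input and forget gates (sigmoid), tanh candidate,
#' memory update `c = f * c_prev + i * cbar`, output gate (sigmoid, reading
#' the updated cell when peepholes are on) and `h = o * tanh(c)`.
#'
#' @param x Input vector of length `m` (or `m x B` matrix for a batch).
#' @param state List with memory vector `c` and hidden vector `h` (length `n`
#'   each, or `n x B` matrices).
#' @param params An [lstm_cell_params()] object.
#' @return List with updated `c` and `h` in the same shape as `state`.
#' @examples
#' p <- lstm_cell_params(n = 2, m = 1, seed = 1)
#' lstm_cell_step(0.3, list(c = c(0, 0), h = c(0, 0)), p)
#' @export
lstm_cell_step <- function(x, state, params) {
  d <- cell_dims(params)
  vec_in <- !is.matrix(x)
  x <- if (is.matrix(x)) x else matrix(x, nrow = d$m)
  st <- list(c = if (is.matrix(state$c)) state$c else matrix(state$c, d$n),
             h = if (is.matrix(state$h)) state$h else matrix(state$h, d$n))
  if (nrow(x) != d$m || nrow(st$c) != d$n || nrow(st$h) != d$n ||
      ncol(x) != ncol(st$c) || ncol(x) != ncol(st$h))
    stop("shape mismatch between input, state and cell parameters",
         call. = FALSE)
  out <- cell_step_batch(x, st, params)$state
  if (vec_in) list(c = drop(out$c), h = drop(out$h)) else out
}

# Run a cell across a sequence (list of T inputs, each m x B) from zero state.
# reverse = TRUE consumes the sequence T..1; states are stored by position.
cell_run_batch <- function(xs, p, reverse = FALSE) {
  T_ <- length(xs)
  n <- cell_dims(p)$n
  B <- ncol(xs[[1]])
  state <- list(c = matrix(0, n, B), h = matrix(0, n, B))
  H <- C <- caches <- vector("list", T_)
  for (t in if (reverse) T_:1 else 1:T_) {
    step <- cell_step_batch(xs[[t]], state, p)
    state <- step$state
    H[[t]] <- state$h
    C[[t]] <- state$c
    caches[[t]] <- step$cache
  }
  list(H = H, C = C, caches = caches)
}

#' Run an LSTM cell over a scalar-step sequence
#'
#' Convenience wrapper for a single sequence with per-step width 1, starting
#' from the zero state. With `reverse = TRUE` the cell consumes the sequence
#' last-step-first (states are still reported by position), which is how the
#' backward direction of the encoder operates.
#'
#' @param xseq Numeric vector: one input scalar per step.
#' @param params An [lstm_cell_params()] with `m = 1`.
#' @param reverse Consume the sequence in reverse order.
#' @return List with `H` and `C`: `n x T` matrices of hidden and memory
#'   states by position.
#' @export
lstm_cell_run <- function(xseq, params, reverse = FALSE) {
  if (cell_dims(params)$m != 1L)
    stop("lstm_cell_run expects a cell with per-step width 1", call. = FALSE)
  xs <- lapply(as.numeric(xseq), function(v) matrix(v, 1, 1))
  r <- cell_run_batch(xs, params, reverse = reverse)
  list(H = do.call(cbind, lapply(r$H, drop)),
       C = do.call(cbind, lapply(r$C, drop)))
}
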