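# Full feature-attention E-LSTM: bidirectional peephole encoder over the
# feature sequence, dot-product attention over the per-feature encoder
# states, a single-cell peephole decoder consuming the attention context,
# and a dense + sigmoid head. Each screened feature is one time step
# carrying one standardized scalar, so the attention distribution is a
# distribution over features.

#' Initialize all trainable parameters of the feature-attention E-LSTM
#'
#' Weights are Glorot-uniform, biases zero, forget-gate biases 1. The
#' encoder holds a forward and a backward peephole cell plus the combiner
#' projection (`V`: `n x 2n`, bias `k`) that merges the two directional
#' hidden states into one per-feature state through tanh. The decoder is a
#' peephole cell whose step input is the attention context (width `n`); the
#' head is a dense weight vector plus scalar bias feeding a sigmoid.
#'
#' @param T_ Sequence length = number of input features (9 after default
#'   screening).
#' @param n Hidden size.
#' @param m Per-step input width (the model consumes one scalar per feature;
#'   only `m = 1` is supported by [elstm_forward()]).
#' @param seed Integer seed; identical arguments give identical parameters.
#' @return Object of class `elstm_params`: nested list with `encoder`
#'   (`forward`, `backward`, `V`, `k`), `decoder`, `head` (`w`, `b`), and
#'   attributes `n`, `T`, `m`.
#' @export
elstm_init <- function(T_, n, m = 1L, seed = 1L) {
  if (T_ < 1 || n < 1 || m < 1)
    stop("model dimensions must be >= 1", call. = FALSE)
  with_seed(as.integer(seed), {
    p <- list(
      encoder = list(
        forward  = unclass(lstm_cell_params(n, m, peephole = TRUE)),
        backward = unclass(lstm_cell_params(n, m, peephole = TRUE)),
        V = glorot(n, 2L * n),
        k = numeric(n)),
      decoder = unclass(lstm_cell_params(n, n, peephole = TRUE)),
      head = list(w = drop(glorot(n, 1L)), b = 0))
    structure(p, class = "elstm_params", n = as.integer(n),
              T = as.integer(T_), m = as.integer(m))
  })
}

elstm_dims <- function(params) {
  list(n = attr(params, "n"), T = attr(params, "T"), m = attr(params, "m"))
}

#' Count trainable parameters
#'
#' Exact count of scalar trainables implied by the shape rules (gate
#' matrices, candidate matrices, combiner, decoder, head). A nominal
#' complexity figure of the form `7 * (n^2 + n*m + n)` is conventionally
#' quoted for this architecture; it is available via
#' [nominal_parameter_count()] for reference but does not follow from the
#' shape arithmetic.
#'
#' @param params An [elstm_init()] object.
#' @return Integer: the exact number of trainable scalars.
#' @export
count_parameters <- function(params) {
  length(flatten_params(unclass(params)))
}

#' Nominal parameter-count figure
#'
#' The conventional `7 * (n^2 + n*m + n)` complexity figure quoted for the
#' feature-attention E-LSTM; reported for reference alongside the exact count.
#'
#' @param n Hidden size.
#' @param m Input width.
#' @return Numeric nominal count.
#' @export
nominal_parameter_count <- function(n, m = 1) 7 * (n^2 + n * m + n)

# standardized data matrix (B x T) -> list of T input matrices (1 x B)
seq_inputs <- function(X) {
  lapply(seq_len(ncol(X)), function(t) matrix(X[, t], nrow = 1L))
}

as_cell <- function(p) structure(p, class = "lstm_cell_params")

encode_batch <- function(xs, enc, masks = NULL, dropout_rate = 0) {
  T_ <- length(xs)
  rf <- cell_run_batch(xs, as_cell(enc$forward), reverse = FALSE)
  rb <- cell_run_batch(xs, as_cell(enc$backward), reverse = TRUE)
  G <- Hraw <- Hk <- vector("list", T_)
  for (t in seq_len(T_)) {
    G[[t]] <- rbind(rf$H[[t]], rb$H[[t]])
    Hraw[[t]] <- tanh(enc$V %*% G[[t]] + enc$k)
    Hk[[t]] <- if (is.null(masks)) Hraw[[t]] else
      Hraw[[t]] * masks[[t]] / (1 - dropout_rate)
  }
  # combined candidate: the combiner applied to the final candidate state of
  # each direction (forward direction ends at position T, backward at 1)
  cbar <- tanh(enc$V %*% rbind(rf$caches[[T_]]$cb, rb$caches[[1L]]$cb) + enc$k)
  list(H = Hk, Hraw = Hraw, G = G, rf = rf, rb = rb, candidate = cbar)
}

#' Encode a feature sequence with the bidirectional pre-attention E-LSTM
#'
#' The forward cell consumes the features first-to-last, the backward cell
#' last-to-first, both from zero initial states; at each position the two
#' directional hidden vectors are concatenated and projected through the
#' combiner (`tanh(V [h_fwd ; h_bwd] + k)`) to give the per-feature state
#' that the attention layer consumes.
#'
#' @param xseq Numeric vector of length `T` (the standardized feature
#'   sequence).
#' @param params An [elstm_init()] object.
#' @return List with `H` (`n x T` matrix of projected per-feature states)
#'   and `candidate` (the combined candidate vector, length `n`).
#' @export
elstm_encode <- function(xseq, params) {
  d <- elstm_dims(params)
  xseq <- as.numeric(xseq)
  if (length(xseq) != d$T)
    stop("sequence length ", length(xseq), " does not match model T = ", d$T,
         call. = FALSE)
  if (!all(is.finite(xseq))) stop("sequence must be finite", call. = FALSE)
  r <- encode_batch(seq_inputs(matrix(xseq, nrow = 1L)), params$encoder)
  list(H = do.call(cbind, lapply(r$H, drop)), candidate = drop(r$candidate))
}

attend_batch <- function(c_prev, H) {
  T_ <- length(H)
  e <- do.call(rbind, lapply(H, function(hk) colSums(c_prev * hk)))
  if (!is.matrix(e)) e <- matrix(e, nrow = T_)   # B = 1
  w <- softmax_cols(e)
  ctx <- Reduce(`+`, lapply(seq_len(T_), function(k)
    sweep(H[[k]], 2L, w[k, ], "*")))
  list(scores = e, weights = w, context = ctx)
}

#' Attention distribution over encoder states
#'
#' Scores each per-feature encoder state by its dot product with the decoder
#' memory vector, normalizes the scores with a numerically stable softmax
#' (max subtraction), and returns the weighted sum of encoder states as the
#' context vector. With a zero query all features receive weight `1/T`.
#'
#' @param c_prev Decoder memory vector, length `n`.
#' @param H Encoder states: an `n x T` matrix (columns = features), e.g.
#'   `elstm_encode(...)$H`.
#' @return Object of class `attention_result`: list with `scores`,
#'   `weights` (length `T`, nonnegative, summing to 1) and `context`
#'   (length `n`).
#' @examples
#' a <- elstm_attend(c(1), matrix(c(1, 2), nrow = 1))
#' a$weights   # softmax(1, 2)
#' @export
elstm_attend <- function(c_prev, H) {
  H <- as.matrix(H)
  if (length(c_prev) != nrow(H))
    stop("dimension mismatch between query and encoder states", call. = FALSE)
  Hl <- lapply(seq_len(ncol(H)), function(k) matrix(H[, k], ncol = 1L))
  r <- attend_batch(matrix(c_prev, ncol = 1L), Hl)
  structure(list(scores = drop(r$scores), weights = drop(r$weights),
                 context = drop(r$context)), class = "attention_result")
}

decode_batch <- function(H, dec, steps = 1L) {
  n <- nrow(H[[1]])
  B <- ncol(H[[1]])
  state <- list(c = matrix(0, n, B), h = matrix(0, n, B))
  caches <- vector("list", steps)
  for (s in seq_len(steps)) {
    att <- attend_batch(state$c, H)
    step <- cell_step_batch(att$context, state, as_cell(dec))
    caches[[s]] <- list(att = att, cell = step$cache, c_query = state$c)
    state <- step$state
  }
  list(h = state$h, c = state$c, caches = caches)
}

#' Decode attention contexts into the classification representation
#'
#' The post-feature-attention decoder starts from the zero state; at each
#' step the attention context computed from its current memory vector is fed
#' as the step input to the peephole cell. One step is the default (and the
#' configuration used throughout); more steps recompute attention from the
#' updated memory vector each time.
#'
#' @param H Encoder states, `n x T` matrix.
#' @param params An [elstm_init()] object (its `decoder` cell is used).
#' @param steps Number of decoder iterations (>= 1).
#' @return Final hidden vector, length `n`.
#' @export
elstm_decode <- function(H, params, steps = 1L) {
  if (steps < 1L) stop("steps must be >= 1", call. = FALSE)
  H <- as.matrix(H)
  d <- elstm_dims(params)
  if (nrow(H) != d$n)
    stop("encoder state dimension does not match the decoder", call. = FALSE)
  Hl <- lapply(seq_len(ncol(H)), function(k) matrix(H[, k], ncol = 1L))
  drop(decode_batch(Hl, params$decoder, steps = steps)$h)
}

forward_batch <- function(X, params, masks = NULL, dropout_rate = 0,
                          steps = 1L) {
  enc <- encode_batch(seq_inputs(X), params$encoder, masks = masks,
                      dropout_rate = dropout_rate)
  dec <- decode_batch(enc$H, params$decoder, steps = steps)
  u <- colSums(params$head$w * dec$h) + params$head$b
  list(prob = sigmoid(u), logit = u, enc = enc, dec = dec)
}

#' Forward pass: stress probability for feature sequences
#'
#' encode -> attend/decode -> dense head -> sigmoid. Purely functional and
#' deterministic (dropout is applied only inside the training loop); the
#' output is strictly inside (0, 1).
#'
#' @param x A numeric vector of length `T` (one standardized feature
#'   sequence) or a `B x T` matrix (one sequence per row).
#' @param params An [elstm_init()] object.
#' @param steps Decoder iterations (default 1).
#' @return Numeric vector of high-stress probabilities.
#' @export
elstm_forward <- function(x, params, steps = 1L) {
  d <- elstm_dims(params)
  if (d$m != 1L)
    stop("elstm_forward supports per-step input width m = 1", call. = FALSE)
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != d$T)
    stop("input has ", ncol(X), " features but the model expects T = ", d$T,
         call. = FALSE)
  if (!all(is.finite(X))) stop("inputs must be finite", call. = FALSE)
  forward_batch(X, params, steps = steps)$prob
}
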