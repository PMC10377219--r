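# Reverse-mode gradients of mean BCE + L2 through the full model:
# head -> decoder cell(s) -> attention -> combiner -> both encoder
# directions (BPTT). Verified against central-difference differentiation
# (see check_gradients and the test suite).

zero_like <- function(p) {
  map_params(function(x) if (is.numeric(x)) x * 0 else x, p)
}

# One cell step backward. cache from cell_step_batch; dH, dC_in: n x B
# gradients flowing into this step's h and c. Returns parameter gradients and
# the gradients flowing to the previous state and the step input.
cell_backward_batch <- function(cache, dH, dC_in, p) {
  n <- nrow(cache$c)
  m <- nrow(cache$x)
  rows <- function(z, a, b) z[a:b, , drop = FALSE]

  dO <- dH * cache$th
  dC <- dC_in + dH * cache$o * (1 - cache$th^2)

  aO <- dO * cache$o * (1 - cache$o)
  zo <- if (p$peephole) rbind(cache$c, cache$h_prev, cache$x) else
    rbind(cache$h_prev, cache$x)
  gWo <- aO %*% t(zo)
  gbo <- rowSums(aO)
  dZo <- crossprod(p$Wo, aO)
  if (p$peephole) {
    dC <- dC + rows(dZo, 1L, n)
    dH_prev <- rows(dZo, n + 1L, 2L * n)
    dX <- rows(dZo, 2L * n + 1L, 2L * n + m)
  } else {
    dH_prev <- rows(dZo, 1L, n)
    dX <- rows(dZo, n + 1L, n + m)
  }

  dF <- dC * cache$c_prev
  dI <- dC * cache$cb
  dCb <- dC * cache$i
  dC_prev <- dC * cache$f

  aC <- dCb * (1 - cache$cb^2)
  zc <- rbind(cache$h_prev, cache$x)
  gWc <- aC %*% t(zc)
  gbc <- rowSums(aC)
  dZc <- crossprod(p$Wc, aC)
  dH_prev <- dH_prev + rows(dZc, 1L, n)
  dX <- dX + rows(dZc, n + 1L, n + m)

  aI <- dI * cache$i * (1 - cache$i)
  aF <- dF * cache$f * (1 - cache$f)
  zg <- if (p$peephole) rbind(cache$c_prev, cache$h_prev, cache$x) else zc
  gWi <- aI %*% t(zg)
  gWf <- aF %*% t(zg)
  gbi <- rowSums(aI)
  gbf <- rowSums(aF)
  dZg <- crossprod(p$Wi, aI) + crossprod(p$Wf, aF)
  if (p$peephole) {
    dC_prev <- dC_prev + rows(dZg, 1L, n)
    dH_prev <- dH_prev + rows(dZg, n + 1L, 2L * n)
    dX <- dX + rows(dZg, 2L * n + 1L, 2L * n + m)
  } else {
    dH_prev <- dH_prev + rows(dZg, 1L, n)
    dX <- dX + rows(dZg, n + 1L, n + m)
  }

  list(grads = list(Wi = gWi, Wf = gWf, Wo = gWo, Wc = gWc,
                    bi = gbi, bf = gbf, bo = gbo, bc = gbc),
       dX = dX, dC_prev = dC_prev, dH_prev = dH_prev)
}

add_cell_grads <- function(acc, g) {
  for (nm in names(g$grads)) acc[[nm]] <- acc[[nm]] + g$grads[[nm]]
  acc
}

# Backward through one attention application.
# dctx: n x B; H: list of T encoder states; w: T x B weights; c_query: n x B.
attend_backward <- function(dctx, H, w, c_query) {
  T_ <- length(H)
  dHk <- vector("list", T_)
  dw <- do.call(rbind, lapply(H, function(hk) colSums(dctx * hk)))
  if (!is.matrix(dw)) dw <- matrix(dw, nrow = T_)
  for (k in seq_len(T_)) dHk[[k]] <- sweep(dctx, 2L, w[k, ], "*")
  de <- w * sweep(dw, 2L, colSums(w * dw), "-")
  dquery <- Reduce(`+`, lapply(seq_len(T_), function(k)
    sweep(H[[k]], 2L, de[k, ], "*")))
  for (k in seq_len(T_))
    dHk[[k]] <- dHk[[k]] + sweep(c_query, 2L, de[k, ], "*")
  list(dH = dHk, dquery = dquery)
}

# Full forward + backward on a standardized batch.
# X: B x T matrix, y: 0/1 vector, masks: optional list of T dropout masks
# (n x B each, applied to encoder outputs with inverted scaling).
elstm_backward <- function(X, y, params, lambda = 0, masks = NULL,
                           dropout_rate = 0, steps = 1L) {
  d <- elstm_dims(params)
  B <- nrow(X)
  fw <- forward_batch(X, params, masks = masks, dropout_rate = dropout_rate,
                      steps = steps)
  if (!all(is.finite(fw$logit)))
    stop("non-finite model output during backprop; check inputs and weights",
         call. = FALSE)
  loss <- bce_l2_loss(y, fw$prob, params, lambda = lambda)
  grads <- zero_like(unclass(params))

  du <- (fw$prob - y) / B
  h_final <- fw$dec$h
  grads$head$w <- drop(h_final %*% du)
  grads$head$b <- sum(du)

  n <- d$n
  dH <- outer(params$head$w, du)
  dC <- matrix(0, n, B)
  Hk <- fw$enc$H
  dHk <- lapply(Hk, function(h) h * 0)
  dec_cell <- as_cell(params$decoder)
  for (s in rev(seq_along(fw$dec$caches))) {
    cc <- fw$dec$caches[[s]]
    cb <- cell_backward_batch(cc$cell, dH, dC, dec_cell)
    grads$decoder <- add_cell_grads(grads$decoder, cb)
    ab <- attend_backward(cb$dX, Hk, cc$att$weights, cc$c_query)
    for (k in seq_len(d$T)) dHk[[k]] <- dHk[[k]] + ab$dH[[k]]
    dH <- cb$dH_prev
    dC <- cb$dC_prev + ab$dquery
  }

  # combiner + dropout backward, collecting per-position directional grads
  enc <- params$encoder
  dHf <- dHb <- vector("list", d$T)
  for (t in seq_len(d$T)) {
    dHraw <- if (is.null(masks)) dHk[[t]] else
      dHk[[t]] * masks[[t]] / (1 - dropout_rate)
    dA <- dHraw * (1 - fw$enc$Hraw[[t]]^2)
    grads$encoder$V <- grads$encoder$V + dA %*% t(fw$enc$G[[t]])
    grads$encoder$k <- grads$encoder$k + rowSums(dA)
    dG <- crossprod(enc$V, dA)
    dHf[[t]] <- dG[1:n, , drop = FALSE]
    dHb[[t]] <- dG[(n + 1L):(2L * n), , drop = FALSE]
  }

  # BPTT, forward direction: future is t + 1
  fwd_cell <- as_cell(enc$forward)
  dh <- dc <- matrix(0, n, B)
  for (t in d$T:1) {
    cb <- cell_backward_batch(fw$enc$rf$caches[[t]], dHf[[t]] + dh, dc,
                              fwd_cell)
    grads$encoder$forward <- add_cell_grads(grads$encoder$forward, cb)
    dh <- cb$dH_prev
    dc <- cb$dC_prev
  }
  # BPTT, backward direction: it consumed positions T..1, so its future is
  # t - 1 and gradients flow towards larger t
  bwd_cell <- as_cell(enc$backward)
  dh <- dc <- matrix(0, n, B)
  for (t in 1:d$T) {
    cb <- cell_backward_batch(fw$enc$rb$caches[[t]], dHb[[t]] + dh, dc,
                              bwd_cell)
    grads$encoder$backward <- add_cell_grads(grads$encoder$backward, cb)
    dh <- cb$dH_prev
    dc <- cb$dC_prev
  }

  if (lambda > 0) grads <- add_l2_gradient(grads, params, lambda)
  list(loss = loss, prob = fw$prob, grads = grads)
}

# names of the leaves that count as weights for the L2 penalty (biases and
# the combiner bias are excluded)
is_weight_leaf <- function(name) name %in% c("Wi", "Wf", "Wo", "Wc", "V", "w")

walk_weights <- function(p, f, path = character()) {
  if (is.list(p)) {
    out <- lapply(seq_along(p), function(i)
      walk_weights(p[[i]], f, c(path, names(p)[i])))
    names(out) <- names(p)
    return(out)
  }
  f(p, path)
}

l2_penalty <- function(params) {
  total <- 0
  walk_weights(unclass(params), function(x, path) {
    if (is.numeric(x) && is_weight_leaf(path[length(path)]))
      total <<- total + sum(x^2)
    NULL
  })
  total
}

add_l2_gradient <- function(grads, params, lambda) {
  apply_leaf <- function(g, p, path = character()) {
    if (is.list(g)) {
      out <- lapply(seq_along(g), function(i)
        apply_leaf(g[[i]], p[[i]], c(path, names(g)[i])))
      names(out) <- names(g)
      return(out)
    }
    if (is.numeric(g) && is_weight_leaf(path[length(path)]))
      g + 2 * lambda * p else g
  }
  apply_leaf(grads, unclass(params))
}

#' Analytic gradients of the training loss
#'
#' One gradient array per trainable parameter of the mean binary
#' cross-entropy plus L2 loss on a batch, computed by reverse-mode
#' backpropagation through head, decoder, attention, combiner and both
#' encoder directions.
#'
#' @param X Standardized feature matrix, `B x T`.
#' @param y Binary labels (1 = high stress), length `B`.
#' @param params An [elstm_init()] object.
#' @param lambda L2 coefficient (biases excluded from the penalty).
#' @param steps Decoder iterations.
#' @return List with `loss`, `prob` and `grads` (nested list mirroring
#'   `params`).
#' @export
elstm_gradients <- function(X, y, params, lambda = 0, steps = 1L) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) < 1L) stop("empty batch", call. = FALSE)
  if (length(y) != nrow(X)) stop("labels do not match the batch", call. = FALSE)
  elstm_backward(X, y, params, lambda = lambda, steps = steps)
}

#' Compare analytic gradients with central differences
#'
#' Recomputes every gradient of the batch loss by central-difference
#' numerical differentiation of the forward pass (an independent route that
#' never touches the backpropagation code) and reports the worst
#' relative disagreement, `|a - n| / max(|a|, |n|, 1e-4)` (the floor makes
#' the comparison absolute for negligibly small gradients).
#'
#' @param params An [elstm_init()] object.
#' @param X Standardized feature matrix, `B x T`.
#' @param y Binary labels, length `B`.
#' @param lambda L2 coefficient.
#' @param step Central-difference step (default `1e-6`).
#' @return List with `max_rel_err`, and vectors `analytic`, `numeric` over
#'   the flattened parameters.
#' @export
check_gradients <- function(params, X, y, lambda = 1e-5, step = 1e-6) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  analytic <- flatten_params(elstm_gradients(X, y, params,
                                             lambda = lambda)$grads)
  skeleton <- unclass(params)
  theta <- flatten_params(skeleton)
  loss_at <- function(th) {
    p <- structure(unflatten_params(th, skeleton), class = "elstm_params")
    attributes(p) <- attributes(params)
    fw <- forward_batch(X, p)
    bce_l2_loss(y, fw$prob, p, lambda = lambda)
  }
  numeric <- vapply(seq_along(theta), function(j) {
    tp <- tm <- theta
    tp[j] <- tp[j] + step
    tm[j] <- tm[j] - step
    (loss_at(tp) - loss_at(tm)) / (2 * step)
  }, numeric(1))
  rel <- abs(analytic - numeric) / pmax(abs(analytic), abs(numeric), 1e-4)
  list(max_rel_err = max(rel), analytic = analytic, numeric = numeric)
}
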