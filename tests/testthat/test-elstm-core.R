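test_that("initialization is seeded, shaped and biased as documented", {
  p <- elstm_init(9, 4, seed = 7)
  q <- elstm_init(9, 4, seed = 7)
  expect_identical(p, q)
  expect_false(identical(p, elstm_init(9, 4, seed = 8)))

  n <- 4
  expect_equal(dim(p$encoder$forward$Wi), c(n, 2 * n + 1))
  expect_equal(dim(p$encoder$forward$Wc), c(n, n + 1))
  expect_equal(dim(p$encoder$V), c(n, 2 * n))
  expect_equal(dim(p$decoder$Wi), c(n, 3 * n))   # decoder input width = n
  expect_length(p$head$w, n)

  for (cell in list(p$encoder$forward, p$encoder$backward, p$decoder)) {
    expect_equal(cell$bi, numeric(n))
    expect_equal(cell$bo, numeric(n))
    expect_equal(cell$bc, numeric(n))
    expect_equal(cell$bf, rep(1, n))   # forget bias offset
  }
  expect_error(elstm_init(0, 4), "dimensions")
})

test_that("cell_step matches hand evaluation at zero weights", {
  zero_cell <- function(n, m, peephole = TRUE) {
    p <- lstm_cell_params(n, m, peephole = peephole, seed = 1)
    for (nm in c("Wi", "Wf", "Wo", "Wc")) p[[nm]][] <- 0
    p$bf[] <- 0
    p
  }
  p <- zero_cell(2, 1)
  s <- lstm_cell_step(0.7, list(c = c(0, 0), h = c(0, 0)), p)
  expect_equal(s$c, c(0, 0))
  expect_equal(s$h, c(0, 0))

  # n = 1, c_prev = 1: every gate is 1/2, candidate 0
  p1 <- zero_cell(1, 1)
  s <- lstm_cell_step(5, list(c = 1, h = 0), p1)
  expect_equal(s$c, 0.5, tolerance = 1e-12)
  expect_equal(s$h, 0.5 * tanh(0.5), tolerance = 1e-12)

  expect_error(lstm_cell_step(c(1, 2), list(c = 1, h = 0), p1), "shape")
})

test_that("gate activations stay in (0,1) and hidden components in (-1,1)", {
  set.seed(5)
  p <- lstm_cell_params(3, 2, peephole = TRUE, seed = 5)
  state <- list(c = rnorm(3), h = rnorm(3) / 2)
  for (i in 1:50) {
    state <- lstm_cell_step(rnorm(2, sd = 3), state, p)
    expect_true(all(abs(state$h) < 1))
    expect_true(all(is.finite(state$c)))
  }
})

test_that("zeroing the memory-cell gate columns reduces the peephole cell to the standard cell", {
  n <- 3; m <- 2
  peep <- lstm_cell_params(n, m, peephole = TRUE, seed = 9)
  std <- lstm_cell_params(n, m, peephole = FALSE, seed = 1)
  # share the non-peephole weights; zero the c-columns of the peephole gates
  for (nm in c("Wi", "Wf", "Wo")) {
    peep[[nm]][, 1:n] <- 0
    std[[nm]] <- peep[[nm]][, (n + 1):(2 * n + m), drop = FALSE]
  }
  std$Wc <- peep$Wc
  for (nm in c("bi", "bf", "bo", "bc")) std[[nm]] <- peep[[nm]]

  state_p <- state_s <- list(c = rnorm(n), h = tanh(rnorm(n)))
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(m)
    state_p <- lstm_cell_step(x, state_p, peep)
    state_s <- lstm_cell_step(x, state_s, std)
    expect_equal(state_p$c, state_s$c, tolerance = 1e-12)
    expect_equal(state_p$h, state_s$h, tolerance = 1e-12)
  }
})

test_that("encoder projects both directions and is direction-symmetric", {
  p <- elstm_init(6, 3, seed = 4)
  x <- rnorm(6)

  enc <- elstm_encode(x, p)
  expect_equal(dim(enc$H), c(3, 6))
  expect_identical(enc$H, elstm_encode(x, p)$H)
  expect_error(elstm_encode(rnorm(5), p), "length")

  # zero combiner -> all projected states are tanh(0) = 0
  pz <- p
  pz$encoder$V[] <- 0
  expect_equal(elstm_encode(x, pz)$H, matrix(0, 3, 6))

  # backward states on x equal forward states on rev(x), step-reversed
  bwd <- lstm_cell_run(x, structure(p$encoder$backward,
                                    class = "lstm_cell_params"),
                       reverse = TRUE)
  fwd_on_rev <- lstm_cell_run(rev(x), structure(p$encoder$backward,
                                                class = "lstm_cell_params"))
  expect_equal(bwd$H, fwd_on_rev$H[, 6:1], tolerance = 1e-12)
  expect_equal(bwd$C, fwd_on_rev$C[, 6:1], tolerance = 1e-12)
})

test_that("attention is a proper distribution with the documented special cases", {
  # zero query -> uniform
  a <- elstm_attend(c(0, 0), matrix(rnorm(8), 2, 4))
  expect_equal(a$weights, rep(0.25, 4))

  # identical states -> uniform, context equals the shared state
  H <- matrix(rep(c(0.3, -0.2), 5), 2, 5)
  a <- elstm_attend(c(1, 2), H)
  expect_equal(a$weights, rep(0.2, 5))
  expect_equal(a$context, c(0.3, -0.2))

  # worked softmax example: T = 2, n = 1
  a <- elstm_attend(1, matrix(c(1, 2), 1, 2))
  expect_equal(a$scores, c(1, 2))
  expect_equal(a$weights, exp(1:2) / sum(exp(1:2)), tolerance = 1e-12)
  expect_equal(a$context, sum(a$weights * c(1, 2)), tolerance = 1e-12)

  expect_error(elstm_attend(c(1, 2, 3), matrix(0, 2, 4)), "mismatch")

  # normalization + overflow safety across random and extreme inputs
  set.seed(6)
  for (i in 1:50) {
    n <- sample(1:5, 1); T_ <- sample(2:9, 1)
    q <- rnorm(n, sd = if (i %% 5 == 0) 1e3 else 1)
    H <- matrix(rnorm(n * T_), n, T_)
    a <- elstm_attend(q, H)
    expect_true(all(is.finite(a$weights)))
    expect_true(all(a$weights >= 0))
    expect_equal(sum(a$weights), 1, tolerance = 1e-12)
    expect_equal(a$context, drop(H %*% a$weights), tolerance = 1e-12)
  }
})

test_that("decoder composes attention and cell steps as documented", {
  p <- elstm_init(5, 3, seed = 10)
  H <- elstm_encode(rnorm(5), p)$H

  # zero decoder weights -> zero hidden output regardless of H
  pz <- p
  for (nm in c("Wi", "Wf", "Wo", "Wc")) pz$decoder[[nm]][] <- 0
  for (nm in c("bi", "bf", "bo", "bc")) pz$decoder[[nm]][] <- 0
  expect_equal(elstm_decode(H, pz), rep(0, 3))

  # one step from zero state: the context is the uniform average of H
  a <- elstm_attend(rep(0, 3), H)
  expect_equal(a$context, rowMeans(H), tolerance = 1e-12)

  # two steps reproduce the manual attend -> cell_step composition
  dec <- structure(p$decoder, class = "lstm_cell_params")
  state <- list(c = rep(0, 3), h = rep(0, 3))
  for (s in 1:2) {
    ctx <- elstm_attend(state$c, H)$context
    state <- lstm_cell_step(ctx, state, dec)
  }
  expect_equal(elstm_decode(H, p, steps = 2), state$h, tolerance = 1e-12)

  expect_error(elstm_decode(H, p, steps = 0), "steps")
})

test_that("forward is deterministic, bounded and functional", {
  p <- elstm_init(9, 4, seed = 3)
  x <- rnorm(9)
  expect_identical(elstm_forward(x, p), elstm_forward(x, p))

  pz <- p
  pz$head$w[] <- 0
  pz$head$b <- 0
  expect_equal(elstm_forward(x, pz), 0.5)

  set.seed(12)
  for (i in 1:25) {
    pp <- elstm_init(sample(2:9, 1), sample(1:5, 1), seed = i)
    d <- attr(pp, "T")
    pr <- elstm_forward(matrix(rnorm(3 * d, sd = 2), 3, d), pp)
    expect_true(all(pr > 0 & pr < 1))
  }
  expect_error(elstm_forward(rnorm(3), p), "features")
})

test_that("parameter counting follows the shape arithmetic, not the nominal formula", {
  p1 <- elstm_init(9, 1, seed = 1)
  expect_equal(count_parameters(p1), 50)          # hand shape arithmetic
  expect_equal(nominal_parameter_count(1, 1), 21) # quoted nominal figure

  c2 <- count_parameters(elstm_init(9, 2, seed = 1))
  c4 <- count_parameters(elstm_init(9, 4, seed = 1))
  expect_gt(c4, 3 * c2)   # quadratic growth in hidden size
})
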