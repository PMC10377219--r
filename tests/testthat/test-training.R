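test_that("BCE + L2 loss reproduces closed-form values", {
  expect_equal(bce_l2_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_lt(bce_l2_loss(c(1), c(1 - 1e-7)), 1e-6)
  expect_error(bce_l2_loss(numeric(0), numeric(0)), "empty")
  expect_error(bce_l2_loss(c(1, 0), c(0.5)), "length")

  # L2 adds exactly lambda * sum(w^2), biases excluded
  p <- elstm_init(4, 2, seed = 1)
  p2 <- rapply(unclass(p), function(x) if (is.numeric(x)) x * 0 + 2 else x,
               how = "replace")
  p2 <- structure(p2, class = "elstm_params", n = 2L, T = 4L, m = 1L)
  n_weights <- sum(vapply(
    list(p2$encoder$forward, p2$encoder$backward, p2$decoder),
    function(cell) length(cell$Wi) + length(cell$Wf) + length(cell$Wo) +
      length(cell$Wc), numeric(1))) + length(p2$encoder$V) + length(p2$head$w)
  base <- bce_l2_loss(c(1, 0), c(0.5, 0.5))
  expect_equal(bce_l2_loss(c(1, 0), c(0.5, 0.5), p2, lambda = 1e-5) - base,
               4e-5 * n_weights, tolerance = 1e-12)
})

test_that("analytic gradients match closed forms and central differences", {
  # zero-weight model on zero inputs: p = 1/2 and only the head bias moves
  p <- elstm_init(3, 2, seed = 1)
  p <- rapply(unclass(p), function(x) if (is.numeric(x)) x * 0 else x,
              how = "replace")
  p <- structure(p, class = "elstm_params", n = 2L, T = 3L, m = 1L)
  y <- c(1, 0, 0, 1, 0)
  g <- elstm_gradients(matrix(0, 5, 3), y, p)
  expect_equal(g$grads$head$b, mean(0.5 - y), tolerance = 1e-12)
  expect_equal(g$grads$head$w, rep(0, 2))

  # L2 shifts every weight gradient by exactly 2 * lambda * w
  p <- elstm_init(3, 2, seed = 2)
  X <- matrix(rnorm(15), 5, 3)
  g0 <- elstm_gradients(X, y, p, lambda = 0)$grads
  g1 <- elstm_gradients(X, y, p, lambda = 1e-3)$grads
  expect_equal(g1$encoder$forward$Wi - g0$encoder$forward$Wi,
               2e-3 * p$encoder$forward$Wi, tolerance = 1e-12)
  expect_equal(g1$head$w - g0$head$w, 2e-3 * p$head$w, tolerance = 1e-12)
  expect_equal(g1$decoder$bi, g0$decoder$bi)  # biases unpenalized

  # full numerical check on a small random model
  p <- elstm_init(3, 2, seed = 3)
  chk <- check_gradients(p, matrix(rnorm(12), 4, 3), c(1, 0, 1, 0),
                         lambda = 1e-5, step = 1e-6)
  expect_lt(chk$max_rel_err, 1e-5)
})

test_that("Adam updates satisfy the expected fixed points and unit-step property", {
  p <- elstm_init(3, 2, seed = 4)
  cfg <- training_config()
  zero <- elstm_gradients(matrix(0, 2, 3), c(0, 1),
                          structure(rapply(unclass(p), function(x)
                            if (is.numeric(x)) x * 0 else x, how = "replace"),
                            class = "elstm_params", n = 2L, T = 3L, m = 1L))$grads
  same <- adam_step(p, rapply(zero, function(x) x * 0, how = "replace",
                              classes = "numeric"), NULL, cfg, 1)$params
  expect_equal(flatten_params(unclass(same)), flatten_params(unclass(p)))

  cfg0 <- training_config(learning_rate = 1e-12)
  g <- elstm_gradients(matrix(rnorm(6), 2, 3), c(0, 1), p)$grads
  near <- adam_step(p, g, NULL, cfg0, 1)$params
  expect_equal(flatten_params(unclass(near)), flatten_params(unclass(p)),
               tolerance = 1e-9)

  # single-parameter view: the first Adam step has magnitude ~ learning_rate
  upd <- adam_step(list(w = 1), list(w = 0.37), NULL,
                   training_config(learning_rate = 0.01), 1)
  expect_equal(upd$params$w, 1 - 0.01, tolerance = 1e-6)
})

test_that("fit is reproducible and returns the initialization when epochs = 0", {
  co <- generate_cohort(separable_cohort_spec(60, 60), 21)
  cfg <- training_config(epochs = 0, n_hidden = 3)
  m <- fit_elstm(co, config = cfg, seed = 5)
  expect_equal(nrow(m$history), 0)
  init <- elstm_init(11, 3, seed = elstm:::derive_seed(5, 2L))
  expect_identical(flatten_params(unclass(m$params)),
                   flatten_params(unclass(init)))

  cfg <- training_config(epochs = 3, batch_size = 32, n_hidden = 3)
  m1 <- fit_elstm(co, config = cfg, seed = 9)
  m2 <- fit_elstm(co, config = cfg, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(flatten_params(unclass(m1$params)),
                   flatten_params(unclass(m2$params)))

  expect_error(fit_elstm(co[co$stress == "low", ]), "both")
})

test_that("training loss is non-increasing on a separable cohort without dropout", {
  co <- generate_cohort(separable_cohort_spec(100, 100), 17)
  cfg <- training_config(epochs = 25, batch_size = 200, learning_rate = 0.005,
                         dropout_rate = 0, lambda = 0, n_hidden = 4)
  m <- fit_elstm(co, config = cfg, seed = 2)
  drops <- diff(m$history$train_loss)
  expect_gte(mean(drops <= 1e-8), 0.9)
  expect_true(all(is.finite(m$history$train_loss)))
  expect_true(all(m$history$train_loss >= 0))
})
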