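# Stacked LSTM: cell equations, forward pass, gradient exactness against
# finite differences, clipping, and the training loop.

random_layer <- function(d, h, seed) {
  with_seed <- gaittorque:::with_seed
  with_seed(seed, {
    p <- gaittorque:::lstm_layer_params(d, h)
    lapply(p, function(w) if (is.matrix(w)) w + rnorm(length(w), sd = 0.3)
           else rnorm(length(w), sd = 0.3))
  })
}

test_that("cell with zero parameters reproduces the half-activation fixed point", {
  p <- lapply(gaittorque:::lstm_layer_params(2, 3), function(w) w * 0)
  st <- lstm_cell_forward(c(0.7, -0.2), list(h = rep(0, 3), c = rep(0, 3)), p)
  expect_equal(st$f, rep(0.5, 3))
  expect_equal(st$i, rep(0.5, 3))
  expect_equal(st$o, rep(0.5, 3))
  expect_equal(st$c, rep(0, 3))
  expect_equal(st$h, rep(0, 3))
  # with a carried cell state of 2: c = 0.5 * 2 = 1, h = 0.5 * tanh(1)
  p1 <- lapply(gaittorque:::lstm_layer_params(1, 1), function(w) w * 0)
  st1 <- lstm_cell_forward(0, list(h = 0, c = 2), p1)
  expect_equal(st1$c, 1)
  expect_equal(st1$h, 0.5 * tanh(1))
})

test_that("cell output matches a term-by-term transcription of the gate equations", {
  sig <- function(z) 1 / (1 + exp(-z))
  for (seed in 1:5) {
    d <- 4; h <- 3
    p <- random_layer(d, h, seed)
    x <- rnorm(d); h_prev <- rnorm(h, sd = 0.5); c_prev <- rnorm(h, sd = 0.5)
    st <- lstm_cell_forward(x, list(h = h_prev, c = c_prev), p)
    # independent straight-line transcription of the forward equations
    f <- sig(drop(p$Wf %*% x) + drop(p$Uf %*% h_prev) + p$bf)
    i <- sig(drop(p$Wi %*% x) + drop(p$Ui %*% h_prev) + p$bi)
    cb <- tanh(drop(p$Wc %*% x) + drop(p$Uc %*% h_prev) + p$bc)
    o <- sig(drop(p$Wo %*% x) + drop(p$Uo %*% h_prev) + p$bo)
    cc <- f * c_prev + i * cb
    hh <- o * tanh(cc)
    expect_equal(st$f, f); expect_equal(st$i, i)
    expect_equal(st$c_tilde, cb); expect_equal(st$o, o)
    expect_equal(st$c, cc); expect_equal(st$h, hh)
    # gate ranges
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(st$c_tilde > -1 & st$c_tilde < 1))
  }
})

test_that("zero-parameter network outputs its output-layer bias", {
  net <- lstm_network(3, hidden = c(4, 2), seed = 1)
  zeroed <- gaittorque:::set_network_params(
    net, rapply(gaittorque:::network_params(net), function(w) w * 0,
                how = "replace"))
  zeroed$fc$b <- 0.37
  expect_equal(network_forward(matrix(0, 5, 3), zeroed), 0.37)
})

test_that("the prediction is sensitive to the order of time steps", {
  net <- lstm_network(3, hidden = c(4, 2), seed = 7)
  set.seed(8)
  s <- matrix(rnorm(15), 5, 3)
  y1 <- network_forward(s, net)
  y2 <- network_forward(s[c(2, 1, 3, 5, 4), ], net)
  expect_gt(abs(y1 - y2), 1e-8)
})

test_that("BPTT gradients match central finite differences for every parameter", {
  net <- lstm_network(4, hidden = c(3, 2), seed = 3)
  set.seed(4)
  N <- 3; T_len <- 5
  x <- array(rnorm(N * T_len * 4), c(N, T_len, 4))
  y <- rnorm(N)
  gr <- lstm_gradients(net, x, y)
  params <- gaittorque:::network_params(net)
  theta <- gaittorque:::flatten_params(params)
  g_exact <- gaittorque:::flatten_params(gr$grads)
  eps <- 1e-5
  loss_at <- function(v) {
    n2 <- gaittorque:::set_network_params(
      net, gaittorque:::unflatten_params(v, params))
    mean((gaittorque:::net_forward_batch(n2, x)$yhat - y)^2)
  }
  g_num <- vapply(seq_along(theta), function(k) {
    tp <- theta; tp[k] <- tp[k] + eps
    tm <- theta; tm[k] <- tm[k] - eps
    (loss_at(tp) - loss_at(tm)) / (2 * eps)
  }, numeric(1))
  denom <- pmax(abs(g_exact), abs(g_num), 1e-8)
  expect_lt(max(abs(g_exact - g_num) / denom), 1e-5)
})

test_that("loss decreases over the first steps of plain gradient descent", {
  net <- lstm_network(2, hidden = c(3), seed = 5)
  set.seed(6)
  x <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
  y <- rnorm(4)
  params <- gaittorque:::network_params(net)
  theta <- gaittorque:::flatten_params(params)
  losses <- numeric(10)
  for (it in 1:10) {
    n2 <- gaittorque:::set_network_params(
      net, gaittorque:::unflatten_params(theta, params))
    gr <- lstm_gradients(n2, x, y)
    losses[it] <- gr$loss
    theta <- theta - 0.05 * gaittorque:::flatten_params(gr$grads)
  }
  expect_lt(losses[10], losses[1])
})

test_that("gradient clipping rescales only above the global-norm threshold", {
  g <- list(a = c(0.3, 0.4))                      # norm 0.5
  expect_identical(clip_gradients(g, 1), g)
  g2 <- clip_gradients(list(a = c(3, 4)), 1)      # norm 5 -> scaled by 1/5
  expect_equal(g2$a, c(0.6, 0.8))
  set.seed(12)
  for (rep in 1:20) {
    g3 <- list(w = matrix(rnorm(12, sd = 3), 3, 4), b = rnorm(3, sd = 3))
    cl <- clip_gradients(g3, 1)
    expect_lte(sqrt(sum(unlist(cl)^2)), 1 + 1e-12)
  }
  expect_error(clip_gradients(g, 0), "positive")
})

test_that("the learning-rate schedule drops by the factor every period", {
  expect_equal(learning_rate_at(1), 0.005)
  expect_equal(learning_rate_at(125), 0.005)
  expect_equal(learning_rate_at(126), 0.001)
  expect_equal(learning_rate_at(251), 0.0002)
})

test_that("training is deterministic and learns a linear toy target", {
  set.seed(14)
  N <- 60; T_len <- 5; d <- 3
  x <- array(rnorm(N * T_len * d), c(N, T_len, d))
  w <- c(0.8, -0.5, 0.3)
  y <- apply(x, 1, function(s) sum(colMeans(s) * w)) + rnorm(N, sd = 0.02)
  set1 <- list(x = x, y = y)
  f1 <- lstm_train(set1, hidden = c(6, 4), epochs = 200, seed = 2)
  f2 <- lstm_train(set1, hidden = c(6, 4), epochs = 200, seed = 2)
  expect_identical(f1$loss, f2$loss)
  expect_identical(lstm_predict(f1$net, set1), lstm_predict(f2$net, set1))
  # final training fit: NRMSE below 10 %
  expect_lt(nrmse(y, lstm_predict(f1$net, set1)), 10)
})

test_that("batched prediction equals per-sample forward passes", {
  net <- lstm_network(3, hidden = c(4, 2), seed = 20)
  set.seed(21)
  x <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  batched <- lstm_predict(net, list(x = x))
  single <- vapply(1:6, function(k) network_forward(x[k, , ], net), numeric(1))
  expect_equal(batched, single)
  # constant inputs give constant predictions
  xc <- array(0.4, c(5, 5, 3))
  expect_equal(diff(range(lstm_predict(net, list(x = xc)))), 0)
})
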