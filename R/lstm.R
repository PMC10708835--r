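sigmoid <- function(z) 1 / (1 + exp(-z))

glorot_uniform <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

orthogonal_init <- function(h) {
  if (h == 1L) return(matrix(sign(stats::rnorm(1)), 1, 1))
  qr.Q(qr(matrix(stats::rnorm(h * h), h, h)))
}

lstm_layer_params <- function(d, h, forget_bias = 1) {
  list(Wf = glorot_uniform(h, d), Wi = glorot_uniform(h, d),
       Wc = glorot_uniform(h, d), Wo = glorot_uniform(h, d),
       Uf = orthogonal_init(h), Ui = orthogonal_init(h),
       Uc = orthogonal_init(h), Uo = orthogonal_init(h),
       bf = rep(forget_bias, h), bi = numeric(h), bc = numeric(h),
       bo = numeric(h))
}

#' Construct a stacked LSTM regression network
#'
#' Builds the parameter tensors of a stacked LSTM regressor: LSTM layers of
#' the given hidden sizes (the first `length(hidden) - 1` layers emit their
#' full hidden sequence, the final layer only its last hidden state), a
#' sigmoid layer, and an affine map to one output. Weights are initialized
#' Glorot-uniform (input), orthogonal (recurrent) and zero (biases, except
#' the forget-gate bias which starts at 1 so early cell states persist),
#' from the given seed.
#'
#' @param input_dim Number of input features per time step.
#' @param hidden Hidden sizes per LSTM layer (default 32, 16, 8).
#' @param seed Initialization seed.
#' @param forget_bias Initial forget-gate bias.
#' @return An object of class `lstm_network`.
#' @export
lstm_network <- function(input_dim, hidden = c(32L, 16L, 8L), seed = 1L,
                         forget_bias = 1) {
  stopifnot(length(hidden) >= 1L, all(hidden >= 1L))
  with_seed(seed, {
    dims <- c(input_dim, hidden)
    layers <- lapply(seq_along(hidden), function(l) {
      lstm_layer_params(dims[l], dims[l + 1L], forget_bias)
    })
    fc <- list(W = glorot_uniform(1L, hidden[length(hidden)]), b = 0)
    structure(list(layers = layers, fc = fc, input_dim = input_dim,
                   hidden = hidden),
              class = "lstm_network")
  })
}

#' @export
print.lstm_network <- function(x, ...) {
  cat(sprintf("Stacked LSTM: input %d -> [%s] -> sigmoid -> 1 (%d parameters)\n",
              x$input_dim, paste(x$hidden, collapse = ", "),
              length(flatten_params(network_params(x)))))
  invisible(x)
}

network_params <- function(net) list(layers = net$layers, fc = net$fc)

set_network_params <- function(net, params) {
  net$layers <- params$layers
  net$fc <- params$fc
  net
}

#' One LSTM cell step
#'
#' Evaluates the gate equations of a single LSTM unit: forget, input and
#' output gates through the sigmoid, candidate cell through tanh, then
#' `c_t = f * c_prev + i * c_tilde` and `h_t = o * tanh(c_t)`.
#'
#' @param x_t Input vector at time t (length d).
#' @param state_prev List with `h` and `c` (length h each).
#' @param params One layer's parameter list (`Wf, Wi, Wc, Wo, Uf, Ui, Uc, Uo,
#'   bf, bi, bc, bo`).
#' @return List with gates `f`, `i`, `o`, candidate `c_tilde`, and the new
#'   state `c`, `h`.
#' @export
lstm_cell_forward <- function(x_t, state_prev, params) {
  if (length(x_t) != ncol(params$Wf)) stop("input size mismatch", call. = FALSE)
  if (length(state_prev$h) != nrow(params$Uf)) {
    stop("state size mismatch", call. = FALSE)
  }
  st <- cell_forward_batch(matrix(x_t, ncol = 1),
                           matrix(state_prev$h, ncol = 1),
                           matrix(state_prev$c, ncol = 1), params)
  list(f = drop(st$f), i = drop(st$i), o = drop(st$o),
       c_tilde = drop(st$cb), c = drop(st$c), h = drop(st$h))
}

# Batched cell step: columns are samples.
cell_forward_batch <- function(Xt, Hprev, Cprev, p) {
  f  <- sigmoid(p$Wf %*% Xt + p$Uf %*% Hprev + p$bf)
  i  <- sigmoid(p$Wi %*% Xt + p$Ui %*% Hprev + p$bi)
  cb <- tanh(p$Wc %*% Xt + p$Uc %*% Hprev + p$bc)
  o  <- sigmoid(p$Wo %*% Xt + p$Uo %*% Hprev + p$bo)
  c  <- f * Cprev + i * cb
  tc <- tanh(c)
  list(f = f, i = i, cb = cb, o = o, c = c, tc = tc, h = o * tc)
}

# Full forward pass over a batch. x: array [N, T, d]. Returns predictions and
# (optionally) the caches needed for backpropagation through time.
net_forward_batch <- function(net, x, keep_cache = FALSE) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == net$input_dim)
  N <- dim(x)[1]; T_len <- dim(x)[2]
  inp <- lapply(seq_len(T_len), function(t) {
    t(array(x[, t, ], dim = c(N, dim(x)[3])))      # d x N
  })
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    p <- net$layers[[l]]
    h <- nrow(p$Uf)
    Hprev <- matrix(0, h, N); Cprev <- matrix(0, h, N)
    cache_l <- vector("list", T_len)
    out_l <- vector("list", T_len)
    for (t in seq_len(T_len)) {
      st <- cell_forward_batch(inp[[t]], Hprev, Cprev, p)
      if (keep_cache) {
        cache_l[[t]] <- c(st, list(x = inp[[t]], h_prev = Hprev,
                                   c_prev = Cprev))
      }
      out_l[[t]] <- st$h
      Hprev <- st$h; Cprev <- st$c
    }
    caches[[l]] <- cache_l
    inp <- out_l
  }
  h_last <- inp[[T_len]]                 # final layer, last time step
  s <- sigmoid(h_last)
  yhat <- drop(net$fc$W %*% s + net$fc$b)
  list(yhat = yhat, s = s, caches = caches, T_len = T_len, N = N)
}

#' Forward pass on one input sequence
#'
#' @param sequence Matrix time_step x d (rows = time steps).
#' @param net An [lstm_network()].
#' @return Scalar prediction.
#' @export
network_forward <- function(sequence, net) {
  sequence <- as.matrix(sequence)
  if (ncol(sequence) != net$input_dim) stop("wrong input width", call. = FALSE)
  x <- array(0, c(1L, nrow(sequence), ncol(sequence)))
  x[1, , ] <- sequence
  net_forward_batch(net, x)$yhat
}

# Backward through one LSTM layer. dH_ext: list over t of h x N gradients
# arriving from above. Returns parameter gradients and the gradients passed
# to the layer below.
bptt_layer <- function(p, cache_l, dH_ext) {
  T_len <- length(cache_l)
  h <- nrow(p$Uf); N <- ncol(cache_l[[1]]$h)
  g <- lapply(p, function(w) w * 0)
  dh_next <- matrix(0, h, N); dc_next <- matrix(0, h, N)
  dX <- vector("list", T_len)
  for (t in rev(seq_len(T_len))) {
    ch <- cache_l[[t]]
    dh <- dH_ext[[t]] + dh_next
    do <- dh * ch$tc
    dc <- dc_next + dh * ch$o * (1 - ch$tc^2)
    df <- dc * ch$c_prev
    di <- dc * ch$cb
    dcb <- dc * ch$i
    dc_next <- dc * ch$f
    da_f <- df * ch$f * (1 - ch$f)
    da_i <- di * ch$i * (1 - ch$i)
    da_o <- do * ch$o * (1 - ch$o)
    da_c <- dcb * (1 - ch$cb^2)
    g$Wf <- g$Wf + tcrossprod(da_f, ch$x)
    g$Wi <- g$Wi + tcrossprod(da_i, ch$x)
    g$Wc <- g$Wc + tcrossprod(da_c, ch$x)
    g$Wo <- g$Wo + tcrossprod(da_o, ch$x)
    g$Uf <- g$Uf + tcrossprod(da_f, ch$h_prev)
    g$Ui <- g$Ui + tcrossprod(da_i, ch$h_prev)
    g$Uc <- g$Uc + tcrossprod(da_c, ch$h_prev)
    g$Uo <- g$Uo + tcrossprod(da_o, ch$h_prev)
    g$bf <- g$bf + rowSums(da_f)
    g$bi <- g$bi + rowSums(da_i)
    g$bc <- g$bc + rowSums(da_c)
    g$bo <- g$bo + rowSums(da_o)
    dX[[t]] <- crossprod(p$Wf, da_f) + crossprod(p$Wi, da_i) +
      crossprod(p$Wc, da_c) + crossprod(p$Wo, da_o)
    dh_next <- crossprod(p$Uf, da_f) + crossprod(p$Ui, da_i) +
      crossprod(p$Uc, da_c) + crossprod(p$Uo, da_o)
  }
  list(grads = g, dX = dX)
}

#' Loss and exact gradients by backpropagation through time
#'
#' Mean-squared-error loss over a batch and its exact reverse-mode gradients
#' with respect to every parameter (all gate weights, recurrent weights,
#' biases, and the output layer).
#'
#' @param net An [lstm_network()].
#' @param x Input array N x time_step x d.
#' @param y Target vector (length N).
#' @return List with `loss`, `yhat` and `grads` (same structure as the
#'   network's parameters).
#' @export
lstm_gradients <- function(net, x, y) {
  fw <- net_forward_batch(net, x, keep_cache = TRUE)
  N <- fw$N
  resid <- fw$yhat - y
  loss <- mean(resid^2)
  dyhat <- matrix(2 * resid / N, nrow = 1)             # 1 x N
  g_fc <- list(W = tcrossprod(dyhat, fw$s), b = sum(dyhat))
  ds <- crossprod(net$fc$W, dyhat)                     # h x N
  dh_final <- ds * fw$s * (1 - fw$s)
  n_layers <- length(net$layers)
  g_layers <- vector("list", n_layers)
  dH_ext <- NULL
  for (l in rev(seq_len(n_layers))) {
    cache_l <- fw$caches[[l]]
    T_len <- fw$T_len
    if (l == n_layers) {
      h <- nrow(net$layers[[l]]$Uf)
      dH_ext <- lapply(seq_len(T_len), function(t) matrix(0, h, N))
      dH_ext[[T_len]] <- dh_final
    }
    bp <- bptt_layer(net$layers[[l]], cache_l, dH_ext)
    g_layers[[l]] <- bp$grads
    dH_ext <- bp$dX
  }
  list(loss = loss, yhat = fw$yhat,
       grads = list(layers = g_layers, fc = g_fc))
}

#' Clip gradients by global L2 norm
#'
#' If the global L2 norm across all gradients exceeds the threshold, every
#' gradient is scaled by `threshold / norm`; otherwise gradients pass through
#' unchanged.
#'
#' @param grads Gradient structure (nested list of numeric arrays).
#' @param threshold Positive norm threshold.
#' @return Clipped gradients, same structure.
#' @export
clip_gradients <- function(grads, threshold = 1) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  v <- flatten_params(grads)
  nrm <- sqrt(sum(v^2))
  if (nrm <= threshold) return(grads)
  unflatten_params(v * (threshold / nrm), grads)
}

#' Learning rate under the piecewise drop schedule
#'
#' The initial rate is multiplied by the drop factor once per full drop
#' period: with the defaults the rate is 0.005 for epochs 1-125, 0.001 for
#' 126-250, and so on.
#'
#' @param epoch Epoch number (1-based).
#' @param initial Initial learning rate.
#' @param factor Multiplicative drop factor.
#' @param period Epochs between drops.
#' @return The learning rate at `epoch`.
#' @export
learning_rate_at <- function(epoch, initial = 0.005, factor = 0.2,
                             period = 125L) {
  initial * factor^((epoch - 1L) %/% period)
}

#' Train the LSTM regressor
#'
#' Full-batch Adam on the mean-squared error with global-norm gradient
#' clipping and the piecewise learning-rate drop schedule. Training is
#' deterministic given the seed (initialization is the only random element).
#'
#' @param set A `supervised_set` of kind "sequence" (from [make_sequences()]),
#'   or a list with `x` (N x T x d array) and `y`.
#' @param hidden LSTM layer sizes.
#' @param epochs Training epochs.
#' @param lr,lr_drop_factor,lr_drop_period Learning-rate schedule; see
#'   [learning_rate_at()].
#' @param clip Global gradient-norm threshold.
#' @param seed Initialization seed.
#' @param net Optional pre-built [lstm_network()] (overrides `hidden`/`seed`).
#' @param restarts Number of candidate initializations; with more than one,
#'   each candidate is trained for `restart_epochs` epochs and the one with
#'   the lowest training loss is retrained in full (deterministic, and uses
#'   training data only).
#' @param restart_epochs Probe length for initialization selection.
#' @return List with the trained `net` and the per-epoch `loss` history.
#' @export
lstm_train <- function(set, hidden = c(32L, 16L, 8L), epochs = 500L,
                       lr = 0.005, lr_drop_factor = 0.2,
                       lr_drop_period = 125L, clip = 1, seed = 1L,
                       net = NULL, restarts = 1L, restart_epochs = 60L) {
  x <- set$x; y <- set$y
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == length(y), length(y) >= 1L)
  if (is.null(net) && restarts > 1L) {
    # probe several initializations briefly and keep the one with the lowest
    # training loss; selection uses training data only
    probe <- vapply(seq_len(restarts), function(k) {
      cand <- lstm_network(dim(x)[3], hidden, seed + 1000L * (k - 1L))
      fit <- lstm_train(set, epochs = min(restart_epochs, epochs), lr = lr,
                        lr_drop_factor = lr_drop_factor,
                        lr_drop_period = lr_drop_period, clip = clip,
                        net = cand)
      fit$loss[length(fit$loss)]
    }, numeric(1))
    seed <- seed + 1000L * (which.min(probe) - 1L)
  }
  if (is.null(net)) net <- lstm_network(dim(x)[3], hidden, seed)
  theta <- flatten_params(network_params(net))
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    gr <- lstm_gradients(net, x, y)
    if (!is.finite(gr$loss)) {
      stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
    }
    loss_hist[ep] <- gr$loss
    g <- flatten_params(clip_gradients(gr$grads, clip))
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^ep)
    vh <- v / (1 - b2^ep)
    rate <- learning_rate_at(ep, lr, lr_drop_factor, lr_drop_period)
    theta <- theta - rate * mh / (sqrt(vh) + eps)
    net <- set_network_params(
      net, unflatten_params(theta, network_params(net)))
  }
  list(net = net, loss = loss_hist)
}

#' Predict with a trained LSTM
#'
#' @param net A trained [lstm_network()].
#' @param set A `supervised_set` (kind "sequence") or an N x T x d array.
#' @return Numeric vector of predictions, aligned to the set's target rows.
#' @export
lstm_predict <- function(net, set) {
  x <- if (is.list(set)) set$x else set
  stopifnot(length(dim(x)) == 3L)
  net_forward_batch(net, x)$yhat
}
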