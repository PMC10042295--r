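# Minimal neural-network engine used by the classifier harness.
#
# Activations are base-R arrays in (H, W, N, C) layout — batch before
# channels, so a convolution's im2col GEMM writes its output in the layout
# the next layer consumes without reordering. The convolution and pooling
# kernels are compiled (src/nn_kernels.cpp, im2col + BLAS GEMM); dense
# layers, reductions and the optimiser live here. Everything is
# deterministic given R's RNG state.

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# ---- convolution layer -----------------------------------------------------

# Same-padding stride-1 convolution, kernel sides odd. Weights are stored
# transposed (Wt: kh*kw*C x filters) with patch order (dh, dw, c), so both
# the forward GEMM and the weight-gradient GEMM run without transposes.
nn_conv <- function(in_shape, filters, kh, kw = kh,
                    activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  list(type = "conv", in_shape = in_shape,
       out_shape = c(in_shape[1L], in_shape[2L], filters),
       filters = filters, kh = kh, kw = kw,
       ph = (kh - 1L) %/% 2L, pw = (kw - 1L) %/% 2L,
       k2c = kh * kw * in_shape[3L], activation = activation,
       Wt = matrix(0, kh * kw * in_shape[3L], filters),
       b = numeric(filters))
}

conv_init <- function(layer) {
  fan_in <- layer$k2c
  sd <- if (layer$activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
  layer$Wt <- matrix(stats::rnorm(length(layer$Wt), sd = sd),
                     nrow(layer$Wt), ncol(layer$Wt))
  layer$b <- numeric(layer$filters)
  layer
}

conv_forward <- function(layer, x, store = FALSE) {
  d <- dim(x); N <- d[3L]
  out <- cpp_conv_forward(x, d[1L], d[2L], N, d[4L], layer$Wt, layer$b,
                          layer$kh, layer$kw,
                          layer$activation == "relu")
  cache <- if (store) list(x = x, out = out, N = N) else NULL
  list(out = out, cache = cache)
}

conv_backward <- function(layer, cache, dout, need_input_grad) {
  d <- dim(cache$x)
  cpp_conv_backward(cache$x, d[1L], d[2L], d[3L], d[4L], layer$Wt,
                    layer$kh, layer$kw, dout, cache$out,
                    layer$activation == "relu", need_input_grad)
}

# ---- max pooling ------------------------------------------------------------

# (ph x pw) max pooling with stride = window size; trailing rows/columns
# that do not fill a window are dropped (floor semantics)
nn_pool <- function(in_shape, ph, pw) {
  list(type = "pool",
       in_shape = in_shape,
       out_shape = c(in_shape[1L] %/% ph, in_shape[2L] %/% pw, in_shape[3L]),
       ph = ph, pw = pw)
}

pool_forward <- function(layer, x, store = FALSE) {
  d <- dim(x)
  r <- cpp_maxpool_forward(x, d[1L], d[2L], d[3L], d[4L], layer$ph, layer$pw)
  list(out = r$out,
       cache = if (store) list(argmax = r$argmax, len_x = length(x),
                               in_dim = d) else NULL)
}

pool_backward <- function(layer, cache, dout) {
  dx <- cpp_maxpool_backward(dout, cache$argmax, cache$len_x)
  dim(dx) <- cache$in_dim
  dx
}

# ---- dense layers -----------------------------------------------------------

nn_dense <- function(in_dim, out_dim, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       activation = activation,
       W = matrix(0, out_dim, in_dim), b = numeric(out_dim))
}

dense_init <- function(layer) {
  sd <- if (layer$activation == "relu") sqrt(2 / layer$in_dim)
        else sqrt(1 / layer$in_dim)
  layer$W <- matrix(stats::rnorm(length(layer$W), sd = sd),
                    layer$out_dim, layer$in_dim)
  layer$b <- numeric(layer$out_dim)
  layer
}

dense_forward <- function(layer, x, store = FALSE) {
  z <- layer$W %*% x + layer$b
  mask <- NULL
  if (layer$activation == "relu") {
    if (store) mask <- z > 0
    z <- pmax(z, 0)
  }
  list(out = z, cache = if (store) list(x = x, mask = mask) else NULL)
}

dense_backward <- function(layer, cache, dout) {
  if (!is.null(cache$mask)) dout[!cache$mask] <- 0
  list(dW = dout %*% t(cache$x), db = rowSums(dout),
       dx = crossprod(layer$W, dout))
}

# ---- spatial reductions ------------------------------------------------------

# (H, W, N, C) -> feature matrix (C, N), mean over the spatial dims
gap_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1L] * d[2L], d[3L] * d[4L])
  t(matrix(colMeans(m), d[3L], d[4L]))
}

gap_backward <- function(dfeat, in_dim) {
  hw <- in_dim[1L] * in_dim[2L]
  array(rep(as.vector(t(dfeat)) / hw, each = hw), in_dim)
}

# (H, W, N, C) -> (H*W*C, N)
flatten_forward <- function(x) {
  d <- dim(x)
  x <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(x) <- c(d[1L] * d[2L] * d[4L], d[3L])
  x
}

flatten_backward <- function(dfeat, in_dim) {
  dim(dfeat) <- in_dim[c(1L, 2L, 4L, 3L)]
  aperm(dfeat, c(1L, 2L, 4L, 3L))
}

# ---- whole-model forward / backward -----------------------------------------

# xs: list of input arrays, one per branch, each (H, W, N, C)
model_forward <- function(model, xs, store = FALSE) {
  N <- dim(xs[[1L]])[3L]
  branch_caches <- vector("list", length(model$branches))
  branch_out_dims <- vector("list", length(model$branches))
  feats <- vector("list", length(model$branches))
  for (b in seq_along(model$branches)) {
    x <- xs[[b]]
    layers <- model$branches[[b]]
    caches <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      lay <- layers[[i]]
      r <- if (lay$type == "conv") conv_forward(lay, x, store)
           else pool_forward(lay, x, store)
      x <- r$out
      caches[[i]] <- r$cache
    }
    branch_out_dims[[b]] <- dim(x)
    feats[[b]] <- if (model$reduce == "gap") gap_forward(x)
                  else flatten_forward(x)
    branch_caches[[b]] <- caches
  }
  f <- do.call(rbind, feats)
  head_caches <- vector("list", length(model$head))
  for (i in seq_along(model$head)) {
    r <- dense_forward(model$head[[i]], f, store)
    f <- r$out
    head_caches[[i]] <- r$cache
  }
  probs <- softmax_cols(f)
  list(logits = f, probs = probs, N = N,
       branch_caches = branch_caches, branch_out_dims = branch_out_dims,
       head_caches = head_caches)
}

# Backward pass from a gradient at the logits. Returns parameter gradients
# (for trainable layers) and, optionally, the gradient at the output of the
# last convolution of branch `act_grad_branch` (used by GradCAM).
model_backward <- function(model, fw, dlogits, want_params = TRUE,
                           act_grad_branch = 0L) {
  grads <- list()
  d <- dlogits
  for (i in rev(seq_along(model$head))) {
    g <- dense_backward(model$head[[i]], fw$head_caches[[i]], d)
    if (want_params) grads[[paste0("head", i)]] <- g[c("dW", "db")]
    d <- g$dx
  }
  act_grad <- NULL
  backbone_trainable <- want_params && !model$freeze_backbone
  if (backbone_trainable || act_grad_branch > 0L) {
    sizes <- model$branch_feat_dim
    offsets <- cumsum(c(0, sizes))
    for (b in seq_along(model$branches)) {
      if (!backbone_trainable && b != act_grad_branch) next
      df <- d[(offsets[b] + 1L):offsets[b + 1L], , drop = FALSE]
      dx <- if (model$reduce == "gap")
        gap_backward(df, fw$branch_out_dims[[b]])
      else flatten_backward(df, fw$branch_out_dims[[b]])
      layers <- model$branches[[b]]
      last_conv <- max(which(vapply(layers, function(l) l$type == "conv",
                                    logical(1))))
      for (i in rev(seq_along(layers))) {
        lay <- layers[[i]]
        if (lay$type == "pool") {
          dx <- pool_backward(lay, fw$branch_caches[[b]][[i]], dx)
        } else {
          if (b == act_grad_branch && i == last_conv && is.null(act_grad))
            act_grad <- dx
          if (!backbone_trainable && !is.null(act_grad)) break
          g <- conv_backward(lay, fw$branch_caches[[b]][[i]], dx,
                             need_input_grad = i > 1L)
          grads[[paste0("branch", b, "_", i)]] <- g[c("dWt", "db")]
          dx <- g$dx
          if (is.null(dx)) break
        }
      }
    }
  }
  list(grads = grads, act_grad = act_grad)
}

# ---- parameter bookkeeping and Adam -----------------------------------------

trainable_keys <- function(model) {
  keys <- paste0("head", seq_along(model$head))
  if (!model$freeze_backbone) {
    for (b in seq_along(model$branches)) {
      conv_idx <- which(vapply(model$branches[[b]],
                               function(l) l$type == "conv", logical(1)))
      keys <- c(keys, paste0("branch", b, "_", conv_idx))
    }
  }
  keys
}

get_layer <- function(model, key) {
  if (startsWith(key, "head")) {
    model$head[[as.integer(sub("head", "", key))]]
  } else {
    p <- strsplit(sub("branch", "", key), "_", fixed = TRUE)[[1L]]
    model$branches[[as.integer(p[1L])]][[as.integer(p[2L])]]
  }
}

# a layer's weight matrix and its gradient, whichever orientation it stores
layer_weight <- function(layer) if (layer$type == "conv") layer$Wt else layer$W
grad_weight <- function(g) if (!is.null(g$dWt)) g$dWt else g$dW

set_layer_weights <- function(model, key, W, b) {
  assign_one <- function(layer) {
    if (layer$type == "conv") layer$Wt <- W else layer$W <- W
    layer$b <- b
    layer
  }
  if (startsWith(key, "head")) {
    i <- as.integer(sub("head", "", key))
    model$head[[i]] <- assign_one(model$head[[i]])
  } else {
    p <- strsplit(sub("branch", "", key), "_", fixed = TRUE)[[1L]]
    bi <- as.integer(p[1L]); li <- as.integer(p[2L])
    model$branches[[bi]][[li]] <- assign_one(model$branches[[bi]][[li]])
  }
  model
}

adam_init <- function(model) {
  st <- list(t = 0L, m = list(), v = list())
  for (k in trainable_keys(model)) {
    W <- layer_weight(get_layer(model, k))
    b <- get_layer(model, k)$b
    st$m[[k]] <- list(W = W * 0, b = b * 0)
    st$v[[k]] <- list(W = W * 0, b = b * 0)
  }
  st
}

adam_step <- function(model, state, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(state$m)) {
    g <- grads[[k]]
    if (is.null(g)) next
    lay <- get_layer(model, k)
    gW <- grad_weight(g)
    state$m[[k]]$W <- beta1 * state$m[[k]]$W + (1 - beta1) * gW
    state$m[[k]]$b <- beta1 * state$m[[k]]$b + (1 - beta1) * g$db
    state$v[[k]]$W <- beta2 * state$v[[k]]$W + (1 - beta2) * gW^2
    state$v[[k]]$b <- beta2 * state$v[[k]]$b + (1 - beta2) * g$db^2
    W <- layer_weight(lay) - lr * (state$m[[k]]$W / bc1) /
      (sqrt(state$v[[k]]$W / bc2) + eps)
    b <- lay$b - lr * (state$m[[k]]$b / bc1) /
      (sqrt(state$v[[k]]$b / bc2) + eps)
    model <- set_layer_weights(model, k, W, b)
  }
  list(model = model, state = state)
}
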