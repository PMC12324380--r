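# Minimal CPU neural-network layers with manual backpropagation.
#
# Activations are column-major arrays (H, W, C, N); kernels (kh, kw, Cin, Cout).
# Convolutions run through compiled im2col + GEMM (src/nn_ops.cpp); everything
# else is vectorized R. All layers are plain lists so models serialize to JSON.

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad_mode = c("same", "down", "valid")) {
  pad_mode <- match.arg(pad_mode)
  if (pad_mode == "same" && k %% 2L == 0L)
    stop("'same' padding requires an odd kernel size")
  structure(list(type = "conv", in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
                 k = as.integer(k), stride = as.integer(stride), pad_mode = pad_mode,
                 w = NULL, b = NULL), class = "nn_layer")
}

nn_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  structure(list(type = "bn", ch = as.integer(ch), momentum = momentum, eps = eps,
                 gamma = rep(1, ch), beta = rep(0, ch),
                 running_mean = rep(0, ch), running_var = rep(1, ch)),
            class = "nn_layer")
}

nn_relu <- function() structure(list(type = "relu"), class = "nn_layer")

nn_pool_adapt <- function(out_side = 6L)
  structure(list(type = "pool_adapt", out_side = as.integer(out_side)), class = "nn_layer")

nn_dense <- function(in_dim, out_dim)
  structure(list(type = "dense", in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
                 W = NULL, b = NULL), class = "nn_layer")

# Basic residual block: conv3x3-bn-relu-conv3x3-bn + identity skip, then relu.
nn_resblock <- function(ch) {
  structure(list(type = "block", ch = as.integer(ch),
                 conv1 = nn_conv(ch, ch, 3L), bn1 = nn_bn(ch),
                 conv2 = nn_conv(ch, ch, 3L), bn2 = nn_bn(ch)),
            class = "nn_layer")
}

# ---- initialization ---------------------------------------------------------

# He (Kaiming) normal initialization, drawing from the current RNG stream.
layer_init <- function(layer) {
  switch(layer$type,
    conv = {
      fan_in <- layer$k^2 * layer$in_ch
      layer$w <- array(stats::rnorm(layer$k^2 * layer$in_ch * layer$out_ch,
                                    sd = sqrt(2 / fan_in)),
                       dim = c(layer$k, layer$k, layer$in_ch, layer$out_ch))
      layer$b <- rep(0, layer$out_ch)
    },
    bn = {
      layer$gamma <- rep(1, layer$ch); layer$beta <- rep(0, layer$ch)
      layer$running_mean <- rep(0, layer$ch); layer$running_var <- rep(1, layer$ch)
    },
    dense = {
      layer$W <- matrix(stats::rnorm(layer$out_dim * layer$in_dim,
                                     sd = sqrt(2 / layer$in_dim)),
                        layer$out_dim, layer$in_dim)
      layer$b <- rep(0, layer$out_dim)
    },
    block = {
      for (nm in c("conv1", "bn1", "conv2", "bn2")) layer[[nm]] <- layer_init(layer[[nm]])
    }
  )
  layer
}

# ---- parameter access -------------------------------------------------------

layer_params <- function(layer) {
  switch(layer$type,
    conv  = list(w = layer$w, b = layer$b),
    bn    = list(gamma = layer$gamma, beta = layer$beta),
    dense = list(W = layer$W, b = layer$b),
    block = {
      out <- list()
      for (nm in c("conv1", "bn1", "conv2", "bn2")) {
        sub <- layer_params(layer[[nm]])
        names(sub) <- paste(nm, names(sub), sep = ".")
        out <- c(out, sub)
      }
      out
    },
    list()
  )
}

layer_set_params <- function(layer, params) {
  switch(layer$type,
    conv  = { layer$w <- params$w; layer$b <- params$b },
    bn    = { layer$gamma <- params$gamma; layer$beta <- params$beta },
    dense = { layer$W <- params$W; layer$b <- params$b },
    block = {
      for (nm in c("conv1", "bn1", "conv2", "bn2")) {
        idx <- startsWith(names(params), paste0(nm, "."))
        sub <- params[idx]
        names(sub) <- sub(paste0("^", nm, "\\."), "", names(sub))
        layer[[nm]] <- layer_set_params(layer[[nm]], sub)
      }
    }
  )
  layer
}

# ---- helpers ----------------------------------------------------------------

.conv_pads <- function(layer, H, W) {
  switch(layer$pad_mode,
    same  = { p <- (layer$k - 1L) %/% 2L; c(p, p, p, p) },
    valid = c(0L, 0L, 0L, 0L),
    # "down": 2x2 stride-2; pad bottom/right when the side is odd so the
    # output side is ceil(side/2) and 1-px inputs survive.
    down  = c(0L, 0L, H %% 2L, W %% 2L)
  )
}

.pool_bins <- function(n_in, n_out) {
  i <- seq_len(n_out) - 1L
  lo <- floor(i * n_in / n_out) + 1L
  hi <- ceiling((i + 1L) * n_in / n_out)
  cbind(lo, hi)
}

# ---- forward ----------------------------------------------------------------

# Returns list(out=, cache=, layer=): bn layers update running stats in training.
layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      pads <- .conv_pads(layer, d[1], d[2])
      r <- nn_conv_fwd_cache(x, d, layer$w, dim(layer$w), layer$b,
                             layer$stride, pads[1], pads[2], pads[3], pads[4])
      list(out = r$out, cache = list(col = r$col, xd = d, pads = pads), layer = layer)
    },
    bn = {
      d <- dim(x)
      if (training) {
        st <- nn_bn_stats(x, d)
        mu <- st$mean; va <- st$var
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
        layer$running_var  <- (1 - layer$momentum) * layer$running_var  + layer$momentum * va
      } else {
        mu <- layer$running_mean; va <- layer$running_var
      }
      istd <- 1 / sqrt(va + layer$eps)
      r <- nn_bn_fwd(x, d, layer$gamma, layer$beta, mu, istd)
      list(out = r$out, cache = list(xhat = r$xhat, istd = istd, training = training),
           layer = layer)
    },
    relu = {
      out <- nn_relu_fwd(x)
      list(out = out, cache = list(out = out), layer = layer)
    },
    pool_adapt = {
      d <- dim(x); S <- layer$out_side
      hb <- .pool_bins(d[1], S); wb <- .pool_bins(d[2], S)
      out <- array(0, c(S, S, d[3], d[4]))
      for (i in seq_len(S)) for (j in seq_len(S)) {
        sub <- x[hb[i, 1]:hb[i, 2], wb[j, 1]:wb[j, 2], , , drop = FALSE]
        out[i, j, , ] <- colMeans(matrix(sub, prod(dim(sub)[1:2]), d[3] * d[4]))
      }
      list(out = out, cache = list(in_dim = d, hb = hb, wb = wb), layer = layer)
    },
    dense = {
      out <- layer$W %*% x + layer$b
      list(out = out, cache = list(x = x), layer = layer)
    },
    block = {
      f1 <- layer_forward(layer$conv1, x, training);  layer$conv1 <- f1$layer
      f2 <- layer_forward(layer$bn1, f1$out, training); layer$bn1 <- f2$layer
      f3 <- layer_forward(nn_relu(), f2$out)
      f4 <- layer_forward(layer$conv2, f3$out, training); layer$conv2 <- f4$layer
      f5 <- layer_forward(layer$bn2, f4$out, training);   layer$bn2 <- f5$layer
      pre <- f5$out + x
      out <- nn_relu_fwd(pre)
      list(out = out,
           cache = list(c1 = f1$cache, c2 = f2$cache, c3 = f3$cache,
                        c4 = f4$cache, c5 = f5$cache, out = out),
           layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- backward ---------------------------------------------------------------

# Returns list(gin=, grads=) with grads named like layer_params().
# need_gin = FALSE skips the input-gradient computation (first layer).
layer_backward <- function(layer, cache, gout, need_gin = TRUE) {
  switch(layer$type,
    conv = {
      pads <- cache$pads
      r <- nn_conv_bwd_cached(cache$col, cache$xd, layer$w, dim(layer$w), gout,
                              layer$stride, pads[1], pads[2], pads[3], pads[4],
                              need_gin)
      list(gin = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    bn = {
      r <- nn_bn_bwd(cache$xhat, dim(cache$xhat), gout, layer$gamma,
                     cache$istd, cache$training)
      list(gin = r$gin, grads = list(gamma = r$ggamma, beta = r$gbeta))
    },
    relu = {
      list(gin = nn_relu_bwd(cache$out, gout), grads = list())
    },
    pool_adapt = {
      d <- cache$in_dim; S <- layer$out_side
      gin <- array(0, d)
      for (i in seq_len(S)) for (j in seq_len(S)) {
        rows <- cache$hb[i, 1]:cache$hb[i, 2]; cols <- cache$wb[j, 1]:cache$wb[j, 2]
        nb <- length(rows) * length(cols)
        g <- array(rep(as.vector(gout[i, j, , ]) / nb, each = nb),
                   c(length(rows), length(cols), d[3], d[4]))
        gin[rows, cols, , ] <- gin[rows, cols, , , drop = FALSE] + g
      }
      list(gin = gin, grads = list())
    },
    dense = {
      list(gin = crossprod(layer$W, gout),
           grads = list(W = tcrossprod(gout, cache$x), b = rowSums(gout)))
    },
    block = {
      gpre <- nn_relu_bwd(cache$out, gout)
      b5 <- layer_backward(layer$bn2, cache$c5, gpre)
      b4 <- layer_backward(layer$conv2, cache$c4, b5$gin)
      b3 <- layer_backward(nn_relu(), cache$c3, b4$gin)
      b2 <- layer_backward(layer$bn1, cache$c2, b3$gin)
      b1 <- layer_backward(layer$conv1, cache$c1, b2$gin)
      gin <- b1$gin + gpre
      grads <- c(stats::setNames(b1$grads, paste0("conv1.", names(b1$grads))),
                 stats::setNames(b2$grads, paste0("bn1.", names(b2$grads))),
                 stats::setNames(b4$grads, paste0("conv2.", names(b4$grads))),
                 stats::setNames(b5$grads, paste0("bn2.", names(b5$grads))))
      list(gin = gin, grads = grads)
    },
    stop("unknown layer type: ", layer$type)
  )
}
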