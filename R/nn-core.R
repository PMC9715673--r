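# Minimal CNN engine: column-major (H, W, C) feature maps, per-sample
# forward/backward, Adadelta/Adam. Convolutions go through im2col (C++) and
# BLAS; everything else is plain R. This is deliberately small: the package
# needs full control of every layer for relevance propagation, not speed
# records.

he_init <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))

layer_conv <- function(kh, kw, in_ch, out_ch, stride = 1L, pad = 0L) {
  fan_in <- kh * kw * in_ch
  list(type = "conv",
       W = matrix(he_init(fan_in * out_ch, fan_in), fan_in, out_ch),
       b = numeric(out_ch),
       kh = as.integer(kh), kw = as.integer(kw),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       stride = as.integer(stride), pad = as.integer(pad))
}

layer_bn <- function(ch, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, ch), beta = numeric(ch),
       mean = numeric(ch), var = rep(1, ch), ch = as.integer(ch), eps = eps)
}

layer_relu <- function() list(type = "relu")

layer_pool <- function(mode = c("max", "avg"), kh = 2L, kw = 2L,
                       stride = 2L, pad = 0L) {
  list(type = "pool", mode = match.arg(mode),
       kh = as.integer(kh), kw = as.integer(kw),
       stride = as.integer(stride), pad = as.integer(pad))
}

layer_gap <- function() list(type = "gap")

# Parameter-free per-sample standardisation of the pooled embedding
# (layer-norm without affine). Keeps the classifier head well-conditioned in
# the absence of batch normalisation.
layer_featnorm <- function(eps = 1e-6) list(type = "featnorm", eps = eps)

# Instance normalisation (per-sample, per-channel spatial standardisation,
# no affine). The small-batch-friendly substitute for batch normalisation
# that keeps every forward pass a pure per-sample function.
layer_instnorm <- function(eps = 1e-5) list(type = "instnorm", eps = eps)

# Batch normalisation driven by exponential-moving-average statistics: every
# forward pass normalises with the current running per-channel mean/variance
# (global statistics, as at inference time), and the training loop updates
# the running statistics from each sample's batch statistics. This keeps the
# engine strictly per-sample while retaining the optimisation benefits and
# the attribution-friendly global-statistics normalisation of conventional
# batch norm.
layer_ebn <- function(ch, momentum = 0.01, eps = 1e-5) {
  list(type = "ebn", gamma = rep(1, ch), beta = numeric(ch),
       rmean = numeric(ch), rvar = rep(1, ch), ch = as.integer(ch),
       momentum = momentum, eps = eps)
}

# Fixed positive gain on the pooled embedding. Counters the magnitude
# attenuation of deep random-init stacks so the sigmoid head trains at a
# usable rate; a positive scalar scale is transparent to relevance
# propagation.
layer_scale <- function(g) list(type = "scale", g = g)

layer_dense <- function(in_dim, out_dim) {
  list(type = "dense",
       W = matrix(he_init(in_dim * out_dim, in_dim), in_dim, out_dim),
       b = numeric(out_dim), in_dim = as.integer(in_dim),
       out_dim = as.integer(out_dim))
}

# Densely connected unit: run `sub` on the incoming stack and append its
# output along the channel axis (column-major (H, W, C) makes the
# concatenation a plain c()).
layer_dense_unit <- function(sub, growth) {
  list(type = "dense_unit", sub = sub, growth = as.integer(growth))
}

layer_out_shape <- function(layer, s) {
  switch(layer$type,
    conv = {
      oh <- (s[1] + 2L * layer$pad - layer$kh) %/% layer$stride + 1L
      ow <- (s[2] + 2L * layer$pad - layer$kw) %/% layer$stride + 1L
      c(oh, ow, layer$out_ch)
    },
    pool = {
      oh <- (s[1] + 2L * layer$pad - layer$kh) %/% layer$stride + 1L
      ow <- (s[2] + 2L * layer$pad - layer$kw) %/% layer$stride + 1L
      c(oh, ow, s[3])
    },
    gap = s[3],
    featnorm = s,
    instnorm = s,
    scale = s,
    ebn = s,
    dense = layer$out_dim,
    dense_unit = c(s[1], s[2], s[3] + layer$growth),
    s)
}

seq_out_shapes <- function(layers, in_shape) {
  shapes <- vector("list", length(layers))
  s <- in_shape
  for (i in seq_along(layers)) {
    s <- layer_out_shape(layers[[i]], s)
    shapes[[i]] <- s
  }
  shapes
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      cols <- cpp_im2col(x, d[1], d[2], d[3], layer$kh, layer$kw,
                         layer$stride, layer$pad)
      y <- cols %*% layer$W
      y <- sweep(y, 2L, layer$b, "+")
      os <- layer_out_shape(layer, d)
      list(y = array(y, os), cache = list(cols = cols, dim = d))
    },
    bn = {
      sc <- layer$gamma / sqrt(layer$var + layer$eps)
      sh <- layer$beta - layer$mean * sc
      d <- dim(x)
      xm <- matrix(x, prod(d[1:2]), d[3])
      xhat <- sweep(sweep(xm, 2L, sqrt(layer$var + layer$eps), "/"),
                    2L, layer$mean / sqrt(layer$var + layer$eps), "-")
      y <- sweep(sweep(xm, 2L, sc, "*"), 2L, sh, "+")
      list(y = array(y, d), cache = list(xhat = xhat, sc = sc, dim = d))
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask))
    },
    scale = list(y = layer$g * x, cache = NULL),
    pool = {
      d <- dim(x)
      r <- cpp_pool_fwd(x, d[1], d[2], d[3], layer$kh, layer$kw,
                        layer$stride, layer$pad, layer$mode == "max")
      list(y = r$y, cache = list(idx = r$idx, dim = d, x = x, y = r$y))
    },
    gap = {
      d <- dim(x)
      list(y = colMeans(matrix(x, prod(d[1:2]), d[3])),
           cache = list(dim = d, x = x))
    },
    featnorm = {
      x <- as.numeric(x)
      mu <- mean(x)
      sg <- sqrt(mean((x - mu)^2) + layer$eps)
      y <- (x - mu) / sg
      list(y = y, cache = list(y = y, sg = sg))
    },
    instnorm = {
      d <- dim(x)
      p <- prod(d[1:2])
      xm <- matrix(x, p, d[3])
      mu <- colMeans(xm)
      sg <- sqrt(colMeans(xm^2) - mu^2 + layer$eps)
      ym <- sweep(sweep(xm, 2L, mu, "-"), 2L, sg, "/")
      list(y = array(ym, d), cache = list(ym = ym, sg = sg, dim = d))
    },
    ebn = {
      d <- dim(x)
      p <- prod(d[1:2])
      xm <- matrix(x, p, d[3])
      isd <- 1 / sqrt(layer$rvar + layer$eps)
      xhat <- sweep(sweep(xm, 2L, layer$rmean, "-"), 2L, isd, "*")
      y <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
      bmean <- colMeans(xm)
      list(y = array(y, d),
           cache = list(xhat = xhat, sc = layer$gamma * isd, dim = d,
                        bmean = bmean, bvar = colMeans(xm^2) - bmean^2))
    },
    dense = {
      list(y = drop(crossprod(layer$W, as.numeric(x))) + layer$b,
           cache = list(x = as.numeric(x)))
    },
    dense_unit = {
      h <- x
      caches <- vector("list", length(layer$sub))
      for (i in seq_along(layer$sub)) {
        r <- layer_forward(layer$sub[[i]], h)
        caches[[i]] <- r$cache
        h <- r$y
      }
      d <- dim(x)
      list(y = array(c(x, h), c(d[1], d[2], d[3] + layer$growth)),
           cache = list(sub = caches, in_ch = d[3], dim = d))
    },
    stop_config("unknown layer type '%s'", layer$type))
}

# Returns list(gx = gradient w.r.t. input, grads = parameter gradients in the
# same shape as layer_params()).
layer_backward <- function(layer, cache, gy) {
  switch(layer$type,
    conv = {
      os <- layer_out_shape(layer, cache$dim)
      gym <- matrix(gy, prod(os[1:2]), os[3])
      gW <- crossprod(cache$cols, gym)
      gb <- colSums(gym)
      gcols <- gym %*% t(layer$W)
      gx <- cpp_col2im(gcols, cache$dim[1], cache$dim[2], cache$dim[3],
                       layer$kh, layer$kw, layer$stride, layer$pad)
      list(gx = gx, grads = list(W = gW, b = gb))
    },
    bn = {
      d <- cache$dim
      gym <- matrix(gy, prod(d[1:2]), d[3])
      list(gx = array(sweep(gym, 2L, cache$sc, "*"), d),
           grads = list(gamma = colSums(gym * cache$xhat),
                        beta = colSums(gym)))
    },
    relu = list(gx = gy * cache$mask, grads = NULL),
    scale = list(gx = layer$g * gy, grads = NULL),
    pool = {
      d <- cache$dim
      gx <- if (layer$mode == "max")
        cpp_maxpool_bwd(gy, cache$idx, d[1], d[2], d[3])
      else
        cpp_avgpool_bwd(gy, d[1], d[2], d[3], layer$kh, layer$kw,
                        layer$stride, layer$pad)
      list(gx = gx, grads = NULL)
    },
    gap = {
      d <- cache$dim
      p <- prod(d[1:2])
      list(gx = array(rep(gy / p, each = p), d), grads = NULL)
    },
    featnorm = {
      gy <- as.numeric(gy)
      y <- cache$y
      list(gx = (gy - mean(gy) - y * mean(gy * y)) / cache$sg, grads = NULL)
    },
    instnorm = {
      d <- cache$dim
      p <- prod(d[1:2])
      gym <- matrix(gy, p, d[3])
      ym <- cache$ym
      gxm <- sweep(gym, 2L, colMeans(gym), "-") -
        ym * rep(colMeans(gym * ym), each = p)
      list(gx = array(sweep(gxm, 2L, cache$sg, "/"), d), grads = NULL)
    },
    ebn = {
      d <- cache$dim
      gym <- matrix(gy, prod(d[1:2]), d[3])
      list(gx = array(sweep(gym, 2L, cache$sc, "*"), d),
           grads = list(gamma = colSums(gym * cache$xhat),
                        beta = colSums(gym)))
    },
    dense = {
      gy <- as.numeric(gy)
      list(gx = drop(layer$W %*% gy),
           grads = list(W = outer(cache$x, gy), b = gy))
    },
    dense_unit = {
      d <- cache$dim
      n_in <- prod(d[1:2]) * cache$in_ch
      gx_direct <- array(gy[seq_len(n_in)], d)
      gh <- array(gy[-seq_len(n_in)], c(d[1], d[2], layer$growth))
      grads <- vector("list", length(layer$sub))
      for (i in rev(seq_along(layer$sub))) {
        r <- layer_backward(layer$sub[[i]], cache$sub[[i]], gh)
        grads[i] <- list(r$grads)
        gh <- r$gx
      }
      list(gx = gx_direct + gh, grads = list(sub = grads))
    })
}

layer_params <- function(layer) {
  switch(layer$type,
    conv = list(W = layer$W, b = layer$b),
    bn = list(gamma = layer$gamma, beta = layer$beta),
    ebn = list(gamma = layer$gamma, beta = layer$beta),
    dense = list(W = layer$W, b = layer$b),
    dense_unit = list(sub = lapply(layer$sub, layer_params)),
    NULL)
}

layer_set_params <- function(layer, p) {
  switch(layer$type,
    conv = { layer$W <- p$W; layer$b <- p$b },
    bn = { layer$gamma <- p$gamma; layer$beta <- p$beta },
    ebn = { layer$gamma <- p$gamma; layer$beta <- p$beta },
    dense = { layer$W <- p$W; layer$b <- p$b },
    dense_unit = {
      for (i in seq_along(layer$sub))
        layer$sub[[i]] <- layer_set_params(layer$sub[[i]], p$sub[[i]])
    },
    NULL)
  layer
}

# Fold each sample's batch statistics into the running EMA statistics of
# every ebn layer (training-time side effect, applied by the train loop).
layer_update_stats <- function(layer, cache) {
  if (layer$type == "ebn") {
    m <- layer$momentum
    layer$rmean <- (1 - m) * layer$rmean + m * cache$bmean
    layer$rvar <- (1 - m) * layer$rvar + m * cache$bvar
  } else if (layer$type == "dense_unit") {
    for (i in seq_along(layer$sub))
      layer$sub[[i]] <- layer_update_stats(layer$sub[[i]], cache$sub[[i]])
  }
  layer
}

model_update_stats <- function(model, caches) {
  for (i in seq_along(caches)) {
    if (is.null(caches[[i]])) next
    model$layers[[i]] <- layer_update_stats(model$layers[[i]], caches[[i]])
  }
  model
}

# ---- parameter trees -------------------------------------------------------

tree_leaves_apply <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  if (is.null(a)) return(NULL)
  out <- a
  for (i in seq_along(a))
    out[i] <- list(tree_leaves_apply(a[[i]], b[[i]], f))
  out
}

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  tree_leaves_apply(a, b, `+`)
}

tree_zero <- function(a) tree_leaves_apply(a, a, function(x, y) x * 0)

# ---- optimizers ------------------------------------------------------------

make_optimizer <- function(name, learning_rate = 1e-4) {
  name <- match.arg(name, c("adadelta", "adam"))
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$scale <- 1
  if (name == "adadelta") {
    rho <- 0.95; eps <- 1e-6
    step <- function(params, grads) {
      if (is.null(st$Eg)) { st$Eg <- tree_zero(params); st$Ed <- tree_zero(params) }
      st$Eg <- tree_leaves_apply(st$Eg, grads,
                                 function(e, g) rho * e + (1 - rho) * g * g)
      # delta = - sqrt(Ed + eps)/sqrt(Eg + eps) * g, then accumulate Ed
      walk <- function(ed, eg, g) {
        if (is.numeric(g)) return(-st$scale * sqrt(ed + eps) / sqrt(eg + eps) * g)
        if (is.null(g)) return(NULL)
        out <- g
        for (i in seq_along(g)) out[i] <- list(walk(ed[[i]], eg[[i]], g[[i]]))
        out
      }
      delta <- walk(st$Ed, st$Eg, grads)
      st$Ed <- tree_leaves_apply(st$Ed, delta,
                                 function(e, d) rho * e + (1 - rho) * d * d)
      tree_leaves_apply(params, delta, `+`)
    }
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- learning_rate
    step <- function(params, grads) {
      if (is.null(st$m)) { st$m <- tree_zero(params); st$v <- tree_zero(params) }
      st$t <- st$t + 1L
      st$m <- tree_leaves_apply(st$m, grads, function(m, g) b1 * m + (1 - b1) * g)
      st$v <- tree_leaves_apply(st$v, grads, function(v, g) b2 * v + (1 - b2) * g * g)
      corr <- st$scale * lr * sqrt(1 - b2^st$t) / (1 - b1^st$t)
      walk <- function(p, m, v) {
        if (is.numeric(p)) return(p - corr * m / (sqrt(v) + eps))
        if (is.null(p)) return(NULL)
        out <- p
        for (i in seq_along(p)) out[i] <- list(walk(p[[i]], m[[i]], v[[i]]))
        out
      }
      walk(params, st$m, st$v)
    }
  }
  list(name = name, step = step, state = st)
}

row_softmax <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}
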