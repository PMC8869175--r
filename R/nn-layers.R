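# Minimal reverse-mode layer framework.
#
# A layer is a list(kind, par = list(<numeric arrays>), ...state). Feature
# maps travel as (H, W, C, N) arrays; vector features as N x F matrices.
# layer_forward() returns list(y, cache, layer) — `layer` comes back so
# batch-norm can update its running moments. layer_backward() returns
# list(gx, grads) with `grads` mirroring the structure of `par`.

layer_dense <- function(n_in, n_out, init_sd = sqrt(2 / n_in)) {
  list(kind = "dense",
       par = list(W = matrix(rnorm(n_in * n_out, 0, init_sd), n_in, n_out),
                  b = numeric(n_out)))
}

layer_embed <- function(n_classes, dim, init_sd = 0.05) {
  list(kind = "embed",
       par = list(E = matrix(rnorm(n_classes * dim, 0, init_sd), n_classes, dim)))
}

layer_conv <- function(kh, kw, c_in, c_out, pad = (kh - 1L) %/% 2L,
                       init_sd = sqrt(2 / (kh * kw * c_in))) {
  list(kind = "conv", pad = as.integer(pad),
       par = list(w = array(rnorm(kh * kw * c_in * c_out, 0, init_sd),
                            c(kh, kw, c_in, c_out)),
                  b = numeric(c_out)))
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(kind = "bn", momentum = momentum, eps = eps,
       run_mean = numeric(c), run_var = rep(1, c),
       par = list(gamma = rep(1, c), beta = numeric(c)))
}

layer_ln <- function(c, eps = 1e-5) {
  list(kind = "ln", eps = eps, par = list(g = rep(1, c), b = numeric(c)))
}

layer_simple <- function(kind) list(kind = kind, par = list())

layer_forward <- function(layer, x, training = TRUE) {
  switch(layer$kind,
    dense = {
      y <- x %*% layer$par$W
      y <- sweep(y, 2, layer$par$b, `+`)
      list(y = y, cache = list(x = x), layer = layer)
    },
    embed = {
      y <- layer$par$E[x + 1L, , drop = FALSE]
      list(y = y, cache = list(labels = x), layer = layer)
    },
    conv = {
      y <- cs_conv2d_fwd(x, layer$par$w, layer$par$b, layer$pad)
      list(y = y, cache = list(x = x), layer = layer)
    },
    relu = {
      y <- pmax(x, 0)
      list(y = y, cache = list(mask = x > 0), layer = layer)
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = list(y = y), layer = layer)
    },
    up2 = list(y = cs_upsample2_fwd(x), cache = NULL, layer = layer),
    pool2 = list(y = cs_avgpool2_fwd(x), cache = NULL, layer = layer),
    gsp = {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2], d[3] * d[4])
      y <- matrix(colSums(xm), d[3], d[4])  # C x N
      list(y = t(y), cache = list(d = d), layer = layer)
    },
    bn = bn_forward(layer, x, training),
    ln = ln_forward(layer, x),
    stop_input(paste0("unknown layer kind: ", layer$kind), "cytosynth_config_error")
  )
}

layer_backward <- function(layer, cache, gy) {
  switch(layer$kind,
    dense = list(gx = gy %*% t(layer$par$W),
                 grads = list(W = crossprod(cache$x, gy), b = colSums(gy))),
    embed = {
      gE <- matrix(0, nrow(layer$par$E), ncol(layer$par$E))
      idx <- cache$labels + 1L
      for (i in seq_along(idx)) gE[idx[i], ] <- gE[idx[i], ] + gy[i, ]
      list(gx = NULL, grads = list(E = gE))
    },
    conv = {
      out <- cs_conv2d_bwd(cache$x, layer$par$w, gy, layer$pad)
      list(gx = out$gx, grads = list(w = out$gw, b = out$gb))
    },
    relu = list(gx = gy * cache$mask, grads = list()),
    tanh = list(gx = gy * (1 - cache$y^2), grads = list()),
    up2 = list(gx = cs_upsample2_bwd(gy), grads = list()),
    pool2 = list(gx = cs_avgpool2_bwd(gy), grads = list()),
    gsp = {
      d <- cache$d
      gx <- array(rep(as.numeric(t(gy)), each = d[1] * d[2]), d)
      list(gx = gx, grads = list())
    },
    bn = bn_backward(layer, cache, gy),
    ln = ln_backward(layer, cache, gy)
  )
}

# --- batch normalization over (H, W, N) per channel ------------------------

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  xp <- aperm(x, c(1, 2, 4, 3))          # H, W, N, C
  xm <- matrix(xp, d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, `*`)
  ym <- sweep(sweep(xhat, 2, layer$par$gamma, `*`), 2, layer$par$beta, `+`)
  y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, inv = inv, d = d, training = training),
       layer = layer)
}

bn_backward <- function(layer, cache, gy) {
  d <- cache$d
  gym <- matrix(aperm(gy, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  xhat <- cache$xhat
  dgamma <- colSums(gym * xhat)
  dbeta <- colSums(gym)
  m <- nrow(gym)
  dxhat <- sweep(gym, 2, layer$par$gamma, `*`)
  if (cache$training) {
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
    gxm <- sweep(t1 - t2, 2, cache$inv, `*`)
  } else {
    gxm <- sweep(dxhat, 2, cache$inv, `*`)
  }
  gx <- aperm(array(gxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(gx = gx, grads = list(gamma = dgamma, beta = dbeta))
}

# --- layer normalization per sample over (H, W, C), per-channel affine -----

ln_forward <- function(layer, x) {
  d <- dim(x)
  f <- d[1] * d[2] * d[3]
  xm <- matrix(x, f, d[4])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, `*`)
  gvec <- rep(layer$par$g, each = d[1] * d[2])
  bvec <- rep(layer$par$b, each = d[1] * d[2])
  ym <- xhat * gvec + bvec
  list(y = array(ym, d), cache = list(xhat = xhat, inv = inv, d = d, gvec = gvec),
       layer = layer)
}

ln_backward <- function(layer, cache, gy) {
  d <- cache$d
  f <- d[1] * d[2] * d[3]
  gym <- matrix(gy, f, d[4])
  xhat <- cache$xhat
  hw <- d[1] * d[2]
  grp <- rep(seq_len(d[3]), each = hw)
  dg <- rowsum(rowSums(gym * xhat), grp)[, 1]
  db <- rowsum(rowSums(gym), grp)[, 1]
  dxhat <- gym * cache$gvec
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
  gxm <- sweep(t1 - t2, 2, cache$inv, `*`)
  list(gx = array(gxm, d), grads = list(g = dg, b = db))
}

# --- sequential composition ------------------------------------------------

seq_forward <- function(layers, x, training = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    step <- layer_forward(layers[[i]], x, training)
    x <- step$y
    caches[[i]] <- step$cache
    layers[[i]] <- step$layer
  }
  list(y = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    out <- layer_backward(layers[[i]], caches[[i]], gy)
    gy <- out$gx
    grads[[i]] <- out$grads
  }
  list(gx = gy, grads = grads)
}
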