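# Finite-difference verification of the hand-written backward passes.

fd_grad <- function(f, x, idx = seq_along(x), eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

test_that("convolution backward matches finite differences", {
  ns <- asNamespace("cytosynth")
  set.seed(41)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3) * 0.1
  mask <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  bw <- ns$cs_conv2d_bwd(x, w, mask, 1L)

  idx <- sample(length(x), 20)
  fd <- fd_grad(function(z) sum(ns$cs_conv2d_fwd(z, w, b, 1L) * mask), x, idx)
  expect_lt(rel_err(bw$gx[idx], fd), 1e-6)

  idxw <- sample(length(w), 20)
  fdw <- fd_grad(function(z) {
    sum(ns$cs_conv2d_fwd(x, array(z, dim(w)), b, 1L) * mask)
  }, w, idxw)
  expect_lt(rel_err(bw$gw[idxw], fdw), 1e-6)

  fdb <- fd_grad(function(z) sum(ns$cs_conv2d_fwd(x, w, z, 1L) * mask), b)
  expect_lt(rel_err(bw$gb, fdb), 1e-6)
})

test_that("pooling and upsampling backward match finite differences", {
  ns <- asNamespace("cytosynth")
  set.seed(42)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  mk <- array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  fd <- fd_grad(function(z) sum(ns$cs_avgpool2_fwd(z) * mk), x)
  expect_lt(rel_err(as.numeric(ns$cs_avgpool2_bwd(mk)), fd), 1e-6)

  mku <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  fdu <- fd_grad(function(z) sum(ns$cs_upsample2_fwd(z) * mku), x)
  expect_lt(rel_err(as.numeric(ns$cs_upsample2_bwd(mku)), fdu), 1e-6)
})

test_that("batch- and layer-normalization backward match finite differences", {
  ns <- asNamespace("cytosynth")
  set.seed(43)
  x <- array(rnorm(4 * 4 * 3 * 5), c(4, 4, 3, 5))
  mask <- array(rnorm(4 * 4 * 3 * 5), c(4, 4, 3, 5))

  bn <- ns$layer_bn(3)
  fwd <- ns$bn_forward(bn, x, training = TRUE)
  bwd <- ns$bn_backward(bn, fwd$cache, mask)
  idx <- sample(length(x), 25)
  fd <- fd_grad(function(z) {
    sum(ns$bn_forward(bn, array(z, dim(x)), training = TRUE)$y * mask)
  }, x, idx)
  expect_lt(rel_err(bwd$gx[idx], fd), 1e-5)
  fdg <- fd_grad(function(g) {
    l <- bn; l$par$gamma <- g
    sum(ns$bn_forward(l, x, training = TRUE)$y * mask)
  }, bn$par$gamma)
  expect_lt(rel_err(bwd$grads$gamma, fdg), 1e-6)

  ln <- ns$layer_ln(3)
  fwl <- ns$ln_forward(ln, x)
  bwl <- ns$ln_backward(ln, fwl$cache, mask)
  fdl <- fd_grad(function(z) {
    sum(ns$ln_forward(ln, array(z, dim(x)))$y * mask)
  }, x, idx)
  expect_lt(rel_err(bwl$gx[idx], fdl), 1e-5)
})

test_that("full generator and critic backward passes match finite differences", {
  ns <- asNamespace("cytosynth")
  cfg <- gan_config(n_classes = 3, image_size = 16, base_channels = 6,
                    noise_dim = 8)
  set.seed(44)
  gen <- build_generator(cfg)
  critic <- build_critic(cfg)
  n <- 2
  z <- matrix(rnorm(n * cfg$noise_dim), n)
  labels <- c(0L, 2L)
  x <- array(tanh(rnorm(16 * 16 * 3 * n)), c(16, 16, 3, n))
  eps <- 1e-5

  # critic: input gradient and two weight blocks, scalar loss mixing both heads
  ds <- c(1, -0.5)
  dl <- matrix(seq_len(3 * n) / 10, n, 3)
  loss_c <- function(net, xx) {
    fw <- ns$critic_forward(net, xx)
    sum(fw$source * ds) + sum(fw$logits * dl)
  }
  fw <- ns$critic_forward(critic, x)
  bw <- ns$critic_backward(critic, fw$cache, d_source = ds, d_logits = dl)
  idx <- sample(length(x), 20)
  fd <- fd_grad(function(z2) loss_c(critic, array(z2, dim(x))), x, idx)
  expect_lt(rel_err(bw$gx[idx], fd), 1e-5)

  w0 <- critic$conv_in$par$w
  idxw <- sample(length(w0), 15)
  fdw <- fd_grad(function(wv) {
    net <- critic; net$conv_in$par$w <- array(wv, dim(w0))
    loss_c(net, x)
  }, w0, idxw)
  expect_lt(rel_err(bw$grads$conv_in$w[idxw], fdw), 1e-5)

  # generator: two weight blocks through the full forward pass
  mask <- array(rnorm(16 * 16 * 3 * n), c(16, 16, 3, n))
  loss_g <- function(net) {
    sum(ns$generator_forward(net, z, labels, training = FALSE)$y * mask)
  }
  gfw <- ns$generator_forward(gen, z, labels, training = FALSE)
  gbw <- ns$generator_backward(gfw$gen, gfw$cache, mask)

  wz <- gen$dense_z$par$W
  idxz <- sample(length(wz), 15)
  fdz <- fd_grad(function(wv) {
    net <- gen; net$dense_z$par$W <- matrix(wv, nrow(wz))
    loss_g(net)
  }, wz, idxz)
  expect_lt(rel_err(gbw$grads$dense_z$W[idxz], fdz), 1e-5)

  we <- gen$embed$par$E
  fde <- fd_grad(function(wv) {
    net <- gen; net$embed$par$E <- matrix(wv, nrow(we))
    loss_g(net)
  }, we, seq_along(we))
  expect_lt(rel_err(as.numeric(gbw$grads$embed$E), fde), 1e-5)
})

test_that("gradient-penalty weight gradients match finite differences of the penalty", {
  ns <- asNamespace("cytosynth")
  cfg <- gan_config(n_classes = 3, image_size = 16, base_channels = 4,
                    noise_dim = 8)
  set.seed(45)
  critic <- build_critic(cfg)
  n <- 2
  x_nn <- array(tanh(rnorm(16 * 16 * 3 * n)), c(16, 16, 3, n))
  res <- ns$gp_value_and_grads(critic, x_nn, sigma = 10, eps_fd = 1e-3)
  expect_equal(res$value,
               gradient_penalty(critic, cytosynth:::from_nn(x_nn), sigma = 10))

  w0 <- critic$conv_in$par$w
  idx <- sample(length(w0), 10)
  fd <- fd_grad(function(wv) {
    net <- critic; net$conv_in$par$w <- array(wv, dim(w0))
    gradient_penalty(net, cytosynth:::from_nn(x_nn), sigma = 10)
  }, w0, idx, eps = 1e-4)
  expect_lt(rel_err(res$grads$conv_in$w[idx], fd), 1e-4)
})
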