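#' GAN architecture configuration
#'
#' The generator maps a standard-normal noise vector plus a class label to
#' an RGB image in `[-1, 1]` through a stack of residual upsampling blocks;
#' the critic mirrors it with residual downsampling blocks and two linear
#' heads (an unbounded Wasserstein source score and class logits). Spatial
#' resolution starts/ends at 4x4, so `image_size` must be `4 * 2^k`.
#'
#' @param n_classes Number of cell-type classes (at least 2).
#' @param image_size Output side in pixels, a power of two at least 16.
#' @param noise_dim Dimension of the latent noise vector.
#' @param base_channels Channel width of the residual trunk.
#' @param embed_dim Width of the learned class embedding (defaults to
#'   `noise_dim`).
#' @return A `gan_config` list with the derived `n_resblocks`.
#' @export
gan_config <- function(n_classes, image_size = 128, noise_dim = 128,
                       base_channels = 64, embed_dim = noise_dim) {
  if (n_classes < 2) stop_input("n_classes must be >= 2", "cytosynth_config_error")
  n_res <- log2(image_size / 4)
  if (image_size < 16 || n_res != round(n_res)) {
    stop_input("image_size must be a power of two >= 16", "cytosynth_config_error")
  }
  structure(list(n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 noise_dim = as.integer(noise_dim),
                 base_channels = as.integer(base_channels),
                 embed_dim = as.integer(embed_dim),
                 n_resblocks = as.integer(n_res)),
            class = "gan_config")
}

#' @export
print.gan_config <- function(x, ...) {
  cat(sprintf("<gan_config> %dpx, %d classes, noise %d, %d channels, %d resblocks\n",
              x$image_size, x$n_classes, x$noise_dim, x$base_channels, x$n_resblocks))
  invisible(x)
}

#' Residual upsampling / downsampling blocks
#'
#' Pre-activation residual blocks: the up block doubles height and width
#' (nearest-neighbour upsample before the first 3x3 convolution, batch
#' normalization on the residual branch); the down block halves them
#' (average pooling after the second convolution, layer normalization — the
#' critic must not couple samples through batch statistics or the gradient
#' penalty is ill-defined). The skip path is resized the same way and
#' projected with a 1x1 convolution so the addition is well-formed.
#'
#' @param in_ch,out_ch Input/output channel counts.
#' @return A residual block object; apply it with [apply_block()].
#' @export
residual_up_block <- function(in_ch, out_ch) {
  list(kind = "block", direction = "up",
       main = list(layer_bn(in_ch), layer_simple("relu"), layer_simple("up2"),
                   layer_conv(3, 3, in_ch, out_ch), layer_bn(out_ch),
                   layer_simple("relu"), layer_conv(3, 3, out_ch, out_ch)),
       skip = list(layer_simple("up2"), layer_conv(1, 1, in_ch, out_ch, pad = 0L)))
}

#' @rdname residual_up_block
#' @export
residual_down_block <- function(in_ch, out_ch) {
  list(kind = "block", direction = "down",
       main = list(layer_ln(in_ch), layer_simple("relu"),
                   layer_conv(3, 3, in_ch, out_ch), layer_ln(out_ch),
                   layer_simple("relu"), layer_conv(3, 3, out_ch, out_ch),
                   layer_simple("pool2")),
       skip = list(layer_simple("pool2"), layer_conv(1, 1, in_ch, out_ch, pad = 0L)))
}

#' Apply a residual block to a feature map
#'
#' @param block A [residual_up_block()] or [residual_down_block()].
#' @param x Feature map array (h, w, c, n).
#' @param training Use batch statistics (generator blocks) when `TRUE`.
#' @return The transformed feature map (2x or 1/2x spatial size).
#' @export
apply_block <- function(block, x, training = TRUE) {
  block_forward(block, x, training)$y
}

block_forward <- function(block, x, training = TRUE) {
  d <- dim(x)
  if (block$direction == "down" && (d[1] %% 2 != 0 || d[2] %% 2 != 0)) {
    stop_input("down block requires even spatial size", "cytosynth_shape_error")
  }
  mf <- seq_forward(block$main, x, training)
  sf <- seq_forward(block$skip, x, training)
  block$main <- mf$layers
  block$skip <- sf$layers
  list(y = mf$y + sf$y, cache = list(main = mf$caches, skip = sf$caches),
       block = block)
}

block_backward <- function(block, cache, gy) {
  mb <- seq_backward(block$main, cache$main, gy)
  sb <- seq_backward(block$skip, cache$skip, gy)
  list(gx = mb$gx + sb$gx, grads = list(main = mb$grads, skip = sb$grads))
}

# --- generator -------------------------------------------------------------

#' Build the conditional generator
#'
#' Noise and class label each pass through their own projection (a dense
#' layer for the noise; a learned embedding plus dense layer for the label),
#' are reshaped to 4x4 feature maps and concatenated channel-wise, then run
#' through `n_resblocks` residual upsampling blocks, batch normalization,
#' and a final 3x3 convolution with tanh activation, giving images in
#' `[-1, 1]`.
#'
#' @param cfg A [gan_config()].
#' @return A generator object (S3 class `cyto_generator`).
#' @seealso [generate_images()], [build_critic()]
#' @export
build_generator <- function(cfg) {
  stopifnot(inherits(cfg, "gan_config"))
  cz <- cfg$base_channels
  ce <- max(4L, cfg$base_channels %/% 4L)
  blocks <- vector("list", cfg$n_resblocks)
  in_ch <- cz + ce
  for (i in seq_len(cfg$n_resblocks)) {
    blocks[[i]] <- residual_up_block(in_ch, cfg$base_channels)
    in_ch <- cfg$base_channels
  }
  structure(list(cfg = cfg, cz = cz, ce = ce,
                 dense_z = layer_dense(cfg$noise_dim, 16L * cz),
                 embed = layer_embed(cfg$n_classes, cfg$embed_dim),
                 dense_e = layer_dense(cfg$embed_dim, 16L * ce),
                 blocks = blocks,
                 bn_out = layer_bn(cfg$base_channels),
                 conv_out = layer_conv(3, 3, cfg$base_channels, 3L)),
            class = "cyto_generator")
}

#' @export
print.cyto_generator <- function(x, ...) {
  cat(sprintf("<cyto_generator> %dpx, %d classes\n", x$cfg$image_size, x$cfg$n_classes))
  invisible(x)
}

check_labels <- function(labels, n_classes) {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= n_classes)) {
    stop_input(sprintf("labels must lie in [0, %d)", n_classes), "cytosynth_label_error")
  }
  labels
}

# forward pass with caches; x layouts are internal (h, w, c, n)
generator_forward <- function(gen, z, labels, training = TRUE) {
  labels <- check_labels(labels, gen$cfg$n_classes)
  n <- nrow(z)
  fz <- layer_forward(gen$dense_z, z, training); gen$dense_z <- fz$layer
  xz <- array(t(fz$y), c(4L, 4L, gen$cz, n))
  fe1 <- layer_forward(gen$embed, labels, training); gen$embed <- fe1$layer
  fe2 <- layer_forward(gen$dense_e, fe1$y, training); gen$dense_e <- fe2$layer
  xe <- array(t(fe2$y), c(4L, 4L, gen$ce, n))
  x <- array(0, c(4L, 4L, gen$cz + gen$ce, n))
  x[, , seq_len(gen$cz), ] <- xz
  x[, , gen$cz + seq_len(gen$ce), ] <- xe
  bcaches <- vector("list", length(gen$blocks))
  for (i in seq_along(gen$blocks)) {
    bf <- block_forward(gen$blocks[[i]], x, training)
    x <- bf$y
    bcaches[[i]] <- bf$cache
    gen$blocks[[i]] <- bf$block
  }
  fb <- layer_forward(gen$bn_out, x, training); gen$bn_out <- fb$layer
  fr <- layer_forward(layer_simple("relu"), fb$y, training)
  fc <- layer_forward(gen$conv_out, fr$y, training); gen$conv_out <- fc$layer
  ft <- layer_forward(layer_simple("tanh"), fc$y, training)
  list(y = ft$y, gen = gen,
       cache = list(z = fz$cache, embed = fe1$cache, dense_e = fe2$cache,
                    blocks = bcaches, bn_out = fb$cache, relu = fr$cache,
                    conv_out = fc$cache, tanh = ft$cache, n = n))
}

# gradient of a scalar loss wrt generator params, given d(loss)/d(images)
generator_backward <- function(gen, cache, gy) {
  bt <- layer_backward(layer_simple("tanh"), cache$tanh, gy)
  bc <- layer_backward(gen$conv_out, cache$conv_out, bt$gx)
  br <- layer_backward(layer_simple("relu"), cache$relu, bc$gx)
  bb <- layer_backward(gen$bn_out, cache$bn_out, br$gx)
  gx <- bb$gx
  bgrads <- vector("list", length(gen$blocks))
  for (i in rev(seq_along(gen$blocks))) {
    out <- block_backward(gen$blocks[[i]], cache$blocks[[i]], gx)
    gx <- out$gx
    bgrads[[i]] <- out$grads
  }
  n <- cache$n
  gz_map <- gx[, , seq_len(gen$cz), , drop = FALSE]
  ge_map <- gx[, , gen$cz + seq_len(gen$ce), , drop = FALSE]
  g_dense_z <- layer_backward(gen$dense_z, cache$z,
                              t(matrix(gz_map, 16L * gen$cz, n)))
  g_dense_e <- layer_backward(gen$dense_e, cache$dense_e,
                              t(matrix(ge_map, 16L * gen$ce, n)))
  g_embed <- layer_backward(gen$embed, cache$embed, g_dense_e$gx)
  list(grads = list(dense_z = g_dense_z$grads, embed = g_embed$grads,
                    dense_e = g_dense_e$grads, blocks = bgrads,
                    bn_out = bb$grads, conv_out = bc$grads))
}

#' Generate class-conditional images
#'
#' Runs the generator in evaluation mode (running batch-norm statistics) on
#' standard-normal noise. Deterministic given weights, noise and labels; if
#' `noise` is omitted it is drawn under `seed`.
#'
#' @param generator A [build_generator()] object (typically from a trained
#'   checkpoint).
#' @param labels Integer class labels in `[0, n_classes)`.
#' @param noise Optional matrix `length(labels) x noise_dim`.
#' @param seed Seed for noise sampling when `noise` is missing.
#' @return A batch: list with `images` (n, h, w, 3) in `[-1, 1]` and
#'   `labels`.
#' @export
generate_images <- function(generator, labels, noise = NULL, seed = NULL) {
  labels <- check_labels(labels, generator$cfg$n_classes)
  n <- length(labels)
  if (is.null(noise)) {
    noise <- with_seed_(seed, matrix(rnorm(n * generator$cfg$noise_dim), n))
  }
  fwd <- generator_forward(generator, noise, labels, training = FALSE)
  new_batch(from_nn(fwd$y), labels)
}

# --- critic ----------------------------------------------------------------

#' Build the two-headed critic
#'
#' An initial 3x3 convolution, `n_resblocks` residual downsampling blocks
#' (layer-normalized), a ReLU and global sum pooling, then two linear heads:
#' an unbounded per-image Wasserstein source score and per-class logits from
#' the auxiliary classifier. The critic never receives labels, matching the
#' auxiliary-classifier design where class information must be recovered
#' from the image alone.
#'
#' @param cfg A [gan_config()].
#' @return A critic object (S3 class `cyto_critic`).
#' @export
build_critic <- function(cfg) {
  stopifnot(inherits(cfg, "gan_config"))
  blocks <- vector("list", cfg$n_resblocks)
  for (i in seq_len(cfg$n_resblocks)) {
    blocks[[i]] <- residual_down_block(cfg$base_channels, cfg$base_channels)
  }
  structure(list(cfg = cfg,
                 conv_in = layer_conv(3, 3, 3L, cfg$base_channels),
                 blocks = blocks,
                 head_source = layer_dense(cfg$base_channels, 1L,
                                           init_sd = sqrt(1 / cfg$base_channels)),
                 head_class = layer_dense(cfg$base_channels, cfg$n_classes,
                                          init_sd = sqrt(1 / cfg$base_channels))),
            class = "cyto_critic")
}

#' @export
print.cyto_critic <- function(x, ...) {
  cat(sprintf("<cyto_critic> %dpx, %d classes\n", x$cfg$image_size, x$cfg$n_classes))
  invisible(x)
}

# x internal layout (h, w, c, n); collect_features optionally keeps
# per-block activations for the aux-critic metric backbone
critic_forward <- function(critic, x, collect_features = FALSE) {
  d <- dim(x)
  if (d[1] != critic$cfg$image_size || d[2] != critic$cfg$image_size) {
    stop_input(sprintf("critic expects %dpx input, got %dx%d",
                       critic$cfg$image_size, d[1], d[2]), "cytosynth_shape_error")
  }
  fc <- layer_forward(critic$conv_in, x, TRUE); critic$conv_in <- fc$layer
  x <- fc$y
  bcaches <- vector("list", length(critic$blocks))
  feats <- if (collect_features) vector("list", length(critic$blocks)) else NULL
  for (i in seq_along(critic$blocks)) {
    bf <- block_forward(critic$blocks[[i]], x, TRUE)
    x <- bf$y
    bcaches[[i]] <- bf$cache
    critic$blocks[[i]] <- bf$block
    if (collect_features) feats[[i]] <- x
  }
  fr <- layer_forward(layer_simple("relu"), x, TRUE)
  fp <- layer_forward(layer_simple("gsp"), fr$y, TRUE)
  fs <- layer_forward(critic$head_source, fp$y, TRUE); critic$head_source <- fs$layer
  fl <- layer_forward(critic$head_class, fp$y, TRUE); critic$head_class <- fl$layer
  list(source = as.numeric(fs$y), logits = fl$y, pooled = fp$y,
       features = feats, critic = critic,
       cache = list(conv_in = fc$cache, blocks = bcaches, relu = fr$cache,
                    gsp = fp$cache, head_source = fs$cache, head_class = fl$cache))
}

# d_source: length-n vector of upstream grads on the source score;
# d_logits: n x K matrix (either may be zero). Returns weight grads and the
# gradient wrt the input images.
critic_backward <- function(critic, cache, d_source = NULL, d_logits = NULL) {
  n <- length(cache$head_source$x[, 1])
  gp <- matrix(0, n, critic$cfg$base_channels)
  gs_grads <- list(W = critic$head_source$par$W * 0, b = 0)
  gl_grads <- list(W = critic$head_class$par$W * 0,
                   b = numeric(ncol(critic$head_class$par$W)))
  if (!is.null(d_source)) {
    bs <- layer_backward(critic$head_source, cache$head_source, matrix(d_source, ncol = 1))
    gp <- gp + bs$gx
    gs_grads <- bs$grads
  }
  if (!is.null(d_logits)) {
    bl <- layer_backward(critic$head_class, cache$head_class, d_logits)
    gp <- gp + bl$gx
    gl_grads <- bl$grads
  }
  bpool <- layer_backward(layer_simple("gsp"), cache$gsp, gp)
  brelu <- layer_backward(layer_simple("relu"), cache$relu, bpool$gx)
  gx <- brelu$gx
  bgrads <- vector("list", length(critic$blocks))
  for (i in rev(seq_along(critic$blocks))) {
    out <- block_backward(critic$blocks[[i]], cache$blocks[[i]], gx)
    gx <- out$gx
    bgrads[[i]] <- out$grads
  }
  bin <- layer_backward(critic$conv_in, cache$conv_in, gx)
  list(gx = bin$gx,
       grads = list(conv_in = bin$grads, blocks = bgrads,
                    head_source = gs_grads, head_class = gl_grads))
}

#' Score a batch of images with the critic
#'
#' @param critic A [build_critic()] object.
#' @param images Image array (n, h, w, 3) in `[-1, 1]`.
#' @return A list with `source_score` (length-n numeric, unbounded) and
#'   `class_logits` (n x n_classes matrix).
#' @export
critic_scores <- function(critic, images) {
  check_image_batch(images)
  fwd <- critic_forward(critic, to_nn(images))
  list(source_score = fwd$source, class_logits = fwd$logits)
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}
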