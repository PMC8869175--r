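#' Training configuration for the hybrid GAN
#'
#' Defaults follow common practice for Wasserstein critics: several critic
#' steps per generator step, Adam with low first-moment decay, gradient
#' penalty coefficient 10, and an auxiliary class-loss weight of 1.
#'
#' @param learning_rate Adam learning rate (both networks).
#' @param batch_size Minibatch size.
#' @param epochs Training epochs; iterations per epoch are derived from the
#'   training-set size.
#' @param n_critic Critic updates per generator update (>= 1).
#' @param sigma Gradient-penalty coefficient.
#' @param lambda_cls Weight of the auxiliary class loss; 0 recovers plain
#'   WGAN-GP.
#' @param use_gradient_penalty Disable to replace the Wasserstein source
#'   loss with the cross-entropy source loss (the AC-GAN loss family).
#' @param beta1,beta2 Adam moment decays.
#' @param uniform_fake_labels Draw generator conditioning labels uniformly
#'   instead of from the empirical class frequencies of the training split.
#' @param eps_fd Step of the finite-difference directional derivative used
#'   for the penalty's weight gradient.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64, epochs = 50,
                         n_critic = 5, sigma = 10, lambda_cls = 1,
                         use_gradient_penalty = TRUE,
                         beta1 = 0.5, beta2 = 0.9,
                         uniform_fake_labels = FALSE, eps_fd = 1e-3, seed = 1L) {
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1 || n_critic < 1 ||
      sigma < 0 || lambda_cls < 0) {
    stop_input("training hyperparameters must be positive (sigma, lambda_cls >= 0)",
               "cytosynth_config_error")
  }
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), n_critic = as.integer(n_critic),
                 sigma = sigma, lambda_cls = lambda_cls,
                 use_gradient_penalty = isTRUE(use_gradient_penalty),
                 beta1 = beta1, beta2 = beta2,
                 uniform_fake_labels = isTRUE(uniform_fake_labels),
                 eps_fd = eps_fd, seed = as.integer(seed)),
            class = "train_config")
}

#' Load manifest images into a batch array
#'
#' Reads PNG/JPG files listed in a manifest into an (n, h, w, 3) array in
#' `[0, 1]`. All images must share one size (or are average-pool resized to
#' `size` when given).
#'
#' @param manifest A manifest tibble with existing `path`s.
#' @param size Optional target side length.
#' @return A list with `images`, `labels` (0-based integers) and
#'   `class_levels` (label for each integer).
#' @export
load_images <- function(manifest, size = NULL) {
  manifest <- as_manifest(manifest)
  if (nrow(manifest) == 0) stop_input("empty manifest", "cytosynth_input_error")
  class_levels <- sort(unique(manifest$label))
  imgs <- lapply(manifest$path, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3L] == 4L) img <- img[, , 1:3]
    if (!is.null(size) && !all(dim(img)[1:2] == size)) img <- downsample_image(img, size)
    img
  })
  d <- dim(imgs[[1]])
  images <- array(0, c(length(imgs), d))
  for (i in seq_along(imgs)) images[i, , , ] <- imgs[[i]]
  list(images = images,
       labels = match(manifest$label, class_levels) - 1L,
       class_levels = class_levels)
}

#' Train the hybrid conditional GAN
#'
#' Alternating optimization: `n_critic` critic updates (Wasserstein loss
#' plus gradient penalty plus weighted class cross-entropy on both real and
#' generated images) per generator update (negative critic score of the
#' generated batch plus weighted class cross-entropy at the conditioning
#' label). The run aborts with a diagnostic naming the offending term and
#' iteration if any loss becomes non-finite.
#'
#' @param manifest A manifest tibble; rows with `split == "train"` are used
#'   (all rows when no split is assigned).
#' @param gan_cfg A [gan_config()]; its `n_classes` must match the manifest.
#' @param cfg A [train_config()].
#' @param epoch_callback Optional `function(epoch, generator, critic)`; its
#'   return values are collected in the fit's `epoch_info`.
#' @param checkpoint_dir Optional directory for per-epoch checkpoints.
#' @param verbose Print a line per epoch.
#' @return A fit of class `wgan_gp_ac`: generator, critic, per-iteration
#'   `history` tibble (all loss terms plus auxiliary-classifier accuracy on
#'   the real batch), `class_levels`, configs and optimizer state.
#' @export
train_gan <- function(manifest, gan_cfg, cfg = train_config(),
                      epoch_callback = NULL, checkpoint_dir = NULL,
                      verbose = FALSE) {
  manifest <- as_manifest(manifest)
  if ("train" %in% manifest$split) manifest <- manifest[manifest$split == "train", ]
  data <- load_images(manifest, size = gan_cfg$image_size)
  if (length(data$class_levels) != gan_cfg$n_classes) {
    stop_input(sprintf("manifest has %d classes but gan_cfg expects %d",
                       length(data$class_levels), gan_cfg$n_classes),
               "cytosynth_config_error")
  }
  x_all <- to_nn(to_tanh_range(data$images))
  y_all <- data$labels
  n_train <- length(y_all)
  label_freq <- tabulate(y_all + 1L, gan_cfg$n_classes)
  fake_label_prob <- if (cfg$uniform_fake_labels) {
    rep(1 / gan_cfg$n_classes, gan_cfg$n_classes)
  } else label_freq / sum(label_freq)
  nb <- min(cfg$batch_size, n_train)
  iters <- max(1L, n_train %/% nb)

  history <- vector("list", cfg$epochs * iters)
  epoch_info <- vector("list", cfg$epochs)

  with_seed_(cfg$seed, {
    gen <- build_generator(gan_cfg)
    critic <- build_critic(gan_cfg)
    opt_g <- adam_new(cfg$learning_rate, cfg$beta1, cfg$beta2)
    opt_c <- adam_new(cfg$learning_rate, cfg$beta1, cfg$beta2)
    row <- 0L

    for (epoch in seq_len(cfg$epochs)) {
      for (it in seq_len(iters)) {
        terms <- NULL
        for (step in seq_len(cfg$n_critic)) {
          idx <- sample.int(n_train, nb)
          xr <- x_all[, , , idx, drop = FALSE]
          yr <- y_all[idx]
          yf <- sample.int(gan_cfg$n_classes, nb, replace = TRUE,
                           prob = fake_label_prob) - 1L
          z <- matrix(rnorm(nb * gan_cfg$noise_dim), nb)
          gf <- generator_forward(gen, z, yf, training = TRUE)
          gen <- gf$gen
          xf <- gf$y

          fr <- critic_forward(critic, xr); critic <- fr$critic
          ff <- critic_forward(critic, xf); critic <- ff$critic
          ce_r <- ce_from_logits(fr$logits, yr)
          ce_f <- ce_from_logits(ff$logits, yf)

          if (cfg$use_gradient_penalty) {
            d_src_r <- rep(-1 / nb, nb)
            d_src_f <- rep(1 / nb, nb)
            w_loss <- mean(ff$source) - mean(fr$source)
          } else {
            # AC-GAN source loss: cross-entropy on a logistic source unit
            pr <- 1 / (1 + exp(-fr$source))
            pf <- 1 / (1 + exp(-ff$source))
            d_src_r <- (pr - 1) / nb
            d_src_f <- pf / nb
            w_loss <- -(mean(log_sigmoid(fr$source)) + mean(log_sigmoid(-ff$source)))
          }
          br <- critic_backward(critic, fr$cache, d_source = d_src_r,
                                d_logits = cfg$lambda_cls * ce_r$dlogits)
          bf <- critic_backward(critic, ff$cache, d_source = d_src_f,
                                d_logits = cfg$lambda_cls * ce_f$dlogits)
          grads <- grad_tree_add(br$grads, bf$grads)

          gp_val <- 0
          if (cfg$use_gradient_penalty && cfg$sigma > 0) {
            eps <- runif(nb)
            e <- array(rep(eps, each = prod(dim(xr)[1:3])), dim(xr))
            x_hat <- e * xr + (1 - e) * xf
            gp <- gp_value_and_grads(critic, x_hat, cfg$sigma, cfg$eps_fd)
            gp_val <- gp$value
            grads <- grad_tree_add(grads, gp$grads)
          }
          upd <- adam_step(critic, grads, opt_c)
          critic <- upd$net; opt_c <- upd$opt

          aux_acc <- mean(max.col(fr$logits, ties.method = "first") - 1L == yr)
          terms <- tibble(
            critic_wasserstein = w_loss, gradient_penalty = gp_val,
            class_loss_real = ce_r$loss, class_loss_fake = ce_f$loss,
            aux_accuracy_real = aux_acc)
        }

        # generator update
        yf <- sample.int(gan_cfg$n_classes, nb, replace = TRUE,
                         prob = fake_label_prob) - 1L
        z <- matrix(rnorm(nb * gan_cfg$noise_dim), nb)
        gf <- generator_forward(gen, z, yf, training = TRUE)
        ff <- critic_forward(critic, gf$y)
        ce_f <- ce_from_logits(ff$logits, yf)
        bwd <- critic_backward(ff$critic, ff$cache,
                               d_source = rep(-1 / nb, nb),
                               d_logits = cfg$lambda_cls * ce_f$dlogits)
        g_grads <- generator_backward(gf$gen, gf$cache, bwd$gx)$grads
        upd <- adam_step(gf$gen, g_grads, opt_g)
        gen <- upd$net; opt_g <- upd$opt

        row <- row + 1L
        history[[row]] <- dplyr::bind_cols(
          tibble(epoch = epoch, iteration = it),
          terms,
          tibble(generator_adversarial = -mean(ff$source),
                 generator_class = ce_f$loss))
        rec <- history[[row]]
        bad <- names(rec)[vapply(rec, function(v) is.numeric(v) && !is.finite(v), logical(1))]
        if (length(bad) > 0) {
          stop_input(sprintf("non-finite loss term '%s' at epoch %d iteration %d",
                             bad[1], epoch, it), "cytosynth_numerical_error")
        }
      }
      if (!is.null(epoch_callback)) {
        epoch_info[[epoch]] <- epoch_callback(epoch, gen, critic)
      }
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        save_checkpoint(
          new_checkpoint(gen, critic, gan_cfg, cfg, opt_g, opt_c, epoch,
                         data$class_levels),
          file.path(checkpoint_dir, sprintf("epoch_%03d.rds", epoch)))
      }
      if (verbose) {
        message(sprintf("epoch %d/%d  W %.3f  GP %.3f  aux acc %.2f",
                        epoch, cfg$epochs, history[[row]]$critic_wasserstein,
                        history[[row]]$gradient_penalty,
                        history[[row]]$aux_accuracy_real))
      }
    }

    structure(list(generator = gen, critic = critic,
                   history = dplyr::bind_rows(history),
                   epoch_info = epoch_info,
                   class_levels = data$class_levels,
                   gan_cfg = gan_cfg, train_cfg = cfg,
                   checkpoint = new_checkpoint(gen, critic, gan_cfg, cfg, opt_g,
                                               opt_c, cfg$epochs, data$class_levels)),
              class = "wgan_gp_ac")
  })
}

#' @export
print.wgan_gp_ac <- function(x, ...) {
  cat(sprintf("<wgan_gp_ac> %d classes at %dpx, %d epochs, %d iterations\n",
              x$gan_cfg$n_classes, x$gan_cfg$image_size, x$train_cfg$epochs,
              nrow(x$history)))
  invisible(x)
}

new_checkpoint <- function(gen, critic, gan_cfg, train_cfg, opt_g, opt_c,
                           epoch, class_levels) {
  structure(list(version = 1L, generator = gen, critic = critic,
                 gan_cfg = gan_cfg, train_cfg = train_cfg,
                 opt_g = opt_g, opt_c = opt_c, epoch = epoch,
                 class_levels = class_levels,
                 rng_state = .GlobalEnv$.Random.seed),
            class = "gan_checkpoint")
}

#' Save / load a training checkpoint
#'
#' A checkpoint holds generator and critic weights, both configurations,
#' optimizer state, the epoch counter, class levels and the RNG state, under
#' a versioned header.
#'
#' @param checkpoint A `gan_checkpoint` (see [train_gan()]).
#' @param path File path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "gan_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "gan_checkpoint") || is.null(ck$version)) {
    stop_input("not a checkpoint file", "cytosynth_format_error")
  }
  ck
}

#' Synthesize images to balance minority classes
#'
#' Generates, for every class, exactly the number of images its deficit
#' calls for (see [class_deficits()]), conditioning the generator on that
#' class, and writes them as PNG files. Combining the returned manifest with
#' the original yields a dataset balanced at the target count.
#'
#' @param checkpoint A `gan_checkpoint` or `wgan_gp_ac` fit.
#' @param deficits Tibble from [class_deficits()] or a named vector
#'   (label -> count).
#' @param out_dir Output directory for the synthetic images.
#' @param seed Integer seed for the noise draws.
#' @param batch_size Generation chunk size.
#' @return A manifest of the synthetic images with `source = "synthetic"`.
#' @export
synthesize_balanced <- function(checkpoint, deficits, out_dir, seed = 1L,
                                batch_size = 64L) {
  if (inherits(checkpoint, "wgan_gp_ac")) checkpoint <- checkpoint$checkpoint
  stopifnot(inherits(checkpoint, "gan_checkpoint"))
  if (is.data.frame(deficits)) {
    deficits <- setNames(deficits$deficit, deficits$label)
  }
  unknown <- setdiff(names(deficits), checkpoint$class_levels)
  if (length(unknown) > 0) {
    stop_input(paste0("class(es) unknown to the checkpoint: ",
                      paste(unknown, collapse = ", ")), "cytosynth_taxonomy_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  with_seed_(seed, {
    for (lab in names(deficits)) {
      n_lab <- as.integer(deficits[[lab]])
      if (n_lab <= 0) next
      cls <- match(lab, checkpoint$class_levels) - 1L
      cls_dir <- file.path(out_dir, lab)
      dir.create(cls_dir, showWarnings = FALSE)
      paths <- character(n_lab)
      done <- 0L
      while (done < n_lab) {
        k <- min(batch_size, n_lab - done)
        noise <- matrix(rnorm(k * checkpoint$gan_cfg$noise_dim), k)
        batch <- generate_images(checkpoint$generator, rep(cls, k), noise = noise)
        for (j in seq_len(k)) {
          p <- file.path(cls_dir, sprintf("synthetic_%s_%05d.png", lab, done + j))
          png::writePNG(from_tanh_range(batch$images[j, , , ]), p)
          paths[done + j] <- p
        }
        done <- done + k
      }
      rows[[lab]] <- tibble(path = paths, label = lab, source = "synthetic")
    }
  })
  if (length(rows) == 0) {
    return(as_manifest(tibble(path = character(), label = character(),
                              source = character())))
  }
  as_manifest(dplyr::bind_rows(rows))
}
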