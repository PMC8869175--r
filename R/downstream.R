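# Downstream evaluation: does synthetic balancing help a classifier?

cls_arch_registry <- new.env(parent = emptyenv())

#' Register a classifier architecture
#'
#' Architectures are pluggable: a constructor receives the class count and
#' image size and returns the layer list of a network ending in class
#' logits. `small-cnn` (three convolution blocks and a linear head) and
#' `mlp` (one hidden dense layer on raw pixels) ship with the package.
#'
#' @param id Architecture identifier.
#' @param constructor `function(n_classes, image_size)` returning a list of
#'   layers.
#' @return `id`, invisibly.
#' @export
register_classifier_arch <- function(id, constructor) {
  assign(id, constructor, envir = cls_arch_registry)
  invisible(id)
}

default_arches <- function() {
  register_classifier_arch("small-cnn", function(n_classes, image_size) {
    list(layer_conv(3, 3, 3L, 8L), layer_simple("relu"), layer_simple("pool2"),
         layer_conv(3, 3, 8L, 16L), layer_simple("relu"), layer_simple("pool2"),
         layer_conv(3, 3, 16L, 32L), layer_simple("relu"), layer_simple("pool2"),
         layer_simple("gsp"), layer_dense(32L, n_classes, init_sd = sqrt(1 / 32)))
  })
  register_classifier_arch("mlp", function(n_classes, image_size) {
    n_in <- image_size * image_size * 3L
    list(layer_simple("flatten"), layer_dense(n_in, 64L),
         layer_simple("relu2d"), layer_dense(64L, n_classes, init_sd = sqrt(1 / 64)))
  })
}

# flatten (h,w,c,n) -> n x f and plain relu on matrices, for the mlp arch
layer_forward_ext <- function(layer, x, training) {
  if (layer$kind == "flatten") {
    d <- dim(x)
    return(list(y = t(matrix(x, prod(d[1:3]), d[4])), cache = list(d = d),
                layer = layer))
  }
  if (layer$kind == "relu2d") {
    return(list(y = pmax(x, 0), cache = list(mask = x > 0), layer = layer))
  }
  layer_forward(layer, x, training)
}

layer_backward_ext <- function(layer, cache, gy) {
  if (layer$kind == "flatten") {
    return(list(gx = array(t(gy), cache$d), grads = list()))
  }
  if (layer$kind == "relu2d") {
    return(list(gx = gy * cache$mask, grads = list()))
  }
  layer_backward(layer, cache, gy)
}

classifier_forward <- function(layers, x, training = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- layer_forward_ext(layers[[i]], x, training)
    x <- st$y; caches[[i]] <- st$cache; layers[[i]] <- st$layer
  }
  list(logits = x, caches = caches, layers = layers)
}

classifier_backward <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    out <- layer_backward_ext(layers[[i]], caches[[i]], gy)
    gy <- out$gx; grads[[i]] <- out$grads
  }
  grads
}

#' Train a small image classifier
#'
#' Minibatch Adam on the cross-entropy, with early stopping on validation
#' loss. Intended as the desk-scale stand-in for large pretrained
#' backbones in dataset-condition comparisons; the architecture id is
#' recorded so larger registered backbones can be swapped in.
#'
#' @param train,val Manifests with image files (validation may be `NULL`, in
#'   which case a 20% tail of `train` is held out).
#' @param arch Registered architecture id.
#' @param image_size Side length images are resized to.
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed (weights, shuffling).
#' @param class_levels Optional label set fixing the class order (defaults
#'   to the labels present in `train`).
#' @return A `cyto_classifier` with the fitted layers, class levels and the
#'   per-epoch `history` tibble.
#' @export
train_classifier <- function(train, val = NULL, arch = "small-cnn",
                             image_size = 16L, epochs = 30L, batch_size = 32L,
                             learning_rate = 2e-3, patience = 5L, seed = 1L,
                             class_levels = NULL) {
  train <- as_manifest(train)
  if (length(unique(train$label)) < 2 && is.null(class_levels)) {
    stop_input("training data must contain at least 2 classes",
               "cytosynth_training_error")
  }
  if (!exists(arch, envir = cls_arch_registry)) default_arches()
  if (!exists(arch, envir = cls_arch_registry)) {
    stop_input(paste0("unknown classifier architecture: ", arch),
               "cytosynth_config_error")
  }
  with_seed_(seed, {
    if (is.null(val)) {
      idx <- sample.int(nrow(train))
      n_val <- max(1L, floor(nrow(train) * 0.2))
      val <- train[idx[seq_len(n_val)], ]
      train <- train[idx[-seq_len(n_val)], ]
    }
    levels <- class_levels %||% sort(unique(train$label))
    k <- length(levels)
    tr <- load_images(train, size = image_size)
    xt <- to_nn(to_tanh_range(tr$images))
    yt <- match(train$label, levels) - 1L
    vl <- load_images(val, size = image_size)
    xv <- to_nn(to_tanh_range(vl$images))
    yv <- match(val$label, levels) - 1L

    layers <- get(arch, envir = cls_arch_registry)(k, as.integer(image_size))
    opt <- adam_new(learning_rate, beta1 = 0.9, beta2 = 0.999)
    n <- length(yt)
    best <- list(loss = Inf, layers = layers, epoch = 0L)
    hist <- vector("list", epochs)
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0; nb_count <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        fwd <- classifier_forward(layers, xt[, , , idx, drop = FALSE])
        layers <- fwd$layers
        ce <- ce_from_logits(fwd$logits, yt[idx])
        grads <- classifier_backward(layers, fwd$caches, ce$dlogits)
        upd <- adam_step(layers, grads, opt)
        layers <- upd$net; opt <- upd$opt
        tr_loss <- tr_loss + ce$loss; nb_count <- nb_count + 1
      }
      vf <- classifier_forward(layers, xv, training = FALSE)
      vce <- ce_from_logits(vf$logits, yv)
      v_acc <- mean(max.col(vf$logits, ties.method = "first") - 1L == yv)
      hist[[epoch]] <- tibble(epoch = epoch, train_loss = tr_loss / nb_count,
                              val_loss = vce$loss, val_accuracy = v_acc)
      if (vce$loss < best$loss - 1e-6) {
        best <- list(loss = vce$loss, layers = layers, epoch = epoch)
      } else if (epoch - best$epoch >= patience) break
    }
    structure(list(layers = best$layers, class_levels = levels, arch = arch,
                   image_size = as.integer(image_size),
                   history = dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))]),
                   seed = as.integer(seed)),
              class = "cyto_classifier")
  })
}

#' @export
print.cyto_classifier <- function(x, ...) {
  cat(sprintf("<cyto_classifier> arch %s, %d classes at %dpx\n",
              x$arch, length(x$class_levels), x$image_size))
  invisible(x)
}

#' Predict classes for a manifest or image array
#'
#' @param object A [train_classifier()] fit.
#' @param newdata A manifest tibble or an (n, h, w, 3) array in `[0, 1]`.
#' @param ... Unused.
#' @return A tibble with predicted `label` and per-class probabilities.
#' @export
predict.cyto_classifier <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- load_images(newdata, size = object$image_size)$images
  }
  x <- to_nn(to_tanh_range(newdata))
  logits <- classifier_forward(object$layers, x, training = FALSE)$logits
  probs <- softmax_rows(logits)
  colnames(probs) <- object$class_levels
  dplyr::bind_cols(tibble(label = object$class_levels[max.col(logits, ties.method = "first")]),
                   as_tibble(probs))
}

# largest-remainder allocation of target_n over class proportions
allocate_counts <- function(props, target_n) {
  raw <- props * target_n
  base <- floor(raw)
  rem <- target_n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

sample_class_rows <- function(manifest, lab, n_take, allow_oversample) {
  rows <- which(manifest$label == lab)
  if (length(rows) == 0) {
    stop_input(paste0("no records available for class ", lab),
               "cytosynth_config_error")
  }
  if (n_take <= length(rows)) {
    rows[sample.int(length(rows), n_take)]
  } else if (allow_oversample) {
    c(rows, rows[sample.int(length(rows), n_take - length(rows), replace = TRUE)])
  } else {
    stop_input(sprintf("class %s has %d records, %d requested", lab,
                       length(rows), n_take), "cytosynth_config_error")
  }
}

#' Build equally sized dataset conditions for a fair comparison
#'
#' Five training conditions of exactly `target_n` images each, with
#' identical per-class counts (an even split across classes by default):
#' `original` (resampled originals), `synthetic` (generated images only),
#' `augmentation-1/2/3` (originals passed through the named recipe, written
#' to `out_dir`), and `original+synthetic` (half originals, remainder
#' synthetic, per class). Classes short of their quota are oversampled with
#' replacement so every condition sees the same class distribution.
#'
#' @param original Manifest of real images (its train split when assigned).
#' @param synthetic Manifest of generated images covering the same classes.
#' @param target_n Total images per condition.
#' @param aug_specs List of [augmentation_spec()]s (default recipes 1-3).
#' @param out_dir Directory for augmented image files.
#' @param seed Integer seed.
#' @param allow_oversample Permit with-replacement resampling when a class
#'   has fewer records than its quota (otherwise a config error).
#' @return Named list of manifests, one per condition.
#' @export
build_conditions <- function(original, synthetic, target_n, aug_specs = NULL,
                             out_dir = tempfile("aug"), seed = 1L,
                             allow_oversample = TRUE) {
  original <- as_manifest(original)
  if ("train" %in% original$split) original <- original[original$split == "train", ]
  synthetic <- as_manifest(synthetic)
  if (is.null(aug_specs)) {
    aug_specs <- lapply(paste0("augmentation-", 1:3), augmentation_spec, seed = seed)
  }
  levels <- sort(unique(original$label))
  missing_cls <- setdiff(levels, unique(synthetic$label))
  if (length(missing_cls) > 0) {
    stop_input(paste0("synthetic manifest lacks class(es): ",
                      paste(missing_cls, collapse = ", ")), "cytosynth_config_error")
  }
  alloc <- allocate_counts(rep(1 / length(levels), length(levels)), target_n)
  names(alloc) <- levels
  conditions <- list()
  with_seed_(seed, {
    take <- function(m, frac = 1) {
      rows <- unlist(lapply(levels, function(lab) {
        n_take <- if (frac == 1) alloc[[lab]] else floor(alloc[[lab]] * frac)
        if (n_take == 0) return(integer())
        sample_class_rows(m, lab, n_take, allow_oversample)
      }))
      m[rows, ]
    }
    conditions$original <- take(original)
    conditions$synthetic <- take(synthetic)
    for (spec in aug_specs) {
      base <- take(original)
      dat <- load_images(base)
      aug <- augment_images(dat$images, spec)
      dir_k <- file.path(out_dir, spec$name)
      dir.create(dir_k, recursive = TRUE, showWarnings = FALSE)
      paths <- character(nrow(base))
      for (j in seq_len(nrow(base))) {
        paths[j] <- file.path(dir_k, sprintf("%s_%05d.png", base$label[j], j))
        png::writePNG(aug[j, , , ], paths[j])
      }
      conditions[[spec$name]] <- as_manifest(
        tibble(path = paths, label = base$label, source = spec$name))
    }
    combined <- lapply(levels, function(lab) {
      n_orig <- floor(alloc[[lab]] / 2)
      n_syn <- alloc[[lab]] - n_orig
      rbind(original[sample_class_rows(original, lab, n_orig, allow_oversample), ],
            synthetic[sample_class_rows(synthetic, lab, n_syn, allow_oversample), ])
    })
    conditions[["original+synthetic"]] <- as_manifest(dplyr::bind_rows(combined))
  })
  conditions
}

#' Compare classifier performance across dataset conditions
#'
#' Trains one classifier per condition (same architecture, same seed) and
#' evaluates all of them on a single shared held-out test set, reporting
#' macro precision/recall/F1 per condition and per-class accuracy,
#' sensitivity and specificity — one code path ([prf()]) for every number.
#'
#' @param conditions Named list of training manifests (see
#'   [build_conditions()]).
#' @param test Manifest of the shared test split (never used for training
#'   or synthesis conditioning).
#' @param arch Registered classifier architecture id.
#' @param image_size,epochs,batch_size,learning_rate,patience Passed to
#'   [train_classifier()].
#' @param seed Integer seed.
#' @return A `comparison_report`: list with `summary` (one row per
#'   condition) and `per_class` tibbles.
#' @export
compare_conditions <- function(conditions, test, arch = "small-cnn",
                               image_size = 16L, epochs = 30L, batch_size = 32L,
                               learning_rate = 2e-3, patience = 5L, seed = 1L) {
  test <- as_manifest(test)
  levels <- sort(unique(unlist(lapply(conditions, function(m) unique(m$label)))))
  test_dat <- load_images(test, size = image_size)
  rows <- list(); per_class <- list()
  for (nm in names(conditions)) {
    clf <- train_classifier(conditions[[nm]], arch = arch, image_size = image_size,
                            epochs = epochs, batch_size = batch_size,
                            learning_rate = learning_rate, patience = patience,
                            seed = seed, class_levels = levels)
    pred <- predict(clf, test_dat$images)$label
    confusion <- table(factor(test$label, levels = levels),
                       factor(pred, levels = levels))
    res <- prf(unclass(confusion))
    rows[[nm]] <- tibble(condition = nm, n_train = nrow(conditions[[nm]]),
                         precision = res$precision, recall = res$recall,
                         f1 = res$f1)
    per_class[[nm]] <- dplyr::mutate(res$per_class, condition = nm, .before = 1)
  }
  structure(list(summary = dplyr::bind_rows(rows),
                 per_class = dplyr::bind_rows(per_class),
                 arch = arch, image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$summary)
  invisible(x)
}
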