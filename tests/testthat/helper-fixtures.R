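# Shared fixture datasets and one cached smoke GAN run, built lazily once
# per test session. Everything here is deterministic given the seeds below.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

fixture_dataset <- function(key, spec) {
  cached(key, {
    dir <- file.path(tempdir(), paste0("cytosynth-", key))
    generate_fixture_dataset(spec, dir)
  })
}

# --- end-to-end smoke protocol (three majority classes, one minority) ------

smoke_spec <- function() {
  fixture_spec(n_classes = 4, per_class_counts = c(40, 40, 40, 10),
               image_size = 16, seed = 3L)
}

smoke_manifest <- function() fixture_dataset("smoke", smoke_spec())

smoke_gan_config <- function() {
  gan_config(n_classes = 4, image_size = 16, base_channels = 12, noise_dim = 16)
}

smoke_train_config <- function() {
  train_config(epochs = 60, batch_size = 16, n_critic = 2, seed = 9L)
}

# median circular distance between the measured hue of generated samples and
# the hue of the class they were conditioned on; hue-less (grey) samples
# count as the worst case, 180 degrees
median_hue_error <- function(generator, spec) {
  n_per <- 8L
  batch <- generate_images(generator,
                           rep(seq_len(spec$n_classes) - 1L, each = n_per),
                           seed = 42L)
  imgs <- (batch$images + 1) / 2
  errs <- vapply(seq_len(dim(imgs)[1L]), function(i) {
    hue <- measure_nucleus_hue(imgs[i, , , ])
    if (is.na(hue)) return(180)
    cytosynth:::hue_distance(hue, spec$class_params[[batch$labels[i] + 1L]]$hue)
  }, numeric(1))
  stats::median(errs)
}

smoke_fit <- function() {
  cached("smoke_fit", {
    spec <- smoke_spec()
    train_gan(smoke_manifest(), smoke_gan_config(), smoke_train_config(),
              epoch_callback = function(epoch, generator, critic) {
                median_hue_error(generator, spec)
              })
  })
}

# --- tiny training run shared by the training and tidier tests -------------

tiny_manifest <- function() {
  fixture_dataset(
    "train-tiny",
    fixture_spec(n_classes = 2, per_class_counts = c(16, 16),
                 image_size = 16, seed = 91L))
}

tiny_gan_config <- function() {
  gan_config(n_classes = 2, image_size = 16, base_channels = 6, noise_dim = 8)
}

tiny_fit <- function() {
  cached("tiny_fit", {
    train_gan(tiny_manifest(), tiny_gan_config(),
              train_config(epochs = 2, batch_size = 16, n_critic = 1,
                           seed = 5L))
  })
}

# --- small helpers ----------------------------------------------------------

# zero every parameter of a network tree (gives a constant critic)
zero_params <- function(x) {
  if (cytosynth:::is_layer(x)) {
    x$par <- lapply(x$par, function(p) p * 0)
    return(x)
  }
  if (is.list(x) && !inherits(x, "gan_config")) {
    for (i in seq_along(x)) x[[i]] <- zero_params(x[[i]])
  }
  x
}

# maximum elementwise relative error between two numeric arrays
rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(a)), max(abs(b)))
}
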