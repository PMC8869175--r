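test_that("a short training run produces a complete, finite history", {
  fit <- tiny_fit()
  expect_s3_class(fit, "wgan_gp_ac")
  expect_equal(nrow(fit$history), 2L * 2L)  # epochs * (32 %/% 16) iterations
  expect_true(all(vapply(fit$history, function(col) all(is.finite(col)),
                         logical(1))))
  expect_equal(fit$class_levels, c("class1", "class2"))
})

test_that("training is deterministic given the seed", {
  fit2 <- train_gan(tiny_manifest(), tiny_gan_config(),
                    train_config(epochs = 2, batch_size = 16, n_critic = 1,
                                 seed = 5L))
  expect_equal(tiny_fit()$history, fit2$history)
})

test_that("checkpoints round-trip through disk", {
  fit <- tiny_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$checkpoint, path)
  back <- load_checkpoint(path)
  expect_s3_class(back, "gan_checkpoint")
  expect_equal(back$generator$conv_out$par, fit$generator$conv_out$par)
  expect_equal(back$class_levels, fit$class_levels)

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), class = "cytosynth_format_error")
})

test_that("synthesize_balanced writes exactly the deficits", {
  fit <- tiny_fit()
  out <- synthesize_balanced(fit, c(class1 = 3L, class2 = 0L),
                             out_dir = withr::local_tempdir(), seed = 2L)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$label == "class1"))
  expect_true(all(file.exists(out$path)))
  expect_true(all(out$source == "synthetic"))

  none <- synthesize_balanced(fit, c(class1 = 0L, class2 = 0L),
                              out_dir = withr::local_tempdir())
  expect_equal(nrow(none), 0L)
  expect_error(synthesize_balanced(fit, c(ghost = 2L),
                                   out_dir = withr::local_tempdir()),
               class = "cytosynth_taxonomy_error")
})

test_that("configuration errors are caught before training", {
  expect_error(train_config(learning_rate = 0),
               class = "cytosynth_config_error")
  expect_error(train_config(sigma = -1), class = "cytosynth_config_error")
  wrong_k <- gan_config(n_classes = 5, image_size = 16, base_channels = 6,
                        noise_dim = 8)
  expect_error(train_gan(tiny_manifest(), wrong_k,
                         train_config(epochs = 1, seed = 1L)),
               class = "cytosynth_config_error")
})
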