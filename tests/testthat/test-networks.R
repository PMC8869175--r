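test_that("gan_config derives the residual depth and validates the size", {
  expect_equal(gan_config(4, image_size = 16)$n_resblocks, 2L)
  expect_equal(gan_config(4, image_size = 32)$n_resblocks, 3L)
  expect_equal(gan_config(4, image_size = 128)$n_resblocks, 5L)
  expect_error(gan_config(4, image_size = 24), class = "cytosynth_config_error")
  expect_error(gan_config(4, image_size = 8), class = "cytosynth_config_error")
  expect_error(gan_config(1), class = "cytosynth_config_error")
})

test_that("generator emits images of the configured size in [-1, 1]", {
  cfg <- gan_config(n_classes = 3, image_size = 16, noise_dim = 8,
                    base_channels = 6)
  gen <- withr::with_seed(7L, build_generator(cfg))
  batch <- generate_images(gen, labels = c(0L, 1L, 2L, 0L), seed = 1L)
  expect_equal(dim(batch$images), c(4L, 16L, 16L, 3L))
  expect_true(all(abs(batch$images) <= 1))
  expect_true(all(is.finite(batch$images)))

  # deterministic given the seed
  batch2 <- generate_images(gen, labels = c(0L, 1L, 2L, 0L), seed = 1L)
  expect_identical(batch$images, batch2$images)

  expect_error(generate_images(gen, labels = 3L),
               class = "cytosynth_label_error")
})

test_that("residual blocks double and halve the spatial size", {
  up <- withr::with_seed(8L, residual_up_block(4, 6))
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  y <- apply_block(up, x)
  expect_equal(dim(y), c(16L, 16L, 6L, 2L))

  down <- withr::with_seed(9L, residual_down_block(4, 6))
  yd <- apply_block(down, x)
  expect_equal(dim(yd), c(4L, 4L, 6L, 2L))

  odd <- array(rnorm(5 * 5 * 4), c(5, 5, 4, 1))
  expect_error(apply_block(down, odd), class = "cytosynth_shape_error")
})

test_that("a zeroed residual branch reduces a block to its skip projection", {
  down <- withr::with_seed(10L, residual_down_block(3, 3))
  down$main[[6]]$par$w[] <- 0
  down$main[[6]]$par$b[] <- 0
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  skip_only <- cytosynth:::seq_forward(down$skip, x, training = TRUE)$y
  expect_equal(apply_block(down, x), skip_only)
})

test_that("the critic is label-blind and returns both heads", {
  cfg <- gan_config(n_classes = 5, image_size = 16, noise_dim = 8,
                    base_channels = 6)
  critic <- withr::with_seed(11L, build_critic(cfg))
  imgs <- withr::with_seed(12L, array(runif(3 * 16 * 16 * 3, -1, 1),
                                      c(3, 16, 16, 3)))
  out <- critic_scores(critic, imgs)
  expect_length(out$source_score, 3L)
  expect_equal(dim(out$class_logits), c(3L, 5L))
  expect_true(all(is.finite(out$source_score)))
  # no label argument exists: scoring depends on the image alone
  expect_named(formals(critic_scores), c("critic", "images"))

  # finite at the range extremes
  extremes <- array(rep(c(-1, 1), each = 16 * 16 * 3 / 2), c(1, 16, 16, 3))
  out2 <- critic_scores(critic, extremes)
  expect_true(is.finite(out2$source_score))
})
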