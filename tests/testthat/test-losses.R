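test_that("Wasserstein critic loss: hand arithmetic and shift invariance", {
  expect_equal(critic_wasserstein_loss(c(2, 4), c(1, 2)), -1.5)
  expect_equal(critic_wasserstein_loss(c(2, 4) + 10, c(1, 2) + 10), -1.5)
  expect_equal(critic_wasserstein_loss(c(1, 1), c(1, 1)), 0)
  expect_error(critic_wasserstein_loss(numeric(), 1),
               class = "cytosynth_input_error")
})

test_that("interpolation endpoints and midpoint", {
  real <- array(1, c(2, 4, 4, 3))
  fake <- array(0, c(2, 4, 4, 3))
  expect_equal(interpolate_images(real, fake, eps = c(1, 1)), real)
  expect_equal(interpolate_images(real, fake, eps = c(0, 0)), fake)
  expect_true(all(interpolate_images(real, fake, eps = c(0.5, 0.5)) == 0.5))
  # one coefficient per sample
  mixed <- interpolate_images(real, fake, eps = c(1, 0))
  expect_equal(mixed[1, , , ], real[1, , , ])
  expect_equal(mixed[2, , , ], fake[2, , , ])
  expect_error(interpolate_images(real, fake, eps = c(2, 0)),
               class = "cytosynth_input_error")
  expect_error(interpolate_images(real, array(0, c(1, 4, 4, 3))),
               class = "cytosynth_input_error")
})

test_that("class log-likelihood: hand-computed probabilities", {
  # binary logits chosen so the true-class probabilities are 0.8 and 0.6
  logit <- function(p) log(p / (1 - p))
  out_real <- list(source_score = 0,
                   class_logits = matrix(c(logit(0.8), 0), 1))
  out_fake <- list(source_score = 0,
                   class_logits = matrix(c(logit(0.6), 0), 1))
  ll <- source_class_loglik(out_real, out_fake,
                            labels_real = 0L, labels_fake = 0L)
  expect_equal(ll$C_L, log(0.8) + log(0.6), tolerance = 1e-10)
  expect_equal(ll$C_L, -0.7340, tolerance = 1e-4)
  expect_lte(ll$S_L, 0)

  ce <- cytosynth:::ce_from_logits(matrix(c(logit(0.8), 0), 1), 0L)
  expect_equal(ce$loss, -log(0.8), tolerance = 1e-10)
  expect_equal(rowSums(ce$prob), 1)
})

test_that("log_sigmoid is stable at extreme arguments", {
  ls <- cytosynth:::log_sigmoid
  expect_true(all(is.finite(ls(c(-1000, -10, 0, 10, 1000)))))
  expect_equal(ls(0), log(0.5))
  expect_equal(ls(1000), 0, tolerance = 1e-12)
})

test_that("total_losses combines the terms as documented", {
  cfg <- gan_config(n_classes = 2, image_size = 16, noise_dim = 4,
                    base_channels = 4)
  critic <- withr::with_seed(21L, build_critic(cfg))
  mk <- function(seed) {
    imgs <- withr::with_seed(seed, array(runif(4 * 16 * 16 * 3, -1, 1),
                                         c(4, 16, 16, 3)))
    list(images = imgs, labels = c(0L, 1L, 0L, 1L))
  }
  real <- mk(22L)
  fake <- mk(23L)
  tcfg <- train_config(sigma = 10, lambda_cls = 1)
  losses <- total_losses(real, fake, critic, tcfg, seed = 1L)
  expect_s3_class(losses, "tbl_df")
  expect_equal(nrow(losses), 1L)
  expect_equal(losses$critic_total,
               losses$critic_wasserstein + losses$gradient_penalty +
                 losses$class_loss_real + losses$class_loss_fake)
  expect_equal(losses$generator_total,
               losses$generator_adversarial + losses$generator_class)

  # lambda_cls = 0 removes the class term from the generator objective
  tcfg0 <- train_config(sigma = 10, lambda_cls = 0)
  l0 <- total_losses(real, fake, critic, tcfg0, seed = 1L)
  expect_equal(l0$generator_total, l0$generator_adversarial)
  expect_equal(l0$critic_total, l0$critic_wasserstein + l0$gradient_penalty)
})
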