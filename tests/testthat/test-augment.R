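test_that("the empty recipe is the identity", {
  imgs <- withr::with_seed(71L, array(runif(2 * 16 * 16 * 3), c(2, 16, 16, 3)))
  expect_identical(augment_images(imgs, augmentation_spec("none")), imgs)
})

test_that("a full-turn rotation reproduces the image", {
  imgs <- withr::with_seed(72L, array(runif(1 * 16 * 16 * 3), c(1, 16, 16, 3)))
  spec <- augmentation_spec(ops = list(list(op = "rotation",
                                            range = c(360, 360))))
  out <- augment_images(imgs, spec)
  expect_lt(max(abs(out - imgs)), 1e-6)
})

test_that("augmentation is deterministic given the spec seed", {
  imgs <- withr::with_seed(73L, array(runif(3 * 16 * 16 * 3), c(3, 16, 16, 3)))
  s1 <- augmentation_spec("augmentation-1", seed = 5L)
  expect_identical(augment_images(imgs, s1), augment_images(imgs, s1))
  s2 <- augmentation_spec("augmentation-1", seed = 6L)
  expect_false(identical(augment_images(imgs, s1), augment_images(imgs, s2)))
})

test_that("all three named recipes keep shape and range", {
  imgs <- withr::with_seed(74L, array(runif(2 * 16 * 16 * 3), c(2, 16, 16, 3)))
  for (name in paste0("augmentation-", 1:3)) {
    out <- augment_images(imgs, augmentation_spec(name, seed = 1L))
    expect_equal(dim(out), dim(imgs))
    expect_true(all(out >= 0 & out <= 1))
    expect_false(identical(out, imgs))
  }
})

test_that("unknown augmentation ops are rejected", {
  expect_error(augmentation_spec(ops = list(list(op = "solarize",
                                                 range = c(0, 1)))),
               class = "cytosynth_config_error")
})
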