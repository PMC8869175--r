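test_that("inception score bounds and validation", {
  uniform <- matrix(1 / 4, 20, 4)
  expect_equal(inception_score(uniform, splits = 2)$mean, 1)
  expect_error(inception_score(matrix(c(0.2, 0.3), 1)),
               class = "cytosynth_input_error")
  p <- withr::with_seed(51L, matrix(rexp(40 * 6), 40))
  p <- p / rowSums(p)
  res <- inception_score(p)
  expect_gte(res$mean, 1)
  expect_lte(res$mean, 6)
  expect_equal(inception_score(p, splits = 1)$sd, 0)
})

test_that("gaussian moments use the maximum-likelihood covariance", {
  f <- matrix(c(1, 3, 0, 0), 2)
  m <- gaussian_moments(f)
  expect_equal(m$mu, c(2, 0))
  expect_equal(m$sigma[1, 1], 1)   # ((1-2)^2 + (3-2)^2) / 2
  expect_error(gaussian_moments(matrix(1, 1, 2)),
               class = "cytosynth_input_error")
  expect_error(fid(list(mu = c(0, 0), sigma = diag(2)),
                   list(mu = 0, sigma = matrix(1))),
               class = "cytosynth_input_error")
})

test_that("prf reproduces hand-computed values on a 2x2 confusion matrix", {
  confusion <- matrix(c(8, 1, 2, 9), 2,
                      dimnames = list(c("a", "b"), c("a", "b")))
  res <- prf(confusion)
  precision <- mean(c(8 / 9, 9 / 11))
  recall <- mean(c(8 / 10, 9 / 10))
  expect_equal(res$precision, precision)
  expect_equal(res$recall, recall)
  expect_equal(res$f1, 2 * precision * recall / (precision + recall))
  expect_equal(res$per_class$sensitivity, c(8 / 10, 9 / 10))
  expect_equal(res$per_class$specificity, c(9 / 10, 8 / 10))
  expect_equal(res$per_class$accuracy, c(17 / 20, 17 / 20))
  expect_error(prf(matrix(0, 2, 2)), class = "cytosynth_input_error")
})

test_that("ssim and psnr input contracts", {
  a <- array(runif(1 * 8 * 8 * 3), c(1, 8, 8, 3))
  expect_error(ssim(list(real = a, synthetic = a), window = 9),
               class = "cytosynth_parameter_error")
  expect_error(mse_psnr(list(real = a, synthetic = a), R = 0),
               class = "cytosynth_parameter_error")
  b <- array(0.5, c(1, 8, 8, 3))
  expect_equal(ssim(list(real = b, synthetic = b)), 1)
})

test_that("pair_images pairs within class and finds exact duplicates", {
  spec <- fixture_spec(n_classes = 2, per_class_counts = c(4, 4),
                       image_size = 16, seed = 61L)
  dir_r <- withr::local_tempdir()
  real <- generate_fixture_dataset(spec, dir_r)

  # synthetic set = a copy of two of the real files, one per class
  dir_s <- withr::local_tempdir()
  pick <- c(which(real$label == "class1")[2], which(real$label == "class2")[3])
  syn_paths <- file.path(dir_s, basename(real$path[pick]))
  file.copy(real$path[pick], syn_paths)
  synthetic <- as_manifest(tibble::tibble(path = syn_paths,
                                          label = real$label[pick],
                                          source = "synthetic"))

  pairs <- pair_images(real, synthetic, strategy = "nn-within-class")
  expect_s3_class(pairs, "paired_batch")
  expect_equal(pairs$pairs$real_id, real$id[pick])  # nearest = the duplicate
  expect_equal(pairs$pairs$label, real$label[pick])
  expect_equal(pairs$real, pairs$synthetic)

  rnd1 <- pair_images(real, synthetic, strategy = "random-within-class",
                      seed = 3L)
  rnd2 <- pair_images(real, synthetic, strategy = "random-within-class",
                      seed = 3L)
  expect_identical(rnd1$pairs, rnd2$pairs)
  expect_equal(rnd1$pairs$label, synthetic$label)

  stray <- as_manifest(tibble::tibble(path = syn_paths[1], label = "class9",
                                      source = "synthetic"))
  expect_error(pair_images(real, stray), class = "cytosynth_pairing_error")
})

test_that("evaluate_synthesis produces a complete provenance-stamped report", {
  spec <- fixture_spec(n_classes = 2, per_class_counts = c(5, 5),
                       image_size = 16, seed = 62L)
  real <- fixture_dataset("metrics-real", spec)
  syn_spec <- fixture_spec(n_classes = 2, per_class_counts = c(3, 3),
                           image_size = 16, seed = 63L)
  synthetic <- fixture_dataset("metrics-syn", syn_spec)

  report <- evaluate_synthesis(real, synthetic,
                               backbone = backbone_pixel(scales = c(8, 4)),
                               seed = 2L)
  expect_s3_class(report, "metric_report")
  expect_equal(nrow(report), 1L)
  expect_true(all(c("fid", "lpips", "l1", "l2", "mse", "psnr", "ssim",
                    "backbone", "pairing", "n_real", "n_synthetic",
                    "seed") %in% names(report)))
  expect_true(is.finite(report$fid) && report$fid >= 0)
  expect_true(report$ssim <= 1 && report$ssim >= -1)
  expect_true(is.na(report$is_mean))  # pixel backbone has no class head
  expect_equal(report$backbone, "pixel-8/4")

  # self-evaluation: identical sets give the identity optima
  self_rep <- evaluate_synthesis(real, real,
                                 backbone = backbone_pixel(scales = c(8, 4)),
                                 seed = 2L)
  expect_equal(self_rep$ssim, 1)
  expect_equal(self_rep$l1, 0)
  expect_identical(self_rep$psnr, Inf)
  expect_lt(self_rep$fid, 1e-8)
})
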