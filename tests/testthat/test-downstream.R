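downstream_original <- function() {
  fixture_dataset(
    "ds-original",
    fixture_spec(n_classes = 3, per_class_counts = c(40, 40, 10),
                 image_size = 16, seed = 81L))
}

downstream_synthetic <- function() {
  m <- fixture_dataset(
    "ds-synthetic",
    fixture_spec(n_classes = 3, per_class_counts = c(25, 25, 25),
                 image_size = 16, seed = 82L))
  m$source <- "synthetic"
  m
}

test_that("build_conditions yields the named equal-size, class-balanced conditions", {
  conds <- build_conditions(downstream_original(), downstream_synthetic(),
                            target_n = 30L, out_dir = withr::local_tempdir(),
                            seed = 4L)
  expect_named(conds, c("original", "synthetic", "augmentation-1",
                        "augmentation-2", "augmentation-3",
                        "original+synthetic"))
  for (m in conds) {
    expect_equal(nrow(m), 30L)
    expect_equal(class_counts(m)$n, c(10L, 10L, 10L))  # within 1 record
  }
  combined <- conds[["original+synthetic"]]
  expect_setequal(unique(combined$source), c("fixture", "synthetic"))

  missing_class <- downstream_synthetic()
  missing_class <- missing_class[missing_class$label != "class3", ]
  expect_error(build_conditions(downstream_original(), missing_class,
                                target_n = 30),
               class = "cytosynth_config_error")
})

test_that("largest-remainder allocation sums exactly to the target", {
  alloc <- cytosynth:::allocate_counts(rep(1 / 3, 3), 100)
  expect_equal(sum(alloc), 100L)
  expect_true(all(alloc %in% c(33L, 34L)))
  skewed <- cytosynth:::allocate_counts(c(0.5, 0.3, 0.2), 10)
  expect_equal(skewed, c(5L, 3L, 2L))
})

test_that("the classifier separates fixture classes and is deterministic", {
  m <- stratified_split(downstream_original(), split_spec(seed = 2L))
  train <- m[m$split %in% c("train", "val"), ]
  test <- m[m$split == "test", ]
  clf <- train_classifier(train, image_size = 16, epochs = 25, seed = 7L)
  expect_s3_class(clf, "cyto_classifier")
  pred <- predict(clf, test)
  expect_named(pred, c("label", sort(unique(train$label))))
  expect_gt(mean(pred$label == test$label), 0.9)

  clf2 <- train_classifier(train, image_size = 16, epochs = 25, seed = 7L)
  expect_identical(clf$history, clf2$history)

  expect_error(train_classifier(train, arch = "no-such-arch"),
               class = "cytosynth_config_error")
  one_class <- train[train$label == "class1", ]
  expect_error(train_classifier(one_class), class = "cytosynth_training_error")
})

test_that("registered architectures are pluggable", {
  m <- stratified_split(downstream_original(), split_spec(seed = 3L))
  clf <- train_classifier(m[m$split != "test", ], arch = "mlp",
                          image_size = 16, epochs = 5, seed = 1L)
  expect_equal(clf$arch, "mlp")

  register_classifier_arch("tiny-test-arch", function(n_classes, image_size) {
    list(cytosynth:::layer_simple("flatten"),
         cytosynth:::layer_dense(image_size^2 * 3L, n_classes))
  })
  clf2 <- train_classifier(m[m$split != "test", ], arch = "tiny-test-arch",
                           image_size = 16, epochs = 3, seed = 1L)
  expect_equal(clf2$arch, "tiny-test-arch")
})

test_that("compare_conditions reports every condition on the shared test set", {
  m <- stratified_split(downstream_original(), split_spec(seed = 5L))
  conds <- build_conditions(m, downstream_synthetic(), target_n = 60,
                            out_dir = withr::local_tempdir(), seed = 5L)
  report <- compare_conditions(conds, m[m$split == "test", ],
                               image_size = 16, epochs = 20, seed = 5L)
  expect_s3_class(report, "comparison_report")
  expect_setequal(report$summary$condition, names(conds))
  expect_true(all(report$summary$n_train == 60L))
  expect_true(all(report$summary$f1 >= 0 & report$summary$f1 <= 1))
  expect_true(all(c("condition", "label", "accuracy", "sensitivity",
                    "specificity", "precision") %in% names(report$per_class)))
  # sanity ceiling: training on the test distribution itself scores high
  expect_gt(report$summary$f1[report$summary$condition == "original"], 0.9)
})
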