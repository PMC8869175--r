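test_that("as_manifest fills defaults and validates columns", {
  m <- as_manifest(data.frame(path = "a.png", label = "basophil", source = "1"))
  expect_s3_class(m, "tbl_df")
  expect_named(m, c("id", "path", "label", "source", "split"))
  expect_equal(m$split, "unassigned")

  expect_error(as_manifest(data.frame(label = "x")),
               class = "cytosynth_format_error")
  expect_error(
    as_manifest(data.frame(path = "a", label = "x", source = "1",
                           split = "holdout")),
    class = "cytosynth_format_error")
})

test_that("manifest CSV round trip and multi-file loading re-keys records", {
  m <- as_manifest(tibble::tibble(path = c("a.png", "b.png"),
                                  label = c("x", "y"), source = "1"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, f1)
  write_manifest(m, f2)
  both <- load_manifest(c(f1, f2))
  expect_equal(nrow(both), 4L)
  expect_equal(anyDuplicated(both$id), 0L)

  expect_error(load_manifest(f1, taxonomy = default_merge_taxonomy(),
                             strict = TRUE),
               class = "cytosynth_taxonomy_error")
})

test_that("cell-family merging collapses 19 source labels into 12 families", {
  tax <- default_merge_taxonomy()
  expect_equal(length(taxonomy_labels(tax)), 19L)
  expect_equal(length(tax$groups), 12L)

  raw <- bone_marrow_manifest()
  merged <- merge_cell_types(raw, tax)
  expect_equal(nrow(merged), nrow(raw))          # merging conserves records
  expect_equal(length(unique(merged$label)), 12L)

  stray <- as_manifest(tibble::tibble(path = NA, label = "unknown_cell",
                                      source = "1"))
  expect_error(merge_cell_types(stray, tax), class = "cytosynth_taxonomy_error")
})

test_that("taxonomy YAML round trip preserves groups and passthrough", {
  tax <- default_merge_taxonomy()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_taxonomy(tax, f)
  back <- read_taxonomy(f)
  expect_equal(sort(taxonomy_labels(back)), sort(taxonomy_labels(tax)))
  expect_equal(cytosynth:::taxonomy_map(back)[taxonomy_labels(tax)],
               cytosynth:::taxonomy_map(tax)[taxonomy_labels(tax)])
})

test_that("dedupe drops byte-identical files and honours exclusions", {
  dir <- withr::local_tempdir()
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p1 <- file.path(dir, "one.png")
  p2 <- file.path(dir, "two.png")      # identical bytes
  p3 <- file.path(dir, "three.png")
  png::writePNG(img, p1)
  png::writePNG(img, p2)
  png::writePNG(array(runif(16 * 16 * 3), c(16, 16, 3)), p3)
  m <- as_manifest(tibble::tibble(path = c(p1, p2, p3), label = "x",
                                  source = "1"))
  d <- dedupe(m)
  expect_equal(nrow(d), 2L)
  expect_equal(nrow(dedupe(d)), 2L)    # idempotent

  d2 <- dedupe(m, exclusions = p3)
  expect_false(p3 %in% d2$path)
  expect_warning(dedupe(m, exclusions = "no-such-record"),
                 "unknown exclusion")
})

test_that("stratified split follows the 56/14/30 protocol per class", {
  m <- as_manifest(tibble::tibble(path = NA_character_,
                                  label = rep(c("a", "b"), c(100, 50)),
                                  source = "1"))
  s <- stratified_split(m, split_spec(seed = 4L))
  tab <- table(s$label, s$split)
  expect_equal(unname(tab["a", c("train", "val", "test")]), c(56, 14, 30))
  expect_equal(unname(tab["b", c("train", "val", "test")]), c(28, 7, 15))
  expect_equal(sum(tab), nrow(m))                 # partition: no losses

  # deterministic given the seed, different under another seed
  s2 <- stratified_split(m, split_spec(seed = 4L))
  expect_identical(s$split, s2$split)
  s3 <- stratified_split(m, split_spec(seed = 5L))
  expect_false(identical(s$split, s3$split))

  tiny <- as_manifest(tibble::tibble(path = NA, label = c("a", "a"),
                                     source = "1"))
  expect_error(stratified_split(tiny), class = "cytosynth_split_error")
  expect_error(split_spec(train_fraction = 0.7, test_fraction = 0.4),
               class = "cytosynth_config_error")
})

test_that("class deficits reach the target count", {
  m <- as_manifest(tibble::tibble(path = NA_character_,
                                  label = rep(c("a", "b", "c"), c(10, 4, 7)),
                                  source = "1"))
  d <- class_deficits(m, target = "max")
  expect_equal(d$deficit[order(d$label)], c(0L, 6L, 3L))
  d12 <- class_deficits(m, target = 12)
  expect_equal(d12$deficit[order(d12$label)], c(2L, 8L, 5L))
  expect_error(class_deficits(m, target = 5), class = "cytosynth_config_error")
})
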