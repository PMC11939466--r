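test_that("grid extraction enumerates origins and labels by coverage", {
  # single grid cell, no annotations -> one `others` signature
  img <- random_rgb(350, 350, seed = 1)
  sig <- extract_signatures(img, list(), patch_size = 350, stride = 350)
  expect_identical(nrow(sig), 1L)
  expect_equal(as.character(sig$label), "others")

  # 360 x 360, stride 10 -> origins (1,1), (1,11), (11,1), (11,11)
  img2 <- random_rgb(360, 360, seed = 2)
  sig2 <- extract_signatures(img2, list(), patch_size = 350, stride = 10)
  expect_identical(nrow(sig2), 4L)
  expect_setequal(paste(sig2$origin_row, sig2$origin_col),
                  c("1 1", "1 11", "11 1", "11 11"))
  expect_true(all(vapply(sig2$patch, function(p) all(dim(p) == c(350, 350, 3)),
                         TRUE)))

  # full-coverage mask labels the patch with its feature class
  ann <- list(list(feature_class = "irregular_stratification",
                   mask = matrix(TRUE, 350, 350)))
  sig3 <- extract_signatures(img, ann, patch_size = 350, stride = 350,
                             positive_fraction = 0.5)
  expect_equal(as.character(sig3$label), "irregular_stratification")
})

test_that("extraction count follows the grid formula", {
  for (dims in list(c(100, 130, 20, 15), c(64, 64, 32, 32), c(75, 50, 40, 7))) {
    img <- random_rgb(dims[1], dims[2], seed = sum(dims))
    sig <- extract_signatures(img, list(), patch_size = dims[3],
                              stride = dims[4])
    expect_identical(nrow(sig),
                     as.integer(((dims[1] - dims[3]) %/% dims[4] + 1) *
                                  ((dims[2] - dims[3]) %/% dims[4] + 1)))
  }
})

test_that("coverage ties go to the rarer bulbous class", {
  img <- random_rgb(40, 40, seed = 3)
  half_top <- matrix(FALSE, 40, 40); half_top[1:20, ] <- TRUE
  half_bot <- !half_top
  ann <- list(
    list(feature_class = "irregular_stratification", mask = half_top),
    list(feature_class = "bulbous_rete_ridge", mask = half_bot)
  )
  sig <- extract_signatures(img, ann, patch_size = 40, stride = 40,
                            positive_fraction = 0.5)
  expect_equal(as.character(sig$label), "bulbous_rete_ridge")
})

test_that("undersized images and malformed annotations error clearly", {
  img <- random_rgb(30, 30, seed = 4)
  expect_error(extract_signatures(img, list(), image_id = "tiny",
                                  patch_size = 50), "tiny")
  expect_error(extract_signatures(img, list(list(feature_class = "nope",
                                                 mask = matrix(TRUE, 30, 30))),
                                  patch_size = 30), "unknown feature class")
  expect_error(extract_signatures(img, list(list(
    feature_class = "bulbous_rete_ridge", mask = matrix(FALSE, 30, 30))),
    patch_size = 30), "foreground")
})

test_that("ambiguous-coverage cells can be excluded from a library", {
  img <- random_rgb(40, 40, seed = 9)
  m <- matrix(FALSE, 40, 40); m[1:14, ] <- TRUE   # 35% coverage
  ann <- list(list(feature_class = "irregular_stratification", mask = m))
  keep_all <- extract_signatures(img, ann, patch_size = 40, stride = 40)
  excluded <- extract_signatures(img, ann, patch_size = 40, stride = 40,
                                 ambiguous_band = c(0.2, 0.5))
  expect_identical(nrow(keep_all), 1L)
  expect_identical(nrow(excluded), 0L)
})

test_that("minority augmentation multiplies the target class only", {
  # the documented signature-library arithmetic: 607 bulbous -> 2428 under
  # all three transforms, and 6724 + 2634 + 607 -> 11786 in total
  lib <- signature_library(dummy_signatures(c(
    others = 50, irregular_stratification = 20, bulbous_rete_ridge = 607)))
  aug <- augment_minority(lib)
  expect_identical(unname(aug$class_counts["bulbous_rete_ridge"]), 2428L)
  expect_identical(unname(aug$class_counts["others"]), 50L)
  counts_607 <- c(6724, 2634, 607)
  expect_identical(sum(counts_607[1:2]) + 607 * 4, 11786)

  # single transform doubles; empty target class stays empty
  lib10 <- signature_library(dummy_signatures(c(
    others = 3, irregular_stratification = 3, bulbous_rete_ridge = 10)))
  aug1 <- augment_minority(lib10, kinds = "horizontal_flip")
  expect_identical(unname(aug1$class_counts["bulbous_rete_ridge"]), 20L)
  lib0 <- signature_library(dummy_signatures(c(
    others = 3, irregular_stratification = 3, bulbous_rete_ridge = 1)))
  aug0 <- augment_minority(lib0, target_label = "irregular_stratification",
                           kinds = "rotate_180")
  expect_identical(unname(aug0$class_counts["bulbous_rete_ridge"]), 1L)
  expect_error(augment_minority(lib0, target_label = "mystery"), "unknown")

  # augmented patches are the declared transforms of their originals
  b <- dplyr::filter(aug1$train, label == "bulbous_rete_ridge")
  orig <- dplyr::filter(b, is.na(augmentation))
  flip <- dplyr::filter(b, augmentation == "horizontal_flip")
  expect_identical(flip$patch[[1]],
                   apply_augmentation(orig$patch[[1]], "horizontal_flip"))
})

test_that("stratified folds partition the data with balanced labels", {
  sigs <- dummy_signatures(c(others = 60, irregular_stratification = 30,
                             bulbous_rete_ridge = 10))
  folds <- kfold_split(sigs, k = 4, seed = 7)
  expect_length(folds, 4L)
  test_sizes <- vapply(folds, function(f) nrow(f$test), 0L)
  expect_identical(sum(test_sizes), 100L)
  # disjoint test parts: keys appear exactly once
  key <- function(f) paste(f$test$origin_row, seq_len(nrow(f$test)))
  all_rows <- unlist(lapply(folds, function(f) nrow(f$test)))
  expect_identical(sum(all_rows), nrow(sigs))
  # per-fold label proportions within one signature of 15 / 7.5 / 2.5
  for (f in folds) {
    tab <- table(f$test$label)
    expect_lte(abs(tab[["others"]] - 15), 1)
    expect_lte(abs(tab[["irregular_stratification"]] - 7.5), 1)
    expect_lte(abs(tab[["bulbous_rete_ridge"]] - 2.5), 1)
  }
  # determinism
  folds2 <- kfold_split(sigs, k = 4, seed = 7)
  for (i in 1:4) expect_identical(folds[[i]]$test$label, folds2[[i]]$test$label)
  # k beyond the smallest class errors
  expect_error(kfold_split(sigs, k = 11, seed = 1), "smallest class")
})

test_that("train and test portions must come from different images", {
  a <- dummy_signatures(c(others = 2, irregular_stratification = 1,
                          bulbous_rete_ridge = 1), image_id = "shared")
  expect_error(signature_library(a, a), "share source images")
})

test_that("library manifest records provenance without pixels", {
  lib <- signature_library(dummy_signatures(c(others = 2,
                                              irregular_stratification = 1,
                                              bulbous_rete_ridge = 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_library_manifest(lib, path)
  man <- utils::read.csv(path)
  expect_identical(nrow(man), 4L)
  expect_true(all(c("image_id", "origin_row", "origin_col", "label",
                    "augmentation", "split") %in% names(man)))
})
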