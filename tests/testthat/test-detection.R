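# manual score-grid constructor for unit-testing the region logic
make_scores <- function(score_grid, origin_rows, origin_cols, window,
                        stride, image_dim) {
  structure(list(scores = score_grid, origin_rows = origin_rows,
                 origin_cols = origin_cols, window = window, stride = stride,
                 image_dim = image_dim),
            class = "oed_window_scores")
}

test_that("scanning lays out the window grid and renormalised scores", {
  slides <- list(generate_slide(tiny_synth_config(), index = 1))
  scorer <- oracle_scorer(slides)
  # image equal to one window -> a 1 x 1 grid
  img1 <- slides[[1]]$image[1:48, 1:48, , drop = FALSE]
  s1 <- scan_image(scorer, img1, stride = 10, window = 48)
  expect_identical(dim(s1$scores), c(1L, 1L, 3L))
  # grid dimensions follow floor((side - window) / stride) + 1
  img2 <- slides[[1]]$image[1:138, 1:138, , drop = FALSE]
  s2 <- scan_image(scorer, img2, stride = 10, window = 48)
  expect_identical(dim(s2$scores)[1:2], c(10L, 10L))
  # every score triplet sums to one
  sums <- apply(s2$scores, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, 100), tolerance = 1e-6)
  # undersized images are refused
  expect_error(scan_image(scorer, img1[1:30, , , drop = FALSE],
                          window = 48), "smaller than")
})

test_that("a trained model scans with probability outputs", {
  m <- tiny_trained_model()
  sl <- generate_slide(tiny_synth_config(seed = 77), index = 1)
  sc <- scan_image(m, sl$image[1:98, 1:98, , drop = FALSE], stride = 25)
  expect_identical(dim(sc$scores)[1:2], c(3L, 3L))
  expect_equal(as.vector(apply(sc$scores, c(1, 2), sum)), rep(1, 9),
               tolerance = 1e-6)
  tb <- tibble::as_tibble(sc)
  expect_identical(nrow(tb), 9L)
})

test_that("thresholded windows merge into 8-connected regions", {
  # two firing windows 400 px apart leave disjoint extents
  grid <- array(0, dim = c(1, 2, 3))
  grid[1, 1, 3] <- 0.9
  grid[1, 2, 3] <- 0.8
  sc <- make_scores(grid, origin_rows = 1L, origin_cols = c(1L, 401L),
                    window = 350L, stride = 400L, image_dim = c(350L, 800L))
  regs <- regions_at_threshold(sc, "bulbous_rete_ridge", 0.5)
  expect_identical(nrow(regs), 2L)
  expect_equal(regs$peak_score, c(0.9, 0.8))
  expect_identical(regs$col_min, c(1L, 401L))
  expect_identical(regs$col_max, c(350L, 750L))

  # threshold above 1 fires nothing
  expect_identical(nrow(regions_at_threshold(sc, "bulbous_rete_ridge", 1.1)),
                   0L)

  # threshold 0: every window fires; overlapping extents form one region
  grid2 <- array(runif(3 * 3 * 3), dim = c(3, 3, 3))
  sc2 <- make_scores(grid2, origin_rows = c(1L, 11L, 21L),
                     origin_cols = c(1L, 11L, 21L), window = 350L,
                     stride = 10L, image_dim = c(370L, 370L))
  regs2 <- regions_at_threshold(sc2, "irregular_stratification", 0)
  expect_identical(nrow(regs2), 1L)
  expect_identical(regs2$n_pixels, 370L * 370L)
})

test_that("coverage masks nest as the threshold rises", {
  set.seed(30)
  grid <- array(runif(5 * 5 * 3), dim = c(5, 5, 3))
  sc <- make_scores(grid, origin_rows = seq(1L, 41L, 10L),
                    origin_cols = seq(1L, 41L, 10L), window = 48L,
                    stride = 10L, image_dim = c(88L, 88L))
  prev <- NULL
  for (th in c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
    mk <- oedcnn:::coverage_mask(sc, "others", th)
    if (!is.null(prev)) expect_true(all(prev | !mk))  # mk subset of prev
    prev <- mk
  }
})

test_that("FROC evaluation counts detections and false positives", {
  cfg <- tiny_synth_config(seed = 33, n_images = 2)
  slides <- list(generate_slide(cfg, index = 1), generate_slide(cfg, index = 2))
  scorer <- oracle_scorer(slides)
  curve <- froc_evaluate(slides, scorer, thresholds = c(0.05, 0.2, 0.5, 0.9),
                         stride = 16, window = 48)
  expect_s3_class(curve, "oed_froc")
  # the oracle scores ground truth perfectly: full detection, no false
  # positives at a moderate threshold
  mid <- dplyr::filter(curve, threshold == 0.2)
  expect_equal(mid$prob_detection, rep(1, 2))
  expect_equal(mid$fp_per_image, rep(0, 2))
  # detection probability is monotone non-increasing in the threshold
  for (cl in unique(curve$feature_class)) {
    pd <- curve$prob_detection[curve$feature_class == cl]
    expect_true(all(diff(pd) <= 1e-12))
  }
  plt <- ggplot2::autoplot(curve)
  expect_s3_class(plt, "ggplot")
})

test_that("direct counting matches the stated detection rule", {
  # 1 image, 2 GT regions; 3 predicted regions of which 1 overlaps one GT
  pred <- matrix(0L, 20, 60)
  pred[1:5, 1:5] <- 1L; pred[1:5, 21:25] <- 2L; pred[1:5, 41:45] <- 3L
  gt <- matrix(0L, 20, 60)
  gt[3:8, 3:8] <- 1L; gt[15:18, 50:55] <- 2L
  mm <- oedcnn:::match_regions(pred, gt)
  expect_identical(length(mm$detected), 1L)   # prob_detection 0.5
  expect_identical(mm$fp, 2L)                 # 2 FP on the single image
  # IoU matching demands substantial overlap
  mm_iou <- oedcnn:::match_regions(pred, gt, match = "iou", iou = 0.9)
  expect_identical(length(mm_iou$detected), 0L)
})

test_that("a learned detector dominates a random scorer on blind slides", {
  m <- tiny_trained_model()
  cfg <- tiny_synth_config(seed = 91, n_images = 2)
  slides <- list(generate_slide(cfg, index = 1), generate_slide(cfg, index = 2))
  ths <- seq(0.1, 0.9, by = 0.2)
  curve_model <- froc_evaluate(slides, m, thresholds = ths, stride = 24)
  rnd <- local({
    counter <- 0
    function(patches) {
      counter <<- counter + length(patches)
      set.seed(counter)
      p <- matrix(runif(length(patches) * 3), ncol = 3)
      p / rowSums(p)
    }
  })
  curve_rand <- froc_evaluate(slides, rnd, thresholds = ths, stride = 24,
                              window = 48)
  expect_gte(mean(curve_model$prob_detection), mean(curve_rand$prob_detection))
})
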