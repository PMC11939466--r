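test_that("reference dilated convolution matches hand examples", {
  # all-ones 5x5 input, all-ones 3x3 kernel at dilation 2 samples 9 ones
  out <- atrous_convolve_reference(matrix(1, 5, 5), matrix(1, 3, 3), 2)
  expect_equal(out, matrix(9, 1, 1))
  # effective receptive field (w - 1) l + 1 = 5 with only 9 weights
  expect_identical((3 - 1) * 2 + 1, 5)
  expect_identical(length(matrix(1, 3, 3)), 9L)
  # dilation 1 equals standard valid cross-correlation (direct sum)
  set.seed(10)
  x <- matrix(rnorm(36), 6, 6); k <- matrix(rnorm(9), 3, 3)
  ref <- atrous_convolve_reference(x, k, 1)
  manual <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    manual[i, j] <- sum(x[i:(i + 2), j:(j + 2)] * k)
  }
  expect_equal(ref, manual, tolerance = 1e-12)
  # undersized input errors with the required minimum
  expect_error(atrous_convolve_reference(matrix(1, 4, 4), k, 2), "5 x 5")
})

test_that("batched convolution layers match the brute-force oracle", {
  set.seed(11)
  for (l in 1:3) {
    for (w in c(1L, 3L)) {
      if ((w - 1) * l + 1 > 9) next
      cin <- 2L; cout <- 3L
      x <- array(rnorm(9 * 9 * cin * 2), dim = c(9, 9, cin, 2))
      Wm <- matrix(rnorm(w * w * cin * cout), w * w * cin, cout)
      bias <- rnorm(cout)
      out <- oedcnn:::cpp_conv_fwd(x, Wm, bias, w, l)
      # oracle: per (sample, out-channel), sum of per-in-channel references
      for (n in 1:2) for (co in 1:cout) {
        acc <- 0
        for (ci in 1:cin) {
          kflat <- Wm[((ci - 1) * w * w + 1):(ci * w * w), co]
          kern <- matrix(kflat, w, w)   # (ki, kj) column-major
          acc <- acc + atrous_convolve_reference(x[, , ci, n], kern, l)
        }
        expect_equal(out[, , co, n], acc + bias[co], tolerance = 1e-5)
      }
    }
  }
})

test_that("global pooling matches brute force and the log-sum-exp bounds", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(global_pool(m, "GAP"), 2.5)
  expect_equal(global_pool(m, "GMP"), 4)
  expect_equal(global_pool(m, "GLSEP"), log(exp(1) + exp(2) + exp(3) + exp(4)))
  expect_equal(round(global_pool(m, "GLSEP"), 4), 4.4402)
  # constant map: GAP = GMP = c
  cmap <- matrix(2.71, 3, 5)
  expect_equal(global_pool(cmap, "GAP"), global_pool(cmap, "GMP"))

  set.seed(12)
  for (i in 1:50) {
    maps <- array(rnorm(4 * 5 * 3, sd = 3), dim = c(4, 5, 3))
    brute <- apply(maps, 3, function(h) {
      c(mean(h), max(h), log(sum(exp(h))))
    })
    expect_equal(global_pool(maps, "GAP"), brute[1, ], tolerance = 1e-9)
    expect_equal(global_pool(maps, "GMP"), brute[2, ], tolerance = 1e-9)
    expect_equal(global_pool(maps, "GLSEP"), brute[3, ], tolerance = 1e-9)
    # GMP <= GLSEP <= GMP + log(F1 F2)
    expect_true(all(brute[2, ] <= brute[3, ] + 1e-12))
    expect_true(all(brute[3, ] <= brute[2, ] + log(20) + 1e-12))
  }
  # max-shift stability: huge values do not overflow
  big <- matrix(c(1000, 1001, 999, 1000.5), 2, 2)
  expect_true(is.finite(global_pool(big, "GLSEP")))
  expect_gte(global_pool(big, "GLSEP"), 1001)
  expect_error(global_pool(array(0, dim = c(0, 2, 1))), "non-empty")
})

test_that("the proposed architecture counts 1,014,867 parameters", {
  cfg <- proposed_architecture()
  expect_identical(count_parameters(cfg), 1014867L)
  model <- build_network(cfg, seed = 1)
  expect_identical(model$n_params, 1014867L)
})

test_that("parameter counting follows the closed form on edge cases", {
  # classifier only: GAP on raw 3-channel input, h1 = 4 -> 3*4+4 + 4*3+3
  cfg0 <- arch_config(blocks = list(), global_pool = "GAP", hidden_width = 4,
                      input_side = 8)
  expect_identical(count_parameters(cfg0), 31L)
  expect_identical(build_network(cfg0, seed = 1)$n_params, 31L)
  # first block alone: 448 + 32 + 272 + 32 = 784 block parameters
  cfg1 <- arch_config(blocks = list(conv_block_config(16)), hidden_width = 4,
                      input_side = 8)
  head_params <- 16 * 4 + 4 + 4 * 3 + 3
  expect_identical(count_parameters(cfg1), 784L + as.integer(head_params))
  # dropping BN removes exactly 4 * sum(C_out)
  mk <- function(bn) arch_config(
    blocks = lapply(c(8L, 16L), conv_block_config, use_bn = bn),
    hidden_width = 4, input_side = 16)
  expect_identical(count_parameters(mk(TRUE)) - count_parameters(mk(FALSE)),
                   4L * (8L + 16L))
})

test_that("closed-form counts match built models across the design space", {
  archs <- ablation_architectures(input_side = 350)
  expect_identical(nrow(archs), 16L)
  for (i in seq_len(nrow(archs))) {
    cfg <- archs$config[[i]]
    expect_identical(build_network(cfg, seed = 2)$n_params,
                     count_parameters(cfg))
  }
})

test_that("shape inference reproduces the layer table", {
  sh <- infer_shapes(proposed_architecture())
  get <- function(stage) sh[sh$stage == stage, ]
  expect_equal(unlist(get("conv1")[, 2:4], use.names = FALSE), c(16, 348, 348))
  expect_equal(unlist(get("pool1")[, 2:4], use.names = FALSE), c(16, 174, 174))
  expect_equal(unlist(get("pool5")[, 2:4], use.names = FALSE), c(256, 9, 9))
  expect_equal(unlist(get("global_pool")[, 2:4], use.names = FALSE),
               c(256, 1, 1))
  # a 1x1 convolution leaves the side unchanged at any dilation
  cfg <- arch_config(blocks = list(conv_block_config(4, l1 = 1, w1 = 1,
                                                     l2 = 7, w2 = 1)),
                     hidden_width = 4, input_side = 10)
  sh2 <- infer_shapes(cfg)
  expect_equal(sh2$height[sh2$stage == "conv1"], 10)
  # shape underflow errors name the offending block
  expect_error(arch_config(blocks = lapply(c(4L, 8L), conv_block_config,
                                           l1 = 5L),
                           hidden_width = 4, input_side = 12), "block 2")
})

test_that("forward output is a probability vector and dropout is inactive at inference", {
  cfg <- tiny_arch()
  cfg$dropout_rate <- 0.5
  m <- build_network(cfg, seed = 3)
  patch <- random_rgb(48, 48, seed = 6)
  p1 <- predict(m, patch)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  # inference is deterministic despite the dropout rate: identity at eval
  expect_identical(p1, predict(m, patch))
  # training-mode forward with dropout differs across draws
  x <- oedcnn:::stack_patches(oedcnn:::prepare_patches(list(patch), cfg))
  set.seed(1); f1 <- oedcnn:::nn_forward(m, x, training = TRUE)$logits
  set.seed(2); f2 <- oedcnn:::nn_forward(m, x, training = TRUE)$logits
  expect_false(identical(f1, f2))
})
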