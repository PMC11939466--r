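#' Convolution-block configuration
#'
#' One block is `[w1 x w1 conv, dilation l1] -> (BN) -> ReLU ->
#' [w2 x w2 conv, dilation l2] -> (BN) -> ReLU -> 2x2 max pool (stride 2)`.
#' Both convolutions are valid (no padding) and carry bias terms; batch
#' normalisation, when enabled, carries affine scale and shift.
#'
#' @param out_channels number of output channels of both convolutions.
#' @param l1,l2 dilation factors of the first and second convolution.
#' @param w1,w2 kernel sides (odd, >= 1); defaults 3 and 1 (pointwise).
#' @param use_bn include batch normalisation after each convolution.
#' @return a `conv_block_config` list.
#' @export
conv_block_config <- function(out_channels, l1 = 1L, l2 = 1L,
                              w1 = 3L, w2 = 1L, use_bn = TRUE) {
  stopifnot(out_channels >= 1, l1 >= 1, l2 >= 1)
  if (w1 %% 2 == 0 || w2 %% 2 == 0 || w1 < 1 || w2 < 1) {
    abort("kernel sides must be odd and >= 1")
  }
  structure(list(out_channels = as.integer(out_channels),
                 l1 = as.integer(l1), l2 = as.integer(l2),
                 w1 = as.integer(w1), w2 = as.integer(w2),
                 use_bn = isTRUE(use_bn)),
            class = "conv_block_config")
}

#' Network architecture configuration
#'
#' The full hyperparameter tuple spanning the ablation design space:
#' dilations and kernel sides per block, batch normalisation, the global
#' pooling variant, the hidden width of the fully connected classifier, the
#' dropout rate and the colour space the network consumes.
#'
#' @param blocks list of [conv_block_config()]s, applied in order.
#' @param global_pool `"GAP"` (average), `"GMP"` (maximum) or `"GLSEP"`
#'   (log-sum-exp) reduction of the final feature maps.
#' @param hidden_width width of the fully connected hidden layer.
#' @param dropout_rate Bernoulli drop probability `p` in `[0, 1)`; dropped
#'   activations are compensated by `1/(1 - p)` during training and dropout
#'   is the identity at inference.
#' @param input_side input patch side in pixels.
#' @param in_channels input channels (3).
#' @param color_space `"YCbCr"` (patches are converted before the first
#'   convolution) or `"RGB"`.
#' @param rgb_scale scale convention handed to [rgb_to_ycbcr()] when
#'   `color_space = "YCbCr"`: `"unit"` (default) or `"8bit"`.  Note that
#'   under the unit scale the chroma planes vary by less than 1 around
#'   their 128 offset, which in the mixed-precision training mode is close
#'   to the half-float resolution at that magnitude; `"8bit"` restores
#'   headroom.
#' @return an `arch_config` list; validated so every spatial side stays
#'   positive through the blocks.
#' @export
arch_config <- function(blocks, global_pool = c("GAP", "GMP", "GLSEP"),
                        hidden_width = 2048L, dropout_rate = 0,
                        input_side = 350L, in_channels = 3L,
                        color_space = c("YCbCr", "RGB"),
                        rgb_scale = c("unit", "8bit")) {
  global_pool <- match.arg(global_pool)
  color_space <- match.arg(color_space)
  rgb_scale <- match.arg(rgb_scale)
  if (dropout_rate < 0 || dropout_rate >= 1) abort("`dropout_rate` must be in [0, 1)")
  stopifnot(hidden_width >= 1, input_side >= 1)
  cfg <- structure(list(blocks = blocks, global_pool = global_pool,
                        hidden_width = as.integer(hidden_width),
                        dropout_rate = dropout_rate,
                        input_side = as.integer(input_side),
                        in_channels = as.integer(in_channels),
                        num_classes = 3L, color_space = color_space,
                        rgb_scale = rgb_scale),
                   class = "arch_config")
  infer_shapes(cfg)   # errors on shape underflow
  cfg
}

#' The proposed five-block architecture
#'
#' Channel widths 16/32/64/128/256, all dilations 1, 3x3 + pointwise
#' convolutions with batch normalisation, global average pooling, hidden
#' width 2048, no dropout, YCbCr input of side 350.  This configuration has
#' 1,014,867 trainable parameters.
#'
#' @param input_side input patch side (default 350).
#' @return an `arch_config`.
#' @export
proposed_architecture <- function(input_side = 350L) {
  arch_config(
    blocks = lapply(c(16L, 32L, 64L, 128L, 256L), conv_block_config),
    global_pool = "GAP", hidden_width = 2048L, dropout_rate = 0,
    input_side = input_side, color_space = "YCbCr"
  )
}

#' A reduced-scale architecture for desk-scale training
#'
#' Three blocks (8/16/32 channels) on 96x96 patches with a 64-wide hidden
#' layer: the same layer grammar as the full network, small enough to train
#' on a CPU in minutes.
#'
#' @param input_side input patch side (default 96).
#' @param color_space colour space (default `"YCbCr"`).
#' @return an `arch_config`.
#' @export
reduced_architecture <- function(input_side = 96L, color_space = "YCbCr") {
  arch_config(
    blocks = lapply(c(8L, 16L, 32L), conv_block_config),
    global_pool = "GAP", hidden_width = 64L, dropout_rate = 0,
    input_side = input_side, color_space = color_space
  )
}

#' The 16-row ablation design space
#'
#' Enumerates the architecture variants of the component ablation: dilation
#' pairs, kernel sides, batch normalisation on/off, the three global pooling
#' variants, hidden widths 512/1024/2048/4096, dropout 0 or 0.5, and an RGB
#' variant.  Channel widths follow the standard doubling progression for
#' `n_blocks` blocks starting at 16.
#'
#' @param input_side input patch side (default 350).
#' @param n_blocks number of conv blocks (default 5).
#' @return a tibble with columns `id`, `l1`, `l2`, `w1`, `w2`, `bn`,
#'   `pool`, `h1`, `p`, `color_space` and a list column `config` of built
#'   [arch_config()] objects.
#' @export
ablation_architectures <- function(input_side = 350L, n_blocks = 5L) {
  rows <- tibble::tribble(
    ~l1, ~l2, ~w1, ~w2, ~bn,   ~pool,   ~h1,  ~p,  ~color_space,
    1L,  1L,  3L,  1L,  FALSE, "GAP",   1024L, 0,   "YCbCr",
    1L,  1L,  3L,  1L,  TRUE,  "GAP",   1024L, 0,   "YCbCr",
    1L,  1L,  3L,  1L,  TRUE,  "GMP",   1024L, 0,   "YCbCr",
    1L,  1L,  3L,  1L,  TRUE,  "GLSEP", 1024L, 0,   "YCbCr",
    2L,  1L,  3L,  3L,  TRUE,  "GAP",   1024L, 0,   "YCbCr",
    2L,  1L,  3L,  1L,  TRUE,  "GAP",   1024L, 0,   "YCbCr",
    2L,  1L,  3L,  1L,  FALSE, "GAP",   1024L, 0,   "YCbCr",
    3L,  1L,  3L,  1L,  TRUE,  "GAP",   1024L, 0,   "YCbCr",
    3L,  2L,  3L,  1L,  TRUE,  "GAP",   1024L, 0,   "YCbCr",
    1L,  1L,  3L,  1L,  TRUE,  "GAP",   1024L, 0.5, "YCbCr",
    1L,  1L,  3L,  1L,  TRUE,  "GAP",   512L,  0,   "YCbCr",
    1L,  1L,  3L,  1L,  TRUE,  "GAP",   2048L, 0,   "YCbCr",
    1L,  1L,  3L,  1L,  TRUE,  "GAP",   2048L, 0.5, "YCbCr",
    1L,  1L,  3L,  1L,  TRUE,  "GAP",   2048L, 0,   "RGB",
    1L,  1L,  3L,  1L,  TRUE,  "GAP",   4096L, 0,   "YCbCr",
    1L,  1L,  3L,  1L,  TRUE,  "GAP",   4096L, 0.5, "YCbCr"
  )
  channels <- 16L * 2L^(seq_len(n_blocks) - 1L)
  rows$id <- seq_len(nrow(rows))
  rows$config <- purrr::pmap(rows[, 1:9], function(l1, l2, w1, w2, bn, pool,
                                                   h1, p, color_space) {
    arch_config(
      blocks = lapply(channels, conv_block_config,
                      l1 = l1, l2 = l2, w1 = w1, w2 = w2, use_bn = bn),
      global_pool = pool, hidden_width = h1, dropout_rate = p,
      input_side = input_side, color_space = color_space
    )
  })
  dplyr::relocate(rows, "id")
}

#' Shape inference through the network
#'
#' Each valid convolution shrinks the spatial side by `(w - 1) * l`; each
#' 2x2 max pool halves it (floor).  Errors if any side would drop below 1,
#' naming the offending block.
#'
#' @param config an `arch_config`.
#' @return a tibble with columns `stage`, `channels`, `height`, `width`.
#' @export
infer_shapes <- function(config) {
  side <- config$input_side
  ch <- config$in_channels
  out <- list(tibble(stage = "input", channels = ch, height = side, width = side))
  for (i in seq_along(config$blocks)) {
    b <- config$blocks[[i]]
    for (conv in list(c(b$w1, b$l1), c(b$w2, b$l2))) {
      side <- side - (conv[1] - 1L) * conv[2]
      if (side < 1L) {
        abort(sprintf("block %d: spatial side underflows to %d", i, side))
      }
    }
    ch <- b$out_channels
    out[[length(out) + 1L]] <- tibble(stage = sprintf("conv%d", i),
                                      channels = ch, height = side, width = side)
    side <- side %/% 2L
    if (side < 1L) abort(sprintf("block %d: pooled side underflows", i))
    out[[length(out) + 1L]] <- tibble(stage = sprintf("pool%d", i),
                                      channels = ch, height = side, width = side)
  }
  out[[length(out) + 1L]] <- tibble(stage = "global_pool", channels = ch,
                                    height = 1L, width = 1L)
  dplyr::bind_rows(out)
}

#' Closed-form trainable-parameter count
#'
#' Per block: `w1^2 * C_in * C_out + C_out` (first conv + bias), `2 * C_out`
#' (BN scale/shift, if enabled), `w2^2 * C_out^2 + C_out`, `2 * C_out`;
#' then `M * h1 + h1` for the hidden layer and `h1 * 3 + 3` for the output.
#' Matches the built model's trainable tally exactly.
#'
#' @param config an `arch_config`.
#' @return integer parameter count.
#' @export
count_parameters <- function(config) {
  cin <- config$in_channels
  total <- 0
  for (b in config$blocks) {
    co <- b$out_channels
    total <- total + b$w1^2 * cin * co + co + b$w2^2 * co * co + co
    if (b$use_bn) total <- total + 4 * co
    cin <- co
  }
  m <- if (length(config$blocks)) cin else config$in_channels
  total <- total + m * config$hidden_width + config$hidden_width
  total <- total + config$hidden_width * config$num_classes + config$num_classes
  as.integer(total)
}

#' Reference dilated (a trous) convolution
#'
#' Direct-sum implementation of the dilated cross-correlation
#' `(f *_l w)(p) = sum_t f(p + l t) w(t)` (kernels are not flipped) with no
#' padding: a `w x w` kernel at dilation `l` has an effective receptive
#' field of side `(w - 1) * l + 1` but only `w^2` free weights, and the
#' output side is `input side - (w - 1) * l`.  At `l = 1` this is the
#' standard valid cross-correlation.  Deliberately naive: it is the oracle
#' the fast batched layers are tested against.
#'
#' @param input numeric matrix.
#' @param kernel numeric `w x w` matrix.
#' @param dilation integer `l >= 1`.
#' @return numeric matrix of the valid-output size.
#' @export
atrous_convolve_reference <- function(input, kernel, dilation = 1L) {
  w <- nrow(kernel)
  stopifnot(w == ncol(kernel), dilation >= 1)
  eff <- (w - 1L) * dilation + 1L
  if (nrow(input) < eff || ncol(input) < eff) {
    abort(sprintf("input must be at least %d x %d for a %d x %d kernel at dilation %d",
                  eff, eff, w, w, dilation))
  }
  ho <- nrow(input) - eff + 1L
  wo <- ncol(input) - eff + 1L
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) {
    for (j in seq_len(wo)) {
      acc <- 0
      for (ki in seq_len(w)) {
        for (kj in seq_len(w)) {
          acc <- acc + input[i + (ki - 1L) * dilation,
                             j + (kj - 1L) * dilation] * kernel[ki, kj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

#' Global pooling of feature maps
#'
#' Reduces each of the `M` feature maps to a scalar: the mean (`GAP`), the
#' maximum (`GMP`) or the log-sum-exp (`GLSEP`,
#' `log sum_ij exp h_ij`, computed max-shifted for numerical stability).
#' For any map, `GMP <= GLSEP <= GMP + log(F1 * F2)`.
#'
#' @param maps numeric array `F1 x F2 x M` (or a single matrix for `M = 1`).
#' @param variant `"GAP"`, `"GMP"` or `"GLSEP"`.
#' @return numeric vector of length `M`.
#' @export
global_pool <- function(maps, variant = c("GAP", "GMP", "GLSEP")) {
  variant <- match.arg(variant)
  if (is.matrix(maps)) maps <- array(maps, dim = c(dim(maps), 1L))
  stopifnot(is.array(maps), length(dim(maps)) == 3L)
  if (any(dim(maps)[1:2] < 1L)) abort("feature maps must be non-empty")
  m <- matrix(maps, nrow = prod(dim(maps)[1:2]))
  switch(variant,
    GAP = colMeans(m),
    GMP = apply(m, 2L, max),
    GLSEP = {
      mx <- apply(m, 2L, max)
      mx + log(colSums(exp(sweep(m, 2L, mx, "-"))))
    }
  )
}
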