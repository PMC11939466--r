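# Model construction and the forward/backward passes.
#
# Parameters live in a flat named list (matrices/vectors); the optimizer
# walks that list.  Batches are 4-D arrays dim c(H, W, C, N).  The heavy
# kernels (dilated conv, max pool) are C++; batch norm, ReLU, pooling heads
# and the dense classifier are vectorised R.

#' Build a trainable network from an architecture configuration
#'
#' Initialises all weights (He-normal for convolutions and dense layers,
#' unit scale / zero shift for batch normalisation, zero biases) and
#' returns a model handle.  The trainable-parameter tally always equals
#' [count_parameters()] of the same configuration.
#'
#' @param config an [arch_config()].
#' @param seed integer seed for the weight initialisation.
#' @return an object of class `oed_cnn`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "arch_config"))
  infer_shapes(config)  # validate
  params <- list()
  state <- list()
  with_local_seed(seed, {
    cin <- config$in_channels
    for (i in seq_along(config$blocks)) {
      b <- config$blocks[[i]]
      co <- b$out_channels
      for (half in 1:2) {
        w <- if (half == 1) b$w1 else b$w2
        ci <- if (half == 1) cin else co
        fan_in <- w * w * ci
        params[[sprintf("b%d_conv%d_W", i, half)]] <-
          matrix(rnorm(fan_in * co, sd = sqrt(2 / fan_in)), fan_in, co)
        params[[sprintf("b%d_conv%d_b", i, half)]] <- numeric(co)
        if (b$use_bn) {
          params[[sprintf("b%d_bn%d_g", i, half)]] <- rep(1, co)
          params[[sprintf("b%d_bn%d_be", i, half)]] <- numeric(co)
          state[[sprintf("b%d_bn%d", i, half)]] <-
            list(mean = numeric(co), var = numeric(co), n_updates = 0L,
                 frozen = FALSE)
        }
      }
      cin <- co
    }
    m <- cin
    params$head_W1 <- matrix(rnorm(m * config$hidden_width,
                                   sd = sqrt(2 / m)), m, config$hidden_width)
    params$head_b1 <- numeric(config$hidden_width)
    params$head_W2 <- matrix(rnorm(config$hidden_width * config$num_classes,
                                   sd = sqrt(2 / config$hidden_width)),
                             config$hidden_width, config$num_classes)
    params$head_b2 <- numeric(config$num_classes)
  })
  structure(list(config = config, params = params, bn_state = state,
                 n_params = sum(vapply(params, length, 0L)),
                 trained = FALSE, history = NULL),
            class = "oed_cnn")
}

#' @export
print.oed_cnn <- function(x, ...) {
  cat(sprintf("CNN dysplasia classifier: %d conv block(s), %s, h1 = %d, p = %g, %s input\n",
              length(x$config$blocks), x$config$global_pool,
              x$config$hidden_width, x$config$dropout_rate,
              x$config$color_space))
  cat(sprintf("  input %d x %d, %s trainable parameters, %s\n",
              x$config$input_side, x$config$input_side,
              format(x$n_params, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# batch norm over a 4-D array, statistics per channel across (H, W, N)
bn_forward <- function(x, g, be, st, training) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- matrix(x, nrow = hw)                 # columns indexed (c, n)
  if (training) {
    s1 <- .colSums(m, hw, C * N); s2 <- .colSums(m * m, hw, C * N)
    cnt <- hw * N
    mu <- .rowSums(matrix(s1, C, N), C, N) / cnt
    vv <- .rowSums(matrix(s2, C, N), C, N) / cnt - mu^2
    vv <- pmax(vv, 0)
    st$mean <- (1 - .bn_momentum) * st$mean + .bn_momentum * mu
    st$var <- (1 - .bn_momentum) * st$var + .bn_momentum * vv
    st$n_updates <- st$n_updates + 1L
    st$frozen <- FALSE
  } else if (isTRUE(st$frozen)) {
    # population statistics from a frozen-weight calibration pass
    mu <- st$mean; vv <- st$var
  } else if (st$n_updates > 0L) {
    # the running stats are exponential moving averages initialised at
    # zero; debias by the accumulated EMA weight so short runs are unbiased
    bias <- 1 - (1 - .bn_momentum)^st$n_updates
    mu <- st$mean / bias
    vv <- st$var / bias
  } else {
    mu <- numeric(length(g)); vv <- rep(1, length(g))
  }
  istd <- 1 / sqrt(vv + .bn_eps)
  xhat <- (m - rep(rep(mu, N), each = hw)) * rep(rep(istd, N), each = hw)
  y <- xhat * rep(rep(g, N), each = hw) + rep(rep(be, N), each = hw)
  dim(y) <- d
  list(out = y, xhat = xhat, istd = istd, state = st, mu = mu, vv = vv,
       n_elem = hw * N)
}

bn_backward <- function(dout, cache, g) {
  d <- dim(dout); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dm <- matrix(dout, nrow = hw)
  xhat <- cache$xhat
  cnt <- hw * N
  per_ch <- function(v) .rowSums(matrix(.colSums(v, hw, C * N), C, N), C, N)
  dg <- per_ch(dm * xhat)
  dbe <- per_ch(dm)
  dxhat <- dm * rep(rep(g, N), each = hw)
  t1 <- per_ch(dxhat)
  t2 <- per_ch(dxhat * xhat)
  dx <- (dxhat - rep(rep(t1 / cnt, N), each = hw) -
           xhat * rep(rep(t2 / cnt, N), each = hw)) *
    rep(rep(cache$istd, N), each = hw)
  dim(dx) <- d
  list(dx = dx, dg = dg, dbe = dbe)
}

# global pooling over a 4-D array -> features N x M (plus backward cache)
gpool_forward <- function(x, variant) {
  d <- dim(x); hw <- d[1] * d[2]; M <- d[3]; N <- d[4]
  m <- matrix(x, nrow = hw)
  cache <- list(dim = d)
  feat <- switch(variant,
    GAP = .colMeans(m, hw, M * N),
    GMP = {
      idx <- max.col(t(m), ties.method = "first")
      cache$idx <- idx
      m[cbind(idx, seq_len(M * N))]
    },
    GLSEP = {
      mx <- m[cbind(max.col(t(m), ties.method = "first"), seq_len(M * N))]
      sm <- exp(m - rep(mx, each = hw))
      z <- .colSums(sm, hw, M * N)
      cache$softmax <- sm / rep(z, each = hw)
      mx + log(z)
    }
  )
  list(out = t(matrix(feat, M, N)), cache = cache)   # N x M
}

gpool_backward <- function(dfeat, variant, cache) {
  d <- cache$dim; hw <- d[1] * d[2]
  dcol <- as.vector(t(dfeat))                        # length M*N, (m, n) order
  dx <- switch(variant,
    GAP = matrix(rep(dcol / hw, each = hw), nrow = hw),
    GMP = {
      z <- matrix(0, hw, length(dcol))
      z[cbind(cache$idx, seq_along(dcol))] <- dcol
      z
    },
    GLSEP = cache$softmax * rep(dcol, each = hw)
  )
  dim(dx) <- d
  dx
}

# Forward pass.  `quantize` is applied to every layer output (the
# mixed-precision hook); `identity` in full precision.
nn_forward <- function(model, x, training = FALSE, quantize = identity,
                       keep_cache = training, collect_bn = NULL) {
  cfg <- model$config
  p <- model$params
  cache <- list(blocks = vector("list", length(cfg$blocks)))
  for (i in seq_along(cfg$blocks)) {
    b <- cfg$blocks[[i]]
    bc <- list()
    for (half in 1:2) {
      w <- if (half == 1) b$w1 else b$w2
      l <- if (half == 1) b$l1 else b$l2
      key <- function(s) sprintf("b%d_%s%d", i, s, half)
      if (keep_cache) bc[[sprintf("x%d", half)]] <- x
      x <- quantize(cpp_conv_fwd(x, p[[paste0(key("conv"), "_W")]],
                                 p[[paste0(key("conv"), "_b")]], w, l))
      if (b$use_bn) {
        bn <- bn_forward(x, p[[paste0(key("bn"), "_g")]],
                         p[[paste0(key("bn"), "_be")]],
                         model$bn_state[[key("bn")]], training)
        if (training) model$bn_state[[key("bn")]] <- bn$state
        if (!is.null(collect_bn)) {
          k <- key("bn")
          acc <- collect_bn[[k]]
          if (is.null(acc)) acc <- list(s1 = 0, s2 = 0, n = 0)
          acc$s1 <- acc$s1 + bn$mu * bn$n_elem
          acc$s2 <- acc$s2 + (bn$vv + bn$mu^2) * bn$n_elem
          acc$n <- acc$n + bn$n_elem
          collect_bn[[k]] <- acc
        }
        x <- quantize(bn$out)
        if (keep_cache) bc[[sprintf("bn%d", half)]] <- bn[c("xhat", "istd")]
      }
      mask <- x > 0
      x <- x * mask
      if (keep_cache) bc[[sprintf("relu%d", half)]] <- mask
    }
    if (keep_cache) bc$prepool_dim <- dim(x)
    mp <- cpp_maxpool_fwd(x)
    x <- mp$out
    if (keep_cache) bc$amax <- mp$amax
    cache$blocks[[i]] <- bc
  }
  gp <- gpool_forward(x, cfg$global_pool)
  feat <- quantize(gp$out)                            # N x M
  cache$gpool <- gp$cache
  cache$feat <- feat
  h_pre <- feat %*% p$head_W1 + rep(p$head_b1, each = nrow(feat))
  hmask <- h_pre > 0
  h <- quantize(h_pre * hmask)
  cache$hmask <- hmask
  if (training && cfg$dropout_rate > 0) {
    keep <- matrix(runif(length(h)) >= cfg$dropout_rate, nrow(h), ncol(h))
    h <- h * keep / (1 - cfg$dropout_rate)
    cache$dropout <- keep
  }
  cache$h <- h
  logits <- h %*% p$head_W2 + rep(p$head_b2, each = nrow(h))
  list(logits = quantize(logits), cache = if (keep_cache) cache,
       model = model)
}

# Backward pass from d(loss)/d(logits); returns gradients named like params.
nn_backward <- function(model, dlogits, cache, quantize = identity) {
  cfg <- model$config
  p <- model$params
  g <- list()
  g$head_W2 <- crossprod(cache$h, dlogits)
  g$head_b2 <- colSums(dlogits)
  dh <- quantize(dlogits %*% t(p$head_W2))
  if (!is.null(cache$dropout)) {
    dh <- dh * cache$dropout / (1 - cfg$dropout_rate)
  }
  dh <- dh * cache$hmask
  g$head_W1 <- crossprod(cache$feat, dh)
  g$head_b1 <- colSums(dh)
  dfeat <- quantize(dh %*% t(p$head_W1))
  dx <- gpool_backward(dfeat, cfg$global_pool, cache$gpool)
  for (i in rev(seq_along(cfg$blocks))) {
    b <- cfg$blocks[[i]]
    bc <- cache$blocks[[i]]
    dx <- cpp_maxpool_bwd(dx, bc$amax, bc$prepool_dim[1], bc$prepool_dim[2])
    for (half in 2:1) {
      w <- if (half == 1) b$w1 else b$w2
      l <- if (half == 1) b$l1 else b$l2
      key <- function(s) sprintf("b%d_%s%d", i, s, half)
      dx <- dx * bc[[sprintf("relu%d", half)]]
      if (b$use_bn) {
        bn <- bn_backward(dx, bc[[sprintf("bn%d", half)]],
                          p[[paste0(key("bn"), "_g")]])
        g[[paste0(key("bn"), "_g")]] <- bn$dg
        g[[paste0(key("bn"), "_be")]] <- bn$dbe
        dx <- bn$dx
      }
      cv <- cpp_conv_bwd(bc[[sprintf("x%d", half)]],
                         p[[paste0(key("conv"), "_W")]], dx, w, l)
      g[[paste0(key("conv"), "_W")]] <- cv$dW
      g[[paste0(key("conv"), "_b")]] <- cv$db
      dx <- quantize(cv$dx)
    }
  }
  g
}

# stack a list of H x W x C patches into a 4-D batch array
stack_patches <- function(patches) {
  d <- dim(patches[[1]])
  array(unlist(patches, use.names = FALSE), dim = c(d, length(patches)))
}

# colour conversion as configured, applied to a list of RGB patches
prepare_patches <- function(patches, config) {
  if (config$color_space == "YCbCr") {
    scale <- if (is.null(config$rgb_scale)) "unit" else config$rgb_scale
    patches <- lapply(patches, rgb_to_ycbcr, rgb_scale = scale)
  }
  patches
}

#' Predict class probabilities for image patches
#'
#' Patches are RGB in `[0, 1]`; colour conversion to the network's
#' configured space happens internally.  Inference runs with batch-norm
#' running statistics and dropout disabled, and ends in a softmax, so each
#' row of the returned matrix is a probability vector over
#' `others`, `irregular_stratification`, `bulbous_rete_ridge`.
#'
#' @param object an `oed_cnn`.
#' @param patches a list of `side x side x 3` arrays, or a single such
#'   array, or a 4-D batch array.
#' @param type `"prob"` for the `N x 3` probability matrix, `"class"` for a
#'   factor of predicted labels.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return matrix or factor, by `type`.
#' @export
predict.oed_cnn <- function(object, patches, type = c("prob", "class"),
                            batch_size = 32L, ...) {
  type <- match.arg(type)
  if (is.array(patches) && length(dim(patches)) == 3L) patches <- list(patches)
  if (is.array(patches) && length(dim(patches)) == 4L) {
    patches <- lapply(seq_len(dim(patches)[4]),
                      function(i) patches[, , , i, drop = TRUE])
  }
  patches <- prepare_patches(patches, object$config)
  n <- length(patches)
  probs <- matrix(NA_real_, n, 3L, dimnames = list(NULL, oed_classes()))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- stack_patches(patches[idx])
    logits <- nn_forward(object, x, training = FALSE, keep_cache = FALSE)$logits
    probs[idx, ] <- softmax_rows(logits)
  }
  if (type == "class") {
    factor(oed_classes()[max.col(probs, ties.method = "first")],
           levels = oed_classes())
  } else {
    probs
  }
}

softmax_rows <- function(logits) {
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}
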