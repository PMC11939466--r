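#' Inverse-frequency class weights
#'
#' Weights are inversely proportional to the per-class sample counts,
#' `w_c` proportional to `1 / n_c`.  Under the default normalisation the
#' weights are rescaled so they sum to the number of classes (equal counts
#' then give unit weights); any positive rescaling only multiplies the loss
#' by a constant.
#'
#' @param class_counts named or unnamed vector of positive per-class counts.
#' @param normalization `"sum_c"` (default, weights sum to `C`) or `"none"`
#'   (raw `1 / n_c`).
#' @return numeric vector of positive weights, names preserved.
#' @export
compute_class_weights <- function(class_counts,
                                  normalization = c("sum_c", "none")) {
  normalization <- match.arg(normalization)
  counts <- as.numeric(class_counts)
  if (any(!is.finite(counts)) || any(counts < 1)) {
    abort("all class counts must be >= 1")
  }
  w <- 1 / counts
  if (normalization == "sum_c") w <- w * length(w) / sum(w)
  names(w) <- names(class_counts)
  w
}

#' Weighted cross-entropy loss
#'
#' Per-sample loss `l_n = -w_{y_n} log softmax(x_n)_{y_n}`, evaluated on
#' unnormalised logits through the log-sum-exp identity
#' `l_n = w_{y_n} (logsumexp(x_n) - x_{n, y_n})` for numerical stability.
#' With unit weights this is the standard cross-entropy.
#'
#' @param logits numeric matrix `N x C` (or a single `C`-vector).
#' @param target integer class indices in `1..C`, length `N`.
#' @param weights positive per-class weights of length `C` (default unit).
#' @return numeric vector of `N` per-sample losses.
#' @export
weighted_cross_entropy <- function(logits, target, weights = NULL) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1L)
  if (any(!is.finite(logits))) abort("logits must be finite")
  C <- ncol(logits)
  if (is.null(weights)) weights <- rep(1, C)
  stopifnot(length(weights) == C, all(weights > 0),
            length(target) == nrow(logits), all(target >= 1), all(target <= C))
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  weights[target] * (lse - logits[cbind(seq_len(nrow(logits)), target)])
}

#' Training configuration
#'
#' @param epochs number of passes over the training signatures.
#' @param batch_size minibatch size.
#' @param initial_lr initial learning rate (default `1e-3`).
#' @param lr_halving_period epochs between halvings of the learning rate
#'   (default 50).
#' @param seed master seed: drives weight initialisation, shuffling,
#'   dropout masks and fold assignment.
#' @param precision `"full_32"` or `"mixed_16_32"`; the mixed mode computes
#'   forward and backward activations at emulated half precision and keeps
#'   master weights and optimiser state in full precision.
#' @param optimizer optimiser name; `"adam"` (adaptive moment estimation)
#'   is the only built-in.
#' @param early_stop_acc stop early once training accuracy reaches this
#'   value (fraction; `Inf` disables).
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 200L, batch_size = 32L,
                            initial_lr = 1e-3, lr_halving_period = 50L,
                            seed = 1L, precision = c("full_32", "mixed_16_32"),
                            optimizer = "adam", early_stop_acc = Inf) {
  precision <- match.arg(precision)
  stopifnot(initial_lr > 0, lr_halving_period >= 1, epochs >= 0,
            batch_size >= 1, optimizer == "adam")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_halving_period = as.integer(lr_halving_period),
                 seed = as.integer(seed), precision = precision,
                 optimizer = optimizer, early_stop_acc = early_stop_acc),
            class = "training_config")
}

#' Learning rate at an epoch
#'
#' The stepped halving schedule `initial_lr * 0.5^floor(epoch / period)`:
#' `1e-3` for epochs 0--49, `5e-4` for 50--99, and so on under the
#' defaults.  Epochs are 0-based.
#'
#' @param epoch 0-based epoch index.
#' @param config a [training_config()].
#' @return the learning rate.
#' @export
lr_at_epoch <- function(epoch, config = training_config()) {
  stopifnot(all(epoch >= 0))
  config$initial_lr * 0.5^(epoch %/% config$lr_halving_period)
}

half_quantize <- function(x) {
  out <- cpp_round_half(as.numeric(x))
  attributes(out) <- attributes(x)
  out
}

#' Train a network on labelled signatures
#'
#' Minimises the class-weighted cross-entropy with Adam under the stepped
#' halving learning-rate schedule.  Weights default to inverse class
#' frequency computed from the training labels.  All randomness (shuffling,
#' dropout) is driven by `train_cfg$seed`, so identical data, configuration
#' and seed reproduce the run exactly.
#'
#' @param model an `oed_cnn` from [build_network()].
#' @param signatures training signature tibble (columns `patch`, `label`).
#' @param train_cfg a [training_config()].
#' @param class_weights optional per-class weights (length 3); computed
#'   from the label counts when `NULL`.
#' @param validation optional signature tibble evaluated each epoch.
#' @param verbose print per-epoch progress.
#' @return the trained `oed_cnn`, with a `history` tibble
#'   (`epoch`, `lr`, `train_loss`, `train_accuracy`, `val_accuracy`).
#' @export
train_network <- function(model, signatures, train_cfg = training_config(),
                          class_weights = NULL, validation = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(model, "oed_cnn"))
  y <- as.integer(signatures$label)
  if (anyNA(y)) abort("signatures carry labels outside the three classes")
  counts <- tabulate(y, nbins = 3L)
  if (is.null(class_weights)) {
    class_weights <- compute_class_weights(pmax(counts, 1L))
    class_weights[counts == 0L] <- 0  # absent class cannot be weighted
    if (any(counts == 0L)) {
      warn("some classes are absent from the training signatures")
    }
  }
  patches <- prepare_patches(signatures$patch, model$config)
  quantize <- if (train_cfg$precision == "mixed_16_32") half_quantize else identity
  n <- length(patches)

  adam <- list(m = lapply(model$params, function(p) p * 0),
               v = lapply(model$params, function(p) p * 0), t = 0L)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  hist <- vector("list", train_cfg$epochs)

  with_local_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs) - 1L) {
      lr <- lr_at_epoch(epoch, train_cfg)
      ord <- sample.int(n)
      ep_loss <- 0; ep_hit <- 0
      for (start in seq(1L, n, by = train_cfg$batch_size)) {
        idx <- ord[start:min(start + train_cfg$batch_size - 1L, n)]
        x <- stack_patches(patches[idx])
        if (train_cfg$precision == "mixed_16_32") x <- half_quantize(x)
        fw <- nn_forward(model, x, training = TRUE, quantize = quantize)
        model <- fw$model
        logits <- fw$logits
        yb <- y[idx]
        losses <- weighted_cross_entropy(logits, yb, class_weights)
        probs <- softmax_rows(logits)
        onehot <- matrix(0, length(idx), 3L)
        onehot[cbind(seq_along(idx), yb)] <- 1
        dlogits <- (probs - onehot) * class_weights[yb] / length(idx)
        grads <- nn_backward(model, dlogits, fw$cache, quantize = quantize)
        adam$t <- adam$t + 1L
        corr <- sqrt(1 - beta2^adam$t) / (1 - beta1^adam$t)
        for (k in names(grads)) {
          gk <- grads[[k]]                 # gradients back to full precision
          adam$m[[k]] <- beta1 * adam$m[[k]] + (1 - beta1) * gk
          adam$v[[k]] <- beta2 * adam$v[[k]] + (1 - beta2) * gk * gk
          model$params[[k]] <- model$params[[k]] -
            lr * corr * adam$m[[k]] / (sqrt(adam$v[[k]]) + eps)
        }
        ep_loss <- ep_loss + sum(losses)
        ep_hit <- ep_hit + sum(max.col(probs, ties.method = "first") == yb)
      }
      val_acc <- NA_real_
      if (!is.null(validation)) {
        model <- calibrate_bn_stats(model, patches, train_cfg$batch_size)
        pred <- predict(model, validation$patch, type = "class")
        val_acc <- mean(pred == validation$label)
      }
      hist[[epoch + 1L]] <- tibble(epoch = epoch, lr = lr,
                                   train_loss = ep_loss / n,
                                   train_accuracy = ep_hit / n,
                                   val_accuracy = val_acc)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.3f%s",
                        epoch, lr, ep_loss / n, ep_hit / n,
                        if (is.na(val_acc)) "" else sprintf("  val %.3f", val_acc)))
      }
      if (ep_hit / n >= train_cfg$early_stop_acc) break
    }
    model <- calibrate_bn_stats(model, patches, train_cfg$batch_size)
  })
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model$train_cfg <- train_cfg
  model$class_weights <- class_weights
  model
}

# Recompute batch-norm population statistics with frozen weights: one
# forward sweep over the (colour-converted) training patches accumulating
# exact per-channel means and variances at every BN layer.  Short training
# runs need this because the running averages lag the weight updates, and
# the feature means here are orders of magnitude larger than their spreads
# (the YCbCr offsets propagate through the convolutions), so even a small
# lag misnormalises the features at inference.
calibrate_bn_stats <- function(model, patches, batch_size = 32L) {
  if (!length(model$bn_state)) return(model)
  env <- new.env(parent = emptyenv())
  calib <- model
  calib$config$dropout_rate <- 0   # statistics pass: no dropout
  n <- length(patches)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- stack_patches(patches[idx])
    nn_forward(calib, x, training = TRUE, keep_cache = FALSE,
               collect_bn = env)
  }
  for (k in names(model$bn_state)) {
    acc <- env[[k]]
    if (is.null(acc)) next
    mu <- acc$s1 / acc$n
    model$bn_state[[k]]$mean <- mu
    model$bn_state[[k]]$var <- pmax(acc$s2 / acc$n - mu^2, 0)
    model$bn_state[[k]]$frozen <- TRUE
  }
  model
}

#' Classification metrics from a confusion table
#'
#' Rows are true classes, columns predicted.  Per-class precision, recall
#' and F1 are combined by support-weighted averaging (weights proportional
#' to the true-class counts); accuracy is the trace over the total.  Under
#' support weighting the averaged recall is identically the accuracy.
#' All four metrics are returned as percentages.
#'
#' @param confusion square numeric matrix of non-negative counts.
#' @return a one-row tibble: `accuracy`, `f1`, `precision`, `recall`
#'   (percent), `n`, and the confusion matrix in the list column
#'   `confusion`.
#' @export
evaluate_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!nrow(confusion) || nrow(confusion) != ncol(confusion) ||
      any(confusion < 0)) {
    abort("`confusion` must be a non-empty square matrix of counts")
  }
  total <- sum(confusion)
  if (total == 0) abort("`confusion` is empty")
  support <- rowSums(confusion)
  pred_tot <- colSums(confusion)
  tp <- diag(confusion)
  prec_c <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  wts <- support / total
  tibble(
    accuracy = 100 * sum(tp) / total,
    f1 = 100 * sum(wts * f1_c),
    precision = 100 * sum(wts * prec_c),
    recall = 100 * sum(wts * rec_c),
    n = as.integer(total),
    confusion = list(confusion)
  )
}

confusion_matrix <- function(truth, pred) {
  lv <- oed_classes()
  table(factor(truth, levels = lv), factor(pred, levels = lv))
}

#' Stratified k-fold cross-validation of an architecture
#'
#' Splits the library's training signatures into `k` stratified folds
#' ([kfold_split()]), trains one network per fold on the other `k - 1`
#' chunks and evaluates it on the held-out chunk, with inverse-frequency
#' class weights recomputed per fold.
#'
#' @param library a `signature_library` (its training portion is used).
#' @param arch an [arch_config()].
#' @param train_cfg a [training_config()]; its `seed` drives fold
#'   assignment and every per-fold run.
#' @param k number of folds (default 4).
#' @param keep_models retain the `k` trained models in the result.
#' @param verbose print progress.
#' @return an `oed_cv` object: tibble of per-fold metrics with attributes
#'   `mean_accuracy` and `sd_accuracy`; see [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
cross_validate <- function(library, arch, train_cfg = training_config(),
                           k = 4L, keep_models = FALSE, verbose = FALSE) {
  folds <- kfold_split(library, k = k, seed = train_cfg$seed)
  models <- list()
  rows <- purrr::imap(folds, function(fold, i) {
    present <- table(droplevels(fold$train$label))
    if (length(setdiff(unique(as.character(fold$test$label)),
                       names(present)))) {
      abort(sprintf("fold %d: a test class is absent from its training chunk", i))
    }
    cfg_i <- train_cfg
    cfg_i$seed <- train_cfg$seed + i
    model <- build_network(arch, seed = cfg_i$seed)
    model <- train_network(model, fold$train, cfg_i, verbose = verbose)
    if (keep_models) models[[i]] <<- model
    pred <- predict(model, fold$test$patch, type = "class")
    met <- evaluate_metrics(confusion_matrix(fold$test$label, pred))
    dplyr::mutate(met, fold = i, .before = 1L)
  })
  res <- dplyr::bind_rows(rows)
  structure(res,
            class = c("oed_cv", class(res)),
            mean_accuracy = mean(res$accuracy),
            sd_accuracy = stats::sd(res$accuracy),
            k = length(folds),
            models = if (keep_models) models)
}

#' @export
print.oed_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: accuracy %.2f%% +/- %.2f%%\n",
              attr(x, "k"), attr(x, "mean_accuracy"), attr(x, "sd_accuracy")))
  print(tibble::as_tibble(x)[, c("fold", "accuracy", "f1", "precision", "recall")])
  invisible(x)
}

#' Write per-fold metrics as CSV
#'
#' Columns mirror the cross-validation reporting layout: fold, accuracy,
#' F1 score, precision and recall, all in percent.
#'
#' @param cv an `oed_cv`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fold_metrics <- function(cv, path) {
  utils::write.csv(
    as.data.frame(cv)[, c("fold", "accuracy", "f1", "precision", "recall")],
    path, row.names = FALSE)
  invisible(path)
}
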