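# broom-style accessors and ggplot2 autoplot methods for the result types

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted network
#'
#' One row per layer stage with its output shape and cumulative parameter
#' count context; see [infer_shapes()].
#'
#' @param x an `oed_cnn`.
#' @param ... unused.
#' @return a tibble of layer stages.
#' @export
tidy.oed_cnn <- function(x, ...) {
  infer_shapes(x$config)
}

#' @rdname tidy.oed_cnn
#' @export
glance.oed_cnn <- function(x, ...) {
  tibble(
    n_blocks = length(x$config$blocks),
    global_pool = x$config$global_pool,
    hidden_width = x$config$hidden_width,
    dropout_rate = x$config$dropout_rate,
    color_space = x$config$color_space,
    input_side = x$config$input_side,
    n_params = x$n_params,
    trained = x$trained,
    final_train_loss = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$train_loss, 1L)
  )
}

#' Tidy cross-validation results
#'
#' @param x an `oed_cv`.
#' @param ... unused.
#' @return per-fold metrics tibble (percent).
#' @export
tidy.oed_cv <- function(x, ...) {
  tibble::as_tibble(x)[, c("fold", "accuracy", "f1", "precision", "recall", "n")]
}

#' @rdname tidy.oed_cv
#' @export
glance.oed_cv <- function(x, ...) {
  tibble(k = attr(x, "k"),
         mean_accuracy = attr(x, "mean_accuracy"),
         sd_accuracy = attr(x, "sd_accuracy"))
}

#' Plot an FROC curve
#'
#' Probability of detection against false positives per image, one line
#' per feature class across the threshold sweep.
#'
#' @param object an `oed_froc` tibble from [froc_evaluate()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.oed_froc <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fp_per_image,
                               y = .data$prob_detection,
                               colour = .data$feature_class)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "false positives per image",
                  y = "probability of detection", colour = "class") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss and accuracy traces over epochs for a trained network.
#'
#' @param object a trained `oed_cnn`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.oed_cnn <- function(object, ...) {
  if (is.null(object$history)) abort("model has no training history")
  long <- tidyr::pivot_longer(object$history,
                              cols = c("train_loss", "train_accuracy",
                                       "val_accuracy"),
                              names_to = "metric", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}
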