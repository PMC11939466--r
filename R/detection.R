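#' Sliding-window scores over a full image
#'
#' Slides the model's input window over the image on a regular grid
#' (default stride 10 pixels; windows fully inside the image) and records
#' the three class probabilities at every grid position.  Each window is
#' colour-converted per the model's configuration before scoring.
#'
#' @param model an `oed_cnn`, or a plain function taking a list of RGB
#'   window arrays and returning an `N x 3` score matrix (rows summing
#'   to 1) -- the functional form is how reference scorers (e.g. a
#'   ground-truth oracle) plug into the evaluation.  The list handed to a
#'   functional scorer carries attributes `origins` (an `N x 2` matrix of
#'   1-based top-left corners), `window` and `image` (the full slide), so
#'   a scorer may look windows up by position rather than pixel content.
#' @param image numeric array `H x W x 3` in `[0, 1]`, at least the window
#'   side in both dimensions.
#' @param stride grid step in pixels (default 10).
#' @param window window side; taken from the model configuration when the
#'   model is an `oed_cnn`.
#' @param batch_size scoring batch size.
#' @return an `oed_window_scores` object: list with `scores`
#'   (`n_rows x n_cols x 3` array), `origin_rows`, `origin_cols` (1-based
#'   top-left corners), `window`, `stride` and `image_dim`.
#' @export
scan_image <- function(model, image, stride = 10L, window = NULL,
                       batch_size = 64L) {
  assert_image(image)
  if (is.null(window)) {
    if (!inherits(model, "oed_cnn")) {
      abort("`window` must be given when `model` is not an oed_cnn")
    }
    window <- model$config$input_side
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < window || w < window) {
    abort(sprintf("image (%d x %d) is smaller than the %d-pixel window; partial windows lose information",
                  h, w, window))
  }
  stride <- as.integer(stride)
  if (stride < 1L) abort("`stride` must be >= 1")
  rows <- seq(1L, h - window + 1L, by = stride)
  cols <- seq(1L, w - window + 1L, by = stride)
  grid <- expand.grid(r = rows, c = cols, KEEP.OUT.ATTRS = FALSE)
  scores <- matrix(NA_real_, nrow(grid), 3L)
  scorer <- if (inherits(model, "oed_cnn")) {
    function(p) predict(model, p, type = "prob", batch_size = batch_size)
  } else if (is.function(model)) {
    model
  } else {
    abort("`model` must be an oed_cnn or a scoring function")
  }
  for (start in seq(1L, nrow(grid), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(grid))
    patches <- purrr::map2(grid$r[idx], grid$c[idx], function(r, c) {
      image[r:(r + window - 1L), c:(c + window - 1L), , drop = FALSE]
    })
    attr(patches, "origins") <- cbind(grid$r[idx], grid$c[idx])
    attr(patches, "window") <- window
    attr(patches, "image") <- image
    scores[idx, ] <- scorer(patches)
  }
  structure(list(
    scores = array(scores, dim = c(length(rows), length(cols), 3L)),
    origin_rows = rows, origin_cols = cols,
    window = window, stride = stride, image_dim = c(h, w)
  ), class = "oed_window_scores")
}

#' @export
print.oed_window_scores <- function(x, ...) {
  cat(sprintf("window scores: %d x %d grid (window %d, stride %d) over a %d x %d image\n",
              length(x$origin_rows), length(x$origin_cols),
              x$window, x$stride, x$image_dim[1], x$image_dim[2]))
  invisible(x)
}

#' @export
as_tibble.oed_window_scores <- function(x, ...) {
  grid <- expand.grid(origin_row = x$origin_rows, origin_col = x$origin_cols,
                      KEEP.OUT.ATTRS = FALSE)
  out <- tibble::as_tibble(grid)
  sc <- matrix(x$scores, ncol = 3L)
  out[[oed_classes()[1]]] <- sc[, 1]
  out[[oed_classes()[2]]] <- sc[, 2]
  out[[oed_classes()[3]]] <- sc[, 3]
  out
}

class_index <- function(feature_class) {
  i <- match(feature_class, oed_classes())
  if (is.na(i)) abort(sprintf("unknown class '%s'", feature_class))
  i
}

# grid positions whose class score reaches the threshold, as an n x 2
# matrix of (row, col) grid indices (robust to 1-cell grids)
firing_windows <- function(scores, ci, threshold) {
  sl <- scores$scores[, , ci]
  dim(sl) <- dim(scores$scores)[1:2]
  which(sl >= threshold, arr.ind = TRUE)
}

coverage_mask <- function(scores, feature_class, threshold,
                          paint = c("extent", "center")) {
  paint <- match.arg(paint)
  ci <- class_index(feature_class)
  h <- scores$image_dim[1]; w <- scores$image_dim[2]
  mask <- matrix(FALSE, h, w)
  fire <- firing_windows(scores, ci, threshold)
  if (nrow(fire)) {
    win <- scores$window
    for (k in seq_len(nrow(fire))) {
      r <- scores$origin_rows[fire[k, 1]]
      c <- scores$origin_cols[fire[k, 2]]
      if (paint == "extent") {
        mask[r:(r + win - 1L), c:(c + win - 1L)] <- TRUE
      } else {
        mask[r + win %/% 2L, c + win %/% 2L] <- TRUE
      }
    }
  }
  mask
}

#' Detection regions at a probability threshold
#'
#' Windows whose class score reaches `threshold` paint their full extent
#' (or, alternatively, their centre pixel) onto a coverage mask; the
#' 8-connected components of that mask are the countable detection
#' regions.  Coverage is monotone: raising the threshold can only shrink
#' the mask, so region sets nest across thresholds.
#'
#' @param scores an `oed_window_scores` from [scan_image()].
#' @param feature_class class to detect (one of [oed_classes()]).
#' @param threshold probability threshold in `[0, 1]` (values above 1
#'   yield no regions).
#' @param paint `"extent"` (default) or `"center"`.
#' @return a tibble with one row per region: `region`, `n_pixels`,
#'   `peak_score`, bounding box (`row_min`, `row_max`, `col_min`,
#'   `col_max`); the image-sized integer label matrix is in the
#'   `labels` attribute.
#' @export
regions_at_threshold <- function(scores, feature_class, threshold,
                                 paint = c("extent", "center")) {
  paint <- match.arg(paint)
  stopifnot(inherits(scores, "oed_window_scores"))
  if (threshold < 0) abort("`threshold` must be non-negative")
  ci <- class_index(feature_class)
  mask <- coverage_mask(scores, feature_class, threshold, paint)
  lab <- cpp_label8(mask)
  nreg <- max(lab)
  if (nreg == 0L) {
    out <- tibble(region = integer(), n_pixels = integer(),
                  peak_score = numeric(), row_min = integer(),
                  row_max = integer(), col_min = integer(),
                  col_max = integer())
    attr(out, "labels") <- lab
    return(out)
  }
  # peak score: the best firing-window score whose painted pixel(s) fall in
  # the region; the window's top-left painted pixel identifies its region
  fire <- firing_windows(scores, ci, threshold)
  win_reg <- integer(nrow(fire)); win_sc <- numeric(nrow(fire))
  off <- if (paint == "extent") 0L else scores$window %/% 2L
  for (k in seq_len(nrow(fire))) {
    r <- scores$origin_rows[fire[k, 1]] + off
    c <- scores$origin_cols[fire[k, 2]] + off
    win_reg[k] <- lab[r, c]
    win_sc[k] <- scores$scores[fire[k, 1], fire[k, 2], ci]
  }
  peak <- vapply(seq_len(nreg), function(i) max(win_sc[win_reg == i]), 0)
  idx <- which(lab > 0L)
  ri <- (idx - 1L) %% nrow(lab) + 1L
  cj <- (idx - 1L) %/% nrow(lab) + 1L
  li <- lab[idx]
  out <- tibble(
    region = seq_len(nreg),
    n_pixels = as.integer(tabulate(li, nreg)),
    peak_score = peak,
    row_min = as.integer(tapply(ri, li, min)),
    row_max = as.integer(tapply(ri, li, max)),
    col_min = as.integer(tapply(cj, li, min)),
    col_max = as.integer(tapply(cj, li, max))
  )
  attr(out, "labels") <- lab
  out
}

# detected GT regions and false-positive count for one image and class
match_regions <- function(pred_lab, gt_lab, match = "any", iou = 0.1) {
  n_pred <- max(pred_lab)
  n_gt <- max(gt_lab)
  if (n_pred == 0L) return(list(detected = integer(), fp = 0L))
  both <- pred_lab > 0L & gt_lab > 0L
  if (match == "any") {
    detected <- unique(gt_lab[both])
    fp_ids <- setdiff(seq_len(n_pred), unique(pred_lab[both]))
    return(list(detected = detected, fp = length(fp_ids)))
  }
  # IoU matching: cross-tabulate overlaps
  inter <- matrix(0, n_pred, n_gt)
  if (any(both)) {
    tt <- table(pred_lab[both], gt_lab[both])
    inter[cbind(as.integer(rownames(tt))[row(tt)],
                as.integer(colnames(tt))[col(tt)])] <- as.vector(tt)
  }
  pa <- tabulate(pred_lab[pred_lab > 0L], n_pred)
  ga <- tabulate(gt_lab[gt_lab > 0L], n_gt)
  iou_mat <- inter / (outer(pa, ga, "+") - inter)
  detected <- which(apply(iou_mat >= iou, 2L, any))
  fp_ids <- which(!apply(iou_mat >= iou, 1L, any))
  list(detected = detected, fp = length(fp_ids))
}

#' FROC-style detection evaluation
#'
#' Sweeps probability thresholds over sliding-window scores on a blind set
#' and, per class and threshold, reports the probability of detection
#' (ground-truth regions touched by at least one detection region, over
#' all ground-truth regions) against false positives per image (detection
#' regions touching no ground-truth region of that class).  One detection
#' region overlapping several ground-truth regions detects all of them; a
#' ground-truth region hit by several detections counts once.
#'
#' @param images list of slides, each a list with `image` (RGB array) and
#'   `masks` (named list of logical ground-truth masks per feature class).
#' @param model an `oed_cnn` or scoring function (see [scan_image()]).
#' @param thresholds increasing probability thresholds (default 101 evenly
#'   spaced values in `[0, 1]`).
#' @param stride sliding-window stride (default 10).
#' @param window window side (from the model when `NULL`).
#' @param classes feature classes to evaluate.
#' @param paint region painting rule, see [regions_at_threshold()].
#' @param match `"any"` (>= 1 pixel overlap, default) or `"iou"`.
#' @param iou IoU threshold when `match = "iou"`.
#' @return an `oed_froc` tibble: `feature_class`, `threshold`,
#'   `fp_per_image`, `prob_detection`, `n_gt_regions`.  Classes with no
#'   ground-truth region in the whole set are omitted with a warning.
#' @export
froc_evaluate <- function(images, model, thresholds = seq(0, 1, length.out = 101),
                          stride = 10L, window = NULL,
                          classes = c("irregular_stratification",
                                      "bulbous_rete_ridge"),
                          paint = c("extent", "center"),
                          match = c("any", "iou"), iou = 0.1) {
  paint <- match.arg(paint)
  match <- match.arg(match)
  thresholds <- sort(thresholds)
  scans <- purrr::map(images, function(im) {
    scan_image(model, im$image, stride = stride, window = window)
  })
  gt_labs <- purrr::map(images, function(im) {
    purrr::map(im$masks[intersect(classes, names(im$masks))], cpp_label8)
  })
  out <- list()
  for (cl in classes) {
    n_gt <- sum(purrr::map_int(gt_labs, function(g) {
      if (is.null(g[[cl]])) 0L else max(g[[cl]])
    }))
    if (n_gt == 0L) {
      warn(sprintf("no ground-truth regions for class '%s'; curve omitted", cl))
      next
    }
    rows <- purrr::map(thresholds, function(th) {
      det <- 0L; fp <- 0L
      for (i in seq_along(images)) {
        regs <- regions_at_threshold(scans[[i]], cl, th, paint = paint)
        gl <- gt_labs[[i]][[cl]]
        if (is.null(gl)) gl <- matrix(0L, nrow(attr(regs, "labels")),
                                      ncol(attr(regs, "labels")))
        mm <- match_regions(attr(regs, "labels"), gl, match = match, iou = iou)
        det <- det + length(mm$detected)
        fp <- fp + mm$fp
      }
      tibble(feature_class = cl, threshold = th,
             fp_per_image = fp / length(images),
             prob_detection = det / n_gt, n_gt_regions = n_gt)
    })
    out[[cl]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("oed_froc", class(res))
  res
}

#' Write an FROC curve as CSV
#'
#' @param curve an `oed_froc` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_froc_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
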