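#' Class labels used throughout the package
#'
#' Ordered as the network's three output nodes: `others`,
#' `irregular_stratification`, `bulbous_rete_ridge`.
#' @export
oed_classes <- function() c("others", "irregular_stratification", "bulbous_rete_ridge")

.feature_classes <- c("irregular_stratification", "bulbous_rete_ridge")

new_signature_tbl <- function(image_id = character(), origin_row = integer(),
                              origin_col = integer(), label = character(),
                              augmentation = character(), patch = list()) {
  tibble(
    image_id = image_id,
    origin_row = as.integer(origin_row),
    origin_col = as.integer(origin_col),
    label = factor(label, levels = oed_classes()),
    augmentation = augmentation,
    patch = patch
  )
}

#' Extract labelled signatures from an annotated image
#'
#' Slides a `patch_size` window over a regular grid (top-left origins at
#' `1, 1 + stride, ...` in both directions, windows fully inside the image)
#' and labels each patch by mask coverage: the patch takes the feature class
#' whose mask covers at least `positive_fraction` of its area, ties broken
#' toward `bulbous_rete_ridge` (the rarer class); otherwise it is labelled
#' `others`.
#'
#' @param image numeric array `H x W x 3` in `[0, 1]`.
#' @param annotations list of region annotations, each a list with elements
#'   `feature_class` (one of the two dysplastic feature labels) and `mask`
#'   (logical matrix of the image's spatial dimensions with at least one
#'   foreground pixel).  May be empty.
#' @param image_id identifier recorded with every signature.
#' @param patch_size window side in pixels (default 350).
#' @param stride grid step in pixels (default 50).
#' @param positive_fraction coverage threshold in `(0, 1]` (default 0.5).
#' @param ambiguous_band optional numeric `c(lo, hi)`: grid cells whose
#'   largest feature coverage falls in `[lo, hi)` are omitted from the
#'   output instead of being labelled `others`.  Partial overlaps are
#'   neither clean background nor clean feature, so libraries built for
#'   training usually discard them; `NULL` (default) keeps every cell.
#' @return a tibble with one row per grid position (minus any ambiguous
#'   cells): `image_id`,
#'   `origin_row`, `origin_col` (1-based top-left corner), `label`,
#'   `augmentation` (`NA` for originals) and the `patch` array in a list
#'   column.
#' @export
extract_signatures <- function(image, annotations = list(), image_id = "image",
                               patch_size = 350L, stride = 50L,
                               positive_fraction = 0.5,
                               ambiguous_band = NULL) {
  assert_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (patch_size > h || patch_size > w) {
    abort(sprintf("image '%s' (%d x %d) is smaller than the %d-pixel patch",
                  image_id, h, w, patch_size))
  }
  if (stride < 1L) abort("`stride` must be >= 1")
  if (positive_fraction <= 0 || positive_fraction > 1) {
    abort("`positive_fraction` must lie in (0, 1]")
  }
  for (ann in annotations) {
    if (!ann$feature_class %in% .feature_classes) {
      abort(sprintf("unknown feature class '%s'", ann$feature_class))
    }
    if (!identical(dim(ann$mask), c(h, w))) {
      abort("annotation mask dimensions must equal the image dimensions")
    }
    if (!any(ann$mask)) abort("annotation mask has no foreground pixel")
  }

  rows <- seq(1L, h - patch_size + 1L, by = stride)
  cols <- seq(1L, w - patch_size + 1L, by = stride)
  grid <- expand.grid(origin_row = rows, origin_col = cols,
                      KEEP.OUT.ATTRS = FALSE)
  area <- patch_size^2

  # cumulative-sum integral images make per-window coverage O(1)
  coverage <- function(mask) {
    s <- apply(apply(mask, 2L, cumsum), 1L, cumsum)   # s[j, i] = sum mask[1:i, 1:j]
    s <- rbind(0, cbind(0, s))                        # pad for zero-index
    r0 <- grid$origin_row - 1L; r1 <- grid$origin_row + patch_size - 1L
    c0 <- grid$origin_col - 1L; c1 <- grid$origin_col + patch_size - 1L
    (s[cbind(c1 + 1L, r1 + 1L)] - s[cbind(c0 + 1L, r1 + 1L)] -
       s[cbind(c1 + 1L, r0 + 1L)] + s[cbind(c0 + 1L, r0 + 1L)]) / area
  }

  cov <- matrix(0, nrow(grid), length(.feature_classes),
                dimnames = list(NULL, .feature_classes))
  for (ann in annotations) {
    cov[, ann$feature_class] <- pmax(cov[, ann$feature_class],
                                     coverage(ann$mask))
  }
  label <- rep("others", nrow(grid))
  hit <- cov >= positive_fraction
  # ties toward bulbous_rete_ridge: test the rarer class last so it wins
  label[hit[, "irregular_stratification"]] <- "irregular_stratification"
  label[hit[, "bulbous_rete_ridge"] &
          cov[, "bulbous_rete_ridge"] >= cov[, "irregular_stratification"]] <-
    "bulbous_rete_ridge"

  if (!is.null(ambiguous_band)) {
    stopifnot(length(ambiguous_band) == 2L,
              ambiguous_band[1] <= ambiguous_band[2])
    top <- pmax(cov[, 1], cov[, 2])
    keep <- top < ambiguous_band[1] | top >= ambiguous_band[2]
    grid <- grid[keep, , drop = FALSE]
    label <- label[keep]
  }

  patches <- purrr::map2(grid$origin_row, grid$origin_col, function(r, c) {
    image[r:(r + patch_size - 1L), c:(c + patch_size - 1L), , drop = FALSE]
  })
  new_signature_tbl(image_id = rep(image_id, nrow(grid)),
                    origin_row = grid$origin_row, origin_col = grid$origin_col,
                    label = label,
                    augmentation = rep(NA_character_, nrow(grid)),
                    patch = patches)
}

#' Assemble a signature library
#'
#' @param train tibble of training signatures (as from
#'   [extract_signatures()]).
#' @param test tibble of held-out signatures, disjoint from `train` by
#'   source image.
#' @return a `signature_library`: a list with `train`, `test` and
#'   `class_counts` (per-label tallies of the training portion).
#' @export
signature_library <- function(train, test = NULL) {
  if (is.null(test)) test <- train[0, ]
  overlap <- intersect(unique(train$image_id), unique(test$image_id))
  if (length(overlap)) {
    abort(sprintf("train and test share source images: %s",
                  paste(overlap, collapse = ", ")))
  }
  structure(
    list(train = train, test = test,
         class_counts = table(train$label)),
    class = "signature_library"
  )
}

#' @export
print.signature_library <- function(x, ...) {
  cat("Signature library\n")
  cnt <- rbind(train = table(x$train$label), test = table(x$test$label))
  print(cbind(cnt, total = rowSums(cnt)))
  invisible(x)
}

#' Augment a minority class of the training signatures
#'
#' Every *training* signature carrying `target_label` gains one transformed
#' copy per augmentation kind; other labels and the test set are untouched,
#' so the target-class count is multiplied by `1 + length(kinds)`.  With the
#' three kinds this quadruples the minority class.
#'
#' @param library a `signature_library`.
#' @param target_label label to augment (default `"bulbous_rete_ridge"`).
#' @param kinds augmentation kinds, a non-empty subset of
#'   `c("horizontal_flip", "vertical_flip", "rotate_180")`.
#' @return the library with augmented training signatures appended and
#'   `class_counts` updated.
#' @export
augment_minority <- function(library, target_label = "bulbous_rete_ridge",
                             kinds = c("horizontal_flip", "vertical_flip",
                                       "rotate_180")) {
  stopifnot(inherits(library, "signature_library"))
  if (!target_label %in% oed_classes()) {
    abort(sprintf("unknown label '%s'", target_label))
  }
  if (!length(kinds)) abort("`kinds` must be non-empty")
  kinds <- vapply(kinds, match.arg, "", choices = .augmentation_kinds)

  base <- dplyr::filter(library$train, .data$label == target_label)
  extra <- purrr::map(kinds, function(k) {
    out <- base
    out$augmentation <- k
    out$patch <- purrr::map(base$patch, apply_augmentation, kind = k)
    out
  })
  train <- dplyr::bind_rows(c(list(library$train), extra))
  signature_library(train, library$test)
}

#' Stratified k-fold split
#'
#' Partitions signatures into `k` folds, stratified by label: within each
#' label, rows are shuffled deterministically under `seed` and dealt
#' round-robin to folds, so fold label proportions differ from the overall
#' ones by at most one signature per label.
#'
#' @param signatures a signature tibble, or a `signature_library` (its
#'   training portion is split).
#' @param k number of folds (>= 2).
#' @param seed integer controlling the shuffle; the same seed reproduces the
#'   same folds.
#' @return a list of `k` elements, each a list with tibbles `train` and
#'   `test`; the `test` parts are disjoint and their union is the input.
#' @export
kfold_split <- function(signatures, k = 4L, seed = 1L) {
  if (inherits(signatures, "signature_library")) signatures <- signatures$train
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be at least 2")
  counts <- table(droplevels(signatures$label))
  if (any(counts < k)) {
    abort(sprintf("k = %d exceeds the smallest class count (%d)",
                  k, min(counts)))
  }
  fold <- integer(nrow(signatures))
  with_local_seed(seed, {
    for (lab in names(counts)) {
      idx <- which(signatures$label == lab)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(i) {
    list(train = signatures[fold != i, , drop = FALSE],
         test  = signatures[fold == i, , drop = FALSE])
  })
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Write a signature-library manifest as CSV
#'
#' Records provenance (source image, origin, label, augmentation) without
#' the pixel data; `split` marks each row as train or test.
#'
#' @param library a `signature_library`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_library_manifest <- function(library, path) {
  man <- dplyr::bind_rows(
    dplyr::mutate(dplyr::select(library$train, -"patch"), split = "train"),
    dplyr::mutate(dplyr::select(library$test, -"patch"), split = "test")
  )
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
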